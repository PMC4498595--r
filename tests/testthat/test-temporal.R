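test_that("marginal increases reproduce the published sweep arithmetic", {
  series <- c(4, 6, 8, 11, 16, 20, 27, 34, 56, 225)
  inc <- marginal_increase(series)
  expect_equal(tail(inc, 2), c(65L, 302L))
  expect_equal(marginal_increase(c(34, 56))[1], 65L)   # 64.71 rounds to 65
  expect_equal(marginal_increase(c(10, 10))[1], 0L)
  expect_equal(attr(marginal_increase(c(34, 56)), "raw"), 100 * 22 / 34)
  expect_warning(out <- marginal_increase(c(0, 5)), "zero denominator")
  expect_true(is.na(out[1]))
  expect_length(marginal_increase(7), 0)
})

test_that("target sweep on the fixture follows the exact oracle", {
  fx <- make_fixture()
  cfg <- test_config(n_solutions = 30)
  sw <- sweep_targets(fx$counts, fx$pu, cfg,
                      targets = c(0.1, 0.5, 0.8, 1.0))
  expect_equal(sw$n_pus[sw$target == 0.1], 1)
  expect_equal(sw$n_pus[sw$target == 0.8], 3)
  # p = 1: every PU holding counts
  expect_equal(sw$n_pus[sw$target == 1.0], 4)
  # counts monotone non-decreasing in p, matching the exact oracle sizes
  expect_true(all(diff(sw$n_pus) >= 0))
  ex_sizes <- vapply(c(0.1, 0.5, 0.8, 1.0), function(p)
    exact_minset(fixture_instance(p))$solution$size, numeric(1))
  expect_equal(sw$n_pus, unname(ex_sizes))
  expect_true(is.na(sw$pct_increase[1]))
})

test_that("years classify into dry/normal/wet by strict flow quantiles", {
  cov <- data.frame(year = 1:8, flow_total = 1:8)
  ph <- classify_years(cov)
  expect_equal(ph$phase, c("dry", "dry", rep("normal", 4), "wet", "wet"))
  cuts <- attr(ph, "cutpoints")
  expect_equal(unname(cuts), c(2.75, 6.25))
  # constant flows: no year is extreme (strict inequalities)
  flat <- data.frame(year = 1:6, flow_total = 5)
  expect_true(all(classify_years(flat)$phase == "normal"))
  # permuting year order does not change the labels
  perm <- cov[sample(8), ]
  ph2 <- classify_years(perm)
  expect_equal(ph2$phase[order(ph2$year)], ph$phase)
  expect_error(classify_years(data.frame(year = 1:2, flow_total = 1:2)),
               "at least 4 years")
  expect_error(classify_years(data.frame(year = 1:5,
                                         flow_total = c(1, 2, NA, 4, 5))),
               "missing flow")
})

test_that("annual prioritisation separates wet and dry fixture years", {
  fx <- make_fixture("phases")
  cfg <- test_config(n_solutions = 30, target_fraction = 0.8)
  ann <- annual_prioritisation(fx$counts, fx$pu, cfg)
  # dry year 2001 requires the refuge PU; wet year 2002 the floodplain
  expect_equal(ann$irsc["R", "2001"], 1)
  expect_equal(ann$irsc["F", "2001"], 0)
  expect_equal(ann$irsc["F", "2002"], 1)
  expect_equal(ann$irsc["R", "2002"], 0)
  expect_equal(ann$n_pus$n_pus, c(1, 1))
  # the per-year optima agree with the exact oracle
  for (yr in c(2001L, 2002L)) {
    slice <- fx$counts[fx$counts$year == yr, ]
    inst <- problem_instance(slice[, c("species_id", "pu_id", "count")],
                             fx$pu, target_fraction = 0.8)
    expect_equal(exact_minset(inst)$optima[[1]],
                 if (yr == 2001L) "R" else "F")
  }
})

test_that("identical counts in two years give identical scores", {
  fx <- make_fixture()
  twice <- rbind(fx$counts,
                 transform(fx$counts, year = 2001L))
  cfg <- test_config(n_solutions = 15, target_fraction = 0.8)
  ann <- annual_prioritisation(twice, fx$pu, cfg)
  expect_equal(ann$irsc[, "2000"], ann$irsc[, "2001"])
})

test_that("an all-zero year selects nothing", {
  fx <- make_fixture()
  zero <- data.frame(species_id = "s1", pu_id = "A", year = 2001L,
                     count = 0)
  counts <- rbind(fx$counts, zero)
  cfg <- test_config(n_solutions = 5, target_fraction = 0.8)
  expect_message(ann <- annual_prioritisation(counts, fx$pu, cfg),
                 "all counts zero")
  expect_equal(ann$n_pus$n_pus[ann$n_pus$year == 2001], 0)
  expect_true(all(ann$irsc[, "2001"] == 0))
})

test_that("functional classes reproduce the published wet/dry patterns", {
  # printed exemplars: (wet 0.47, dry 1) refuge; (wet 1, dry 0.47)
  # breeding; (wet 1, dry 0.94) both
  m <- matrix(c(1.00, 0.47,
                0.47, 1.00,
                0.94, 1.00,
                0.10, 0.20),
              nrow = 4, byrow = TRUE,
              dimnames = list(c("coolmunda", "cuttaburra", "lowbidgee",
                                "minor"), c("d1", "w1")))
  phases <- data.frame(year = c("d1", "w1"), phase = c("dry", "wet"))
  fc <- functional_classification(m, phases)
  expect_equal(fc$role, c("refuge", "breeding", "both", "neither"))
  expect_equal(fc$dry_mean, m[, "d1"], ignore_attr = TRUE)
  # roles partition the PUs: one role per PU, nothing dropped
  expect_equal(sum(table(fc$role)), nrow(m))
  expect_equal(anyDuplicated(fc$pu_id), 0)
  # threshold boundary: a mean of exactly 0.6 counts as high
  m2 <- matrix(c(0.6, 0.59), 1, dimnames = list("edge", c("d1", "w1")))
  expect_equal(functional_classification(m2, phases)$role, "refuge")
  # missing phases are named in the error
  expect_error(functional_classification(
    m, data.frame(year = c("d1", "w1"), phase = c("dry", "normal"))),
    "no wet years")
})

test_that("roles partition PUs over random score matrices", {
  set.seed(30)
  phases <- data.frame(year = as.character(1:6),
                       phase = rep(c("dry", "wet", "normal"), 2))
  for (i in 1:20) {
    m <- matrix(runif(60), 10, 6,
                dimnames = list(sprintf("p%d", 1:10), as.character(1:6)))
    fc <- functional_classification(m, phases)
    expect_true(all(fc$role %in% c("refuge", "breeding", "both", "neither")))
    expect_equal(nrow(fc), 10)
  }
})

test_that("type irreplaceability is area-corrected and normalised", {
  pu <- pu_table(c("a", "b"), wetland_type = c("lacustrine", "palustrine"),
                 area = c(1, 4))
  prop <- type_irreplaceability(c(a = 1, b = 1), pu)
  expect_equal(unname(prop[c("lacustrine", "palustrine")]), c(0.8, 0.2))
  expect_equal(sum(prop), 1, tolerance = 1e-12)
  # single type
  pu1 <- pu_table("a", wetland_type = "riverine", area = 3)
  expect_equal(unname(type_irreplaceability(c(a = 0.4), pu1)), 1)
  # zero-area type with score is an error; all-zero scores are flagged
  pu0 <- pu_table(c("a", "b"), wetland_type = c("riverine", "lacustrine"),
                  area = c(0, 2))
  expect_error(type_irreplaceability(c(a = 0.5, b = 0.1), pu0),
               "zero total area")
  expect_warning(out <- type_irreplaceability(c(a = 0, b = 0), pu),
                 "undefined")
  expect_true(all(is.na(out)))
  # proportions sum to 1 on random scores
  set.seed(4)
  pu4 <- pu_table(sprintf("p%d", 1:12),
                  wetland_type = sample(c("estuarine", "lacustrine",
                                          "palustrine", "riverine"), 12,
                                        replace = TRUE),
                  area = runif(12, 0.5, 9))
  for (i in 1:10) {
    sc <- setNames(runif(12), pu4$pu_id)
    expect_equal(sum(type_irreplaceability(sc, pu4)), 1, tolerance = 1e-12)
  }
})

test_that("chi-squared statistic matches the closed form and stats oracle", {
  res <- pearson_chisq(matrix(c(10, 20, 20, 10), 2))
  expect_equal(res$statistic, 4 * 25 / 15, tolerance = 1e-12)
  expect_equal(res$df, 1)
  # O = E -> statistic 0
  expect_equal(pearson_chisq(matrix(5, 3, 2))$statistic, 0)
  # 4x2 table has df 3
  expect_equal(pearson_chisq(matrix(1:8, 4, 2))$df, 3)
  # agreement with the uncorrected stats::chisq.test on random tables
  set.seed(17)
  for (i in 1:20) {
    tab <- matrix(runif(8, 1, 50), 4, 2)
    ours <- pearson_chisq(tab)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
  expect_error(pearson_chisq(matrix(c(0, 0, 1, 2), 2)), "zero margin")
  expect_error(pearson_chisq(matrix(1:3, 3, 1)), "at least 2")
  expect_error(pearson_chisq(matrix(c(-1, 2, 3, 4), 2)), "nonnegative")
})

test_that("type-phase table feeds the chi-squared contrast", {
  fx <- make_fixture("phases")
  dry <- c(F = 0, R = 1, X = 0.5, Y = 0.2)
  wet <- c(F = 1, R = 0.1, X = 0.2, Y = 0.5)
  tab <- type_phase_table(dry, wet, fx$pu)
  expect_equal(colnames(tab), c("dry", "wet"))
  expect_equal(sum(tab[, "dry"]), sum(dry), tolerance = 1e-12)
  expect_equal(sum(tab[, "wet"]), sum(wet), tolerance = 1e-12)
  res <- pearson_chisq(tab)
  expect_equal(res$df, (nrow(tab) - 1) * 1)
})
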