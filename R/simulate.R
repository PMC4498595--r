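# Synthetic boom-bust waterbird system. Flow drives yearly species totals
# (booms in wet years), and per-PU habitat weights split each total across
# planning units: refuge weight r_i is always active, flood weight f_i only
# when standardized log flow is positive. Designated refuge / breeding /
# both / neither roles are recorded as ground truth for recovery tests.

RAIN_REGIONS <- c("mdb", "leb", "se", "e", "n", "s")

#' Parameters of a synthetic boom-bust scenario
#'
#' @param n_species,n_pus,n_years system dimensions.
#' @param type_mix proportions of PUs over wetland types (must sum to 1).
#' @param mu_logflow mean of log annual flow.
#' @param phi AR(1) coefficient of log flow, in \[0, 1).
#' @param sigma innovation standard deviation of log flow (must be >= 0).
#' @param beta_soi coupling of log flow to the climate index.
#' @param phi_soi AR(1) coefficient of the standardized climate index.
#' @param rain_flow_cor named correlation coefficients tying each region's
#'   log rainfall to standardized log flow; regions nearer the basin couple
#'   more strongly.
#' @param gamma_range range of per-species boom elasticity gamma_s: the
#'   log-abundance response of a species' yearly total to a one-sd change in
#'   standardized log flow; species get evenly spaced values.
#' @param n_total_range range of species baseline totals N_s (log-spaced:
#'   few abundant species, many rare ones).
#' @param n_refuge,n_breeding,n_both numbers of PUs designated as dry-year
#'   refugia, wet-year breeding habitat, or both; the rest are background.
#' @param w_high,w_low,w_background habitat weights: a designated role gets
#'   `w_high` on its active weight and `w_low` on the other, background PUs
#'   get `w_background` on both. With the defaults the within-PU ratio of
#'   active to inactive weight is 50:1.
#' @param flood_gain multiplier on the flood weight of breeding/both PUs, so
#'   floodplain capacity dominates in wet years and refugia are not needed
#'   to meet targets when the system is booming.
#' @param k negative-binomial dispersion of counts (k > 0; smaller = more
#'   overdispersed).
#' @param start_year first calendar year label.
#' @param seed default seed for the generators.
#' @return validated parameter list (class `scenario_params`).
#' @export
scenario_params <- function(n_species = 12, n_pus = 60, n_years = 30,
                            type_mix = c(estuarine = 0.05, lacustrine = 0.25,
                                         palustrine = 0.40, riverine = 0.20,
                                         reservoir = 0.10),
                            mu_logflow = 9, phi = 0.3, sigma = 0.8,
                            beta_soi = 0.4, phi_soi = 0.5,
                            rain_flow_cor = c(mdb = 0.7, leb = 0.5,
                                              se = 0.35, e = 0.35, n = 0.2,
                                              s = 0.3),
                            gamma_range = c(0.3, 2.0),
                            n_total_range = c(200, 20000),
                            n_refuge = 8, n_breeding = 8, n_both = 4,
                            w_high = 1, w_low = 0.02, w_background = 0.05,
                            flood_gain = 20, k = 5,
                            start_year = 1983, seed = 42) {
  type_mix <- type_mix[!names(type_mix) %in% "unmapped"]
  type_mix <- type_mix / sum(type_mix)
  stopifnot(n_species >= 1, n_pus >= 1, n_years >= 2,
            abs(sum(type_mix) - 1) < 1e-12,
            phi >= 0, phi < 1, phi_soi >= 0, phi_soi < 1,
            all(abs(rain_flow_cor) <= 1),
            setequal(names(rain_flow_cor), RAIN_REGIONS), k > 0,
            n_refuge + n_breeding + n_both <= n_pus)
  if (sigma < 0) stop("sigma must be >= 0")
  structure(as.list(environment()), class = "scenario_params")
}

#' Named scenario presets
#'
#' `demo` is the default 12-species, 60-PU, 30-year system; `recovery` is a
#' 50-PU system with strong refuge/flood contrast used for ground-truth
#' recovery checks; `large` approaches the scale of a basin-wide survey
#' record (50 species, 300 PUs).
#'
#' @param name one of `"demo"`, `"recovery"`, `"large"`.
#' @param seed master seed.
#' @return a [scenario_params] list.
#' @export
scenario_preset <- function(name = c("demo", "recovery", "large"),
                            seed = 42) {
  name <- match.arg(name)
  switch(name,
    demo = scenario_params(seed = seed),
    recovery = scenario_params(n_species = 12, n_pus = 50, n_years = 30,
                               n_refuge = 8, n_breeding = 8, n_both = 4,
                               seed = seed),
    large = scenario_params(n_species = 50, n_pus = 300, n_years = 30,
                            n_refuge = 20, n_breeding = 20, n_both = 10,
                            seed = seed))
}

#' Simulate a boom-bust covariate series
#'
#' Log flow follows an AR(1) process around `mu_logflow` with a climate-index
#' coupling: `log flow_t = mu + phi (log flow_{t-1} - mu) + beta_soi soi_t +
#' eps_t`, `eps ~ N(0, sigma^2)`; `soi_t` is a standardized AR(1) index.
#' Regional log rainfall is correlated with the flow innovation with
#' coefficient `rain_flow_cor`. A fixed seed reproduces the series exactly.
#'
#' @param params a [scenario_params].
#' @param seed integer seed.
#' @return a [validate_covariates] data frame: `year`, `flow_total`,
#'   `rain_<region>` columns, `soi`.
#' @export
simulate_covariates <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "scenario_params"))
  if (params$sigma < 0) stop("sigma must be >= 0")
  set.seed(seed)
  n <- params$n_years
  soi <- numeric(n)
  e_soi <- rnorm(n)
  soi[1] <- e_soi[1]
  for (t in 2:n) soi[t] <- params$phi_soi * soi[t - 1] +
    sqrt(1 - params$phi_soi^2) * e_soi[t]
  lf <- numeric(n)
  eps <- rnorm(n, 0, params$sigma)
  lf[1] <- params$mu_logflow + params$beta_soi * soi[1] + eps[1]
  for (t in 2:n)
    lf[t] <- params$mu_logflow + params$phi * (lf[t - 1] - params$mu_logflow) +
      params$beta_soi * soi[t] + eps[t]
  zf <- if (sd(lf) > 0) (lf - mean(lf)) / sd(lf) else rep(0, n)
  rain <- sapply(RAIN_REGIONS, function(r) {
    rho <- params$rain_flow_cor[[r]]
    exp(log(600) + 0.3 * (rho * zf + sqrt(1 - rho^2) * rnorm(n)))
  })
  colnames(rain) <- paste0("rain_", RAIN_REGIONS)
  out <- data.frame(year = params$start_year + seq_len(n) - 1,
                    flow_total = exp(lf), rain, soi = soi)
  validate_covariates(out)
}

#' Simulate boom-bust abundance counts with known ground truth
#'
#' Yearly species totals are `lambda_st = N_s exp(gamma_s z_t)` with `z_t`
#' the standardized log flow; per-PU shares are proportional to
#' `r_i + f_i max(z_t, 0)` (flood weight active only in wet-signed years);
#' counts are negative-binomial around `lambda_st * w_it` with dispersion
#' `k`. The returned ground truth records each PU's designated role and each
#' year's phase, together with the weight cutoffs that define the roles.
#'
#' @param params a [scenario_params].
#' @param covariates a covariate series covering `n_years` (from
#'   [simulate_covariates]).
#' @param seed integer seed.
#' @return list: `counts` (long abundance table), `pu` (a [pu_table]),
#'   `truth` (data frame `pu_id`, `r`, `f`, `role`), `phases` (data frame
#'   `year`, `phase`), `weights` (PU-by-year share matrix).
#' @export
simulate_counts <- function(params, covariates, seed = params$seed) {
  stopifnot(inherits(params, "scenario_params"))
  covariates <- validate_covariates(covariates)
  if (nrow(covariates) < params$n_years)
    stop("covariates must cover n_years")
  cov <- covariates[seq_len(params$n_years), ]
  set.seed(seed)
  n_pus <- params$n_pus; n_sp <- params$n_species; n_yr <- params$n_years

  lf <- log(cov$flow_total)
  z <- if (sd(lf) > 0) (lf - mean(lf)) / sd(lf) else rep(0, n_yr)

  # species guilds: evenly spaced boom elasticity, log-spaced baselines,
  # shuffled against each other so abundance and elasticity are unlinked
  gamma_s <- seq(params$gamma_range[1], params$gamma_range[2],
                 length.out = n_sp)
  n_s <- exp(seq(log(params$n_total_range[1]), log(params$n_total_range[2]),
                 length.out = n_sp))
  n_s <- n_s[sample.int(n_sp)]

  # habitat weights by designated role
  pu_ids <- sprintf("pu%03d", seq_len(n_pus))
  role <- rep("neither", n_pus)
  idx <- sample.int(n_pus)  # random placement of roles among PUs
  take <- function(k) { out <- idx[seq_len(k)]; idx <<- idx[-seq_len(k)]; out }
  if (params$n_refuge > 0) role[take(params$n_refuge)] <- "refuge"
  if (params$n_breeding > 0) role[take(params$n_breeding)] <- "breeding"
  if (params$n_both > 0) role[take(params$n_both)] <- "both"
  r <- ifelse(role %in% c("refuge", "both"), params$w_high,
              ifelse(role == "breeding", params$w_low, params$w_background))
  f <- ifelse(role %in% c("breeding", "both"),
              params$w_high * params$flood_gain,
              ifelse(role == "refuge", params$w_low, params$w_background))

  # PU attributes: wetland types depend on role -- refugia are permanent
  # water bodies (lakes, river reaches, impoundments), breeding habitat is
  # flood-filled swamp/floodplain; background PUs follow the global mix.
  # Areas lognormal.
  type_mix_of <- function(ro) switch(ro,
    refuge = c(lacustrine = 0.40, riverine = 0.35, reservoir = 0.25),
    breeding = c(palustrine = 0.70, lacustrine = 0.30),
    both = c(lacustrine = 0.50, palustrine = 0.50),
    params$type_mix)
  types <- vapply(role, function(ro) {
    mix <- type_mix_of(ro)
    sample(names(mix), 1, prob = mix)
  }, character(1))
  areas <- round(exp(rnorm(n_pus, log(20), 0.8)), 2)
  pu <- pu_table(pu_id = pu_ids, cost = 1, wetland_type = types, area = areas)

  # shares and counts
  w <- matrix(r, n_pus, n_yr) + outer(f, pmax(z, 0))  # n_pus x n_yr
  colsum <- colSums(w)
  if (any(colsum <= 0)) stop("all PU weights zero in year ",
                             cov$year[which(colsum <= 0)[1]])
  w <- sweep(w, 2, colsum, "/")

  lambda <- matrix(n_s, n_sp, n_yr) * exp(outer(gamma_s, z))  # n_sp x n_yr
  recs <- vector("list", n_yr)
  for (t in seq_len(n_yr)) {
    mu <- lambda[, t] %o% w[, t]                 # n_sp x n_pus
    cnt <- rnbinom(length(mu), size = params$k, mu = as.numeric(mu))
    recs[[t]] <- data.frame(
      species_id = rep(sprintf("sp%02d", seq_len(n_sp)), times = n_pus),
      pu_id = rep(pu_ids, each = n_sp),
      year = cov$year[t],
      count = cnt)
  }
  counts <- do.call(rbind, recs)   # zero cells retained: the PU set is fixed

  qs <- quantile(cov$flow_total, c(0.25, 0.75), type = 7)
  phase <- ifelse(cov$flow_total < qs[1], "dry",
                  ifelse(cov$flow_total > qs[2], "wet", "normal"))
  r_cut <- sqrt(params$w_background * params$w_high)
  f_cut <- sqrt(params$w_background * params$w_high * params$flood_gain)
  truth <- data.frame(pu_id = pu_ids, r = r, f = f,
                      role = ifelse(r >= r_cut & f < f_cut, "refuge",
                             ifelse(f >= f_cut & r < r_cut, "breeding",
                             ifelse(r >= r_cut & f >= f_cut, "both",
                                    "neither"))),
                      stringsAsFactors = FALSE)
  stopifnot(identical(truth$role, role))  # cutoffs reproduce the design
  attr(truth, "cutoffs") <- c(r_cut = r_cut, f_cut = f_cut)
  list(counts = validate_abundance(counts, pu), pu = pu, truth = truth,
       phases = data.frame(year = cov$year, phase = phase), weights = w)
}

#' Deterministic worked fixtures
#'
#' `"pooled"` returns the 4-PU-by-3-species matrix used throughout the
#' solver examples: every species totals 100 individuals; PU `B` alone
#' carries at least 10% of every species, so it is the unique minimum set at
#' a 10% target; `{A, B, C}` is the unique optimum at 80% (each of A, B, C
#' is indispensable for one species) and `D` (20 individuals of `s3` only)
#' is never needed. `"phases"` returns a 2-year wet/dry variant in which the
#' refuge PU `R` holds the birds in the dry year and the floodplain PU `F`
#' in the wet year.
#'
#' @param type `"pooled"` or `"phases"`.
#' @return list with `counts` (long abundance table), `pu` (a [pu_table])
#'   and for `"phases"` also `flows` (a two-row covariate series).
#' @export
make_fixture <- function(type = c("pooled", "phases")) {
  type <- match.arg(type)
  if (type == "pooled") {
    a <- matrix(c(90, 10,  0,  0,
                   0, 10, 90,  0,
                   0, 80,  0, 20),
                nrow = 3, byrow = TRUE,
                dimnames = list(c("s1", "s2", "s3"), c("A", "B", "C", "D")))
    counts <- data.frame(species_id = rep(rownames(a), times = 4),
                         pu_id = rep(colnames(a), each = 3),
                         year = 2000L, count = as.numeric(a))
    pu <- pu_table(pu_id = c("A", "B", "C", "D"), cost = 1,
                   wetland_type = c("lacustrine", "palustrine", "riverine",
                                    "reservoir"),
                   area = c(2, 1, 1, 4))
    counts <- counts[counts$count > 0, ]
    return(list(counts = validate_abundance(counts, pu), pu = pu))
  }
  # phases: 4 PUs (R refuge, F floodplain, X, Y minor), 2 species, 2 years
  dry <- data.frame(species_id = c("s1", "s2", "s1", "s2"),
                    pu_id = c("R", "R", "X", "Y"),
                    year = 2001L, count = c(90, 90, 10, 10))
  wet <- data.frame(species_id = c("s1", "s2", "s1", "s2"),
                    pu_id = c("F", "F", "X", "Y"),
                    year = 2002L, count = c(90, 90, 10, 10))
  pu <- pu_table(pu_id = c("F", "R", "X", "Y"), cost = 1,
                 wetland_type = c("palustrine", "lacustrine", "riverine",
                                  "riverine"),
                 area = c(3, 1, 1, 1))
  flows <- data.frame(year = c(2001L, 2002L), flow_total = c(100, 10000))
  list(counts = validate_abundance(rbind(dry, wet), pu), pu = pu,
       flows = validate_covariates(flows))
}
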