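# Analyses layered over the solver: representation-target sweeps, per-year
# prioritisation, wet/dry phase classification, refugia/breeding functional
# classes, area-corrected wetland-type irreplaceability and its chi-squared
# contrast.

#' Representation-target sweep
#'
#' Runs selection-frequency irreplaceability over the pooled (all-years)
#' counts for each target fraction and counts the PUs with
#' IrSc >= `config$irsc_threshold`, together with the percent marginal
#' increase between consecutive targets — the curve whose knee identifies a
#' cost-effective representation target.
#'
#' @param counts long count table (pooled over years, or carrying a `year`
#'   column which is summed out).
#' @param pu a [pu_table].
#' @param config a [run_config].
#' @param targets increasing target fractions (default 0.1 ... 1.0).
#' @return data frame `target`, `n_pus`, `pct_increase` (class `sweep_result`,
#'   with the per-target irreplaceability tables in attribute `irsc`).
#' @export
sweep_targets <- function(counts, pu, config = run_config(),
                          targets = seq(0.1, 1, by = 0.1)) {
  if (is.unsorted(targets, strictly = TRUE))
    stop("targets must be strictly increasing")
  pooled <- aggregate(count ~ species_id + pu_id, data = counts, FUN = sum)
  irsc_tabs <- vector("list", length(targets))
  n_pus <- integer(length(targets))
  for (j in seq_along(targets)) {
    inst <- problem_instance(pooled, pu, target_fraction = targets[j],
                             spf = config$spf)
    sf <- selection_frequency(inst, config)
    irsc_tabs[[j]] <- sf
    n_pus[j] <- sum(sf$irsc >= config$irsc_threshold)
  }
  out <- data.frame(target = targets, n_pus = n_pus,
                    pct_increase = c(NA, marginal_increase(n_pus)))
  attr(out, "irsc") <- irsc_tabs
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Percent marginal increase along a count series
#'
#' `100 * (n[k+1] - n[k]) / n[k]`, rounded to the nearest integer percent
#' (the convention used when reporting the cost of raising a representation
#' target). A zero denominator makes the increment undefined: it is returned
#' as `NA` with a warning.
#'
#' @param counts positive series (e.g. PUs required per target).
#' @return integer vector of length `length(counts) - 1`; unrounded values in
#'   attribute `raw`.
#' @export
marginal_increase <- function(counts) {
  if (length(counts) < 2) return(integer(0))
  num <- diff(counts)
  den <- counts[-length(counts)]
  raw <- 100 * num / den
  if (any(den == 0)) {
    warning("zero denominator: marginal increase undefined at step(s) ",
            paste(which(den == 0), collapse = ", "))
    raw[den == 0] <- NA_real_
  }
  out <- as.integer(round(raw))
  attr(out, "raw") <- raw
  out
}

#' Per-year prioritisation
#'
#' Runs an independent selection-frequency analysis for every survey year at
#' the configured representation target, reporting per-year irreplaceability
#' and the number of PUs with IrSc >= threshold. Years are independent
#' scenarios and share the same seed sequence, so two years with identical
#' counts get identical scores. A year with all-zero counts has zero
#' targets, selects nothing, and is reported with 0 PUs.
#'
#' @param counts long abundance table with a `year` column.
#' @param pu a [pu_table].
#' @param config a [run_config].
#' @return list: `irsc` (PU-by-year matrix of IrSc), `n_pus` (data frame
#'   `year`, `n_pus`), `per_year` (list of per-year irreplaceability tables).
#' @export
annual_prioritisation <- function(counts, pu, config = run_config()) {
  counts <- validate_abundance(counts, pu)
  years <- sort(unique(counts$year))
  ids <- sort(pu$pu_id)
  irsc <- matrix(0, length(ids), length(years),
                 dimnames = list(ids, as.character(years)))
  per_year <- setNames(vector("list", length(years)), as.character(years))
  n_pus <- integer(length(years))
  for (j in seq_along(years)) {
    slice <- counts[counts$year == years[j], ]
    if (sum(slice$count) == 0) {
      message("year ", years[j], ": all counts zero; nothing to represent")
      per_year[[j]] <- data.frame(pu_id = ids, irsc = 0,
                                  class = classify_irsc(rep(0, length(ids))))
      next
    }
    inst <- problem_instance(slice[, c("species_id", "pu_id", "count")], pu,
                             target_fraction = config$target_fraction,
                             spf = config$spf)
    sf <- selection_frequency(inst, config)
    per_year[[j]] <- sf
    irsc[sf$pu_id, j] <- sf$irsc
    n_pus[j] <- sum(sf$irsc >= config$irsc_threshold)
  }
  list(irsc = irsc, n_pus = data.frame(year = years, n_pus = n_pus),
       per_year = per_year)
}

#' Classify years into dry / normal / wet phases by flow quantiles
#'
#' Dry years fall strictly below the lower flow quantile and wet years
#' strictly above the upper one (type-7 quantiles); everything else is
#' normal. With constant flows no year is extreme.
#'
#' @param covariates a covariate series (needs `year`, `flow_total`).
#' @param q_low,q_high quantile cutpoints (defaults 0.25 and 0.75).
#' @return data frame `year`, `phase` with attribute `cutpoints`.
#' @export
classify_years <- function(covariates, q_low = 0.25, q_high = 0.75) {
  covariates <- validate_covariates(covariates)
  if (nrow(covariates) < 4) stop("need at least 4 years to classify phases")
  if (anyNA(covariates$flow_total))
    stop("missing flow for year(s) ",
         paste(covariates$year[is.na(covariates$flow_total)], collapse = ", "))
  stopifnot(q_low < q_high)
  qs <- quantile(covariates$flow_total, c(q_low, q_high), type = 7,
                 names = FALSE)
  phase <- ifelse(covariates$flow_total < qs[1], "dry",
                  ifelse(covariates$flow_total > qs[2], "wet", "normal"))
  out <- data.frame(year = covariates$year, phase = phase,
                    stringsAsFactors = FALSE)
  attr(out, "cutpoints") <- setNames(qs, c("q_low", "q_high"))
  out
}

#' Refugia / breeding functional classification of planning units
#'
#' Averages each PU's per-year irreplaceability over the dry years and over
#' the wet years, and assigns an ecological role: `refuge` when the dry-year
#' mean reaches the threshold but the wet-year mean does not (habitat in
#' busts only), `breeding` for the converse (flooded habitat in booms only),
#' `both` when both means reach it, otherwise `neither`. Roles partition the
#' PUs.
#'
#' @param annual_irsc PU-by-year IrSc matrix (from [annual_prioritisation]),
#'   with year columns named.
#' @param phases phase assignment (from [classify_years]).
#' @param threshold IrSc threshold for a "high" score (0.6).
#' @return data frame `pu_id`, `dry_mean`, `wet_mean`, `role`.
#' @export
functional_classification <- function(annual_irsc, phases, threshold = 0.6) {
  stopifnot(is.matrix(annual_irsc))
  dry <- as.character(phases$year[phases$phase == "dry"])
  wet <- as.character(phases$year[phases$phase == "wet"])
  if (length(dry) == 0) stop("no dry years in the phase assignment")
  if (length(wet) == 0) stop("no wet years in the phase assignment")
  miss <- setdiff(c(dry, wet), colnames(annual_irsc))
  if (length(miss))
    stop("annual_irsc lacks year column(s): ", paste(miss, collapse = ", "))
  dry_mean <- rowMeans(annual_irsc[, dry, drop = FALSE])
  wet_mean <- rowMeans(annual_irsc[, wet, drop = FALSE])
  role <- ifelse(dry_mean >= threshold & wet_mean >= threshold, "both",
          ifelse(dry_mean >= threshold, "refuge",
          ifelse(wet_mean >= threshold, "breeding", "neither")))
  data.frame(pu_id = rownames(annual_irsc), dry_mean = unname(dry_mean),
             wet_mean = unname(wet_mean), role = unname(role),
             stringsAsFactors = FALSE)
}

#' Area-corrected wetland-type irreplaceability
#'
#' For each wetland type, the summed IrSc of its PUs divided by the type's
#' total area, normalised so the proportions sum to 1: the share of
#' (area-corrected) irreplaceability carried by each wetland type under a
#' given phase.
#'
#' @param irsc named numeric vector of per-PU IrSc, or a data frame with
#'   `pu_id` and `irsc`.
#' @param pu a [pu_table] typing every scored PU, with positive type areas.
#' @return named numeric vector of proportions over the types present.
#' @export
type_irreplaceability <- function(irsc, pu) {
  if (is.data.frame(irsc)) irsc <- setNames(irsc$irsc, irsc$pu_id)
  pu <- validate_pu_table(pu)
  miss <- setdiff(names(irsc), pu$pu_id)
  if (length(miss)) stop("untyped PU(s): ", paste(miss, collapse = ", "))
  type <- setNames(pu$wetland_type, pu$pu_id)[names(irsc)]
  area_type <- tapply(pu$area, pu$wetland_type, sum)[unique(type)]
  ssum <- tapply(irsc, type, sum)
  zero_area <- names(ssum)[area_type[names(ssum)] == 0 & ssum > 0]
  if (length(zero_area))
    stop("wetland type with zero total area but nonzero IrSc: ",
         paste(zero_area, collapse = ", "))
  score <- ssum / area_type[names(ssum)]
  if (sum(score) == 0) {
    warning("all IrSc zero: type proportions undefined")
    return(setNames(rep(NA_real_, length(score)), names(score)))
  }
  setNames(as.numeric(score / sum(score)), names(score))
}

#' Wetland-type by phase score table
#'
#' Builds the two-column (dry, wet) table contrasted by the chi-squared
#' test: per phase, the area-corrected type proportions rescaled to that
#' phase's total summed IrSc. Input scores are not counts; the test is
#' applied to this score table as a procedural contrast.
#'
#' @param dry_irsc,wet_irsc named per-PU IrSc vectors (phase means).
#' @param pu a [pu_table].
#' @return matrix with one row per wetland type and columns `dry`, `wet`.
#' @export
type_phase_table <- function(dry_irsc, wet_irsc, pu) {
  pd <- type_irreplaceability(dry_irsc, pu)
  pw <- type_irreplaceability(wet_irsc, pu)
  types <- sort(union(names(pd), names(pw)))
  tab <- cbind(dry = pd[types] * sum(dry_irsc),
               wet = pw[types] * sum(wet_irsc))
  rownames(tab) <- types
  tab[is.na(tab)] <- 0
  tab
}

#' Pearson's chi-squared test of a two-way table
#'
#' `X^2 = sum (O - E)^2 / E` with expected cells from the row and column
#' margins, `df = (r - 1)(c - 1)`, and the p-value from the upper tail of
#' the chi-squared distribution. Accepts non-integer entries (the type
#' contrast feeds in area-corrected scores).
#'
#' @param observed numeric matrix, >= 2 rows and columns, nonnegative.
#' @return list `statistic`, `df`, `p_value`, `expected`.
#' @export
pearson_chisq <- function(observed) {
  observed <- as.matrix(observed)
  if (nrow(observed) < 2 || ncol(observed) < 2)
    stop("need a table with at least 2 rows and 2 columns")
  if (any(observed < 0)) stop("table entries must be nonnegative")
  rs <- rowSums(observed); cs <- colSums(observed)
  if (any(rs == 0) || any(cs == 0)) stop("zero margin in the table")
  expected <- outer(rs, cs) / sum(observed)
  stat <- sum((observed - expected)^2 / expected)
  df <- (nrow(observed) - 1) * (ncol(observed) - 1)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE), expected = expected)
}
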