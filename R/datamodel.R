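#' @useDynLib wetlandprior, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats quantile rnorm rnbinom pchisq sd var cor lm.fit glm.fit
#'   poisson dpois setNames aggregate
#' @importFrom utils read.table write.table head tail
NULL

WETLAND_TYPES <- c("estuarine", "lacustrine", "palustrine", "riverine",
                   "reservoir", "unmapped")

#' Build and validate a planning-unit table
#'
#' The planning unit (PU) is the atomic spatial unit of the prioritisation:
#' a grid cell, or an aggregate of cells covering one wetland complex. Costs
#' default to 1 (constant cost), so minimising cost minimises the number of
#' selected PUs.
#'
#' @param pu_id vector of unique PU identifiers.
#' @param cost nonnegative per-PU cost, recycled; default 1.
#' @param wetland_id optional identifier of the wetland complex a PU was
#'   merged into (`NA` for singleton cells).
#' @param wetland_type one of `r paste(WETLAND_TYPES, collapse = ", ")`.
#' @param area nonnegative PU area (km^2).
#' @return a `data.frame` with class `pu_table`.
#' @export
pu_table <- function(pu_id, cost = 1, wetland_id = NA_character_,
                     wetland_type = "unmapped", area = 0) {
  df <- data.frame(pu_id = as.character(pu_id),
                   cost = as.numeric(cost),
                   wetland_id = as.character(wetland_id),
                   wetland_type = as.character(wetland_type),
                   area = as.numeric(area),
                   stringsAsFactors = FALSE)
  validate_pu_table(df)
}

#' @rdname pu_table
#' @param df a data frame with at least `pu_id`; missing optional columns are
#'   filled with defaults.
#' @export
validate_pu_table <- function(df) {
  stopifnot(is.data.frame(df))
  if (!"pu_id" %in% names(df)) stop("pu_table requires a 'pu_id' column")
  df$pu_id <- as.character(df$pu_id)
  if (is.null(df$cost)) df$cost <- 1
  if (is.null(df$wetland_id)) df$wetland_id <- NA_character_
  if (is.null(df$wetland_type)) df$wetland_type <- "unmapped"
  if (is.null(df$area)) df$area <- 0
  if (anyDuplicated(df$pu_id))
    stop("duplicate pu_id: ", paste(unique(df$pu_id[duplicated(df$pu_id)]),
                                    collapse = ", "))
  if (any(!is.finite(df$cost)) || any(df$cost < 0))
    stop("pu costs must be finite and >= 0")
  if (any(df$area < 0, na.rm = TRUE)) stop("pu areas must be >= 0")
  bad <- setdiff(unique(df$wetland_type), WETLAND_TYPES)
  if (length(bad))
    stop("unknown wetland_type: ", paste(bad, collapse = ", "))
  class(df) <- c("pu_table", "data.frame")
  df
}

#' Validate a long-format abundance table
#'
#' The survey record: nonnegative integer counts indexed by
#' (species, planning unit, year). Keys must be unique and every `pu_id`
#' must appear in the planning-unit table when one is supplied.
#'
#' @param df data frame with columns `species_id`, `pu_id`, `year`, `count`.
#' @param pu optional `pu_table` used to check referential integrity.
#' @return the validated data frame (class `abundance_table`).
#' @export
validate_abundance <- function(df, pu = NULL) {
  need <- c("species_id", "pu_id", "year", "count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("abundance table missing column(s): ", paste(miss, collapse = ", "))
  df$species_id <- as.character(df$species_id)
  df$pu_id <- as.character(df$pu_id)
  bad <- which(!is.finite(df$count) | df$count < 0)
  if (length(bad))
    stop("negative or non-finite count at record ", bad[1])
  key <- paste(df$species_id, df$pu_id, df$year, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (species, pu, year) key at record ",
         which(duplicated(key))[1])
  if (!is.null(pu)) {
    orphan <- setdiff(unique(df$pu_id), pu$pu_id)
    if (length(orphan))
      stop("pu_id not in planning-unit table: ",
           paste(head(orphan, 5), collapse = ", "))
  }
  class(df) <- c("abundance_table", "data.frame")
  df
}

#' Validate a per-year covariate series
#'
#' One record per year: total annual flow (must be positive wherever present,
#' so its log transform is defined), rainfall depth by named region
#' (`rain_*` columns) and an annual climate index (`soi`).
#'
#' @param df data frame with columns `year`, `flow_total`, optionally
#'   `rain_*` columns and `soi`.
#' @return validated data frame (class `covariate_series`).
#' @export
validate_covariates <- function(df) {
  need <- c("year", "flow_total")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("covariate series missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$year)) stop("covariate series: duplicate year")
  present <- !is.na(df$flow_total)
  if (any(df$flow_total[present] <= 0))
    stop("flow_total must be > 0 (log transform must be defined)")
  class(df) <- c("covariate_series", "data.frame")
  df
}

# ---- Marxan file dialect ---------------------------------------------------

.read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
             strip.white = TRUE)
}

.require_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("file '%s' is missing required column(s): %s",
                 path, paste(miss, collapse = ", ")))
  invisible(df)
}

#' Read a Marxan-style dataset (pu / spec / puvspr triplet)
#'
#' Accepts comma- or tab-delimited files with a header row. The `status`
#' column of the pu file is read but ignored by the solver (no locked-in /
#' locked-out support). Unknown columns are preserved.
#'
#' @param pu_path,spec_path,puvspr_path file paths.
#' @return a list with elements `pu` (a [pu_table]), `targets` (the species
#'   table: id, target, spf, name) and `records` (species, pu, amount).
#' @export
read_marxan_dataset <- function(pu_path, spec_path, puvspr_path) {
  pu_raw <- .require_cols(.read_delim_auto(pu_path), c("id", "cost"), pu_path)
  sp_raw <- .require_cols(.read_delim_auto(spec_path), c("id"), spec_path)
  pv_raw <- .require_cols(.read_delim_auto(puvspr_path),
                          c("species", "pu", "amount"), puvspr_path)
  bad <- which(pv_raw$amount < 0)
  if (length(bad))
    stop(sprintf("file '%s': negative amount at record %d", puvspr_path,
                 bad[1]))
  pu <- validate_pu_table(data.frame(pu_id = pu_raw$id, cost = pu_raw$cost,
                                     stringsAsFactors = FALSE))
  extra <- setdiff(names(pu_raw), c("id", "cost"))
  if (length(extra)) attr(pu, "marxan_extra") <- pu_raw[, extra, drop = FALSE]
  list(pu = pu, targets = sp_raw, records = pv_raw)
}

#' Write a Marxan-style dataset
#'
#' Files are written comma-delimited with deterministic ordering (pu file
#' ascending by id; puvspr sorted by pu then species) so the output is
#' byte-stable for a given input. Marxan scenario files are per-year slices,
#' so the records must not carry a year dimension.
#'
#' @param pu a [pu_table].
#' @param targets species table: columns `id`, `target`, `spf`, `name`.
#' @param records data frame with `species`, `pu`, `amount`.
#' @param out_dir output directory, created if needed.
#' @return named character vector of the three file paths.
#' @export
write_marxan_dataset <- function(pu, targets, records, out_dir) {
  pu <- validate_pu_table(pu)
  if (!all(c("species", "pu", "amount") %in% names(records)))
    stop("records must have columns species, pu, amount")
  if (any(records$amount %% 1 != 0))
    warning("non-integer amounts in puvspr records (counts expected)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(pu = file.path(out_dir, "pu.dat"),
             spec = file.path(out_dir, "spec.dat"),
             puvspr = file.path(out_dir, "puvspr.dat"))
  pu_out <- data.frame(id = pu$pu_id, cost = pu$cost, status = 0L)
  pu_out <- pu_out[order(pu_out$id), ]
  write.table(pu_out, paths[["pu"]], sep = ",", row.names = FALSE,
              quote = FALSE)
  tg <- targets[order(targets$id), , drop = FALSE]
  write.table(tg, paths[["spec"]], sep = ",", row.names = FALSE, quote = FALSE)
  rec <- records[order(records$pu, records$species),
                 c("species", "pu", "amount")]
  write.table(rec, paths[["puvspr"]], sep = ",", row.names = FALSE,
              quote = FALSE)
  paths
}

# ---- cell -> wetland aggregation ------------------------------------------

#' Aggregate survey grid cells into wetland planning units
#'
#' All cells sharing a `wetland_id` merge into a single PU whose counts and
#' areas are sums; cells with no wetland mapping (e.g. farm dams intersecting
#' no mapped waterbody) become singleton PUs. The merged PU takes the type of
#' the mapped wetland. The cell-to-wetland mapping must be a function: a cell
#' listed twice is an error.
#'
#' @param cells data frame: `cell_id`, `wetland_id` (`NA` for unmapped),
#'   `area`, `type`.
#' @param counts long abundance table keyed by `pu_id` = cell id (columns
#'   `species_id`, `pu_id`, `year`, `count`).
#' @return list with `pu` (a [pu_table]) and `counts` (aggregated
#'   abundance table keyed by the new PU ids). Total count per species per
#'   year and total area are conserved exactly.
#' @export
aggregate_cells <- function(cells, counts) {
  need <- c("cell_id", "wetland_id", "area", "type")
  miss <- setdiff(need, names(cells))
  if (length(miss))
    stop("cell table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(cells$cell_id))
    stop("cell mapped more than once: ",
         cells$cell_id[duplicated(cells$cell_id)][1])
  counts <- validate_abundance(counts)
  orphan <- setdiff(unique(counts$pu_id), cells$cell_id)
  if (length(orphan))
    stop("counts reference unknown cell(s): ",
         paste(head(orphan, 5), collapse = ", "))

  cells$cell_id <- as.character(cells$cell_id)
  cells$wetland_id <- as.character(cells$wetland_id)
  new_id <- ifelse(is.na(cells$wetland_id), cells$cell_id, cells$wetland_id)
  area <- tapply(cells$area, new_id, sum)
  type <- vapply(split(cells$type, new_id), function(tt) {
    u <- unique(tt)
    if (length(u) > 1)
      stop("conflicting wetland types within one wetland: ",
           paste(u, collapse = ", "))
    u
  }, character(1))
  ids <- sort(names(area))
  pu <- pu_table(pu_id = ids, cost = 1, area = as.numeric(area[ids]),
                 wetland_type = as.character(type[ids]),
                 wetland_id = NA_character_)

  map <- setNames(new_id, cells$cell_id)
  counts$pu_id <- unname(map[counts$pu_id])
  agg <- aggregate(count ~ species_id + pu_id + year, data = counts, FUN = sum)
  list(pu = pu, counts = validate_abundance(agg, pu))
}

# ---- long-format CSV helpers ----------------------------------------------

#' Read / write long-format abundance and covariate CSV files
#'
#' @param path file path.
#' @param pu optional [pu_table] for referential checks on read.
#' @return the validated table.
#' @export
read_abundance_csv <- function(path, pu = NULL) {
  validate_abundance(read.table(path, header = TRUE, sep = ",",
                                stringsAsFactors = FALSE), pu)
}

#' @rdname read_abundance_csv
#' @param df table to write.
#' @export
write_abundance_csv <- function(df, path) {
  df <- validate_abundance(df)
  df <- df[order(df$year, df$pu_id, df$species_id), ]
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_abundance_csv
#' @export
read_covariates_csv <- function(path) {
  validate_covariates(read.table(path, header = TRUE, sep = ",",
                                 stringsAsFactors = FALSE))
}

#' @rdname read_abundance_csv
#' @export
write_covariates_csv <- function(df, path) {
  df <- validate_covariates(df)
  write.table(df[order(df$year), ], path, sep = ",", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

# ---- run configuration -----------------------------------------------------

#' Solver and pipeline run configuration
#'
#' @param target_fraction representation target: the fraction of each
#'   species' total abundance that a selected set must contain, in (0, 1].
#' @param n_solutions number of independent annealing runs whose selection
#'   frequency defines irreplaceability (1000 in a full analysis).
#' @param iterations annealing iterations per run.
#' @param spf species penalty factor weighting target shortfalls in the
#'   annealing objective. The repair pass makes feasibility independent of
#'   its value.
#' @param seed master random seed.
#' @param irsc_threshold irreplaceability score above which a PU counts as
#'   selected for reporting (0.6).
#' @param q_low,q_high flow quantiles delimiting dry and wet years.
#' @param temp_floor_ratio ratio of final to initial annealing temperature
#'   for the geometric cooling schedule.
#' @return validated configuration list (class `run_config`).
#' @export
run_config <- function(target_fraction = 0.8, n_solutions = 1000,
                       iterations = 100000, spf = 100, seed = 1,
                       irsc_threshold = 0.6, q_low = 0.25, q_high = 0.75,
                       temp_floor_ratio = 1e-5) {
  stopifnot(target_fraction > 0, target_fraction <= 1,
            n_solutions >= 1, iterations >= 1, spf >= 0,
            q_low < q_high, q_low >= 0, q_high <= 1,
            temp_floor_ratio > 0, temp_floor_ratio <= 1)
  structure(list(target_fraction = target_fraction,
                 n_solutions = as.integer(n_solutions),
                 iterations = as.integer(iterations), spf = spf,
                 seed = as.integer(seed), irsc_threshold = irsc_threshold,
                 q_low = q_low, q_high = q_high,
                 temp_floor_ratio = temp_floor_ratio),
            class = "run_config")
}
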