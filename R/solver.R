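# Minimum-set reserve selection under per-species proportional abundance
# targets. A solution is a PU set whose summed counts reach T_s = p * total_s
# for every species s, at minimum total cost.

# Continued-fraction rational approximation of the target fraction p, so that
# feasibility can be tested in exact integer arithmetic (held * den >=
# total * num) when counts are integers: a floating T_s = p * total_s misses
# boundaries at p = 0.1 and the like.
.as_rational <- function(p, tol = 1e-9, max_den = 1000000L) {
  stopifnot(p > 0, p <= 1)
  h0 <- 0; h1 <- 1; k0 <- 1; k1 <- 0; x <- p
  repeat {
    a <- floor(x)
    h2 <- a * h1 + h0; k2 <- a * k1 + k0
    if (k2 > max_den) break
    h0 <- h1; h1 <- h2; k0 <- k1; k1 <- k2
    if (abs(p - h1 / k1) < tol) break
    frac <- x - a
    if (frac < 1e-12) break
    x <- 1 / frac
  }
  list(num = h1, den = k1)
}

#' Build a single-scenario prioritisation problem
#'
#' Pools a count table into a species-by-PU matrix, derives per-species
#' abundance targets `T_s = p * sum_i a_si`, and precomputes the
#' single-species greedy base costs used to scale shortfall penalties.
#' PU columns are ordered by `pu_id`, which fixes all tie-breaks.
#'
#' @param counts long count table with `species_id`, `pu_id`, `count`
#'   (a year slice or pooled over years), or a species-by-PU numeric matrix
#'   with dimnames.
#' @param pu a [pu_table]; defaults to unit costs over the PUs present.
#' @param target_fraction representation target p in (0, 1].
#' @param spf species penalty factor (see [run_config]).
#' @return list of class `reserve_problem`: count matrix `a`, `cost`,
#'   rationalised target fraction, targets `T`, base costs.
#' @export
problem_instance <- function(counts, pu = NULL, target_fraction, spf = 100) {
  if (is.matrix(counts)) {
    a <- counts
    if (is.null(colnames(a)) || is.null(rownames(a)))
      stop("count matrix needs species rownames and pu colnames")
  } else {
    need <- c("species_id", "pu_id", "count")
    miss <- setdiff(need, names(counts))
    if (length(miss))
      stop("counts missing column(s): ", paste(miss, collapse = ", "))
    sp <- sort(unique(as.character(counts$species_id)))
    ids <- if (is.null(pu)) sort(unique(as.character(counts$pu_id)))
           else sort(pu$pu_id)
    a <- matrix(0, length(sp), length(ids), dimnames = list(sp, ids))
    agg <- aggregate(count ~ species_id + pu_id, data = counts, FUN = sum)
    a[cbind(as.character(agg$species_id), as.character(agg$pu_id))] <-
      agg$count
  }
  if (any(a < 0)) stop("counts must be nonnegative")
  a <- a[, order(colnames(a)), drop = FALSE]
  if (is.null(pu)) {
    cost <- setNames(rep(1, ncol(a)), colnames(a))
  } else {
    pu <- validate_pu_table(pu)
    cost <- setNames(pu$cost, pu$pu_id)[colnames(a)]
    if (anyNA(cost)) stop("pu table lacks costs for some count columns")
  }
  if (spf < 0) stop("spf must be >= 0")
  rat <- .as_rational(target_fraction)
  totals <- rowSums(a)
  inst <- structure(list(a = a, cost = cost, p = target_fraction,
                         num = rat$num, den = rat$den, totals = totals,
                         targets = totals * rat$num / rat$den, spf = spf),
                    class = "reserve_problem")
  inst$base <- vapply(rownames(a), function(s) .species_base_cost(inst, s),
                      numeric(1))
  inst
}

# Greedy cost of meeting species s's target alone from the empty set:
# repeatedly take the PU with the largest capped contribution per unit cost.
.species_base_cost <- function(inst, s) {
  tnum <- inst$totals[s] * inst$num
  if (tnum == 0) return(0)
  av <- inst$a[s, ]
  held <- 0; total_cost <- 0; in_set <- logical(length(av))
  while (held * inst$den < tnum) {
    unmet <- (tnum - held * inst$den) / inst$den
    score <- pmin(av, unmet) / inst$cost
    score[in_set] <- -Inf
    i <- which.max(score)
    if (score[i] <= 0) stop("species ", s, " target unreachable")
    in_set[i] <- TRUE
    held <- held + av[i]
    total_cost <- total_cost + inst$cost[i]
  }
  unname(total_cost)
}

.sel_logical <- function(inst, S) {
  ids <- colnames(inst$a)
  if (is.logical(S)) {
    stopifnot(length(S) == length(ids))
    return(S)
  }
  S <- as.character(S)
  bad <- setdiff(S, ids)
  if (length(bad)) stop("unknown pu_id in selection: ", bad[1])
  ids %in% S
}

.held_counts <- function(inst, sel) {
  if (!any(sel)) return(setNames(numeric(nrow(inst$a)), rownames(inst$a)))
  rowSums(inst$a[, sel, drop = FALSE])
}

.is_feasible <- function(inst, held) {
  all(held * inst$den >= inst$totals * inst$num)
}

# Exact-zero shortfalls at the boundary: work on the integer scale first.
.shortfalls <- function(inst, held) {
  pmax(0, inst$totals * inst$num - held * inst$den) / inst$den
}

#' Annealing objective: selected cost plus scaled shortfall penalties
#'
#' `sum_i c_i + sum_s spf * (shortfall_s / T_s) * base_s`, where `base_s` is
#' the greedy cost of meeting species s's target alone from the empty set.
#' Species with a zero target contribute nothing. A feasible set scores
#' exactly its summed cost.
#'
#' @param inst a [problem_instance].
#' @param S selected PU ids (character) or a logical mask over PU columns.
#' @param spf species penalty factor; defaults to the instance's.
#' @return scalar objective value.
#' @export
objective_value <- function(inst, S, spf = inst$spf) {
  if (spf < 0) stop("spf must be >= 0")
  sel <- .sel_logical(inst, S)
  held <- .held_counts(inst, sel)
  short <- .shortfalls(inst, held)
  pos <- inst$targets > 0
  sum(inst$cost[sel]) +
    spf * sum(inst$base[pos] * short[pos] / inst$targets[pos])
}

.new_solution <- function(inst, sel) {
  held <- .held_counts(inst, sel)
  short <- .shortfalls(inst, held)
  structure(list(selected = colnames(inst$a)[sel],
                 cost = sum(inst$cost[sel]),
                 objective = objective_value(inst, sel),
                 shortfall = short,
                 feasible = .is_feasible(inst, held),
                 size = sum(sel)),
            class = "reserve_solution")
}

# One greedy addition step: the unselected PU with the greatest summed
# fractional unmet-target contribution per unit cost; ties break to the
# lowest pu_id (columns are id-ordered, which.max takes the first).
.greedy_step <- function(inst, sel, held) {
  unmet <- .shortfalls(inst, held)
  pos <- inst$targets > 0 & unmet > 0
  if (!any(pos)) return(NA_integer_)
  contrib <- pmin(inst$a[pos, , drop = FALSE], unmet[pos]) /
    inst$targets[pos]
  score <- colSums(contrib) / pmax(inst$cost, .Machine$double.eps)
  score[sel] <- -Inf
  i <- which.max(score)
  if (score[i] <= 0) stop("targets unreachable: no PU contributes")
  i
}

.prune <- function(inst, sel, order_idx) {
  held <- .held_counts(inst, sel)
  for (i in order_idx) {
    if (!sel[i]) next
    held_wo <- held - inst$a[, i]
    if (.is_feasible(inst, held_wo)) {
      sel[i] <- FALSE
      held <- held_wo
    }
  }
  sel
}

#' Greedy minimum-set heuristic
#'
#' Repeatedly adds the PU with the greatest summed fractional unmet-target
#' contribution per unit cost until all targets are met, then reverse-prunes
#' (scanning in reverse addition order) any PU whose removal keeps the set
#' feasible. Always returns a feasible, irredundant solution.
#'
#' @inheritParams objective_value
#' @return a `reserve_solution`.
#' @export
greedy_minset <- function(inst) {
  sel <- logical(ncol(inst$a))
  held <- .held_counts(inst, sel)
  added <- integer(0)
  while (!.is_feasible(inst, held)) {
    i <- .greedy_step(inst, sel, held)
    sel[i] <- TRUE
    held <- held + inst$a[, i]
    added <- c(added, i)
  }
  sel <- .prune(inst, sel, rev(added))
  .new_solution(inst, sel)
}

#' Exhaustive minimum-set oracle
#'
#' Enumerates all subsets of the PUs carrying any counts (zero-count PUs can
#' never help) and returns one minimum-cost feasible set together with the
#' full list of co-optimal sets, for tie-break-free irreplaceability checks.
#' Intended for small test instances.
#'
#' @inheritParams objective_value
#' @param max_pu refuse instances with more than this many nonzero-count PUs.
#' @return list: `solution` (a `reserve_solution`), `optima` (list of pu-id
#'   vectors), `n_optima`.
#' @export
exact_minset <- function(inst, max_pu = 20) {
  nz <- colSums(inst$a) > 0
  m <- sum(nz)
  if (m > max_pu)
    stop("instance too large for exact search: ", m, " nonzero PUs > ",
         max_pu)
  anz <- inst$a[, nz, drop = FALSE]
  cost_nz <- inst$cost[nz]
  tnum <- inst$totals * inst$num
  n_sub <- 2^m
  best_cost <- Inf
  best_sets <- list()
  block <- 65536L
  for (start in seq(0, n_sub - 1, by = block)) {
    idx <- start + seq_len(min(block, n_sub - start)) - 1
    memb <- vapply(seq_len(m), function(b) bitwAnd(idx, bitwShiftL(1, b - 1)) > 0,
                   logical(length(idx)))
    if (is.null(dim(memb))) memb <- matrix(memb, nrow = 1)
    held <- anz %*% t(memb)                       # species x subsets
    feas <- colSums(held * inst$den >= tnum) == nrow(anz)
    if (!any(feas)) next
    costs <- as.numeric(memb %*% cost_nz)
    costs[!feas] <- Inf
    mc <- min(costs)
    if (mc < best_cost - 1e-9) {
      best_cost <- mc
      best_sets <- list()
    }
    if (is.finite(mc) && mc <= best_cost + 1e-9) {
      hit <- which(feas & abs(costs - best_cost) <= 1e-9)
      best_sets <- c(best_sets,
                     lapply(hit, function(j) colnames(anz)[memb[j, ]]))
    }
  }
  if (!length(best_sets)) stop("no feasible subset exists")
  sel <- .sel_logical(inst, best_sets[[1]])
  list(solution = .new_solution(inst, sel), optima = best_sets,
       n_optima = length(best_sets))
}

#' Simulated-annealing minimum-set solver
#'
#' Single-PU flip moves with Metropolis acceptance `min(1, exp(-delta/T))`.
#' The initial temperature is set adaptively so that a move of the median
#' absolute size seen over 100 random probe moves is accepted with
#' probability ~0.8; cooling is geometric down to
#' `temp_floor_ratio * T0` over `iterations` moves. The annealed set is then
#' repaired: greedy additions to feasibility followed by a greedy prune
#' (least-useful-first), so the result is always feasible and irredundant.
#' A fixed seed gives an identical trajectory.
#'
#' @inheritParams objective_value
#' @param config a [run_config].
#' @param seed integer seed for this run.
#' @return a `reserve_solution`.
#' @export
anneal_minset <- function(inst, config = run_config(), seed = config$seed) {
  set.seed(seed)
  pos <- inst$targets > 0
  pen_coef <- numeric(nrow(inst$a))
  pen_coef[pos] <- config$spf * inst$base[pos] / inst$targets[pos]
  sel <- anneal_core(inst$a, unname(inst$cost), inst$totals * inst$num,
                     inst$den, pen_coef, as.integer(config$iterations),
                     config$temp_floor_ratio)
  sel <- repair_solution(inst, sel)
  .new_solution(inst, sel)
}

#' Repair a candidate selection to feasibility and irredundancy
#'
#' Greedy additions until every target is met, then a prune scan that visits
#' selected PUs in increasing order of total fractional contribution
#' (least useful first) and drops any whose removal keeps feasibility.
#'
#' @inheritParams objective_value
#' @param sel logical selection mask over the instance's PU columns.
#' @return repaired logical mask.
#' @export
repair_solution <- function(inst, sel) {
  sel <- .sel_logical(inst, sel)
  held <- .held_counts(inst, sel)
  while (!.is_feasible(inst, held)) {
    i <- .greedy_step(inst, sel, held)
    sel[i] <- TRUE
    held <- held + inst$a[, i]
  }
  pos <- inst$targets > 0
  if (any(pos)) {
    frac <- colSums(inst$a[pos, , drop = FALSE] / inst$targets[pos])
  } else frac <- colSums(inst$a)
  ord <- order(frac, colnames(inst$a))   # least useful first, id tie-break
  .prune(inst, sel, ord)
}

#' Selection-frequency irreplaceability
#'
#' Runs the annealer `R = config$n_solutions` times with seeds
#' `seed + 1, ..., seed + R` and reports, for each PU, the fraction of runs
#' in which it was selected (IrSc in \[0, 1\]), together with its
#' irreplaceability class.
#'
#' @inheritParams anneal_minset
#' @return data frame `pu_id`, `irsc`, `class`, with attributes `runs`
#'   (per-run size/objective/feasibility) and `R`.
#' @export
selection_frequency <- function(inst, config = run_config(),
                                seed = config$seed) {
  R <- config$n_solutions
  ids <- colnames(inst$a)
  hits <- setNames(numeric(length(ids)), ids)
  runs <- data.frame(run = seq_len(R), size = NA_integer_,
                     objective = NA_real_, feasible = NA)
  for (r in seq_len(R)) {
    sol <- anneal_minset(inst, config, seed = seed + r)
    hits[sol$selected] <- hits[sol$selected] + 1
    runs$size[r] <- sol$size
    runs$objective[r] <- sol$objective
    runs$feasible[r] <- sol$feasible
  }
  irsc <- hits / R
  out <- data.frame(pu_id = ids, irsc = unname(irsc),
                    class = classify_irsc(unname(irsc)),
                    stringsAsFactors = FALSE)
  attr(out, "runs") <- runs
  attr(out, "R") <- R
  out
}

IRSC_CLASSES <- c("very low", "low", "moderate", "high", "very high",
                  "completely irreplaceable")

#' Irreplaceability class bands
#'
#' Left-closed, right-open bands: \[0, 0.2) very low; \[0.2, 0.4) low;
#' \[0.4, 0.6) moderate; \[0.6, 0.8) high; \[0.8, 1) very high; exactly 1 is
#' completely irreplaceable.
#'
#' @param irsc numeric vector in \[0, 1\].
#' @return factor with the six class labels.
#' @export
classify_irsc <- function(irsc) {
  if (any(irsc < 0 | irsc > 1 | !is.finite(irsc)))
    stop("irsc must lie in [0, 1]")
  lab <- ifelse(irsc == 1, "completely irreplaceable",
         ifelse(irsc >= 0.8, "very high",
         ifelse(irsc >= 0.6, "high",
         ifelse(irsc >= 0.4, "moderate",
         ifelse(irsc >= 0.2, "low", "very low")))))
  factor(lab, levels = IRSC_CLASSES)
}

#' @export
print.reserve_solution <- function(x, ...) {
  cat(sprintf("reserve solution: %d PUs, cost %.6g, %s\n", x$size, x$cost,
              if (x$feasible) "feasible" else "infeasible"))
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
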