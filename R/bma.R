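# Drivers analysis: predictor standardisation, VIF collinearity screening,
# Gaussian/Poisson likelihoods, and BIC-approximate Bayesian model averaging
# over the full enumeration of predictor subsets, with Efron's pseudo-R^2 as
# goodness of fit.

#' Standardise a predictor matrix
#'
#' Centres each predictor to mean 0 and scales to sample standard deviation
#' 1 (n - 1 denominator), so coefficients are comparable across predictors.
#' Columns named in `log_cols` are log-transformed first (the convention for
#' flow volumes). The response is never touched.
#'
#' @param X numeric matrix or data frame of predictors.
#' @param log_cols column names to log-transform before scaling.
#' @return matrix of standardised predictors with attribute
#'   `standardized = TRUE`.
#' @export
scale_predictors <- function(X, log_cols = character(0)) {
  X <- as.matrix(X)
  for (cl in intersect(log_cols, colnames(X))) {
    if (any(X[, cl] <= 0)) stop("cannot log-transform column '", cl,
                                "': nonpositive values")
    X[, cl] <- log(X[, cl])
  }
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  out <- scale(X)          # (x - mean) / sd, n-1 denominator
  attr(out, "standardized") <- TRUE
  out
}

#' Iterative variance-inflation-factor screen
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing predictor j on the remaining
#' predictors. The predictor with the largest VIF at or above the threshold
#' is dropped (largest column index on ties; a perfectly collinear column
#' has infinite VIF) and VIFs are recomputed, until all remaining VIFs fall
#' below the threshold.
#'
#' @param X numeric predictor matrix (>= 2 columns to screen).
#' @param threshold drop columns with VIF at or above this value (default 5).
#' @return list: `retained` (column names kept), `vif` (final VIFs),
#'   `trace` (data frame of drops: column, VIF at removal).
#' @export
vif_screen <- function(X, threshold = 5) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least 2 predictors to screen")
  vif_of <- function(M) {
    vapply(seq_len(ncol(M)), function(j) {
      fit <- lm.fit(cbind(1, M[, -j, drop = FALSE]), M[, j])
      rss <- sum(fit$residuals^2)
      tss <- sum((M[, j] - mean(M[, j]))^2)
      r2 <- 1 - rss / tss
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  trace <- data.frame(column = character(0), vif = numeric(0))
  repeat {
    if (ncol(X) < 2) break
    v <- setNames(vif_of(X), colnames(X))
    if (all(v < threshold)) break
    worst <- max(v)
    j <- max(which(v == worst))          # largest index on ties
    trace <- rbind(trace,
                   data.frame(column = colnames(X)[j], vif = worst))
    X <- X[, -j, drop = FALSE]
  }
  v <- if (ncol(X) >= 2) setNames(vif_of(X), colnames(X))
       else setNames(rep(1, ncol(X)), colnames(X))
  list(retained = colnames(X), vif = v, trace = trace)
}

#' Maximum-likelihood GLM fit for one predictor subset
#'
#' Intercept always included. Gaussian: closed-form least squares with the
#' error variance profiled out, so the log-likelihood is
#' `-n/2 (log(2 pi RSS/n) + 1)` and the parameter count is the number of
#' coefficients plus one for the variance. Poisson: log link fitted by
#' iteratively reweighted least squares.
#'
#' @param y response vector.
#' @param X predictor matrix for the subset (may have zero columns).
#' @param family `"gaussian"` or `"poisson"`.
#' @return list: `coefficients` (named, intercept first), `loglik`, `df`
#'   (estimated-parameter count), `fitted`, `se` (coefficient standard
#'   errors).
#' @export
glm_fit <- function(y, X = NULL, family = c("gaussian", "poisson")) {
  family <- match.arg(family)
  n <- length(y)
  if (is.null(X)) X <- matrix(numeric(0), nrow = n, ncol = 0)
  X <- as.matrix(X)
  if (nrow(X) != n) stop("X and y lengths differ")
  k <- ncol(X) + 1
  if (n <= k) stop("need more observations than parameters")
  Xi <- cbind(`(Intercept)` = 1, X)
  if (family == "gaussian") {
    fit <- lm.fit(Xi, y)
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / n
    loglik <- -n / 2 * (log(2 * pi * sigma2) + 1)
    xtxi <- chol2inv(chol(crossprod(Xi)))
    se <- sqrt(diag(xtxi) * rss / (n - k))
    list(coefficients = setNames(fit$coefficients, colnames(Xi)),
         loglik = loglik, df = k + 1, fitted = as.numeric(Xi %*% fit$coefficients),
         se = setNames(se, colnames(Xi)))
  } else {
    fit <- glm.fit(Xi, y, family = poisson())
    if (!fit$converged) stop("Poisson IRLS did not converge")
    mu <- fit$fitted.values
    loglik <- sum(dpois(y, mu, log = TRUE))
    W <- mu
    xtwxi <- chol2inv(chol(crossprod(Xi * sqrt(W))))
    list(coefficients = setNames(fit$coefficients, colnames(Xi)),
         loglik = loglik, df = k,
         fitted = as.numeric(mu),
         se = setNames(sqrt(diag(xtwxi)), colnames(Xi)))
  }
}

#' BIC-approximate Bayesian model averaging over all predictor subsets
#'
#' Enumerates every subset of the candidate predictors, fits each by maximum
#' likelihood, and weights models by `exp(-BIC/2)` (normalised), the
#' large-sample approximation to posterior model probability under vague
#' priors. Models whose posterior odds against the best exceed
#' `occam_odds` are discarded before renormalising (Occam's window). Reports
#' per-predictor posterior inclusion probabilities, unconditional and
#' conditional-on-inclusion averaged coefficients, averaging s.d. by the law
#' of total variance, and Efron's pseudo-R^2 of the model-averaged fit.
#'
#' @param y response vector.
#' @param X candidate predictor matrix (at most 20 columns).
#' @param family `"gaussian"` or `"poisson"`.
#' @param occam_odds posterior-odds cutoff for Occam's window (default 20);
#'   `Inf` keeps every model.
#' @return list of class `model_posterior`: `models` (data frame of subsets,
#'   BIC, posterior probabilities), `terms` (data frame `term`, `pp`,
#'   `beta_mean`, `beta_sd`, `beta_cond`), `pseudo_r2`, `fitted`.
#' @export
bma_average <- function(y, X = NULL, family = c("gaussian", "poisson"),
                        occam_odds = 20) {
  family <- match.arg(family)
  if (is.null(X)) X <- matrix(numeric(0), nrow = length(y), ncol = 0)
  X <- as.matrix(X)
  k <- ncol(X)
  if (k > 20) stop("full enumeration limited to 20 predictors")
  n <- length(y)
  subsets <- if (k == 0) list(integer(0)) else
    lapply(0:(2^k - 1), function(m) which(bitwAnd(m, bitwShiftL(1, 0:(k - 1))) > 0))
  fits <- lapply(subsets, function(js)
    glm_fit(y, X[, js, drop = FALSE], family))
  bic <- vapply(fits, function(f) -2 * f$loglik + f$df * log(n), numeric(1))
  w <- exp(-0.5 * (bic - min(bic)))
  keep <- if (is.finite(occam_odds)) w * occam_odds >= max(w)
          else rep(TRUE, length(w))    # posterior odds vs best <= occam_odds
  subsets <- subsets[keep]; fits <- fits[keep]; bic <- bic[keep]
  w <- w[keep] / sum(w[keep])

  terms <- c("(Intercept)", colnames(X))
  beta <- matrix(0, length(fits), length(terms),
                 dimnames = list(NULL, terms))
  sevm <- matrix(0, length(fits), length(terms),
                 dimnames = list(NULL, terms))
  inmod <- matrix(FALSE, length(fits), length(terms),
                  dimnames = list(NULL, terms))
  for (m in seq_along(fits)) {
    cf <- fits[[m]]$coefficients
    beta[m, names(cf)] <- cf
    sevm[m, names(cf)] <- fits[[m]]$se
    inmod[m, names(cf)] <- TRUE
  }
  pp <- colSums(w * inmod)
  beta_mean <- colSums(w * beta)
  # law of total variance: E[var within] + var of means across models
  beta_var <- colSums(w * (sevm^2 + beta^2)) - beta_mean^2
  beta_var <- pmax(beta_var, 0)
  beta_cond <- ifelse(pp > 0, colSums(w * beta) / pp, NA_real_)

  fitted_avg <- Reduce(`+`, Map(function(wm, f) wm * f$fitted, w, fits))
  r2 <- efron_r2(y, fitted_avg)

  models <- data.frame(
    predictors = vapply(subsets, function(js)
      paste(colnames(X)[js], collapse = "+"), character(1)),
    n_predictors = lengths(subsets), bic = bic, posterior = w)
  models <- models[order(-models$posterior), ]
  structure(list(models = models,
                 terms = data.frame(term = terms, pp = unname(pp),
                                    beta_mean = unname(beta_mean),
                                    beta_sd = unname(sqrt(beta_var)),
                                    beta_cond = unname(beta_cond),
                                    stringsAsFactors = FALSE),
                 pseudo_r2 = r2, fitted = fitted_avg, family = family),
            class = "model_posterior")
}

#' Efron's pseudo-R^2
#'
#' The squared Pearson correlation between observed and fitted responses. A
#' constant fitted vector carries no association and returns 0 with a
#' warning.
#'
#' @param y observed responses.
#' @param fitted fitted values of equal length.
#' @return scalar in \[0, 1\].
#' @export
efron_r2 <- function(y, fitted) {
  if (length(y) != length(fitted)) stop("y and fitted lengths differ")
  if (length(y) < 2) stop("need at least 2 observations")
  if (sd(fitted) == 0) {
    warning("constant fitted values: pseudo-R^2 undefined, returning 0")
    return(0)
  }
  cor(y, fitted)^2
}

#' @export
print.model_posterior <- function(x, ...) {
  cat(sprintf("BIC model averaging (%s), %d models, pseudo-R2 = %.3f\n",
              x$family, nrow(x$models), x$pseudo_r2))
  print(x$terms, row.names = FALSE, digits = 3)
  invisible(x)
}
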