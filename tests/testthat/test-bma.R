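test_that("predictor scaling centres, scales and log-transforms", {
  X <- cbind(a = c(1, 2, 3), b = c(10, 20, 60))
  Xs <- scale_predictors(X)
  expect_equal(Xs[, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(mean(Xs[, "b"]), 0)
  expect_equal(sd(Xs[, "b"]), 1)
  # idempotent on an already standardized column
  expect_equal(unname(scale_predictors(Xs)[, "a"]), unname(Xs[, "a"]),
               tolerance = 1e-12)
  # flow-style log transform happens before scaling
  Xl <- scale_predictors(cbind(flow = c(1, 10, 100)), log_cols = "flow")
  expect_equal(Xl[, "flow"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_error(scale_predictors(cbind(a = c(1, 1, 1))), "zero-variance")
  expect_error(scale_predictors(cbind(flow = c(-1, 2, 3)),
                                log_cols = "flow"), "nonpositive")
})

test_that("VIF screen drops collinear predictors iteratively", {
  set.seed(21)
  # mutually uncorrelated columns: all VIF 1, nothing dropped
  u <- scale(rnorm(10))[, 1]
  v <- scale(resid(lm(rnorm(10) ~ u)))[, 1]
  w <- scale(resid(lm(rnorm(10) ~ u + v)))[, 1]
  Xo <- cbind(u = u, v = v, w = w)
  sc <- vif_screen(Xo)
  expect_equal(unname(sc$vif), rep(1, 3), tolerance = 1e-10)
  expect_equal(sc$retained, c("u", "v", "w"))

  # exact duplicate: infinite VIF, the larger index goes
  x1 <- rnorm(20); x3 <- rnorm(20)
  Xd <- cbind(x1 = x1, x2 = x1, x3 = x3)
  sd2 <- vif_screen(Xd)
  expect_equal(sd2$retained, c("x1", "x3"))
  expect_equal(sd2$trace$column, "x2")
  expect_true(is.infinite(sd2$trace$vif))

  # two columns correlated at exactly r = 0.5: VIF = 1/(1 - 0.25)
  z1 <- scale(rnorm(40))[, 1]
  z2r <- scale(resid(lm(rnorm(40) ~ z1)))[, 1]
  z2 <- 0.5 * z1 + sqrt(0.75) * z2r
  sc3 <- vif_screen(cbind(a = z1, b = z2))
  expect_equal(unname(sc3$vif), c(4 / 3, 4 / 3), tolerance = 1e-9)
  expect_equal(sc3$retained, c("a", "b"))
})

test_that("gaussian fits match the normal-equations oracle", {
  # intercept-only: mean and the closed-form normal log-likelihood
  y <- c(2, 4, 9, 1, 5)
  f0 <- glm_fit(y, NULL, "gaussian")
  expect_equal(unname(f0$coefficients), mean(y))
  s2 <- mean((y - mean(y))^2)
  expect_equal(f0$loglik, sum(dnorm(y, mean(y), sqrt(s2), log = TRUE)))
  expect_equal(f0$df, 2)  # intercept + variance

  # 5x2 system against an independent solve of the normal equations
  set.seed(2)
  X <- cbind(x = rnorm(5))
  yy <- 1 + 2 * X[, 1] + rnorm(5)
  fit <- glm_fit(yy, X, "gaussian")
  Xi <- cbind(1, X)
  beta_hat <- solve(t(Xi) %*% Xi, t(Xi) %*% yy)
  expect_equal(unname(fit$coefficients), as.numeric(beta_hat),
               tolerance = 1e-10)
  expect_error(glm_fit(yy, cbind(X, X, X, X, X), "gaussian"),
               "more observations")
})

test_that("poisson fits agree with direct likelihood maximisation", {
  # no predictors: MLE of the Poisson mean is the sample mean
  f <- glm_fit(c(1, 2, 3), NULL, "poisson")
  expect_equal(unname(f$coefficients), log(2), tolerance = 1e-8)
  # one predictor: compare against optim on the log-likelihood
  set.seed(5)
  x <- rnorm(30)
  y <- rpois(30, exp(1 + 0.5 * x))
  fit <- glm_fit(y, cbind(x = x), "poisson")
  nll <- function(b) -sum(dpois(y, exp(b[1] + b[2] * x), log = TRUE))
  opt <- optim(c(0, 0), nll, method = "BFGS")
  expect_equal(unname(fit$coefficients), opt$par, tolerance = 1e-6)
  expect_equal(fit$loglik, -opt$value, tolerance = 1e-6)
})

test_that("BMA posterior matches a hand enumeration on a fixed table", {
  set.seed(1)
  n <- 8
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  y <- 1 + 0.8 * X[, 1] + rnorm(n)

  # independent oracle: closed-form gaussian loglik per subset, BIC weights
  loglik_of <- function(cols) {
    Xi <- cbind(1, X[, cols, drop = FALSE])
    r <- y - Xi %*% solve(t(Xi) %*% Xi, t(Xi) %*% y)
    s2 <- sum(r^2) / n
    -n / 2 * (log(2 * pi * s2) + 1)
  }
  subsets <- list(integer(0), 1, 2, c(1, 2))
  bic <- vapply(subsets, function(js)
    -2 * loglik_of(js) + (length(js) + 2) * log(n), numeric(1))
  w_hand <- exp(-0.5 * (bic - min(bic)))
  w_hand <- w_hand / sum(w_hand)

  post <- bma_average(y, X, "gaussian", occam_odds = Inf)
  expect_equal(nrow(post$models), 4)
  expect_equal(sort(post$models$posterior), sort(w_hand), tolerance = 1e-10)
  expect_equal(sum(post$models$posterior), 1, tolerance = 1e-12)
  # inclusion probabilities from the same hand weights
  pp1 <- sum(w_hand[c(2, 4)])
  expect_equal(post$terms$pp[post$terms$term == "x1"], pp1,
               tolerance = 1e-10)
  # pp equals the summed weights of models containing the term
  in_x2 <- grepl("x2", post$models$predictors)
  expect_equal(post$terms$pp[post$terms$term == "x2"],
               sum(post$models$posterior[in_x2]), tolerance = 1e-12)
})

test_that("BMA degenerate cases collapse to single fits", {
  y <- c(3, 1, 4, 1, 5, 9, 2, 6)
  # no candidate predictors: one model with weight 1, intercept = mean
  # (the constant fit makes pseudo-R^2 degenerate, which is flagged)
  expect_warning(p0 <- bma_average(y, NULL, "gaussian"), "constant fitted")
  expect_equal(nrow(p0$models), 1)
  expect_equal(p0$models$posterior, 1)
  expect_equal(p0$terms$beta_mean[1], mean(y))
  # averaged intercept equals mean(y) exactly with standardized predictors
  set.seed(8)
  X <- scale_predictors(cbind(a = rnorm(8), b = rnorm(8)))
  pa <- bma_average(y, X, "gaussian", occam_odds = Inf)
  expect_equal(pa$terms$beta_mean[pa$terms$term == "(Intercept)"], mean(y),
               tolerance = 1e-12)
  expect_equal(pa$terms$pp[pa$terms$term == "(Intercept)"], 1)
  # with one candidate predictor, the conditional-on-inclusion coefficient
  # is exactly the fit of the single model containing it
  Xb <- X[, "a", drop = FALSE]
  fit <- glm_fit(y, Xb, "gaussian")
  pb <- bma_average(y, Xb, "gaussian", occam_odds = Inf)
  expect_equal(pb$terms$beta_cond[pb$terms$term == "a"],
               unname(fit$coefficients["a"]), tolerance = 1e-10)
})

test_that("occam's window discards implausible models and renormalises", {
  set.seed(12)
  n <- 60
  X <- cbind(good = rnorm(n), junk = rnorm(n))
  y <- 2 + 3 * X[, "good"] + rnorm(n, 0, 0.5)
  full <- bma_average(y, X, "gaussian", occam_odds = Inf)
  trimmed <- bma_average(y, X, "gaussian", occam_odds = 20)
  expect_lt(nrow(trimmed$models), nrow(full$models))
  expect_equal(sum(trimmed$models$posterior), 1, tolerance = 1e-12)
  best <- max(trimmed$models$posterior)
  expect_true(all(best / trimmed$models$posterior <= 20 + 1e-9))
})

test_that("efron pseudo-R2 is the squared observed-fitted correlation", {
  expect_equal(efron_r2(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(efron_r2(c(1, 2, 3), c(1, 2, 4)), 27 / 28, tolerance = 1e-12)
  expect_warning(r0 <- efron_r2(c(1, 2, 3), c(2, 2, 2)), "constant")
  expect_equal(r0, 0)
  expect_error(efron_r2(1:3, 1:4), "lengths differ")
  expect_error(efron_r2(1, 1), "at least 2")
})
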