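test_that("bayesian ridge recovers exact linear weights in the noiseless case", {
  set.seed(2)
  n <- 400
  X <- matrix(rnorm(n * 3), n)
  t <- rnorm(n)
  y <- 2 + 1.5 * t + drop(X %*% c(1, -2, 0.5))
  fit <- fit_bayesian_ridge(make_design(X, t, y))
  expect_equal(unname(fit$posterior_mean), c(1.5, 1, -2, 0.5),
               tolerance = 1e-3)
  expect_true(fit$iterations <= 300)
  # infinite-shrinkage limit: all weights collapse to zero
  fit0 <- fit_bayesian_ridge(make_design(X, t, y), fixed_alpha = 1e12,
                             fixed_beta = 1)
  expect_lt(max(abs(fit0$posterior_mean)), 1e-6)
  # posterior covariance is symmetric PSD and treatment SD matches Sigma
  ev <- eigen(fit$posterior_cov, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-12)
  expect_equal(fit$treatment_posterior_sd, sqrt(fit$posterior_cov[1, 1]))
})

test_that("learned hyperparameters beat a 20x20 evidence grid", {
  set.seed(5)
  n <- 50
  X <- matrix(rnorm(n * 2), n)
  t <- rnorm(n)
  y <- 1 + 0.8 * t + drop(X %*% c(1, -1)) + 0.7 * rnorm(n)
  dm <- make_design(X, t, y)
  fit <- fit_bayesian_ridge(dm)
  Z <- cbind(dm$t, dm$X)
  grid <- expand.grid(a = 10^seq(-4, 4, length.out = 20),
                      b = 10^seq(-4, 4, length.out = 20))
  evs <- mapply(function(a, b) wbcausal:::.bayes_ridge_evidence(Z, dm$y, a, b),
                grid$a, grid$b)
  expect_gte(fit$evidence, max(evs))
})

test_that("Nystroem with all-row landmarks reproduces exact kernel ridge", {
  set.seed(3)
  X <- matrix(rnorm(30 * 4), 30)
  y <- rnorm(30)
  bw <- 1.5; lam <- 0.7
  map <- nystroem_map(X, n_landmarks = 30, bandwidth = bw)
  pred <- wbcausal:::ridge_fit(feature_map(map, X), y, lam,
                               intercept = FALSE)$fitted
  K <- wbcausal:::rbf_kernel(X, X, bw)
  oracle <- drop(K %*% solve(K + lam * diag(30), y))
  expect_equal(pred, oracle, tolerance = 1e-9)
})

test_that("kernel Bayesian model degenerates gracefully and ignores row duplication", {
  set.seed(4)
  n <- 60
  X <- matrix(rnorm(n * 2), n)
  t <- rnorm(n)
  y <- sin(t) + X[, 1]^2          # noiseless smooth surface
  dm <- make_design(X, t, y)
  # bandwidth -> infinity: all mapped features constant => intercept-only fit
  flat <- fit_kernel_bayesian(dm, bandwidth = 1e8, n_landmarks = 20)
  expect_equal(stats::predict(flat, dm$X, dm$t), rep(mean(y), n),
               tolerance = 1e-4)
  # duplicating every row leaves the fit point (essentially) unchanged:
  # in the noiseless, data-dominated limit the evidence-maximizing fit
  # approaches the least-squares fit, which is weighting invariant
  fit1 <- fit_kernel_bayesian(dm, n_landmarks = n, bandwidth = 2)
  dm2 <- make_design(rbind(X, X), c(t, t), c(y, y))
  fit2 <- fit_kernel_bayesian(dm2, map = fit1$map)
  expect_equal(stats::predict(fit1, dm$X, dm$t),
               stats::predict(fit2, dm$X, dm$t), tolerance = 1e-4)
})

test_that("two-stage at zero penalty equals OLS (Frisch-Waugh) incl. its s.e.", {
  set.seed(6)
  n <- 20
  X <- matrix(rnorm(n * 3), n)
  t <- rnorm(n)
  y <- 1 + 2 * t + drop(X %*% c(1, -1, 0.5)) + rnorm(n)
  dm <- make_design(X, t, y)
  ts <- fit_two_stage_ridge(dm, map = NULL, lambda1 = 0, lambda2 = 0)
  ols <- stats::lm(y ~ t + X)
  expect_equal(ts$treatment_coef, unname(stats::coef(ols)["t"]),
               tolerance = 1e-10)
  expect_equal(ols_se_treatment(ts),
               unname(summary(ols)$coefficients["t", "Std. Error"]),
               tolerance = 1e-10)
})

test_that("orthogonal treatment is recovered exactly for any penalties", {
  set.seed(7)
  n <- 100
  X <- matrix(rnorm(n * 3), n)
  t <- rnorm(n)                       # independent of X
  y <- 2 * t                          # no control signal, no noise
  dm <- make_design(X, t, y)
  for (lam in c(0, 1, 50)) {
    ts <- fit_two_stage_ridge(dm, map = NULL, lambda1 = lam, lambda2 = lam)
    # beta stays 2 up to the finite-sample correlation the penalty cannot
    # remove; at lam = 0 it is exact
    if (lam == 0) expect_equal(ts$treatment_coef, 2, tolerance = 1e-10)
    else expect_equal(ts$treatment_coef, 2, tolerance = 0.05)
  }
  # stage-1 residual definition
  ts <- fit_two_stage_ridge(dm, map = NULL, lambda1 = 3, lambda2 = 1)
  Phi <- cbind(1, dm$X)
  expect_equal(ts$stage1_residuals,
               dm$t - drop(Phi %*% ts$stage1_weights), tolerance = 1e-12)
})

test_that("two-stage beta ignores lambda2 when features are orthogonal to t", {
  set.seed(8)
  n <- 60
  t <- rnorm(n)
  raw <- matrix(rnorm(n * 3), n)
  # project out the (intercept, t) span so the features carry no treatment
  X <- stats::resid(stats::lm(raw ~ t))
  y <- 1 + 2 * t + drop(X %*% c(1, -1, 0.5)) + 0.3 * rnorm(n)
  dm <- make_design(X, t, y)
  betas <- vapply(c(0, 1, 100, 1e4), function(l2)
    fit_two_stage_ridge(dm, map = NULL, lambda1 = 0,
                        lambda2 = l2)$treatment_coef, numeric(1))
  expect_equal(betas, rep(betas[1], 4), tolerance = 1e-8)
})

test_that("two-stage recovers the true effect on confounded synthetic cohorts", {
  sim <- generate_cohort(recovery_config(n = 2000, true_ate = 35, seed = 31))
  dm <- build_design(sim$cohort)
  ts <- fit_two_stage_ridge(dm, map = NULL, lambda1 = 1, lambda2 = 1)
  se <- ols_se_treatment(ts)
  expect_lt(abs(ts$treatment_coef - 35), 2 * se)
})

test_that("boosting matches a hand-rolled staged-residual oracle", {
  # 10-row fixed instance, K = 3 stumps, learning rate 0.5
  x <- c(0.1, 0.9, 1.7, 2.4, 3.2, 4.1, 5.0, 5.8, 6.6, 7.5)
  t <- c(-1.2, 0.4, 1.1, -0.6, 0.9, -1.5, 0.3, 1.8, -0.2, 0.7)
  y <- c(1, 1.2, 0.8, 4.1, 4.4, 3.9, 8.2, 8.4, 7.9, 8.1)
  dm <- make_design(cbind(x), t, y)
  fit <- fit_gradient_boosting(dm, n_trees = 3, max_depth = 1,
                               learning_rate = 0.5, min_split = 2,
                               min_bucket = 1)
  # oracle: exhaustive best-SSE stump on each feature, staged residuals
  stump <- function(M, r) {
    best <- list(sse = Inf)
    for (j in seq_len(ncol(M))) {
      v <- M[, j]
      for (cut in (sort(unique(v))[-1] + utils::head(sort(unique(v)), -1)) / 2) {
        left <- v < cut
        pr <- ifelse(left, mean(r[left]), mean(r[!left]))
        sse <- sum((r - pr)^2)
        if (sse < best$sse) best <- list(sse = sse, pred = pr)
      }
    }
    best$pred
  }
  M <- cbind(x, t)
  pred <- rep(mean(y), 10)
  for (k in 1:3) pred <- pred + 0.5 * stump(M, y - pred)
  expect_equal(stats::predict(fit, cbind(x), t), pred, tolerance = 1e-10)
})

test_that("boosting training RMSE is non-increasing in the stage count", {
  dm <- toy_design(n = 120, seed = 9)
  fit <- fit_gradient_boosting(dm, n_trees = 40, max_depth = 2,
                               learning_rate = 0.3, min_split = 5)
  expect_true(all(diff(fit$rmse_trace) <= 1e-10))
  # single depth-1 tree at rate 1 nails a 2-level step function of t
  tt <- rep(c(-1, 1), each = 10)
  dm2 <- make_design(matrix(0, 20, 1), tt, ifelse(tt < 0, 2, 6))
  one <- fit_gradient_boosting(dm2, n_trees = 1, max_depth = 1,
                               learning_rate = 1, min_split = 2,
                               min_bucket = 1)
  expect_equal(stats::predict(one, matrix(0, 20, 1), tt),
               ifelse(tt < 0, 2, 6), tolerance = 1e-12)
})

test_that("DML with zero nuisances equals the simple regression slope", {
  dm <- toy_design(n = 90, seed = 10)
  fit <- fit_dml(dm, n_folds = 3, nuisance = "zero", seed = 1)
  expect_equal(fit$treatment_coef,
               unname(stats::coef(stats::lm(dm$y ~ dm$t))[2]),
               tolerance = 1e-10)
  expect_error(fit_dml(dm, n_folds = 30, nuisance = "zero"), "fewer than 5")
})

test_that("DML and two-stage agree on linear unconfounded cohorts", {
  sim <- generate_cohort(recovery_config(n = 1500, true_ate = 35, seed = 23,
                                         confounding_strength = 0))
  dm <- build_design(sim$cohort)
  ts <- fit_two_stage_ridge(dm, map = NULL, lambda1 = 1, lambda2 = 1)
  dml <- fit_dml(dm, nuisance = "ridge", seed = 4)
  comb <- sqrt(ols_se_treatment(ts)^2 + dml$treatment_se^2)
  expect_lt(abs(ts$treatment_coef - dml$treatment_coef), 2 * comb)
  # out-of-fold residual means are ~0 by construction
  expect_equal(mean(dml$t_resid), 0, tolerance = 1e-12)
  expect_equal(mean(dml$y_resid), 0, tolerance = 1e-12)
})

test_that("DML handles nonlinear confounding that breaks the linear ridge", {
  reps <- 8
  err_dml <- err_br <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- generate_cohort(recovery_config(
      n = 900, true_ate = 35, seed = 400 + r, n_raw_controls = 12,
      nonlinear_outcome = TRUE, nonlinear_treatment = TRUE))
    dm <- build_design(sim$cohort)
    dml <- fit_dml(dm, nuisance = "boosting",
                   nuisance_params = list(n_trees = 60, max_depth = 2),
                   seed = r)
    br <- fit_bayesian_ridge(dm)
    err_dml[r] <- abs(dml$treatment_coef - 35)
    err_br[r] <- abs(br$treatment_coef - 35)
  }
  expect_lt(mean(err_dml), mean(err_br))
})

test_that("all families honour the shared predict contract", {
  dm <- toy_design(n = 100, seed = 12)
  fits <- list(
    fit_bayesian_ridge(dm),
    fit_kernel_bayesian(dm, n_landmarks = 40, seed = 1),
    fit_two_stage_ridge(dm, map = nystroem_map(dm$X, 40, seed = 1),
                        lambda1 = 1, lambda2 = 1),
    fit_gradient_boosting(dm, n_trees = 20, max_depth = 2),
    fit_dml(dm, n_folds = 4, nuisance = "ridge", seed = 2))
  for (fit in fits) {
    p <- stats::predict(fit, dm$X[1:7, , drop = FALSE], 0.3)
    expect_length(p, 7)
    expect_true(all(is.finite(p)))
    # deterministic after fit
    expect_identical(p, stats::predict(fit, dm$X[1:7, , drop = FALSE], 0.3))
  }
})
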