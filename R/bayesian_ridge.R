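# Evidence-maximizing Bayesian linear regression (type-II maximum
# likelihood / empirical Bayes).  Model: y = Zw + e, w ~ N(0, 1/a I),
# e ~ N(0, 1/b I).  Hyperparameters (a, b) maximize the log marginal
# likelihood by the classic fixed-point updates; the intercept is handled by
# centering and is effectively unpenalized.

.bayes_ridge_core <- function(Z, y, max_iter = 300L, tol = 1e-6,
                              fixed_a = NULL, fixed_b = NULL) {
  Z <- as.matrix(Z)
  n <- nrow(Z); D <- ncol(Z)
  z_center <- colMeans(Z)
  Zc <- sweep(Z, 2, z_center)
  y_center <- mean(y)
  yc <- y - y_center

  ZtZ <- crossprod(Zc)
  Zty <- crossprod(Zc, yc)
  eg <- eigen(ZtZ, symmetric = TRUE)
  ev <- pmax(eg$values, 0)

  vy <- stats::var(yc)
  a <- if (is.null(fixed_a)) 1 else fixed_a
  b <- if (is.null(fixed_b)) {
    if (vy > 0) 1 / vy else 1
  } else fixed_b

  mu <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # posterior mean via the eigenbasis: mu = b V diag(1/(a + b ev)) V' Z'y
    Vty <- crossprod(eg$vectors, Zty)
    mu <- drop(eg$vectors %*% (b * Vty / (a + b * ev)))
    if (!is.null(fixed_a) && !is.null(fixed_b)) { converged <- TRUE; break }
    rss <- sum((yc - Zc %*% mu)^2)
    gamma_eff <- sum(b * ev / (a + b * ev))
    a_new <- if (is.null(fixed_a)) {
      mm <- sum(mu^2)
      if (mm > 0) gamma_eff / mm else 1e10
    } else a
    b_new <- if (is.null(fixed_b)) {
      denom <- max(rss, 1e-300)
      max(n - gamma_eff, 1e-10) / denom
    } else b
    a_new <- min(max(a_new, 1e-12), 1e12)
    b_new <- min(max(b_new, 1e-12), 1e12)
    rel <- abs(a_new - a) / (abs(a) + 1e-30) +
      abs(b_new - b) / (abs(b) + 1e-30)
    a <- a_new; b <- b_new
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged && is.null(fixed_a))
    warning("evidence maximization did not converge in ", max_iter,
            " iterations; returning last iterate")
  Vty <- crossprod(eg$vectors, Zty)
  mu <- drop(eg$vectors %*% (b * Vty / (a + b * ev)))
  Sigma <- eg$vectors %*% (t(eg$vectors) / (a + b * ev))
  rss <- sum((yc - Zc %*% mu)^2)
  evidence <- 0.5 * (D * log(a) + n * log(b) - b * rss - a * sum(mu^2) -
                       sum(log(a + b * ev)) - n * log(2 * pi))
  list(posterior_mean = mu, posterior_cov = Sigma,
       alpha = a, beta = b, noise_var = 1 / b, evidence = evidence,
       z_center = z_center, y_center = y_center, iterations = it,
       converged = converged)
}

# log marginal likelihood at fixed hyperparameters (for grid checks)
.bayes_ridge_evidence <- function(Z, y, a, b) {
  .bayes_ridge_core(Z, y, fixed_a = a, fixed_b = b)$evidence
}

#' Fit a fully linear Bayesian ridge response surface
#'
#' Regresses the outcome on the standardized treatment plus all encoded
#' controls under a common zero-mean Gaussian prior whose precision, along
#' with the noise precision, is learned by type-II maximum likelihood
#' (iterating the evidence fixed-point updates to relative tolerance `tol`).
#' Returns the posterior mean and covariance; the treatment's posterior SD
#' feeds the conservative Bayesian t-test.
#'
#' @param dm a `wb_design` from [build_design()].
#' @param max_iter,tol evidence-maximization iteration controls.
#' @param fixed_alpha,fixed_beta optionally pin the weight / noise precision
#'   instead of learning them (used for limit checks).
#' @return object of classes `wb_bayes_ridge` and `wb_surface` with fields
#'   `posterior_mean`, `posterior_cov`, `treatment_coef`,
#'   `treatment_posterior_sd`, `noise_var`, `evidence`.
#' @export
fit_bayesian_ridge <- function(dm, max_iter = 300L, tol = 1e-6,
                               fixed_alpha = NULL, fixed_beta = NULL) {
  stopifnot(inherits(dm, "wb_design"))
  Z <- cbind(`..t` = dm$t, dm$X)
  fit <- .bayes_ridge_core(Z, dm$y, max_iter, tol, fixed_alpha, fixed_beta)
  structure(list(
    posterior_mean = stats::setNames(fit$posterior_mean, colnames(Z)),
    posterior_cov = fit$posterior_cov,
    treatment_coef = fit$posterior_mean[1],
    treatment_posterior_sd = sqrt(fit$posterior_cov[1, 1]),
    noise_var = fit$noise_var, alpha = fit$alpha, beta = fit$beta,
    evidence = fit$evidence, z_center = fit$z_center,
    y_center = fit$y_center, iterations = fit$iterations,
    n = dm$n, d_model = ncol(Z) + 1L,   # columns + intercept
    model_kind = "bayesian_ridge"),
    class = c("wb_bayes_ridge", "wb_surface"))
}

#' @export
predict.wb_bayes_ridge <- function(object, X, t, ...) {
  X <- as.matrix(X)
  if (length(t) == 1) t <- rep(t, nrow(X))
  Z <- cbind(t, X)
  drop(sweep(Z, 2, object$z_center) %*% object$posterior_mean) +
    object$y_center
}

#' Fit a Nystroem-kernelized Bayesian regression response surface
#'
#' Maps the joint (controls, treatment) rows through an RBF Nystroem feature
#' map and fits the same evidence-maximizing Bayesian linear model in that
#' feature space, so the fitted surface is nonlinear in both the controls
#' and the treatment.
#'
#' @param dm a `wb_design`.
#' @param map optional precomputed [nystroem_map()] over `cbind(X, t)`;
#'   built from `n_landmarks`, `bandwidth`, `seed` when `NULL`.
#' @param n_landmarks,bandwidth,seed forwarded to [nystroem_map()].
#' @inheritParams fit_bayesian_ridge
#' @return object of classes `wb_kernel_bayes` and `wb_surface`.
#' @export
fit_kernel_bayesian <- function(dm, map = NULL, n_landmarks = NULL,
                                bandwidth = NULL, seed = 1L,
                                max_iter = 300L, tol = 1e-6) {
  stopifnot(inherits(dm, "wb_design"))
  Zraw <- cbind(dm$X, `..t` = dm$t)
  if (is.null(map))
    map <- nystroem_map(Zraw, n_landmarks = n_landmarks,
                        bandwidth = bandwidth, seed = seed)
  F <- feature_map(map, Zraw)
  fit <- .bayes_ridge_core(F, dm$y, max_iter, tol)
  structure(list(map = map, posterior_mean = fit$posterior_mean,
                 posterior_cov = fit$posterior_cov,
                 noise_var = fit$noise_var, evidence = fit$evidence,
                 z_center = fit$z_center, y_center = fit$y_center,
                 iterations = fit$iterations, n = dm$n,
                 model_kind = "kernel_bayesian"),
            class = c("wb_kernel_bayes", "wb_surface"))
}

#' @export
predict.wb_kernel_bayes <- function(object, X, t, ...) {
  X <- as.matrix(X)
  if (length(t) == 1) t <- rep(t, nrow(X))
  F <- feature_map(object$map, cbind(X, `..t` = t))
  drop(sweep(F, 2, object$z_center) %*% object$posterior_mean) +
    object$y_center
}
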