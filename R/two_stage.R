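#' Two-stage (kernelized) ridge regression with unregularized treatment
#' coefficient
#'
#' Stage 1 predicts the standardized treatment from the (optionally
#' Nystroem-mapped) controls by ridge regression; stage 2 regresses the
#' outcome jointly on the stage-1 residual and the mapped controls, where
#' the residualized-treatment coefficient carries *no* penalty and the
#' control weights carry `lambda2`.  Leaving the treatment coefficient
#' unpenalized removes the shrinkage-induced (regularization) bias that a
#' direct penalized regression puts on the effect estimate.
#'
#' @param dm a `wb_design`.
#' @param map a [nystroem_map()] over the control matrix, or `NULL` for the
#'   identity (linear) feature map.
#' @param lambda1,lambda2 non-negative ridge penalties for stage 1 (controls
#'   -> treatment) and the stage-2 control weights.
#' @return object of classes `wb_two_stage` and `wb_surface`: fields include
#'   `treatment_coef` (beta), `stage1_weights`, `stage2_control_weights`,
#'   `stage1_residuals`, `stage2_residuals`, the stage noise variances, and
#'   the treatment standard error ingredients (see [ols_se_treatment()]).
#' @export
fit_two_stage_ridge <- function(dm, map = NULL, lambda1 = 0.1,
                                lambda2 = 0.1) {
  stopifnot(inherits(dm, "wb_design"), lambda1 >= 0, lambda2 >= 0)
  Phi <- feature_map(map, dm$X)
  s1 <- ridge_fit(Phi, dm$t, lambda1, intercept = TRUE)
  nu <- s1$residuals

  A <- cbind(nu = nu, `(Intercept)` = 1, Phi)
  pen <- c(0, 0, rep(1, ncol(Phi)))
  M <- crossprod(A) + diag(lambda2 * pen, ncol(A))
  w <- tryCatch(drop(solve(M, crossprod(A, dm$y))), error = function(e)
    stop("stage-2 system is singular; increase lambda2", call. = FALSE))
  fitted <- drop(A %*% w)
  eps <- dm$y - fitted

  n <- dm$n
  d_model <- ncol(A)                 # residualized treatment + intercept + controls
  M_inv <- solve(M)
  cov_unscaled <- (M_inv %*% crossprod(A) %*% M_inv)[1, 1]

  structure(list(
    treatment_coef = w[[1]],
    stage1_weights = s1$coef, stage2_control_weights = w[-1],
    stage1_residuals = nu, stage2_residuals = eps,
    stage1_noise_var = mean(nu^2), stage2_noise_var = mean(eps^2),
    lambda1 = lambda1, lambda2 = lambda2, map = map,
    rss = sum(eps^2), n = n, d_model = d_model,
    cov_unscaled = cov_unscaled,
    model_kind = "two_stage"),
    class = c("wb_two_stage", "wb_surface"))
}

#' @export
predict.wb_two_stage <- function(object, X, t, ...) {
  X <- as.matrix(X)
  if (length(t) == 1) t <- rep(t, nrow(X))
  Phi <- feature_map(object$map, X)
  P <- cbind(1, Phi)
  t_hat <- drop(P %*% object$stage1_weights)
  object$treatment_coef * (t - t_hat) +
    drop(P %*% object$stage2_control_weights)
}

#' Heavily penalized direct ridge (treatment coefficient penalized too)
#'
#' The comparison estimator for regularization-bias studies: a single ridge
#' regression of outcome on (treatment, controls) where the treatment
#' coefficient is shrunk along with everything else.
#'
#' @param dm a `wb_design`.
#' @param lambda ridge penalty applied to every coefficient except the
#'   intercept.
#' @return object of classes `wb_direct_ridge` and `wb_surface`.
#' @export
fit_direct_ridge <- function(dm, lambda) {
  stopifnot(inherits(dm, "wb_design"), lambda >= 0)
  Z <- cbind(`..t` = dm$t, dm$X)
  fit <- ridge_fit(Z, dm$y, lambda, intercept = TRUE)
  structure(list(coef = fit$coef, treatment_coef = fit$coef[["..t"]],
                 lambda = lambda, n = dm$n,
                 model_kind = "direct_ridge"),
            class = c("wb_direct_ridge", "wb_surface"))
}

#' @export
predict.wb_direct_ridge <- function(object, X, t, ...) {
  X <- as.matrix(X)
  if (length(t) == 1) t <- rep(t, nrow(X))
  drop(cbind(1, t, X) %*% object$coef)
}
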