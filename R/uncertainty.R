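#' Standardize an effect and its standard error by the outcome SD
#'
#' The treatment is standardized before fitting, so dividing the coefficient
#' and its standard error by the sample SD of the outcome expresses the
#' effect in outcome SDs per treatment SD (the standardized ATE, beta*).
#'
#' @param beta unstandardized treatment coefficient (outcome points per
#'   treatment SD).
#' @param se_beta its standard error (or posterior SD).
#' @param s_y sample standard deviation of the outcome (> 0).
#' @return list with `beta_std` and `se_std`.
#' @export
standardize_effect <- function(beta, se_beta, s_y) {
  if (!is.finite(s_y) || s_y <= 0) stop("s_y must be positive", call. = FALSE)
  list(beta_std = beta / s_y, se_std = se_beta / s_y)
}

#' Finite-sample OLS-style standard error of the two-stage treatment
#' coefficient
#'
#' Residual variance uses divisor `df = N - D` with D counting every stage-2
#' design column including the intercept; the variance of the treatment
#' entry comes from the sandwich of the penalized stage-2 system, which at
#' zero penalty reduces to the textbook OLS standard error.  Conservative by
#' construction: regularization lowers the effective D, so this
#' over-estimates the uncertainty.
#'
#' @param fit a `wb_two_stage`.
#' @param df degrees of freedom; default `fit$n - fit$d_model`.
#' @return standard error of the treatment coefficient.
#' @export
ols_se_treatment <- function(fit, df = NULL) {
  stopifnot(inherits(fit, "wb_two_stage"))
  if (is.null(df)) df <- fit$n - fit$d_model
  if (df <= 0) stop("degrees of freedom must be positive", call. = FALSE)
  sigma2 <- fit$rss / df
  sqrt(sigma2 * fit$cov_unscaled)
}

#' Two-sided t-test for a treatment coefficient
#'
#' @param beta coefficient estimate.
#' @param se_beta standard error (> 0; a zero standard error with a nonzero
#'   coefficient returns p = 0 with a warning).
#' @param df degrees of freedom N - D (>= 1).
#' @return list with `t_stat` and `p_value`.
#' @export
t_test <- function(beta, se_beta, df) {
  if (df < 1) stop("df must be >= 1", call. = FALSE)
  if (se_beta < 0) stop("se_beta must be non-negative", call. = FALSE)
  if (se_beta == 0) {
    if (beta == 0) return(list(t_stat = 0, p_value = 1))
    warning("zero standard error with nonzero coefficient; p = 0")
    return(list(t_stat = sign(beta) * Inf, p_value = 0))
  }
  t_stat <- beta / se_beta
  list(t_stat = t_stat, p_value = 2 * stats::pt(-abs(t_stat), df))
}

#' Conservative Bayesian t-test from the posterior over the treatment weight
#'
#' Uses the posterior standard deviation of the treatment coefficient in
#' place of a frequentist standard error in the same two-sided t statistic;
#' the shrinkage prior and the N - D degrees of freedom both make the test
#' conservative.
#'
#' @param fit a `wb_bayes_ridge`.
#' @param df degrees of freedom; default `fit$n - fit$d_model`.
#' @return list with `t_stat` and `p_value`.
#' @export
bayesian_t_test <- function(fit, df = NULL) {
  stopifnot(inherits(fit, "wb_bayes_ridge"))
  if (is.null(df)) df <- fit$n - fit$d_model
  t_test(fit$treatment_coef, fit$treatment_posterior_sd, df)
}

#' Symmetric confidence interval for a standardized effect
#'
#' `beta_std` plus/minus the two-sided critical value times `se_std`.  The
#' normal quantile is the default; at the cohort sizes this package targets
#' (thousands of rows) the t quantile is indistinguishable to 4 decimals.
#'
#' @param beta_std,se_std standardized effect and standard error.
#' @param level coverage level in (0, 1).
#' @param df degrees of freedom, used only when `use_t = TRUE`.
#' @param use_t use the t critical value instead of the normal one.
#' @return list with `ci_low` and `ci_high`.
#' @export
confidence_interval <- function(beta_std, se_std, level = 0.95, df = Inf,
                                use_t = FALSE) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  if (se_std < 0) stop("se_std must be non-negative", call. = FALSE)
  q <- if (use_t) stats::qt(1 - (1 - level) / 2, df)
       else stats::qnorm(1 - (1 - level) / 2)
  list(ci_low = beta_std - q * se_std, ci_high = beta_std + q * se_std)
}

#' Assemble the full effect estimate for a linear-in-treatment fit
#'
#' Pulls the unstandardized coefficient and its uncertainty from the fit
#' (OLS-style for the two-stage model, posterior SD for the Bayesian ridge,
#' robust slope s.e. for DML), standardizes by the outcome SD, and returns
#' one effect-table row.
#'
#' @param fit a `wb_two_stage`, `wb_bayes_ridge` or `wb_dml`.
#' @param dm the `wb_design` the fit was computed on.
#' @param level interval coverage (default 0.95).
#' @param cv_rmse optional cross-validated RMSE to carry along (NA for DML,
#'   mirroring how its rows are reported).
#' @return object of class `wb_effect` (also a one-row data frame): `beta`,
#'   `beta_std`, `se_std`, `t_stat`, `df`, `p_value`, `ci_low`, `ci_high`,
#'   `n`, `model_kind`, `cv_rmse`.
#' @export
effect_estimate <- function(fit, dm, level = 0.95, cv_rmse = NA_real_) {
  stopifnot(inherits(dm, "wb_design"))
  if (inherits(fit, "wb_two_stage")) {
    beta <- fit$treatment_coef
    df <- fit$n - fit$d_model
    se <- ols_se_treatment(fit, df)
  } else if (inherits(fit, "wb_bayes_ridge")) {
    beta <- fit$treatment_coef
    df <- fit$n - fit$d_model
    se <- fit$treatment_posterior_sd
  } else if (inherits(fit, "wb_dml")) {
    beta <- fit$treatment_coef
    df <- fit$n - 2L          # residual-on-residual slope + intercept
    se <- fit$treatment_se
  } else {
    stop("effect_estimate needs a linear-in-treatment fit", call. = FALSE)
  }
  std <- standardize_effect(beta, se, dm$s_y)
  tt <- t_test(beta, se, df)
  ci <- confidence_interval(std$beta_std, std$se_std, level)
  out <- data.frame(beta = beta, beta_std = std$beta_std,
                    se_std = std$se_std, t_stat = tt$t_stat, df = df,
                    p_value = tt$p_value, ci_low = ci$ci_low,
                    ci_high = ci$ci_high, n = dm$n,
                    model_kind = fit$model_kind, cv_rmse = cv_rmse)
  class(out) <- c("wb_effect", class(out))
  out
}
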