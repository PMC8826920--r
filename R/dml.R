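#' Double machine learning with cross-fitting
#'
#' Orthogonalized effect estimation: flexible nuisance regressions predict
#' the treatment and the outcome from the controls with out-of-fold
#' (cross-fitted) predictions; the effect is the no-intercept slope of the
#' centered outcome residuals on the centered treatment residuals, with a
#' heteroscedasticity-robust (HC0) standard error.  Folds are school
#' stratified so school-level controls cannot leak across folds.
#'
#' @param dm a `wb_design`.
#' @param n_folds number of cross-fitting folds (>= 2).
#' @param nuisance `"boosting"` (gradient-boosted trees, the default),
#'   `"ridge"` (linear ridge), or `"zero"` (the degenerate zero function,
#'   which collapses the estimator to the simple regression slope) for both
#'   nuisance regressions.
#' @param nuisance_params named list of parameters for the nuisance learner:
#'   for boosting `n_trees`, `max_depth`, `learning_rate`; for ridge
#'   `lambda`.
#' @param seed integer seed for the fold split.
#' @return object of classes `wb_dml` and `wb_surface`: `treatment_coef`,
#'   `treatment_se` (robust), out-of-fold residuals `t_resid`/`y_resid`, the
#'   fold plan, and full-data nuisance fits used by the prediction contract
#'   `f(x, t) = h(x) + beta (t - g(x))`.
#' @export
fit_dml <- function(dm, n_folds = 5L,
                    nuisance = c("boosting", "ridge", "zero"),
                    nuisance_params = list(), seed = 1L) {
  stopifnot(inherits(dm, "wb_design"), n_folds >= 2)
  nuisance <- match.arg(nuisance)
  plan <- school_stratified_folds(dm$school_id, n_folds, seed = seed)
  sizes <- tabulate(plan$assignment, n_folds)
  if (any(sizes < 5))
    stop("a cross-fitting fold has fewer than 5 rows; reduce n_folds",
         call. = FALSE)

  p <- utils::modifyList(list(n_trees = 100L, max_depth = 3L,
                              learning_rate = 0.1, lambda = 1.0),
                         nuisance_params)
  fit_nuis <- function(X, target) {
    if (nuisance == "zero") {
      NULL
    } else if (nuisance == "ridge") {
      ridge_fit(X, target, p$lambda, intercept = TRUE)
    } else {
      sub <- structure(list(X = X, t = rep(0, nrow(X)), y = target,
                            n = nrow(X)), class = "wb_design")
      fit_gradient_boosting(sub, n_trees = p$n_trees,
                            max_depth = p$max_depth,
                            learning_rate = p$learning_rate)
    }
  }
  pred_nuis <- function(fit, X) {
    if (nuisance == "zero") rep(0, nrow(X))
    else if (nuisance == "ridge") drop(cbind(1, X) %*% fit$coef)
    else stats::predict(fit, X, t = rep(0, nrow(X)))
  }

  t_hat <- y_hat <- numeric(dm$n)
  for (k in seq_len(n_folds)) {
    hold <- which(plan$assignment == k)
    train <- which(plan$assignment != k)
    gfit <- fit_nuis(dm$X[train, , drop = FALSE], dm$t[train])
    hfit <- fit_nuis(dm$X[train, , drop = FALSE], dm$y[train])
    t_hat[hold] <- pred_nuis(gfit, dm$X[hold, , drop = FALSE])
    y_hat[hold] <- pred_nuis(hfit, dm$X[hold, , drop = FALSE])
  }
  t_res <- dm$t - t_hat; t_res <- t_res - mean(t_res)
  y_res <- dm$y - y_hat; y_res <- y_res - mean(y_res)
  stt <- sum(t_res^2)
  if (stt == 0) stop("degenerate treatment residuals in DML", call. = FALSE)
  beta <- sum(t_res * y_res) / stt
  eps <- y_res - beta * t_res
  se <- sqrt(sum(t_res^2 * eps^2)) / stt      # HC0 sandwich slope s.e.

  g_full <- fit_nuis(dm$X, dm$t)
  h_full <- fit_nuis(dm$X, dm$y)

  structure(list(treatment_coef = beta, treatment_se = se,
                 t_resid = t_res, y_resid = y_res,
                 n_crossfit_folds = n_folds, fold_plan = plan,
                 nuisance = nuisance, nuisance_params = p,
                 g_full = g_full, h_full = h_full,
                 pred_nuis = pred_nuis,
                 n = dm$n, model_kind = "dml"),
            class = c("wb_dml", "wb_surface"))
}

#' @export
predict.wb_dml <- function(object, X, t, ...) {
  X <- as.matrix(X)
  if (length(t) == 1) t <- rep(t, nrow(X))
  g <- object$pred_nuis(object$g_full, X)
  h <- object$pred_nuis(object$h_full, X)
  h + object$treatment_coef * (t - g)
}
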