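#' Plugin partial-dependence curve of E[Y | do(T = t)]
#'
#' For each treatment grid value t, averages the fitted response surface
#' over the empirical control distribution: \eqn{(1/N) \sum_i f(x_i, t)}.
#' Under the package's structural assumptions this is the plugin estimate of
#' the interventional mean E[Y | do(T = t)]; for a linear-in-treatment model
#' it collapses to \eqn{\beta t + c}.
#'
#' @param model a fitted response surface (any `wb_surface`).
#' @param dm the `wb_design` whose rows define the mixing distribution.
#' @param grid treatment grid (standardized units); default `n_points`
#'   evenly spaced values across the observed treatment range.
#' @param n_points grid size when `grid` is `NULL`.
#' @return object of class `wb_pd_curve`: `grid`, `mean_curve`,
#'   `bootstrap_curves` (`NULL` here), `treatment_density` (histogram of the
#'   observed treatment), `B = 0`.
#' @export
partial_dependence <- function(model, dm, grid = NULL, n_points = 50L) {
  stopifnot(inherits(dm, "wb_design"))
  if (is.null(grid))
    grid <- seq(min(dm$t), max(dm$t), length.out = n_points)
  if (length(grid) == 0) stop("empty treatment grid", call. = FALSE)
  mean_curve <- vapply(grid, function(t0)
    mean(stats::predict(model, dm$X, rep(t0, dm$n))), numeric(1))
  structure(list(grid = grid, mean_curve = mean_curve,
                 bootstrap_curves = NULL,
                 treatment_density = graphics::hist(dm$t, breaks = 30,
                                                    plot = FALSE),
                 B = 0L),
            class = "wb_pd_curve")
}

#' Bootstrap partial-dependence curves with re-imputation
#'
#' Resamples cohort rows with replacement, re-runs imputation and encoding
#' on each resample (so single imputation inside the bootstrap acts as a
#' simplified multiple-imputation scheme), refits the model with *fixed*
#' hyperparameters, and recomputes the PD curve on a common grid.  The mean
#' curve is the pointwise mean of the replicates.  Replicates whose refit
#' fails on a degenerate resample are dropped and counted.
#'
#' @param cohort a `wb_cohort` (raw, pre-imputation).
#' @param treatment,outcome,extra_controls as in [build_design()].
#' @param family model family name (see [grid_search()]).
#' @param params fixed hyperparameters for the refits (select them first
#'   with [grid_search()]).
#' @param grid treatment grid in standardized units of the *full-sample*
#'   treatment; default 50 points over the full-sample range.  Replicates
#'   reuse the full-sample treatment values for their resampled rows, so
#'   every curve shares this grid's scale.
#' @param B number of bootstrap replicates (>= 2; 50 by default).
#' @param seed integer seed driving the resampling.
#' @return a `wb_pd_curve` with `bootstrap_curves` (achieved-B x grid
#'   matrix), `mean_curve` their pointwise mean, `B` the achieved count, and
#'   `n_failed`.
#' @export
bootstrap_pd <- function(cohort, treatment = "wellbeing_index",
                         outcome = "outcome_numeracy",
                         extra_controls = character(),
                         family = "two_stage", params = list(),
                         grid = NULL, B = 50L, seed = 1L) {
  stopifnot(inherits(cohort, "wb_cohort"))
  if (B < 2) stop("B must be >= 2", call. = FALSE)
  dm0 <- build_design(cohort, treatment, outcome, extra_controls)
  if (is.null(grid))
    grid <- seq(min(dm0$t), max(dm0$t), length.out = 50L)

  base <- cohort$data[dm0$rows, , drop = FALSE]
  curves <- matrix(NA_real_, nrow = B, ncol = length(grid))
  set.seed(seed)
  boot_seeds <- sample.int(2^31 - 2, B)
  n_failed <- 0L
  for (b in seq_len(B)) {
    set.seed(boot_seeds[b])
    idx <- sample.int(nrow(base), replace = TRUE)
    res <- tryCatch({
      bco <- structure(list(data = base[idx, , drop = FALSE],
                            control_spec = cohort$control_spec,
                            config = cohort$config), class = "wb_cohort")
      dmb <- build_design(bco, treatment, outcome, extra_controls)
      # replicate rows are resampled base rows: reuse the full-sample
      # treatment values so every curve lives on one treatment scale
      # (imputation and the model refit still vary per replicate)
      dmb$t <- dm0$t[idx][dmb$rows]
      fit <- fit_family(family, dmb, params)
      vapply(grid, function(t0)
        mean(stats::predict(fit, dmb$X, rep(t0, dmb$n))), numeric(1))
    }, error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L else curves[b, ] <- res
  }
  ok <- !is.na(curves[, 1])
  if (sum(ok) < 2)
    stop("fewer than 2 bootstrap replicates succeeded", call. = FALSE)
  curves <- curves[ok, , drop = FALSE]
  structure(list(grid = grid, mean_curve = colMeans(curves),
                 bootstrap_curves = curves,
                 treatment_density = graphics::hist(dm0$t, breaks = 30,
                                                    plot = FALSE),
                 B = nrow(curves), n_failed = n_failed),
            class = "wb_pd_curve")
}

#' Write PD curves to long CSV
#'
#' Format: `model,replicate_id,t,expected_outcome`, with `replicate_id = 0`
#' holding the mean curve.
#'
#' @param pd a `wb_pd_curve`.
#' @param model model label for the first column.
#' @param path output path.
#' @export
pd_to_csv <- function(pd, model, path) {
  rows <- data.frame(model = model, replicate_id = 0L, t = pd$grid,
                     expected_outcome = pd$mean_curve)
  if (!is.null(pd$bootstrap_curves)) {
    for (b in seq_len(nrow(pd$bootstrap_curves)))
      rows <- rbind(rows, data.frame(model = model, replicate_id = b,
                                     t = pd$grid,
                                     expected_outcome =
                                       pd$bootstrap_curves[b, ]))
  }
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
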