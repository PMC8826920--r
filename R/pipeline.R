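#' Analysis run configuration
#'
#' Validates and normalizes the settings for [run_analysis()].  Can also be
#' loaded from a YAML or JSON file with [read_run_config()].
#'
#' @param treatments character vector of treatment definitions:
#'   `"wellbeing_index"` and/or subscale column names.
#' @param outcomes outcome columns (default both Numeracy and Reading).
#' @param models subset of `c("bayesian_ridge", "kernel_bayesian",
#'   "two_stage", "boosting", "dml")`.
#' @param extra_controls_per_treatment named list mapping a treatment to
#'   extra columns to adjust for (e.g. hold depression fixed when anxiety is
#'   the treatment).
#' @param grids named list of hyperparameter grids per model family; each a
#'   list of parameter lists.  Missing entries use single-point default
#'   grids.
#' @param K cross-validation folds for grid search (default 5).
#' @param B bootstrap replicates for PD uncertainty (default 50).
#' @param pd_points PD grid size (default 50).
#' @param bootstrap_models families whose PD curves get bootstrap bands
#'   (default all requested models); `character()` skips the bootstrap.
#' @param seed integer seed (mandatory); drives folds, landmark draws and
#'   bootstrap resampling.
#' @return list of class `wb_run_config`.
#' @export
run_config <- function(treatments = "wellbeing_index",
                       outcomes = c("outcome_numeracy", "outcome_reading"),
                       models = c("bayesian_ridge", "two_stage", "dml"),
                       extra_controls_per_treatment = list(),
                       grids = list(), K = 5L, B = 50L, pd_points = 50L,
                       bootstrap_models = models, seed = NULL) {
  if (is.null(seed)) stop("seed is mandatory in run_config", call. = FALSE)
  known <- c("bayesian_ridge", "kernel_bayesian", "two_stage", "boosting",
             "dml")
  bad <- setdiff(models, known)
  if (length(bad)) stop("unknown models: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(treatments = treatments, outcomes = outcomes,
                 models = models,
                 extra_controls_per_treatment = extra_controls_per_treatment,
                 grids = grids, K = as.integer(K), B = as.integer(B),
                 pd_points = as.integer(pd_points),
                 bootstrap_models = intersect(bootstrap_models, models),
                 seed = as.integer(seed)),
            class = "wb_run_config")
}

#' Read a run configuration from YAML or JSON
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$treatments <- unlist(cfg$treatments)
  cfg$outcomes <- unlist(cfg$outcomes)
  cfg$models <- unlist(cfg$models)
  do.call(run_config, cfg)
}

# default single-point grids per family; kernel length-scales use the
# median heuristic when bandwidth is NULL
.default_grids <- function() list(
  bayesian_ridge = list(list()),
  kernel_bayesian = list(list(n_landmarks = 300L)),
  two_stage = list(list(lambda1 = 1, lambda2 = 1, n_landmarks = 300L)),
  boosting = list(list(n_trees = 300L, max_depth = 3L, learning_rate = 0.1)),
  dml = list(list(n_folds = 5L, nuisance = "boosting"))
)

.log_line <- function(log, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%OS1"),
                  sprintf(...))
  message(line)
  c(log, line)
}

#' Run the full sensitivity analysis over treatments, outcomes and models
#'
#' For every (treatment, outcome, model) cell: restricts to rows with the
#' treatment and outcome observed, imputes and encodes the controls, selects
#' hyperparameters by school-stratified cross-validation (recording the CV
#' RMSE; reported as NA for DML), fits the model on the full cell, computes
#' the standardized effect with its conservative t-test for the
#' linear-in-treatment families, and computes the PD curve (with bootstrap
#' re-imputation bands for the families requested).  Deterministic under the
#' config seed.
#'
#' @param cohort a `wb_cohort`.
#' @param config a `wb_run_config`.
#' @return list with `effect_table` (one row per linear-in-treatment cell,
#'   Table-style columns `target, model, n, beta_std, ci_low, ci_high,
#'   se_std, p_value, cv_rmse`), `pd_curves` (long data frame across all
#'   cells), and `log` (character vector of stage lines).
#' @export
run_analysis <- function(cohort, config) {
  stopifnot(inherits(cohort, "wb_cohort"), inherits(config, "wb_run_config"))
  linear_models <- c("bayesian_ridge", "two_stage", "dml")
  grids <- utils::modifyList(.default_grids(), config$grids)
  log <- character()
  effect_rows <- list()
  pd_rows <- list()
  log <- .log_line(log, "run_analysis: %d treatments x %d outcomes x %d models, seed=%d",
                   length(config$treatments), length(config$outcomes),
                   length(config$models), config$seed)

  for (tr in config$treatments) for (out in config$outcomes) {
    extra <- unlist(config$extra_controls_per_treatment[[tr]]) %||% character()
    dm <- build_design(cohort, tr, out, extra)
    log <- .log_line(log, "cell %s -> %s: %d rows, %d encoded controls",
                     tr, out, dm$n, ncol(dm$X))
    plan <- school_stratified_folds(dm$school_id, config$K,
                                    seed = config$seed)
    for (fam in config$models) {
      if (fam == "dml") {
        best <- grids$dml[[1]]
        best$seed <- config$seed
        cv <- NA_real_                     # reported NA for DML rows
      } else {
        grid <- lapply(grids[[fam]], function(p) { p$seed <- config$seed; p })
        gs <- grid_search(fam, grid, dm, plan)
        best <- gs$best_params
        cv <- gs$cv_rmse
      }
      fit <- fit_family(fam, dm, best)
      log <- .log_line(log, "  %s: fitted (cv_rmse=%s)", fam,
                       formatC(cv, digits = 4, format = "fg"))
      if (fam %in% linear_models) {
        eff <- effect_estimate(fit, dm, cv_rmse = cv)
        effect_rows[[length(effect_rows) + 1L]] <- data.frame(
          target = out, model = fam, n = dm$n, beta_std = eff$beta_std,
          ci_low = eff$ci_low, ci_high = eff$ci_high, se_std = eff$se_std,
          p_value = eff$p_value, cv_rmse = cv, treatment = tr,
          beta = eff$beta)
      }
      pd <- if (fam %in% config$bootstrap_models && config$B >= 2) {
        bootstrap_pd(cohort, tr, out, extra, family = fam, params = best,
                     B = config$B, seed = config$seed)
      } else partial_dependence(fit, dm, n_points = config$pd_points)
      cell <- data.frame(treatment = tr, target = out, model = fam,
                         replicate_id = 0L, t = pd$grid,
                         expected_outcome = pd$mean_curve)
      if (!is.null(pd$bootstrap_curves))
        for (b in seq_len(nrow(pd$bootstrap_curves)))
          cell <- rbind(cell, data.frame(treatment = tr, target = out,
                                         model = fam, replicate_id = b,
                                         t = pd$grid,
                                         expected_outcome =
                                           pd$bootstrap_curves[b, ]))
      pd_rows[[length(pd_rows) + 1L]] <- cell
      log <- .log_line(log, "  %s: PD curve done (B=%d)", fam,
                       if (is.null(pd$B)) 0L else pd$B)
    }
  }
  effect_table <- if (length(effect_rows)) do.call(rbind, effect_rows)
    else data.frame()
  pd_curves <- if (length(pd_rows)) do.call(rbind, pd_rows)
    else data.frame()
  list(effect_table = effect_table, pd_curves = pd_curves, log = log)
}

#' Translate a standardized effect into outcome points and percent of the
#' average prior-to-outcome gain
#'
#' @param effect a `wb_effect` row (or anything with `beta_std`).
#' @param s_y sample SD of the outcome.
#' @param mean_gain average outcome-minus-prior gain in points (> 0).
#' @return list with `points` (`beta_std * s_y`) and `percent`
#'   (`100 * points / mean_gain`).
#' @export
summarize_in_points <- function(effect, s_y, mean_gain) {
  if (mean_gain <= 0) stop("mean_gain must be positive", call. = FALSE)
  beta_std <- if (is.list(effect) || is.data.frame(effect))
    effect$beta_std else effect
  points <- beta_std * s_y
  list(points = points, percent = 100 * points / mean_gain)
}

#' Replicated parameter-recovery experiment
#'
#' Generates `n_reps` cohorts from `base_config` (varying only the seed),
#' estimates the treatment effect with each requested estimator, and
#' reports per-replicate estimates, standard errors, and whether the
#' estimate fell within `z * se` of the generating truth.
#'
#' @param base_config a [simulation_config()]; its `true_ate` is the truth.
#' @param estimators named list mapping an estimator label to a list with
#'   `family` and `params` (see [fit_family()] families).
#' @param n_reps replicate count.
#' @param treatment,outcome columns to analyse.
#' @param z half-width of the recovery band in standard errors (default 2).
#' @param seed master seed; replicate r uses cohort seed `seed + r`.
#' @return data frame with one row per (replicate, estimator): `estimate`,
#'   `se`, `truth`, `error`, `covered`.
#' @export
recover_params <- function(base_config, estimators, n_reps = 100L,
                           treatment = "wellbeing_index",
                           outcome = "outcome_numeracy", z = 2, seed = 1L) {
  stopifnot(inherits(base_config, "simulation_config"))
  rows <- list()
  for (r in seq_len(n_reps)) {
    cfg <- base_config
    cfg$seed <- as.integer((seed + 7919 * r) %% 2147483629)
    sim <- generate_cohort(cfg)
    dm <- build_design(sim$cohort, treatment, outcome)
    for (lab in names(estimators)) {
      est <- estimators[[lab]]
      fit <- fit_family(est$family, dm, est$params %||% list())
      se <- if (inherits(fit, "wb_two_stage")) ols_se_treatment(fit)
        else if (inherits(fit, "wb_dml")) fit$treatment_se
        else if (inherits(fit, "wb_bayes_ridge")) fit$treatment_posterior_sd
        else NA_real_
      beta <- fit$treatment_coef
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, estimator = lab, estimate = beta, se = se,
        truth = cfg$true_ate, error = beta - cfg$true_ate,
        covered = is.finite(se) && abs(beta - cfg$true_ate) <= z * se)
    }
  }
  do.call(rbind, rows)
}
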