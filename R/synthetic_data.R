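#' Configuration for the synthetic school-cohort generator
#'
#' Bundles and validates every knob of the structural model used by
#' [generate_cohort()].  Defaults mirror the observational study the
#' generator emulates: 7887 students across 19 high schools, a ~50% survey
#' match rate, just-over-80% participation per standardized test, an average
#' grade-7-to-9 Numeracy gain of 42.52 points, and 40 raw control variables
#' that expand to roughly 141 encoded columns.
#'
#' @param n_students number of student rows.
#' @param n_schools number of schools (>= 2).
#' @param true_ate true causal effect, in outcome points per 1 SD of the
#'   latent well-being treatment.
#' @param confounding_strength unitless >= 0; scales every edge from the
#'   controls (and the ability/school factors behind them) into both the
#'   treatment and the outcome.  0 gives an unconfounded cohort.
#' @param nonlinear_outcome add smooth quadratic + interaction terms to the
#'   controls -> outcome baseline.
#' @param nonlinear_treatment add the matching quadratic + interaction terms
#'   to the controls -> latent-well-being map (shared terms, so linear
#'   adjustment cannot remove the confounding they carry).
#' @param outcome_noise_sd outcome noise SD in test-score points.
#' @param treatment_noise_sd SD of the exogenous part of latent well-being.
#' @param subscale_noise_sd measurement noise of the three survey subscales,
#'   as a fraction of each subscale's loading on latent well-being.  Set to 0
#'   to make the composite index recover the latent treatment exactly
#'   (useful for parameter-recovery experiments).
#' @param survey_match_rate probability a student's well-being survey is
#'   matched (row-level availability of the three subscales).
#' @param test_participation_rate per-test probability an outcome score is
#'   observed (applied independently to Numeracy and Reading).
#' @param control_missing_rate per-cell missingness rate of the controls and
#'   the prior score.
#' @param control_missing_mechanism `"MCAR"` (default) or `"MAR"`, where MAR
#'   ties the cell-missingness rate to the school effect.
#' @param mean_prior_gain expected value of outcome minus prior score, in
#'   points.
#' @param n_raw_controls number of raw control variables; roughly one third
#'   are generated as categoricals with 3--8 levels so that dummy + missing
#'   encoding expands toward ~141 columns.
#' @param seed integer master seed; the generator derives per-stage seeds
#'   from it (structure, noise, missingness) so the cohort is fully
#'   reproducible.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_students = 7887L, n_schools = 19L,
                              true_ate = 2.2, confounding_strength = 1,
                              nonlinear_outcome = FALSE,
                              nonlinear_treatment = FALSE,
                              outcome_noise_sd = 35, treatment_noise_sd = 1,
                              subscale_noise_sd = 0.25,
                              survey_match_rate = 0.50,
                              test_participation_rate = 0.80,
                              control_missing_rate = 0.10,
                              control_missing_mechanism = c("MCAR", "MAR"),
                              mean_prior_gain = 42.52,
                              n_raw_controls = 40L, seed = 1L) {
  control_missing_mechanism <- match.arg(control_missing_mechanism)
  rates <- c(survey_match_rate = survey_match_rate,
             test_participation_rate = test_participation_rate,
             control_missing_rate = control_missing_rate)
  if (any(rates < 0 | rates > 1))
    stop("all rates must lie in [0, 1]", call. = FALSE)
  if (n_schools < 2) stop("n_schools must be >= 2", call. = FALSE)
  if (n_students < n_schools)
    stop("n_students must be >= n_schools", call. = FALSE)
  if (outcome_noise_sd < 0 || treatment_noise_sd < 0 || subscale_noise_sd < 0)
    stop("noise SDs must be non-negative", call. = FALSE)
  if (confounding_strength < 0)
    stop("confounding_strength must be >= 0", call. = FALSE)
  if (n_raw_controls < 3) stop("n_raw_controls must be >= 3", call. = FALSE)
  structure(list(
    n_students = as.integer(n_students), n_schools = as.integer(n_schools),
    true_ate = true_ate, confounding_strength = confounding_strength,
    nonlinear_outcome = isTRUE(nonlinear_outcome),
    nonlinear_treatment = isTRUE(nonlinear_treatment),
    outcome_noise_sd = outcome_noise_sd,
    treatment_noise_sd = treatment_noise_sd,
    subscale_noise_sd = subscale_noise_sd,
    survey_match_rate = survey_match_rate,
    test_participation_rate = test_participation_rate,
    control_missing_rate = control_missing_rate,
    control_missing_mechanism = control_missing_mechanism,
    mean_prior_gain = mean_prior_gain,
    n_raw_controls = as.integer(n_raw_controls),
    seed = as.integer(seed)), class = "simulation_config")
}

# deterministic per-stage seed sequence below 2^31
.stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 97 + 11) %% 2147483587) + 1L
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# fixed structural constants of the generator (points / SD units)
.GEN <- list(
  prior_intercept = 500, prior_ability = 60, prior_school = 15,
  prior_noise = 25, ability_wb = 0.4,
  sub_int = c(anxiety = 0.8, depression = 1.5, positive_affect = 4.0),
  sub_load = c(anxiety = -0.25, depression = -0.5, positive_affect = 0.8),
  sub_max = c(anxiety = 2, depression = 4, positive_affect = 7),
  cont_outcome_sd = 6, cont_treat_sd = 0.2, n_treat_controls = 10L,
  cat_effect_sd = 5,
  nl_outcome_coef = c(12, 12, 8), nl_treat_coef = c(0.35, 0.35)
)

#' Generate a synthetic student cohort with known causal ground truth
#'
#' Draws a cohort from a hierarchical structural causal model: a per-school
#' effect (observed as the first, school-level "climate" control column), a
#' latent student ability driving the grade-7 prior score, mixed
#' continuous/categorical controls, a latent well-being variable confounded
#' with the controls and ability, three bounded survey subscales loading on
#' it (anxiety and depression negatively, positive affect positively), and
#' grade-9 Numeracy/Reading outcomes equal to a confounded baseline plus
#' `true_ate` times the standardized latent well-being plus noise.  Survey
#' match, test participation and control missingness are then applied at the
#' configured rates.
#'
#' @param config a [simulation_config()].
#' @return a list with `cohort` (class `wb_cohort`: `$data` data frame with
#'   columns `student_id, school_id, anxiety, depression, positive_affect,
#'   prior_score, outcome_numeracy, outcome_reading, c01..cNN` and
#'   `$control_spec`) and `truth` (class `wb_true_params`: every generating
#'   coefficient plus the realized standardized latent treatment).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  g <- .GEN
  n <- config$n_students
  S <- config$n_schools
  cs <- config$confounding_strength

  ## ---- structure: coefficients, schools, controls -----------------------
  set.seed(.stage_seed(config$seed, 1L))
  n_cont <- ceiling(2 / 3 * config$n_raw_controls)
  n_cat <- config$n_raw_controls - n_cont
  n_school_lvl <- min(4L, n_cont)          # school-level continuous controls
  school_of <- sort(rep_len(seq_len(S), n))
  u <- stats::rnorm(S)                     # school effect, unit scale
  # school-level controls: col 1 IS the school effect (observed climate),
  # so the school -> outcome/treatment backdoor is blocked by the controls
  Xs <- cbind(u, matrix(stats::rnorm(S * (n_school_lvl - 1)), S))
  Xc <- cbind(Xs[school_of, , drop = FALSE],
              matrix(stats::rnorm(n * (n_cont - n_school_lvl)), n))
  colnames(Xc) <- sprintf("c%02d", seq_len(n_cont))

  cat_levels <- rep_len(3:8, max(n_cat, 1L))[seq_len(n_cat)]
  cats <- list(); cat_fx_num <- list(); cat_fx_read <- list()
  for (k in seq_len(n_cat)) {
    L <- cat_levels[k]
    lv <- paste0("l", seq_len(L))
    cats[[k]] <- factor(sample(lv, n, replace = TRUE), levels = lv)
    fx <- stats::rnorm(L, sd = g$cat_effect_sd)
    cat_fx_num[[k]] <- fx - mean(fx)
    fx2 <- stats::rnorm(L, sd = g$cat_effect_sd)
    cat_fx_read[[k]] <- fx2 - mean(fx2)
  }

  theta_y_num <- stats::rnorm(n_cont, sd = g$cont_outcome_sd)
  theta_y_read <- stats::rnorm(n_cont, sd = g$cont_outcome_sd)
  theta_t <- numeric(n_cont)
  idx_t <- c(1L, seq(n_school_lvl + 1L,
                     length.out = min(g$n_treat_controls,
                                      n_cont - n_school_lvl)))
  theta_t[idx_t] <- stats::rnorm(length(idx_t), sd = g$cont_treat_sd)

  ## ---- noise stage: ability, prior, treatment, outcomes -----------------
  set.seed(.stage_seed(config$seed, 2L))
  ability <- stats::rnorm(n)
  prior <- .clip(g$prior_intercept + g$prior_ability * ability +
                   g$prior_school * u[school_of] +
                   g$prior_noise * stats::rnorm(n), 0, 1000)

  nl_cols <- seq(max(1L, n_cont - 3L), n_cont)  # columns shared by both
  nl_cols <- rep_len(nl_cols, 4L)               # nonlinear maps
  nl_t <- nl_y_num <- nl_y_read <- 0
  if (config$nonlinear_treatment) {
    nl_t <- g$nl_treat_coef[1] * (Xc[, nl_cols[1]]^2 - 1) +
      g$nl_treat_coef[2] * Xc[, nl_cols[2]] * Xc[, nl_cols[3]]
  }
  if (config$nonlinear_outcome) {
    q <- g$nl_outcome_coef
    nl_y_num <- q[1] * (Xc[, nl_cols[1]]^2 - 1) +
      q[2] * Xc[, nl_cols[2]] * Xc[, nl_cols[3]] +
      q[3] * (Xc[, nl_cols[4]]^2 - 1)
    nl_y_read <- q[1] * (Xc[, nl_cols[4]]^2 - 1) +
      q[2] * Xc[, nl_cols[2]] * Xc[, nl_cols[3]] +
      q[3] * (Xc[, nl_cols[1]]^2 - 1)
  }

  wb_raw <- cs * (drop(Xc %*% theta_t) + g$ability_wb * ability + nl_t) +
    config$treatment_noise_sd * stats::rnorm(n)
  wb_mean <- mean(wb_raw)
  wb_sd <- stats::sd(wb_raw)
  if (!is.finite(wb_sd) || wb_sd == 0) wb_sd <- 1
  z <- (wb_raw - wb_mean) / wb_sd          # standardized latent treatment

  cat_sum <- function(fx) {
    if (n_cat == 0) return(0)
    Reduce(`+`, Map(function(f, eff) eff[as.integer(f)], cats, fx))
  }
  base_num <- (prior - g$prior_intercept) + drop(Xc %*% theta_y_num) +
    cat_sum(cat_fx_num) + nl_y_num
  base_read <- (prior - g$prior_intercept) + drop(Xc %*% theta_y_read) +
    cat_sum(cat_fx_read) + nl_y_read
  out_num <- .clip(g$prior_intercept + config$mean_prior_gain +
                     cs * base_num + config$true_ate * z +
                     config$outcome_noise_sd * stats::rnorm(n), 0, 1000)
  out_read <- .clip(g$prior_intercept + config$mean_prior_gain +
                      cs * base_read + config$true_ate * z +
                      config$outcome_noise_sd * stats::rnorm(n), 0, 1000)

  subscale <- function(name) {
    load <- g$sub_load[[name]]
    .clip(g$sub_int[[name]] + load * z +
            config$subscale_noise_sd * abs(load) * stats::rnorm(n),
          0, g$sub_max[[name]])
  }
  anxiety <- subscale("anxiety")
  depression <- subscale("depression")
  positive_affect <- subscale("positive_affect")

  ## ---- missingness ------------------------------------------------------
  set.seed(.stage_seed(config$seed, 3L))
  surveyed <- stats::runif(n) < config$survey_match_rate
  anxiety[!surveyed] <- NA_real_
  depression[!surveyed] <- NA_real_
  positive_affect[!surveyed] <- NA_real_
  out_num[stats::runif(n) >= config$test_participation_rate] <- NA_real_
  out_read[stats::runif(n) >= config$test_participation_rate] <- NA_real_

  miss_rate <- rep(config$control_missing_rate, n)
  if (config$control_missing_mechanism == "MAR" &&
      config$control_missing_rate > 0) {
    # school-keyed MAR: worse-climate schools lose more cells
    miss_rate <- .clip(config$control_missing_rate *
                         (1 - 0.8 * tanh(u[school_of])), 0, 1)
  }
  controls <- as.data.frame(Xc)
  for (k in seq_len(n_cat)) controls[[sprintf("c%02d", n_cont + k)]] <- cats[[k]]
  if (config$control_missing_rate > 0) {
    for (j in seq_along(controls)) {
      controls[[j]][stats::runif(n) < miss_rate] <- NA
    }
    prior[stats::runif(n) < miss_rate] <- NA_real_
  }

  pairs_ok <- min(sum(surveyed & !is.na(out_num)),
                  sum(surveyed & !is.na(out_read)))
  if (pairs_ok < 10)
    stop("missingness leaves fewer than 10 complete treatment/outcome pairs",
         call. = FALSE)

  data <- data.frame(
    student_id = sprintf("s%05d", seq_len(n)),
    school_id = sprintf("sch%02d", school_of),
    anxiety = anxiety, depression = depression,
    positive_affect = positive_affect,
    prior_score = prior,
    outcome_numeracy = out_num, outcome_reading = out_read,
    controls, stringsAsFactors = FALSE, check.names = FALSE)

  control_spec <- stats::setNames(
    c(rep("continuous", n_cont), rep("categorical", n_cat)),
    sprintf("c%02d", seq_len(n_cont + n_cat)))

  cohort <- structure(list(data = data,
                           control_spec = as.list(control_spec),
                           config = config),
                      class = "wb_cohort")
  truth <- structure(list(
    true_ate = config$true_ate,
    school_effects = stats::setNames(u, sprintf("sch%02d", seq_len(S))),
    control_coefficients = list(
      prior = cs, continuous_numeracy = theta_y_num,
      continuous_reading = theta_y_read,
      categorical_numeracy = cat_fx_num,
      categorical_reading = cat_fx_read,
      nonlinear_outcome = if (config$nonlinear_outcome) g$nl_outcome_coef,
      nonlinear_treatment = if (config$nonlinear_treatment) g$nl_treat_coef),
    treatment_coefficients = list(
      continuous = cs * theta_t, continuous_raw = theta_t,
      ability = cs * g$ability_wb),
    structural = list(prior_ability = g$prior_ability,
                      prior_school = g$prior_school,
                      prior_noise = g$prior_noise,
                      treatment_noise_sd = config$treatment_noise_sd,
                      wb_mean = wb_mean, wb_sd = wb_sd),
    latent_treatment = z,
    seed = config$seed), class = "wb_true_params")
  list(cohort = cohort, truth = truth)
}

#' Closed-form naive (unadjusted) regression slope implied by the generator
#'
#' For a fully linear cohort, the population slope of outcome on the
#' standardized latent treatment without any adjustment is the true effect
#' plus the omitted-variable bias carried by the ability, school, and shared
#' control paths.  Computed analytically from the stored generating
#' coefficients; used to check the generator's confounding calibration
#' against a large-n empirical regression.
#'
#' @param truth a `wb_true_params` object from a linear cohort.
#' @param outcome `"numeracy"` or `"reading"`.
#' @return the population slope, in outcome points per SD of treatment.
#' @export
naive_slope_truth <- function(truth, outcome = c("numeracy", "reading")) {
  outcome <- match.arg(outcome)
  g <- .GEN
  st <- truth$structural
  cs <- truth$control_coefficients$prior   # = confounding_strength
  theta_t <- truth$treatment_coefficients$continuous_raw
  theta_y <- if (outcome == "numeracy")
    truth$control_coefficients$continuous_numeracy else
      truth$control_coefficients$continuous_reading
  kappa <- g$ability_wb
  # cov(non-treatment outcome part, raw latent wb), population version
  cov_num <- cs^2 * (st$prior_ability * kappa +
                       st$prior_school * theta_t[1] +
                       sum(theta_y * theta_t))
  sd_raw <- sqrt(cs^2 * (sum(theta_t^2) + kappa^2) + st$treatment_noise_sd^2)
  truth$true_ate + cov_num / sd_raw
}

#' @export
print.wb_cohort <- function(x, ...) {
  d <- x$data
  cat(sprintf("synthetic student cohort: %d students, %d schools, %d controls\n",
              nrow(d), length(unique(d$school_id)), length(x$control_spec)))
  cat(sprintf("  survey observed: %d; numeracy observed: %d; reading observed: %d\n",
              sum(!is.na(d$anxiety)), sum(!is.na(d$outcome_numeracy)),
              sum(!is.na(d$outcome_reading))))
  invisible(x)
}
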