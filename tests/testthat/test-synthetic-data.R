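test_that("config validation rejects bad rates, school counts and noise", {
  expect_error(simulation_config(survey_match_rate = 1.2), "rates")
  expect_error(simulation_config(control_missing_rate = -0.1), "rates")
  expect_error(simulation_config(n_schools = 1), "n_schools")
  expect_error(simulation_config(n_students = 5, n_schools = 10),
               "n_students")
  expect_error(simulation_config(outcome_noise_sd = -1), "noise")
  expect_error(simulation_config(confounding_strength = -0.5),
               "confounding")
})

test_that("fixed seed gives identical cohorts; different seeds differ", {
  cfg <- simulation_config(n_students = 300, n_schools = 5, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cohort$data, b$cohort$data)
  expect_identical(a$truth$latent_treatment, b$truth$latent_treatment)
  cfg2 <- simulation_config(n_students = 300, n_schools = 5, seed = 8)
  expect_false(identical(generate_cohort(cfg2)$cohort$data, a$cohort$data))
})

test_that("noiseless unconfounded cohort: slope of outcome on latent equals true_ate", {
  cfg <- simulation_config(n_students = 500, n_schools = 5, true_ate = 3.7,
                           confounding_strength = 0, outcome_noise_sd = 0,
                           subscale_noise_sd = 0, survey_match_rate = 1,
                           test_participation_rate = 1,
                           control_missing_rate = 0, seed = 3)
  sim <- generate_cohort(cfg)
  z <- sim$truth$latent_treatment
  y <- sim$cohort$data$outcome_numeracy
  slope <- stats::cov(y, z) / stats::var(z)
  expect_equal(slope, 3.7, tolerance = 1e-10)
})

test_that("naive regression bias matches the closed-form omitted-variable bias", {
  cfg <- simulation_config(n_students = 200000, n_schools = 500,
                           true_ate = 2.2, subscale_noise_sd = 0,
                           survey_match_rate = 1,
                           test_participation_rate = 1,
                           control_missing_rate = 0, seed = 1)
  sim <- generate_cohort(cfg)
  z <- sim$truth$latent_treatment
  y <- sim$cohort$data$outcome_numeracy
  emp <- stats::cov(y, z) / stats::var(z)
  pred <- naive_slope_truth(sim$truth)
  # the confounding is material (bias of many points) ...
  expect_gt(abs(pred - 2.2), 5)
  # ... and the large-n empirical slope matches the analytic prediction
  # (tolerance ~3x the Monte-Carlo error of the school-level moments)
  expect_lt(abs(emp - pred), 1.0)
})

test_that("subscales respect instrument ranges and missingness rates multiply", {
  cfg <- simulation_config(n_students = 7887, n_schools = 19, seed = 5)
  sim <- generate_cohort(cfg)
  d <- sim$cohort$data
  expect_true(all(d$anxiety >= 0 & d$anxiety <= 2, na.rm = TRUE))
  expect_true(all(d$depression >= 0 & d$depression <= 4, na.rm = TRUE))
  expect_true(all(d$positive_affect >= 0 & d$positive_affect <= 7,
                  na.rm = TRUE))
  expect_true(all(d$prior_score >= 0 & d$prior_score <= 1000, na.rm = TRUE))
  expect_true(all(d$outcome_numeracy >= 0 & d$outcome_numeracy <= 1000,
                  na.rm = TRUE))
  # 0.5 survey x 0.8 test => ~0.4 of rows have treatment and outcome
  frac <- mean(!is.na(d$anxiety) & !is.na(d$outcome_numeracy))
  se <- sqrt(0.4 * 0.6 / nrow(d))
  expect_lt(abs(frac - 0.4), 4 * se)
})

test_that("mean outcome-minus-prior gain approaches the configured value", {
  cfg <- simulation_config(n_students = 20000, n_schools = 50, seed = 9,
                           control_missing_rate = 0)
  sim <- generate_cohort(cfg)
  d <- sim$cohort$data
  ok <- !is.na(d$outcome_numeracy)
  gain <- d$outcome_numeracy[ok] - d$prior_score[ok]
  expect_lt(abs(mean(gain) - 42.52), 3 * stats::sd(gain) / sqrt(sum(ok)))
})

test_that("generator rejects configs leaving too few complete pairs", {
  expect_error(generate_cohort(
    simulation_config(n_students = 60, n_schools = 2,
                      survey_match_rate = 0.02,
                      test_participation_rate = 0.1, seed = 2)),
    "fewer than 10")
})

test_that("cohort CSV round trip is lossless, including missing cells", {
  # handwritten 3-row cohort with one missing depression cell
  d <- data.frame(student_id = c("s1", "s2", "s3"),
                  school_id = c("A", "A", "B"),
                  anxiety = c(0.5, 1, 1.5),
                  depression = c(2, NA, 0.25),
                  positive_affect = c(6.5, 3, 4),
                  prior_score = c(512.25, 488, 530),
                  outcome_numeracy = c(540, 510.5, NA),
                  outcome_reading = c(NA, 500, 560),
                  c01 = c(1.25, -0.5, NA),
                  c02 = factor(c("a", NA, "b")),
                  stringsAsFactors = FALSE)
  co <- structure(list(data = d,
                       control_spec = list(c01 = "continuous",
                                           c02 = "categorical"),
                       config = NULL), class = "wb_cohort")
  path <- withr::local_tempfile(fileext = ".csv")
  cohort_to_csv(co, path)
  back <- csv_to_cohort(path)
  expect_identical(back$data$depression, d$depression)
  expect_identical(back$data$c01, d$c01)
  expect_identical(as.character(back$data$c02), as.character(d$c02))
  expect_identical(back$control_spec,
                   list(c01 = "continuous", c02 = "categorical"))

  # empty cohort: header-only file round trips
  co0 <- structure(list(data = d[0, ], control_spec = co$control_spec,
                        config = NULL), class = "wb_cohort")
  path0 <- withr::local_tempfile(fileext = ".csv")
  cohort_to_csv(co0, path0)
  back0 <- csv_to_cohort(path0)
  expect_equal(nrow(back0$data), 0)
  expect_identical(names(back0$data), names(d))

  # generated cohort (n=500): bitwise value/mask equality after round trip
  sim <- generate_cohort(simulation_config(n_students = 500, n_schools = 7,
                                           seed = 21))
  pathg <- withr::local_tempfile(fileext = ".csv")
  cohort_to_csv(sim$cohort, pathg)
  backg <- csv_to_cohort(pathg)
  for (nm in names(sim$cohort$data)) {
    orig <- sim$cohort$data[[nm]]
    got <- backg$data[[nm]]
    if (is.numeric(orig)) expect_identical(got, unname(orig))
    else expect_identical(as.character(got), as.character(orig))
  }
})

test_that("cohort CSV reader rejects bad schema and bad values", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("student_id,school_id,anxiety", path)
  expect_error(csv_to_cohort(path), "missing required columns")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(paste("student_id,school_id,anxiety,depression,",
                     "positive_affect,prior_score,outcome_numeracy,",
                     "outcome_reading,c01", sep = ""),
               "s1,A,oops,1,2,500,510,520,1.5"), path2)
  expect_error(csv_to_cohort(path2, control_spec = list(c01 = "continuous")),
               "non-numeric")
})
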