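# Shared fixtures built in code.

# Wrap raw matrices as a design (bypasses cohort plumbing for estimator
# unit tests).
make_design <- function(X, t, y, school_id = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(school_id)) school_id <- rep("schA", nrow(X))
  structure(list(X = X, t = as.numeric(t), y = as.numeric(y), n = nrow(X),
                 school_id = school_id, column_names = colnames(X),
                 s_y = stats::sd(y), s_t_raw = stats::sd(t),
                 t_center = 0, t_scale = 1,
                 treatment = "t", outcome = "y"),
            class = "wb_design")
}

# Small linear design with a confounded treatment, fixed seed.
toy_design <- function(n = 80, d = 4, seed = 42, beta = 2, noise = 0.5) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n)
  t <- drop(X %*% rep(0.4, d)) + rnorm(n)
  t <- (t - mean(t)) / sd(t)
  y <- 1 + beta * t + drop(X %*% seq_len(d)) + noise * rnorm(n)
  make_design(X, t, y, school_id = rep(c("schA", "schB"), length.out = n))
}

# Independent row-subsetting used by CV oracles (does not reuse the
# package's internal subsetting).
subset_design_oracle <- function(dm, idx) {
  make_design(dm$X[idx, , drop = FALSE], dm$t[idx], dm$y[idx],
              dm$school_id[idx])
}

# Generator config with no missingness and noiseless subscales: the
# composite index recovers the latent treatment, so `true_ate` is the exact
# estimand (used for recovery/null/bias experiments).
recovery_config <- function(n = 2000, true_ate = 35, seed = 1, ...) {
  simulation_config(n_students = n, n_schools = 19, true_ate = true_ate,
                    subscale_noise_sd = 0, survey_match_rate = 1,
                    test_participation_rate = 1, control_missing_rate = 0,
                    seed = seed, ...)
}
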