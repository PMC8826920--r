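#' Root mean squared error
#' @param pred,y equal-length numeric vectors.
#' @export
rmse <- function(pred, y) {
  stopifnot(length(pred) == length(y))
  sqrt(mean((pred - y)^2))
}

#' School-stratified K-fold assignment
#'
#' Within each school the rows are shuffled (seeded) and dealt round-robin
#' to the K folds, so every fold mirrors the school composition of the data
#' (per-school fold counts differ by at most 1).  Stratifying on school
#' prevents models from overfitting school-level control values and biasing
#' out-of-fold error estimates.  With `grouped = TRUE` whole schools are
#' instead assigned to folds (leave-schools-out mode).
#'
#' @param school_id per-row school labels.
#' @param K number of folds (>= 2, <= number of rows).
#' @param seed integer seed for the within-school shuffles.
#' @param grouped assign whole schools to folds instead of stratifying.
#' @return object of class `wb_fold_plan`: `n_folds`, `assignment` (per-row
#'   fold label in 1..K), `school_id`, `seed`.
#' @export
school_stratified_folds <- function(school_id, K, seed = 1L,
                                    grouped = FALSE) {
  n <- length(school_id)
  K <- as.integer(K)
  if (K < 2) stop("K must be >= 2", call. = FALSE)
  if (K > n) stop("K cannot exceed the number of rows", call. = FALSE)
  set.seed(seed)
  assignment <- integer(n)
  if (grouped) {
    schools <- sample(unique(school_id))
    fold_of_school <- stats::setNames(rep_len(seq_len(K), length(schools)),
                                      schools)
    assignment <- unname(fold_of_school[as.character(school_id)])
  } else {
    for (s in unique(school_id)) {
      rows <- which(school_id == s)
      rows <- if (length(rows) > 1) sample(rows) else rows
      assignment[rows] <- rep_len(seq_len(K), length(rows))
    }
  }
  structure(list(n_folds = K, assignment = assignment,
                 school_id = school_id, seed = as.integer(seed)),
            class = "wb_fold_plan")
}

#' Write a fold plan to CSV
#' @param plan a `wb_fold_plan`.
#' @param student_id per-row student identifiers.
#' @param path output path.
#' @export
fold_plan_to_csv <- function(plan, student_id, path) {
  utils::write.csv(data.frame(student_id = student_id,
                              fold = plan$assignment),
                   path, row.names = FALSE)
  invisible(path)
}

# Fit one model family on a design with a named parameter list.  The single
# dispatch point shared by grid search, bootstrap refits and the pipeline.
fit_family <- function(family, dm, params = list()) {
  params <- as.list(params)
  switch(family,
    bayesian_ridge = fit_bayesian_ridge(dm),
    kernel_bayesian = fit_kernel_bayesian(
      dm, n_landmarks = params$n_landmarks, bandwidth = params$bandwidth,
      seed = params$seed %||% 1L),
    two_stage = {
      map <- NULL
      if (!identical(params$feature_map %||% "kernel", "identity"))
        map <- nystroem_map(dm$X, n_landmarks = params$n_landmarks,
                            bandwidth = params$bandwidth,
                            seed = params$seed %||% 1L)
      fit_two_stage_ridge(dm, map = map,
                          lambda1 = params$lambda1 %||% 0.1,
                          lambda2 = params$lambda2 %||% 0.1)
    },
    boosting = fit_gradient_boosting(
      dm, n_trees = params$n_trees %||% 300L,
      max_depth = params$max_depth %||% 3L,
      learning_rate = params$learning_rate %||% 0.1),
    dml = fit_dml(dm, n_folds = params$n_folds %||% 5L,
                  nuisance = params$nuisance %||% "boosting",
                  nuisance_params = params$nuisance_params %||% list(),
                  seed = params$seed %||% 1L),
    direct_ridge = fit_direct_ridge(dm, lambda = params$lambda %||% 1),
    stop("unknown model family: ", family, call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# regularization strength used to break CV ties toward the smoother model
.reg_strength <- function(params) {
  if (!is.null(params$lambda2)) return(params$lambda2)
  if (!is.null(params$lambda)) return(params$lambda)
  if (!is.null(params$bandwidth)) return(params$bandwidth)
  if (!is.null(params$n_trees)) return(-params$n_trees)
  0
}

#' Grid search by school-stratified cross-validation
#'
#' For every point of the hyperparameter grid, fits the model family on each
#' training fold and records the mean out-of-fold RMSE; the winner is the
#' argmin, with ties broken toward stronger regularization and then grid
#' order.  Selection happens once, before any bootstrap resampling; the
#' winning point's CV RMSE is the value reported in effect tables.
#'
#' @param model_family one of `"bayesian_ridge"`, `"kernel_bayesian"`,
#'   `"two_stage"`, `"boosting"`, `"dml"`, `"direct_ridge"`.
#' @param grid list of named parameter lists (one per grid point); a single
#'   empty `list()` point evaluates the family defaults.
#' @param dm a `wb_design`.
#' @param fold_plan a `wb_fold_plan` over the rows of `dm`.
#' @return list with `best_params`, `cv_rmse`, and the full `table`
#'   (data frame of grid point vs mean out-of-fold RMSE).
#' @export
grid_search <- function(model_family, grid, dm, fold_plan) {
  stopifnot(inherits(dm, "wb_design"), inherits(fold_plan, "wb_fold_plan"))
  if (length(grid) == 0) stop("empty hyperparameter grid", call. = FALSE)
  if (!is.null(names(grid)) && !is.list(grid[[1]])) grid <- list(grid)
  K <- fold_plan$n_folds
  scores <- vapply(seq_along(grid), function(gi) {
    fold_rmse <- rep(NA_real_, K)
    for (k in seq_len(K)) {
      hold <- which(fold_plan$assignment == k)
      train <- which(fold_plan$assignment != k)
      fold_rmse[k] <- tryCatch({
        fit <- fit_family(model_family, subset_design(dm, train), grid[[gi]])
        pred <- stats::predict(fit, dm$X[hold, , drop = FALSE], dm$t[hold])
        rmse(pred, dm$y[hold])
      }, error = function(e) NA_real_)
    }
    if (all(is.na(fold_rmse))) NA_real_ else mean(fold_rmse, na.rm = TRUE)
  }, numeric(1))
  if (all(is.na(scores)))
    stop("every grid point failed on all folds", call. = FALSE)
  best_score <- min(scores, na.rm = TRUE)
  tied <- which(!is.na(scores) & scores <= best_score + 1e-12)
  if (length(tied) > 1) {
    reg <- vapply(grid[tied], .reg_strength, numeric(1))
    tied <- tied[order(-reg, seq_along(tied))]
  }
  best <- tied[1]
  tab <- data.frame(grid_point = seq_along(grid), cv_rmse = scores)
  tab$params <- vapply(grid, function(p)
    paste(names(p), unlist(p), sep = "=", collapse = ", "), character(1))
  list(best_params = grid[[best]], cv_rmse = scores[best], table = tab)
}
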