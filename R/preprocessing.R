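#' Standardize a numeric vector to mean 0, sample SD 1
#'
#' @param x numeric vector, length >= 2, non-constant.
#' @return standardized vector with attributes `center` and `scale`.
#' @export
standardize <- function(x) {
  if (length(x) < 2) stop("need at least 2 values to standardize", call. = FALSE)
  if (anyNA(x)) stop("missing values not allowed in standardize()", call. = FALSE)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("cannot standardize a zero-variance vector", call. = FALSE)
  out <- (x - mean(x)) / s
  attr(out, "center") <- mean(x)
  attr(out, "scale") <- s
  out
}

#' Composite subjective well-being index
#'
#' Standardizes the three subscale means, reverses the negative-affect scales
#' (anxiety, depression), and returns the first principal component of the
#' resulting 3-column matrix, sign-aligned so that higher index means greater
#' well-being (non-negative correlation with positive affect), then
#' standardized to mean 0, SD 1.
#'
#' @param anxiety,depression,positive_affect equal-length numeric vectors
#'   with no missing entries (rows with missing subscales are excluded from
#'   analysis upstream).
#' @return numeric index vector with attribute `explained` (fraction of
#'   variance carried by the first component).
#' @export
wellbeing_index <- function(anxiety, depression, positive_affect) {
  n <- length(anxiety)
  stopifnot(length(depression) == n, length(positive_affect) == n)
  M <- cbind(-standardize(anxiety), -standardize(depression),
             standardize(positive_affect))
  pc <- stats::prcomp(M, center = FALSE, scale. = FALSE)
  idx <- pc$x[, 1]
  if (stats::cor(idx, positive_affect) < 0) idx <- -idx
  out <- standardize(idx)
  attr(out, "explained") <- pc$sdev[1]^2 / sum(pc$sdev^2)
  out
}

#' Impute and encode a table of mixed-type controls
#'
#' Continuous controls: missing cells are replaced by the column mean of the
#' observed values and, whenever any cell was missing, a paired 0/1
#' missing-indicator column is added.  Categorical controls: one dummy column
#' per observed level plus an explicit `"missing"` level when needed (the
#' dummies of one control partition each row).  Continuous columns are then
#' standardized; indicator and dummy columns are kept 0/1.  Column order is
#' deterministic: for each control in spec order, its encoded columns, then
#' its indicator.
#'
#' @param controls data frame of raw control columns.
#' @param control_spec named list/vector mapping each control name to
#'   `"continuous"` or `"categorical"`; defaults to type inference
#'   (numeric -> continuous).
#' @param standardize_continuous standardize the continuous columns after
#'   imputation (default).  Set `FALSE` to keep them on their raw scale.
#' @return numeric matrix with informative column names.
#' @export
impute_and_encode <- function(controls, control_spec = NULL,
                              standardize_continuous = TRUE) {
  controls <- as.data.frame(controls)
  if (is.null(control_spec)) {
    control_spec <- lapply(controls, function(x)
      if (is.numeric(x)) "continuous" else "categorical")
  }
  control_spec <- as.list(control_spec)
  unknown <- setdiff(names(controls), names(control_spec))
  if (length(unknown))
    stop("controls missing from control_spec: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  n <- nrow(controls)
  blocks <- list()
  for (nm in names(controls)) {
    x <- controls[[nm]]
    kind <- control_spec[[nm]]
    if (identical(kind, "continuous")) {
      x <- as.numeric(x)
      miss <- is.na(x)
      if (all(miss))
        stop("control '", nm, "' is entirely missing; cannot impute a mean",
             call. = FALSE)
      if (any(miss)) x[miss] <- mean(x[!miss])
      xs <- x
      if (standardize_continuous) {
        s <- stats::sd(x)
        xs <- if (is.finite(s) && s > 0) (x - mean(x)) / s else x - mean(x)
      }
      blocks[[length(blocks) + 1L]] <-
        stats::setNames(list(xs), nm)
      if (any(miss))
        blocks[[length(blocks) + 1L]] <-
          stats::setNames(list(as.numeric(miss)), paste0(nm, "_missing"))
    } else {
      f <- as.character(x)
      f[is.na(f)] <- "missing"
      lv <- unique(f)
      lv <- c(sort(setdiff(lv, "missing")), intersect("missing", lv))
      dm <- outer(f, lv, "==") * 1
      colnames(dm) <- paste0(nm, "=", lv)
      blocks[[length(blocks) + 1L]] <-
        stats::setNames(lapply(seq_along(lv), function(j) dm[, j]),
                        colnames(dm))
    }
  }
  cols <- unlist(blocks, recursive = FALSE)
  X <- matrix(unlist(cols, use.names = FALSE), nrow = n,
              dimnames = list(NULL, names(cols)))
  if (anyNA(X)) stop("internal error: encoded design contains NA")
  X
}

#' Build the numeric design an estimator consumes
#'
#' Restricts the cohort to rows where the treatment and the requested outcome
#' are both observed (students with any missing well-being subscale are
#' excluded), computes the treatment column (a raw column or the composite
#' `"wellbeing_index"`), standardizes it, and encodes the controls with
#' [impute_and_encode()].  The grade-7 prior score is always part of the
#' controls (mean-imputed with an indicator like any continuous control).
#'
#' @param cohort a `wb_cohort` (or its `$data` data frame plus a spec).
#' @param treatment `"wellbeing_index"`, `"anxiety"`, `"depression"` or
#'   `"positive_affect"`.
#' @param outcome `"outcome_numeracy"` or `"outcome_reading"`.
#' @param extra_controls character vector of additional cohort columns to
#'   adjust for (e.g. hold `depression` fixed when `anxiety` is the
#'   treatment).
#' @return an object of class `wb_design`: list with `X` (encoded control
#'   matrix), `t` (standardized treatment), `y` (outcome, raw points), `n`,
#'   `school_id`, `column_names`, `s_y` (sample SD of y), `s_t_raw` (sample
#'   SD of the raw treatment), `t_center`/`t_scale` and the row indices kept.
#' @export
build_design <- function(cohort, treatment = "wellbeing_index",
                         outcome = "outcome_numeracy",
                         extra_controls = character()) {
  stopifnot(inherits(cohort, "wb_cohort"))
  d <- cohort$data
  if (!outcome %in% names(d)) stop("unknown outcome column: ", outcome)
  subscales <- c("anxiety", "depression", "positive_affect")
  treat_cols <- if (treatment == "wellbeing_index") subscales else treatment
  if (!all(treat_cols %in% names(d)))
    stop("unknown treatment column: ", treatment)
  keep <- stats::complete.cases(d[subscales]) & !is.na(d[[outcome]])
  if (sum(keep) < 10)
    stop("fewer than 10 rows with observed treatment and outcome",
         call. = FALSE)
  d <- d[keep, , drop = FALSE]

  t_raw <- if (treatment == "wellbeing_index")
    as.numeric(wellbeing_index(d$anxiety, d$depression, d$positive_affect))
  else as.numeric(d[[treatment]])
  s_t_raw <- stats::sd(t_raw)
  t_std <- standardize(t_raw)

  ctrl <- d[names(cohort$control_spec)]
  spec <- cohort$control_spec
  ctrl$prior_score <- d$prior_score
  spec$prior_score <- "continuous"
  for (ec in setdiff(extra_controls, names(ctrl))) {
    ctrl[[ec]] <- d[[ec]]
    spec[[ec]] <- if (is.numeric(d[[ec]])) "continuous" else "categorical"
  }
  X <- impute_and_encode(ctrl, spec)
  y <- as.numeric(d[[outcome]])
  structure(list(X = X, t = as.numeric(t_std), y = y, n = nrow(X),
                 school_id = d$school_id, column_names = colnames(X),
                 s_y = stats::sd(y), s_t_raw = s_t_raw,
                 t_center = attr(t_std, "center"),
                 t_scale = attr(t_std, "scale"),
                 treatment = treatment, outcome = outcome,
                 rows = which(keep)),
            class = "wb_design")
}

#' Subset a design matrix by row indices
#' @param dm a `wb_design`.
#' @param idx integer row indices.
#' @keywords internal
subset_design <- function(dm, idx) {
  out <- dm
  out$X <- dm$X[idx, , drop = FALSE]
  out$t <- dm$t[idx]
  out$y <- dm$y[idx]
  out$n <- length(idx)
  out$school_id <- dm$school_id[idx]
  out
}

#' @export
print.wb_design <- function(x, ...) {
  cat(sprintf("design: %d rows x %d encoded controls; treatment '%s' -> outcome '%s'\n",
              x$n, ncol(x$X), x$treatment, x$outcome))
  invisible(x)
}
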