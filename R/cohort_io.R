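#' Write a cohort to CSV (lossless round trip)
#'
#' Columns are written in the canonical order `student_id, school_id,
#' anxiety, depression, positive_affect, prior_score, outcome_numeracy,
#' outcome_reading, c01..cNN`; missing cells become empty fields; numeric
#' values are printed with 17 significant digits so a read-back reproduces
#' them bit-for-bit.  The control-kind spec is written as JSON alongside
#' unless `spec_path = NULL`.
#'
#' @param cohort a `wb_cohort`.
#' @param path output CSV path.
#' @param spec_path path for the control-spec JSON; default
#'   `paste0(path, ".spec.json")`; `NULL` suppresses it.
#' @return `path`, invisibly.
#' @export
cohort_to_csv <- function(cohort, path,
                          spec_path = paste0(path, ".spec.json")) {
  stopifnot(inherits(cohort, "wb_cohort"))
  d <- cohort$data
  fixed <- c("student_id", "school_id", "anxiety", "depression",
             "positive_affect", "prior_score", "outcome_numeracy",
             "outcome_reading")
  d <- d[c(fixed, names(cohort$control_spec))]
  out <- lapply(d, function(x) {
    if (is.numeric(x)) {
      s <- sprintf("%.17g", x)
      s[is.na(x)] <- ""
      s
    } else {
      x <- as.character(x)
      x[is.na(x)] <- ""
      x
    }
  })
  out <- as.data.frame(out, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(spec_path))
    jsonlite::write_json(cohort$control_spec, spec_path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a cohort from CSV
#'
#' @param path CSV written by [cohort_to_csv()] (schema above).
#' @param control_spec named list of control kinds, or a path to the spec
#'   JSON, or `NULL` to look for `paste0(path, ".spec.json")` and fall back
#'   to type inference.
#' @return a `wb_cohort`.
#' @export
csv_to_cohort <- function(path, control_spec = NULL) {
  if (is.character(control_spec) && length(control_spec) == 1 &&
      file.exists(control_spec))
    control_spec <- jsonlite::read_json(control_spec)
  if (is.null(control_spec) && file.exists(paste0(path, ".spec.json")))
    control_spec <- jsonlite::read_json(paste0(path, ".spec.json"))
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                       colClasses = "character", na.strings = "")
  fixed <- c("student_id", "school_id", "anxiety", "depression",
             "positive_affect", "prior_score", "outcome_numeracy",
             "outcome_reading")
  if (!all(fixed %in% names(d)))
    stop("cohort CSV is missing required columns: ",
         paste(setdiff(fixed, names(d)), collapse = ", "), call. = FALSE)
  ctrl_names <- setdiff(names(d), fixed)
  if (is.null(control_spec))
    control_spec <- stats::setNames(
      lapply(ctrl_names, function(nm) {
        v <- d[[nm]][!is.na(d[[nm]])]
        if (length(v) == 0 || !anyNA(suppressWarnings(as.numeric(v))))
          "continuous" else "categorical"
      }), ctrl_names)
  control_spec <- as.list(control_spec)
  unknown <- setdiff(ctrl_names, names(control_spec))
  if (length(unknown))
    stop("unknown columns in cohort CSV: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  to_num <- function(x, nm) {
    bad <- !is.na(x) & is.na(suppressWarnings(as.numeric(x)))
    if (any(bad))
      stop("non-numeric values in numeric column '", nm, "'", call. = FALSE)
    as.numeric(x)
  }
  for (nm in c("anxiety", "depression", "positive_affect", "prior_score",
               "outcome_numeracy", "outcome_reading"))
    d[[nm]] <- to_num(d[[nm]], nm)
  for (nm in ctrl_names) {
    if (identical(control_spec[[nm]], "continuous"))
      d[[nm]] <- to_num(d[[nm]], nm)
    else
      d[[nm]] <- factor(d[[nm]])
  }
  structure(list(data = d[c(fixed, ctrl_names)],
                 control_spec = control_spec[ctrl_names],
                 config = NULL),
            class = "wb_cohort")
}

#' Serialize generator ground truth to JSON
#' @param truth a `wb_true_params`.
#' @param path output path.
#' @export
true_params_to_json <- function(truth, path) {
  stopifnot(inherits(truth, "wb_true_params"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
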