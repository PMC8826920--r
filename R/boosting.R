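#' Stagewise least-squares gradient boosting with regression trees
#'
#' Classic residual boosting: starting from the outcome mean, each of `K`
#' depth-limited regression trees is fit to the current residuals and added
#' with step size `learning_rate`.  The fitted surface is nonlinear in both
#' the controls and the treatment.
#'
#' @param dm a `wb_design`.
#' @param n_trees number of boosting stages K (>= 1).
#' @param max_depth maximum tree depth.
#' @param learning_rate stagewise step size in (0, 2].
#' @param min_split minimum node size eligible for splitting (rpart
#'   `minsplit`).
#' @param min_bucket minimum leaf size (rpart `minbucket`).
#' @return object of classes `wb_boost` and `wb_surface` with the tree list
#'   and training-RMSE trace (non-increasing in K).
#' @export
fit_gradient_boosting <- function(dm, n_trees = 300L, max_depth = 3L,
                                  learning_rate = 0.1, min_split = 20L,
                                  min_bucket = max(1L, min_split %/% 3L)) {
  stopifnot(inherits(dm, "wb_design"), n_trees >= 1,
            learning_rate > 0, learning_rate <= 2)
  df <- as.data.frame(dm$X)
  names(df) <- paste0("f", seq_len(ncol(dm$X)))
  df$..t <- dm$t
  y <- dm$y
  f0 <- mean(y)
  pred <- rep(f0, length(y))
  trees <- vector("list", n_trees)
  rmse_trace <- numeric(n_trees)
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = 0,
                               minsplit = min_split, minbucket = min_bucket,
                               xval = 0, maxsurrogate = 0, maxcompete = 0)
  for (k in seq_len(n_trees)) {
    df$..r <- y - pred
    tr <- rpart::rpart(..r ~ ., data = df[c(names(df)[names(df) != "..r"],
                                            "..r")],
                       method = "anova", control = ctrl)
    pred <- pred + learning_rate * stats::predict(tr, df)
    trees[[k]] <- tr
    rmse_trace[k] <- sqrt(mean((y - pred)^2))
  }
  structure(list(trees = trees, intercept = f0,
                 learning_rate = learning_rate, max_depth = max_depth,
                 n_trees = n_trees, rmse_trace = rmse_trace,
                 feature_names = setdiff(names(df), c("..r")),
                 n = dm$n, model_kind = "boosting"),
            class = c("wb_boost", "wb_surface"))
}

#' @export
predict.wb_boost <- function(object, X, t, ...) {
  X <- as.matrix(X)
  if (length(t) == 1) t <- rep(t, nrow(X))
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  df$..t <- t
  pred <- rep(object$intercept, nrow(df))
  for (tr in object$trees)
    pred <- pred + object$learning_rate * stats::predict(tr, df)
  unname(pred)
}
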