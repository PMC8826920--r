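#' Penalized least squares with per-column penalties
#'
#' Solves the ridge normal equations \eqn{(X'X + \Lambda) w = X'y} where
#' \eqn{\Lambda} is a diagonal penalty matrix.  Individual columns can be
#' exempted from the penalty (penalty factor 0), which is how the two-stage
#' estimator keeps its treatment coefficient unregularized.
#'
#' @param X numeric matrix (no intercept column; see `intercept`).
#' @param y numeric response vector, `length(y) == nrow(X)`.
#' @param lambda non-negative scalar ridge penalty.
#' @param intercept if `TRUE` an unpenalized intercept column is prepended.
#' @param penalty optional vector of per-column penalty factors for the
#'   columns of `X` (multiplied by `lambda`); defaults to 1 for every column.
#' @return list with `coef` (named, intercept first when present), `fitted`,
#'   `residuals`, and the matrices needed for sandwich-style standard errors
#'   (`M_inv`, `XtX`).
#' @keywords internal
ridge_fit <- function(X, y, lambda, intercept = TRUE, penalty = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), lambda >= 0)
  if (is.null(penalty)) penalty <- rep(1, ncol(X))
  stopifnot(length(penalty) == ncol(X))
  if (intercept) {
    X <- cbind(`(Intercept)` = 1, X)
    penalty <- c(0, penalty)
  }
  XtX <- crossprod(X)
  M <- XtX + diag(lambda * penalty, ncol(X))
  coef <- tryCatch(
    drop(solve(M, crossprod(X, y))),
    error = function(e) stop("singular penalized system; increase lambda", call. = FALSE)
  )
  names(coef) <- colnames(X)
  fitted <- drop(X %*% coef)
  list(coef = coef, fitted = fitted, residuals = y - fitted,
       M_inv = solve(M), XtX = XtX, lambda = lambda, penalty = penalty,
       intercept = intercept)
}

#' Radial-basis-function kernel matrix
#'
#' @param A,B numeric matrices with matching column count.
#' @param bandwidth kernel length-scale \eqn{\ell}; entries are
#'   \eqn{\exp(-\|a-b\|^2 / (2\ell^2))}.
#' @keywords internal
rbf_kernel <- function(A, B, bandwidth) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(ncol(A) == ncol(B), bandwidth > 0)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * bandwidth^2))
}

#' Median-heuristic kernel bandwidth
#'
#' Median pairwise Euclidean distance over at most `max_rows` rows — the
#' standard default length-scale when none is supplied or cross-validated.
#'
#' @param X numeric matrix.
#' @param max_rows subsample cap for the pairwise-distance computation.
#' @param seed integer seed controlling the subsample.
#' @export
median_bandwidth <- function(X, max_rows = 500L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n > max_rows) {
    idx <- local({ set.seed(seed); sample.int(n, max_rows) })
    X <- X[idx, , drop = FALSE]
  }
  d <- stats::dist(X)
  bw <- stats::median(d[d > 0])
  if (!is.finite(bw) || bw <= 0) bw <- 1
  bw
}

#' Nystroem feature map for a radial basis kernel
#'
#' Approximates the RBF kernel feature space from a subset of landmark rows:
#' \eqn{\phi(x) = K(x, Z) U D^{-1/2}} where \eqn{K(Z,Z) = U D U'}.  With all
#' rows as landmarks, \eqn{\phi(X)\phi(X)' } reproduces the exact Gram matrix.
#'
#' @param X numeric matrix of rows to draw landmarks from.
#' @param n_landmarks number of landmark rows, capped at `nrow(X)`
#'   (default `min(300, nrow(X))`).
#' @param bandwidth RBF length-scale; `NULL` uses [median_bandwidth()].
#' @param seed integer seed for the landmark draw.
#' @return an object of class `nystroem_map` usable with [feature_map()].
#' @export
nystroem_map <- function(X, n_landmarks = NULL, bandwidth = NULL, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(n_landmarks)) n_landmarks <- min(300L, n)
  n_landmarks <- min(as.integer(n_landmarks), n)
  stopifnot(n_landmarks >= 1)
  if (is.null(bandwidth)) bandwidth <- median_bandwidth(X, seed = seed)
  idx <- if (n_landmarks == n) seq_len(n) else
    local({ set.seed(seed); sort(sample.int(n, n_landmarks)) })
  Z <- X[idx, , drop = FALSE]
  W <- rbf_kernel(Z, Z, bandwidth)
  eg <- eigen((W + t(W)) / 2, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-10
  structure(list(landmarks = Z, bandwidth = bandwidth,
                 U = eg$vectors[, keep, drop = FALSE],
                 d = eg$values[keep], landmark_idx = idx),
            class = "nystroem_map")
}

#' Apply a Nystroem map to new rows
#'
#' @param map a `nystroem_map` from [nystroem_map()], or `NULL` for the
#'   identity map (returns `X` unchanged — the linear-feature case).
#' @param X numeric matrix with the same columns the map was built on.
#' @return numeric feature matrix with one column per retained landmark
#'   eigen-direction.
#' @export
feature_map <- function(map, X) {
  X <- as.matrix(X)
  if (is.null(map)) return(X)
  stopifnot(inherits(map, "nystroem_map"))
  Kxz <- rbf_kernel(X, map$landmarks, map$bandwidth)
  Kxz %*% (map$U %*% diag(1 / sqrt(map$d), length(map$d)))
}
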