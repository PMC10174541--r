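#' Train a radial basis function network
#'
#' Hidden units are Gaussian bases phi_k(x) = exp(-||x - c_k||^2 / (2
#' sigma^2)) around centers chosen by k-means on the training features; the
#' output is a linear combination of the basis activations whose weights
#' are solved by linear least squares. The shared width defaults to the
#' heuristic sigma = d_max / sqrt(2 p), with d_max the maximum
#' inter-center distance and p the number of centers.
#'
#' @param X Scaled feature matrix.
#' @param y Numeric response vector.
#' @param centers Number of hidden units (default 120). Capped at the
#'   number of distinct training rows. A matrix may be given to fix the
#'   centers explicitly (e.g. every training point, for exact
#'   interpolation).
#' @param width Shared Gaussian width; `NULL` for the d_max heuristic.
#' @param bias If `TRUE`, append an intercept to the linear solve. The
#'   default `FALSE` matches the plain weighted-sum output.
#' @param ridge Ridge penalty used only as a fallback when the basis
#'   matrix is numerically rank-deficient.
#' @param seed Integer seed for the k-means center selection.
#' @return Object of class `rbf_net`.
#' @export
train_rbf <- function(X, y, centers = 120L, width = NULL, bias = FALSE,
                      ridge = 1e-8, seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(is.finite(X)), all(is.finite(y)))
  if (is.matrix(centers)) {
    C <- centers
    stopifnot(ncol(C) == ncol(X))
  } else {
    k <- as.integer(centers)
    n_distinct <- nrow(unique(X))
    if (k > nrow(X)) stop("more centers than training rows")
    k <- min(k, n_distinct)
    if (k == n_distinct) {
      C <- unique(X)
    } else {
      set.seed(seed)
      C <- stats::kmeans(X, centers = k, iter.max = 100, nstart = 1)$centers
    }
  }
  p <- nrow(C)
  D2 <- pairwise_sqdist(C, C)
  d_max <- sqrt(max(D2))
  if (is.null(width)) width <- d_max / sqrt(2 * p)
  if (!is.finite(width) || width <= 1e-8) width <- 1e-8  # collapsed centers
  Phi <- exp(-pairwise_sqdist(X, C) / (2 * width^2))
  if (bias) Phi <- cbind(Phi, 1)
  qr_fit <- qr(Phi)
  if (qr_fit$rank < ncol(Phi)) {
    warning("rank-deficient RBF basis; falling back to ridge solve")
    A <- crossprod(Phi) + diag(ridge, ncol(Phi))
    w <- solve(A, crossprod(Phi, y))
  } else {
    w <- qr.coef(qr_fit, y)
  }
  structure(
    list(centers = C, width = width, weights = as.numeric(w), bias = bias),
    class = "rbf_net"
  )
}

#' Predict from a trained RBF network
#'
#' @param object An `rbf_net` model.
#' @param newdata Matrix of query rows on the training metric.
#' @param ... Unused.
#' @return Numeric vector of weighted-sum outputs.
#' @export
predict.rbf_net <- function(object, newdata, ...) {
  Q <- as.matrix(newdata)
  stopifnot(ncol(Q) == ncol(object$centers))
  Phi <- exp(-pairwise_sqdist(Q, object$centers) / (2 * object$width^2))
  if (object$bias) Phi <- cbind(Phi, 1)
  as.vector(Phi %*% object$weights)
}
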