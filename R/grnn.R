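# Squared Euclidean distances between row sets (q x d vs n x d).
pairwise_sqdist <- function(A, B) {
  D2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
  pmax(D2, 0)
}

#' Train a generalized regression neural network
#'
#' A GRNN stores the training patterns and predicts by normalized Gaussian
#' kernel regression (Nadaraya-Watson): the S-summation accumulates the
#' kernel weights, the D-summation the target-weighted kernel weights, and
#' the output is their ratio, so every prediction is a convex combination
#' of stored targets. The only free parameter is the kernel width
#' (smoothing parameter) sigma, selected here by leave-one-out grid search
#' on the training set.
#'
#' Under replicated designs many training rows share an identical feature
#' vector; leaving out a single row then measures pure replicate noise
#' rather than generalization and drives sigma to the grid boundary. The
#' default `loo = "design"` therefore holds out all rows sharing the
#' held-out row's feature vector (it reduces to ordinary row-level LOO
#' when all rows are distinct); `loo = "row"` gives the plain scheme.
#'
#' @param X Scaled feature matrix (rows x inputs), at least 2 rows.
#' @param y Numeric response vector.
#' @param sigma_grid Candidate widths on the scaled-input metric (default
#'   25 log-spaced points over 1e-2 .. 1e1).
#' @param loo `"design"` (group identical feature rows) or `"row"`.
#' @param sigma Optional fixed width, skipping the search.
#' @return Object of class `grnn` with stored patterns, targets, the
#'   selected `sigma`, and the LOO RMSE profile.
#' @export
train_grnn <- function(X, y,
                       sigma_grid = 10^seq(-2, 1, length.out = 25),
                       loo = c("design", "row"), sigma = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) >= 2L, nrow(X) == length(y), all(is.finite(X)),
            all(is.finite(y)))
  loo <- match.arg(loo)
  loo_profile <- NULL
  if (is.null(sigma)) {
    D2 <- pairwise_sqdist(X, X)
    key <- apply(round(X, 10), 1, paste, collapse = "\r")
    group <- if (loo == "design") match(key, unique(key)) else seq_along(y)
    mask <- outer(group, group, "==")  # held-out row's own design point
    if (all(mask)) stop("all training rows share one design point")
    # nearest *eligible* distance per row, for underflow-safe weights
    D2m <- D2
    D2m[mask] <- Inf
    d0 <- apply(D2m, 1, min)
    loo_profile <- vapply(sigma_grid, function(s) {
      W <- exp(-sweep(D2, 1, d0, "-") / (2 * s^2))
      W[mask] <- 0
      pred <- as.vector(W %*% y) / rowSums(W)
      sqrt(mean((y - pred)^2))
    }, numeric(1))
    sigma <- sigma_grid[which.min(loo_profile)]
    if (which.min(loo_profile) %in% c(1L, length(sigma_grid))) {
      warning("LOO-selected sigma lies on the grid boundary; ",
              "the fit may be under- or over-smoothed")
    }
  }
  stopifnot(is.numeric(sigma), sigma > 0)
  structure(
    list(X = X, y = y, sigma = sigma, loo = loo,
         sigma_grid = sigma_grid, loo_rmse = loo_profile),
    class = "grnn"
  )
}

#' Predict from a trained GRNN
#'
#' @param object A `grnn` model.
#' @param newdata Matrix of query rows on the same scaled metric as the
#'   training features.
#' @param ... Unused.
#' @return Numeric vector of predictions, each within the range of the
#'   stored training targets. As `sigma -> 0` the prediction tends to the
#'   nearest stored pattern's target (ties averaged); as `sigma -> Inf` it
#'   tends to the mean of all targets.
#' @export
predict.grnn <- function(object, newdata, ...) {
  Q <- as.matrix(newdata)
  stopifnot(ncol(Q) == ncol(object$X))
  D2 <- pairwise_sqdist(Q, object$X)
  d0 <- apply(D2, 1, min)
  # subtracting the per-query nearest distance leaves predictions unchanged
  # (weights are normalized) but keeps the sigma -> 0 limit finite
  W <- exp(-sweep(D2, 1, d0, "-") / (2 * object$sigma^2))
  as.vector(W %*% object$y) / rowSums(W)
}
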