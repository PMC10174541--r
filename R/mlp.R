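mlp_shapes <- function(d, hidden) {
  h1 <- hidden[1]; h2 <- hidden[2]
  list(
    d = d, h1 = h1, h2 = h2,
    n_par = d * h1 + h1 + h1 * h2 + h2 + h2 + 1
  )
}

mlp_unpack <- function(theta, s) {
  i <- 0L
  take <- function(k) {
    v <- theta[(i + 1L):(i + k)]
    i <<- i + k
    v
  }
  list(
    W1 = matrix(take(s$d * s$h1), s$d, s$h1),
    b1 = take(s$h1),
    W2 = matrix(take(s$h1 * s$h2), s$h1, s$h2),
    b2 = take(s$h2),
    w3 = take(s$h2),
    b3 = take(1L)
  )
}

mlp_forward <- function(theta, X, s) {
  p <- mlp_unpack(theta, s)
  A1 <- tanh(sweep(X %*% p$W1, 2, p$b1, "+"))
  A2 <- tanh(sweep(A1 %*% p$W2, 2, p$b2, "+"))
  list(pred = as.vector(A2 %*% p$w3 + p$b3), A1 = A1, A2 = A2, par = p)
}

# Jacobian of predictions w.r.t. the packed parameter vector, n x n_par,
# column order matching mlp_unpack.
mlp_jacobian <- function(fw, X, s) {
  delta2 <- (1 - fw$A2^2) * matrix(fw$par$w3, nrow(X), s$h2, byrow = TRUE)
  delta1 <- (delta2 %*% t(fw$par$W2)) * (1 - fw$A1^2)
  J_W1 <- X[, rep(seq_len(s$d), times = s$h1), drop = FALSE] *
    delta1[, rep(seq_len(s$h1), each = s$d), drop = FALSE]
  J_W2 <- fw$A1[, rep(seq_len(s$h1), times = s$h2), drop = FALSE] *
    delta2[, rep(seq_len(s$h2), each = s$h1), drop = FALSE]
  cbind(J_W1, delta1, J_W2, delta2, fw$A2, 1)
}

# One damped Gauss-Newton (Levenberg-Marquardt) step. Solved in the dual
# (n x n) space, delta = J' (J J' + lambda I)^-1 r, algebraically equal to
# (J'J + lambda I)^-1 J' r but cheap for overparameterized networks. As
# lambda -> Inf the step tends to J' r / lambda, the gradient-descent
# direction scaled by 1/lambda.
lm_step <- function(J, r, lambda, JJt = tcrossprod(J)) {
  u <- solve(JJt + diag(lambda, nrow(JJt)), r)
  as.vector(crossprod(J, u))
}

#' Train a two-hidden-layer perceptron by Levenberg-Marquardt
#'
#' Feed-forward network (inputs -> `hidden[1]` -> `hidden[2]` -> 1) with
#' hyperbolic-tangent hidden activations and a linear output, fitted by
#' minimizing the mean squared training error with damped Gauss-Newton
#' updates. An inner validation split provides early stopping, which is
#' what keeps the deliberately overparameterized default architecture
#' (128/64 hidden units on ~600 rows) in check.
#'
#' @param X Scaled feature matrix, at least 10 rows.
#' @param y Numeric response vector.
#' @param hidden Two hidden-layer sizes, default `c(128, 64)`.
#' @param seed Integer seed (weight init and validation split).
#' @param maxit Maximum accepted LM iterations.
#' @param val_fraction Fraction of rows held out for early stopping; 0
#'   disables it.
#' @param patience Accepted steps without validation improvement before
#'   stopping.
#' @param lambda0,lambda_factor Initial damping and its up/down factor.
#' @param lambda_max Damping ceiling; exceeded means divergence, and the
#'   best parameters so far are returned with a warning.
#' @return Object of class `mlp` with the packed parameter vector and
#'   training history.
#' @export
train_mlp <- function(X, y, hidden = c(128L, 64L), seed = 1L, maxit = 30L,
                      val_fraction = 0.1, patience = 5L, lambda0 = 1e-2,
                      lambda_factor = 10, lambda_max = 1e10) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(length(hidden) == 2L, all(hidden >= 1L))
  if (nrow(X) < 10L || nrow(X) != length(y)) {
    stop("need at least 10 rows with matching response length")
  }
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("non-finite training inputs")
  }
  s <- mlp_shapes(ncol(X), as.integer(hidden))
  set.seed(seed)
  n <- nrow(X)
  n_val <- floor(val_fraction * n)
  val_idx <- if (n_val >= 1L) sample(n, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xt <- X[tr_idx, , drop = FALSE]; yt <- y[tr_idx]
  Xv <- X[val_idx, , drop = FALSE]; yv <- y[val_idx]

  theta <- c(
    stats::rnorm(s$d * s$h1, sd = 1 / sqrt(s$d)), rep(0, s$h1),
    stats::rnorm(s$h1 * s$h2, sd = 1 / sqrt(s$h1)), rep(0, s$h2),
    stats::rnorm(s$h2, sd = 1 / sqrt(s$h2)), mean(y)
  )
  fw <- mlp_forward(theta, Xt, s)
  sse <- sum((yt - fw$pred)^2)
  val_rmse <- function(th) {
    if (length(val_idx) == 0L) return(NA_real_)
    sqrt(mean((yv - mlp_forward(th, Xv, s)$pred)^2))
  }
  best_theta <- theta
  best_val <- val_rmse(theta)
  stall <- 0L
  lambda <- lambda0
  diverged <- FALSE
  history <- numeric(0)
  for (it in seq_len(maxit)) {
    r <- yt - fw$pred
    J <- mlp_jacobian(fw, Xt, s)
    JJt <- tcrossprod(J)
    accepted <- FALSE
    while (!accepted) {
      delta <- lm_step(J, r, lambda, JJt)
      cand <- theta + delta
      fw_cand <- mlp_forward(cand, Xt, s)
      sse_cand <- sum((yt - fw_cand$pred)^2)
      if (is.finite(sse_cand) && sse_cand < sse) {
        theta <- cand; fw <- fw_cand; sse <- sse_cand
        lambda <- max(lambda / lambda_factor, 1e-12)
        accepted <- TRUE
      } else {
        lambda <- lambda * lambda_factor
        if (lambda > lambda_max) {
          diverged <- TRUE
          break
        }
      }
    }
    if (diverged) break
    history <- c(history, sqrt(sse / length(yt)))
    v <- val_rmse(theta)
    if (!is.na(v)) {
      if (is.na(best_val) || v < best_val - 1e-12) {
        best_val <- v; best_theta <- theta; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    } else {
      best_theta <- theta
    }
  }
  if (diverged) {
    warning("LM damping exceeded its ceiling; returning best parameters so far")
  }
  if (is.na(best_val)) best_theta <- theta
  structure(
    list(theta = best_theta, shapes = s, hidden = as.integer(hidden),
         train_rmse = history, val_rmse = best_val, seed = seed),
    class = "mlp"
  )
}

#' Predict from a trained MLP
#'
#' @param object An `mlp` model.
#' @param newdata Matrix of query rows on the training metric.
#' @param ... Unused.
#' @return Numeric vector of network outputs.
#' @export
predict.mlp <- function(object, newdata, ...) {
  Q <- as.matrix(newdata)
  stopifnot(ncol(Q) == object$shapes$d)
  mlp_forward(object$theta, Q, object$shapes)$pred
}
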