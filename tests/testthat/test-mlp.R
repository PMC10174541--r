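test_that("a constant target is fitted by the output bias alone", {
  set.seed(41)
  X <- matrix(runif(60), 20, 3)
  y <- rep(37, 20)
  m <- train_mlp(X, y, hidden = c(8, 4), seed = 1, val_fraction = 0)
  expect_lt(rmse(y, predict(m, X)), 1e-3)
})

test_that("a noiseless linear function is learned almost exactly", {
  set.seed(42)
  X <- matrix(runif(150), 50, 3)
  y <- 3 * X[, 1] + 2
  m <- train_mlp(X, y, hidden = c(8, 4), seed = 2, maxit = 60,
                 val_fraction = 0)
  expect_gt(r2(y, predict(m, X)), 0.99)
})

test_that("training is deterministic given the seed", {
  set.seed(43)
  X <- matrix(runif(100), 25, 4)
  y <- rowSums(X) + rnorm(25, sd = 0.1)
  m1 <- train_mlp(X, y, hidden = c(6, 3), seed = 7, maxit = 10)
  m2 <- train_mlp(X, y, hidden = c(6, 3), seed = 7, maxit = 10)
  expect_identical(m1$theta, m2$theta)
  m3 <- train_mlp(X, y, hidden = c(6, 3), seed = 8, maxit = 10)
  expect_false(identical(m1$theta, m3$theta))
})

test_that("the damped step tends to scaled gradient descent as damping grows", {
  set.seed(44)
  J <- matrix(rnorm(40), 10, 4)
  r <- rnorm(10)
  lambda <- 1e8
  step <- sterilopt:::lm_step(J, r, lambda)
  grad_dir <- as.vector(crossprod(J, r)) / lambda
  expect_equal(step, grad_dir, tolerance = 1e-6)
  # and the dual-space solve equals the primal normal-equations solve
  lambda <- 0.5
  primal <- solve(crossprod(J) + diag(lambda, 4), crossprod(J, r))
  expect_equal(sterilopt:::lm_step(J, r, lambda), as.vector(primal),
               tolerance = 1e-10)
})

test_that("the analytic Jacobian matches finite differences", {
  set.seed(45)
  X <- matrix(runif(18), 6, 3)
  s <- sterilopt:::mlp_shapes(3, c(4, 2))
  theta <- rnorm(s$n_par, sd = 0.5)
  fw <- sterilopt:::mlp_forward(theta, X, s)
  J <- sterilopt:::mlp_jacobian(fw, X, s)
  eps <- 1e-6
  J_fd <- vapply(seq_len(s$n_par), function(k) {
    tp <- theta; tp[k] <- tp[k] + eps
    tm <- theta; tm[k] <- tm[k] - eps
    (sterilopt:::mlp_forward(tp, X, s)$pred -
       sterilopt:::mlp_forward(tm, X, s)$pred) / (2 * eps)
  }, numeric(6))
  expect_equal(J, J_fd, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("MLP input validation", {
  X <- matrix(runif(12), 4, 3)
  expect_error(train_mlp(X, runif(4)), "at least 10 rows")
  X2 <- matrix(runif(60), 20, 3)
  y2 <- runif(20)
  y2[3] <- NA
  expect_error(train_mlp(X2, y2), "non-finite")
})
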