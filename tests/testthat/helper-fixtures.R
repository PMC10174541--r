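# Shared fixtures, built in code once per test run.

the_records <- load_treatment_tables()

# tiny synthetic record set for fast unit tests
toy_records <- function() {
  data.frame(
    disinfectant = rep(c("NaOCl", "H2O2"), each = 4),
    concentration = c(0, 0, 1, 1, 0, 0, 10, 10),
    time_min = c(5, 15, 5, 15, 5, 15, 5, 15),
    contamination_mean = c(90, 90, 20, 10, 90, 90, 30, 25),
    contamination_se = c(0.5, 0.5, 0.4, 0.3, 0.5, 0.5, 0.6, 0.2),
    germination_mean = c(15, 15, 70, 80, 15, 15, 60, 65),
    germination_se = c(0.3, 0.3, 0.5, 0.4, 0.3, 0.3, 0.5, 0.5)
  )
}

# independent O(n^2) dominance oracle (all objectives minimized)
brute_force_fronts <- function(M) {
  n <- nrow(M)
  dominates <- function(i, j) {
    all(M[i, ] <= M[j, ]) && any(M[i, ] < M[j, ])
  }
  left <- seq_len(n)
  fronts <- list()
  while (length(left)) {
    nd <- vapply(left, function(j) {
      !any(vapply(left, function(i) i != j && dominates(i, j), logical(1)))
    }, logical(1))
    fronts[[length(fronts) + 1L]] <- left[nd]
    left <- left[!nd]
  }
  fronts
}

# independent nearest-neighbour regressor (ties averaged)
nn_oracle <- function(X, y, Q) {
  apply(as.matrix(Q), 1, function(q) {
    d <- colSums((t(X) - q)^2)
    mean(y[d <= min(d) + 1e-12])
  })
}
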