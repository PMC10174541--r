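fit_on_matrix <- function(X, y, kind, seed, ...) {
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(scaler, X)
  model <- switch(kind,
    grnn = train_grnn(Xs, y, ...),
    rbf = train_rbf(Xs, y, seed = seed, ...),
    mlp = train_mlp(Xs, y, seed = seed, ...)
  )
  list(scaler = scaler, model = model)
}

predict_on_matrix <- function(fit, X) {
  predict(fit$model, apply_scaler(fit$scaler, X))
}

#' Input-importance ranking by variable removal (VSE / VSR)
#'
#' For each of the seven inputs, retrains the chosen surrogate on the six
#' remaining inputs (same split and seed as the full model) and records
#' the test RMSE with that input removed — the variable sensitivity error
#' (VSE). The variable sensitivity ratio VSR = VSE / full-model test RMSE
#' exceeds 1 when the removed input carried information; inputs are ranked
#' by descending VSR (rank 1 = most important), ties broken by input
#' order. Removal means retraining without the column, not zeroing it at
#' prediction time: a zeroed concentration column is indistinguishable
#' from the untreated control in this encoding.
#'
#' @param table Replicate-level `observation_table` (the full dataset).
#' @param kind Surrogate family to use (default `"grnn"`, the study's
#'   best-scoring model).
#' @param train_fraction,seed Split settings, as in [split_train_test()].
#' @param ... Passed to the trainer.
#' @return Data frame with columns `response`, `input`, `vse`, `vsr`,
#'   `rank`, `failed`.
#' @export
sensitivity_analysis <- function(table, kind = c("grnn", "rbf", "mlp"),
                                 train_fraction = 0.8, seed = 1L, ...) {
  kind <- match.arg(kind)
  sp <- split_train_test(table, train_fraction, seed)
  out <- list()
  for (resp in c("contamination", "germination")) {
    y_tr <- sp$train$responses[, resp]
    y_te <- sp$test$responses[, resp]
    full <- fit_on_matrix(sp$train$features, y_tr, kind, seed, ...)
    rmse_full <- rmse(y_te, predict_on_matrix(full, sp$test$features))
    vse <- rep(NA_real_, 7)
    failed <- rep(FALSE, 7)
    for (j in seq_len(7)) {
      res <- tryCatch({
        fit_j <- fit_on_matrix(
          sp$train$features[, -j, drop = FALSE], y_tr, kind, seed, ...
        )
        rmse(y_te, predict_on_matrix(fit_j, sp$test$features[, -j,
          drop = FALSE]))
      }, error = function(e) NA_real_)
      if (is.na(res)) failed[j] <- TRUE else vse[j] <- res
    }
    vsr <- vse / rmse_full
    rk <- rep(NA_integer_, 7)
    ok <- !failed
    rk[ok] <- rank(-vsr[ok], ties.method = "first")
    out[[resp]] <- data.frame(
      response = resp, input = feature_names(),
      vse = vse, vsr = vsr, rank = rk, failed = failed
    )
  }
  report <- do.call(rbind, out)
  rownames(report) <- NULL
  report
}
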