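check_metric_inputs <- function(observed, predicted) {
  stopifnot(
    length(observed) == length(predicted), length(observed) > 0,
    all(is.finite(observed)), all(is.finite(predicted))
  )
}

#' Goodness-of-fit metrics
#'
#' The package's model-quality triad: coefficient of determination
#' `R2 = 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)`, root mean
#' square error, and mean bias error `MBE = mean(pred - obs)` (negative
#' MBE means under-prediction). All on the raw percent scale.
#'
#' @param observed,predicted Equal-length finite numeric vectors.
#' @return A single number.
#' @export
r2 <- function(observed, predicted) {
  check_metric_inputs(observed, predicted)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot <= 0) stop("R2 undefined: observed values have zero variance")
  1 - sum((observed - predicted)^2) / ss_tot
}

#' @rdname r2
#' @export
rmse <- function(observed, predicted) {
  check_metric_inputs(observed, predicted)
  sqrt(mean((observed - predicted)^2))
}

#' @rdname r2
#' @export
mbe <- function(observed, predicted) {
  check_metric_inputs(observed, predicted)
  mean(predicted - observed)
}

#' Score surrogate models on the train/test split
#'
#' Builds the full metrics grid — every surrogate family x response x
#' subset scored by R2, RMSE and MBE — and flags the best family as the
#' one with the highest test R2 averaged over the two responses.
#'
#' @param sets Named list of `surrogate_set` objects (e.g. `mlp`, `grnn`,
#'   `rbf`), all fitted on the same training table.
#' @param train,test The `observation_table`s of the split the sets were
#'   trained on.
#' @return Data frame with columns `model`, `response`, `subset`, `r2`,
#'   `rmse`, `mbe`, ordered by the input model order, with attribute
#'   `best_model`.
#' @export
compare_models <- function(sets, train, test) {
  stopifnot(length(sets) >= 1, !is.null(names(sets)))
  dg <- split_digest(train)
  for (nm in names(sets)) {
    if (!identical(sets[[nm]]$digest, dg)) {
      stop("model '", nm, "' was not trained on the supplied training table")
    }
  }
  grid <- expand.grid(
    model = names(sets), response = c("contamination", "germination"),
    subset = c("train", "test"), stringsAsFactors = FALSE
  )
  grid <- grid[order(match(grid$model, names(sets))), ]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    tab <- if (grid$subset[i] == "train") train else test
    obs <- tab$responses[, grid$response[i]]
    pred <- predict_surrogates(sets[[grid$model[i]]], tab$features)[,
      grid$response[i]]
    data.frame(
      model = grid$model[i], response = grid$response[i],
      subset = grid$subset[i],
      r2 = r2(obs, pred), rmse = rmse(obs, pred), mbe = mbe(obs, pred)
    )
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  test_r2 <- with(
    report[report$subset == "test", ],
    tapply(r2, model, mean)
  )
  attr(report, "best_model") <- names(test_r2)[which.max(test_r2)]
  report
}
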