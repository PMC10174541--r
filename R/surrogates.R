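split_digest <- function(table) {
  c(nrow(table$features), round(sum(table$features), 6),
    round(sum(table$responses), 6))
}

#' Fit one surrogate family to both responses
#'
#' Fits the requested regressor (GRNN, RBF network, or LM-trained MLP)
#' separately to contamination rate and seed germination percentage,
#' sharing one min-max input scaler fitted on the training features.
#' Responses stay on the raw percent scale.
#'
#' @param train An `observation_table` of training rows.
#' @param kind `"grnn"`, `"rbf"` or `"mlp"`.
#' @param seed Integer seed passed to the stochastic trainers.
#' @param ... Extra arguments passed through to [train_grnn()],
#'   [train_rbf()] or [train_mlp()].
#' @return Object of class `surrogate_set`: the scaler, the two fitted
#'   models, and a digest of the training rows used for provenance checks.
#' @export
fit_surrogates <- function(train, kind = c("grnn", "rbf", "mlp"),
                           seed = 1L, ...) {
  kind <- match.arg(kind)
  stopifnot(inherits(train, "observation_table"))
  scaler <- fit_scaler(train$features)
  Xs <- apply_scaler(scaler, train$features)
  fit_one <- function(y) {
    switch(kind,
      grnn = train_grnn(Xs, y, ...),
      rbf = train_rbf(Xs, y, seed = seed, ...),
      mlp = train_mlp(Xs, y, seed = seed, ...)
    )
  }
  structure(
    list(
      kind = kind, scaler = scaler,
      models = list(
        contamination = fit_one(train$responses[, "contamination"]),
        germination = fit_one(train$responses[, "germination"])
      ),
      digest = split_digest(train), seed = seed
    ),
    class = "surrogate_set"
  )
}

#' Predict both responses from a surrogate set
#'
#' @param set A `surrogate_set`.
#' @param X Raw (unscaled) feature matrix, 7 columns.
#' @return Matrix with columns `contamination` and `germination`.
#' @export
predict_surrogates <- function(set, X) {
  stopifnot(inherits(set, "surrogate_set"))
  Xs <- apply_scaler(set$scaler, as.matrix(X))
  cbind(
    contamination = predict(set$models$contamination, Xs),
    germination = predict(set$models$germination, Xs)
  )
}

#' @export
print.surrogate_set <- function(x, ...) {
  cat("surrogate_set:", toupper(x$kind), "models for contamination and",
      "germination,", x$digest[1], "training rows\n")
  invisible(x)
}

#' Serialize a surrogate set to a self-describing JSON artifact
#'
#' Writes architecture, fitted parameters, scaler and seed so a model can
#' be reloaded and audited without the training session.
#'
#' @param set A `surrogate_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_surrogates <- function(set, path) {
  stopifnot(inherits(set, "surrogate_set"))
  strip <- function(m) {
    u <- unclass(m)
    u <- lapply(u, function(v) {
      if (is.matrix(v)) list(data = as.vector(v), dim = dim(v)) else v
    })
    u$class <- class(m)
    u
  }
  obj <- list(
    kind = set$kind, seed = set$seed, digest = set$digest,
    scaler = unclass(set$scaler),
    models = lapply(set$models, strip)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_surrogates
#' @export
read_surrogates <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rebuild <- function(m) {
    cls <- m$class
    m$class <- NULL
    m <- lapply(m, function(v) {
      if (is.list(v) && identical(sort(names(v)), c("data", "dim"))) {
        matrix(unlist(v$data), v$dim[1], v$dim[2])
      } else {
        v
      }
    })
    if (!is.null(m$shapes)) m$shapes <- as.list(m$shapes)
    structure(m, class = cls)
  }
  scaler <- obj$scaler
  structure(
    list(
      kind = obj$kind, seed = obj$seed, digest = obj$digest,
      scaler = structure(
        list(min = scaler$min, max = scaler$max,
             constant = as.logical(scaler$constant)),
        class = "minmax_scaler"
      ),
      models = lapply(obj$models, rebuild)
    ),
    class = "surrogate_set"
  )
}
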