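#' Disinfectant registry
#'
#' The six sterilants screened in the petunia seed experiment, in the fixed
#' order used throughout the package for feature encoding: four conventional
#' chemical disinfectants (dosed as percent solutions) and two carbon
#' nanotube materials (dosed in mg/L).
#'
#' @return A data frame with columns `label` and `unit`, one row per
#'   disinfectant, in canonical slot order.
#' @export
#' @examples
#' disinfectant_info()
disinfectant_info <- function() {
  data.frame(
    label = c("NaOCl", "CaClO2", "HgCl2", "H2O2", "NWCNFe", "MWCNT"),
    unit  = c("%", "%", "%", "%", "mg/L", "mg/L"),
    stringsAsFactors = FALSE
  )
}

#' Names of the seven model inputs, in encoding order
#' @return Character vector: the six concentration slots then `time_min`.
#' @export
feature_names <- function() c(disinfectant_info()$label, "time_min")

treatment_columns <- c(
  "disinfectant", "concentration", "time_min",
  "contamination_mean", "contamination_se",
  "germination_mean", "germination_se"
)

#' Load the packaged treatment tables
#'
#' Reads the six transcribed disinfectant tables (mean and standard error of
#' contamination rate and seed germination percentage for every
#' concentration x immersion-time treatment, untreated controls included per
#' table) and returns them as one record per printed table row.
#'
#' @param path Directory holding the `table*.csv` fixtures. Defaults to the
#'   copies installed with the package.
#' @return A data frame of 90 treatment records (15 per disinfectant table)
#'   with columns `disinfectant`, `concentration`, `time_min`,
#'   `contamination_mean`, `contamination_se`, `germination_mean`,
#'   `germination_se`. Control rows carry concentration 0 under the table's
#'   disinfectant label.
#' @export
#' @examples
#' records <- load_treatment_tables()
#' nrow(records)
load_treatment_tables <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", package = "sterilopt")
  }
  files <- c(
    "table1_naocl.csv", "table2_caclo2.csv", "table3_hgcl2.csv",
    "table4_h2o2.csv", "table5_nwcnfe.csv", "table6_mwcnt.csv"
  )
  out <- vector("list", length(files))
  for (i in seq_along(files)) {
    fp <- file.path(path, files[i])
    if (!file.exists(fp)) {
      stop("treatment table fixture missing: ", files[i])
    }
    tab <- utils::read.csv(fp, stringsAsFactors = FALSE)
    if (!identical(names(tab), treatment_columns) || nrow(tab) != 15L) {
      stop("treatment table fixture corrupt: ", files[i])
    }
    validate_treatment_records(tab, files[i])
    out[[i]] <- tab
  }
  records <- do.call(rbind, out)
  rownames(records) <- NULL
  records
}

validate_treatment_records <- function(tab, what = "records") {
  ok_label <- tab$disinfectant %in% disinfectant_info()$label
  resp <- c(tab$contamination_mean, tab$germination_mean)
  if (!all(ok_label) ||
      any(!is.finite(as.matrix(tab[, -1]))) ||
      any(tab$concentration < 0) ||
      any(resp < 0 | resp > 100) ||
      any(tab$contamination_se < 0) ||
      any(tab$germination_se < 0)) {
    stop("treatment table fixture corrupt: ", what)
  }
  invisible(tab)
}

#' Encode treatment records as the 7-input feature matrix
#'
#' One row per record; the active disinfectant's concentration slot carries
#' its dose, the other five slots are zero, and the last column is the
#' immersion time in minutes. Controls (concentration 0) encode as all-zero
#' concentration slots. The design never mixes disinfectants, so at most one
#' slot is nonzero per row.
#'
#' @param records Data frame with at least `disinfectant`, `concentration`
#'   and `time_min` columns.
#' @return Numeric matrix (rows x 7) with columns [feature_names()].
#' @export
encode_features <- function(records) {
  info <- disinfectant_info()
  slot <- match(records$disinfectant, info$label)
  if (anyNA(slot)) {
    stop("unknown disinfectant label in records")
  }
  n <- nrow(records)
  X <- matrix(0, n, 7, dimnames = list(NULL, feature_names()))
  X[cbind(seq_len(n), slot)] <- records$concentration
  X[, 7] <- records$time_min
  if (any(rowSums(X[, 1:6, drop = FALSE] != 0) > 1)) {
    stop("a record activates more than one disinfectant slot")
  }
  if (any(!is.finite(X))) stop("non-finite feature values")
  X
}

#' Min-max scaler over feature columns
#'
#' Fits the per-column minimum and maximum of a training feature matrix so
#' that observed min maps to 0 and observed max to 1. Constant columns map
#' to 0 by convention (and invert back to their constant).
#'
#' @param X Numeric matrix with at least 2 rows.
#' @return An object of class `minmax_scaler`.
#' @export
fit_scaler <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 rows to fit a scaler")
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  structure(
    list(min = lo, max = hi, constant = hi <= lo),
    class = "minmax_scaler"
  )
}

#' @rdname fit_scaler
#' @param scaler A fitted `minmax_scaler`.
#' @export
apply_scaler <- function(scaler, X) {
  X <- as.matrix(X)
  stopifnot(inherits(scaler, "minmax_scaler"), ncol(X) == length(scaler$min))
  rng <- scaler$max - scaler$min
  rng[scaler$constant] <- 1  # constant columns map to 0
  S <- sweep(sweep(X, 2, scaler$min, "-"), 2, rng, "/")
  S[, scaler$constant] <- 0
  S
}

#' @rdname fit_scaler
#' @export
invert_scaler <- function(scaler, X) {
  X <- as.matrix(X)
  stopifnot(inherits(scaler, "minmax_scaler"), ncol(X) == length(scaler$min))
  rng <- scaler$max - scaler$min
  rng[scaler$constant] <- 0
  sweep(sweep(X, 2, rng, "*"), 2, scaler$min, "+")
}

#' Replicate-level observation table
#'
#' Container pairing a 7-column feature matrix with a 2-column response
#' matrix (contamination %, germination %) and the provenance of each row
#' (which printed treatment it came from).
#'
#' @param features Numeric matrix, rows x 7.
#' @param responses Numeric matrix, rows x 2, columns `contamination`,
#'   `germination`, values in \[0, 100\].
#' @param provenance Data frame with `disinfectant`, `concentration`,
#'   `time_min` (and optionally `record_id`) per row.
#' @return An object of class `observation_table`.
#' @export
observation_table <- function(features, responses, provenance) {
  features <- as.matrix(features)
  responses <- as.matrix(responses)
  stopifnot(
    nrow(features) == nrow(responses),
    nrow(features) == nrow(provenance),
    ncol(features) == 7L, ncol(responses) == 2L
  )
  if (any(responses < 0 | responses > 100)) {
    stop("responses must lie in [0, 100]")
  }
  colnames(features) <- feature_names()
  colnames(responses) <- c("contamination", "germination")
  structure(
    list(features = features, responses = responses, provenance = provenance),
    class = "observation_table"
  )
}

#' @export
print.observation_table <- function(x, ...) {
  cat(
    "observation_table:", nrow(x$features), "rows,",
    length(unique(x$provenance$disinfectant)), "disinfectant groups\n"
  )
  invisible(x)
}

subset_observation_table <- function(table, idx) {
  observation_table(
    table$features[idx, , drop = FALSE],
    table$responses[idx, , drop = FALSE],
    table$provenance[idx, , drop = FALSE]
  )
}

#' Merge records and responses into an observation table
#'
#' Convenience constructor used for mean-level (one row per treatment)
#' tables; [expand_replicates()] builds the replicate-level version.
#'
#' @param records Treatment records as from [load_treatment_tables()].
#' @return An `observation_table` with one row per record.
#' @export
records_to_table <- function(records) {
  observation_table(
    encode_features(records),
    cbind(
      contamination = records$contamination_mean,
      germination = records$germination_mean
    ),
    records[, c("disinfectant", "concentration", "time_min")]
  )
}

#' Stratified train/test split of an observation table
#'
#' Randomly partitions the rows into disjoint training and test subsets,
#' stratified by disinfectant so that every disinfectant appears in both
#' subsets. The global training size is `floor(train_fraction * n)`,
#' apportioned across strata by largest remainder.
#'
#' @param table An `observation_table`.
#' @param train_fraction Fraction of rows assigned to training, in (0, 1).
#' @param seed Integer seed; the same seed always yields the same partition.
#' @return List with `train` and `test` observation tables and the integer
#'   row indices `train_idx`, `test_idx`.
#' @export
split_train_test <- function(table, train_fraction = 0.8, seed = 1L) {
  stopifnot(
    inherits(table, "observation_table"),
    train_fraction > 0, train_fraction < 1
  )
  n <- nrow(table$features)
  strata <- as.character(table$provenance$disinfectant)
  # fix the stratum order by first appearance: locale-independent, so the
  # seeded partition is identical across platforms and collation settings
  groups <- split(seq_len(n), factor(strata, levels = unique(strata)))
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    stop("too few rows per disinfectant to stratify the split")
  }
  n_train <- floor(train_fraction * n)
  if (n_train < length(groups) || n - n_train < length(groups)) {
    stop("table too small to place every disinfectant in both subsets")
  }
  # largest-remainder apportionment, each stratum keeping >= 1 row per side
  quota <- train_fraction * sizes
  base <- pmin(pmax(floor(quota), 1L), sizes - 1L)
  rem <- n_train - sum(base)
  ord <- order(quota - floor(quota), decreasing = TRUE)
  i <- 1L
  while (rem != 0L && i <= 1000L) {
    k <- ord[((i - 1L) %% length(base)) + 1L]
    if (rem > 0L && base[k] < sizes[k] - 1L) {
      base[k] <- base[k] + 1L; rem <- rem - 1L
    } else if (rem < 0L && base[k] > 1L) {
      base[k] <- base[k] - 1L; rem <- rem + 1L
    }
    i <- i + 1L
  }
  set.seed(seed)
  train_idx <- sort(unlist(
    Map(function(idx, k) sample(idx)[seq_len(k)], groups, base),
    use.names = FALSE
  ))
  test_idx <- setdiff(seq_len(n), train_idx)
  list(
    train = subset_observation_table(table, train_idx),
    test = subset_observation_table(table, test_idx),
    train_idx = train_idx, test_idx = test_idx
  )
}
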