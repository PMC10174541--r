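#' Truncated-normal draws on [lo, hi]
#'
#' Exact inverse-CDF sampling (no clipping, so no point mass at the
#' bounds). Degenerate sd = 0 returns the mean.
#'
#' @keywords internal
rtruncnorm_unit <- function(n, mean, sd, lo = 0, hi = 100) {
  if (sd <= 0) return(rep(mean, n))
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

#' Expand printed treatment means into replicate-level observations
#'
#' The published tables report the mean and standard error of each
#' treatment over its sub-set datapoints; the raw replicate values are not
#' published. This generator reconstructs a replicate-level dataset by
#' drawing, for each treatment, `replicates` values per response from a
#' normal law centred on the printed mean with per-datapoint standard
#' deviation `SE * sqrt(replicates)`, truncated to \[0, 100\] (truncation by
#' resampling, realized exactly through the inverse CDF, so the bounds
#' carry no point mass).
#'
#' @param records Treatment records as from [load_treatment_tables()].
#' @param replicates Positive integer, datapoints simulated per treatment
#'   (default 8, the sub-set count of the original design).
#' @param seed Integer seed; same seed, same table.
#' @param noise_subsets Number of sub-set datapoints the printed standard
#'   errors are assumed to average over; the reconstructed per-datapoint
#'   sd is `SE * sqrt(noise_subsets)`. Kept separate from `replicates` so
#'   simulating more datapoints does not inflate the reconstructed noise.
#' @return An `observation_table` with `replicates * nrow(records)` rows.
#' @export
#' @examples
#' obs <- expand_replicates(load_treatment_tables(), replicates = 8, seed = 1)
#' nrow(obs$features)
expand_replicates <- function(records, replicates = 8L, seed = 1L,
                              noise_subsets = 8L) {
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) {
    stop("replicates must be a positive integer")
  }
  validate_treatment_records(records)
  set.seed(seed)
  n <- nrow(records)
  idx <- rep(seq_len(n), each = replicates)
  sd_scale <- sqrt(noise_subsets)  # printed SE averages the sub-set datapoints
  cont <- germ <- numeric(length(idx))
  for (i in seq_len(n)) {
    rows <- which(idx == i)
    cont[rows] <- rtruncnorm_unit(
      replicates, records$contamination_mean[i],
      records$contamination_se[i] * sd_scale
    )
    germ[rows] <- rtruncnorm_unit(
      replicates, records$germination_mean[i],
      records$germination_se[i] * sd_scale
    )
  }
  prov <- records[idx, c("disinfectant", "concentration", "time_min")]
  prov$record_id <- idx
  observation_table(
    encode_features(records)[idx, , drop = FALSE],
    cbind(contamination = cont, germination = germ),
    prov
  )
}

benchmark_registry <- function() {
  list(
    # unimodal germination bump, logistic contamination decay in dose
    # (higher dose and longer soak kill contaminants but stress seeds)
    germ_peak = list(
      conc_range = c(0, 10), time_range = c(5, 20),
      germination = function(c, t) {
        5 + 90 * exp(-((c - 6)^2 / (2 * 2^2) + (t - 12)^2 / (2 * 3^2)))
      },
      contamination = function(c, t) {
        1 + 96 / (1 + exp(1.1 * (c - 3))) * (1 - 0.25 * (t - 5) / 15)
      }
    ),
    sharp_peak = list(
      conc_range = c(0, 10), time_range = c(5, 20),
      germination = function(c, t) {
        3 + 92 * exp(-((c - 7.5)^2 / (2 * 1.2^2) + (t - 8)^2 / (2 * 2^2)))
      },
      contamination = function(c, t) {
        2 + 94 / (1 + exp(1.6 * (c - 5))) * (1 - 0.15 * (t - 5) / 15)
      }
    )
  )
}

#' Synthetic bi-objective benchmark surface with a known optimum
#'
#' Builds an analytic pair of response surfaces over (concentration,
#' immersion time) — a unimodal germination peak and a monotone-decreasing
#' contamination curve — samples them on a grid with optional additive
#' truncated-normal noise, and returns both the sampled observation table
#' and the generating truth. The truth records the utopia values (surface
#' minimum contamination, maximum germination over the domain) and the
#' input minimizing the Euclidean distance to them, found by dense grid
#' search, so optimizer runs can be checked against a known answer.
#'
#' @param kind One of `"germ_peak"`, `"sharp_peak"`.
#' @param noise_sd Additive noise standard deviation (percent points).
#' @param seed Integer seed.
#' @param grid_n Grid points per input axis for the sampled table.
#' @param active_slot Which disinfectant slot (1-6) carries the
#'   concentration in the encoded features.
#' @return List with `table` (an `observation_table`) and `surface` (the
#'   generating functions, domain, utopia values and `optimum_input`).
#' @export
make_benchmark_surface <- function(kind = "germ_peak", noise_sd = 0,
                                   seed = 1L, grid_n = 12L,
                                   active_slot = 1L) {
  reg <- benchmark_registry()
  if (!kind %in% names(reg)) {
    stop("unknown benchmark surface kind: ", kind)
  }
  surf <- reg[[kind]]
  # dense grid search for the true utopia point and ideal input
  cc <- seq(surf$conc_range[1], surf$conc_range[2], length.out = 201)
  tt <- seq(surf$time_range[1], surf$time_range[2], length.out = 201)
  gg <- expand.grid(conc = cc, time = tt)
  f_cont <- surf$contamination(gg$conc, gg$time)
  f_germ <- surf$germination(gg$conc, gg$time)
  m <- min(f_cont); n_util <- max(f_germ)
  d <- sqrt((f_cont - m)^2 + (f_germ - n_util)^2)
  best <- which.min(d)
  surface <- list(
    kind = kind,
    contamination = surf$contamination, germination = surf$germination,
    conc_range = surf$conc_range, time_range = surf$time_range,
    noise_sd = noise_sd, utopia = c(contamination = m, germination = n_util),
    optimum_input = c(conc = gg$conc[best], time = gg$time[best]),
    active_slot = as.integer(active_slot)
  )
  set.seed(seed)
  gconc <- seq(surf$conc_range[1], surf$conc_range[2], length.out = grid_n)
  gtime <- seq(surf$time_range[1], surf$time_range[2], length.out = grid_n)
  pts <- expand.grid(conc = gconc, time = gtime)
  n <- nrow(pts)
  mu_c <- surf$contamination(pts$conc, pts$time)
  mu_g <- surf$germination(pts$conc, pts$time)
  cont <- germ <- numeric(n)
  for (i in seq_len(n)) {
    cont[i] <- rtruncnorm_unit(1, mu_c[i], noise_sd)
    germ[i] <- rtruncnorm_unit(1, mu_g[i], noise_sd)
  }
  X <- matrix(0, n, 7, dimnames = list(NULL, feature_names()))
  X[, active_slot] <- pts$conc
  X[, 7] <- pts$time
  label <- disinfectant_info()$label[active_slot]
  tab <- observation_table(
    X, cbind(contamination = cont, germination = germ),
    data.frame(
      disinfectant = label, concentration = pts$conc, time_min = pts$time
    )
  )
  list(table = tab, surface = surface)
}
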