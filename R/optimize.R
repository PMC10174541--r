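#' Build a per-disinfectant optimization scenario
#'
#' Freezes the five inactive disinfectant slots at zero and lets the
#' active concentration vary over \[0, max tested level\] and the
#' immersion time over the tested time range of that disinfectant's
#' table. The observed reference values for ideal-point selection — the
#' subset's minimum contamination mean `m` and maximum germination mean
#' `n` — are taken from the same subset.
#'
#' @param records Treatment records as from [load_treatment_tables()].
#' @param disinfectant One label from [disinfectant_info()].
#' @return Object of class `scenario`.
#' @export
make_scenario <- function(records, disinfectant) {
  info <- disinfectant_info()
  slot <- match(disinfectant, info$label)
  if (is.na(slot)) stop("unknown disinfectant: ", disinfectant)
  sub <- records[records$disinfectant == disinfectant, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no records for disinfectant: ", disinfectant)
  structure(
    list(
      disinfectant = disinfectant, slot = slot,
      conc_bounds = c(0, max(sub$concentration)),
      time_bounds = range(sub$time_min),
      m = min(sub$contamination_mean),
      n = max(sub$germination_mean)
    ),
    class = "scenario"
  )
}

#' Select the ideal point of a Pareto front
#'
#' Returns the front member minimizing the Euclidean distance
#' sqrt((contamination - m)^2 + (germination - n)^2) to the utopia point
#' formed by the minimum observed contamination `m` and maximum observed
#' germination `n`. Exact ties are broken in favour of lower
#' contamination.
#'
#' @param objectives Matrix with columns `contamination` and
#'   `germination` (natural percent scale), one row per front member.
#' @param m,n Observed reference values.
#' @return Integer index of the selected member, with the distance vector
#'   as attribute `distance`.
#' @export
ideal_point_select <- function(objectives, m, n) {
  objectives <- as.matrix(objectives)
  if (nrow(objectives) == 0L) stop("empty Pareto front")
  d <- sqrt((objectives[, 1] - m)^2 + (objectives[, 2] - n)^2)
  best <- which(d <= min(d) + 1e-12)
  idx <- best[which.min(objectives[best, 1])]
  attr(idx, "distance") <- d
  idx
}

#' Run NSGA-II over a surrogate pair for one disinfectant scenario
#'
#' Drives the two trained response models with the genetic search:
#' contamination is minimized and germination maximized over the
#' scenario's (concentration, time) box while the other five
#' concentration genes stay fixed at zero. The returned solution is the
#' first front of the final population plus its ideal-point member.
#'
#' @param set A `surrogate_set` (both responses).
#' @param scenario A `scenario` from [make_scenario()].
#' @param pop_size,generations,crossover_rate,mutation_rate,mutation_sd_frac
#'   GA settings; see [nsga2()].
#' @param seed Integer seed.
#' @return Object of class `pareto_result`: `front` (decision matrix
#'   `X` and `objectives`), `ideal` (input vector, objective pair and
#'   distance), the references `m`, `n`, and the per-generation
#'   ideal-distance `trace`.
#' @export
evolve <- function(set, scenario, pop_size = 85L, generations = 800L,
                   crossover_rate = 0.70, mutation_rate = 0.01,
                   mutation_sd_frac = 0.1, seed = 1L) {
  stopifnot(inherits(set, "surrogate_set"), inherits(scenario, "scenario"))
  if (diff(scenario$conc_bounds) < 0 || diff(scenario$time_bounds) < 0) {
    stop("scenario bounds are inverted")
  }
  lower <- rep(0, 7)
  upper <- rep(0, 7)
  lower[scenario$slot] <- scenario$conc_bounds[1]
  upper[scenario$slot] <- scenario$conc_bounds[2]
  lower[7] <- scenario$time_bounds[1]
  upper[7] <- scenario$time_bounds[2]
  active <- c(scenario$slot, 7L)
  repair <- function(X) {
    X[, setdiff(seq_len(7), active)] <- 0
    X
  }
  res <- nsga2(
    objective = function(X) predict_surrogates(set, X),
    n_var = 7L, lower = lower, upper = upper,
    senses = c("min", "max"), pop_size = pop_size,
    generations = generations, crossover_rate = crossover_rate,
    mutation_rate = mutation_rate, mutation_sd_frac = mutation_sd_frac,
    seed = seed, repair = repair,
    utopia = c(scenario$m, scenario$n)
  )
  f1 <- res$fronts[[1]]
  front_X <- res$X[f1, , drop = FALSE]
  front_obj <- res$objectives[f1, , drop = FALSE]
  idx <- ideal_point_select(front_obj, scenario$m, scenario$n)
  structure(
    list(
      scenario = scenario,
      front = list(X = front_X, objectives = front_obj),
      ideal = list(
        x = front_X[idx, ],
        objectives = front_obj[idx, ],
        distance = attr(idx, "distance")[idx]
      ),
      m = scenario$m, n = scenario$n,
      trace = res$trace,
      config = list(
        pop_size = pop_size, generations = generations,
        crossover_rate = crossover_rate, mutation_rate = mutation_rate,
        mutation_sd_frac = mutation_sd_frac, seed = seed
      )
    ),
    class = "pareto_result"
  )
}

#' @export
print.pareto_result <- function(x, ...) {
  cat(
    "pareto_result:", x$scenario$disinfectant, "-",
    nrow(x$front$X), "front members; ideal point:",
    sprintf(
      "%.2f %s x %.2f min -> contamination %.2f%%, germination %.2f%%\n",
      x$ideal$x[x$scenario$slot],
      disinfectant_info()$unit[x$scenario$slot],
      x$ideal$x[7], x$ideal$objectives[1], x$ideal$objectives[2]
    )
  )
  invisible(x)
}
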