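as_minimization <- function(obj, senses) {
  obj <- as.matrix(obj)
  stopifnot(length(senses) == ncol(obj), all(senses %in% c("min", "max")))
  for (k in which(senses == "max")) obj[, k] <- -obj[, k]
  obj
}

dominance_matrix <- function(M) {
  # dom[i, j] TRUE when i dominates j (all objectives <=, at least one <)
  le <- Reduce(`&`, lapply(seq_len(ncol(M)), function(k) {
    outer(M[, k], M[, k], `<=`)
  }))
  lt <- Reduce(`|`, lapply(seq_len(ncol(M)), function(k) {
    outer(M[, k], M[, k], `<`)
  }))
  le & lt
}

#' Fast non-dominated sorting
#'
#' Partitions a set of objective vectors into Pareto fronts F1, F2, ...:
#' every member of F1 is non-dominated in the whole set, and each member
#' of a later front is dominated only by members of earlier fronts.
#'
#' @param obj Numeric matrix, one row per solution, one column per
#'   objective.
#' @param senses Character vector, `"min"` or `"max"` per objective.
#' @return List of integer vectors of row indices, one per front (empty
#'   list for empty input).
#' @export
fast_non_dominated_sort <- function(obj, senses = rep("min", ncol(obj))) {
  obj <- as.matrix(obj)
  if (nrow(obj) == 0L) return(list())
  stopifnot(all(is.finite(obj)))
  M <- as_minimization(obj, senses)
  dom <- dominance_matrix(M)
  n <- nrow(M)
  assigned <- rep(FALSE, n)
  fronts <- list()
  while (!all(assigned)) {
    una <- which(!assigned)
    nd <- colSums(dom[una, una, drop = FALSE])
    f <- una[nd == 0]
    fronts[[length(fronts) + 1L]] <- f
    assigned[f] <- TRUE
  }
  fronts
}

#' Crowding distance within one front
#'
#' Per objective, the solutions at the sorted extremes receive infinite
#' distance; interior solutions accumulate the gap between their two
#' neighbors normalized by the objective's range (zero-range objectives
#' contribute nothing).
#'
#' @param obj Numeric matrix of the front's objective values (senses do
#'   not matter for spacing).
#' @return Numeric vector of crowding distances.
#' @export
crowding_distance <- function(obj) {
  obj <- as.matrix(obj)
  n <- nrow(obj)
  if (n == 0L) return(numeric(0))
  d <- rep(0, n)
  for (k in seq_len(ncol(obj))) {
    v <- obj[, k]
    ord <- order(v)
    d[ord[1]] <- Inf
    d[ord[n]] <- Inf
    rng <- v[ord[n]] - v[ord[1]]
    if (n > 2L && rng > 0) {
      mid <- ord[2:(n - 1L)]
      d[mid] <- d[mid] + (v[ord[3:n]] - v[ord[1:(n - 2L)]]) / rng
    }
  }
  d
}

rank_and_crowd <- function(obj, senses) {
  fronts <- fast_non_dominated_sort(obj, senses)
  n <- nrow(obj)
  rk <- integer(n)
  cd <- numeric(n)
  for (i in seq_along(fronts)) {
    f <- fronts[[i]]
    rk[f] <- i
    cd[f] <- crowding_distance(obj[f, , drop = FALSE])
  }
  list(rank = rk, crowding = cd, fronts = fronts)
}

two_point_crossover <- function(a, b) {
  nv <- length(a)
  cuts <- sort(sample(0:nv, 2))
  if (cuts[1] < cuts[2]) {
    seg <- (cuts[1] + 1L):cuts[2]
    tmp <- a[seg]
    a[seg] <- b[seg]
    b[seg] <- tmp
  }
  list(a, b)
}

#' NSGA-II over box-bounded real decision vectors
#'
#' Elitist multi-objective genetic algorithm: binary tournament selection
#' on (rank, crowding distance), two-point crossover, per-gene Gaussian
#' mutation clipped to bounds, and (mu + lambda) environmental selection
#' by non-dominated rank with crowding-distance truncation of the last
#' admitted front.
#'
#' @param objective Function taking a population matrix (rows =
#'   individuals) and returning a matrix of objective values.
#' @param n_var Number of decision variables.
#' @param lower,upper Bound vectors (equal bounds freeze a gene).
#' @param senses `"min"`/`"max"` per objective.
#' @param pop_size,generations,crossover_rate,mutation_rate GA settings
#'   (defaults: 85, 800, 0.70, 0.01 — the study's calibration).
#' @param mutation_sd_frac Mutation step s.d. as a fraction of each
#'   gene's range.
#' @param seed Integer seed; runs are reproducible.
#' @param repair Optional function applied to the population matrix after
#'   variation (e.g. re-masking frozen genes).
#' @param utopia Optional objective-space reference point; when given,
#'   the per-generation minimum Euclidean distance of the population to
#'   it is recorded in `trace`.
#' @return List with final `X`, `objectives`, `fronts` (indices into the
#'   final population), and `trace`.
#' @export
nsga2 <- function(objective, n_var, lower, upper,
                  senses = c("min", "min"), pop_size = 85L,
                  generations = 800L, crossover_rate = 0.70,
                  mutation_rate = 0.01, mutation_sd_frac = 0.1,
                  seed = 1L, repair = NULL, utopia = NULL) {
  stopifnot(
    length(lower) == n_var, length(upper) == n_var, all(upper >= lower),
    crossover_rate >= 0, crossover_rate <= 1,
    mutation_rate >= 0, mutation_rate <= 1, pop_size >= 2L
  )
  set.seed(seed)
  rng <- upper - lower
  clip <- function(X) {
    for (j in seq_len(n_var)) {
      X[, j] <- pmin(pmax(X[, j], lower[j]), upper[j])
    }
    X
  }
  fix <- function(X) if (is.null(repair)) X else repair(X)
  P <- fix(sweep(
    matrix(stats::runif(pop_size * n_var), pop_size, n_var), 2, rng, `*`
  ) + matrix(lower, pop_size, n_var, byrow = TRUE))
  obj_P <- as.matrix(objective(P))
  trace <- if (is.null(utopia)) NULL else numeric(generations)
  for (gen in seq_len(generations)) {
    rc <- rank_and_crowd(obj_P, senses)
    pick <- function() {
      ij <- sample.int(pop_size, 2L, replace = TRUE)
      i <- ij[1]; j <- ij[2]
      if (rc$rank[i] < rc$rank[j]) i
      else if (rc$rank[j] < rc$rank[i]) j
      else if (rc$crowding[i] >= rc$crowding[j]) i else j
    }
    Q <- matrix(0, pop_size, n_var)
    i <- 1L
    while (i <= pop_size) {
      pa <- P[pick(), ]
      pb <- P[pick(), ]
      if (stats::runif(1) < crossover_rate) {
        ch <- two_point_crossover(pa, pb)
        pa <- ch[[1]]; pb <- ch[[2]]
      }
      Q[i, ] <- pa
      if (i + 1L <= pop_size) Q[i + 1L, ] <- pb
      i <- i + 2L
    }
    mut <- matrix(stats::runif(pop_size * n_var) < mutation_rate,
                  pop_size, n_var)
    if (any(mut)) {
      step <- matrix(stats::rnorm(pop_size * n_var), pop_size, n_var) *
        matrix(mutation_sd_frac * rng, pop_size, n_var, byrow = TRUE)
      Q <- Q + mut * step
    }
    Q <- fix(clip(Q))
    obj_Q <- as.matrix(objective(Q))
    R <- rbind(P, Q)
    obj_R <- rbind(obj_P, obj_Q)
    rcR <- rank_and_crowd(obj_R, senses)
    keep <- integer(0)
    for (f in rcR$fronts) {
      if (length(keep) + length(f) <= pop_size) {
        keep <- c(keep, f)
      } else {
        need <- pop_size - length(keep)
        cd <- crowding_distance(obj_R[f, , drop = FALSE])
        keep <- c(keep, f[order(cd, decreasing = TRUE)[seq_len(need)]])
        break
      }
    }
    P <- R[keep, , drop = FALSE]
    obj_P <- obj_R[keep, , drop = FALSE]
    if (!is.null(trace)) {
      trace[gen] <- min(sqrt(rowSums(
        sweep(obj_P, 2, utopia, `-`)^2
      )))
    }
  }
  rc <- rank_and_crowd(obj_P, senses)
  list(X = P, objectives = obj_P, fronts = rc$fronts, trace = trace)
}
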