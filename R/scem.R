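#' SCEM-UA sampler configuration
#'
#' Tuning constants of the Shuffled Complex Evolution Metropolis sampler.
#' `population_size` (s) points are ranked and dealt into `n_complexes`
#' (q) complexes of m = s/q members; each complex drives one Metropolis
#' sequence for `steps_per_shuffle` (L) steps between shuffles. The
#' proposal is a multivariate normal with covariance `jump_scale^2` (c_n^2)
#' times the complex covariance, re-centered on the complex mean when the
#' sequence density trails the complex mean density by more than a factor
#' `density_ratio_threshold` (T) or the acceptance rate drops below
#' `min_accept_rate` (AR_min). Shuffling stops when every parameter's
#' Gelman-Rubin statistic falls below `gr_threshold` or after
#' `max_shuffles` rounds.
#'
#' @param population_size number of points s, divisible by `n_complexes`.
#' @param n_complexes number of complexes q (= number of sequences).
#' @param steps_per_shuffle Metropolis steps L per complex per shuffle;
#'   `NULL` uses the complex size m.
#' @param density_ratio_threshold trigger T for re-centering a stuck
#'   sequence on its complex mean.
#' @param min_accept_rate acceptance-rate trigger AR_min for the same.
#' @param jump_scale proposal scale c_n; `NULL` uses 2.4/sqrt(n_params),
#'   the asymptotically optimal normal jump rate.
#' @param gr_threshold Gelman-Rubin convergence bound (> 1).
#' @param max_shuffles cap on shuffling rounds.
#' @param burn_fraction leading fraction of each sequence discarded before
#'   the convergence diagnostic.
#' @return object of class `scem_config`.
#' @export
scem_config <- function(population_size = 40, n_complexes = 5,
                        steps_per_shuffle = NULL,
                        density_ratio_threshold = 1e6,
                        min_accept_rate = 0.1, jump_scale = NULL,
                        gr_threshold = 1.2, max_shuffles = 30,
                        burn_fraction = 0.5) {
  s <- population_size; q <- n_complexes
  if (s < 2 * q || s %% q != 0)
    stop("'population_size' must be a multiple of 'n_complexes' with at least 2 points per complex",
         call. = FALSE)
  if (!is.null(steps_per_shuffle) && steps_per_shuffle < 1)
    stop("'steps_per_shuffle' must be >= 1", call. = FALSE)
  if (min_accept_rate <= 0 || min_accept_rate >= 1)
    stop("'min_accept_rate' must be in (0, 1)", call. = FALSE)
  if (!is.null(jump_scale) && jump_scale <= 0)
    stop("'jump_scale' must be positive", call. = FALSE)
  if (gr_threshold <= 1)
    stop("'gr_threshold' must exceed 1", call. = FALSE)
  if (burn_fraction < 0 || burn_fraction >= 1)
    stop("'burn_fraction' must be in [0, 1)", call. = FALSE)
  structure(list(population_size = s, n_complexes = q,
                 steps_per_shuffle = steps_per_shuffle,
                 density_ratio_threshold = density_ratio_threshold,
                 min_accept_rate = min_accept_rate,
                 jump_scale = jump_scale, gr_threshold = gr_threshold,
                 max_shuffles = max_shuffles,
                 burn_fraction = burn_fraction),
            class = "scem_config")
}

#' Draw the initial population from the uniform prior
#'
#' @param objective function `(theta, bounds) -> log density`.
#' @param bounds a [param_bounds()] object.
#' @param s population size.
#' @return unranked population: list with `points` (s x n matrix) and
#'   `densities` (length-s log densities).
#' @export
sample_prior <- function(objective, bounds, s) {
  stopifnot(inherits(bounds, "param_bounds"))
  n <- length(bounds$lower)
  pts <- vapply(seq_len(n), function(j) {
    stats::runif(s, bounds$lower[j], bounds$upper[j])
  }, numeric(s))
  pts <- matrix(pts, nrow = s, ncol = n)
  dens <- apply(pts, 1L, objective, bounds = bounds)
  if (any(is.nan(dens)))
    stop("objective returned NaN on a prior sample", call. = FALSE)
  list(points = pts, densities = dens)
}

#' Rank a population by decreasing posterior density
#'
#' Stable sort: ties keep their original relative order. Point-density
#' pairing is preserved.
#'
#' @param population list with `points` matrix and `densities` vector.
#' @return the population with rows reordered so densities are
#'   nonincreasing.
#' @export
rank_population <- function(population) {
  ord <- order(-population$densities)   # order() is a stable sort
  list(points = population$points[ord, , drop = FALSE],
       densities = population$densities[ord])
}

#' Deal a ranked population into complexes
#'
#' Striped partition: complex k receives ranked points q(j-1)+k for
#' j = 1..m, so every complex spans the full density range.
#'
#' @param population a ranked population.
#' @param q number of complexes; must divide the population size.
#' @return list of q complexes, each a list with `points` and `densities`.
#' @export
partition_complexes <- function(population, q) {
  s <- nrow(population$points)
  if (s %% q != 0)
    stop("population size must be divisible by the number of complexes",
         call. = FALSE)
  lapply(seq_len(q), function(k) {
    idx <- seq(k, s, by = q)
    list(points = population$points[idx, , drop = FALSE],
         densities = population$densities[idx])
  })
}

#' Merge complexes back into a ranked population
#'
#' @param complexes list of complexes as produced by
#'   [partition_complexes()].
#' @return ranked population containing the union of all members.
#' @export
shuffle_back <- function(complexes) {
  pop <- list(
    points = do.call(rbind, lapply(complexes, `[[`, "points")),
    densities = unlist(lapply(complexes, `[[`, "densities"))
  )
  rank_population(pop)
}

# Proposal covariance from complex spread: c_n^2 * cov(points), with a
# small diagonal jitter (scaled by the squared bound widths) so degenerate
# complexes still propose moves.
.proposal_cov <- function(points, jump_scale, bounds) {
  n <- ncol(points)
  sigma <- if (nrow(points) >= 2) stats::cov(points) else
    matrix(0, n, n)
  width <- bounds$upper - bounds$lower
  jump_scale^2 * sigma + diag(1e-10 * width^2, n)
}

#' One sequence-evolution (SEM) pass over a complex
#'
#' Runs `n_steps` Metropolis steps of the sequence attached to a complex.
#' Candidates are drawn from a multivariate normal centered on the current
#' draw (or on the complex mean when the sequence is stuck, see
#' [scem_config()]) with covariance `jump_scale^2 * cov(complex)`.
#' Accepted candidates extend the sequence and replace the worst complex
#' member; rejected steps repeat the current draw, as in any Metropolis
#' chain, but a rejected candidate that still beats the worst complex
#' member takes that member's place, so the complex keeps contracting
#' toward the high-density region.
#'
#' @param sequence list with `points` matrix, `densities`, `n_proposed`,
#'   `n_accepted`.
#' @param complex one complex (list with `points`, `densities`).
#' @param cfg a [scem_config()] object.
#' @param objective function `(theta, bounds) -> log density`.
#' @param bounds a [param_bounds()] object.
#' @param n_steps number of Metropolis steps.
#' @return list with updated `sequence`, `complex`, and `best` (the
#'   highest-density point evaluated, with its density).
#' @export
sem_update <- function(sequence, complex, cfg, objective, bounds,
                       n_steps) {
  n <- ncol(complex$points)
  jump <- if (is.null(cfg$jump_scale)) 2.4 / sqrt(n) else cfg$jump_scale
  cur <- sequence$points[nrow(sequence$points), ]
  cur_d <- sequence$densities[length(sequence$densities)]
  best <- list(theta = cur, density = cur_d)
  log_T <- log(cfg$density_ratio_threshold)

  for (step in seq_len(n_steps)) {
    sigma <- .proposal_cov(complex$points, jump, bounds)
    finite_d <- complex$densities[is.finite(complex$densities)]
    mean_d <- if (length(finite_d)) mean(finite_d) else -Inf
    ar <- if (sequence$n_proposed > 0)
      sequence$n_accepted / sequence$n_proposed else 1
    stuck <- (is.finite(mean_d) && (mean_d - cur_d) > log_T) ||
      ar < cfg$min_accept_rate
    center <- if (stuck) colMeans(complex$points) else cur

    cand <- MASS::mvrnorm(1, mu = center, Sigma = sigma)
    cand_d <- objective(cand, bounds)
    if (is.nan(cand_d))
      stop("objective returned NaN during sequence evolution",
           call. = FALSE)
    sequence$n_proposed <- sequence$n_proposed + 1L
    accepted <- is.finite(cand_d) &&
      log(stats::runif(1)) < (cand_d - cur_d)
    if (accepted) {
      sequence$n_accepted <- sequence$n_accepted + 1L
      cur <- cand
      cur_d <- cand_d
    }
    # an accepted candidate always enters the complex; a rejected one
    # still replaces the worst member when it improves on it, which keeps
    # the complex contracting toward the high-density region
    worst <- which.min(complex$densities)
    if (accepted || (is.finite(cand_d) &&
                     cand_d > complex$densities[worst])) {
      complex$points[worst, ] <- cand
      complex$densities[worst] <- cand_d
    }
    sequence$points <- rbind(sequence$points, cur)
    sequence$densities <- c(sequence$densities, cur_d)
    if (cand_d > best$density) best <- list(theta = cand, density = cand_d)
  }
  list(sequence = sequence, complex = complex, best = best)
}

#' Gelman-Rubin convergence diagnostic
#'
#' Per-parameter potential scale reduction
#' `R_hat = sqrt(((n-1)/n * W + B/n) / W)` over the retained (post-burn)
#' portion of the sequences, with W the mean within-chain variance and
#' B = n * var(chain means). Zero within-chain variance yields an `Inf`
#' sentinel (not converged).
#'
#' @param chains list (>= 2) of draw matrices, one row per draw, one
#'   column per parameter.
#' @param burn_fraction leading fraction of each chain to discard.
#' @return numeric vector of R-hat values, one per parameter.
#' @export
gelman_rubin <- function(chains, burn_fraction = 0.5) {
  if (length(chains) < 2L)
    stop("at least two chains are required", call. = FALSE)
  chains <- lapply(chains, function(ch) {
    ch <- as.matrix(ch)
    keep <- seq.int(floor(burn_fraction * nrow(ch)) + 1L, nrow(ch))
    ch[keep, , drop = FALSE]
  })
  len <- min(vapply(chains, nrow, integer(1)))
  if (len < 2L)
    stop("each chain needs at least two retained draws", call. = FALSE)
  chains <- lapply(chains, function(ch)
    ch[seq.int(nrow(ch) - len + 1L, nrow(ch)), , drop = FALSE])
  n_par <- ncol(chains[[1]])
  vapply(seq_len(n_par), function(j) {
    draws <- vapply(chains, function(ch) ch[, j], numeric(len))
    w <- mean(apply(draws, 2L, stats::var))
    b <- len * stats::var(colMeans(draws))
    if (w <= 0) return(Inf)
    sqrt(((len - 1) / len * w + b / len) / w)
  }, numeric(1))
}

#' Run the SCEM-UA global search
#'
#' Full sampler loop: draw the prior population, rank, seed one sequence
#' per complex from the top-ranked points, then alternate striped
#' partitioning, sequence evolution within each complex, and shuffling
#' until every parameter's Gelman-Rubin statistic is below the threshold
#' or the shuffle budget is spent. The best point ever evaluated is
#' returned regardless of convergence.
#'
#' @param objective function `(theta, bounds) -> log density`.
#' @param bounds a [param_bounds()] object.
#' @param cfg a [scem_config()] object.
#' @param seed optional integer seed ([set.seed()]) for a reproducible run.
#' @return list of class `scem_result`: `theta`, `log_density`, `chains`
#'   (per-chain draw matrices with a `shuffle` index column), `r_hat`,
#'   `converged`, `n_shuffles`, `n_evaluations`.
#' @export
run_scem <- function(objective, bounds, cfg = scem_config(), seed = NULL) {
  stopifnot(inherits(cfg, "scem_config"), inherits(bounds, "param_bounds"))
  if (!is.null(seed)) set.seed(seed)
  s <- cfg$population_size
  q <- cfg$n_complexes
  m <- s %/% q
  L <- if (is.null(cfg$steps_per_shuffle)) m else cfg$steps_per_shuffle
  n <- length(bounds$lower)

  pop <- rank_population(sample_prior(objective, bounds, s))
  n_eval <- s
  best_i <- which.max(pop$densities)
  best <- list(theta = pop$points[best_i, ], density = pop$densities[best_i])

  sequences <- lapply(seq_len(q), function(k) list(
    points = pop$points[k, , drop = FALSE],
    densities = pop$densities[k],
    shuffle = 0L,
    n_proposed = 0L, n_accepted = 0L))

  r_hat <- rep(Inf, n)
  converged <- FALSE
  shuffle <- 0L
  while (shuffle < cfg$max_shuffles) {
    shuffle <- shuffle + 1L
    complexes <- partition_complexes(pop, q)
    for (k in seq_len(q)) {
      upd <- sem_update(sequences[[k]], complexes[[k]], cfg, objective,
                        bounds, L)
      upd$sequence$shuffle <- c(sequences[[k]]$shuffle, rep(shuffle, L))
      sequences[[k]] <- upd$sequence
      complexes[[k]] <- upd$complex
      n_eval <- n_eval + L
      if (upd$best$density > best$density) best <- upd$best
    }
    pop <- shuffle_back(complexes)
    if (shuffle >= 2L) {
      r_hat <- gelman_rubin(lapply(sequences, `[[`, "points"),
                            cfg$burn_fraction)
      if (all(r_hat < cfg$gr_threshold)) {
        converged <- TRUE
        break
      }
    }
  }

  chains <- lapply(sequences, function(sq) {
    pts <- sq$points
    dimnames(pts) <- list(NULL, paste0("par", seq_len(n)))
    cbind(pts, log_density = unname(sq$densities), shuffle = sq$shuffle)
  })
  list(theta = unname(best$theta), log_density = unname(best$density),
       chains = chains, r_hat = r_hat, converged = converged,
       n_shuffles = shuffle, n_evaluations = n_eval) |>
    structure(class = "scem_result")
}
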