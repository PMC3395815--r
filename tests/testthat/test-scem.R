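# Simple separable quadratic log-density with known mode, for sampler tests.
quad_objective <- function(mode, scale = 50) {
  function(theta, bounds) {
    if (any(theta < bounds$lower) || any(theta > bounds$upper)) return(-Inf)
    -scale * sum((theta - mode)^2)
  }
}

test_that("prior samples stay in the box and are reproducible", {
  b <- param_bounds(c(-1, 2), c(1, 5))
  obj <- quad_objective(c(0, 3))
  set.seed(101)
  pop <- sample_prior(obj, b, 50)
  expect_equal(dim(pop$points), c(50L, 2L))
  expect_true(all(t(pop$points) >= b$lower & t(pop$points) <= b$upper))
  set.seed(101)
  expect_identical(sample_prior(obj, b, 50), pop)
})

test_that("ranking sorts by decreasing density, stably, preserving pairing", {
  pop <- list(points = matrix(1:6, ncol = 2), densities = c(1, 3, 2))
  r <- rank_population(pop)
  expect_equal(r$densities, c(3, 2, 1))
  expect_equal(r$points, pop$points[c(2, 3, 1), ])
  # idempotence
  expect_identical(rank_population(r), r)
  # ties keep original order: oracle is an index-decorated sort
  pop2 <- list(points = matrix(1:10, ncol = 1),
               densities = c(2, 5, 2, 5, 1, 5, 2, 1, 5, 2))
  oracle <- order(-pop2$densities, seq_along(pop2$densities))
  r2 <- rank_population(pop2)
  expect_equal(r2$points[, 1], pop2$points[oracle, 1])
})

test_that("striped partition deals ranks round-robin and shuffles back losslessly", {
  pop <- rank_population(list(points = matrix(rnorm(12), ncol = 2),
                              densities = 6:1))
  cs <- partition_complexes(pop, 2)
  expect_equal(cs[[1]]$densities, c(6, 4, 2))  # ranks 1, 3, 5
  expect_equal(cs[[2]]$densities, c(5, 3, 1))  # ranks 2, 4, 6
  expect_equal(cs[[1]]$points, pop$points[c(1, 3, 5), ])

  pop4 <- rank_population(list(points = matrix(rnorm(8), ncol = 2),
                               densities = 4:1))
  cs4 <- partition_complexes(pop4, 2)
  expect_equal(cs4[[1]]$densities, c(4, 2))
  expect_equal(cs4[[2]]$densities, c(3, 1))

  # q = 1 keeps the whole ranked population
  one <- partition_complexes(pop, 1)
  expect_identical(one[[1]], pop)

  # round trip conserves the point multiset and returns it ranked
  back <- shuffle_back(cs)
  expect_identical(back, pop)
  expect_error(partition_complexes(pop, 4), "divisible")
})

test_that("sequence evolution accepts uphill moves, rejects out-of-bounds, finds quadratic optima", {
  b <- param_bounds(c(-2, -2), c(2, 2))
  obj <- quad_objective(c(0.4, -0.3))
  cfg <- scem_config(population_size = 20, n_complexes = 4)
  set.seed(5)
  pop <- rank_population(sample_prior(obj, b, 20))
  cs <- partition_complexes(pop, 4)
  seq1 <- list(points = pop$points[1, , drop = FALSE],
               densities = pop$densities[1], n_proposed = 0L,
               n_accepted = 0L)
  upd <- sem_update(seq1, cs[[1]], cfg, obj, b, n_steps = 500)
  # within 1% of the box width (4) of the analytic optimum
  expect_lt(sum((upd$best$theta - c(0.4, -0.3))^2)^0.5, 0.04)
  # best-ever density never below the starting density
  expect_gte(upd$best$density, pop$densities[1])
  # chain grew by one state per step
  expect_equal(nrow(upd$sequence$points), 501L)
  # NaN objective is a sampler error
  expect_error(
    sem_update(seq1, cs[[1]], cfg, function(theta, bounds) NaN, b, 1),
    "NaN")
})

test_that("Gelman-Rubin matches the hand-computed example and its guards", {
  chains <- list(matrix(c(1, 2, 3), ncol = 1), matrix(c(2, 3, 4), ncol = 1))
  # W = 1, B = 3 * var(c(2, 3)) = 1.5, R = sqrt((2/3 + 0.5)/1)
  expect_equal(gelman_rubin(chains, burn_fraction = 0),
               sqrt(7 / 6), tolerance = 1e-12)
  expect_equal(gelman_rubin(chains, burn_fraction = 0), 1.0801,
               tolerance = 1e-4)

  # identical constant chains -> not-converged sentinel
  const <- list(matrix(1, 5, 1), matrix(1, 5, 1))
  expect_identical(gelman_rubin(const, 0), Inf)

  expect_error(gelman_rubin(chains[1], 0), "two chains")
  expect_error(gelman_rubin(list(matrix(1:2, ncol = 1),
                                 matrix(3:4, ncol = 1)), 0.5),
               "retained draws")
})

test_that("Gelman-Rubin tends to 1 for chains from a common distribution", {
  set.seed(77)
  chains <- lapply(1:4, function(i) matrix(rnorm(4000), ncol = 2))
  r <- gelman_rubin(chains, burn_fraction = 0.5)
  # the finite-sample statistic can dip slightly below 1 when the
  # between-chain variance is tiny; it must still be close to 1
  expect_true(all(r > 0.95))
  expect_true(all(abs(r - 1) < 0.05))
})

test_that("the full SCEM loop localizes a known mode reproducibly", {
  b <- param_bounds(c(-1, -1), c(1, 1))
  obj <- quad_objective(c(0.3, -0.5), scale = 200)
  cfg <- scem_config(population_size = 30, n_complexes = 5,
                     max_shuffles = 40, gr_threshold = 1.05)
  res <- run_scem(obj, b, cfg, seed = 13)
  expect_s3_class(res, "scem_result")
  expect_lt(max(abs(res$theta - c(0.3, -0.5))), 0.01)
  # grid-search oracle agreement within grid resolution
  g <- as.matrix(expand.grid(seq(-1, 1, by = 0.02), seq(-1, 1, by = 0.02)))
  gd <- apply(g, 1L, obj, bounds = b)
  oracle <- g[which.max(gd), ]
  expect_lt(max(abs(res$theta - oracle)), 0.02)
  # bitwise reproducibility under the same seed
  res2 <- run_scem(obj, b, cfg, seed = 13)
  expect_identical(res, res2)
})

test_that("SCEM drives the SSE of noiseless synthetic data to zero", {
  u <- w1118_reference()$params
  sim <- simulate_dynamics(u, assay_config(550), noise = FALSE)
  d <- ai_dataset(sim$time_min, sim$ai, 550)
  b <- param_bounds(c(0, 0), c(0.01, 2))
  res <- run_scem(make_objective(d), b,
                  scem_config(max_shuffles = 100, gr_threshold = 1.05),
                  seed = 21)
  fit_sse <- sum(ai_residuals(utility_params(res$theta[1], res$theta[2]),
                              d)^2)
  expect_lt(fit_sse, 1e-6)
})

test_that("best-ever density is monotone nondecreasing across shuffles", {
  b <- param_bounds(c(-1, -1), c(1, 1))
  obj <- quad_objective(c(0.2, 0.2))
  bests <- vapply(1:6, function(k) {
    cfg <- scem_config(population_size = 20, n_complexes = 4,
                       max_shuffles = k, gr_threshold = 1 + 1e-9)
    run_scem(obj, b, cfg, seed = 91)$log_density
  }, numeric(1))
  expect_true(all(diff(bests) >= 0))
})

test_that("sampler configuration rejects inconsistent settings", {
  expect_error(scem_config(population_size = 21, n_complexes = 5),
               "multiple")
  expect_error(scem_config(min_accept_rate = 1.5), "accept")
  expect_error(scem_config(gr_threshold = 1), "exceed 1")
  expect_error(scem_config(burn_fraction = 1), "burn_fraction")
})
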