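quad1 <- function(mode) {
  function(theta, bounds) {
    if (any(theta < bounds$lower) || any(theta > bounds$upper)) return(-Inf)
    -100 * (theta[1] - mode)^2
  }
}

test_that("bound repair swaps inverted intervals, floors widths, is idempotent", {
  r <- repair_bounds(list(lower = c(2, 0), upper = c(1, 5)), 1e-6)
  expect_equal(r$lower, c(1, 0))
  expect_equal(r$upper, c(2, 5))

  ok <- param_bounds(c(0, 0), c(1, 2))
  expect_equal(repair_bounds(ok, 1e-6), ok)

  z <- repair_bounds(list(lower = c(0.5, 0), upper = c(0.5, 1)), 0.01)
  expect_equal(z$upper[1] - z$lower[1], 0.01)
  expect_equal(c(z$lower[2], z$upper[2]), c(0, 1))

  # clipping keeps the box inside the initial bounds without collapsing
  clip <- param_bounds(c(0, 0), c(1, 1))
  c1 <- repair_bounds(list(lower = c(0.999, 0), upper = c(1.2, 1)), 0.01,
                      clip = clip)
  expect_true(all(c1$lower >= clip$lower & c1$upper <= clip$upper))
  expect_true(all(c1$upper - c1$lower >= 0.01 - 1e-12))
})

test_that("a huge stopping tolerance stops after exactly two inner runs", {
  cfg <- iscem_config(param_bounds(-1, 1), epsilon = 1e6,
                      scem = scem_config(population_size = 20,
                                         n_complexes = 4,
                                         max_shuffles = 5))
  fit <- run_iscem(quad1(0.3), cfg, seed = 8)
  expect_equal(fit$n_outer_iters, 2L)
  expect_true(fit$converged)
})

test_that("ISCEM localizes a 1-D convex objective's known minimizer", {
  cfg <- iscem_config(param_bounds(-1, 1),
                      scem = scem_config(population_size = 20,
                                         n_complexes = 4,
                                         max_shuffles = 15))
  fit <- run_iscem(quad1(0.3), cfg, seed = 15)
  expect_lt(abs(fit$theta - 0.3), 0.01)
  expect_s3_class(fit, "iscem_fit")
  expect_equal(fit$log_density, quad1(0.3)(fit$theta, cfg$initial_bounds))
})

test_that("the returned estimate never leaves the initial box and bounds shrink inside it", {
  init <- param_bounds(c(0, 0), c(1, 10))
  cfg <- iscem_config(init, max_outer_iters = 6,
                      scem = scem_config(population_size = 20,
                                         n_complexes = 4,
                                         max_shuffles = 8))
  obj <- function(theta, bounds) {
    if (any(theta < bounds$lower) || any(theta > bounds$upper)) return(-Inf)
    -50 * sum((theta - c(0.4, 2.5))^2)
  }
  fit <- run_iscem(obj, cfg, seed = 33)
  expect_true(all(fit$theta >= init$lower & fit$theta <= init$upper))
  for (b in fit$bound_history) {
    expect_true(all(b$lower >= init$lower - 1e-12))
    expect_true(all(b$upper <= init$upper + 1e-12))
    expect_true(all(b$lower < b$upper))
  }
  expect_equal(length(fit$scem_converged), fit$n_outer_iters)
})

test_that("best log density is monotone nondecreasing over outer iterations", {
  # with a fixed seed, runs with growing outer caps share their prefix
  init <- param_bounds(c(0, 0), c(1, 1))
  obj <- function(theta, bounds) {
    if (any(theta < bounds$lower) || any(theta > bounds$upper)) return(-Inf)
    -30 * sum((theta - c(0.6, 0.2))^2)
  }
  dens <- vapply(2:5, function(k) {
    cfg <- iscem_config(init, epsilon = 1e-12, max_outer_iters = k,
                        scem = scem_config(population_size = 20,
                                           n_complexes = 4,
                                           max_shuffles = 4))
    run_iscem(obj, cfg, seed = 44)$log_density
  }, numeric(1))
  expect_true(all(diff(dens) >= 0))
})

test_that("noiseless synthetic data are recovered to within one percent", {
  ref <- w1118_reference()
  sim <- simulate_dynamics(ref$params, assay_config(550), noise = FALSE)
  d <- ai_dataset(sim$time_min, sim$ai, 550)
  fit <- fit_utility_model(d, seed = 42)
  rel <- abs(fit$theta - c(0.001459, 0.56532)) / c(0.001459, 0.56532)
  expect_lt(rel[1], 0.01)
  expect_lt(rel[2], 0.01)
  expect_s3_class(fit$params, "utility_params")
})

test_that("ISCEM configuration validates its tolerances", {
  b <- param_bounds(0, 1)
  expect_error(iscem_config(b, epsilon = 0), "epsilon")
  expect_error(iscem_config(b, max_outer_iters = 1), "max_outer_iters")
  expect_error(iscem_config(b, floor_width = 2), "floor_width")
})
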