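test_that("single unbiased window inverts a Gaussian Boltzmann distribution", {
  set.seed(11)
  sigma <- 0.3
  temperature <- 310
  kT <- phys_constants$R_kcal * temperature
  w <- umbrella_window(0, 0, rnorm(40000, 0, sigma), temperature = temperature)
  prof <- wham_solve(list(w), bin_width = 0.1)
  pop <- !is.na(prof$g) & prof$counts >= 200
  x <- prof$bin_centers[pop]
  g_theory <- kT * x^2 / (2 * sigma^2)
  g_theory <- g_theory - min(g_theory)
  # allow 3x the Poisson counting error per bin
  tol <- 3 * kT / sqrt(prof$counts[pop])
  expect_true(all(abs(prof$g[pop] - g_theory) < pmax(tol, 0.05)))
})

test_that("pooling identity: duplicated window equals concatenated samples", {
  set.seed(12)
  s1 <- rnorm(800, -0.3, 0.25)
  s2 <- rnorm(800, -0.3, 0.25)
  temperature <- 310
  split2 <- list(umbrella_window(-0.3, 50, s1, temperature),
                 umbrella_window(-0.3, 50, s2, temperature))
  pooled <- list(umbrella_window(-0.3, 50, c(s1, s2), temperature))
  br <- seq(-1.5, 1.0, by = 0.1)
  p1 <- wham_solve(split2, breaks = br, tol = 1e-10)
  p2 <- wham_solve(pooled, breaks = br, tol = 1e-10)
  expect_equal(p1$g, p2$g, tolerance = 1e-6)
})

test_that("iterative solver matches an independent brute-force fixed point", {
  set.seed(13)
  temperature <- 310
  wins <- list(
    umbrella_window(-0.5, 30, rnorm(400, -0.45, 0.2), temperature),
    umbrella_window(0.0, 30, rnorm(400, 0.05, 0.2), temperature),
    umbrella_window(0.5, 30, rnorm(400, 0.48, 0.2), temperature))
  br <- seq(-1.3, 1.3, by = 0.1)
  fast <- wham_solve(wins, breaks = br, tol = 1e-12)
  slow <- wham_oracle(wins, breaks = br, tol = 1e-13)
  pop <- !is.na(fast$g)
  expect_equal(fast$g[pop], slow[pop], tolerance = 1e-8)
})

test_that("double-well benchmark is recovered within 0.2 kcal/mol RMS", {
  dw <- default_double_well(10)
  wins <- gen_umbrella_dataset(dw, centers = seq(-2.9, 2.6, by = 0.2),
                               force_constant = 100, n_per_window = 1000,
                               seed = 7)
  prof <- wham_solve(wins)
  pop <- !is.na(prof$g)
  truth <- dw(prof$bin_centers[pop])
  truth <- truth - min(truth)
  rms <- sqrt(mean((prof$g[pop] - truth)^2))
  expect_lt(rms, 0.2)
})

test_that("disconnected window groups are rejected", {
  temperature <- 310
  wins <- list(umbrella_window(-2, 500, rnorm(200, -2, 0.03), temperature),
               umbrella_window(2, 500, rnorm(200, 2, 0.03), temperature))
  expect_error(wham_solve(wins, bin_width = 0.1), "disconnected")
})

test_that("solver reports non-convergence with the last residual", {
  set.seed(14)
  wins <- list(umbrella_window(-0.2, 40, rnorm(300, -0.2, 0.2)),
               umbrella_window(0.2, 40, rnorm(300, 0.2, 0.2)))
  expect_error(wham_solve(wins, tol = 1e-14, max_iter = 3), "convergence")
})

test_that("windows at different temperatures are rejected", {
  wins <- list(umbrella_window(0, 10, rnorm(50), temperature = 300),
               umbrella_window(0, 10, rnorm(50), temperature = 310))
  expect_error(wham_solve(wins), "temperature")
})

test_that("bootstrap errors are seeded, non-negative and scale like 1/sqrt(n)", {
  gprof <- function(R) 2 * R^2
  mk <- function(n, seed) gen_umbrella_dataset(
    gprof, centers = c(-0.6, 0, 0.6), force_constant = 20,
    n_per_window = n, seed = seed, range = c(-1.8, 1.8))
  wins <- mk(400, 21)
  b1 <- bootstrap_profile(wins, n_trials = 10, seed = 42)
  b2 <- bootstrap_profile(wins, n_trials = 10, seed = 42)
  expect_identical(b1$stderr, b2$stderr)
  pop <- !is.na(b1$g)
  expect_true(all(b1$stderr[pop] >= 0))
  # 4x the samples should roughly halve the bootstrap error
  wins4 <- mk(1600, 22)
  b4 <- bootstrap_profile(wins4, n_trials = 10, seed = 42)
  pop4 <- !is.na(b4$g) & pop & b1$counts >= 30 & b4$counts >= 30
  ratio <- mean(b4$stderr[pop4]) / mean(b1$stderr[pop4])
  expect_gt(ratio, 0.25)
  expect_lt(ratio, 0.75)
})

test_that("barrier height is measured between reactant and TS ranges", {
  prof <- structure(
    list(bin_centers = seq(-2, 2, by = 0.5),
         g = c(1, 0.2, 0, 1.5, 4, 6, 4.5, 2, 1),
         stderr = rep(NA_real_, 9), counts = rep(10, 9),
         breaks = seq(-2.25, 2.25, by = 0.5), temperature = 310,
         iterations = 1L, residual = 0),
    class = "fep_profile")
  rep1 <- barrier_height(prof, c(-2, -1), c(-0.5, 1))
  expect_equal(rep1$delta_g_barrier, 6)
  expect_equal(rep1$reactant_R, -1)
  expect_equal(rep1$ts_R, 0.5)
  # flat profile
  flat <- prof; flat$g <- rep(1, 9)
  expect_equal(barrier_height(flat, c(-2, 0), c(0, 2))$delta_g_barrier, 0)
  # identical ranges on a monotone profile give max - min of that range
  mono <- prof; mono$g <- seq(0, 4, by = 0.5)
  expect_equal(barrier_height(mono, c(-2, 2), c(-2, 2))$delta_g_barrier, 4)
  # ties break towards the lowest R
  expect_equal(barrier_height(flat, c(-2, 0), c(0, 2))$reactant_R, -2)
  expect_error(barrier_height(prof, c(5, 6), c(0, 1)), "range")
})

test_that("double-well barrier is recovered from umbrella data", {
  dw <- default_double_well(10)
  wins <- gen_umbrella_dataset(dw, centers = seq(-2.9, 2.6, by = 0.2),
                               force_constant = 100, n_per_window = 1000,
                               seed = 7)
  prof <- wham_solve(wins)
  rep <- barrier_height(prof, reactant_range = c(-2.6, -1.2),
                        ts_range = c(-0.8, 0.6))
  expect_equal(rep$delta_g_barrier, 10, tolerance = 0.05)
})
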