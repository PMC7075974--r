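test_that("mono-exponential fits recover truth exactly without noise", {
  x <- seq(0, 100, by = 2)
  y <- 1 * exp(-x / 10) + 0.2
  fit <- suppressWarnings(fit_monoexponential(x, y))
  expect_true(fit$converged)
  expect_equal(unname(fit$estimate[c("A1", "t1", "y0")]), c(1, 10, 0.2),
               tolerance = 1e-8)
  expect_equal(unname(fit$estimate["k_app"]), 0.1, tolerance = 1e-8)
})

test_that("mono-exponential fits recover noisy generator truth within 3 SE", {
  tr <- gen_fret_trace(A1 = 1, t1 = 50, y0 = 0.2, sigma = 0.01,
                       times = seq(0, 250, length.out = 100), seed = 41)
  fit <- fit_monoexponential(tr$time, tr$value)
  truth <- attr(tr, "truth")
  for (p in c("A1", "t1", "y0"))
    expect_lt(abs(fit$estimate[[p]] - truth[[p]]), 3 * fit$se[[p]])
  expect_error(fit_monoexponential(1:3, c(1, 2, 3)), ">= 4")
  expect_error(fit_monoexponential(1:10, rep(2, 10)), "constant")
})

test_that("a ten-fold apparent-rate difference is recovered from two traces", {
  slow <- gen_fret_trace(A1 = 1, t1 = 50, y0 = 0.2, sigma = 0.01,
                         times = seq(0, 250, length.out = 200), seed = 42)
  fast <- gen_fret_trace(A1 = 1, t1 = 5, y0 = 0.2, sigma = 0.01,
                         times = seq(0, 25, length.out = 200), seed = 43)
  k_slow <- fit_monoexponential(slow$time, slow$value)$estimate[["k_app"]]
  k_fast <- fit_monoexponential(fast$time, fast$value)$estimate[["k_app"]]
  expect_equal(k_fast / k_slow, 10, tolerance = 0.1)
})

test_that("ADP-release slope conversion follows the assay equation", {
  expect_equal(adp_release_rate(0, c_hsp90 = 3e-6), 0)
  expect_equal(adp_release_rate(-9.33e-3, 6220, 3e-6), 0.5, tolerance = 1e-3)
  expect_equal(adp_release_rate(-9.33e-3, 6220, 6e-6),
               adp_release_rate(-9.33e-3, 6220, 3e-6) / 2)
  expect_error(adp_release_rate(-1e-3, c_hsp90 = 0), "> 0")
})

test_that("ADP trace fitting recovers the release rate", {
  x <- seq(0, 10, 0.1)
  exact <- 1 - 6220 * 3e-6 * 0.5 * x
  f0 <- suppressWarnings(fit_adp_trace(x, exact, c_hsp90 = 3e-6))
  expect_equal(unname(f0$estimate["k"]), 0.5, tolerance = 1e-10)
  # background slope equal to the signal slope gives k = 0
  fbg <- suppressWarnings(
    fit_adp_trace(x, exact, background_slope = -6220 * 3e-6 * 0.5,
                  c_hsp90 = 3e-6))
  expect_equal(unname(fbg$estimate["k"]), 0, tolerance = 1e-10)
  tr <- gen_adp_trace(k = 0.5, sigma = 2e-4, seed = 44)
  fn <- fit_adp_trace(tr$time, tr$absorbance, c_hsp90 = 3e-6)
  expect_lt(abs(fn$estimate[["k"]] - 0.5), 3 * fn$se[["k"]])
  # radicicol background segment is excluded via the fit window
  tr2 <- gen_adp_trace(k = 0.5, duration = 14, radicicol_time = 10,
                       background_slope = -1e-4, sigma = 2e-4, seed = 45)
  f2 <- fit_adp_trace(tr2$time, tr2$absorbance, fit_window = c(0, 10),
                      background_slope = -1e-4, c_hsp90 = 3e-6)
  expect_lt(abs(f2$estimate[["k"]] - (0.5 - 1e-4 / (6220 * 3e-6))),
            4 * f2$se[["k"]])
  expect_error(fit_adp_trace(x, exact, fit_window = c(100, 101),
                             c_hsp90 = 3e-6), "window")
})

test_that("Michaelis-Menten fits recover Vmax and K_M", {
  mm0 <- gen_mm_dataset(Vmax = 0.5, K_M = 0.4, sigma = 0, seed = 46)
  f0 <- suppressWarnings(fit_michaelis_menten(mm0$conc, mm0$rate))
  expect_equal(unname(f0$estimate), c(0.5, 0.4), tolerance = 1e-8)
  # half-saturation identity: predicted rate at x = K_M is Vmax/2
  vm <- f0$estimate[["Vmax"]]; km <- f0$estimate[["K_M"]]
  expect_equal(vm * km / (km + km), vm / 2, tolerance = 1e-12)
  mm <- gen_mm_dataset(Vmax = 0.5, K_M = 0.4, sigma = 0.01, seed = 47)
  fn <- fit_michaelis_menten(mm$conc, mm$rate)
  expect_lt(abs(fn$estimate[["Vmax"]] - 0.5), 3 * fn$se[["Vmax"]])
  expect_lt(abs(fn$estimate[["K_M"]] - 0.4), 3 * fn$se[["K_M"]])
  expect_error(fit_michaelis_menten(c(1, 1, 1), c(1, 2, 3)), "distinct")
})

test_that("anisotropy competition fits recover K_D", {
  # at high receptor and no competitor the probe is fully bound
  expect_equal(anisotropy_competition_model(0, K_D = 1e-9, F_P = 0.1,
                                            F_PL = 0.3, c_H = 1e-4),
               0.3, tolerance = 1e-4)
  t0 <- gen_titration(K_D = 1e-7, sigma = 0, seed = 48)
  f0 <- fit_anisotropy_competition(t0$titrant, t0$anisotropy, c_hsp90 = 5e-7)
  expect_equal(unname(f0$estimate["K_D"]), 1e-7, tolerance = 1e-6)
  tn <- gen_titration(K_D = 1e-7, sigma = 0.002, seed = 49)
  fn <- fit_anisotropy_competition(tn$titrant, tn$anisotropy, c_hsp90 = 5e-7)
  expect_lt(abs(fn$estimate[["K_D"]] - 1e-7), 3 * fn$se[["K_D"]])
  expect_error(fit_anisotropy_competition(1:3, 1:3, 1e-6), ">= 5")
})

test_that("chemical-shift perturbation follows the combined-shift formula", {
  A <- data.frame(residue = 1:3, H_ppm = c(8, 8.5, 7.9),
                  N_ppm = c(120, 118, 125))
  expect_equal(csp(A, A)$csp, rep(0, 3))
  B <- A; B$H_ppm[2] <- B$H_ppm[2] + 0.1; B$N_ppm[2] <- B$N_ppm[2] + 0.5
  out <- csp(A, B)
  expect_equal(out$csp[2], sqrt(0.1^2 + (0.1689 * 0.5)^2), tolerance = 1e-12)
  expect_equal(out$csp[2], 0.1309, tolerance = 1e-3)
  # pure nitrogen shift scales by alpha
  C <- A; C$N_ppm[1] <- C$N_ppm[1] + 1
  expect_equal(csp(A, C)$csp[1], 0.1689, tolerance = 1e-12)
  # symmetry and unmatched reporting
  expect_equal(csp(A, B)$csp, csp(B, A)$csp)
  D <- rbind(B, data.frame(residue = 9, H_ppm = 8, N_ppm = 110))
  out2 <- csp(A, D)
  expect_equal(attr(out2, "unmatched")$B_only, 9)
})

test_that("heteronuclear NOE ratio and its propagated error are correct", {
  expect_equal(het_noe(1, 1)$noe, 1)
  h <- het_noe(0.58, 1.0, 0.02)
  expect_equal(h$noe, 0.58)
  expect_equal(h$noe_err, 0.58 * sqrt((0.02 / 0.58)^2 + (0.02 / 1)^2),
               tolerance = 1e-12)
  expect_equal(h$noe_err, 0.023, tolerance = 0.01)
  expect_equal(het_noe(0.5, 1, 0)$noe_err, 0)
  expect_error(het_noe(1, 0), "non-zero")
})

test_that("Guinier fits recover the radius of gyration", {
  for (rg_true in c(53.1, 62.3)) {
    g <- gen_guinier_curve(Rg = rg_true, sigma_rel = 0)
    fit <- guinier_fit(g$q, g$I, g$sigma)
    expect_equal(unname(fit$estimate["Rg"]), rg_true, tolerance = 1e-6)
    expect_equal(unname(fit$estimate["I0"]), 100, tolerance = 1e-6)
  }
  gn <- gen_guinier_curve(Rg = 53.1, sigma_rel = 0.01, seed = 50)
  fn <- guinier_fit(gn$q, gn$I, gn$sigma)
  expect_lt(abs(fn$estimate[["Rg"]] - 53.1), 3 * fn$se[["Rg"]])
  # aggregated sample: rising intensity
  q <- seq(0.005, 0.02, length.out = 20)
  expect_error(guinier_fit(q, exp(q^2 * 1000)), "slope")
})

test_that("P(r) from coordinates obeys the two-point and sphere identities", {
  two <- rbind(c(0, 0, 0), c(3, 4, 0))
  pr <- pr_from_coordinates(two, bin_width = 1)
  expect_equal(pr$rg, 2.5)
  expect_equal(pr$d_max, 5)
  expect_equal(sum(pr$counts), 1)
  # dense uniform sphere: Rg -> sqrt(3/5) a
  set.seed(51)
  n <- 2000; a <- 10
  u <- matrix(rnorm(3 * n), ncol = 3)
  pts <- u / sqrt(rowSums(u^2)) * (runif(n)^(1 / 3) * a)
  prs <- pr_from_coordinates(pts)
  expect_equal(prs$rg, sqrt(3 / 5) * a, tolerance = 0.02)
  # rigid rotation leaves P(r) unchanged
  rot <- random_rotation()
  pr_rot <- pr_from_coordinates(pts %*% t(rot))
  expect_equal(pr_rot$counts, prs$counts)
  expect_equal(pr_rot$rg, prs$rg, tolerance = 1e-12)
  expect_error(pr_from_coordinates(matrix(0, 1, 3)), "2 points")
})

test_that("Guinier and P(r) radii agree on scattering from one point cloud", {
  set.seed(52)
  n <- 400; a <- 20
  u <- matrix(rnorm(3 * n), ncol = 3)
  pts <- u / sqrt(rowSums(u^2)) * (runif(n)^(1 / 3) * a)
  rg_pr <- pr_from_coordinates(pts)$rg
  q <- seq(0.002, 1.3 / rg_pr, length.out = 40)
  curve <- gen_scattering_from_coords(pts, q)
  rg_guinier <- guinier_fit(curve$q, curve$I)$estimate[["Rg"]]
  expect_equal(rg_guinier, rg_pr, tolerance = 0.02)
})
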