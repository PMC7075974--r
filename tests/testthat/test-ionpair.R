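test_that("sidechain distances are computed per frame and validated", {
  f1 <- make_frame(c("ARG", "GLU"), "A", c(32, 33), c("CZ", "CD"),
                   x = c(0, 3), y = c(0, 4), z = c(0, 0))
  f2 <- make_frame(c("ARG", "GLU"), "A", c(32, 33), c("CZ", "CD"),
                   x = c(0, 6), y = c(0, 8), z = c(0, 0))
  traj <- traj_frames(list(f1, f2), times = c(0, 1))
  tr <- sidechain_distance_trace(traj, atom_label("A", 32, "CZ"),
                                 atom_label("A", 33, "CD"))
  expect_equal(tr$distance_A, c(5, 10))
  expect_error(
    sidechain_distance_trace(traj, atom_label("A", 32, "CZ"),
                             atom_label("B", 33, "CD")),
    "B:33:CD.*frame 1")
  # coincident atoms flagged but returned
  f0 <- make_frame(c("ARG", "GLU"), "A", c(32, 33), c("CZ", "CD"),
                   x = c(1, 1), y = c(1, 1), z = c(1, 1))
  expect_warning(
    tr0 <- sidechain_distance_trace(traj_frames(list(f0)),
                                    atom_label("A", 32, "CZ"),
                                    atom_label("A", 33, "CD")),
    "coincident")
  expect_equal(tr0$distance_A, 0)
})

test_that("open/closed classification applies a hard threshold, tie closed", {
  tr <- distance_trace(0:4, c(4, 6, 4, 6, 5))
  st <- classify_ionpair(tr, threshold = 5)
  expect_equal(as.character(st$state), c("closed", "open", "closed", "open", "closed"))
  occ <- attr(st, "occupancy")
  expect_equal(unname(occ["closed"]), 0.6)
  expect_equal(sum(occ), 1)
  st4 <- classify_ionpair(distance_trace(0:3, rep(4, 4)))
  expect_equal(unname(attr(st4, "occupancy")["closed"]), 1)
})

test_that("classification composed with distances is rotation invariant", {
  set.seed(31)
  rot <- random_rotation()
  shift <- c(5, -3, 2)
  frames <- lapply(1:20, function(i) {
    xyz <- matrix(rnorm(6, sd = 3), 2, 3)
    make_frame(c("ARG", "GLU"), "A", c(32, 33), c("CZ", "CD"),
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  })
  frames_rot <- lapply(frames, function(f) {
    xyz <- t(rot %*% t(cbind(f$x, f$y, f$z))) + rep(shift, each = 2)
    f$x <- xyz[, 1]; f$y <- xyz[, 2]; f$z <- xyz[, 3]
    f
  })
  a <- atom_label("A", 32, "CZ"); b <- atom_label("A", 33, "CD")
  t1 <- sidechain_distance_trace(traj_frames(frames), a, b)
  t2 <- sidechain_distance_trace(traj_frames(frames_rot), a, b)
  expect_equal(t1$distance_A, t2$distance_A, tolerance = 1e-10)
  s1 <- classify_ionpair(t1); s2 <- classify_ionpair(t2)
  expect_equal(as.character(s1$state), as.character(s2$state))
})

test_that("telegraph-trace occupancy follows the stationary law", {
  tr <- gen_two_state_trace(rate_open = 0.02, rate_close = 0.02,
                            dt = 0.5, t_total = 5000, seed = 3)
  st <- classify_ionpair(tr, threshold = 5)
  occ <- attr(st, "occupancy")
  expect_equal(unname(occ["open"]), 0.5, tolerance = 0.1)
  expect_lt(abs(occ[["open"]] - 0.5), 0.05)
  # asymmetric rates: stationary open fraction = k_open/(k_open + k_close)
  tr2 <- gen_two_state_trace(rate_open = 0.03, rate_close = 0.01,
                             dt = 0.5, t_total = 20000, seed = 4)
  occ2 <- attr(classify_ionpair(tr2), "occupancy")
  expect_lt(abs(occ2[["open"]] - 0.75), 0.05)
})

test_that("dwell times recover the exponential dwell law", {
  tr <- gen_two_state_trace(rate_open = 0.02, rate_close = 0.02, sd = 0.05,
                            dt = 0.5, t_total = 20000, seed = 5)
  st <- classify_ionpair(tr)
  dw <- dwell_times(st)
  sem <- sd(dw$open) / sqrt(length(dw$open))
  # mean open dwell = 1/rate_close = 50 ns (+ dt/2 discretisation bias)
  expect_lt(abs(dw$means[["open"]] - 50), 3 * sem + 0.5)
  # censored first/last runs are reported
  expect_equal(nrow(dw$censored), 2)
})

test_that("dwell-time edge cases behave as documented", {
  const <- classify_ionpair(distance_trace(0:9, rep(4, 10)))
  dwc <- dwell_times(const)
  expect_equal(nrow(dwc$censored), 1)
  expect_equal(dwc$censored$duration_ns, 10)
  expect_true(is.na(dwc$means[["closed"]]))
  alt <- classify_ionpair(distance_trace(seq(0, 0.9, 0.1),
                                         rep(c(4, 6), 5)))
  dwa <- dwell_times(alt)
  expect_true(all(abs(c(dwa$open, dwa$closed) - 0.1) < 1e-9))
  irregular <- classify_ionpair(distance_trace(c(0, 1, 3), c(4, 6, 4)))
  expect_error(dwell_times(irregular), "non-uniform")
})

test_that("salt-bridge counting is geometric, symmetric and monotone", {
  frame <- rbind(
    make_frame("ARG", "A", 10, "NH1", 0, 0, 0),
    make_frame("GLU", "B", 20, "OE1", 3.5, 0, 0),
    make_frame("LYS", "A", 11, "NZ", 10, 0, 0),
    make_frame("ASP", "B", 21, "OD1", 10, 4.5, 0))
  gA <- data.frame(chain = c("A", "A"), resno = c(10, 11))
  gB <- data.frame(chain = c("B", "B"), resno = c(20, 21))
  expect_equal(count_ion_pairs(frame, gA, gB, cutoff = 4.0)$count, 1)
  expect_equal(count_ion_pairs(frame, gA, gB, cutoff = 3.0)$count, 0)
  expect_equal(count_ion_pairs(frame, gA, gB, cutoff = 5.0)$count, 2)
  # symmetry
  expect_equal(count_ion_pairs(frame, gB, gA, cutoff = 4.0)$count,
               count_ion_pairs(frame, gA, gB, cutoff = 4.0)$count)
  # monotone in cutoff
  counts <- sapply(c(2, 3, 4, 5, 12),
                   function(cc) count_ion_pairs(frame, gA, gB, cutoff = cc)$count)
  expect_true(all(diff(counts) >= 0))
  # empty groups and residues without charged atoms
  empty <- data.frame(chain = character(), resno = integer())
  expect_equal(count_ion_pairs(frame, empty, gB)$count, 0)
  frame2 <- rbind(frame, make_frame("ALA", "A", 12, "CB", 1, 1, 1))
  gA2 <- rbind(gA, data.frame(chain = "A", resno = 12))
  expect_warning(res <- count_ion_pairs(frame2, gA2, gB, cutoff = 4.0),
                 "no charged atoms")
  expect_equal(res$count, 1)
  # like charges across groups never pair
  gA_neg <- data.frame(chain = "B", resno = 21)
  gB_neg <- data.frame(chain = "B", resno = 20)
  expect_equal(count_ion_pairs(frame, gA_neg, gB_neg, cutoff = 50)$count, 0)
})

test_that("inverse-distance barrier model is recovered by least squares", {
  d <- c(3, 3.5, 4, 4.5, 5, 6, 7, 8)
  exact <- 15 + 20 / d
  fit <- suppressWarnings(fit_inverse_distance(d, exact))
  expect_equal(unname(fit$estimate["a"]), 15, tolerance = 1e-10)
  expect_equal(unname(fit$estimate["b"]), 20, tolerance = 1e-10)
  set.seed(32)
  noisy <- exact + rnorm(8, 0, 0.5)
  fitn <- fit_inverse_distance(d, noisy)
  expect_lt(abs(fitn$estimate[["a"]] - 15), 3 * fitn$se[["a"]])
  expect_lt(abs(fitn$estimate[["b"]] - 20), 3 * fitn$se[["b"]])
  fconst <- suppressWarnings(fit_inverse_distance(d, rep(17, 8)))
  expect_lt(abs(fconst$estimate[["b"]]), 1e-10)
  expect_error(fit_inverse_distance(rep(4, 5), 1:5), "identical")
  expect_error(fit_inverse_distance(c(3, 4), c(1, 2)), ">= 3")
})

test_that("coulombic pKa shift matches the point-charge model", {
  # protein interior (eps = 4), contact distance 5.5 A: about 10 pKa units
  expect_equal(coulomb_pka_shift(5.5, epsilon = 4, temperature = 310),
               10.64, tolerance = 1e-3)
  # screening limit
  expect_lt(coulomb_pka_shift(5.5, epsilon = 1e9), 1e-6)
  # 1/d law
  expect_equal(coulomb_pka_shift(11, epsilon = 4),
               coulomb_pka_shift(5.5, epsilon = 4) / 2)
  expect_error(coulomb_pka_shift(-1), "d must be")
  expect_error(coulomb_pka_shift(5, epsilon = 0), "epsilon")
})
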