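# Seeded synthetic-data generators.
#
# Every generator takes a top-level integer seed and derives its own
# substream seed from a fixed per-generator offset, so adding a generator
# never shifts the stream of an existing one. Truth parameters are attached
# to each output as attr(x, "truth") to drive recovery tests.

.gen_offsets <- c(
  umbrella = 101L, telegraph = 211L, fret = 307L, adp = 401L,
  mm = 503L, titration = 601L, peaklists = 701L, hetnoe = 809L,
  guinier = 907L, scattering = 1009L)

.substream <- function(seed, generator) {
  off <- .gen_offsets[[generator]]
  set.seed(as.integer((as.numeric(seed) * 1021 + off) %% 2147483647))
}

#' Default double-well free-energy benchmark
#'
#' Analytic quartic double-well over the reaction-coordinate range
#' -2.9 to 2.6 Angstrom with minima near R = -1.9 and R = 1.6 and a barrier
#' of `barrier` kcal mol^-1 (default 10) at the saddle, used as the ground
#' truth for umbrella-sampling/WHAM recovery tests.
#'
#' @param barrier Barrier height, kcal mol^-1.
#' @return Function G(R) returning kcal mol^-1, with attributes `barrier`,
#'   `minima` and `saddle`.
#' @export
default_double_well <- function(barrier = 10) {
  mid <- -0.15; hw <- 1.75
  f <- function(R) {
    x <- (R - mid) / hw
    barrier * (x^2 - 1)^2
  }
  attr(f, "barrier") <- barrier
  attr(f, "minima") <- c(mid - hw, mid + hw)
  attr(f, "saddle") <- mid
  f
}

#' Generate umbrella-sampling windows from a known free-energy profile
#'
#' Draws reaction-coordinate samples for each window from the biased
#' Boltzmann density \eqn{p(R) \propto \exp(-(G(R) + U_{bias}(R))/k_BT)}
#' by inverse-CDF sampling on a fine grid, emulating restrained sampling
#' along the hydrolysis coordinate.
#'
#' @param profile Function G(R) in kcal mol^-1 (e.g.
#'   [default_double_well()]).
#' @param centers Bias centres, Angstrom.
#' @param force_constant Force constant(s), kcal mol^-1 A^-2 (recycled).
#' @param n_per_window Samples per window.
#' @param temperature Temperature, K.
#' @param seed Integer seed.
#' @param range Sampling range (min, max R); default -3.4 to 3.1.
#' @param grid_n Grid resolution for the inverse CDF.
#' @param bias_convention Passed to [umbrella_window()].
#' @return List of [umbrella_window()] objects with attribute `truth`
#'   (the profile function and parameters).
#' @export
gen_umbrella_dataset <- function(profile, centers, force_constant = 100,
                                 n_per_window = 1000, temperature = 310,
                                 seed = 1, range = c(-3.4, 3.1),
                                 grid_n = 4000,
                                 bias_convention = "half_k") {
  .substream(seed, "umbrella")
  kT <- kT_kcal(temperature)
  kk <- rep_len(force_constant, length(centers))
  grid <- seq(range[1], range[2], length.out = grid_n)
  G <- profile(grid)
  if (any(!is.finite(G)))
    stop_invalid("gen_umbrella_dataset: profile not finite on sampling range")
  pref <- if (bias_convention == "half_k") 0.5 else 1.0
  windows <- vector("list", length(centers))
  for (i in seq_along(centers)) {
    U <- G + pref * kk[i] * (grid - centers[i])^2
    logw <- -(U - min(U)) / kT
    w <- exp(logw)
    if (sum(w) <= 0)
      stop_invalid("gen_umbrella_dataset: unnormalisable density in window %d", i)
    cdf <- cumsum(w); cdf <- cdf / cdf[length(cdf)]
    u <- stats::runif(n_per_window)
    samples <- stats::approx(cdf, grid, xout = u, ties = "ordered",
                             yleft = grid[1], yright = grid[grid_n])$y
    windows[[i]] <- umbrella_window(centers[i], kk[i], samples,
                                    temperature = temperature,
                                    bias_convention = bias_convention)
  }
  attr(windows, "truth") <- list(profile = profile, centers = centers,
                                 force_constant = kk,
                                 temperature = temperature, seed = seed)
  windows
}

#' Generate a two-state telegraph ion-pair distance trace
#'
#' Continuous-time two-state Markov (telegraph) process with exponential
#' dwell times, discretised on a uniform grid and observed through Gaussian
#' noise around the state means. Defaults emulate an interdomain salt
#' bridge switching on 50 ns timescales between a closed (4 Angstrom) and
#' an open (8 Angstrom) conformation.
#'
#' @param rate_open Closed-to-open switching rate, ns^-1 (default 0.02,
#'   i.e. mean closed dwell 50 ns).
#' @param rate_close Open-to-closed switching rate, ns^-1 (default 0.02).
#' @param mean_closed,mean_open State means, Angstrom (defaults 4 and 8).
#' @param sd Observation noise SD, Angstrom (default 0.4).
#' @param dt Frame spacing, ns (> 0).
#' @param t_total Trace length, ns.
#' @param seed Integer seed.
#' @return A [distance_trace()] with attribute `truth` (parameters plus the
#'   noise-free state sequence).
#' @export
gen_two_state_trace <- function(rate_open = 0.02, rate_close = 0.02,
                                mean_closed = 4.0, mean_open = 8.0,
                                sd = 0.4, dt = 0.5, t_total = 5000,
                                seed = 1) {
  if (dt <= 0) stop_invalid("gen_two_state_trace: dt must be > 0")
  if (rate_open <= 0 || rate_close <= 0)
    stop_invalid("gen_two_state_trace: rates must be > 0")
  if (mean_closed <= 0 || mean_open <= 0)
    stop_invalid("gen_two_state_trace: state means must be positive")
  .substream(seed, "telegraph")
  times <- seq(0, t_total, by = dt)
  n <- length(times)
  # simulate jump times of the CTMC, then sample on the grid
  p_open0 <- rate_open / (rate_open + rate_close)  # stationary start
  state <- integer(n)  # 0 closed, 1 open
  cur <- as.integer(stats::runif(1) < p_open0)
  t_now <- 0
  i <- 1L
  while (i <= n) {
    rate <- if (cur == 0L) rate_open else rate_close
    t_jump <- t_now + stats::rexp(1, rate)
    while (i <= n && times[i] < t_jump) {
      state[i] <- cur
      i <- i + 1L
    }
    cur <- 1L - cur
    t_now <- t_jump
  }
  mu <- ifelse(state == 1L, mean_open, mean_closed)
  d <- mu + stats::rnorm(n, 0, sd)
  d <- pmax(d, 1e-6)
  tr <- distance_trace(times, d)
  attr(tr, "truth") <- list(
    rate_open = rate_open, rate_close = rate_close,
    mean_closed = mean_closed, mean_open = mean_open, sd = sd,
    occupancy_open = p_open0, states = ifelse(state == 1L, "open", "closed"),
    seed = seed)
  tr
}

#' Generate a mono-exponential FRET trace
#'
#' Model curve \eqn{y = A_1 e^{-t/t_1} + y_0} plus i.i.d. Gaussian noise,
#' emulating a dimer closing/re-opening FRET transient.
#'
#' @param A1 Amplitude.
#' @param t1 Time constant (> 0), same unit as `times`.
#' @param y0 Offset.
#' @param sigma Gaussian noise SD.
#' @param times Sampling times.
#' @param seed Integer seed.
#' @return Data frame `time`, `value` with attribute `truth`.
#' @export
gen_fret_trace <- function(A1 = 1, t1 = 50, y0 = 0.2, sigma = 0.01,
                           times = seq(0, 250, length.out = 200), seed = 1) {
  if (t1 <= 0) stop_invalid("gen_fret_trace: t1 must be > 0")
  .substream(seed, "fret")
  y <- A1 * exp(-times / t1) + y0 + stats::rnorm(length(times), 0, sigma)
  out <- data.frame(time = times, value = y)
  attr(out, "truth") <- list(A1 = A1, t1 = t1, y0 = y0, k_app = 1 / t1,
                             sigma = sigma, seed = seed)
  out
}

#' Generate an NADH-depletion absorbance trace for the ADP-release assay
#'
#' Linear absorbance decay \eqn{A(t) = A_0 - \varepsilon c k t} plus
#' Gaussian noise; after `radicicol_time` the slope switches to
#' `background_slope`, emulating inhibition of the enzyme at the end of the
#' measurement to record the assay background.
#'
#' @param k True ADP-release rate, min^-1.
#' @param eps NADH extinction coefficient, M^-1 cm^-1 (default 6220).
#' @param c Enzyme concentration, M (default 3e-6).
#' @param A0 Initial absorbance, AU.
#' @param sigma Noise SD, AU.
#' @param duration Trace length, min.
#' @param dt Sampling interval, min.
#' @param radicicol_time Time of inhibitor addition, min (default `Inf`,
#'   i.e. no background segment).
#' @param background_slope Post-inhibition slope, AU min^-1.
#' @param seed Integer seed.
#' @return Data frame `time`, `absorbance` with attribute `truth`.
#' @export
gen_adp_trace <- function(k = 0.5, eps = 6220, c = 3e-6, A0 = 1.0,
                          sigma = 2e-4, duration = 10, dt = 0.1,
                          radicicol_time = Inf, background_slope = 0,
                          seed = 1) {
  if (k < 0 || eps <= 0 || c <= 0)
    stop_invalid("gen_adp_trace: k must be >= 0 and eps, c > 0")
  .substream(seed, "adp")
  times <- seq(0, duration, by = dt)
  slope <- -eps * c * k
  A <- numeric(length(times))
  pre <- times <= radicicol_time
  A[pre] <- A0 + slope * times[pre]
  if (any(!pre)) {
    A_break <- A0 + slope * radicicol_time
    A[!pre] <- A_break + background_slope * (times[!pre] - radicicol_time)
  }
  A <- A + stats::rnorm(length(times), 0, sigma)
  out <- data.frame(time = times, absorbance = A)
  attr(out, "truth") <- list(k = k, eps = eps, c = c, A0 = A0, sigma = sigma,
                             slope = slope, radicicol_time = radicicol_time,
                             background_slope = background_slope, seed = seed)
  out
}

#' Generate a Michaelis-Menten rate table
#'
#' @param Vmax,K_M Truth parameters (rate and concentration units).
#' @param conc Substrate concentrations (default 0.1-5 mM).
#' @param sigma Gaussian noise SD on rates.
#' @param seed Integer seed.
#' @return Data frame `conc`, `rate` with attribute `truth`.
#' @export
gen_mm_dataset <- function(Vmax = 0.5, K_M = 0.4,
                           conc = c(0.1, 0.2, 0.4, 0.8, 1.5, 2.5, 3.5, 5),
                           sigma = 0.01, seed = 1) {
  .substream(seed, "mm")
  v <- Vmax * conc / (K_M + conc) + stats::rnorm(length(conc), 0, sigma)
  out <- data.frame(conc = conc, rate = v)
  attr(out, "truth") <- list(Vmax = Vmax, K_M = K_M, sigma = sigma, seed = seed)
  out
}

#' Generate a competition anisotropy titration
#'
#' Uses [anisotropy_competition_model()] as truth.
#'
#' @param K_D Dissociation constant, M (default 1e-7).
#' @param F_P,F_PL Free / bound probe anisotropy.
#' @param c_hsp90 Receptor concentration, M.
#' @param titrant Competitor concentrations, M.
#' @param sigma Gaussian noise SD on anisotropy.
#' @param seed Integer seed.
#' @return Data frame `titrant`, `anisotropy` with attribute `truth`.
#' @export
gen_titration <- function(K_D = 1e-7, F_P = 0.12, F_PL = 0.26,
                          c_hsp90 = 5e-7,
                          titrant = c(0, 10^seq(-9, -4.5, length.out = 17)),
                          sigma = 0.002, seed = 1) {
  .substream(seed, "titration")
  r <- anisotropy_competition_model(titrant, K_D, F_P, F_PL, c_hsp90) +
    stats::rnorm(length(titrant), 0, sigma)
  out <- data.frame(titrant = titrant, anisotropy = r)
  attr(out, "truth") <- list(K_D = K_D, F_P = F_P, F_PL = F_PL,
                             c_hsp90 = c_hsp90, sigma = sigma, seed = seed)
  out
}

#' Generate a pair of HSQC amide peak lists
#'
#' A reference list with random but reproducible shifts, and a perturbed
#' list in which a chosen subset of residues is shifted by given 1H/15N
#' offsets (plus optional noise), emulating a ligand-induced CSP pattern.
#'
#' @param n_residues Number of residues.
#' @param perturbed Residue numbers to perturb.
#' @param dH,dN Perturbation sizes, ppm.
#' @param sigma_H,sigma_N Measurement noise SDs, ppm.
#' @param seed Integer seed.
#' @return List with `A` (reference), `B` (perturbed) and attribute `truth`.
#' @export
gen_peaklists <- function(n_residues = 50, perturbed = c(30, 31, 32, 33, 34),
                          dH = 0.08, dN = 0.5, sigma_H = 0, sigma_N = 0,
                          seed = 1) {
  .substream(seed, "peaklists")
  res <- seq_len(n_residues)
  A <- data.frame(residue = res,
                  resname = sample(c("ALA", "GLY", "LEU", "SER", "VAL"),
                                   n_residues, replace = TRUE),
                  H_ppm = stats::runif(n_residues, 6.5, 10),
                  N_ppm = stats::runif(n_residues, 105, 130))
  B <- A
  hit <- B$residue %in% perturbed
  B$H_ppm[hit] <- B$H_ppm[hit] + dH
  B$N_ppm[hit] <- B$N_ppm[hit] + dN
  B$H_ppm <- B$H_ppm + stats::rnorm(n_residues, 0, sigma_H)
  B$N_ppm <- B$N_ppm + stats::rnorm(n_residues, 0, sigma_N)
  out <- list(A = A, B = B)
  attr(out, "truth") <- list(perturbed = perturbed, dH = dH, dN = dN,
                             sigma_H = sigma_H, sigma_N = sigma_N, seed = seed)
  out
}

#' Generate saturated/reference intensity pairs for a heteronuclear NOE
#'
#' Reference intensity 1 and saturated intensity equal to the true NOE
#' ratio, both observed through Gaussian baseplane noise.
#'
#' @param ratio True NOE ratio (default 0.58, a rigid arginine sidechain).
#' @param noise_rmsd Baseplane noise RMSD on unit reference intensity.
#' @param n Number of independent pairs.
#' @param seed Integer seed.
#' @return Data frame `I_sat`, `I_ref` with attribute `truth`.
#' @export
gen_hetnoe <- function(ratio = 0.58, noise_rmsd = 0.02, n = 1, seed = 1) {
  .substream(seed, "hetnoe")
  I_ref <- 1 + stats::rnorm(n, 0, noise_rmsd)
  I_sat <- ratio + stats::rnorm(n, 0, noise_rmsd)
  out <- data.frame(I_sat = I_sat, I_ref = I_ref)
  attr(out, "truth") <- list(ratio = ratio, noise_rmsd = noise_rmsd,
                             seed = seed)
  out
}

#' Generate a Guinier-regime scattering curve
#'
#' \eqn{I(q) = I_0 \exp(-q^2 R_g^2 / 3)} with optional relative Gaussian
#' noise, on a q-grid covering the Guinier regime of the requested radius
#' of gyration.
#'
#' @param Rg Radius of gyration, Angstrom.
#' @param I0 Forward scattering.
#' @param n Number of q points.
#' @param q_max Maximum q (default 1.3/Rg times 1.5, extending past the
#'   Guinier limit so the range-selection logic is exercised).
#' @param sigma_rel Relative noise level (0 for noiseless).
#' @param seed Integer seed.
#' @return Data frame `q`, `I`, `sigma` with attribute `truth`.
#' @export
gen_guinier_curve <- function(Rg = 53.1, I0 = 100, n = 60, q_max = NULL,
                              sigma_rel = 0, seed = 1) {
  .substream(seed, "guinier")
  if (is.null(q_max)) q_max <- 1.5 * 1.3 / Rg
  q <- seq(q_max / n, q_max, length.out = n)
  I_true <- I0 * exp(-q^2 * Rg^2 / 3)
  sig <- pmax(sigma_rel * I_true, 1e-12)
  I_obs <- I_true + if (sigma_rel > 0) stats::rnorm(n, 0, sig) else 0
  out <- data.frame(q = q, I = I_obs, sigma = sig)
  attr(out, "truth") <- list(Rg = Rg, I0 = I0, sigma_rel = sigma_rel,
                             seed = seed)
  out
}

#' Generate a scattering curve from coordinates (Debye formula)
#'
#' Exact Debye sum over identical point scatterers,
#' \eqn{I(q) = \sum_{ij} \mathrm{sinc}(q r_{ij})}, used to cross-check the
#' Guinier radius against the coordinate-space P(r) radius.
#'
#' @param coords n x 3 coordinate matrix, Angstrom.
#' @param q Scattering vector grid, inverse Angstrom.
#' @return Data frame `q`, `I` (normalised to I(0) = 1).
#' @export
gen_scattering_from_coords <- function(coords, q) {
  coords <- as.matrix(coords)
  d <- as.numeric(stats::dist(coords))
  n <- nrow(coords)
  I <- vapply(q, function(qi) {
    x <- qi * d
    n + 2 * sum(ifelse(x < 1e-8, 1, sin(x) / x))
  }, numeric(1))
  data.frame(q = q, I = I / (n + 2 * length(d)))
}
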