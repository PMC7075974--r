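# Shared container for fit results -------------------------------------------

new_biophys_fit <- function(model, estimate, se, residuals, converged,
                            extra = list()) {
  structure(c(list(model = model, estimate = estimate, se = se,
                   residuals = residuals, converged = converged), extra),
            class = "biophys_fit")
}

#' @export
print.biophys_fit <- function(x, ...) {
  cat(sprintf("fit [%s]%s\n", x$model,
              if (isTRUE(x$converged)) "" else "  (NOT CONVERGED)"))
  for (p in names(x$estimate))
    cat(sprintf("  %-8s %.6g +/- %.3g\n", p, x$estimate[p],
                if (p %in% names(x$se)) x$se[p] else NA))
  cat(sprintf("  residual sd %.3g (n = %d)\n",
              stats::sd(x$residuals), length(x$residuals)))
  invisible(x)
}

.nls_fit <- function(formula, data, start, model_tag, weights = NULL) {
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500)
  fit <- tryCatch(
    if (is.null(weights))
      minpack.lm::nlsLM(formula, data = data, start = start, control = ctrl)
    else
      minpack.lm::nlsLM(formula, data = data, start = start, control = ctrl,
                        weights = weights),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(new_biophys_fit(model_tag,
                           estimate = stats::setNames(rep(NA_real_, length(start)),
                                                      names(start)),
                           se = stats::setNames(rep(NA_real_, length(start)),
                                                names(start)),
                           residuals = rep(NA_real_, nrow(data)),
                           converged = FALSE,
                           extra = list(message = conditionMessage(fit))))
  }
  cf <- summary(fit)$coefficients
  new_biophys_fit(model_tag,
                  estimate = stats::setNames(cf[, 1], rownames(cf)),
                  se = stats::setNames(cf[, 2], rownames(cf)),
                  residuals = unname(stats::residuals(fit)),
                  converged = TRUE,
                  extra = list(fit = fit))
}

# Mono-exponential kinetics ----------------------------------------------------

#' Fit a mono-exponential decay to a kinetic trace
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' \deqn{y = A_1 e^{-x/t_1} + y_0,}
#' the standard model for FRET closing/re-opening kinetics. The apparent
#' rate constant is \eqn{k_{App} = 1/t_1}, with its standard error
#' propagated as \eqn{se(k) = se(t_1)/t_1^2}. Starting values come from a
#' log-linear pre-fit of \eqn{|y - y_0|} after estimating the plateau from
#' the trailing 10 percent of points.
#'
#' @param times Time points (declared unit, typically min), strictly
#'   increasing, >= 4 points.
#' @param values Signal values.
#' @return A `biophys_fit` with estimates `A1`, `t1`, `y0`, `k_app` and
#'   standard errors; non-convergence yields a flagged (not thrown) result.
#'   A converged optimum with `t1 <= 0` is rejected with an error.
#' @export
fit_monoexponential <- function(times, values) {
  if (length(times) != length(values) || length(times) < 4)
    stop_invalid("fit_monoexponential: need >= 4 (time, value) points")
  if (stats::sd(values) == 0)
    stop_invalid("fit_monoexponential: signal is constant")
  ntail <- max(2L, ceiling(length(values) * 0.1))
  y0_0 <- mean(utils::tail(values, ntail))
  A1_0 <- values[1] - y0_0
  if (A1_0 == 0) A1_0 <- max(values) - y0_0
  dy <- values - y0_0
  usable <- sign(dy) == sign(A1_0) & abs(dy) > 1e-3 * abs(A1_0)
  t1_0 <- if (sum(usable) >= 3) {
    sl <- unname(stats::coef(stats::lm(log(abs(dy[usable])) ~ times[usable]))[2])
    if (is.finite(sl) && sl < 0) -1 / sl else diff(range(times)) / 3
  } else diff(range(times)) / 3
  res <- .nls_fit(y ~ A1 * exp(-x / t1) + y0,
                  data = data.frame(x = times, y = values),
                  start = list(A1 = A1_0, t1 = t1_0, y0 = y0_0),
                  model_tag = "monoexponential")
  if (isTRUE(res$converged)) {
    if (res$estimate["t1"] <= 0)
      stop_invalid("fit_monoexponential: optimum has non-positive t1 (%.3g)",
                   res$estimate["t1"])
    k <- 1 / res$estimate[["t1"]]
    res$estimate <- c(res$estimate, k_app = k)
    res$se <- c(res$se, k_app = unname(res$se["t1"]) * k^2)
  }
  res
}

# ADP-release (NADH-coupled regenerating) assay --------------------------------

#' ADP-release rate from an NADH-depletion slope
#'
#' Converts the linear absorbance slope of an NADH-coupled ATP-regenerating
#' assay into a per-enzyme ADP-release rate,
#' \deqn{k = -m / (\varepsilon_{NADH} \cdot c_{Hsp90} \cdot \ell).}
#'
#' @param m Absorbance slope, AU min^-1 (negative while NADH is consumed).
#' @param eps_nadh NADH extinction coefficient, M^-1 cm^-1 (default 6220 at
#'   340 nm).
#' @param c_hsp90 Enzyme concentration, M.
#' @param path_cm Optical path length, cm (default 1).
#' @return Release rate in min^-1.
#' @export
adp_release_rate <- function(m, eps_nadh = 6220, c_hsp90, path_cm = 1) {
  if (eps_nadh <= 0 || c_hsp90 <= 0 || path_cm <= 0)
    stop_invalid("adp_release_rate: eps_nadh, c_hsp90 and path_cm must be > 0")
  -m / (eps_nadh * c_hsp90 * path_cm)
}

#' Fit an ADP-release rate from an absorbance trace
#'
#' Ordinary least-squares slope over the chosen time window, minus the
#' background slope (measured after adding a competitive inhibitor such as
#' radicicol), converted with [adp_release_rate()].
#'
#' @param times Time points, minutes.
#' @param absorbance Absorbance values, AU.
#' @param fit_window Length-2 time interval to fit (default whole trace).
#' @param background_slope Instrument/background slope to subtract,
#'   AU min^-1 (default 0).
#' @inheritParams adp_release_rate
#' @return A `biophys_fit` with estimates `slope` and `k` (min^-1) and
#'   standard errors.
#' @export
fit_adp_trace <- function(times, absorbance, fit_window = range(times),
                          background_slope = 0, eps_nadh = 6220, c_hsp90,
                          path_cm = 1) {
  if (length(times) != length(absorbance))
    stop_invalid("fit_adp_trace: length mismatch")
  inw <- times >= min(fit_window) & times <= max(fit_window)
  if (sum(inw) < 3)
    stop_invalid("fit_adp_trace: fit window contains fewer than 3 points")
  fit <- stats::lm(absorbance[inw] ~ times[inw])
  cf <- summary(fit)$coefficients
  slope <- unname(cf[2, 1]); se_slope <- unname(cf[2, 2])
  denom <- eps_nadh * c_hsp90 * path_cm
  new_biophys_fit(
    model = "adp_release",
    estimate = c(slope = slope, k = -(slope - background_slope) / denom),
    se = c(slope = se_slope, k = se_slope / denom),
    residuals = unname(stats::residuals(fit)),
    converged = TRUE)
}

# Michaelis-Menten --------------------------------------------------------------

#' Fit the Michaelis-Menten equation to rate-vs-substrate data
#'
#' Nonlinear least squares of \eqn{v = V_{max} x / (K_M + x)}; typical ATP
#' titrations span 0.1-5 mM.
#'
#' @param conc Substrate concentrations (>= 3 distinct values).
#' @param rate Observed rates.
#' @return A `biophys_fit` with `Vmax` and `K_M` (in the units of `rate` and
#'   `conc`).
#' @export
fit_michaelis_menten <- function(conc, rate) {
  if (length(conc) != length(rate) || length(unique(conc)) < 3)
    stop_invalid("fit_michaelis_menten: need >= 3 distinct concentrations")
  vmax0 <- max(rate)
  km0 <- conc[which.min(abs(rate - vmax0 / 2))]
  if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(conc)
  res <- .nls_fit(v ~ Vmax * x / (K_M + x),
                  data = data.frame(x = conc, v = rate),
                  start = list(Vmax = vmax0, K_M = km0),
                  model_tag = "michaelis_menten")
  res
}

# Anisotropy competition binding -------------------------------------------------

# Quadratic single-site ligand-depletion occupancy: [HL] given totals.
.quadratic_bound <- function(c_H, c_L, K_D) {
  s <- c_H + c_L + K_D
  (s - sqrt(pmax(s^2 - 4 * c_H * c_L, 0))) / 2
}

#' Anisotropy model for a competition titration with a trace labelled probe
#'
#' The unlabelled titrant L binds the receptor H (total concentration `c_H`)
#' with the exact single-site ligand-depletion (quadratic) isotherm; a trace
#' labelled probe sharing the same site and affinity then reports the free
#' receptor through its own bound fraction `free / (free + K_D)`. Anisotropy
#' interpolates between `F_PL` (probe fully bound, no competitor) and `F_P`
#' (probe displaced).
#'
#' @param c_L Titrant (competitor) concentrations, M.
#' @param K_D Dissociation constant, M.
#' @param F_P,F_PL Anisotropy of free and bound probe.
#' @param c_H Receptor concentration, M.
#' @return Predicted anisotropy values.
#' @export
anisotropy_competition_model <- function(c_L, K_D, F_P, F_PL, c_H) {
  HL <- .quadratic_bound(c_H, c_L, K_D)
  free <- pmax(c_H - HL, 0)
  fb <- free / (free + K_D)
  F_P + (F_PL - F_P) * fb
}

#' Fit a competition anisotropy titration
#'
#' Fits `K_D`, `F_P` and `F_PL` of [anisotropy_competition_model()] to an
#' anisotropy-vs-titrant series by Levenberg-Marquardt least squares.
#'
#' @param titrant Titrant concentrations, M, non-negative and increasing.
#' @param anisotropy Measured anisotropy values.
#' @param c_hsp90 Receptor concentration, M (fixed, known).
#' @return A `biophys_fit` with `K_D`, `F_P`, `F_PL`; a converged optimum
#'   with `K_D <= 0` is rejected.
#' @export
fit_anisotropy_competition <- function(titrant, anisotropy, c_hsp90) {
  if (length(titrant) != length(anisotropy) || length(titrant) < 5)
    stop_invalid("fit_anisotropy_competition: need >= 5 titration points")
  if (any(titrant < 0) || any(diff(titrant) < 0))
    stop_invalid("fit_anisotropy_competition: titrant must be non-negative and increasing")
  FPL0 <- anisotropy[1]
  FP0 <- anisotropy[length(anisotropy)]
  mid <- (FPL0 + FP0) / 2
  KD0 <- titrant[which.min(abs(anisotropy - mid))]
  if (!is.finite(KD0) || KD0 <= 0) KD0 <- stats::median(titrant[titrant > 0])
  res <- .nls_fit(r ~ anisotropy_competition_model(cL, K_D, F_P, F_PL, c_H = c_hsp90),
                  data = data.frame(cL = titrant, r = anisotropy),
                  start = list(K_D = KD0, F_P = FP0, F_PL = FPL0),
                  model_tag = "anisotropy_competition")
  if (isTRUE(res$converged) && res$estimate["K_D"] <= 0)
    stop_invalid("fit_anisotropy_competition: optimum has non-positive K_D")
  res
}

# NMR ---------------------------------------------------------------------------

#' Combined 1H/15N chemical-shift perturbation
#'
#' Per-residue CSP between two amide peak lists,
#' \deqn{\Delta\delta = \sqrt{\Delta\delta_H^2 + (\alpha \Delta\delta_N)^2},}
#' with the nitrogen scaling factor alpha = 0.1689 (ratio of the 1H and 15N
#' shift ranges). Residues are matched by residue number; residues present
#' in only one list are reported in the `unmatched` attribute, and
#' mismatched residue names raise a warning.
#'
#' @param peaksA,peaksB Data frames with columns `residue`, `H_ppm`,
#'   `N_ppm` and optionally `resname`.
#' @param alpha 15N scaling factor, default 0.1689.
#' @return Data frame `residue`, `delta_H`, `delta_N`, `csp` (ppm), with
#'   attribute `unmatched` (list `A_only`, `B_only`).
#' @export
csp <- function(peaksA, peaksB, alpha = 0.1689) {
  for (nm in c("residue", "H_ppm", "N_ppm")) {
    if (!nm %in% names(peaksA) || !nm %in% names(peaksB))
      stop_invalid("csp: peak lists need columns residue, H_ppm, N_ppm")
  }
  if (anyDuplicated(peaksA$residue) || anyDuplicated(peaksB$residue))
    stop_invalid("csp: residue keys must be unique within a peak list")
  common <- intersect(peaksA$residue, peaksB$residue)
  a <- peaksA[match(common, peaksA$residue), ]
  b <- peaksB[match(common, peaksB$residue), ]
  if ("resname" %in% names(a) && "resname" %in% names(b) &&
      any(a$resname != b$resname))
    warning("csp: residue-name mismatch for matched residue numbers",
            call. = FALSE)
  dH <- a$H_ppm - b$H_ppm
  dN <- a$N_ppm - b$N_ppm
  out <- data.frame(residue = common, delta_H = dH, delta_N = dN,
                    csp = sqrt(dH^2 + (alpha * dN)^2))
  attr(out, "unmatched") <- list(
    A_only = setdiff(peaksA$residue, common),
    B_only = setdiff(peaksB$residue, common))
  out
}

#' Heteronuclear NOE ratio with baseplane-noise error propagation
#'
#' Steady-state heteronuclear NOE value as the saturated/reference peak
#' intensity ratio, with the error propagated from the spectral baseplane
#' noise RMSD:
#' \deqn{\sigma_{NOE} = |I_{sat}/I_{ref}|
#'   \sqrt{(\sigma/I_{sat})^2 + (\sigma/I_{ref})^2}.}
#'
#' @param I_sat,I_ref Peak intensities with and without saturation
#'   (vectorised); `I_ref` must be non-zero.
#' @param noise_rmsd Baseplane noise RMSD (same intensity units), default 0.
#' @return Data frame with `noe` and `noe_err`.
#' @export
het_noe <- function(I_sat, I_ref, noise_rmsd = 0) {
  if (any(I_ref == 0)) stop_invalid("het_noe: I_ref must be non-zero")
  ratio <- I_sat / I_ref
  err <- abs(ratio) * sqrt((noise_rmsd / I_sat)^2 + (noise_rmsd / I_ref)^2)
  data.frame(noe = ratio, noe_err = err)
}

# SAXS --------------------------------------------------------------------------

#' Guinier fit of a small-angle scattering curve
#'
#' Weighted linear fit of \eqn{\ln I} versus \eqn{q^2} over the low-q
#' Guinier regime, \eqn{\ln I(q) = \ln I_0 - q^2 R_g^2 / 3}. The fit range
#' is the largest low-q prefix satisfying \eqn{q R_g \le} `qmax_rg`
#' (default 1.3), iterated to self-consistency since the limit depends on
#' the fitted radius of gyration itself.
#'
#' @param q Scattering vector, inverse Angstrom, increasing.
#' @param I Intensities (must be positive within the fit range).
#' @param sigma Optional per-point intensity errors (used as weights
#'   \eqn{(I/\sigma)^2} on the log scale).
#' @param qmax_rg Upper Guinier limit on q*Rg, default 1.3.
#' @return A `biophys_fit` with `Rg` (Angstrom) and `I0`, plus `n_used` and
#'   `q_limit`. A non-negative slope (aggregation / non-globular signal)
#'   raises an error.
#' @export
guinier_fit <- function(q, I, sigma = NULL, qmax_rg = 1.3) {
  if (length(q) != length(I)) stop_invalid("guinier_fit: length mismatch")
  use <- rep(TRUE, length(q))
  rg <- NA_real_
  for (iter in 1:100) {
    qs <- q[use]; Is <- I[use]
    if (sum(use) < 3)
      stop_invalid("guinier_fit: fewer than 3 points in the Guinier regime")
    if (any(Is <= 0))
      stop_invalid("guinier_fit: non-positive intensities in fit range")
    w <- if (is.null(sigma)) NULL else (Is / sigma[use])^2
    fit <- stats::lm(log(Is) ~ I(qs^2), weights = w)
    slope <- unname(stats::coef(fit)[2])
    if (slope >= 0)
      stop_invalid("guinier_fit: non-negative Guinier slope (aggregated or non-globular sample)")
    rg_new <- sqrt(-3 * slope)
    use_new <- q * rg_new <= qmax_rg
    use_new[1:min(3, length(q))] <- TRUE  # keep at least the lowest-q points
    if (identical(use_new, use)) { rg <- rg_new; break }
    use <- use_new
    rg <- rg_new
  }
  cf <- summary(fit)$coefficients
  se_slope <- unname(cf[2, 2])
  new_biophys_fit(
    model = "guinier",
    estimate = c(Rg = rg, I0 = exp(unname(cf[1, 1]))),
    se = c(Rg = 3 * se_slope / (2 * rg),
           I0 = exp(unname(cf[1, 1])) * unname(cf[1, 2])),
    residuals = unname(stats::residuals(fit)),
    converged = TRUE,
    extra = list(n_used = sum(use), q_limit = qmax_rg / rg))
}

#' Pair-distance distribution P(r) and radius of gyration from coordinates
#'
#' Histogram of all pairwise distances between points (uniform weights) with
#' the maximum dimension \eqn{D_{max}} and the radius of gyration from the
#' exact second moment of the pair-distance distribution,
#' \eqn{R_g^2 = \sum_{i<j} r_{ij}^2 / N^2} (computed from the unbinned
#' distances, so that two points separated by d give exactly
#' \eqn{R_g = d/2}, and a dense cloud recovers
#' \eqn{R_g^2 = \langle r^2\rangle/2}).
#'
#' @param coords Numeric matrix (n x 3) of coordinates, Angstrom, n >= 2.
#' @param bin_width Histogram bin width, Angstrom (default 1).
#' @return List of class `pr_dist` with `r` (bin centres), `p` (normalised
#'   pair fraction per bin), `counts`, `d_max` and `rg`.
#' @export
pr_from_coordinates <- function(coords, bin_width = 1) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2)
    stop_invalid("pr_from_coordinates: need at least 2 points")
  if (ncol(coords) != 3)
    stop_invalid("pr_from_coordinates: coords must be n x 3")
  d <- as.numeric(stats::dist(coords))
  dmax <- max(d)
  breaks <- seq(0, (floor(dmax / bin_width) + 1) * bin_width, by = bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  structure(
    list(r = h$mids, p = h$counts / sum(h$counts), counts = h$counts,
         d_max = dmax, rg = sqrt(sum(d^2)) / nrow(coords)),
    class = "pr_dist")
}

#' @export
print.pr_dist <- function(x, ...) {
  cat(sprintf("P(r): %d bins, D_max = %.2f A, Rg = %.2f A\n",
              length(x$r), x$d_max, x$rg))
  invisible(x)
}
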