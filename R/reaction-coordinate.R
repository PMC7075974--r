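#' Hydrolysis reaction coordinate from bond distances
#'
#' The ATP-hydrolysis reaction is followed along a one-dimensional coordinate
#' built from the four distances that change during the concerted proton
#' transfer and phosphate cleavage: the proton-transfer bond-forming (`r1`)
#' and bond-breaking (`r2`) distances and the phosphate bond-forming (`r3`)
#' and bond-breaking (`r4`) distances,
#' \deqn{R = r_4 - r_3 + r_2 - r_1.}
#' Reactants sit near R = -2.9 Angstrom and products near R = 2.6 Angstrom.
#'
#' @param r1,r2,r3,r4 Bond distances in Angstrom; positive and finite.
#'   Vectors of equal length are accepted and evaluated elementwise.
#' @return Reaction-coordinate value(s) R in Angstrom.
#' @examples
#' reaction_coordinate(1.0, 1.8, 2.0, 2.1)  # 0.9
#' @export
reaction_coordinate <- function(r1, r2, r3, r4) {
  d <- cbind(r1, r2, r3, r4)
  if (any(!is.finite(d)))
    stop_invalid("reaction_coordinate: all distances must be finite")
  if (any(d <= 0))
    stop_invalid("reaction_coordinate: all distances must be positive")
  unname(r4 - r3 + r2 - r1)
}

#' Construct an umbrella-sampling window
#'
#' One biased sampling window: a harmonic restraint of strength
#' `force_constant` centred at `center` on the reaction coordinate, together
#' with the R values sampled under that bias. The restraint convention is
#' declared per window because force-constant reporting differs between codes:
#' `"half_k"` means U(R) = k/2 (R - R0)^2, `"full_k"` means U(R) = k (R - R0)^2.
#'
#' @param center Bias centre R0 (Angstrom).
#' @param force_constant Harmonic force constant (kcal mol^-1 A^-2), >= 0.
#'   Typical umbrella values here are 100 or 500.
#' @param samples Numeric vector of sampled reaction-coordinate values (A).
#' @param temperature Simulation temperature (K), default 310.
#' @param bias_convention `"half_k"` (default) or `"full_k"`.
#' @return An object of class `umbrella_window`.
#' @seealso [bias_potential()], [wham_solve()]
#' @export
umbrella_window <- function(center, force_constant, samples,
                            temperature = 310,
                            bias_convention = c("half_k", "full_k")) {
  bias_convention <- match.arg(bias_convention)
  if (!is.finite(center))
    stop_invalid("umbrella_window: center must be finite")
  if (!is.finite(force_constant) || force_constant < 0)
    stop_invalid("umbrella_window: force_constant must be >= 0")
  if (length(samples) == 0 || any(!is.finite(samples)))
    stop_invalid("umbrella_window: samples must be non-empty and finite")
  if (!is.finite(temperature) || temperature <= 0)
    stop_invalid("umbrella_window: temperature must be > 0")
  structure(
    list(center = center, force_constant = force_constant,
         samples = as.numeric(samples), temperature = temperature,
         bias_convention = bias_convention),
    class = "umbrella_window")
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat(sprintf(
    "umbrella window: center %.3f A, k = %g kcal/mol/A^2 (%s), %d samples, T = %g K\n",
    x$center, x$force_constant, x$bias_convention,
    length(x$samples), x$temperature))
  invisible(x)
}

#' Harmonic bias energy of a window at given coordinate values
#'
#' @param window An [umbrella_window()].
#' @param R Reaction-coordinate value(s), Angstrom.
#' @return Bias energy in kcal mol^-1 (vectorised over `R`).
#' @examples
#' w <- umbrella_window(0, 100, samples = 0)
#' bias_potential(w, 0.1)  # 0.5 kcal/mol
#' @export
bias_potential <- function(window, R) {
  stopifnot(inherits(window, "umbrella_window"))
  pref <- if (window$bias_convention == "half_k") 0.5 else 1.0
  pref * window$force_constant * (R - window$center)^2
}
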