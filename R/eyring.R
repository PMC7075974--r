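#' Rate constant from a free-energy barrier (Eyring equation)
#'
#' Transition-state-theory conversion of an activation free energy into a
#' unimolecular rate constant,
#' \deqn{k = \kappa \frac{k_B T}{h} e^{-\Delta G^*/RT},}
#' with the reflection (transmission) coefficient \eqn{\kappa} defaulting
#' to 1. At 310 K the prefactor \eqn{k_BT/h} is about 6.46e12 s^-1; an
#' 18 kcal mol^-1 barrier then corresponds to about 1.3 s^-1 and a
#' 25 kcal mol^-1 barrier to about 1.5e-5 s^-1 (hours timescale).
#'
#' @param delta_g_barrier Activation free energy, kcal mol^-1 (vectorised).
#' @param temperature Absolute temperature, K (default 310).
#' @param kappa Reflection coefficient in (0, 1], default 1.
#' @return Rate constant(s) in s^-1.
#' @export
rate_from_barrier <- function(delta_g_barrier, temperature = 310, kappa = 1) {
  .check_rate_query(temperature, kappa)
  if (any(!is.finite(delta_g_barrier)))
    stop_invalid("rate_from_barrier: barrier must be finite")
  expo <- -delta_g_barrier / (phys_constants$R_kcal * temperature)
  if (any(expo > 700))
    stop_invalid("rate_from_barrier: barrier %g kcal/mol would overflow exp()",
                 min(delta_g_barrier))
  kappa * (phys_constants$kB * temperature / phys_constants$h) * exp(expo)
}

#' Free-energy barrier from a rate constant
#'
#' Algebraic inverse of [rate_from_barrier()]:
#' \eqn{\Delta G^* = RT \ln(\kappa k_B T / (h k))}.
#'
#' @param k Rate constant(s), s^-1, > 0.
#' @inheritParams rate_from_barrier
#' @return Barrier(s) in kcal mol^-1.
#' @export
barrier_from_rate <- function(k, temperature = 310, kappa = 1) {
  .check_rate_query(temperature, kappa)
  if (any(!is.finite(k)) || any(k <= 0))
    stop_invalid("barrier_from_rate: rate must be positive and finite")
  pref <- kappa * phys_constants$kB * temperature / phys_constants$h
  phys_constants$R_kcal * temperature * log(pref / k)
}

.check_rate_query <- function(temperature, kappa) {
  if (any(!is.finite(temperature)) || any(temperature <= 0))
    stop_invalid("temperature must be > 0")
  if (any(!is.finite(kappa)) || any(kappa <= 0) || any(kappa > 1))
    stop_invalid("kappa must lie in (0, 1]")
}

#' Human-readable timescale of a rate constant
#'
#' Maps the characteristic time 1/k onto a coarse label. Boundaries:
#' 1/k < 60 s -> "seconds"; < 3600 s -> "minutes"; < 86400 s -> "hours";
#' otherwise "days".
#'
#' @param k Rate constant, s^-1, > 0.
#' @return Character label, one of "seconds", "minutes", "hours", "days".
#' @examples
#' timescale_label(1.3)      # "seconds"
#' timescale_label(1.5e-5)   # "hours"
#' @export
timescale_label <- function(k) {
  if (any(!is.finite(k)) || any(k <= 0))
    stop_invalid("timescale_label: rate must be positive")
  tau <- 1 / k
  ifelse(tau < 60, "seconds",
         ifelse(tau < 3600, "minutes",
                ifelse(tau < 86400, "hours", "days")))
}
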