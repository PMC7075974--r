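#' Physical constants used throughout the package
#'
#' A single table of CODATA-2018 physical constants shared by every module,
#' so that the Eyring prefactor, the WHAM Boltzmann factors and the coulombic
#' electrostatics all use identical values. Energies are handled in
#' kcal mol^-1, distances in Angstrom, temperatures in Kelvin.
#'
#' @format A named list:
#' \describe{
#'   \item{kB}{Boltzmann constant, J K^-1 (exact).}
#'   \item{h}{Planck constant, J s (exact).}
#'   \item{N_A}{Avogadro constant, mol^-1 (exact).}
#'   \item{J_per_kcal}{Joule per thermochemical kilocalorie, 4184 exact.}
#'   \item{R_kcal}{Molar gas constant in kcal mol^-1 K^-1.}
#'   \item{coulomb_kcal}{Coulomb prefactor e^2/(4 pi eps0) in
#'     kcal Angstrom mol^-1 e^-2 (332.06).}
#' }
#' @export
phys_constants <- list(
  kB           = 1.380649e-23,
  h            = 6.62607015e-34,
  N_A          = 6.02214076e23,
  J_per_kcal   = 4184,
  R_kcal       = 8.31446261815324 / 4184,
  coulomb_kcal = 332.06
)

# kT in kcal/mol at temperature T (K)
kT_kcal <- function(temperature) phys_constants$R_kcal * temperature

`%||%` <- function(a, b) if (is.null(a)) b else a

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
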