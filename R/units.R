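#' alchemfe: alchemical free energies with softcore many-body potentials
#'
#' Softcore dimer-curve construction, lambda-scaled decoupling of two-body
#' features in a body-ordered potential, replica-exchange sampling, and
#' TI/BAR/MBAR free-energy estimation, together with an end-to-end solvation
#' / log P pipeline and synthetic fixtures with closed-form answers.
#'
#' @keywords internal
"_PACKAGE"

#' Physical constants in the package working units
#'
#' Working units are kcal/mol for energies, Angstrom for lengths, Kelvin for
#' temperature and atm for pressure. Synthetic fluid fixtures instead use
#' reduced (dimensionless) units by setting `kB = 1` in their thermodynamic
#' state; all samplers and estimators take the Boltzmann constant from the
#' state rather than hard-coding it.
#'
#' @format `kB_kcal` is the Boltzmann constant in kcal/(mol K); `ev_kcal`
#'   converts eV to kcal/mol; `atm_A3_kcal` converts a pressure-volume
#'   product in atm * Angstrom^3 to kcal/mol.
#' @name constants
NULL

#' @rdname constants
#' @export
kB_kcal <- 1.9872e-3

#' @rdname constants
#' @export
ev_kcal <- 23.0605

#' @rdname constants
#' @export
atm_A3_kcal <- 1.4584e-5

#' Thermodynamic state of one alchemical window
#'
#' @param temperature temperature (K, or reduced temperature when `kB = 1`)
#' @param pressure pressure (atm, or reduced); `NULL` selects the NVT ensemble
#' @param lambda alchemical coupling parameter in \[0, 1\]
#' @param kB Boltzmann constant in the energy units of the model;
#'   default kcal/(mol K)
#' @param pv_to_energy conversion factor taking pressure * volume into the
#'   model energy units (atm * A^3 -> kcal/mol by default; use 1 for
#'   reduced units)
#' @return an object of class `thermo_state`
#' @export
thermo_state <- function(temperature, pressure = NULL, lambda = 1,
                         kB = kB_kcal, pv_to_energy = atm_A3_kcal) {
  if (!is.numeric(temperature) || length(temperature) != 1L || temperature <= 0)
    stop("temperature must be a single positive number")
  if (!is.null(pressure) && (!is.numeric(pressure) || length(pressure) != 1L))
    stop("pressure must be NULL (NVT) or a single number")
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1)
    stop("lambda must lie in [0, 1]")
  structure(list(temperature = temperature, pressure = pressure,
                 lambda = lambda, kB = kB, pv_to_energy = pv_to_energy),
            class = "thermo_state")
}

#' Reduced (dimensionless) potential of a configuration
#'
#' Computes u* = u / (kB T) in NVT, u* = (u + p V) / (kB T) in NPT, the
#' quantity consumed by multistate estimators such as MBAR.
#'
#' @param u potential energy (model energy units)
#' @param state a [thermo_state()]
#' @param volume system volume; required when `state` carries a pressure
#' @return dimensionless reduced potential (vectorised over `u`)
#' @export
reduced_potential <- function(u, state, volume = NULL) {
  stopifnot(inherits(state, "thermo_state"))
  beta <- 1 / (state$kB * state$temperature)
  if (is.null(state$pressure)) return(u * beta)
  if (is.null(volume))
    stop("NPT reduced potential requires the system volume")
  (u + state$pressure * state$pv_to_energy * volume) * beta
}
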