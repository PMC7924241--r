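# Archetype energetics: per-ASU normalization, thermal-energy windows,
# Boltzmann populations, energy-occupancy consistency, and the
# static/dynamic/implausible classification of disorder.

#' Hartree in kJ/mol (CODATA)
#' @export
HARTREE_KJ_MOL <- 2625.4996

#' Molar gas constant in J/(mol K)
#' @export
GAS_CONSTANT_J <- 8.314

#' Thermal energy window RT
#'
#' The molar thermal energy available to a molecule at temperature T: the
#' energy window within which archetype conformations must lie for disorder
#' to be plausible, and which an interconversion barrier must not exceed
#' for the disorder to be dynamic.
#'
#' @param temperature Temperature in Kelvin (>= 0).
#' @return R x T in kJ/mol (2.48 kJ/mol at 298 K).
#' @export
thermal_energy <- function(temperature) {
  if (any(!is.finite(temperature)) || any(temperature < 0)) {
    stop("temperature must be non-negative (Kelvin)", call. = FALSE)
  }
  GAS_CONSTANT_J * temperature / 1000
}

#' Normalize a total energy to one ASU content
#'
#' Cluster or supercell computations can contain several copies of the
#' asymmetric-unit content; archetype energies are compared per ASU
#' throughout.
#'
#' @param total_energy Total energy in Hartree.
#' @param n_asu_units Number of ASU contents in the computed system (>= 1).
#' @return Energy in kJ/mol per ASU.
#' @export
normalize_per_asu <- function(total_energy, n_asu_units = 1) {
  if (any(n_asu_units < 1)) {
    stop("n_asu_units must be at least 1", call. = FALSE)
  }
  total_energy * HARTREE_KJ_MOL / n_asu_units
}

#' Energy records for a set of archetypes
#'
#' @param archetype Identifier per archetype.
#' @param total_energy Total energies in Hartree.
#' @param n_asu_units ASU copies in each computed system.
#' @return Tibble with the inputs plus `energy_per_asu` (kJ/mol).
#' @export
energy_records <- function(archetype, total_energy, n_asu_units = 1) {
  tibble::tibble(
    archetype = archetype,
    total_energy = total_energy,
    n_asu_units = n_asu_units,
    energy_per_asu = normalize_per_asu(total_energy, n_asu_units)
  )
}

#' Boltzmann populations of archetype conformations
#'
#' `p_i = exp(-E_i / RT) / sum_j exp(-E_j / RT)`, computed with the
#' minimum-energy shift for numerical safety. At T = 0 all probability mass
#' sits on the minimum-energy archetype (ties split equally).
#'
#' @param energies_per_asu Energies in kJ/mol (any common offset cancels).
#' @param temperature Temperature in Kelvin.
#' @return Fractions summing to 1.
#' @export
boltzmann_occupancies <- function(energies_per_asu, temperature) {
  if (length(energies_per_asu) < 2) {
    stop("need at least two archetype energies", call. = FALSE)
  }
  if (temperature < 0) stop("temperature must be non-negative", call. = FALSE)
  if (temperature == 0) {
    win <- energies_per_asu <= min(energies_per_asu) + 1e-12
    return(win / sum(win))
  }
  rt <- thermal_energy(temperature)
  w <- exp(-(energies_per_asu - min(energies_per_asu)) / rt)
  w / sum(w)
}

#' Check consistency of experimental occupancies with archetype energies
#'
#' The higher occupancy should belong to the lower-energy archetype. Near
#' 50/50 occupancies carry no ranking information, so pairs whose occupancy
#' gap does not exceed `tie_band` are exempt from the check.
#'
#' @param energies_per_asu Energies in kJ/mol, one per archetype.
#' @param experimental_occupancies Occupancies summing to 1 (within 0.01).
#' @param tie_band Occupancy-gap width treated as "50/50 or close"
#'   (default 0.05).
#' @return List with `verdict` ("consistent", "exempt" or "inconsistent"),
#'   `occupancy_gap`, and the two rankings.
#' @export
check_occupancy_energy_consistency <- function(energies_per_asu,
                                               experimental_occupancies,
                                               tie_band = 0.05) {
  if (length(energies_per_asu) != length(experimental_occupancies)) {
    stop("energies and occupancies have different lengths", call. = FALSE)
  }
  if (abs(sum(experimental_occupancies) - 1) > 0.01) {
    stop("experimental occupancies must sum to 1 (within 0.01)",
         call. = FALSE)
  }
  gap <- max(experimental_occupancies) - min(experimental_occupancies)
  occ_rank <- order(experimental_occupancies, decreasing = TRUE)
  en_rank <- order(energies_per_asu, decreasing = FALSE)
  verdict <- if (gap <= tie_band) {
    "exempt"
  } else if (identical(occ_rank, en_rank)) {
    "consistent"
  } else {
    "inconsistent"
  }
  list(verdict = verdict, occupancy_gap = gap,
       occupancy_ranking = occ_rank, energy_ranking = en_rank)
}

#' Classify disorder as static, dynamic, or implausible
#'
#' Applies the energy requirement for disorder and the barrier criterion:
#' archetype energies must be similar (around RT at crystallization
#' conditions) for disorder to occur at all; given similar energies, the
#' disorder is dynamic when the interconversion barrier can be overcome
#' within the thermal window RT at the given temperature, and static when
#' it cannot.
#'
#' @param delta_E Archetype energy difference per ASU in kJ/mol
#'   (minor - major; sign is ignored for the plausibility check).
#' @param barrier Interconversion barrier in kJ/mol, or `NA` if unknown.
#' @param temperature Temperature in Kelvin at which the behaviour is
#'   assessed (default 298).
#' @param similarity_factor Multiple of RT(crystallization) regarded as
#'   "similar energy" (default 1); energies beyond 3 x this window give the
#'   disorder-unlikely verdict.
#' @param crystallization_temperature Temperature in Kelvin assumed for
#'   crystal growth (default 298: crystals are usually grown at ambient
#'   conditions).
#' @return A `disorder_assessment` list: `delta_E`, `barrier`,
#'   `temperature`, `thermal_window` (RT at `temperature`),
#'   `predicted_occupancies` (Boltzmann fractions of the two archetypes at
#'   `temperature`), and `verdict` in `dynamic`, `static`,
#'   `disorder-unlikely`, `barrier-unknown`.
#' @examples
#' classify_disorder(delta_E = 0.6, barrier = 0.2, temperature = 298)
#' @export
classify_disorder <- function(delta_E, barrier = NA_real_, temperature = 298,
                              similarity_factor = 1,
                              crystallization_temperature = 298) {
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  window_cryst <- similarity_factor * thermal_energy(crystallization_temperature)
  window_here <- thermal_energy(temperature)
  verdict <- if (abs(delta_E) > 3 * window_cryst) {
    "disorder-unlikely"
  } else if (is.na(barrier)) {
    "barrier-unknown"
  } else if (barrier <= window_here) {
    "dynamic"
  } else {
    "static"
  }
  pops <- boltzmann_occupancies(c(0, abs(delta_E)), temperature)
  structure(
    list(delta_E = delta_E, barrier = barrier, temperature = temperature,
         thermal_window = window_here,
         predicted_occupancies = pops, verdict = verdict),
    class = "disorder_assessment"
  )
}

#' @export
print.disorder_assessment <- function(x, ...) {
  cat(sprintf("<disorder_assessment> verdict: %s\n", x$verdict))
  cat(sprintf("  delta E = %.3f kJ/mol, barrier = %s kJ/mol, T = %.1f K (RT = %.3f kJ/mol)\n",
              x$delta_E,
              if (is.na(x$barrier)) "unknown" else sprintf("%.3f", x$barrier),
              x$temperature, x$thermal_window))
  cat(sprintf("  Boltzmann occupancies at T: %s\n",
              paste(sprintf("%.3f", x$predicted_occupancies), collapse = " / ")))
  invisible(x)
}
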