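# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a disorder assessment
#'
#' @param x A `disorder_assessment` from [classify_disorder()].
#' @param ... Unused.
#' @return One-row tibble with the energies, window, Boltzmann occupancies
#'   and verdict.
#' @export
tidy.disorder_assessment <- function(x, ...) {
  tibble::tibble(
    delta_E = x$delta_E, barrier = x$barrier, temperature = x$temperature,
    thermal_window = x$thermal_window,
    occupancy_major = max(x$predicted_occupancies),
    occupancy_minor = min(x$predicted_occupancies),
    verdict = x$verdict
  )
}

#' @rdname tidy.disorder_assessment
#' @export
glance.disorder_assessment <- function(x, ...) {
  tibble::tibble(verdict = x$verdict,
                 barrier_known = !is.na(x$barrier),
                 delta_E_within_window = abs(x$delta_E) <= x$thermal_window)
}

#' Tidy an optimization result
#'
#' @param x An `optimization_result` from [iterate_optimization()].
#' @param ... Unused.
#' @return The per-cycle trace tibble.
#' @export
tidy.optimization_result <- function(x, ...) x$trace

#' @rdname tidy.optimization_result
#' @export
glance.optimization_result <- function(x, ...) {
  tibble::tibble(
    backend = x$backend, n_cycles = nrow(x$trace), energy = x$energy,
    final_rms_displacement = x$trace$rms_displacement[nrow(x$trace)]
  )
}

#' Tidy a pipeline result
#'
#' @param x A `pipeline_result` from [run_pipeline()].
#' @param ... Unused.
#' @return The stage-count log tibble.
#' @export
tidy.pipeline_result <- function(x, ...) x$counts

#' @rdname tidy.pipeline_result
#' @export
glance.pipeline_result <- function(x, ...) {
  tibble::tibble(
    n_archetypes = length(x$archetypes),
    n_restraints = nrow(x$restraints),
    n_constraints = nrow(x$constraints),
    parameters_free = count_parameters(x$recombined),
    parameters_constrained = count_parameters(x$recombined, x$plan),
    verdict = if (is.null(x$assessment)) NA_character_ else
      x$assessment$verdict
  )
}

#' Plot the optimization energy trace
#'
#' @param object An `optimization_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.optimization_result <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$cycle, y = .data$energy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "cycle", y = "total energy (Hartree)",
                  title = "Molecule-in-cluster optimization trace") +
    ggplot2::theme_minimal()
}

#' Plot Boltzmann major-component occupancy against energy difference
#'
#' Shows where an assessment's energy difference sits on the two-state
#' Boltzmann curve at its temperature, with the RT window marked.
#'
#' @param object A `disorder_assessment`.
#' @param max_delta Upper end of the energy-difference axis in kJ/mol.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.disorder_assessment <- function(object, max_delta = 10, ...) {
  grid <- tibble::tibble(delta = seq(0, max_delta, length.out = 200))
  grid$major <- vapply(grid$delta, function(d) {
    max(boltzmann_occupancies(c(0, d), object$temperature))
  }, numeric(1))
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$delta, y = .data$major)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$thermal_window,
                        linetype = "dashed") +
    ggplot2::annotate("point", x = abs(object$delta_E),
                      y = max(object$predicted_occupancies)) +
    ggplot2::labs(
      x = "archetype energy difference (kJ/mol per ASU)",
      y = "Boltzmann occupancy of major archetype",
      title = sprintf("Two-state populations at %.0f K (dashed: RT)",
                      object$temperature)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
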