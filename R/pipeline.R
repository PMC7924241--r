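# End-to-end orchestration: split -> per-archetype cluster optimization ->
# restraints -> recombine -> constraints -> instruction files ->
# energy-based disorder classification.

#' Pipeline configuration
#'
#' @param structure A [crystal_structure()], or `NULL` to generate
#'   `fixture`.
#' @param fixture A [fixture_spec()] used when `structure` is `NULL`.
#' @param backend Optimization backend (default [backend_mock()]).
#' @param n_cycles Optimization repeat cycles (default 10).
#' @param cutoff Cluster selection distance, Angstrom (default 3.75).
#' @param sigma Restraint standard uncertainty (default 0.005).
#' @param h_scale X-H shrink factor for restraint targets (default 0.865).
#' @param threshold Constraint proximity threshold, Angstrom (default 0.5).
#' @param mode Constraint mode: `"eadp"`, `"eadp+exyz"` or `"simu"`.
#' @param simu_sigma SIMU standard uncertainty (default 0.02).
#' @param temperature Temperature (K) for the disorder assessment
#'   (default 298).
#' @param barrier User-supplied interconversion barrier in kJ/mol (`NA` if
#'   unknown; the pipeline never computes barriers itself).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(structure = NULL, fixture = fixture_spec(),
                            backend = backend_mock(), n_cycles = 10,
                            cutoff = 3.75, sigma = 0.005, h_scale = 0.865,
                            threshold = 0.5, mode = "eadp",
                            simu_sigma = 0.02, temperature = 298,
                            barrier = NA_real_) {
  structure(
    list(structure = structure, fixture = fixture, backend = backend,
         n_cycles = n_cycles, cutoff = cutoff, sigma = sigma,
         h_scale = h_scale, threshold = threshold, mode = mode,
         simu_sigma = simu_sigma, temperature = temperature,
         barrier = barrier),
    class = "pipeline_config"
  )
}

#' Run the full disorder-modelling pipeline
#'
#' Splits the model into archetypes, optimizes each inside its
#' symmetry-generated cluster, generates archetype-specific DFIX/DANG
#' restraints, recombines the optimized archetypes into one residue-scoped
#' disorder model, assigns proximity constraints, writes the SHELXL
#' instruction file and the refinable model, and classifies the disorder
#' from the archetype energies.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_result` list: `model` (input), `archetypes`,
#'   `optimizations`, `restraints`, `recombined`, `mapping`, `constraints`,
#'   `plan`, `instruction_file`, `shelx_file`, `energies`, `assessment`,
#'   `consistency` and `counts` (the stage-count log tibble).
#' @examples
#' res <- run_pipeline(pipeline_config(fixture = fixture_spec(), n_cycles = 2))
#' res$counts
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  model <- stage("input", config$structure %||% make_fixture(config$fixture))

  archetypes <- stage("split", split_archetypes(model))
  n <- length(archetypes)
  if (n == 1) {
    message("1 archetype, nothing to recombine: input is ordered")
    opt <- stage("optimize",
                 iterate_optimization(archetypes[[1]], config$backend,
                                      n_cycles = config$n_cycles,
                                      cutoff = config$cutoff))
    restraints <- stage("restraints",
                        generate_restraints(opt$structure,
                                            sigma = config$sigma,
                                            h_scale = config$h_scale,
                                            residue = 1L))
    plan <- refinement_plan(restraints, strategy = "restrained+EADP")
    out <- list(
      model = model, archetypes = archetypes, optimizations = list(opt),
      restraints = restraints, recombined = model,
      mapping = NULL, constraints = plan$constraints, plan = plan,
      instruction_file = write_instruction_file(plan),
      shelx_file = write_shelx(model),
      energies = energy_records(1L, opt$energy),
      assessment = NULL, consistency = NULL,
      counts = tibble::tibble(
        stage = c("archetypes", "restraints", "constraints",
                  "parameters_free"),
        count = c(1L, nrow(restraints), 0L, count_parameters(model))
      )
    )
    class(out) <- "pipeline_result"
    return(out)
  }

  opts <- stage("optimize", lapply(archetypes, function(a) {
    iterate_optimization(a, config$backend, n_cycles = config$n_cycles,
                         cutoff = config$cutoff)
  }))
  optimized <- lapply(opts, function(o) o$structure)
  for (i in seq_len(n)) {
    attr(optimized[[i]], "part") <- attr(archetypes[[i]], "part")
  }

  restraints <- stage("restraints", dplyr::bind_rows(
    lapply(seq_len(n), function(i) {
      generate_restraints(optimized[[i]], sigma = config$sigma,
                          h_scale = config$h_scale, residue = i)
    })
  ))

  # occupancies carried over from the parent model's disorder parts
  parts <- vapply(archetypes, function(a) attr(a, "part"), integer(1))
  occs <- vapply(parts, function(p) {
    mean(model$sites$occupancy[model$sites$part == p])
  }, numeric(1))
  occs <- occs / sum(occs)
  recombined <- stage("recombine", recombine(optimized, occupancies = occs))

  mappings <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- optimized[[i]]; b <- optimized[[j]]
    a$sites$residue <- i; b$sites$residue <- j
    mappings[[length(mappings) + 1L]] <- map_atoms(a, b)
  }
  mapping <- dplyr::bind_rows(mappings)
  constraints <- stage("constraints",
                       assign_constraints(mapping,
                                          threshold = config$threshold,
                                          mode = config$mode,
                                          simu_sigma = config$simu_sigma))
  strategy <- switch(config$mode, simu = "restrained+SIMU",
                     "restrained+EADP")
  plan <- stage("plan", refinement_plan(
    restraints, constraints,
    occupancy_plan = recombined$metadata$occupancy_plan,
    strategy = strategy, sump = recombined$metadata$sump
  ))
  instruction_file <- write_instruction_file(plan)
  shelx_file <- write_shelx(recombined,
                            extra = instruction_file$main_stub)

  energies <- energy_records(parts,
                             vapply(opts, function(o) o$energy, numeric(1)))
  major <- which.max(occs)
  minor <- which.min(occs)
  if (major == minor) { major <- 1L; minor <- 2L }
  delta_E <- energies$energy_per_asu[minor] - energies$energy_per_asu[major]
  assessment <- stage("classify",
                      classify_disorder(delta_E, barrier = config$barrier,
                                        temperature = config$temperature))
  consistency <- check_occupancy_energy_consistency(
    energies$energy_per_asu, occs
  )

  counts <- tibble::tibble(
    stage = c("archetypes",
              sprintf("cluster_size_archetype_%d_final", seq_len(n)),
              "restraints", "constraints", "parameters_free",
              "parameters_constrained"),
    count = c(n,
              vapply(opts, function(o) {
                as.integer(o$trace$n_environment[nrow(o$trace)])
              }, integer(1)),
              nrow(restraints), nrow(constraints),
              count_parameters(recombined),
              count_parameters(recombined, plan))
  )

  out <- list(
    model = model, archetypes = archetypes, optimizations = opts,
    restraints = restraints, recombined = recombined, mapping = mapping,
    constraints = constraints, plan = plan,
    instruction_file = instruction_file, shelx_file = shelx_file,
    energies = energies, assessment = assessment,
    consistency = consistency, counts = counts
  )
  class(out) <- "pipeline_result"
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$counts, n = nrow(x$counts))
  if (!is.null(x$assessment)) print(x$assessment)
  invisible(x)
}
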