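# Archetype handling: splitting a disordered model into hypothetical
# ordered structures (one per disorder group, completed with the shared
# atoms), recombining optimized archetypes into one refinable model, and
# measuring geometric differences between archetypes.

#' Split a disordered model into ordered archetype structures
#'
#' Produces one archetype per distinct nonzero PART id: all shared (part 0)
#' sites plus that part's sites, in parent order, with every occupancy
#' reset to 1 and free-variable coding cleared — each archetype is computed
#' as if it were an ordered structure.
#'
#' @param model A [crystal_structure()].
#' @return A list of `archetype` objects (crystal structures carrying
#'   `part` — the disorder group realized — and `provenance`, the parent
#'   site row indices).
#' @export
split_archetypes <- function(model) {
  parts <- disorder_parts(model)
  if (length(parts) == 0) {
    arch <- model
    arch$sites$occupancy <- 1
    arch$sites$fv_ref <- NA_integer_
    attr(arch, "part") <- 0L
    attr(arch, "provenance") <- seq_len(nrow(model$sites))
    class(arch) <- c("archetype", class(model))
    return(list(arch))
  }
  lapply(parts, function(p) {
    keep <- which(model$sites$part %in% c(0L, p))
    if (!any(model$sites$part[keep] == p)) {
      stop(sprintf("disorder part %d has no atoms", p), call. = FALSE)
    }
    shared_lab <- model$sites$label[model$sites$part == 0L]
    part_lab <- model$sites$label[model$sites$part == p]
    clash <- intersect(shared_lab, part_lab)
    if (length(clash)) {
      stop("labels used both in shared atoms and in part ", p, ": ",
           paste(clash, collapse = ", "), call. = FALSE)
    }
    sites <- model$sites[keep, ]
    sites$occupancy <- 1
    sites$fv_ref <- NA_integer_
    sites$part <- 0L
    arch <- crystal_structure(model$cell, sites, symm = model$symm,
                              latt = model$latt, fvar = 1,
                              title = sprintf("%s archetype part %d",
                                              model$title, p),
                              metadata = model$metadata)
    attr(arch, "part") <- p
    attr(arch, "provenance") <- keep
    class(arch) <- c("archetype", class(arch))
    arch
  })
}

#' Recombine archetypes into one refinable disorder model
#'
#' All archetypes are present in full: atoms that would share a split site
#' become separate sites, scoped by residue (RESI) so labels can repeat.
#' Occupancies are linked through whole-molecule free variables: for two
#' archetypes one variable (codes `10*fv + 1` and `-(10*fv + 1)`, i.e. fv
#' and 1 - fv); for n > 2 one variable per archetype with a sum-to-one
#' SUMP plan (emit via [write_instruction_file()]).
#'
#' @param archetypes List of archetypes over the same cell and operations.
#' @param occupancies Numeric occupancy per archetype, summing to 1
#'   (default: equal shares).
#' @return A [crystal_structure()] with residues `1..n`; its
#'   `metadata$occupancy_plan` records the free-variable assignment.
#' @export
recombine <- function(archetypes, occupancies = NULL) {
  n <- length(archetypes)
  stopifnot(n >= 1)
  if (n == 1) return(archetypes[[1]])
  cell0 <- archetypes[[1]]$cell
  for (a in archetypes[-1]) {
    if (max(abs(unlist(a$cell) - unlist(cell0))) > 1e-8) {
      stop("archetypes have mismatched unit cells", call. = FALSE)
    }
  }
  if (is.null(occupancies)) occupancies <- rep(1 / n, n)
  if (abs(sum(occupancies) - 1) > 1e-6) {
    stop("archetype occupancies must sum to 1", call. = FALSE)
  }
  if (n == 2) {
    fvar <- c(1, occupancies[1])
    fv_refs <- c(2L, -2L)
    plan <- tibble::tibble(
      residue = 1:2, fv = c(2L, 2L), coding = c("fv", "1-fv"),
      occupancy = occupancies
    )
  } else {
    fvar <- c(1, occupancies)
    fv_refs <- seq(2L, n + 1L)
    plan <- tibble::tibble(
      residue = seq_len(n), fv = fv_refs, coding = "fv",
      occupancy = occupancies
    )
  }
  pieces <- lapply(seq_len(n), function(i) {
    sites <- archetypes[[i]]$sites
    sites$residue <- i
    sites$part <- i
    sites$occupancy <- occupancies[i]
    sites$fv_ref <- fv_refs[i]
    sites
  })
  model <- crystal_structure(
    cell0, dplyr::bind_rows(pieces),
    symm = archetypes[[1]]$symm, latt = archetypes[[1]]$latt,
    fvar = fvar,
    title = sub(" archetype part.*$", "", archetypes[[1]]$title),
    metadata = archetypes[[1]]$metadata
  )
  model$metadata$occupancy_plan <- plan
  if (n > 2) {
    model$metadata$sump <- sprintf(
      "SUMP 1 0.001 %s",
      paste(sprintf("1 %d", fv_refs), collapse = " ")
    )
  }
  model
}

#' Map atoms between two archetypes by sequence position
#'
#' Pairs the i-th site of `a` with the i-th site of `b` (the archetypes are
#' written in the same sequence) and reports the Cartesian distance of each
#' pair in the shared crystal frame — no superposition is performed, both
#' archetypes live in the same fixed cell.
#'
#' @param a,b Archetypes ([crystal_structure()] objects) with equal site
#'   counts and matching element sequences.
#' @return An `atom_pair_mapping` tibble with columns `label_a`, `label_b`,
#'   `element`, `residue_a`, `residue_b` and `distance` (Angstrom).
#' @export
map_atoms <- function(a, b) {
  if (nrow(a$sites) != nrow(b$sites)) {
    stop(sprintf("site counts differ: %d vs %d", nrow(a$sites),
                 nrow(b$sites)), call. = FALSE)
  }
  mism <- which(a$sites$element != b$sites$element)
  if (length(mism)) {
    stop(sprintf("element sequence mismatch at position %d: %s vs %s",
                 mism[1], a$sites$element[mism[1]], b$sites$element[mism[1]]),
         call. = FALSE)
  }
  ca <- site_cartesian(a)
  cb <- site_cartesian(b)
  out <- tibble::tibble(
    label_a = a$sites$label, label_b = b$sites$label,
    element = a$sites$element,
    residue_a = a$sites$residue, residue_b = b$sites$residue,
    distance = sqrt(rowSums((ca - cb)^2))
  )
  class(out) <- c("atom_pair_mapping", class(out))
  out
}

#' Root-mean-square Cartesian displacement
#'
#' `sqrt(mean(d^2))` over the mapped atom pairs, in the fixed crystal frame
#' (no fitting). The standard single number for how much two archetypes of
#' the same structure differ geometrically.
#'
#' @param mapping An [map_atoms()] result (or any table with a `distance`
#'   column).
#' @return RMSCD in Angstrom.
#' @export
rmscd <- function(mapping) {
  if (nrow(mapping) == 0) stop("empty atom mapping", call. = FALSE)
  sqrt(mean(mapping$distance^2))
}
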