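# Restraint and constraint generation for least-squares refinement.
#
# Each archetype keeps its optimized geometry through DFIX (1-2, bonded)
# and DANG (1-3, angle-defining) distance restraints; proximate atoms
# across archetypes get EADP (shared ADPs), optionally EXYZ (shared
# positions) or SIMU (similar-ADP restraint) treatment so the recombined
# model is not over-parameterized.

#' Generate DFIX/DANG restraints from an optimized archetype geometry
#'
#' One DFIX per covalent bond and one DANG per 1-3 pair, each with the
#' optimized distance as target. Bond distances to hydrogen are shrunk by
#' the X-ray correction factor `h_scale` (13.5 % by default): the hydrogen
#' is repositioned along its bond vector and all targets, including the
#' 1-3 targets that involve that hydrogen, are recomputed from the
#' repositioned atom. That keeps bond angles invariant under the shrink,
#' which is the physically intended correction when going from theory
#' (nuclear positions) to X-ray experiment (electron-density centroids).
#'
#' @param archetype An optimized archetype ([crystal_structure()]).
#' @param graph Optional precomputed [structure_bond_graph()] on that
#'   geometry.
#' @param sigma Restraint standard uncertainty (default 0.005).
#' @param h_scale Multiplicative shrink for X-H bond lengths
#'   (default 0.865, i.e. a 13.5 % reduction).
#' @param residue Residue number the restraints are scoped to (default: the
#'   archetype's disorder part id, else 1).
#' @param exclude Optional two-column matrix / data frame of label pairs to
#'   omit (an override hook for atoms whose computed geometry is not
#'   trusted).
#' @return A `restraint_set` tibble: `kind` ("DFIX"/"DANG"), `target` (A),
#'   `sigma`, `label1`, `label2`, `residue`.
#' @export
generate_restraints <- function(archetype, graph = NULL, sigma = 0.005,
                                h_scale = 0.865, residue = NULL,
                                exclude = NULL) {
  if (is.null(graph)) graph <- structure_bond_graph(archetype)
  if (is.null(residue)) {
    residue <- attr(archetype, "part") %||% 1L
    if (residue == 0L) residue <- 1L
  }
  cart <- graph$cart
  # reposition each hydrogen along its bond vector toward the bonded atom
  hyd <- which(is_hydrogen(graph$elements))
  for (h in hyd) {
    k <- which(graph$edges$i == h | graph$edges$j == h)
    if (length(k) == 0) next
    partner <- ifelse(graph$edges$i[k[1]] == h, graph$edges$j[k[1]],
                      graph$edges$i[k[1]])
    cart[h, ] <- cart[partner, ] + h_scale * (graph$cart[h, ] - cart[partner, ])
  }
  pair_distance <- function(i, j) sqrt(rowSums((cart[i, , drop = FALSE] -
                                                cart[j, , drop = FALSE])^2))
  b12 <- one_two_pairs(graph)
  b13 <- one_three_pairs(graph)
  labels <- archetype$sites$label
  out <- dplyr::bind_rows(
    tibble::tibble(kind = "DFIX",
                   target = pair_distance(b12$i, b12$j),
                   sigma = sigma,
                   label1 = labels[b12$i], label2 = labels[b12$j],
                   residue = as.integer(residue)),
    tibble::tibble(kind = "DANG",
                   target = pair_distance(b13$i, b13$j),
                   sigma = sigma,
                   label1 = labels[b13$i], label2 = labels[b13$j],
                   residue = as.integer(residue))
  )
  if (any(!is.finite(out$target)) || any(out$target <= 0)) {
    stop("non-finite or non-positive restraint target encountered",
         call. = FALSE)
  }
  if (!is.null(exclude) && length(exclude)) {
    ex <- as.data.frame(exclude)
    ex_keys <- c(paste(ex[[1]], ex[[2]]), paste(ex[[2]], ex[[1]]))
    out <- out[!paste(out$label1, out$label2) %in% ex_keys, ]
  }
  out <- out[order(out$kind, out$label1, out$label2), ]
  class(out) <- c("restraint_set", class(out))
  out
}

#' Assign proximity constraints across archetypes
#'
#' For every mapped atom pair whose inter-archetype distance is below
#' `threshold`, emits the constraint appropriate to the strategy:
#' EADP (shared displacement parameters, the recommended default), EADP
#' plus positional EXYZ, or SIMU similarity restraints in place of EADP.
#' EXYZ is off by default because the DFIX/DANG restraints already capture
#' the small positional differences of nearly overlaying atoms.
#'
#' @param mapping An [map_atoms()] result computed on the final
#'   (restraint-target) geometries, carrying residue-scoped labels.
#' @param threshold Proximity threshold in Angstrom (default 0.5).
#' @param mode `"eadp"` (default), `"eadp+exyz"`, or `"simu"`.
#' @param simu_sigma Standard uncertainty for SIMU records (default 0.02).
#' @return A `constraint_set` tibble: `kind`, `sigma` (`NA` except SIMU),
#'   `label1`, `residue1`, `label2`, `residue2`, `distance`.
#' @export
assign_constraints <- function(mapping, threshold = 0.5,
                               mode = c("eadp", "eadp+exyz", "simu"),
                               simu_sigma = 0.02) {
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("threshold must be a positive distance in Angstrom", call. = FALSE)
  }
  close <- mapping[mapping$distance < threshold, ]
  base <- tibble::tibble(
    label1 = close$label_a, residue1 = close$residue_a,
    label2 = close$label_b, residue2 = close$residue_b,
    distance = close$distance
  )
  mk <- function(kind, sigma) {
    dplyr::bind_cols(
      tibble::tibble(kind = rep(kind, nrow(base)),
                     sigma = rep(sigma, nrow(base))),
      base
    )
  }
  out <- if (mode == "simu") {
    mk("SIMU", simu_sigma)
  } else if (mode == "eadp+exyz") {
    dplyr::bind_rows(mk("EADP", NA_real_), mk("EXYZ", NA_real_))
  } else {
    mk("EADP", NA_real_)
  }
  out <- out[order(out$kind, out$label1, out$residue1), ]
  class(out) <- c("constraint_set", class(out))
  out
}

#' Assemble a refinement plan
#'
#' @param restraints A `restraint_set` (possibly several row-bound).
#' @param constraints A `constraint_set`.
#' @param occupancy_plan Occupancy free-variable table (from
#'   `recombine()`'s `metadata$occupancy_plan`).
#' @param strategy One of `"free"`, `"restrained+EADP"`,
#'   `"restrained+SIMU"`.
#' @param sump Optional SUMP line for n > 2 archetypes.
#' @return A `refinement_plan` list.
#' @export
refinement_plan <- function(restraints, constraints = NULL,
                            occupancy_plan = NULL,
                            strategy = c("restrained+EADP", "free",
                                         "restrained+SIMU"),
                            sump = NULL) {
  strategy <- match.arg(strategy)
  if (is.null(constraints)) {
    constraints <- tibble::tibble(kind = character(), sigma = numeric(),
                                  label1 = character(), residue1 = integer(),
                                  label2 = character(), residue2 = integer(),
                                  distance = numeric())
  }
  if (nrow(restraints) > 0 && any(constraints$kind == "EXYZ")) {
    conflict <- dplyr::inner_join(
      restraints[restraints$kind == "DFIX", c("label1", "label2", "residue")],
      constraints[constraints$kind == "EXYZ",
                  c("label1", "label2", "residue1")],
      by = c("label1", "label2")
    )
    if (nrow(conflict) > 0 && any(conflict$residue == conflict$residue1)) {
      stop("a DFIX restraint and an EXYZ constraint target the same atom pair",
           call. = FALSE)
    }
  }
  structure(
    list(restraints = restraints, constraints = constraints,
         occupancy_plan = occupancy_plan, strategy = strategy, sump = sump),
    class = "refinement_plan"
  )
}

#' @export
print.refinement_plan <- function(x, ...) {
  cat(sprintf("<refinement_plan> strategy %s: %d restraint(s), %d constraint record(s)\n",
              x$strategy, nrow(x$restraints), nrow(x$constraints)))
  invisible(x)
}

fmt_target <- function(x) {
  s <- sprintf("%.4f", x)
  s <- sub("0+$", "", s)
  sub("\\.$", ".0", s)
}

#' Write a SHELXL instruction file for a refinement plan
#'
#' Emits one RESI card per residue followed by its DFIX/DANG lines with
#' residue-qualified atom names (`C1_1`), then the EADP/EXYZ/SIMU records,
#' in deterministic order (restraints by residue, kind, then atom labels).
#' Also returns the one-line main-file stub (`+filename`) that makes
#' SHELXL read the instructions.
#'
#' @param plan A [refinement_plan()].
#' @param filename Name used in the `+filename` include stub.
#' @return List with `instructions` (file content, single string) and
#'   `main_stub` (the `+filename` line).
#' @export
write_instruction_file <- function(plan, filename = "restraints.ins") {
  out <- character(0)
  r <- plan$restraints
  for (res in sort(unique(r$residue))) {
    out <- c(out, sprintf("RESI %d", res))
    rr <- r[r$residue == res, ]
    rr <- rr[order(match(rr$kind, c("DFIX", "DANG")), rr$label1, rr$label2), ]
    out <- c(out, sprintf("%s %s %g %s_%d %s_%d", rr$kind,
                          fmt_target(rr$target), rr$sigma,
                          rr$label1, rr$residue, rr$label2, rr$residue))
  }
  cc <- plan$constraints
  if (nrow(cc) > 0) {
    cc <- cc[order(cc$kind, cc$label1, cc$residue1, cc$label2), ]
    for (k in seq_len(nrow(cc))) {
      a1 <- sprintf("%s_%d", cc$label1[k], cc$residue1[k])
      a2 <- sprintf("%s_%d", cc$label2[k], cc$residue2[k])
      out <- c(out, if (cc$kind[k] == "SIMU") {
        sprintf("SIMU %g %s %s", cc$sigma[k], a1, a2)
      } else {
        sprintf("%s %s %s", cc$kind[k], a1, a2)
      })
    }
  }
  if (!is.null(plan$sump)) out <- c(out, plan$sump)
  list(instructions = paste0(paste(out, collapse = "\n"), "\n"),
       main_stub = paste0("+", filename))
}

#' Parse a SHELXL instruction file back into a refinement plan
#'
#' Round-trip companion of [write_instruction_file()]: reads RESI scoping,
#' DFIX/DANG restraints and EADP/EXYZ/SIMU constraint records
#' (residue-qualified `name_resi` atom names override the current RESI
#' scope).
#'
#' @param text Instruction file content.
#' @return A [refinement_plan()] (strategy inferred: SIMU records present
#'   means `"restrained+SIMU"`, else `"restrained+EADP"`).
#' @export
parse_instruction_file <- function(text) {
  if (length(text) > 1) text <- paste(text, collapse = "\n")
  lines <- shelx_logical_lines(text)
  residue <- 0L
  restraints <- list(); constraints <- list(); sump <- NULL
  split_name <- function(tok, cur) {
    if (grepl("_[0-9]+$", tok)) {
      list(label = sub("_[0-9]+$", "", tok),
           residue = as.integer(sub("^.*_", "", tok)))
    } else {
      list(label = tok, residue = cur)
    }
  }
  for (ln in lines) {
    toks <- strsplit(ln, "[[:space:]]+")[[1]]
    card <- toupper(toks[1])
    if (card == "RESI") {
      residue <- as.integer(toks[2])
    } else if (card %in% c("DFIX", "DANG")) {
      a <- split_name(toks[4], residue); b <- split_name(toks[5], residue)
      restraints[[length(restraints) + 1L]] <- tibble::tibble(
        kind = card, target = as.numeric(toks[2]),
        sigma = as.numeric(toks[3]),
        label1 = a$label, label2 = b$label, residue = a$residue
      )
    } else if (card %in% c("EADP", "EXYZ")) {
      a <- split_name(toks[2], residue); b <- split_name(toks[3], residue)
      constraints[[length(constraints) + 1L]] <- tibble::tibble(
        kind = card, sigma = NA_real_,
        label1 = a$label, residue1 = a$residue,
        label2 = b$label, residue2 = b$residue, distance = NA_real_
      )
    } else if (card == "SIMU") {
      a <- split_name(toks[3], residue); b <- split_name(toks[4], residue)
      constraints[[length(constraints) + 1L]] <- tibble::tibble(
        kind = card, sigma = as.numeric(toks[2]),
        label1 = a$label, residue1 = a$residue,
        label2 = b$label, residue2 = b$residue, distance = NA_real_
      )
    } else if (card == "SUMP") {
      sump <- ln
    }
  }
  r <- dplyr::bind_rows(restraints)
  c_ <- dplyr::bind_rows(constraints)
  if (nrow(r)) class(r) <- c("restraint_set", class(r))
  if (nrow(c_)) class(c_) <- c("constraint_set", class(c_))
  refinement_plan(
    r, if (nrow(c_)) c_ else NULL,
    strategy = if (nrow(c_) && any(c_$kind == "SIMU")) "restrained+SIMU"
               else "restrained+EADP",
    sump = sump
  )
}

#' Count least-squares refinement parameters
#'
#' Counts under the standard small-molecule convention: 9 parameters per
#' anisotropic atom (3 positional + 6 Uij), 4 per isotropic atom
#' (3 positional + 1 U), plus 1 overall scale factor and 1 per independent
#' occupancy free variable. Each EADP group of g atoms removes
#' `(g - 1) * 6` parameters if anisotropic (else `(g - 1) * 1`); each EXYZ
#' group removes `(g - 1) * 3`. SIMU records are restraints and remove
#' nothing.
#'
#' @param model A recombined [crystal_structure()] with ADP declarations.
#' @param plan Optional [refinement_plan()] whose constraints reduce the
#'   count.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model, plan = NULL) {
  aniso <- site_is_aniso(model$sites)
  n <- sum(ifelse(aniso, 9L, 4L))
  n_occ_fv <- max(0L, length(model$fvar) - 1L)
  if (!is.null(model$metadata$sump)) n_occ_fv <- n_occ_fv - 1L
  n <- n + 1L + n_occ_fv
  if (!is.null(plan) && nrow(plan$constraints) > 0) {
    key <- paste(model$sites$label, model$sites$residue)
    for (kind in c("EADP", "EXYZ")) {
      cc <- plan$constraints[plan$constraints$kind == kind, ]
      if (nrow(cc) == 0) next
      nodes <- unique(c(paste(cc$label1, cc$residue1),
                        paste(cc$label2, cc$residue2)))
      g <- igraph::graph_from_data_frame(
        data.frame(from = paste(cc$label1, cc$residue1),
                   to = paste(cc$label2, cc$residue2)),
        directed = FALSE, vertices = nodes
      )
      memb <- igraph::components(g)$membership
      for (grp in split(names(memb), memb)) {
        if (length(grp) < 2) next
        if (kind == "EXYZ") {
          n <- n - (length(grp) - 1L) * 3L
        } else {
          idx <- match(grp[1], key)
          per <- if (!is.na(idx) && aniso[idx]) 6L else 1L
          n <- n - (length(grp) - 1L) * per
        }
      }
    }
  }
  as.integer(n)
}

#' Count restraints in a refinement plan
#'
#' @param plan A [refinement_plan()].
#' @return Integer: number of DFIX + DANG records (SIMU records, being
#'   restraints, are counted separately in `attr(, "simu")`).
#' @export
count_restraints <- function(plan) {
  n <- nrow(plan$restraints)
  structure(as.integer(n),
            simu = sum(plan$constraints$kind == "SIMU"))
}
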