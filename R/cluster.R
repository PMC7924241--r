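# Symmetry expansion of an ordered structure into a cluster of whole
# neighbour molecules around the asymmetric unit.
#
# An environment image is one molecular component mapped by one space-group
# operation plus one integer lattice translation. Images are generated
# unwrapped: the operation is applied to the component's unwrapped
# coordinates (periodic wrapping inside the parent model is resolved first
# by walking the bond graph and choosing minimum-image neighbours), so an
# image is always a connected whole molecule and the integer translation is
# canonical for that representative.

#' Build a molecular cluster around the asymmetric unit
#'
#' Expands all symmetry operation x lattice translation images of every
#' molecular component over a translation range wide enough to cover
#' `cutoff` plus the molecular diameter, and keeps an image iff any of its
#' atoms lies within `cutoff` of any ASU atom (any-atom criterion). The
#' identity image of the ASU itself is never part of the environment.
#'
#' @param structure An ordered [crystal_structure()] (one archetype).
#' @param asu_components Integer vector of molecule component ids that make
#'   up the central system (default: all components in the cell contents).
#' @param cutoff Any-atom selection distance in Angstrom (default 3.75).
#' @param graph Optional precomputed [structure_bond_graph()].
#' @return An object of class `cluster`: list with `cell`, `cutoff`,
#'   `asu` (site tibble with unwrapped fractional coordinates),
#'   `asu_cart` (n x 3 Cartesian matrix) and `environment`, a list of
#'   images each carrying `op` (operation index), `translation` (integer
#'   3-vector), `component`, `labels`, `elements` and `cart`.
#' @export
build_cluster <- function(structure, asu_components = NULL, cutoff = 3.75,
                          graph = NULL) {
  if (!is.numeric(cutoff) || cutoff <= 0) {
    stop("cutoff must be a positive distance in Angstrom", call. = FALSE)
  }
  s <- structure
  if (is.null(graph)) graph <- structure_bond_graph(s)
  comps <- molecule_components(graph)
  floaters <- lengths(comps) == 1 & length(comps) > 1
  if (any(floaters)) {
    # may be legitimate (an ion, a fully-occupied special-position solvent)
    # but often signals a connectivity problem; it is kept as its own molecule
    warning("unbonded single-atom molecule(s) in the cell contents: ",
            paste(s$sites$label[vapply(comps[floaters], min, integer(1))],
                  collapse = ", "),
            call. = FALSE)
  }
  if (is.null(asu_components)) asu_components <- seq_along(comps)

  frac <- frac_matrix(s$sites)
  unwrapped <- unwrap_components(frac, comps, graph)
  m_orth <- orthogonalization_matrix(s$cell)

  asu_idx <- sort(unlist(comps[asu_components]))
  asu_frac <- unwrapped[asu_idx, , drop = FALSE]
  asu_cart <- t(m_orth %*% t(asu_frac))
  asu_sites <- s$sites[asu_idx, ]
  asu_sites$x <- asu_frac[, 1]; asu_sites$y <- asu_frac[, 2]
  asu_sites$z <- asu_frac[, 3]

  # translation range guaranteeing coverage of cutoff + molecular diameter
  all_cart <- t(m_orth %*% t(unwrapped))
  diam <- 0
  for (cmp in comps) {
    if (length(cmp) > 1) {
      diam <- max(diam, max(stats::dist(all_cart[cmp, , drop = FALSE])))
    }
  }
  h <- cell_heights(s$cell)
  rng <- ceiling((cutoff + diam) / h) + 1

  environment <- list()
  grid <- expand.grid(
    tx = -rng[1]:rng[1], ty = -rng[2]:rng[2], tz = -rng[3]:rng[3]
  )
  for (oi in seq_along(s$operations)) {
    op <- s$operations[[oi]]
    op_is_id <- is_identity_op(op)
    for (ci in seq_along(comps)) {
      cmp <- comps[[ci]]
      rep_frac <- apply_symop(op, unwrapped[cmp, , drop = FALSE])
      rep_cart <- t(m_orth %*% t(rep_frac))
      for (g in seq_len(nrow(grid))) {
        tvec <- as.integer(grid[g, ])
        if (op_is_id && all(tvec == 0L) && ci %in% asu_components) next
        img_cart <- sweep(rep_cart, 2, drop(m_orth %*% tvec), `+`)
        if (min_pair_distance(img_cart, asu_cart) <= cutoff) {
          environment[[length(environment) + 1L]] <- list(
            op = oi, translation = tvec, component = ci,
            labels = s$sites$label[cmp], elements = s$sites$element[cmp],
            cart = img_cart
          )
        }
      }
    }
  }
  structure(
    list(cell = s$cell, cutoff = cutoff, asu = asu_sites,
         asu_cart = asu_cart, environment = environment),
    class = "cluster"
  )
}

#' @export
print.cluster <- function(x, ...) {
  n_env_atoms <- sum(vapply(x$environment, function(e) nrow(e$cart),
                            integer(1)))
  cat(sprintf(
    "<cluster> %d ASU atoms (free) + %d environment molecules / %d atoms (fixed), cutoff %.2f A\n",
    nrow(x$asu), length(x$environment), n_env_atoms, x$cutoff))
  invisible(x)
}

# smallest Cartesian distance between any atom of a and any atom of b
min_pair_distance <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

# resolve periodic wrapping: walk each component's bond graph from its
# lowest-index atom, placing every neighbour at its minimum-image position
# relative to the atom already placed
unwrap_components <- function(frac, comps, graph) {
  adj <- adjacency_list(graph)
  out <- frac
  for (cmp in comps) {
    root <- min(cmp)
    placed <- c(root)
    queue <- c(root)
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      for (j in adj[[i]]) {
        if (j %in% placed) next
        out[j, ] <- frac[j, ] + round(out[i, ] - frac[j, ])
        placed <- c(placed, j)
        queue <- c(queue, j)
      }
    }
  }
  out
}

#' Environment provenance table of a cluster
#'
#' @param cluster A [build_cluster()] result.
#' @return Tibble with one row per environment molecule: `op`, `tx`, `ty`,
#'   `tz`, `component`, `n_atoms`, `min_distance` (closest approach to the
#'   ASU in Angstrom).
#' @export
cluster_provenance <- function(cluster) {
  if (length(cluster$environment) == 0) {
    return(tibble::tibble(op = integer(), tx = integer(), ty = integer(),
                          tz = integer(), component = integer(),
                          n_atoms = integer(), min_distance = numeric()))
  }
  dplyr::bind_rows(lapply(cluster$environment, function(e) {
    tibble::tibble(
      op = e$op, tx = e$translation[1], ty = e$translation[2],
      tz = e$translation[3], component = e$component,
      n_atoms = nrow(e$cart),
      min_distance = min_pair_distance(e$cart, cluster$asu_cart)
    )
  }))
}
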