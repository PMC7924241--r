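# Independent brute-force oracles used to cross-check the implementation.

# connected components by plain breadth-first search over an edge list
bfs_components <- function(n, edges_i, edges_j) {
  adj <- vector("list", n)
  for (k in seq_along(edges_i)) {
    adj[[edges_i[k]]] <- c(adj[[edges_i[k]]], edges_j[k])
    adj[[edges_j[k]]] <- c(adj[[edges_j[k]]], edges_i[k])
  }
  seen <- rep(FALSE, n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    comp <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(vapply(comps, min, integer(1)))]
}

# all-pairs shortest path lengths by repeated BFS (for 1-2 / 1-3 counting)
bfs_path_lengths <- function(n, edges_i, edges_j) {
  adj <- vector("list", n)
  for (k in seq_along(edges_i)) {
    adj[[edges_i[k]]] <- c(adj[[edges_i[k]]], edges_j[k])
    adj[[edges_j[k]]] <- c(adj[[edges_j[k]]], edges_i[k])
  }
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.infinite(d[s, w])) {
          d[s, w] <- d[s, v] + 1
          queue <- c(queue, w)
        }
      }
    }
  }
  d
}

# brute-force cluster oracle: expand every operation x component over a
# fixed translation grid and apply the any-atom distance rule directly
brute_force_cluster_keys <- function(structure, asu_components = NULL,
                                     cutoff = 3.75, t_range = 3) {
  graph <- structure_bond_graph(structure)
  comps <- molecule_components(graph)
  if (is.null(asu_components)) asu_components <- seq_along(comps)
  frac <- as.matrix(structure$sites[, c("x", "y", "z")])
  m <- orthogonalization_matrix(structure$cell)
  asu_idx <- sort(unlist(comps[asu_components]))
  asu_cart <- t(m %*% t(frac[asu_idx, , drop = FALSE]))
  keys <- character(0)
  for (oi in seq_along(structure$operations)) {
    op <- structure$operations[[oi]]
    for (ci in seq_along(comps)) {
      base <- apply_symop(op, frac[comps[[ci]], , drop = FALSE])
      for (tx in -t_range:t_range) for (ty in -t_range:t_range)
        for (tz in -t_range:t_range) {
          if (oi == 1 && tx == 0 && ty == 0 && tz == 0 &&
              ci %in% asu_components) next
          img <- sweep(base, 2, c(tx, ty, tz), `+`)
          cart <- t(m %*% t(img))
          d2 <- outer(rowSums(cart^2), rowSums(asu_cart^2), `+`) -
            2 * cart %*% t(asu_cart)
          if (sqrt(max(0, min(d2))) <= cutoff) {
            keys <- c(keys, paste(oi, tx, ty, tz, ci))
          }
        }
    }
  }
  sort(keys)
}

cluster_keys <- function(cluster) {
  sort(vapply(cluster$environment, function(e) {
    paste(e$op, e$translation[1], e$translation[2], e$translation[3],
          e$component)
  }, character(1)))
}

# minimal CIF writer used to exercise the CIF parser against the SHELX route
structure_to_cif <- function(s) {
  ops <- vapply(s$operations, symop_to_string, character(1), style = "cif")
  sites <- s$sites
  dg <- ifelse(sites$part == 0L, ".", as.character(sites$part))
  c(
    "data_fixture",
    sprintf("_cell_length_a %.6f", s$cell$a),
    sprintf("_cell_length_b %.6f", s$cell$b),
    sprintf("_cell_length_c %.6f", s$cell$c),
    sprintf("_cell_angle_alpha %.6f", s$cell$alpha),
    sprintf("_cell_angle_beta %.6f", s$cell$beta),
    sprintf("_cell_angle_gamma %.6f", s$cell$gamma),
    "loop_",
    "_space_group_symop_operation_xyz",
    sprintf("'%s'", ops),
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "_atom_site_occupancy",
    "_atom_site_disorder_group",
    sprintf("%s %s %.6f %.6f %.6f %.4f %s", sites$label, sites$element,
            sites$x, sites$y, sites$z, sites$occupancy, dg)
  )
}

propionamide_model <- function(seed = 1L) {
  make_fixture(fixture_spec("propionamide-P21/c", seed = seed))
}
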