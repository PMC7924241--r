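# Bond perception and molecular connectivity.
#
# Bonds are perceived from geometry with the Cordero (2008) single-bond
# covalent radii and a fixed 0.40 A tolerance; this is the de-facto standard
# rule when a structure file carries no explicit connectivity. Perception is
# always run on one ordered geometry (a single archetype), never across
# disorder parts: alternative parts are alternative realities and must not
# be bonded to one another.

#' Covalent radii table
#'
#' Single-bond covalent radii (Angstrom) after Cordero et al. (2008),
#' Dalton Trans., 2832. For carbon the sp3 value is used; for Mn/Fe/Co the
#' high-spin value.
#'
#' @return Named numeric vector, names are element symbols. Deuterium is
#'   aliased to hydrogen.
#' @export
covalent_radii <- function() {
  c(
    H = 0.31, D = 0.31, He = 0.28,
    Li = 1.28, Be = 0.96, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
    Ne = 0.58,
    Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11, P = 1.07, S = 1.05,
    Cl = 1.02, Ar = 1.06,
    K = 2.03, Ca = 1.76, Sc = 1.70, Ti = 1.60, V = 1.53, Cr = 1.39,
    Mn = 1.61, Fe = 1.52, Co = 1.50, Ni = 1.24, Cu = 1.32, Zn = 1.22,
    Ga = 1.22, Ge = 1.20, As = 1.19, Se = 1.20, Br = 1.20, Kr = 1.16,
    Rb = 2.20, Sr = 1.95, Y = 1.90, Zr = 1.75, Nb = 1.64, Mo = 1.54,
    Tc = 1.47, Ru = 1.46, Rh = 1.42, Pd = 1.39, Ag = 1.45, Cd = 1.44,
    In = 1.42, Sn = 1.39, Sb = 1.39, Te = 1.38, I = 1.39, Xe = 1.40,
    Cs = 2.44, Ba = 2.15, La = 2.07, Ce = 2.04,
    W = 1.62, Re = 1.51, Os = 1.44, Ir = 1.41, Pt = 1.36, Au = 1.36,
    Hg = 1.32, Tl = 1.45, Pb = 1.46, Bi = 1.48
  )
}

#' Perceive covalent bonds from geometry
#'
#' Atoms i and j are bonded iff their Cartesian distance does not exceed
#' `r_cov(i) + r_cov(j) + tol`. A hydrogen may carry at most one bond: if
#' several candidates fall inside the tolerance only the shortest is kept.
#'
#' @param elements Character vector of element symbols.
#' @param cart n x 3 matrix of Cartesian coordinates (Angstrom).
#' @param tol Distance tolerance in Angstrom added to the radius sum.
#' @return A `bond_graph`: list with `n` (atom count), `elements`, `cart`,
#'   and `edges`, a tibble with columns `i`, `j` (`i < j`) and `distance`.
#' @examples
#' g <- perceive_bonds(c("C", "H"), rbind(c(0, 0, 0), c(1.09, 0, 0)))
#' g$edges
#' @export
perceive_bonds <- function(elements, cart, tol = 0.40) {
  elements <- normalize_element(elements)
  radii <- covalent_radii()
  unknown <- setdiff(unique(elements), names(radii))
  if (length(unknown)) {
    stop("no covalent radius for element(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cart <- as.matrix(cart)
  n <- length(elements)
  stopifnot(nrow(cart) == n, ncol(cart) == 3)
  r <- radii[elements]
  edges <- tibble::tibble(i = integer(), j = integer(), distance = numeric())
  if (n >= 2) {
    d <- as.matrix(stats::dist(cart))
    cut <- outer(r, r, `+`) + tol
    hit <- which(d <= cut & upper.tri(d), arr.ind = TRUE)
    # exclude fused atoms (numerically zero distance): not a chemical bond
    keep <- d[hit] > 1e-6
    hit <- hit[keep, , drop = FALSE]
    edges <- tibble::tibble(
      i = as.integer(hit[, 1]), j = as.integer(hit[, 2]),
      distance = d[hit]
    )
    edges <- edges[order(edges$i, edges$j), ]
    # enforce hydrogen degree <= 1, keeping the shortest contact
    for (h in which(is_hydrogen(elements))) {
      at <- which(edges$i == h | edges$j == h)
      if (length(at) > 1) {
        drop_idx <- at[-which.min(edges$distance[at])]
        edges <- edges[-drop_idx, ]
      }
    }
  }
  structure(list(n = n, elements = elements, cart = cart, edges = edges),
            class = "bond_graph")
}

#' Bond graph for one structure or archetype
#'
#' Convenience wrapper: perceives bonds on the Cartesian geometry of a
#' [crystal_structure()] (which should be ordered, i.e. one archetype).
#'
#' @param structure A [crystal_structure()].
#' @inheritParams perceive_bonds
#' @export
structure_bond_graph <- function(structure, tol = 0.40) {
  if (length(disorder_parts(structure)) > 1) {
    stop("bond perception runs on one archetype at a time; ",
         "split the disorder parts first", call. = FALSE)
  }
  perceive_bonds(structure$sites$element, site_cartesian(structure), tol)
}

#' @export
print.bond_graph <- function(x, ...) {
  cat(sprintf("<bond_graph> %d atoms, %d bonds, %d molecules\n",
              x$n, nrow(x$edges), length(molecule_components(x))))
  invisible(x)
}

#' Connected molecular components
#'
#' @param graph A `bond_graph` from [perceive_bonds()].
#' @return List of integer vectors (atom indices), each sorted; components
#'   ordered by their smallest member index.
#' @export
molecule_components <- function(graph) {
  if (graph$n == 0) return(list())
  g <- igraph::make_empty_graph(n = graph$n, directed = FALSE)
  if (nrow(graph$edges) > 0) {
    g <- igraph::add_edges(g, rbind(graph$edges$i, graph$edges$j))
  }
  memb <- igraph::components(g)$membership
  comps <- split(seq_len(graph$n), memb)
  comps <- lapply(comps, function(v) sort(as.integer(v)))
  comps <- comps[order(vapply(comps, min, integer(1)))]
  names(comps) <- NULL
  comps
}

adjacency_list <- function(graph) {
  adj <- vector("list", graph$n)
  for (k in seq_len(nrow(graph$edges))) {
    i <- graph$edges$i[k]; j <- graph$edges$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

#' Bonded (1-2) atom pairs
#'
#' @param graph A `bond_graph`.
#' @return Tibble with columns `i`, `j` (`i < j`) and `distance`.
#' @export
one_two_pairs <- function(graph) graph$edges

#' Angle-defining (1-3) atom pairs
#'
#' All unordered pairs sharing a bonded common neighbour that are not
#' themselves bonded (a pair in a three-membered ring is 1-2 only, so that
#' downstream DFIX/DANG targets never conflict).
#'
#' @param graph A `bond_graph`.
#' @return Tibble with columns `i`, `j` (`i < j`), `via` (the common
#'   neighbour of the first such path found) and `distance`.
#' @export
one_three_pairs <- function(graph) {
  adj <- adjacency_list(graph)
  bonded <- paste(graph$edges$i, graph$edges$j)
  seen <- character(0)
  out_i <- integer(0); out_j <- integer(0); out_via <- integer(0)
  for (j in seq_len(graph$n)) {
    nb <- adj[[j]]
    if (length(nb) < 2) next
    for (a in seq_len(length(nb) - 1)) for (b in (a + 1):length(nb)) {
      i <- min(nb[a], nb[b]); k <- max(nb[a], nb[b])
      key <- paste(i, k)
      if (key %in% bonded || key %in% seen) next
      seen <- c(seen, key)
      out_i <- c(out_i, i); out_j <- c(out_j, k); out_via <- c(out_via, j)
    }
  }
  ord <- order(out_i, out_j)
  d <- sqrt(rowSums((graph$cart[out_i, , drop = FALSE] -
                     graph$cart[out_j, , drop = FALSE])^2))
  tibble::tibble(i = out_i[ord], j = out_j[ord], via = out_via[ord],
                 distance = d[ord])
}
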