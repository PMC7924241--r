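# Cluster geometry export: TURBOMOLE coord files (Bohr) for the
# tight-binding optimizer, XYZ (Angstrom) for visual inspection.

#' CODATA Bohr radius in Angstrom
#' @export
BOHR_ANGSTROM <- 0.529177210903

#' Write a cluster as a TURBOMOLE coord file
#'
#' One line per atom, `x y z element`, coordinates in Bohr; environment
#' atoms carry the fixed-atom flag `f`. ASU atoms come first in site order,
#' then environment atoms in generation order; the block is delimited by
#' `$coord` and `$end`.
#'
#' @param cluster A [build_cluster()] result.
#' @return A single string.
#' @export
write_turbomole_coord <- function(cluster) {
  if (nrow(cluster$asu) == 0) stop("empty cluster", call. = FALSE)
  fmt <- function(cart, elements, fixed) {
    b <- cart / BOHR_ANGSTROM
    sprintf("%.8f %.8f %.8f %s%s", b[, 1], b[, 2], b[, 3],
            tolower(elements), if (fixed) " f" else "")
  }
  out <- c("$coord", fmt(cluster$asu_cart, cluster$asu$element, FALSE))
  for (e in cluster$environment) {
    out <- c(out, fmt(e$cart, e$elements, TRUE))
  }
  paste0(paste(c(out, "$end"), collapse = "\n"), "\n")
}

#' Control block fixing the environment atoms for the external optimizer
#'
#' Lists the 1-based indices of all fixed (environment) atoms in the order
#' they appear in the coord file, as an `$fix` block understood by xtb.
#'
#' @param cluster A [build_cluster()] result.
#' @return A single string, empty-environment clusters give a block fixing
#'   nothing.
#' @export
write_xtb_fix_block <- function(cluster) {
  n_free <- nrow(cluster$asu)
  n_env <- sum(vapply(cluster$environment, function(e) nrow(e$cart),
                      integer(1)))
  if (n_env == 0) return("$fix\n$end\n")
  sprintf("$fix\n atoms: %d-%d\n$end\n", n_free + 1, n_free + n_env)
}

#' Write Cartesian coordinates in XYZ format
#'
#' @param elements Character vector of element symbols.
#' @param cart n x 3 Cartesian matrix in Angstrom.
#' @param comment Second-line comment.
#' @return A single string.
#' @export
write_xyz <- function(elements, cart, comment = "") {
  cart <- as.matrix(cart)
  lines <- sprintf("%-2s %12.6f %12.6f %12.6f", elements,
                   cart[, 1], cart[, 2], cart[, 3])
  paste0(paste(c(length(elements), comment, lines), collapse = "\n"), "\n")
}

#' Write a structure's asymmetric unit as XYZ
#'
#' @param structure A [crystal_structure()].
#' @inheritParams write_xyz
#' @export
structure_to_xyz <- function(structure, comment = structure$title) {
  write_xyz(structure$sites$element, site_cartesian(structure), comment)
}
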