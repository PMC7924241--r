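#' Unit cell
#'
#' Constructs a unit cell from lengths (Angstrom) and angles (degrees).
#' The cell is experimental input throughout the pipeline: it is parsed,
#' used for coordinate transforms and symmetry expansion, and never refined.
#'
#' @param a,b,c Cell edge lengths in Angstrom. Must be positive.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return An object of class `unit_cell` with fields `a`, `b`, `c`,
#'   `alpha`, `beta`, `gamma`.
#' @examples
#' cell <- unit_cell(10, 10, 10, 90, 90, 90)
#' cell_volume(cell)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  len <- c(a = a, b = b, c = c)
  ang <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(len)) || any(len <= 0)) {
    stop("cell lengths must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180)) {
    stop("cell angles must lie in (0, 180) degrees", call. = FALSE)
  }
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180)
  metric <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (metric <= 0) {
    stop("cell angles are metrically impossible (non-positive volume)",
         call. = FALSE)
  }
  structure(
    list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma),
    class = "unit_cell"
  )
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf(
    "<unit_cell> a=%.4f b=%.4f c=%.4f alpha=%.3f beta=%.3f gamma=%.3f (V=%.3f A^3)\n",
    x$a, x$b, x$c, x$alpha, x$beta, x$gamma, cell_volume(x)
  ))
  invisible(x)
}

#' Cell volume from the standard metric formula
#'
#' @param cell A [unit_cell()].
#' @return Volume in cubic Angstrom.
#' @export
cell_volume <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  cell$a * cell$b * cell$c *
    sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
}

#' Orthogonalization matrix (fractional to Cartesian)
#'
#' Uses the common crystallographic convention: `a` along Cartesian x,
#' `b` in the x-y plane. Cartesian coordinates are `M %*% frac`.
#'
#' @param cell A [unit_cell()].
#' @return A 3x3 numeric matrix in Angstrom.
#' @export
orthogonalization_matrix <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  sg <- sin(cell$gamma * pi / 180)
  v <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  matrix(c(
    cell$a, cell$b * cg, cell$c * cb,
    0,      cell$b * sg, cell$c * (ca - cb * cg) / sg,
    0,      0,           cell$c * v / sg
  ), nrow = 3, byrow = TRUE)
}

#' Fractional to Cartesian coordinates
#'
#' @param cell A [unit_cell()].
#' @param frac Fractional coordinates: a length-3 vector or an n x 3 matrix.
#' @return Cartesian coordinates in Angstrom, same shape as `frac`.
#' @seealso [cart_to_frac()]
#' @export
frac_to_cart <- function(cell, frac) {
  m <- orthogonalization_matrix(cell)
  if (is.matrix(frac)) {
    t(m %*% t(frac))
  } else {
    drop(m %*% frac)
  }
}

#' Cartesian to fractional coordinates
#'
#' Inverse of [frac_to_cart()]; the round trip is exact to well below
#' 1e-10 Angstrom for any valid cell.
#'
#' @inheritParams frac_to_cart
#' @param cart Cartesian coordinates in Angstrom (length-3 vector or n x 3).
#' @export
cart_to_frac <- function(cell, cart) {
  mi <- solve(orthogonalization_matrix(cell))
  if (is.matrix(cart)) {
    t(mi %*% t(cart))
  } else {
    drop(mi %*% cart)
  }
}

# Perpendicular spacing between lattice planes normal to each cell axis,
# i.e. how far one unit translation moves a molecule at minimum. Used to
# bound the translation search when building clusters.
cell_heights <- function(cell) {
  mi <- solve(orthogonalization_matrix(cell))
  # row i of mi is the gradient of fractional coordinate i in Cartesian space;
  # plane spacing along axis i is 1 / |row_i|
  1 / sqrt(rowSums(mi^2))
}
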