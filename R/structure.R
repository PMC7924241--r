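#' Crystal structure container
#'
#' The parsed experimental model: a unit cell, the fully expanded list of
#' space-group symmetry operations, and an ordered table of atom sites
#' carrying the disorder bookkeeping (PART group, RESI residue, occupancy
#' and its free-variable coding, displacement parameters).
#'
#' Coordinates are fractional internally; Cartesian values are always
#' derived on demand via [frac_to_cart()].
#'
#' @param cell A [unit_cell()].
#' @param sites A data frame of atom sites; see [atom_sites()] for the
#'   column contract. Coerced through [atom_sites()].
#' @param symm List of [symop()] generators (the SYMM cards; identity
#'   implied).
#' @param latt SHELX LATT code; positive adds the inversion centre,
#'   `abs(latt)` selects centering (1 P, 2 I, 3 R, 4 F, 5 A, 6 B, 7 C).
#' @param fvar Numeric vector of free-variable values. Slot 1 is the
#'   overall scale factor by SHELX convention; occupancy codes refer to
#'   slots 2 and up.
#' @param title Optional title string.
#' @param metadata Optional named list (temperature, wavelength, ...).
#' @return An object of class `crystal_structure`.
#' @export
crystal_structure <- function(cell, sites, symm = list(), latt = -1L,
                              fvar = 1, title = "", metadata = list()) {
  stopifnot(inherits(cell, "unit_cell"))
  sites <- atom_sites(sites)
  key <- paste(sites$label, sites$residue)
  if (anyDuplicated(key)) {
    stop("duplicate (label, residue) pairs: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  ops <- expand_operations(symm, latt)
  structure(
    list(cell = cell, sites = sites, symm = symm, latt = as.integer(latt),
         operations = ops, fvar = as.numeric(fvar), title = title,
         metadata = metadata),
    class = "crystal_structure"
  )
}

#' Atom site table
#'
#' Validates and normalizes a table of atom sites into the tibble used
#' throughout the package, with columns:
#' \describe{
#'   \item{label}{atom name, unique within a residue}
#'   \item{element}{chemical symbol}
#'   \item{x, y, z}{fractional coordinates}
#'   \item{occupancy}{site occupancy in (0, 1]}
#'   \item{fv_ref}{occupancy free-variable index (`NA` = fixed); negative
#'     values encode the SHELX `1 - fv` complement coding}
#'   \item{part}{disorder group id (0 = shared atoms)}
#'   \item{residue}{residue id (RESI)}
#'   \item{u_iso}{isotropic U in A^2 (`NA` for anisotropic atoms)}
#'   \item{u11 ... u12}{anisotropic Uij in A^2, SHELX order
#'     (U11 U22 U33 U23 U13 U12); `NA` for isotropic atoms}
#' }
#'
#' @param df A data frame with at least `label`, `element`, `x`, `y`, `z`.
#' @return A tibble with the full column set, missing columns filled with
#'   defaults (occupancy 1, part 0, residue 0, u_iso 0.05).
#' @export
atom_sites <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("label", "element", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("atom site table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  defaults <- list(
    occupancy = 1, fv_ref = NA_integer_, part = 0L, residue = 0L,
    u_iso = 0.05, u11 = NA_real_, u22 = NA_real_, u33 = NA_real_,
    u23 = NA_real_, u13 = NA_real_, u12 = NA_real_
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(df)) df[[nm]] <- defaults[[nm]]
  }
  df$element <- normalize_element(df$element)
  unknown <- setdiff(unique(df$element), names(covalent_radii()))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$occupancy <= 0 | df$occupancy > 1 + 1e-9)) {
    stop("occupancies must lie in (0, 1]", call. = FALSE)
  }
  df$part <- as.integer(df$part)
  df$residue <- as.integer(df$residue)
  df$fv_ref <- as.integer(df$fv_ref)
  df[c(need, names(defaults))]
}

normalize_element <- function(el) {
  el <- as.character(el)
  paste0(toupper(substring(el, 1, 1)), tolower(substring(el, 2)))
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat(sprintf("<crystal_structure> %s\n", x$title))
  print(x$cell)
  cat(sprintf("  %d symmetry operations (LATT %d, %d SYMM cards)\n",
              length(x$operations), x$latt, length(x$symm)))
  cat(sprintf("  %d atom sites, disorder parts: %s\n", nrow(x$sites),
              paste(sort(unique(x$sites$part)), collapse = " ")))
  invisible(x)
}

#' Cartesian coordinates of a structure's sites
#'
#' @param structure A [crystal_structure()].
#' @return n x 3 matrix of Cartesian coordinates in Angstrom.
#' @export
site_cartesian <- function(structure) {
  frac_to_cart(structure$cell, frac_matrix(structure$sites))
}

frac_matrix <- function(sites) {
  m <- as.matrix(sites[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

is_hydrogen <- function(element) element %in% c("H", "D")

site_is_aniso <- function(sites) !is.na(sites$u11)

#' Disorder part ids present in a structure
#'
#' @param structure A [crystal_structure()].
#' @return Sorted integer vector of nonzero part ids (empty if ordered).
#' @export
disorder_parts <- function(structure) {
  sort(setdiff(unique(structure$sites$part), 0L))
}
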