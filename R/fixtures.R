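# Deterministic synthetic crystal structures. These stand in for deposited
# experimental structures so that every pipeline stage is testable offline:
# a monatomic P1 "crystal", a generic two/three-orientation disordered
# fragment in P-1, and a propionamide-like amide in P21/c whose two
# disorder parts are the up/down out-of-plane hydrogen conformers.

#' Fixture specification
#'
#' @param template One of `"monatomic-P1"`, `"propionamide-P21/c"`,
#'   `"two-part-generic"`.
#' @param cell Optional [unit_cell()] overriding the template default.
#' @param disorder `"none"`, `"two-part"` or `"three-part"`
#'   (default: the template's natural mode; `"three-part"` is only
#'   supported by the generic template).
#' @param perturbation Amplitude (Angstrom) of uniform random Cartesian
#'   noise added to every atom; 0 keeps the idealized geometry.
#' @param seed Random seed; fully determines the output.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(template = c("propionamide-P21/c", "monatomic-P1",
                                      "two-part-generic"),
                         cell = NULL, disorder = NULL, perturbation = 0,
                         seed = 1L) {
  template <- match.arg(template)
  if (is.null(disorder)) {
    disorder <- switch(template,
      "monatomic-P1" = "none",
      "propionamide-P21/c" = "two-part",
      "two-part-generic" = "two-part"
    )
  }
  disorder <- match.arg(disorder, c("none", "two-part", "three-part"))
  structure(list(template = template, cell = cell, disorder = disorder,
                 perturbation = perturbation, seed = as.integer(seed)),
            class = "fixture_spec")
}

unit3 <- function(v) v / sqrt(sum(v^2))

# idealized bond lengths used by the generator (Angstrom)
FIXTURE_BONDS <- c(CC = 1.52, CO = 1.23, CN = 1.33, CH = 1.09, NH = 1.01)

# propionamide-like CH3-CH2-C(=O)NH2 Cartesian geometry: heavy-atom skeleton
# planar in z = 0; hydrogens of one conformer puckered "up" (flip = +1) or
# "down" (flip = -1), with a small methyl torsion offset distinguishing the
# conformers beyond the mirror.
propionamide_conformer <- function(flip = 1) {
  b <- FIXTURE_BONDS
  C3 <- c(0, 0, 0)
  C2 <- c(-b["CC"], 0, 0)
  O1 <- b["CO"] * c(cos(pi / 3), sin(pi / 3), 0)
  N1 <- b["CN"] * c(cos(-pi / 3), sin(-pi / 3), 0)
  C1 <- C2 + b["CC"] * c(cos(111 * pi / 180), sin(111 * pi / 180), 0)

  heavy <- rbind(C1 = C1, C2 = C2, C3 = C3, O1 = O1, N1 = N1)

  # amide hydrogens: sp2 directions away from C3, puckered out of plane
  u <- unit3(C3 - N1)
  v <- c(-u[2], u[1], 0)
  pucker <- c(0, 0, flip * 0.20)
  HN <- lapply(list(+1, -1), function(s) {
    d <- -u * cos(pi / 3) + s * v * sin(pi / 3)
    N1 + b["NH"] * unit3(d + pucker)
  })

  # methylene hydrogens: perpendicular to the C1-C2-C3 plane
  bis <- -unit3(unit3(C1 - C2) + unit3(C3 - C2))
  w <- c(0, 0, 1)
  HC2 <- lapply(list(+1, -1), function(s) {
    C2 + b["CH"] * unit3(bis + s * 1.25 * w)
  })

  # methyl hydrogens: threefold about the C2->C1 axis, torsion offset
  # distinguishes the conformers
  a <- unit3(C1 - C2)
  p <- unit3(c(-a[2], a[1], 0))
  q <- pracma_cross(a, p)
  phi0 <- if (flip > 0) 0 else 40 * pi / 180
  HC1 <- lapply(0:2, function(k) {
    phi <- phi0 + flip * 2 * pi * k / 3
    d <- a * cos(70.53 * pi / 180) +
      sin(70.53 * pi / 180) * (p * cos(phi) + q * sin(phi))
    C1 + b["CH"] * d
  })

  list(heavy = heavy,
       hydrogens = do.call(rbind, c(HC1, HC2, HN)))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

aniso_u <- function(u = 0.02) {
  list(u11 = u, u22 = u, u33 = u, u23 = 0, u13 = 0, u12 = 0)
}

#' Generate a synthetic crystal structure
#'
#' @param spec A [fixture_spec()].
#' @return A [crystal_structure()]. The same spec (same seed) always yields
#'   a byte-identical [write_shelx()] round trip.
#' @examples
#' make_fixture(fixture_spec("propionamide-P21/c"))
#' @export
make_fixture <- function(spec = fixture_spec()) {
  if (!inherits(spec, "fixture_spec")) stop("need a fixture_spec()",
                                            call. = FALSE)
  rng <- local({
    set.seed(spec$seed)
    function(n) stats::runif(n, -spec$perturbation, spec$perturbation)
  })
  switch(spec$template,
    "monatomic-P1" = fixture_monatomic(spec, rng),
    "propionamide-P21/c" = fixture_propionamide(spec, rng),
    "two-part-generic" = fixture_generic(spec, rng),
    stop("unknown fixture template: ", spec$template, call. = FALSE)
  )
}

fixture_monatomic <- function(spec, rng) {
  cell <- spec$cell %||% unit_cell(10, 10, 10, 90, 90, 90)
  frac <- c(0, 0, 0) + cart_to_frac(cell, rng(3))
  sites <- tibble::tibble(
    label = "AR1", element = "Ar",
    x = frac[1], y = frac[2], z = frac[3],
    occupancy = 1, u_iso = 0.03
  )
  crystal_structure(cell, sites, symm = list(), latt = -1L,
                    title = "monatomic P1 fixture", fvar = 1)
}

fixture_propionamide <- function(spec, rng) {
  cell <- spec$cell %||% unit_cell(5.9, 5.7, 9.7, 90, 98, 90)
  # P21/c: 2_1 screw along b plus inversion (LATT 1)
  symm <- list(parse_symop_string("-X, 1/2+Y, 1/2-Z"))
  up <- propionamide_conformer(+1)
  heavy_cart <- up$heavy + matrix(rng(15), 5, 3)
  place <- function(cart) {
    fr <- cart_to_frac(cell, cart)
    sweep(fr, 2, c(0.20, 0.15, 0.10), `+`)
  }
  heavy_frac <- place(heavy_cart)
  heavy <- tibble::tibble(
    label = c("C1", "C2", "C3", "O1", "N1"),
    element = c("C", "C", "C", "O", "N"),
    x = heavy_frac[, 1], y = heavy_frac[, 2], z = heavy_frac[, 3],
    occupancy = 1, part = 0L, u_iso = NA_real_,
    u11 = 0.02, u22 = 0.02, u33 = 0.02, u23 = 0, u13 = 0, u12 = 0
  )
  if (spec$disorder == "none") {
    h_frac <- place(up$hydrogens + matrix(rng(21), 7, 3))
    hyd <- tibble::tibble(
      label = c("H11", "H12", "H13", "H21", "H22", "H31", "H32"),
      element = "H",
      x = h_frac[, 1], y = h_frac[, 2], z = h_frac[, 3],
      occupancy = 1, part = 0L, u_iso = 0.03
    )
    return(crystal_structure(cell, dplyr::bind_rows(heavy, hyd), symm = symm,
                             latt = 1L, fvar = 1,
                             title = "propionamide fixture (ordered)",
                             metadata = list(temperature_c = -173)))
  }
  if (spec$disorder != "two-part") {
    stop("the propionamide template supports disorder 'none' or 'two-part'",
         call. = FALSE)
  }
  down <- propionamide_conformer(-1)
  h_up <- place(up$hydrogens + matrix(rng(21), 7, 3))
  h_down <- place(down$hydrogens + matrix(rng(21), 7, 3))
  hyd <- function(frac, labels, part, fv_ref) {
    tibble::tibble(
      label = labels, element = "H",
      x = frac[, 1], y = frac[, 2], z = frac[, 3],
      occupancy = 0.5, fv_ref = fv_ref, part = part, u_iso = 0.03
    )
  }
  sites <- dplyr::bind_rows(
    heavy,
    hyd(h_up, c("H11", "H12", "H13", "H21", "H22", "H31", "H32"), 1L, 2L),
    hyd(h_down, c("H41", "H42", "H43", "H51", "H52", "H61", "H62"), 2L, -2L)
  )
  crystal_structure(cell, sites, symm = symm, latt = 1L, fvar = c(1, 0.5),
                    title = "propionamide fixture (two-part H disorder)",
                    metadata = list(temperature_c = -173))
}

fixture_generic <- function(spec, rng) {
  cell <- spec$cell %||% unit_cell(7, 8, 9, 85, 95, 100)
  n_parts <- switch(spec$disorder, "none" = 0L, "two-part" = 2L,
                    "three-part" = 3L)
  base <- c(0, 0, 0)
  shared <- tibble::tibble(
    label = "C1", element = "C", x = 0, y = 0, z = 0,
    occupancy = 1, part = 0L, u_iso = NA_real_,
    u11 = 0.025, u22 = 0.025, u33 = 0.025, u23 = 0, u13 = 0, u12 = 0
  )
  offset <- c(0.25, 0.30, 0.20)
  place <- function(cart) {
    fr <- cart_to_frac(cell, matrix(cart, ncol = 3))
    sweep(fr, 2, offset, `+`)
  }
  sf <- place(base + rng(3))
  shared$x <- sf[1]; shared$y <- sf[2]; shared$z <- sf[3]
  if (n_parts == 0L) {
    of <- place(c(FIXTURE_BONDS["CO"], 0, 0) + rng(3))
    o <- tibble::tibble(label = "O1", element = "O", x = of[1], y = of[2],
                        z = of[3], occupancy = 1, part = 0L, u_iso = 0.03)
    return(crystal_structure(cell, dplyr::bind_rows(shared, o), symm = list(),
                             latt = 1L, fvar = 1,
                             title = "generic ordered fixture"))
  }
  occ <- rep(1 / n_parts, n_parts)
  parts <- lapply(seq_len(n_parts), function(p) {
    ang <- (p - 1) * 25 * pi / 180
    cart <- FIXTURE_BONDS["CO"] * c(cos(ang), sin(ang), 0.1 * (p - 1)) + rng(3)
    fr <- place(cart)
    fv <- if (n_parts == 2L) c(2L, -2L)[p] else NA_integer_
    tibble::tibble(label = sprintf("O%d", p), element = "O",
                   x = fr[1], y = fr[2], z = fr[3],
                   occupancy = occ[p], fv_ref = fv, part = p, u_iso = 0.03)
  })
  fvar <- if (n_parts == 2L) c(1, 0.5) else 1
  crystal_structure(cell, dplyr::bind_rows(c(list(shared), parts)),
                    symm = list(), latt = 1L, fvar = fvar,
                    title = sprintf("generic %d-part fixture", n_parts))
}
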