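# Space-group symmetry operations.
#
# An operation maps fractional coordinates x to R %*% x + t. Rotation parts
# have integer entries in {-1, 0, 1}; translation parts are exact rational
# fractions stored as integer twelfths so that composition and deduplication
# never suffer float drift (all standard space-group translations are
# multiples of 1/12).

TWELFTHS <- 12L

#' Symmetry operation
#'
#' @param rotation Integer 3x3 matrix with entries in -1, 0, 1 and
#'   determinant +/-1.
#' @param translation Length-3 translation. Either numeric fractions
#'   (rounded to the nearest twelfth) or integer twelfths if
#'   `twelfths = TRUE`. Reduced mod 1 into [0, 1).
#' @param twelfths Interpret `translation` as integer twelfths.
#' @return An object of class `symop` with fields `rotation` (integer
#'   matrix) and `translation_12` (integer twelfths in [0, 12)).
#' @examples
#' symop(diag(c(-1, 1, -1)), c(0, 0.5, 0))   # 2-fold screw component
#' @export
symop <- function(rotation, translation = c(0, 0, 0), twelfths = FALSE) {
  rot <- matrix(as.integer(round(rotation)), 3, 3)
  if (any(abs(rotation - rot) > 1e-9) || any(abs(rot) > 1L)) {
    stop("rotation entries must be -1, 0 or 1", call. = FALSE)
  }
  d <- round(det(rot))
  if (!d %in% c(-1, 1)) {
    stop("rotation determinant must be +1 or -1", call. = FALSE)
  }
  if (twelfths) {
    t12 <- as.integer(round(translation))
  } else {
    t12 <- as.integer(round(translation * TWELFTHS))
    if (any(abs(translation * TWELFTHS - t12) > 1e-6)) {
      stop("translation components must be multiples of 1/12", call. = FALSE)
    }
  }
  t12 <- ((t12 %% TWELFTHS) + TWELFTHS) %% TWELFTHS
  structure(list(rotation = rot, translation_12 = t12), class = "symop")
}

#' @export
print.symop <- function(x, ...) {
  cat("<symop>", symop_to_string(x), "\n")
  invisible(x)
}

symop_translation <- function(op) op$translation_12 / TWELFTHS

symop_identity <- function() symop(diag(3))

is_identity_op <- function(op) {
  all(op$rotation == diag(3)) && all(op$translation_12 == 0L)
}

#' Apply a symmetry operation to fractional coordinates
#'
#' @param op A [symop()].
#' @param frac Length-3 fractional vector or n x 3 matrix.
#' @return Transformed fractional coordinates (not wrapped into the cell).
#' @export
apply_symop <- function(op, frac) {
  tr <- symop_translation(op)
  if (is.matrix(frac)) {
    sweep(frac %*% t(op$rotation), 2, tr, `+`)
  } else {
    drop(op$rotation %*% frac) + tr
  }
}

#' Compose two symmetry operations
#'
#' `compose_symops(a, b)` returns the operation equivalent to applying `b`
#' first, then `a`; the translation is reduced mod 1.
#'
#' @param a,b [symop()] objects.
#' @export
compose_symops <- function(a, b) {
  rot <- a$rotation %*% b$rotation
  t12 <- a$rotation %*% b$translation_12 + a$translation_12
  symop(rot, as.integer(round(t12)), twelfths = TRUE)
}

symop_key <- function(op) {
  paste(c(op$rotation, op$translation_12), collapse = ",")
}

dedup_symops <- function(ops) {
  keys <- vapply(ops, symop_key, character(1))
  ops[!duplicated(keys)]
}

#' Parse a symmetry operator string
#'
#' Accepts the xyz notation used on SHELX `SYMM` cards and in CIF
#' `_symmetry_equiv_pos_as_xyz` loops, e.g. `"-X, 1/2+Y, -Z"` or
#' `"x, -y+1/2, z+1/2"`. Case-insensitive; fractions may be `p/q` or
#' decimals that are multiples of 1/12.
#'
#' @param text Operator string with three comma-separated components.
#' @return A [symop()].
#' @examples
#' parse_symop_string("-X, 1/2+Y, -Z")
#' @export
parse_symop_string <- function(text) {
  parts <- strsplit(text, ",", fixed = TRUE)[[1]]
  if (length(parts) != 3) {
    stop(sprintf("malformed symmetry operator '%s': need 3 components", text),
         call. = FALSE)
  }
  rot <- matrix(0L, 3, 3)
  t12 <- integer(3)
  for (i in 1:3) {
    comp <- gsub("[[:space:]]", "", tolower(parts[i]))
    if (!nzchar(comp)) {
      stop(sprintf("malformed symmetry operator '%s': empty component", text),
           call. = FALSE)
    }
    # tokenize into signed terms
    terms <- regmatches(comp, gregexpr("[+-]?[^+-]+", comp))[[1]]
    for (term in terms) {
      sign <- 1L
      body <- term
      if (startsWith(term, "+")) body <- substring(term, 2)
      if (startsWith(term, "-")) { sign <- -1L; body <- substring(term, 2) }
      if (body %in% c("x", "y", "z")) {
        j <- match(body, c("x", "y", "z"))
        rot[i, j] <- rot[i, j] + sign
      } else if (grepl("^[0-9]+/[0-9]+$", body)) {
        pq <- as.numeric(strsplit(body, "/", fixed = TRUE)[[1]])
        val <- 12 * pq[1] / pq[2]
        if (abs(val - round(val)) > 1e-6) {
          stop(sprintf("translation %s in '%s' is not a multiple of 1/12",
                       body, text), call. = FALSE)
        }
        t12[i] <- t12[i] + sign * as.integer(round(val))
      } else if (grepl("^[0-9.]+$", body)) {
        val <- 12 * as.numeric(body)
        if (abs(val - round(val)) > 1e-6) {
          stop(sprintf("translation %s in '%s' is not a multiple of 1/12",
                       body, text), call. = FALSE)
        }
        t12[i] <- t12[i] + sign * as.integer(round(val))
      } else {
        stop(sprintf("cannot parse term '%s' in symmetry operator '%s'",
                     term, text), call. = FALSE)
      }
    }
  }
  symop(rot, t12, twelfths = TRUE)
}

#' Format a symmetry operation as an xyz string
#'
#' @param op A [symop()].
#' @param style `"shelx"` (upper case, `1/2+Y`) or `"cif"` (lower case,
#'   `y+1/2`).
#' @export
symop_to_string <- function(op, style = c("shelx", "cif")) {
  style <- match.arg(style)
  axes <- if (style == "shelx") c("X", "Y", "Z") else c("x", "y", "z")
  comps <- character(3)
  for (i in 1:3) {
    s <- ""
    for (j in 1:3) {
      r <- op$rotation[i, j]
      if (r == 1L) s <- paste0(s, if (nzchar(s)) "+" else "", axes[j])
      if (r == -1L) s <- paste0(s, "-", axes[j])
    }
    t12 <- op$translation_12[i]
    if (t12 != 0L) {
      g <- gcd_int(t12, TWELFTHS)
      fr <- sprintf("%d/%d", t12 %/% g, TWELFTHS %/% g)
      s <- if (style == "shelx") paste0(fr, "+", s) else paste0(s, "+", fr)
    }
    if (!nzchar(s)) s <- "0"
    comps[i] <- s
  }
  paste(comps, collapse = ", ")
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

# SHELX LATT centering vectors, in twelfths.
latt_centering_12 <- function(latt_code) {
  code <- abs(latt_code)
  half <- 6L
  third <- 4L
  vecs <- switch(as.character(code),
    "1" = list(),                                            # P
    "2" = list(c(half, half, half)),                         # I
    "3" = list(c(8L, 4L, 4L), c(4L, 8L, 8L)),                # R (obverse)
    "4" = list(c(0L, half, half), c(half, 0L, half),
               c(half, half, 0L)),                           # F
    "5" = list(c(0L, half, half)),                           # A
    "6" = list(c(half, 0L, half)),                           # B
    "7" = list(c(half, half, 0L)),                           # C
    stop(sprintf("unknown LATT code %d", latt_code), call. = FALSE)
  )
  vecs
}

#' Expand a generator set to the full list of symmetry operations
#'
#' Follows the SHELX convention: the generators are the identity plus the
#' `SYMM` operators; a positive `LATT` code adds the inversion centre; the
#' absolute code value selects lattice centering (1 P, 2 I, 3 R, 4 F,
#' 5 A, 6 B, 7 C), whose translations are composed onto every operator.
#' The result is closed under composition for any valid space group.
#'
#' @param generators List of [symop()] (the `SYMM` cards; identity optional).
#' @param latt SHELX LATT code (default 1, primitive centrosymmetric;
#'   negative means non-centrosymmetric).
#' @return List of [symop()] with the identity first, no duplicates.
#' @export
expand_operations <- function(generators, latt = 1L) {
  ops <- c(list(symop_identity()), generators)
  # close under composition of the generator set (point ops + translations)
  repeat {
    keys <- vapply(ops, symop_key, character(1))
    new_ops <- list()
    for (a in ops) for (b in ops) {
      ab <- compose_symops(a, b)
      if (!symop_key(ab) %in% keys) {
        new_ops[[length(new_ops) + 1L]] <- ab
        keys <- c(keys, symop_key(ab))
      }
    }
    if (length(new_ops) == 0) break
    ops <- c(ops, new_ops)
    if (length(ops) > 192) {
      stop("symmetry generator set does not close (more than 192 operations)",
           call. = FALSE)
    }
  }
  if (latt > 0) {
    inv <- symop(-diag(3))
    ops <- c(ops, lapply(ops, function(o) compose_symops(inv, o)))
  }
  for (cv in latt_centering_12(latt)) {
    shift <- symop(diag(3), cv, twelfths = TRUE)
    ops <- c(ops, lapply(ops, function(o) compose_symops(shift, o)))
  }
  ops <- dedup_symops(ops)
  # identity first, stable order otherwise
  idx <- which(vapply(ops, is_identity_op, logical(1)))
  c(ops[idx], ops[-idx])
}
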