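# SHELX .ins/.res reading and writing.
#
# The dialect follows SHELXL-2018 semantics: |LATT| selects centering
# (P/I/R/F/A/B/C), a positive LATT adds the inversion centre, SYMM cards are
# generators, and site occupancy factors carry free-variable codes
# (10*m + p refers to free variable m with multiplier p; m = 1 means the
# value is fixed; a negative code means p*(1 - fv_m)).

SHELX_COMMANDS <- c(
  "TITL", "CELL", "ZERR", "LATT", "SYMM", "SFAC", "UNIT", "TEMP", "SIZE",
  "FVAR", "PART", "RESI", "L.S.", "CGLS", "PLAN", "BOND", "CONF", "LIST",
  "ACTA", "WGHT", "FMAP", "HKLF", "END", "MORE", "TIME", "OMIT", "SHEL",
  "BASF", "TWIN", "EXTI", "SWAT", "MERG", "EADP", "EXYZ", "DFIX", "DANG",
  "SADI", "SAME", "CHIV", "FLAT", "DELU", "SIMU", "RIGU", "ISOR", "NCSY",
  "SUMP", "BLOC", "DAMP", "STIR", "WPDB", "BIND", "FRAG", "FEND", "SPEC",
  "MOVE", "ANIS", "AFIX", "HFIX", "MPLA", "RTAB", "HTAB", "EQIV", "XNPD",
  "ABIN", "ANSC", "ANSR", "LAUE", "REM", "GRID", "MOLE", "EOF"
)

# join "=" continuation lines and drop blank/REM lines
shelx_logical_lines <- function(text) {
  raw <- strsplit(text, "\r?\n")[[1]]
  out <- character(0)
  buf <- NULL
  for (ln in raw) {
    ln <- sub("!.*$", "", ln)
    piece <- ln
    if (!is.null(buf)) {
      out_line <- paste(buf, piece)
      buf <- NULL
      ln <- out_line
    }
    trimmed <- trimws(ln)
    if (grepl("=\\s*$", trimmed)) {
      buf <- sub("=\\s*$", "", trimmed)
      next
    }
    if (nzchar(trimmed)) out <- c(out, trimmed)
  }
  if (!is.null(buf)) out <- c(out, buf)
  out[!grepl("^REM\\b", out, ignore.case = TRUE)]
}

# decode a SHELX parameter that may carry the +10 "fixed" offset
shelx_unfix <- function(v) {
  ifelse(v > 5, v - 10, ifelse(v < -5, v + 10, v))
}

decode_sof <- function(code, fvar) {
  if (abs(code) < 5) {
    return(list(occupancy = code, fv_ref = NA_integer_))
  }
  m <- floor(abs(code) / 10)
  p <- abs(code) - 10 * m
  if (m == 1) {
    return(list(occupancy = p, fv_ref = NA_integer_))
  }
  if (m > length(fvar)) {
    stop(sprintf("occupancy code %.4f refers to free variable %d but only %d FVAR value(s) given",
                 code, m, length(fvar)), call. = FALSE)
  }
  if (code > 0) {
    list(occupancy = p * fvar[m], fv_ref = as.integer(m))
  } else {
    list(occupancy = p * (1 - fvar[m]), fv_ref = as.integer(-m))
  }
}

encode_sof <- function(occupancy, fv_ref, fvar) {
  if (is.na(fv_ref)) {
    return(10 + occupancy)
  }
  m <- abs(fv_ref)
  if (m > length(fvar)) {
    stop(sprintf("site refers to free variable %d but FVAR has only %d slot(s)",
                 m, length(fvar)), call. = FALSE)
  }
  denom <- if (fv_ref > 0) fvar[m] else 1 - fvar[m]
  p <- occupancy / denom
  sign(fv_ref) * (10 * m + p)
}

#' Parse a SHELX ins/res file
#'
#' Reads CELL/LATT/SYMM/SFAC/UNIT/FVAR/PART/RESI and atom records into a
#' [crystal_structure()]. Symmetry operations are fully expanded following
#' the LATT conventions; occupancy free-variable codes are decoded into
#' numeric occupancies plus a `fv_ref` bookkeeping column so that
#' [write_shelx()] can reproduce the original coding.
#'
#' @param text SHELX file content (single string or character vector of
#'   lines).
#' @return A [crystal_structure()].
#' @examples
#' ins <- write_shelx(make_fixture(fixture_spec("monatomic-P1")))
#' parse_shelx(ins)
#' @export
parse_shelx <- function(text) {
  if (length(text) > 1) text <- paste(text, collapse = "\n")
  lines <- shelx_logical_lines(text)

  cell <- NULL; latt <- 1L; symm <- list(); sfac <- character(0)
  fvar <- 1; title <- ""; metadata <- list()
  part <- 0L; residue <- 0L
  fvar_seen <- FALSE
  sites <- list()
  sof_codes <- numeric(0)

  for (ln in lines) {
    toks <- strsplit(ln, "[[:space:]]+")[[1]]
    card <- toupper(substr(toks[1], 1, 4))
    if (card == "TITL") {
      title <- trimws(sub("^\\S+\\s*", "", ln))
    } else if (card == "CELL") {
      v <- as.numeric(toks[2:8])
      metadata$wavelength <- v[1]
      cell <- unit_cell(v[2], v[3], v[4], v[5], v[6], v[7])
    } else if (card == "LATT") {
      latt <- as.integer(toks[2])
    } else if (card == "SYMM") {
      opstr <- trimws(sub("^\\S+\\s*", "", ln))
      op <- tryCatch(parse_symop_string(opstr), error = function(e) {
        stop(sprintf("cannot parse SYMM card '%s': %s", ln, conditionMessage(e)),
             call. = FALSE)
      })
      symm <- c(symm, list(op))
    } else if (card == "SFAC") {
      rest <- toks[-1]
      if (length(rest) > 1 && !is.na(suppressWarnings(as.numeric(rest[2])))) {
        sfac <- c(sfac, rest[1])   # long-form SFAC: element then coefficients
      } else {
        sfac <- c(sfac, rest)
      }
    } else if (card == "FVAR") {
      v <- as.numeric(toks[-1])
      fvar <- if (fvar_seen) c(fvar, v) else v
      fvar_seen <- TRUE
    } else if (card == "TEMP") {
      metadata$temperature_c <- as.numeric(toks[2])
    } else if (card == "PART") {
      part <- as.integer(toks[2])
    } else if (card == "RESI") {
      residue <- as.integer(toks[2])
    } else if (card %in% c("HKLF", "END")) {
      break
    } else if (card %in% SHELX_COMMANDS) {
      # bookkeeping or refinement card not modelled here
    } else if (length(toks) >= 5 &&
               !anyNA(suppressWarnings(as.numeric(toks[2:5])))) {
      # atom record: label sfac# x y z [sof [U...]]
      v <- suppressWarnings(as.numeric(toks[-1]))
      isf <- as.integer(v[1])
      if (isf < 1 || isf > length(sfac)) {
        stop(sprintf("atom '%s' refers to SFAC entry %d but SFAC lists %d element(s)",
                     toks[1], isf, length(sfac)), call. = FALSE)
      }
      xyz <- shelx_unfix(v[2:4])
      sof_code <- if (length(v) >= 5) v[5] else 11
      occ <- decode_sof(sof_code, fvar)
      u <- v[-(1:5)]
      site <- list(
        label = toks[1], element = sfac[isf],
        x = xyz[1], y = xyz[2], z = xyz[3],
        occupancy = occ$occupancy, fv_ref = occ$fv_ref,
        part = part, residue = residue,
        u_iso = NA_real_, u11 = NA_real_, u22 = NA_real_, u33 = NA_real_,
        u23 = NA_real_, u13 = NA_real_, u12 = NA_real_
      )
      if (length(u) >= 6) {
        site[c("u11", "u22", "u33", "u23", "u13", "u12")] <- as.list(u[1:6])
      } else if (length(u) >= 1) {
        site$u_iso <- u[1]
      } else {
        site$u_iso <- 0.05
      }
      sites[[length(sites) + 1L]] <- site
      sof_codes <- c(sof_codes, sof_code)
    }
  }
  if (is.null(cell)) stop("SHELX input has no CELL card", call. = FALSE)
  if (length(sites) == 0) stop("SHELX input has no atom records", call. = FALSE)
  df <- dplyr::bind_rows(lapply(sites, tibble::as_tibble))
  crystal_structure(cell, df, symm = symm, latt = latt, fvar = fvar,
                    title = title, metadata = metadata)
}

#' Write a crystal structure as a SHELX ins file
#'
#' Emits CELL/ZERR/LATT/SYMM/SFAC/UNIT/FVAR and atom records, reproducing
#' PART/RESI scoping and occupancy free-variable codes, so that
#' `parse_shelx(write_shelx(m))` equals `m` up to numeric formatting
#' (coordinates to 6 decimals).
#'
#' @param structure A [crystal_structure()].
#' @param wavelength X-ray wavelength for the CELL card (default: the
#'   parsed value, else Mo K-alpha 0.71073).
#' @param extra Character vector of extra instruction lines inserted before
#'   the atom list (e.g. a `+restraints.ins` include stub).
#' @return A single string of SHELX content.
#' @export
write_shelx <- function(structure, wavelength = NULL, extra = character(0)) {
  s <- structure
  if (is.null(wavelength)) {
    wavelength <- s$metadata$wavelength %||% 0.71073
  }
  m <- max(c(0L, abs(s$sites$fv_ref)), na.rm = TRUE)
  if (m > length(s$fvar)) {
    stop(sprintf("sites reference free variable %d but FVAR has only %d slot(s)",
                 m, length(s$fvar)), call. = FALSE)
  }
  sfac <- unique(s$sites$element)
  counts <- table(factor(s$sites$element, levels = sfac))
  out <- c(
    paste("TITL", s$title),
    sprintf("CELL %.5f %.5f %.5f %.5f %.4f %.4f %.4f", wavelength,
            s$cell$a, s$cell$b, s$cell$c, s$cell$alpha, s$cell$beta,
            s$cell$gamma),
    "ZERR 1 0 0 0 0 0 0",
    sprintf("LATT %d", s$latt),
    vapply(s$symm, function(op) paste("SYMM", symop_to_string(op)),
           character(1)),
    paste("SFAC", paste(toupper(sfac), collapse = " ")),
    paste("UNIT", paste(as.integer(counts), collapse = " "))
  )
  if (!is.null(s$metadata$temperature_c)) {
    out <- c(out, sprintf("TEMP %g", s$metadata$temperature_c))
  }
  out <- c(out, paste("FVAR", paste(sprintf("%.5f", s$fvar), collapse = " ")))
  out <- c(out, extra)
  part <- 0L; residue <- 0L
  for (k in seq_len(nrow(s$sites))) {
    st <- s$sites[k, ]
    if (st$residue != residue) {
      out <- c(out, sprintf("RESI %d", st$residue))
      residue <- st$residue
    }
    if (st$part != part) {
      out <- c(out, sprintf("PART %d", st$part))
      part <- st$part
    }
    sof <- encode_sof(st$occupancy, st$fv_ref, s$fvar)
    head <- sprintf("%-5s %d %10.6f %10.6f %10.6f %9.5f", st$label,
                    match(st$element, sfac), st$x, st$y, st$z, sof)
    if (!is.na(st$u11)) {
      out <- c(out, paste0(head, sprintf(" %8.5f %8.5f =", st$u11, st$u22)),
               sprintf("  %8.5f %8.5f %8.5f %8.5f", st$u33, st$u23, st$u13,
                       st$u12))
    } else {
      out <- c(out, paste0(head, sprintf(" %8.5f", st$u_iso)))
    }
  }
  if (part != 0L) out <- c(out, "PART 0")
  out <- c(out, "HKLF 4", "END")
  paste0(paste(out, collapse = "\n"), "\n")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
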