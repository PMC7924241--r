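# Minimal core-dialect CIF reader: cell parameters, symmetry operator loop
# and the atom_site loop, which is what CSD-style small-molecule CIFs carry.
# PART information survives CIF deposition only as _atom_site_disorder_group,
# which is mapped back onto the part column; RESI scoping is not representable
# in the current CIF standard and comes back as residue 0.

cif_strip_su <- function(x) as.numeric(sub("\\(.*\\)", "", x))

# split a CIF data line into tokens, honouring single/double quotes
cif_tokens <- function(line) {
  toks <- regmatches(line,
    gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line))[[1]]
  gsub("^['\"]|['\"]$", "", toks)
}

#' Parse a crystallographic CIF file
#'
#' Supports the core small-molecule dialect: `_cell_*` items,
#' a `_symmetry_equiv_pos_as_xyz` / `_space_group_symop_operation_xyz`
#' loop, and the `_atom_site_*` loop. `_atom_site_disorder_group` values
#' map onto disorder parts (`.` means 0, i.e. shared atoms); missing
#' occupancies default to 1. Only the first data block of a multi-block
#' file is read (with a warning).
#'
#' @param text CIF content (single string or character vector of lines).
#' @return A [crystal_structure()].
#' @export
parse_cif <- function(text) {
  if (length(text) > 1) text <- paste(text, collapse = "\n")
  lines <- strsplit(text, "\r?\n")[[1]]
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- trimws(lines)

  blocks <- grep("^data_", lines)
  if (length(blocks) > 1) {
    warning("multi-block CIF: using the first data block only")
    lines <- lines[seq(blocks[1], blocks[2] - 1)]
  }

  items <- list()
  loops <- list()
  i <- 1
  n <- length(lines)
  while (i <= n) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "data_")) { i <- i + 1; next }
    if (tolower(ln) == "loop_") {
      tags <- character(0)
      i <- i + 1
      while (i <= n && startsWith(lines[i], "_")) {
        tags <- c(tags, tolower(strsplit(lines[i], "[[:space:]]+")[[1]][1]))
        i <- i + 1
      }
      rows <- list()
      vals <- character(0)
      while (i <= n && nzchar(lines[i]) && !startsWith(lines[i], "_") &&
             tolower(lines[i]) != "loop_" && !startsWith(lines[i], "data_")) {
        vals <- c(vals, cif_tokens(lines[i]))
        while (length(vals) >= length(tags)) {
          rows[[length(rows) + 1L]] <- vals[seq_along(tags)]
          vals <- vals[-seq_along(tags)]
        }
        i <- i + 1
      }
      if (length(rows)) {
        df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
        names(df) <- tags
        loops[[length(loops) + 1L]] <- df
      }
      next
    }
    if (startsWith(ln, "_")) {
      toks <- cif_tokens(ln)
      tag <- tolower(toks[1])
      if (length(toks) >= 2) {
        items[[tag]] <- paste(toks[-1], collapse = " ")
      } else if (i < n && startsWith(lines[i + 1], ";")) {
        # multi-line text field: skip to closing semicolon
        i <- i + 1
        while (i < n && !(startsWith(lines[i + 1], ";"))) i <- i + 1
        i <- i + 1
      }
    }
    i <- i + 1
  }

  cell_tags <- c("_cell_length_a", "_cell_length_b", "_cell_length_c",
                 "_cell_angle_alpha", "_cell_angle_beta", "_cell_angle_gamma")
  if (!all(cell_tags %in% names(items))) {
    stop("CIF lacks cell parameters (_cell_length_*/_cell_angle_*)",
         call. = FALSE)
  }
  cv <- vapply(items[cell_tags], cif_strip_su, numeric(1))
  cell <- unit_cell(cv[1], cv[2], cv[3], cv[4], cv[5], cv[6])

  sym_tags <- c("_symmetry_equiv_pos_as_xyz", "_space_group_symop_operation_xyz")
  sym_loop <- NULL
  for (lp in loops) {
    if (any(sym_tags %in% names(lp))) { sym_loop <- lp; break }
  }
  if (is.null(sym_loop)) {
    stop("CIF has no symmetry operator loop; supply operators via ",
         "_symmetry_equiv_pos_as_xyz or _space_group_symop_operation_xyz",
         call. = FALSE)
  }
  col <- intersect(sym_tags, names(sym_loop))[1]
  ops <- lapply(sym_loop[[col]], parse_symop_string)
  symm <- ops[!vapply(ops, is_identity_op, logical(1))]

  site_loop <- NULL
  for (lp in loops) {
    if ("_atom_site_label" %in% names(lp) &&
        "_atom_site_fract_x" %in% names(lp)) { site_loop <- lp; break }
  }
  if (is.null(site_loop)) {
    stop("CIF has no _atom_site loop", call. = FALSE)
  }
  lbl <- site_loop[["_atom_site_label"]]
  el <- site_loop[["_atom_site_type_symbol"]]
  if (is.null(el)) el <- gsub("[^A-Za-z].*$", "", lbl)
  occ <- site_loop[["_atom_site_occupancy"]]
  occ <- if (is.null(occ)) rep(1, length(lbl)) else {
    o <- cif_strip_su(ifelse(occ %in% c(".", "?"), "1", occ))
    ifelse(is.na(o), 1, o)
  }
  dg <- site_loop[["_atom_site_disorder_group"]]
  part <- if (is.null(dg)) rep(0L, length(lbl)) else {
    as.integer(ifelse(dg %in% c(".", "?"), "0", gsub("-", "", dg)))
  }
  uiso <- site_loop[["_atom_site_u_iso_or_equiv"]]
  uiso <- if (is.null(uiso)) rep(0.05, length(lbl)) else {
    u <- cif_strip_su(ifelse(uiso %in% c(".", "?"), "0.05", uiso))
    ifelse(is.na(u), 0.05, u)
  }
  sites <- tibble::tibble(
    label = lbl, element = el,
    x = cif_strip_su(site_loop[["_atom_site_fract_x"]]),
    y = cif_strip_su(site_loop[["_atom_site_fract_y"]]),
    z = cif_strip_su(site_loop[["_atom_site_fract_z"]]),
    occupancy = occ, part = part, u_iso = uiso
  )
  crystal_structure(cell, sites, symm = symm, latt = -1L,
                    title = items[["_chemical_name_common"]] %||% "",
                    metadata = list())
}
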