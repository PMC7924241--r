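# Parsing, writing and the fractional/Cartesian coordinate contract.

test_that("frac_to_cart follows the a-along-x convention", {
  cubic <- unit_cell(10, 10, 10, 90, 90, 90)
  expect_equal(frac_to_cart(cubic, c(0.5, 0.5, 0.5)), c(5, 5, 5),
               tolerance = 1e-12)
  ortho <- unit_cell(2, 3, 4, 90, 90, 90)
  expect_equal(frac_to_cart(ortho, c(1, 1, 1)), c(2, 3, 4),
               tolerance = 1e-12)
  # monoclinic cell with beta = 90 degenerates to the orthorhombic result
  mono <- unit_cell(2, 3, 4, 90, 90, 90)
  mono90 <- unit_cell(2, 3, 4, 90, 90.0, 90)
  frac <- c(0.21, -0.4, 1.7)
  expect_equal(frac_to_cart(mono90, frac), frac_to_cart(mono, frac),
               tolerance = 1e-12)
})

test_that("frac/cart round trip is exact over random cells and points", {
  set.seed(42)
  for (k in 1:40) {
    cell <- unit_cell(runif(1, 3, 30), runif(1, 3, 30), runif(1, 3, 30),
                      runif(1, 60, 120), runif(1, 60, 120), runif(1, 60, 120))
    frac <- matrix(runif(75, -2, 2), ncol = 3)
    back <- cart_to_frac(cell, frac_to_cart(cell, frac))
    cart_err <- max(abs(frac_to_cart(cell, back) - frac_to_cart(cell, frac)))
    expect_lt(cart_err, 1e-10)
  }
})

test_that("unit cell validation rejects impossible metrics", {
  expect_error(unit_cell(-1, 5, 5, 90, 90, 90), "positive")
  expect_error(unit_cell(5, 5, 5, 190, 90, 90), "angles")
  expect_error(unit_cell(5, 5, 5, 1, 1, 170), "impossible")
})

test_that("symmetry operator strings parse to the stated matrices", {
  op <- parse_symop_string("-X, 1/2+Y, -Z")
  expect_equal(op$rotation, matrix(as.integer(diag(c(-1, 1, -1))), 3, 3))
  expect_equal(op$translation_12, c(0L, 6L, 0L))
  expect_true(is_identity_op <- all(parse_symop_string("x,y,z")$rotation == diag(3)))
  expect_error(parse_symop_string("x,y"), "3 components")
  expect_error(parse_symop_string("x,q,z"), "cannot parse")
})

test_that("LATT sign convention controls the inversion centre", {
  expect_length(expand_operations(list(), latt = -1L), 1)
  expect_length(expand_operations(list(), latt = 1L), 2)
  # centering: C-centred non-centrosymmetric cell has 2 operations
  expect_length(expand_operations(list(), latt = -7L), 2)
  # P21/c: one screw generator + inversion -> 4 operations
  p21c <- expand_operations(list(parse_symop_string("-X, 1/2+Y, 1/2-Z")),
                            latt = 1L)
  expect_length(p21c, 4)
})

test_that("parsed operator sets are closed under composition", {
  gens <- list(
    "P1" = list(),
    "P-1" = list(),
    "P21/c" = list(parse_symop_string("-X, 1/2+Y, 1/2-Z"))
  )
  latts <- c("P1" = -1L, "P-1" = 1L, "P21/c" = 1L)
  for (sg in names(gens)) {
    ops <- expand_operations(gens[[sg]], latt = latts[sg])
    keys <- vapply(ops, disorderkit:::symop_key, character(1))
    for (a in ops) for (b in ops) {
      expect_true(disorderkit:::symop_key(compose_symops(a, b)) %in% keys,
                  label = sprintf("%s closure", sg))
    }
  }
})

test_that("SHELX round trip preserves sites, operators, parts and fv codes", {
  for (tmpl in c("propionamide-P21/c", "monatomic-P1", "two-part-generic")) {
    s <- make_fixture(fixture_spec(tmpl, seed = 7L))
    s2 <- parse_shelx(write_shelx(s))
    expect_equal(nrow(s2$sites), nrow(s$sites))
    expect_identical(s2$sites$label, s$sites$label)
    expect_identical(s2$sites$element, s$sites$element)
    expect_identical(s2$sites$part, s$sites$part)
    expect_identical(s2$sites$residue, s$sites$residue)
    expect_identical(s2$sites$fv_ref, s$sites$fv_ref)
    expect_equal(s2$sites$occupancy, s$sites$occupancy, tolerance = 1e-4)
    expect_lt(max(abs(as.matrix(s2$sites[, c("x", "y", "z")]) -
                      as.matrix(s$sites[, c("x", "y", "z")]))), 1e-6)
    expect_length(s2$operations, length(s$operations))
    expect_equal(s2$latt, s$latt)
  }
})

test_that("SHELX free-variable occupancy codes decode per the manual", {
  ins <- c(
    "TITL fv decoding",
    "CELL 0.71073 10 10 10 90 90 90",
    "LATT -1",
    "SFAC C",
    "UNIT 4",
    "FVAR 1.0 0.7",
    "C1 1 0.1 0.1 0.1 21.0000 0.05",
    "C2 1 0.2 0.2 0.2 -21.0000 0.05",
    "C3 1 0.3 0.3 0.3 10.5000 0.05",
    "C4 1 0.4 0.4 0.4 11.0000 0.05",
    "HKLF 4"
  )
  s <- parse_shelx(ins)
  expect_equal(s$sites$occupancy, c(0.7, 0.3, 0.5, 1.0))
  expect_identical(s$sites$fv_ref, c(2L, -2L, NA_integer_, NA_integer_))
  # re-encoding reproduces the codes
  out <- write_shelx(s)
  expect_match(out, " 21.00000", fixed = TRUE)
  expect_match(out, "-21.00000", fixed = TRUE)
})

test_that("parser errors are specific", {
  expect_error(parse_shelx(c("TITL x", "SFAC C", "C1 1 0 0 0 11 0.05")),
               "no CELL")
  expect_error(parse_shelx(c("TITL x", "CELL 0.7 10 10 10 90 90 90",
                             "LATT -1", "SYMM x, qq, z", "SFAC C",
                             "C1 1 0 0 0 11 0.05")),
               "SYMM")
  expect_error(parse_shelx(c("TITL x", "CELL 0.7 10 10 10 90 90 90",
                             "LATT -1", "SFAC C",
                             "C1 2 0 0 0 11 0.05")),
               "SFAC")
})

test_that("writing fails when sites reference missing FVAR slots", {
  s <- make_fixture(fixture_spec("propionamide-P21/c"))
  s$fvar <- 1   # drop the occupancy free variable
  expect_error(write_shelx(s), "FVAR")
})

test_that("TURBOMOLE coord output is in Bohr with fixed-environment flags", {
  cell <- unit_cell(20, 20, 20, 90, 90, 90)
  sites <- tibble::tibble(label = "H1", element = "H",
                          x = BOHR_ANGSTROM / 20, y = 0, z = 0,
                          occupancy = 1, u_iso = 0.03)
  s <- crystal_structure(cell, sites, latt = -1L, title = "one H")
  cl <- build_cluster(s, cutoff = 1)
  txt <- write_turbomole_coord(cl)
  lines <- strsplit(txt, "\n")[[1]]
  expect_identical(lines[1], "$coord")
  expect_identical(lines[2], "1.00000000 0.00000000 0.00000000 h")
  expect_identical(lines[length(lines)], "$end")
  # empty environment: exactly n_ASU coordinate lines between the markers
  expect_length(lines, 3)

  # environment atoms are flagged fixed, one flag per environment atom
  s2 <- make_fixture(fixture_spec("monatomic-P1"))
  cl2 <- build_cluster(s2, cutoff = 12)
  txt2 <- write_turbomole_coord(cl2)
  body <- strsplit(txt2, "\n")[[1]]
  body <- body[-c(1, length(body))]
  n_env <- sum(vapply(cl2$environment, function(e) nrow(e$cart), integer(1)))
  expect_equal(sum(grepl(" f$", body)), n_env)
  expect_false(grepl(" f$", body[1]))
  # and the fix control block points at exactly those atoms
  expect_match(write_xtb_fix_block(cl2),
               sprintf("atoms: 2-%d", 1 + n_env), fixed = TRUE)
})

test_that("optimized coord files parse back (xtb backend plumbing)", {
  s <- make_fixture(fixture_spec("monatomic-P1"))
  cl <- build_cluster(s, cutoff = 12)
  parsed <- disorderkit:::parse_turbomole_coord(write_turbomole_coord(cl))
  expect_equal(parsed$cart[1, ], cl$asu_cart[1, ], tolerance = 1e-6)
  expect_false(parsed$fixed[1])
  expect_true(all(parsed$fixed[-1]))
  expect_identical(unique(parsed$elements), "Ar")
})

test_that("XYZ export carries element and Angstrom coordinates", {
  txt <- write_xyz(c("C", "H"), rbind(c(0, 0, 0), c(1.09, 0, 0)), "demo")
  lines <- strsplit(txt, "\n")[[1]]
  expect_identical(lines[1], "2")
  expect_match(lines[3], "^C ")
  expect_match(lines[4], "1.090000")
})
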