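# Symmetry expansion into clusters and the optimization loop contract.

test_that("an isolated atom in a roomy P1 cell has an empty environment", {
  s <- make_fixture(fixture_spec("monatomic-P1"))
  cl <- build_cluster(s, cutoff = 3.75)
  expect_length(cl$environment, 0)
  expect_equal(nrow(cl$asu), 1)
})

test_that("widening the cutoff in cubic P1 recovers the brute-force shell", {
  s <- make_fixture(fixture_spec("monatomic-P1"))
  cl <- build_cluster(s, cutoff = 10.5)
  expect_identical(cluster_keys(cl),
                   brute_force_cluster_keys(s, cutoff = 10.5, t_range = 2))
  # at 10.5 A only the 6 face neighbours (10 A) of the cubic lattice reach
  expect_length(cl$environment, 6)
  prov <- cluster_provenance(cl)
  expect_true(all(abs(prov$tx) + abs(prov$ty) + abs(prov$tz) == 1))
  # at 14.5 A the 12 edge neighbours (14.14 A) join
  cl2 <- build_cluster(s, cutoff = 14.5)
  expect_length(cl2$environment, 18)
  expect_identical(cluster_keys(cl2),
                   brute_force_cluster_keys(s, cutoff = 14.5, t_range = 3))
})

test_that("P21/c propionamide cluster equals the brute-force oracle", {
  arch <- split_archetypes(propionamide_model())[[1]]
  cl <- build_cluster(arch, cutoff = 3.75)
  expect_identical(cluster_keys(cl),
                   brute_force_cluster_keys(arch, cutoff = 3.75, t_range = 3))
  expect_gt(length(cl$environment), 0)
  # every environment molecule is whole and within reach
  prov <- cluster_provenance(cl)
  expect_true(all(prov$n_atoms == nrow(arch$sites)))
  expect_true(all(prov$min_distance <= 3.75))
  # no duplicate provenance
  expect_false(anyDuplicated(cluster_keys(cl)) > 0)
})

test_that("P-1 generic fixture cluster equals the brute-force oracle", {
  arch <- split_archetypes(make_fixture(fixture_spec("two-part-generic")))[[1]]
  cl <- build_cluster(arch, cutoff = 3.75)
  expect_identical(cluster_keys(cl),
                   brute_force_cluster_keys(arch, cutoff = 3.75, t_range = 3))
})

test_that("building twice yields identical provenance (dedup idempotence)", {
  arch <- split_archetypes(propionamide_model())[[1]]
  expect_identical(cluster_keys(build_cluster(arch)),
                   cluster_keys(build_cluster(arch)))
})

test_that("periodically wrapped input molecules are unwrapped", {
  arch <- split_archetypes(propionamide_model())[[1]]
  ref <- build_cluster(arch)
  wrapped <- arch
  # push two hydrogens a full lattice translation away
  wrapped$sites$x[6] <- wrapped$sites$x[6] + 1
  wrapped$sites$y[7] <- wrapped$sites$y[7] - 1
  # bond perception must run on the unwrapped geometry, so hand it the graph
  g <- structure_bond_graph(arch)
  g$cart <- site_cartesian(arch)
  cl <- build_cluster(wrapped, graph = g)
  expect_identical(cluster_keys(cl), cluster_keys(ref))
  expect_equal(cl$asu_cart, ref$asu_cart, tolerance = 1e-9)
})

test_that("cluster size is invariant under applying a space-group operator", {
  arch <- split_archetypes(propionamide_model())[[1]]
  n0 <- length(build_cluster(arch)$environment)
  for (oi in 2:length(arch$operations)) {
    moved <- arch
    frac <- apply_symop(arch$operations[[oi]],
                        as.matrix(arch$sites[, c("x", "y", "z")]))
    moved$sites$x <- frac[, 1]; moved$sites$y <- frac[, 2]
    moved$sites$z <- frac[, 3]
    expect_length(build_cluster(moved)$environment, n0)
  }
})

test_that("a floating unbonded atom warns and becomes its own molecule", {
  s <- crystal_structure(
    unit_cell(12, 12, 12, 90, 90, 90),
    tibble::tibble(label = c("C1", "O1"), element = c("C", "O"),
                   x = c(0.1, 0.4), y = 0.1, z = 0.1, u_iso = 0.03),
    latt = -1L
  )
  expect_warning(cl <- build_cluster(s, cutoff = 4), "unbonded")
  expect_equal(nrow(cl$asu), 2)
  # a genuinely monatomic cell does not warn
  expect_no_warning(build_cluster(make_fixture(fixture_spec("monatomic-P1"))))
})

test_that("cutoff validation", {
  s <- make_fixture(fixture_spec("monatomic-P1"))
  expect_error(build_cluster(s, cutoff = 0), "positive")
  expect_error(build_cluster(s, cutoff = -2), "positive")
})

test_that("the identity backend is a fixed point of the ten-cycle loop", {
  arch <- split_archetypes(propionamide_model())[[1]]
  res <- iterate_optimization(arch, backend_identity())
  expect_equal(nrow(res$trace), 10)   # published protocol: ten repeat cycles
  expect_equal(res$structure$sites$x, arch$sites$x, tolerance = 1e-12)
  expect_equal(res$structure$sites$z, arch$sites$z, tolerance = 1e-12)
  expect_true(all(res$trace$rms_displacement == 0))
  expect_true(all(res$trace$energy == 0))
  expect_equal(length(unique(res$trace$n_environment)), 1)
})

test_that("early stop halts on sub-threshold displacement", {
  arch <- split_archetypes(propionamide_model())[[1]]
  res <- iterate_optimization(arch, backend_shift(0.005), early_stop = TRUE)
  expect_equal(nrow(res$trace), 1)
  # without early stop the full cycle count runs and the atom keeps moving
  res10 <- iterate_optimization(arch, backend_shift(0.005))
  expect_equal(nrow(res10$trace), 10)
  moved <- site_cartesian(res10$structure)[1, 1] - site_cartesian(arch)[1, 1]
  expect_equal(moved, 0.05, tolerance = 1e-9)
})

test_that("backend failures carry the cycle number", {
  arch <- split_archetypes(propionamide_model())[[1]]
  bomb <- function(cluster) stop("boom")
  expect_error(iterate_optimization(arch, bomb), "cycle 1")
  nf <- function(cluster) list(coords = cluster$asu_cart, energy = NaN)
  expect_error(iterate_optimization(arch, nf), "non-finite")
})

test_that("mock backend returns finite geometry-dependent energies", {
  archs <- split_archetypes(propionamide_model())
  e <- vapply(archs, function(a) {
    iterate_optimization(a, backend_mock(), n_cycles = 1)$energy
  }, numeric(1))
  expect_true(all(is.finite(e)))
  expect_true(all(e > 0))
  expect_false(e[1] == e[2])   # the two conformers see different contacts
})
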