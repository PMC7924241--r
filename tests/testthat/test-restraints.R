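# Restraint/constraint generation, instruction files, parameter counting.

big_p1_structure <- function(sites) {
  crystal_structure(unit_cell(30, 30, 30, 90, 90, 90), sites, latt = -1L,
                    title = "test fragment")
}

test_that("X-H bond targets are shrunk by 13.5 percent", {
  s <- big_p1_structure(tibble::tibble(
    label = c("C1", "H1"), element = c("C", "H"),
    x = c(0, 1.090 / 30), y = 0, z = 0, u_iso = 0.03
  ))
  r <- generate_restraints(s)
  expect_equal(nrow(r), 1)
  expect_equal(r$kind, "DFIX")
  expect_equal(r$target, 1.090 * 0.865, tolerance = 1e-9)
  expect_equal(r$sigma, 0.005)
})

test_that("1-3 targets with hydrogens are recomputed, keeping angles fixed", {
  # water-like: O with two H at 104.5 degrees
  ang <- 104.5 * pi / 180
  s <- big_p1_structure(tibble::tibble(
    label = c("O1", "H1", "H2"), element = c("O", "H", "H"),
    x = c(0, 0.96, 0.96 * cos(ang)) / 30,
    y = c(0, 0, 0.96 * sin(ang)) / 30,
    z = 0, u_iso = 0.03
  ))
  r <- generate_restraints(s)
  dang <- r[r$kind == "DANG", ]
  expect_equal(nrow(dang), 1)
  # both O-H scaled to 0.96 * 0.865; H...H target follows from the law of
  # cosines at the unchanged angle
  oh <- 0.96 * 0.865
  expect_equal(dang$target, sqrt(2 * oh^2 * (1 - cos(ang))), tolerance = 1e-9)
})

test_that("the propionamide archetypes give 29 restraints each, 58 total", {
  archs <- split_archetypes(propionamide_model())
  r1 <- generate_restraints(archs[[1]], residue = 1)
  r2 <- generate_restraints(archs[[2]], residue = 2)
  expect_equal(sum(r1$kind == "DFIX"), 11)
  expect_equal(sum(r1$kind == "DANG"), 18)
  expect_equal(nrow(r1), 29)
  expect_equal(nrow(r1) + nrow(r2), 58)
  expect_true(all(c(r1$sigma, r2$sigma) == 0.005))
  expect_true(all(r1$residue == 1L) && all(r2$residue == 2L))
})

test_that("restraint count equals 2 x (bonds + 1-3 pairs) from the pair oracle", {
  archs <- split_archetypes(propionamide_model())
  total <- 0
  for (a in archs) {
    g <- structure_bond_graph(a)
    d <- bfs_path_lengths(g$n, g$edges$i, g$edges$j)
    total <- total + sum(d[upper.tri(d)] %in% c(1, 2))
  }
  r <- dplyr::bind_rows(generate_restraints(archs[[1]], residue = 1),
                        generate_restraints(archs[[2]], residue = 2))
  expect_equal(nrow(r), total)
})

test_that("the exclude hook drops named pairs", {
  archs <- split_archetypes(propionamide_model())
  r <- generate_restraints(archs[[1]],
                           exclude = data.frame(a = "N1", b = "H31"))
  expect_equal(nrow(r), 28)
  expect_false(any(r$label1 == "N1" & r$label2 == "H31"))
})

test_that("proximity constraints follow the threshold and mode", {
  m <- tibble::tibble(
    label_a = c("C1", "C2"), label_b = c("C1", "C2"),
    element = "C", residue_a = 1L, residue_b = 2L,
    distance = c(0.10, 0.60)
  )
  cc <- assign_constraints(m)
  expect_equal(nrow(cc), 1)
  expect_equal(cc$kind, "EADP")
  expect_identical(cc$label1, "C1")
  simu <- assign_constraints(m, mode = "simu")
  expect_equal(simu$kind, "SIMU")
  expect_equal(simu$sigma, 0.02)
  tight <- assign_constraints(m, mode = "simu", simu_sigma = 0.005)
  expect_equal(tight$sigma, 0.005)
  both <- assign_constraints(m, mode = "eadp+exyz")
  expect_identical(sort(both$kind), c("EADP", "EXYZ"))
  expect_error(assign_constraints(m, threshold = 0), "positive")
})

test_that("lowering the threshold never adds constraints (monotone)", {
  archs <- split_archetypes(propionamide_model())
  a <- archs[[1]]; b <- archs[[2]]
  a$sites$residue <- 1L; b$sites$residue <- 2L
  m <- map_atoms(a, b)
  thresholds <- seq(1.2, 0.05, by = -0.05)
  counts <- vapply(thresholds, function(t) {
    nrow(assign_constraints(m, threshold = t))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("instruction files are bit-stable and round-trip losslessly", {
  archs <- split_archetypes(propionamide_model())
  a <- archs[[1]]; b <- archs[[2]]
  a$sites$residue <- 1L; b$sites$residue <- 2L
  restraints <- dplyr::bind_rows(generate_restraints(archs[[1]], residue = 1),
                                 generate_restraints(archs[[2]], residue = 2))
  constraints <- assign_constraints(map_atoms(a, b))
  plan <- refinement_plan(restraints, constraints)
  out <- write_instruction_file(plan)
  expect_identical(out$main_stub, "+restraints.ins")
  expect_equal(length(gregexpr("RESI", out$instructions)[[1]]), 2)
  # deterministic output
  expect_identical(out$instructions, write_instruction_file(plan)$instructions)
  # round trip: restraint and constraint multisets survive
  back <- parse_instruction_file(out$instructions)
  key <- function(r) sort(paste(r$kind, disorderkit:::fmt_target(r$target),
                                r$sigma, r$label1, r$label2, r$residue))
  expect_identical(key(back$restraints), key(plan$restraints))
  ckey <- function(cc) sort(paste(cc$kind, cc$label1, cc$residue1,
                                  cc$label2, cc$residue2))
  expect_identical(ckey(back$constraints), ckey(plan$constraints))
})

test_that("DFIX lines use residue-qualified names in SHELXL format", {
  plan <- refinement_plan(tibble::tibble(
    kind = "DFIX", target = 1.523, sigma = 0.005,
    label1 = "C1", label2 = "C2", residue = 1L
  ))
  out <- write_instruction_file(plan)
  expect_match(out$instructions, "DFIX 1.523 0.005 C1_1 C2_1", fixed = TRUE)
})

test_that("a DFIX/EXYZ clash on the same pair is rejected", {
  r <- tibble::tibble(kind = "DFIX", target = 1.5, sigma = 0.005,
                      label1 = "C1", label2 = "C2", residue = 1L)
  cc <- tibble::tibble(kind = "EXYZ", sigma = NA_real_, label1 = "C1",
                       residue1 = 1L, label2 = "C2", residue2 = 1L,
                       distance = 0.1)
  expect_error(refinement_plan(r, cc), "same atom pair")
})

test_that("free-refinement parameter counting follows the convention", {
  # single ordered anisotropic atom: 9 + scale = 10
  one <- crystal_structure(
    unit_cell(10, 10, 10, 90, 90, 90),
    tibble::tibble(label = "C1", element = "C", x = 0.1, y = 0.1, z = 0.1,
                   u_iso = NA_real_, u11 = 0.02, u22 = 0.02, u33 = 0.02,
                   u23 = 0, u13 = 0, u12 = 0),
    latt = -1L
  )
  expect_equal(count_parameters(one), 10)

  # two-archetype propionamide model: 10 aniso + 14 iso + scale + 1 fv = 148
  model <- recombine(split_archetypes(propionamide_model()),
                     occupancies = c(0.5, 0.5))
  expect_equal(count_parameters(model), 148)
})

test_that("EADP and EXYZ groups reduce the parameter count", {
  model <- recombine(split_archetypes(propionamide_model()),
                     occupancies = c(0.5, 0.5))
  heavy <- c("C1", "C2", "C3", "O1", "N1")
  hyd <- c("H11", "H12", "H13", "H21", "H22")
  hyd2 <- c("H41", "H42", "H43", "H51", "H52")
  cc <- tibble::tibble(
    kind = "EADP", sigma = NA_real_,
    label1 = c(heavy, hyd), residue1 = 1L,
    label2 = c(heavy, hyd2), residue2 = 2L,
    distance = 0
  )
  plan <- refinement_plan(
    tibble::tibble(kind = character(), target = numeric(), sigma = numeric(),
                   label1 = character(), label2 = character(),
                   residue = integer()),
    cc
  )
  # 5 anisotropic pairs x 6 + 5 isotropic pairs x 1 = 35 fewer parameters
  expect_equal(count_parameters(model, plan), 148 - 35)
  expect_equal(count_parameters(model, plan), 113)

  # EXYZ removes 3 positional parameters per extra group member
  cc_xyz <- cc[1, ]
  cc_xyz$kind <- "EXYZ"
  plan2 <- refinement_plan(plan$restraints, cc_xyz)
  expect_equal(count_parameters(model, plan2), 148 - 3)

  # chained EADP pairs merge into one group
  chain <- tibble::tibble(
    kind = "EADP", sigma = NA_real_,
    label1 = c("C1", "C1"), residue1 = c(1L, 1L),
    label2 = c("C1", "C2"), residue2 = c(2L, 2L),
    distance = 0
  )
  plan3 <- refinement_plan(plan$restraints, chain)
  expect_equal(count_parameters(model, plan3), 148 - 2 * 6)
})

test_that("constraints never increase and only constraints reduce the count", {
  model <- recombine(split_archetypes(propionamide_model()),
                     occupancies = c(0.5, 0.5))
  a <- split_archetypes(model)
  m <- map_atoms(a[[1]], a[[2]])
  free <- count_parameters(model)
  for (t in c(0.1, 0.5, 1.0)) {
    plan <- refinement_plan(
      generate_restraints(a[[1]], residue = 1),
      assign_constraints(m, threshold = t)
    )
    expect_lte(count_parameters(model, plan), free)
  }
  empty_plan <- refinement_plan(generate_restraints(a[[1]], residue = 1))
  expect_equal(count_parameters(model, empty_plan), free)
})
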