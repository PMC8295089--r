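test_that("united-atom partition follows the heavy-atom-plus-hydrogens rule", {
  wt <- water_topology()
  expect_length(wt$molecules, 1)
  expect_length(wt$united_atoms[[1]], 1)       # one UA: O with both H
  expect_setequal(wt$united_atoms[[1]][[1]], 1:3)
  expect_equal(nrow(wt$flexible_dihedrals[[1]]), 0)

  expect_length(octanol_skeleton_topology()$united_atoms[[1]], 9)

  mt <- methane_topology()
  expect_length(mt$united_atoms[[1]], 1)
  expect_length(mt$united_atoms[[1]][[1]], 5)
})

test_that("united-atom partition covers every atom exactly once", {
  for (top in list(water_topology(), methane_topology(),
                   octanol_box(2, 1)$topology)) {
    covered <- unlist(lapply(top$united_atoms, unlist))
    expect_setequal(covered, seq_along(top$masses))
    expect_equal(anyDuplicated(covered), 0L)
    ## exactly one heavy atom per UA
    for (uas in top$united_atoms)
      for (u in uas)
        expect_equal(sum(top$elements[u] != "H"), 1L)
  }
})

test_that("a hydrogen bonded to two heavy atoms is a topology error", {
  expect_error(
    mcc_topology(masses = c(12, 12, 1), elements = c("C", "C", "H"),
                 bonds = rbind(c(1, 3), c(2, 3), c(1, 2)),
                 molecules = list(1:3), species = "other", sigma = 1),
    "hydrogen")
})

test_that("dihedral auto-detection skips ring bonds and terminal heavy atoms", {
  ## butanol chain C-C-C-O: only the central C2-C3 bond is rotatable
  tpl <- butanol_template()
  top <- mcc_topology(tpl$masses, tpl$elements, tpl$bonds, list(1:12),
                      species = "solute", sigma = 1)
  expect_equal(nrow(top$flexible_dihedrals[[1]]), 1)
  expect_equal(top$flexible_dihedrals[[1]][1, ], c(1, 2, 3, 4))

  ## cyclopropane ring: all heavy bonds in a ring, no dihedrals
  ring <- mcc_topology(masses = rep(12, 3), elements = rep("C", 3),
                       bonds = rbind(c(1, 2), c(2, 3), c(1, 3)),
                       molecules = list(1:3), species = "other", sigma = 6)
  expect_equal(nrow(ring$flexible_dihedrals[[1]]), 0)
})

test_that("YAML topology round-trips all fields, with dihedral override", {
  tpl <- butanol_template()
  top <- mcc_topology(tpl$masses, tpl$elements, tpl$bonds, list(1:12),
                      species = "solute", sigma = 1)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_topology(top, path)
  back <- read_topology(path, "yaml")
  expect_equal(back$masses, top$masses)
  expect_equal(back$elements, top$elements)
  expect_equal(back$bonds, top$bonds)
  expect_equal(back$molecules, top$molecules)
  expect_equal(back$species, top$species)
  expect_equal(back$sigma, top$sigma)
  expect_equal(back$flexible_dihedrals, top$flexible_dihedrals)

  ## explicit dihedral list overrides auto-detection
  txt <- readLines(path)
  writeLines(c(txt), path)
  doc <- yaml::read_yaml(path)
  doc$molecules[[1]]$flexible_dihedrals <- list(c(5, 1, 2, 3))
  yaml::write_yaml(doc, path)
  over <- read_topology(path, "yaml")
  expect_equal(over$flexible_dihedrals[[1]], matrix(c(5L, 1L, 2L, 3L), 1))
})

test_that("malformed topology files name the offending record", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("molecules:\n  - {species: water, atoms: [1]}", path)
  expect_error(read_topology(path, "yaml"), "atoms")
  writeLines("atoms:\n  - {element: O}\nmolecules:\n  - {atoms: [1]}", path)
  expect_error(read_topology(path, "yaml"), "mass")
  expect_error(read_topology(tempfile(), "yaml"), "not found")
})

test_that("minimal prmtop subset reads masses, bonds and finds water", {
  path <- withr::local_tempfile(fileext = ".prmtop")
  writeLines(c(
    "%VERSION  VERSION_STAMP = V0001.000",
    "%FLAG POINTERS", "%FORMAT(10I8)",
    "       6       0       2       4", # natom + filler
    "%FLAG ATOM_NAME", "%FORMAT(20a4)",
    "O   H1  H2  O   H1  H2",
    "%FLAG MASS", "%FORMAT(5E16.8)",
    "  1.59990000E+01  1.00800000E+00  1.00800000E+00",
    "  1.59990000E+01  1.00800000E+00  1.00800000E+00",
    "%FLAG BONDS_INC_HYDROGEN", "%FORMAT(10I8)",
    "       0       3       1       0       6       1",
    "       9      12       1       9      15       1"), path)
  top <- read_topology(path, "prmtop")
  expect_length(top$molecules, 2)
  expect_equal(top$species, c("water", "water"))
  expect_equal(top$sigma, c(2, 2))
  expect_equal(top$elements[1:3], c("O", "H", "H"))
})

test_that("fixture trajectory dialect round-trips bitwise", {
  set.seed(42)
  fr <- mcc_frames(array(rnorm(9 * 3), c(3, 3, 3)),
                   array(rnorm(9 * 3), c(3, 3, 3)),
                   box = c(20, 25, 30), temperature = 298)
  path <- withr::local_tempfile(fileext = ".traj")
  write_frames(fr, path)
  back <- read_frames(path, water_topology())
  expect_identical(back$coords, fr$coords)
  expect_identical(back$forces, fr$forces)
  expect_identical(back$box, fr$box)
  expect_equal(back$temperature, 298)
  expect_equal(back$n_frames, 3)
})

test_that("missing forces and atom-count mismatches are hard errors", {
  expect_error(mcc_frames(array(0, c(2, 3, 1)), NULL, c(10, 10, 10), 298),
               "forces required")
  set.seed(1)
  fr <- mcc_frames(array(rnorm(9), c(3, 3, 1)), array(rnorm(9), c(3, 3, 1)),
                   c(10, 10, 10), 298)
  path <- withr::local_tempfile()
  write_frames(fr, path)
  ## truncate the force block
  lines <- readLines(path)
  writeLines(lines[1:(length(lines) - 2)], path)
  expect_error(read_frames(path, water_topology()), "forces required")
  expect_error(read_frames(path, methane_topology()), "mismatch")
})

test_that("energy series reads tables and mdout logs", {
  path <- withr::local_tempfile()
  writeLines(sprintf("%d 5.0", 1:10), path)
  es <- read_energy_series(path, "wat")
  expect_equal(mean(es$energy), 5.0)
  expect_length(es$energy, 10)
  expect_equal(es$label, "wat")

  writeLines(c(" NSTEP =      500",
               " Etot   =     -9127.3852  EKtot   =      1754.1",
               " Etot   =     -9130.0000  EKtot   =      1755.0",
               " Etot   =     -9125.5     EKtot   =      1753.2",
               " Etot   =     -9128.25    EKtot   =      1754.9"), path)
  es2 <- read_energy_series(path, "oct")
  expect_length(es2$energy, 4)
  expect_equal(es2$energy[2], -9130)

  expect_error(read_energy_series(tempfile(), "wat"), "not found")
  writeLines(c("1 2.0", "2 oops"), path)
  expect_error(read_energy_series(path, "wat"), "non-numeric")
})

test_that("entropy unit conversions are involutive", {
  x <- c(0, 1e-6, 0.05, 123.4)
  expect_equal(entropy_to_kcal(entropy_to_joules(x)), x, tolerance = 1e-12)
  expect_equal(entropy_to_joules(entropy_to_kcal(x)), x, tolerance = 1e-12)
})
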