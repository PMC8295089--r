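test_that("positional entropy is the log volume ratio and cancels V0", {
  expect_equal(as.numeric(positional_entropy(30, 30)), 0)
  s1 <- as.numeric(positional_entropy(100, 25))
  expect_equal(as.numeric(positional_entropy(200, 50)), s1, tolerance = 1e-12)
  expect_error(positional_entropy(-1, 10), "positive")
  expect_error(positional_entropy(10, 0), "positive")
})

test_that("the water/octanol transfer difference in positional entropy is
           -18 J/K/mol for the 34 A box composition", {
  v0 <- 34^3
  s_aq <- as.numeric(positional_entropy(v0, 34^3 / 1300))
  s_oct <- as.numeric(positional_entropy(v0, 34^3 / 150))
  expect_equal(round(s_oct - s_aq), -18)
  ## independent of V0
  expect_equal(as.numeric(positional_entropy(1e5, 34^3 / 150)) -
                 as.numeric(positional_entropy(1e5, 34^3 / 1300)),
               s_oct - s_aq, tolerance = 1e-12)
})

test_that("orientational entropy evaluates the clamped orientation count", {
  kbj <- 0.0019872041 * 4184
  ## Nc = 0 clamps to one orientation
  expect_equal(as.numeric(orientational_entropy(c("0" = 1), sigma = 1)), 0)
  ## Nc = 1, sigma 1, non-water: ln sqrt(pi)
  expect_equal(as.numeric(orientational_entropy(c("1" = 1), sigma = 1)),
               kbj * log(sqrt(pi)), tolerance = 1e-12)
  ## water with p(4) = 1, sigma 2, 1/4 factor inside the logarithm
  expect_equal(as.numeric(orientational_entropy(c("4" = 1), sigma = 2,
                                                is_water = TRUE)),
               kbj * log(max(1, 0.25 * sqrt(4^3 * pi) / 2)),
               tolerance = 1e-12)
  ## mixture weighting
  p <- c("4" = 0.25, "6" = 0.75)
  expect_equal(as.numeric(orientational_entropy(p, sigma = 1)),
               kbj * (0.25 * log(sqrt(64 * pi)) + 0.75 * log(sqrt(216 * pi))),
               tolerance = 1e-12)
  ## monotone non-decreasing in Nc at fixed sigma
  vals <- vapply(1:12, function(nc)
    as.numeric(orientational_entropy(stats::setNames(1, nc), sigma = 2)), 0)
  expect_true(all(diff(vals) >= 0))
  expect_error(orientational_entropy(c("-1" = 1)), "invalid")
  expect_error(orientational_entropy(c("4" = 0.7)), "normalized")
})

test_that("conformer assignment finds the wells of multimodal series", {
  ## single mode -> one conformer, zero conformational entropy
  set.seed(2)
  one <- assign_conformers(rnorm(2000, 60, 8))
  expect_equal(one$n_conformers, 1L)
  expect_equal(as.numeric(conformational_entropy(list(one))), 0)

  ## ideal three-well series, equally populated
  dc <- synth_dihedral_chain(6000, centers = list(c(-60, 60, 180)),
                             probs = list(rep(1 / 3, 3)), noise_sd = 10,
                             seed = 6)
  cf <- assign_conformers(dc$angles[, 1])
  expect_equal(cf$n_conformers, 3L)
  expect_equal(sort(cf$p), rep(1 / 3, 3), tolerance = 0.05)
  expect_equal(sum(cf$p), 1, tolerance = 1e-12)

  ## noisy two-well series with known populations: binomial recovery
  p_true <- 0.9
  dc2 <- synth_dihedral_chain(5000, centers = list(c(-60, 120)),
                              probs = list(c(p_true, 1 - p_true)),
                              noise_sd = 12, seed = 9)
  cf2 <- assign_conformers(dc2$angles[, 1])
  expect_equal(cf2$n_conformers, 2L)
  ci <- 4 * sqrt(p_true * (1 - p_true) / 5000)
  expect_lt(abs(max(cf2$p) - p_true), ci + 0.01)

  ## short series are marked rigid with a warning
  expect_warning(short <- assign_conformers(rnorm(20, 0, 5)), "rigid")
  expect_true(short$rigid)
  expect_equal(short$n_conformers, 1L)
})

test_that("conformational entropy reduces to Shannon for one dihedral and
           does not double-count correlated dihedrals", {
  kbj <- 0.0019872041 * 4184
  ## explicit labels, no histogramming: equal two-state
  half <- structure(list(labels = rep(1:2, 500), n_conformers = 2L,
                         p = c(0.5, 0.5), boundaries = c(0, 180),
                         rigid = FALSE), class = "mcc_conformers")
  expect_equal(as.numeric(conformational_entropy(list(half))),
               kbj * log(2), tolerance = 1e-12)

  ## perfectly correlated pair: still kB ln 2 (4x4 eigendecomposition)
  pair <- list(half, half)
  expect_equal(as.numeric(conformational_entropy(pair)),
               kbj * log(2), tolerance = 1e-12)

  ## independent pair stays below the sum of Shannon entropies
  set.seed(12)
  l1 <- sample(1:2, 2000, replace = TRUE)
  l2 <- sample(1:2, 2000, replace = TRUE)
  mk <- function(l) structure(list(labels = l, n_conformers = 2L,
                                   p = as.numeric(table(l)) / length(l),
                                   boundaries = c(0, 180), rigid = FALSE),
                              class = "mcc_conformers")
  s_ind <- as.numeric(conformational_entropy(list(mk(l1), mk(l2))))
  expect_lt(s_ind, 2 * kbj * log(2) + 1e-9)
  expect_gt(s_ind, kbj * log(2) * 0.9)

  ## deterministic series carries no conformational entropy
  const <- mk(rep(1L, 100))
  const$n_conformers <- 1L; const$p <- 1
  expect_equal(as.numeric(conformational_entropy(list(const))), 0)

  ## joint conformer count bounds the entropy
  expect_lt(s_ind, kbj * log(4))
})

test_that("dihedral angles match the four-point torsion on a known geometry", {
  ## trans-planar chain: torsion 180; then rotate the last atom to +-gauche
  tpl <- butanol_template()
  top <- mcc_topology(tpl$masses, tpl$elements, tpl$bonds, list(1:12),
                      species = "solute", sigma = 1)
  base <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.25, 1.3, 0), c(3.75, 1.3, 0))
  xyz <- tpl$xyz
  xyz[1:4, ] <- base
  coords <- array(xyz + 20, c(12, 3, 1))
  fr <- mcc_frames(coords, array(0, dim(coords)), c(50, 50, 50), 298)
  ang <- dihedral_angles(fr, top, 1)
  expect_equal(abs(ang[1, 1]), 180, tolerance = 1e-6)

  ## a +60 degree rotation of atom 4 about the 2-3 bond shifts the torsion
  axis <- (base[3, ] - base[2, ]) / sqrt(sum((base[3, ] - base[2, ])^2))
  v <- base[4, ] - base[3, ]
  th <- pi / 3
  vrot <- v * cos(th) + eemcc:::.cross3(axis, v) * sin(th) +
    axis * sum(axis * v) * (1 - cos(th))
  xyz[4, ] <- base[3, ] + vrot
  fr2 <- mcc_frames(array(xyz + 20, c(12, 3, 1)), array(0, c(12, 3, 1)),
                    c(50, 50, 50), 298)
  ang2 <- dihedral_angles(fr2, top, 1)
  expect_equal(abs(abs(ang2[1, 1]) - 120), 0, tolerance = 1e-6)
})
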