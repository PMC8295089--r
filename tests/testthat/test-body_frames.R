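test_that("water's C2 symmetry axis is recovered as a principal axis", {
  tpl <- water_template()
  mf <- molecule_frame(tpl$xyz, tpl$masses)
  ## the C2 axis is y in the template frame
  alignment <- abs(drop(crossprod(mf$axes, c(0, 1, 0))))
  expect_true(any(abs(alignment - 1) < 1e-10))
  expect_equal(crossprod(mf$axes), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(mf$moments) >= -1e-12))
  ## right-handed
  expect_equal(drop(crossprod(eemcc:::.cross3(mf$axes[, 1], mf$axes[, 2]),
                              mf$axes[, 3])), 1, tolerance = 1e-10)
})

test_that("molecule frames are equivariant under global rotation", {
  set.seed(5)
  tpl <- butanol_template()
  mf <- molecule_frame(tpl$xyz, tpl$masses)
  for (rep in 1:5) {
    R <- random_rotation()
    mfr <- molecule_frame(tpl$xyz %*% t(R), tpl$masses)
    expect_equal(mfr$moments, mf$moments, tolerance = 1e-8)
    ## axes match up to the fixed sign convention; compare unsigned
    expect_equal(abs(crossprod(mfr$axes, R %*% mf$axes)), diag(3),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("a planar ring's out-of-plane axis carries the largest moment", {
  th <- 2 * pi * (0:5) / 6
  ring <- cbind(cos(th), sin(th), 0)
  mf <- molecule_frame(ring, rep(12, 6))
  ## moments ascending: the largest-moment axis is the third; for a planar
  ## body it must be the out-of-plane (z) direction
  expect_equal(abs(mf$axes[3, 3]), 1, tolerance = 1e-10)
  ## flat body: I_z = I_x + I_y (perpendicular axis theorem)
  expect_equal(mf$moments[3], mf$moments[1] + mf$moments[2],
               tolerance = 1e-10)
})

test_that("collinear molecules are rejected", {
  expect_error(molecule_frame(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                              c(1, 1, 1)), "collinear")
})

test_that("united-atom rotational DOF follow the hydrogen count", {
  tpl <- butanol_template()
  top <- mcc_topology(tpl$masses, tpl$elements, tpl$bonds, list(1:12),
                      species = "solute", sigma = 1)
  dof <- united_atom_dof(top, 1)
  expect_equal(dof[, "n_trans"], rep(3L, 4))
  expect_equal(dof[, "n_rot"], c(3L, 3L, 3L, 2L))  # CH3, CH2, CH2, OH

  ## a bare carbon (no hydrogens) is a point: zero rotational DOF
  skel <- octanol_skeleton_topology()
  expect_equal(united_atom_dof(skel, 1)[, "n_rot"], rep(0L, 9))
})

test_that("net force and torque follow the cross-product oracle", {
  set.seed(11)
  tpl <- butanol_template()
  xyz <- tpl$xyz
  com <- colSums(xyz * tpl$masses) / sum(tpl$masses)
  f <- matrix(rnorm(nrow(xyz) * 3), ncol = 3)
  mf <- molecule_frame(xyz, tpl$masses)

  ## brute-force lab-frame sums, rotated afterwards
  lab_force <- colSums(f)
  lab_tau <- colSums(t(apply(cbind(sweep(xyz, 2, mf$origin), f), 1,
                             function(r) eemcc:::.cross3(r[1:3], r[4:6]))))
  gf <- net_force_torque(xyz, f, mf$origin, mf$axes,
                         halve = list(force = FALSE, torque = FALSE))
  expect_equal(gf$force, drop(crossprod(mf$axes, lab_force)),
               tolerance = 1e-10)
  expect_equal(gf$torque, drop(crossprod(mf$axes, lab_tau)),
               tolerance = 1e-10)

  ## uniform field: zero torque about the COM
  funi <- matrix(rep(c(1, -2, 0.5), each = nrow(xyz)), ncol = 3) *
    tpl$masses / mean(tpl$masses)
  ## gravity-like field proportional to mass -> acts through the COM
  gfu <- net_force_torque(xyz, funi, mf$origin, mf$axes,
                          halve = list(force = FALSE, torque = FALSE))
  expect_equal(gfu$torque, rep(0, 3), tolerance = 1e-9)

  ## equal and opposite forces on symmetric atoms: pure torque
  xyz2 <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, 1, 0))
  f2 <- rbind(c(0, 1, 0), c(0, -1, 0), c(0, 0, 0))
  gf2 <- net_force_torque(xyz2, f2, c(0, 1 / 3, 0), diag(3),
                          halve = list(force = FALSE, torque = FALSE))
  expect_equal(gf2$force, rep(0, 3))
  expect_gt(sum(abs(gf2$torque)), 0.5)
})

test_that("halving flags match the mean-field rule by level", {
  expect_equal(halving_rule("M"), list(force = TRUE, torque = TRUE))
  expect_equal(halving_rule("UA"), list(force = FALSE, torque = TRUE))
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  f <- diag(3)
  full <- net_force_torque(xyz, f, c(0, 0, 0), diag(3),
                           halve = list(force = FALSE, torque = FALSE))
  m <- net_force_torque(xyz, f, c(0, 0, 0), diag(3), halve = halving_rule("M"))
  ua <- net_force_torque(xyz, f, c(0, 0, 0), diag(3),
                         halve = halving_rule("UA"))
  expect_equal(m$force, full$force / 2)
  expect_equal(m$torque, full$torque / 2)
  expect_equal(ua$force, full$force)          # UA forces are NOT halved
  expect_equal(ua$torque, full$torque / 2)
  expect_true(m$halved$force && m$halved$torque)
  expect_false(ua$halved$force)
  expect_true(ua$halved$torque)
})

test_that("united-atom axes follow the bond rules and rotate with the frame", {
  tpl <- butanol_template()
  top <- mcc_topology(tpl$masses, tpl$elements, tpl$bonds, list(1:12),
                      species = "solute", sigma = 1)
  xyz <- tpl$xyz

  ## terminal CH3 (UA 1): single heavy neighbour C2 -> axis1 along C1-C2
  ax1 <- ua_axes(xyz, top, 1, 1)
  bond <- (xyz[2, ] - xyz[1, ]) / sqrt(sum((xyz[2, ] - xyz[1, ])^2))
  expect_equal(abs(sum(ax1$axes[, 1] * bond)), 1, tolerance = 1e-10)

  ## mid-chain CH2 (UA 2): axis1 along the C1-C2-C3 bisector
  ax2 <- ua_axes(xyz, top, 1, 2)
  b1 <- (xyz[1, ] - xyz[2, ]) / sqrt(sum((xyz[1, ] - xyz[2, ])^2))
  b2 <- (xyz[3, ] - xyz[2, ]) / sqrt(sum((xyz[3, ] - xyz[2, ])^2))
  bis <- (b1 + b2) / sqrt(sum((b1 + b2)^2))
  expect_equal(abs(sum(ax2$axes[, 1] * bis)), 1, tolerance = 1e-10)
  expect_equal(crossprod(ax2$axes), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)

  ## equivariance
  set.seed(21)
  R <- random_rotation()
  axr <- ua_axes(xyz %*% t(R), top, 1, 2)
  expect_equal(abs(crossprod(axr$axes, R %*% ax2$axes)), diag(3),
               tolerance = 1e-8, ignore_attr = TRUE)
})
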