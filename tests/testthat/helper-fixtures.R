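## Fixture builders shared across the suite. Everything is generated in code;
## geometries are simple rigid templates placed on a lattice with random
## rigid rotations and per-frame jitter, forces are Gaussian noise unless a
## test needs a specific field.

water_template <- function() {
  ## bent triatomic, O at origin, ~0.96 A bonds, ~104.5 deg angle
  list(xyz = rbind(c(0, 0, 0),
                   c(0.7586, 0.5869, 0),
                   c(-0.7586, 0.5869, 0)),
       elements = c("O", "H", "H"),
       masses = c(15.999, 1.008, 1.008),
       bonds = rbind(c(1, 2), c(1, 3)))
}

## n-butanol-like chain CH3-CH2-CH2-OH: 4 united atoms, 1 flexible dihedral
butanol_template <- function() {
  heavy <- rbind(c(0, 0, 0), c(1.45, 0.6, 0), c(2.9, 0, 0), c(4.25, 0.7, 0))
  hpos <- rbind(
    c(-0.6, -0.5, 0.8), c(-0.6, -0.5, -0.8), c(-0.4, 0.9, 0),  # CH3
    c(1.45, 1.3, 0.85), c(1.45, 1.3, -0.85),                   # CH2
    c(2.9, -0.7, 0.85), c(2.9, -0.7, -0.85),                   # CH2
    c(4.9, 0.2, 0.6))                                          # OH
  list(xyz = rbind(heavy, hpos),
       elements = c("C", "C", "C", "O", rep("H", 8)),
       masses = c(12.011, 12.011, 12.011, 15.999, rep(1.008, 8)),
       bonds = rbind(c(1, 2), c(2, 3), c(3, 4),
                     c(1, 5), c(1, 6), c(1, 7),
                     c(2, 8), c(2, 9), c(3, 10), c(3, 11), c(4, 12)))
}

rotation_matrix <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

random_rotation <- function() rotation_matrix(stats::runif(3, 0, 2 * pi))

## Build a liquid box of template molecules. `templates` is a list of
## template/species pairs, one entry per molecule.
make_liquid_box <- function(mol_specs, n_frames, spacing = 5, jitter = 0.05,
                            force_sd = 2, temperature = 298, seed = 1) {
  set.seed(seed)
  n_mol <- length(mol_specs)
  side <- ceiling(n_mol^(1 / 3))
  grid <- as.matrix(expand.grid(seq_len(side), seq_len(side),
                                seq_len(side)))[seq_len(n_mol), , drop = FALSE]
  sites <- (grid - 0.5) * spacing
  box <- rep(side * spacing, 3)

  masses <- c(); elements <- c(); bonds <- NULL; molecules <- list()
  species <- character(n_mol); sigma <- numeric(n_mol)
  base_xyz <- NULL
  offset <- 0L
  rots <- lapply(seq_len(n_mol), function(i) random_rotation())
  for (i in seq_len(n_mol)) {
    tpl <- mol_specs[[i]]$template
    na <- nrow(tpl$xyz)
    masses <- c(masses, tpl$masses)
    elements <- c(elements, tpl$elements)
    bonds <- rbind(bonds, tpl$bonds + offset)
    molecules[[i]] <- offset + seq_len(na)
    species[i] <- mol_specs[[i]]$species
    sigma[i] <- if (species[i] == "water") 2 else 1
    placed <- tpl$xyz %*% t(rots[[i]])
    placed <- sweep(placed, 2, sites[i, ], "+")
    base_xyz <- rbind(base_xyz, placed)
    offset <- offset + na
  }
  topology <- mcc_topology(masses, elements, bonds, molecules, species, sigma)
  n_atoms <- nrow(base_xyz)
  coords <- array(NA_real_, c(n_atoms, 3, n_frames))
  for (f in seq_len(n_frames))
    coords[, , f] <- (base_xyz + matrix(stats::rnorm(n_atoms * 3, 0, jitter),
                                        ncol = 3)) %% rep(box, each = n_atoms)
  forces <- array(stats::rnorm(n_atoms * 3 * n_frames, 0, force_sd),
                  c(n_atoms, 3, n_frames))
  list(topology = topology,
       frames = mcc_frames(coords, forces, box, temperature))
}

water_box <- function(n_water, n_frames, solute = FALSE, seed = 1) {
  specs <- c(
    if (solute) list(list(template = butanol_template(), species = "solute")),
    replicate(n_water, list(template = water_template(), species = "water"),
              simplify = FALSE))
  make_liquid_box(specs, n_frames, spacing = 7, seed = seed)
}

octanol_box <- function(n_oct, n_frames, solute = FALSE, seed = 1) {
  specs <- c(
    if (solute) list(list(template = butanol_template(), species = "solute")),
    replicate(n_oct, list(template = butanol_template(), species = "octanol"),
              simplify = FALSE))
  make_liquid_box(specs, n_frames, spacing = 7, seed = seed)
}

## Minimal single-molecule topologies used in unit tests
methane_topology <- function() {
  mcc_topology(masses = c(12.011, rep(1.008, 4)),
               elements = c("C", rep("H", 4)),
               bonds = cbind(1L, 2:5),
               molecules = list(1:5),
               species = "solute", sigma = 12)
}

water_topology <- function() {
  tpl <- water_template()
  mcc_topology(tpl$masses, tpl$elements, tpl$bonds, list(1:3),
               species = "water", sigma = 2)
}

## heavy-atom chain C8-O with hydrogens omitted (heavy skeleton only)
octanol_skeleton_topology <- function() {
  n <- 9
  mcc_topology(masses = c(rep(12.011, 8), 15.999),
               elements = c(rep("C", 8), "O"),
               bonds = cbind(1:8, 2:9),
               molecules = list(1:9),
               species = "octanol", sigma = 1)
}
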