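#' Synthetic harmonic liquid with exactly known entropy
#'
#' Point-mass "molecules" are tethered to lattice sites by independent
#' isotropic springs. Configurations are exact Boltzmann samples (Gaussian
#' with variance `kB T / k` per coordinate, no integrator, no timestep bias),
#' forces are `-k * displacement` so `F = -grad U` holds exactly, and the
#' energy series is the sampled potential plus a sampled kinetic energy
#' (`0.5 kB T chi^2_{3N}`). The analytic oracle record carries the exact
#' harmonic frequencies `(1/2pi) sqrt(k/m)` and the exact quantum harmonic
#' oscillator entropy.
#'
#' @param n_molecules number of tethered particles
#' @param n_frames number of Boltzmann samples
#' @param spring spring constant(s), kcal mol^-1 Angstrom^-2; recycled over
#'   molecules
#' @param mass particle mass (amu)
#' @param temperature temperature (K)
#' @param seed RNG seed (integer); same spec + seed gives identical output
#' @param species species label(s) for the molecules (recycled)
#' @param energy_offset constant added to every frame's energy (kcal mol^-1)
#' @param spacing lattice spacing (Angstrom)
#' @return list with `topology`, `frames`, `energy` and `oracle` (per-species
#'   exact frequencies `nu` in s^-1, per-molecule QHO entropy `s_qho` in
#'   J K^-1 mol^-1, equipartition mean energy)
#' @export
synth_harmonic_liquid <- function(n_molecules, n_frames, spring, mass = 12,
                                  temperature = 298, seed = 1,
                                  species = "other", energy_offset = 0,
                                  spacing = 10) {
  set.seed(seed)
  spring <- rep_len(spring, n_molecules)
  species <- rep_len(species, n_molecules)
  if (any(spring <= 0)) stop("spring constants must be positive")
  kbt <- KB_KCAL * temperature

  side <- ceiling(n_molecules^(1 / 3))
  grid <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                                z = seq_len(side)))[seq_len(n_molecules), ,
                                                    drop = FALSE]
  sites <- (grid - 0.5) * spacing
  box <- rep(side * spacing, 3)

  sd_per_mol <- sqrt(kbt / spring)
  disp <- array(stats::rnorm(n_molecules * 3 * n_frames),
                c(n_molecules, 3, n_frames)) *
    array(sd_per_mol, c(n_molecules, 3, n_frames))
  coords <- disp + array(sites, c(n_molecules, 3, n_frames))
  forces <- -disp * array(spring, c(n_molecules, 3, n_frames))

  pot <- apply(disp^2 * array(spring, c(n_molecules, 3, n_frames)),
               3, sum) / 2
  kin <- 0.5 * kbt * stats::rchisq(n_frames, df = 3 * n_molecules)
  energy <- mcc_energy(pot + kin + energy_offset, label = "harmonic")

  topology <- mcc_topology(
    masses = rep(mass, n_molecules),
    elements = rep("C", n_molecules),
    bonds = matrix(integer(0), ncol = 2),
    molecules = as.list(seq_len(n_molecules)),
    species = species, sigma = rep(1, n_molecules))

  oracle <- lapply(split(seq_len(n_molecules), species), function(idx) {
    k <- spring[idx[1]]
    nu1 <- sqrt(k / mass * FREQ2_SI) / (2 * pi)
    list(nu = rep(nu1, 3),
         s_qho = as.numeric(qho_entropy(rep(nu1, 3), temperature)),
         n_molecules = length(idx))
  })
  oracle$mean_energy <- 3 * n_molecules * kbt + energy_offset

  list(topology = topology,
       frames = mcc_frames(coords, forces, box, temperature),
       energy = energy, oracle = oracle)
}

#' Translational entropy estimate for tethered harmonic fixtures
#'
#' Pools the mass-weighted force covariance of every molecule of a species
#' into one 3x3 matrix and converts it to a per-molecule quantum harmonic
#' oscillator entropy. No mean-field halving is applied: the restoring force
#' of a tether fixture is external, not shared with neighbouring cells.
#'
#' @param topology,frames fixture pieces from [synth_harmonic_liquid()]
#' @param species species label to pool
#' @return list with `spectrum` (an `mcc_spectrum`) and `s_per_molecule`
#'   (J K^-1 mol^-1)
#' @export
harmonic_entropy_estimate <- function(topology, frames, species) {
  idx <- which(topology$species == species)
  if (!length(idx)) stop("no molecules of species '", species, "'")
  acc <- cov_accumulator(3, "M", "trans")
  w <- 1 / sqrt(topology$masses[idx[1]])
  obs <- frames$forces[idx, , , drop = FALSE]       # n_mol x 3 x n_frames
  obs <- matrix(aperm(obs, c(1, 3, 2)), ncol = 3)   # (mol, frame) rows
  acc <- cov_accumulate_many(acc, obs, weights = rep(w, 3))
  sp <- frequencies_from_covariance(cov_readout(acc), frames$temperature,
                                    "M", "trans")
  list(spectrum = sp,
       s_per_molecule = as.numeric(qho_entropy(sp, frames$temperature)))
}

#' Synthetic multi-state dihedral series with known entropies
#'
#' Draws conformer states independently per frame from the given
#' probabilities and adds wrapped Gaussian angular noise about each well
#' centre. In correlated mode every dihedral after the first copies the
#' first's state (its own well centres still apply), so the joint entropy
#' equals the first dihedral's Shannon entropy.
#'
#' @param n_frames frames to draw
#' @param centers list of numeric vectors: well centres (degrees) per
#'   dihedral
#' @param probs list of probability vectors matching `centers`
#' @param noise_sd angular noise standard deviation (degrees)
#' @param correlated copy the first dihedral's state to all others
#' @param seed RNG seed
#' @return list with `angles` (`n_frames x n_dihedrals`), `states` (true
#'   labels), `truth` (per-dihedral Shannon entropies and the exact joint
#'   entropy, J K^-1 mol^-1)
#' @export
synth_dihedral_chain <- function(n_frames, centers, probs, noise_sd = 12,
                                 correlated = FALSE, seed = 1) {
  stopifnot(length(centers) == length(probs))
  for (p in probs)
    if (abs(sum(p) - 1) > 1e-9) stop("probabilities must be normalized")
  set.seed(seed)
  n_dih <- length(centers)
  states <- matrix(NA_integer_, n_frames, n_dih)
  angles <- matrix(NA_real_, n_frames, n_dih)
  for (d in seq_len(n_dih)) {
    states[, d] <- if (correlated && d > 1) states[, 1]
    else sample.int(length(probs[[d]]), n_frames, replace = TRUE,
                    prob = probs[[d]])
    ang <- centers[[d]][states[, d]] + stats::rnorm(n_frames, 0, noise_sd)
    angles[, d] <- ((ang + 180) %% 360) - 180
  }
  shannon <- function(p) -sum(ifelse(p > 0, p * log(p), 0))
  per_dih <- vapply(probs, shannon, 0) * R_J
  joint_nats <- if (correlated) shannon(probs[[1]])
  else sum(vapply(probs, shannon, 0))
  list(angles = angles, states = states,
       truth = list(shannon = per_dih, joint = joint_nats * R_J))
}

#' Fixed centre-of-mass geometries with hand-verifiable RAD shells
#'
#' Each geometry names a central particle and a neighbour arrangement whose
#' first shell is determined by direct evaluation of the RAD blocking
#' inequality (computed here by an independent double loop, not by
#' [rad_shell()]).
#'
#' @param name one of `"collinear3"`, `"square4"`, `"octahedron6_plus1"`,
#'   `"random_seeded"`
#' @return list with `com` (matrix), `box`, `center` (index 1) and
#'   `expected` (first-shell indices from the direct evaluation)
#' @export
toy_shell_geometry <- function(name = c("collinear3", "square4",
                                        "octahedron6_plus1",
                                        "random_seeded")) {
  name <- match.arg(name)
  box <- rep(100, 3)
  com <- switch(
    name,
    collinear3 = rbind(c(50, 50, 50), c(52, 50, 50), c(54, 50, 50)),
    square4 = rbind(c(50, 50, 50),
                    c(53, 50, 50), c(47, 50, 50),
                    c(50, 53, 50), c(50, 47, 50)),
    octahedron6_plus1 = rbind(c(50, 50, 50),
                              c(53, 50, 50), c(47, 50, 50),
                              c(50, 53, 50), c(50, 47, 50),
                              c(50, 50, 53), c(50, 50, 47),
                              c(55, 50, 50)),
    random_seeded = {
      set.seed(20260926)
      m <- matrix(stats::runif(21 * 3, 40, 60), ncol = 3)
      m[1, ] <- c(50, 50, 50)
      m
    })
  list(com = com, box = box, center = 1L,
       expected = .rad_direct(com, 1L, box))
}

## Direct evaluation of the RAD blocking inequality: walk candidates in
## ascending minimum-image distance and test each against every already-kept
## closer neighbour, with no pre-cut and no sorting shortcuts.
.rad_direct <- function(com, center, box) {
  idx <- setdiff(seq_len(nrow(com)), center)
  d <- sweep(com[idx, , drop = FALSE], 2, com[center, ])
  d <- d - round(d / rep(box, each = nrow(d))) * rep(box, each = nrow(d))
  r <- sqrt(rowSums(d^2))
  ord <- order(r, idx)
  kept <- integer(0)
  for (jj in ord) {
    ok <- TRUE
    for (kk in kept) {
      costh <- sum(d[jj, ] * d[kk, ]) / (r[jj] * r[kk])
      if (1 / r[jj]^2 < costh / r[kk]^2) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, jj)
  }
  sort(idx[kept])
}

#' Four-box harmonic bundle with prescribed transfer thermodynamics
#'
#' Builds solute-in-water, solute-in-octanol, pure-water and pure-octanol
#' analogues as harmonic liquids sharing solvent parameters, so every solvent
#' contribution cancels in the four-box transfer combination. The solute's
#' spring constant in the octanol-like box is chosen (by root finding on the
#' quantum harmonic oscillator entropy) to realise a prescribed entropy
#' change `ds`, and a constant energy offset on the octanol-like solution box
#' realises a prescribed enthalpy change `dh`. The oracle record carries the
#' exact dG and logP implied by the construction.
#'
#' @param n_frames frames per box
#' @param dh prescribed transfer enthalpy (kcal mol^-1)
#' @param ds prescribed transfer entropy (J K^-1 mol^-1)
#' @param n_solvent solvent molecules per box
#' @param temperature temperature (K)
#' @param seed RNG seed; each box uses a distinct sub-seed
#' @param k_solvent,k_solute solvent and aqueous-solute spring constants
#'   (kcal mol^-1 Angstrom^-2)
#' @return list with boxes `x_aq`, `x_oct`, `wat`, `oct` (each a
#'   [synth_harmonic_liquid()] bundle) and `oracle` (`dH`, `dS`, `dG`,
#'   `logP`)
#' @export
synth_composite_solution <- function(n_frames, dh = -1.3643, ds = 0,
                                     n_solvent = 12, temperature = 298,
                                     seed = 1, k_solvent = 40,
                                     k_solute = 25) {
  mass <- 12
  k_oct <- .spring_for_entropy_change(k_solute, ds, mass, temperature)
  mk_box <- function(sub, springs, species, offset = 0)
    synth_harmonic_liquid(length(springs), n_frames, springs, mass = mass,
                          temperature = temperature,
                          seed = seed * 10L + sub, species = species,
                          energy_offset = offset)
  solv <- rep(k_solvent, n_solvent)
  x_aq <- mk_box(1L, c(solv, k_solute), c(rep("water", n_solvent), "solute"))
  x_oct <- mk_box(2L, c(solv, k_oct), c(rep("octanol", n_solvent), "solute"),
                  offset = dh)
  wat <- mk_box(3L, solv, rep("water", n_solvent))
  oct <- mk_box(4L, solv, rep("octanol", n_solvent))
  ds_kcal <- entropy_to_kcal(ds)
  dg <- dh - temperature * ds_kcal
  list(x_aq = x_aq, x_oct = x_oct, wat = wat, oct = oct,
       oracle = list(dH = dh, dS = ds, dG = dg,
                     logP = logp_from_dg(dg, temperature)))
}

## Solve for the spring constant whose per-molecule QHO entropy differs from
## that of k_ref by ds (J/K/mol). Entropy decreases monotonically with k.
.spring_for_entropy_change <- function(k_ref, ds, mass, temperature) {
  if (ds == 0) return(k_ref)
  s_of <- function(k) {
    nu <- rep(sqrt(k / mass * FREQ2_SI) / (2 * pi), 3)
    as.numeric(qho_entropy(nu, temperature))
  }
  target <- s_of(k_ref) + ds
  stats::uniroot(function(k) s_of(k) - target,
                 interval = c(k_ref * 1e-3, k_ref * 1e3),
                 tol = 1e-12)$root
}

#' Recover transfer thermodynamics from a composite harmonic bundle
#'
#' Runs the estimation pipeline on all four boxes of a
#' [synth_composite_solution()] bundle: mean enthalpies from the energy
#' series and per-species translational entropies from pooled mass-weighted
#' force covariances, combined with the four-box transfer signs.
#'
#' @param bundle output of [synth_composite_solution()]
#' @return list with `dH`, `TdS`, `dG` (kcal mol^-1) and `logP`
#' @export
composite_logp <- function(bundle) {
  T <- bundle$x_aq$frames$temperature
  box_S <- function(b) {
    s <- 0
    for (sp in unique(b$topology$species)) {
      est <- harmonic_entropy_estimate(b$topology, b$frames, sp)
      s <- s + sum(b$topology$species == sp) * est$s_per_molecule
    }
    entropy_to_kcal(s)
  }
  G <- function(b) mean_enthalpy(b$energy) - T * box_S(b)
  dG <- (G(bundle$x_oct) + G(bundle$wat)) - (G(bundle$oct) + G(bundle$x_aq))
  dH <- (mean_enthalpy(bundle$x_oct$energy) +
           mean_enthalpy(bundle$wat$energy)) -
    (mean_enthalpy(bundle$oct$energy) + mean_enthalpy(bundle$x_aq$energy))
  list(dH = dH, TdS = dH - dG, dG = dG, logP = logp_from_dg(dG, T))
}
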