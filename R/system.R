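#' Multiscale entropy decomposition of one simulation box
#'
#' Runs the full pipeline on a trajectory with forces: RAD first-shell
#' detection on molecular centres of mass, molecule-level force/torque
#' covariance entropies (mean-field halved, mass/inertia weighted),
#' united-atom covariance entropies (forces unhalved, six lowest
#' translational modes removed), and the topographical terms (positional,
#' orientational from p(Nc), conformational from dihedral conformers).
#' Covariances and conformer statistics are pooled over all molecules of a
#' species: over the first-shell members in a solution box, over every
#' molecule in a pure liquid.
#'
#' @param topology an [mcc_topology()] with species labels assigned
#' @param frames an [mcc_frames()] object (coordinates and forces)
#' @param energy an `mcc_energy` series for the same box (or `NULL` to skip
#'   the enthalpy)
#' @param solvent `"water"` or `"octanol"`
#' @param match_nc for a pure-liquid box, the mean coordination number of the
#'   matching solution box (stoichiometric matching); ignored when the box
#'   contains a solute
#' @param v_standard available volume V0 for the positional term (Angstrom^3);
#'   defaults to the mean box volume
#' @param precut RAD candidate pre-cut radius (Angstrom, speed only)
#' @return an [mcc_system_result()]; attribute `detail` holds the mode
#'   spectra, shell statistics and conformer assignments
#' @export
mcc_box_entropy <- function(topology, frames, energy = NULL,
                            solvent = c("water", "octanol"),
                            match_nc = NULL, v_standard = NULL, precut = 12) {
  solvent <- match.arg(solvent)
  solute_idx <- which(topology$species == "solute")
  if (length(solute_idx) > 1)
    stop("at most one solute molecule is supported")
  has_solute <- length(solute_idx) == 1L
  solv_idx <- which(topology$species == solvent)
  if (!length(solv_idx)) stop("no molecules of solvent species '", solvent, "'")

  box_vol <- mean(apply(frames$box, 1, prod))
  if (is.null(v_standard)) v_standard <- box_vol
  v_solvent <- box_vol / length(solv_idx)
  T <- frames$temperature

  ## ---- shells -------------------------------------------------------------
  if (has_solute) {
    sh_solute <- shell_statistics(frames, topology, center = solute_idx,
                                  precut = precut)
    mean_nc <- sh_solute$mean_nc
    shell_members <- sh_solute$per_frame
  } else {
    if (is.null(match_nc))
      stop("pure-liquid box needs match_nc from the matching solution box")
    mean_nc <- match_nc
    shell_members <- NULL
  }
  sh_solv <- shell_statistics(frames, topology, center = solv_idx,
                              precut = precut)

  ## which solvent molecules contribute to pooled statistics, per frame
  contrib <- function(f) {
    if (is.null(shell_members)) solv_idx
    else intersect(shell_members[[f]], solv_idx)
  }

  ## ---- molecule-level covariances ----------------------------------------
  mol_acc <- function(mols) {
    tr <- cov_accumulator(3, "M", "trans")
    ro <- cov_accumulator(3, "M", "rot")
    prev <- vector("list", length(topology$molecules))
    for (f in seq_len(frames$n_frames)) {
      mset <- if (is.function(mols)) mols(f) else mols
      for (m in mset) {
        idx <- topology$molecules[[m]]
        xyz <- .unwrap_molecule(matrix(frames$coords[idx, , f], ncol = 3),
                                frames$box[f, ])
        mf <- molecule_frame(xyz, topology$masses[idx],
                             prev_axes = prev[[m]])
        prev[[m]] <- mf$axes
        gf <- net_force_torque(xyz, matrix(frames$forces[idx, , f], ncol = 3),
                               mf$origin, mf$axes, halve = halving_rule("M"))
        tr <- cov_accumulate(tr, gf$force,
                             weights = rep(1 / sqrt(sum(topology$masses[idx])), 3))
        mom <- pmax(mf$moments, 1e-12)
        ro <- cov_accumulate(ro, gf$torque, weights = 1 / sqrt(mom))
      }
    }
    list(trans = tr, rot = ro)
  }

  s_M <- function(accs) {
    sp_t <- frequencies_from_covariance(cov_readout(accs$trans), T, "M", "trans")
    sp_r <- frequencies_from_covariance(cov_readout(accs$rot), T, "M", "rot")
    list(transvib = as.numeric(qho_entropy(sp_t, T)),
         rovib = as.numeric(qho_entropy(sp_r, T)),
         spectra = list(trans = sp_t, rot = sp_r))
  }

  solv_M <- s_M(mol_acc(contrib))
  detail <- list(shells_solvent = sh_solv, solvent_M_spectra = solv_M$spectra)

  breakdown <- c(solv.M.transvib = solv_M$transvib,
                 solv.M.rovib = solv_M$rovib,
                 solv.or = as.numeric(orientational_entropy(
                   sh_solv$p_nc, sigma = topology$sigma[solv_idx[1]],
                   is_water = solvent == "water")))

  ## ---- united-atom level + conformers for octanol solvent -----------------
  if (solvent == "octanol") {
    ua_solv <- .species_ua_entropy(topology, frames, contrib, T)
    conf_solv <- .species_conf_entropy(topology, frames, contrib)
    breakdown <- c(breakdown,
                   solv.UA.transvib = ua_solv$transvib,
                   solv.UA.rovib = ua_solv$rovib,
                   solv.conf = conf_solv)
    detail$solvent_UA_spectra <- ua_solv$spectra
  }

  ## ---- solute terms -------------------------------------------------------
  if (has_solute) {
    sol_M <- s_M(mol_acc(solute_idx))
    ua_sol <- .species_ua_entropy(topology, frames,
                                  function(f) solute_idx, T)
    conf_sol <- .species_conf_entropy(topology, frames,
                                      function(f) solute_idx)
    breakdown <- c(breakdown,
                   X.M.transvib = sol_M$transvib,
                   X.M.rovib = sol_M$rovib,
                   X.pos = as.numeric(positional_entropy(v_standard, v_solvent)),
                   X.or = as.numeric(orientational_entropy(
                     sh_solute$p_nc, sigma = topology$sigma[solute_idx],
                     is_water = FALSE)),
                   X.UA.transvib = ua_sol$transvib,
                   X.UA.rovib = ua_sol$rovib,
                   X.conf = conf_sol)
    detail$shells_solute <- sh_solute
    detail$solute_M_spectra <- sol_M$spectra
    detail$solute_UA_spectra <- ua_sol$spectra
  }

  res <- mcc_system_result(
    label = if (has_solute) {
      if (solvent == "water") "X(aq)" else "X(oct)"
    } else {
      if (solvent == "water") "wat" else "oct"
    },
    enthalpy = if (is.null(energy)) NA_real_ else mean_enthalpy(energy),
    breakdown = breakdown, mean_nc = mean_nc, temperature = T,
    solvent = solvent, has_solute = has_solute)
  attr(res, "detail") <- detail
  res
}

## Pooled united-atom covariance entropies for molecules of one species.
## Forces are expressed in UA body axes and are NOT halved (UA correlations
## are carried explicitly); torques are halved and use the UA rotational
## axes with their per-frame moments of inertia. Molecules with fewer than
## two UAs carry no united-atom entropy (the level is degenerate with the
## molecule level).
.species_ua_entropy <- function(topology, frames, contrib, T) {
  probe <- if (is.function(contrib)) {
    m <- NULL
    for (f in seq_len(frames$n_frames)) {
      set <- contrib(f)
      if (length(set)) { m <- set[1]; break }
    }
    m
  } else contrib[1]
  if (is.null(probe))
    return(list(transvib = 0, rovib = 0, spectra = NULL))
  n_ua <- length(topology$united_atoms[[probe]])
  dof <- united_atom_dof(topology, probe)
  n_rot <- sum(dof[, "n_rot"])
  if (n_ua < 2)
    return(list(transvib = 0, rovib = 0, spectra = NULL))

  tr <- cov_accumulator(3L * n_ua, "UA", "trans")
  ro <- if (n_rot > 0) cov_accumulator(n_rot, "UA", "rot") else NULL
  prev_t <- list(); prev_r <- list()
  for (f in seq_len(frames$n_frames)) {
    mset <- if (is.function(contrib)) contrib(f) else contrib
    for (m in mset) {
      idx <- topology$molecules[[m]]
      key <- as.character(m)
      xyz_all <- matrix(NA_real_, length(topology$masses), 3)
      xyz_all[idx, ] <- .unwrap_molecule(matrix(frames$coords[idx, , f],
                                                ncol = 3),
                                         frames$box[f, ])
      fvec <- numeric(3L * n_ua)
      wvec <- numeric(3L * n_ua)
      tvec <- numeric(n_rot)
      twv <- numeric(n_rot)
      if (is.null(prev_t[[key]])) {
        prev_t[[key]] <- vector("list", n_ua)
        prev_r[[key]] <- vector("list", n_ua)
      }
      rpos <- 0L
      for (u in seq_len(n_ua)) {
        uat <- topology$united_atoms[[m]][[u]]
        ax <- ua_axes(xyz_all, topology, m, u, prev_axes = prev_t[[key]][[u]])
        prev_t[[key]][[u]] <- ax$axes
        gf <- net_force_torque(xyz_all[uat, , drop = FALSE],
                               matrix(frames$forces[uat, , f], ncol = 3),
                               ax$origin, ax$axes,
                               halve = halving_rule("UA"))
        sl <- (3L * (u - 1L) + 1L):(3L * u)
        fvec[sl] <- gf$force
        wvec[sl] <- 1 / sqrt(sum(topology$masses[uat]))
        nr <- dof[u, "n_rot"]
        if (nr > 0) {
          rf <- .ua_rot_frame(xyz_all, topology, m, u, nr,
                              prev_axes = prev_r[[key]][[u]])
          prev_r[[key]][[u]] <- rf$axes
          gt <- net_force_torque(xyz_all[uat, , drop = FALSE],
                                 matrix(frames$forces[uat, , f], ncol = 3),
                                 rf$origin, cbind(rf$axes,
                                                  matrix(0, 3, 3 - nr)),
                                 halve = halving_rule("UA"))
          tvec[rpos + seq_len(nr)] <- gt$torque[seq_len(nr)]
          twv[rpos + seq_len(nr)] <- 1 / sqrt(pmax(rf$moments, 1e-12))
          rpos <- rpos + nr
        }
      }
      tr <- cov_accumulate(tr, fvec, weights = wvec)
      if (!is.null(ro)) ro <- cov_accumulate(ro, tvec, weights = twv)
    }
  }
  sp_t <- frequencies_from_covariance(cov_readout(tr), T, "UA", "trans")
  sp_t <- remove_lowest_modes(sp_t, 6L)
  s_t <- as.numeric(qho_entropy(sp_t, T))
  if (!is.null(ro)) {
    sp_r <- frequencies_from_covariance(cov_readout(ro), T, "UA", "rot")
    s_r <- as.numeric(qho_entropy(sp_r, T))
  } else {
    sp_r <- NULL; s_r <- 0
  }
  list(transvib = s_t, rovib = s_r, spectra = list(trans = sp_t, rot = sp_r))
}

## Pooled conformational entropy for molecules of one species: per-dihedral
## angle series are stacked over all contributing (molecule, frame)
## observations, conformers assigned on the pooled histogram, and the
## conformer correlation matrix built over co-occurrence within a
## molecule-frame.
.species_conf_entropy <- function(topology, frames, contrib) {
  probe_set <- unique(unlist(lapply(seq_len(frames$n_frames), function(f)
    if (is.function(contrib)) contrib(f) else contrib)))
  if (!length(probe_set)) return(0)
  n_dih <- nrow(topology$flexible_dihedrals[[probe_set[1]]])
  if (!n_dih) return(0)
  angles_by_mol <- lapply(probe_set, function(m)
    dihedral_angles(frames, topology, m))
  names(angles_by_mol) <- as.character(probe_set)
  rows <- list()
  for (f in seq_len(frames$n_frames)) {
    mset <- if (is.function(contrib)) contrib(f) else contrib
    for (m in mset)
      rows[[length(rows) + 1L]] <- angles_by_mol[[as.character(m)]][f, ]
  }
  stacked <- do.call(rbind, rows)
  confs <- lapply(seq_len(n_dih), function(k)
    suppressWarnings(assign_conformers(stacked[, k])))
  as.numeric(conformational_entropy(confs))
}

#' @export
print.mcc_system_result <- function(x, ...) {
  cat(sprintf("mcc_system_result '%s' (%s%s) at %.1f K\n", x$label,
              x$solvent, if (x$has_solute) " + solute" else "",
              x$temperature))
  if (!is.na(x$enthalpy))
    cat(sprintf("  H = %.3f kcal/mol\n", x$enthalpy))
  cat(sprintf("  mean Nc = %.3f\n", x$mean_nc))
  cat("  entropy components (J/K/mol):\n")
  print(round(x$breakdown, 3))
  s <- solution_entropy(x)
  cat(sprintf("  total S = %.3f J/K/mol (%.5f kcal/mol/K)\n",
              as.numeric(s), attr(s, "kcal")))
  invisible(x)
}
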