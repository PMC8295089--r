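#' Positional entropy from volume discretisation
#'
#' The volume available to a dilute solute at its standard concentration is
#' discretised by the molecular volume of the solvent:
#' `S_pos = kB ln(V0 / V_solvent)`. `V_solvent` is the volume of a pure
#' solvent box divided by its number of molecules. In a transfer between two
#' solvents `V0` cancels, leaving `delta S_pos = kB ln(V_solvent,A /
#' V_solvent,B)`.
#'
#' @param v_standard available volume `V0` (Angstrom^3)
#' @param v_solvent per-molecule solvent volume (Angstrom^3)
#' @return entropy in J K^-1 mol^-1 (attribute `kcal` in kcal mol^-1 K^-1)
#' @export
positional_entropy <- function(v_standard, v_solvent) {
  if (v_standard <= 0 || v_solvent <= 0) stop("volumes must be positive")
  s_kcal <- KB_KCAL * log(v_standard / v_solvent)
  structure(entropy_to_joules(s_kcal), kcal = s_kcal)
}

#' Orientational entropy from coordination-number statistics
#'
#' Each coordination number `Nc` admits `(Nc^3 pi)^(1/2) / sigma`
#' distinguishable orientations, clamped below at 1 so the count is never
#' fractional downward; for water an extra factor 1/4 multiplies the count
#' inside the logarithm (before clamping) to account for hydrogen-bond
#' directionality. The entropy is the `p(Nc)`-weighted average:
#' `S_or = kB sum_Nc p(Nc) ln(max(1, omega(Nc)))`.
#'
#' @param p_nc named numeric vector: probabilities indexed by Nc (names), or
#'   an `mcc_shells` object
#' @param sigma molecular symmetry number (>= 1); 2 for water
#' @param is_water apply the 1/4 hydrogen-bond correlation factor
#' @return entropy in J K^-1 mol^-1 (attribute `kcal`)
#' @export
orientational_entropy <- function(p_nc, sigma = 1, is_water = FALSE) {
  if (inherits(p_nc, "mcc_shells")) p_nc <- p_nc$p_nc
  if (sigma < 1) stop("symmetry number must be >= 1")
  nc <- as.numeric(names(p_nc))
  if (any(is.na(nc)) || any(nc < 0)) stop("invalid coordination numbers")
  if (abs(sum(p_nc) - 1) > 1e-9) stop("p(Nc) must be normalized")
  omega <- sqrt(nc^3 * pi) / sigma
  if (is_water) omega <- omega / 4
  s_kcal <- KB_KCAL * sum(p_nc * log(pmax(1, omega)))
  structure(entropy_to_joules(s_kcal), kcal = s_kcal)
}

#' Dihedral angles over a trajectory
#'
#' Standard signed torsion about the b-c bond of each a-b-c-d quadruple,
#' computed per frame with molecule-local unwrapping.
#'
#' @param frames an [mcc_frames()] object
#' @param topology an [mcc_topology()]
#' @param molecule molecule index
#' @return matrix `n_frames x n_dihedrals` of angles in degrees in
#'   `[-180, 180)`
#' @export
dihedral_angles <- function(frames, topology, molecule) {
  dh <- topology$flexible_dihedrals[[molecule]]
  idx <- topology$molecules[[molecule]]
  out <- matrix(NA_real_, frames$n_frames, nrow(dh))
  if (!nrow(dh)) return(out)
  for (f in seq_len(frames$n_frames)) {
    un <- .unwrap_molecule(matrix(frames$coords[idx, , f], ncol = 3),
                           frames$box[f, ])
    pos <- matrix(NA_real_, length(topology$masses), 3)
    pos[idx, ] <- un
    for (k in seq_len(nrow(dh)))
      out[f, k] <- .torsion(pos[dh[k, 1], ], pos[dh[k, 2], ],
                            pos[dh[k, 3], ], pos[dh[k, 4], ])
  }
  out
}

.torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang >= 180) ang - 360 else ang
}

#' Assign conformer states from a dihedral angle series
#'
#' Conformers are the maxima of the angle's probability distribution: a
#' periodic histogram (default 72 bins of 5 degrees) is smoothed with a
#' 3-bin circular moving average; local maxima above a 1% occupancy floor
#' become conformers, with boundaries at the minima between adjacent maxima.
#' Each frame is labelled by its enclosing interval.
#'
#' Series shorter than 50 frames are marked rigid (a single conformer), since
#' well detection is unreliable there.
#'
#' @param angles numeric vector of angles in degrees (periodic)
#' @param n_bins histogram bins over `[-180, 180)`
#' @return object of class `mcc_conformers`: list with `labels` (integer per
#'   frame, 1-based), `n_conformers`, `p` (marginal conformer probabilities),
#'   `boundaries` (degrees), `rigid` flag
#' @export
assign_conformers <- function(angles, n_bins = 72) {
  angles <- ((angles + 180) %% 360) - 180
  n <- length(angles)
  if (n < 50) {
    warning("fewer than 50 frames; marking dihedral rigid")
    return(structure(list(labels = rep(1L, n), n_conformers = 1L,
                          p = 1, boundaries = numeric(0), rigid = TRUE),
                     class = "mcc_conformers"))
  }
  width <- 360 / n_bins
  bin <- pmin(floor((angles + 180) / width) + 1L, n_bins)
  counts <- tabulate(bin, n_bins)
  sm <- (counts + counts[c(n_bins, seq_len(n_bins - 1))] +
           counts[c(seq_len(n_bins - 1) + 1, 1)]) / 3
  floor_count <- 0.01 * n
  left <- sm[c(n_bins, seq_len(n_bins - 1))]
  right <- sm[c(seq_len(n_bins - 1) + 1, 1)]
  is_max <- sm >= left & sm >= right & sm > floor_count
  ## plateaus: keep only the first bin of any run of equal smoothed counts
  maxima <- which(is_max)
  if (length(maxima) > 1) {
    keep <- c(TRUE, diff(maxima) > 1 |
                sm[maxima[-length(maxima)]] != sm[maxima[-1]])
    run_start <- maxima[keep]
    drop <- logical(length(maxima))
    for (i in seq_along(maxima)[-1])
      if (maxima[i] - maxima[i - 1] == 1 && sm[maxima[i]] == sm[maxima[i - 1]])
        drop[i] <- TRUE
    maxima <- maxima[!drop]
  }
  if (length(maxima) <= 1) {
    return(structure(list(labels = rep(1L, n), n_conformers = 1L,
                          p = 1, boundaries = numeric(0), rigid = FALSE),
                     class = "mcc_conformers"))
  }
  ## boundary between adjacent maxima = deepest minimum between them
  # (circular: also between the last and first maxima)
  k <- length(maxima)
  bounds_bin <- integer(k)
  for (i in seq_len(k)) {
    a <- maxima[i]
    b <- if (i < k) maxima[i + 1] else maxima[1] + n_bins
    seg <- ((a:(b - 1)) - 1) %% n_bins + 1
    seg <- seg[-1]
    if (!length(seg)) seg <- a
    bounds_bin[i] <- seg[which.min(sm[seg])]
  }
  boundaries <- sort((bounds_bin - 0.5) * width - 180)  # left edge of min bin
  ## label frames by enclosing interval between consecutive boundaries
  lab <- findInterval(angles, boundaries)
  lab[lab == 0L] <- length(boundaries)        # wrap below first boundary
  labs <- sort(unique(lab))
  labels <- match(lab, labs)
  p <- as.numeric(table(factor(labels, levels = seq_along(labs)))) / n
  structure(list(labels = labels, n_conformers = length(labs),
                 p = p, boundaries = boundaries, rigid = FALSE),
            class = "mcc_conformers")
}

#' Conformational entropy from the dihedral-conformer correlation matrix
#'
#' Builds the `N_conf x N_conf` matrix over all (dihedral, conformer) pairs
#' of a molecule: diagonal entries are marginal conformer probabilities,
#' off-diagonal entries between conformers of *different* dihedrals are the
#' symmetrized joint co-occurrence probabilities, and entries between
#' distinct conformers of the *same* dihedral are zero. Eigenvalues are
#' clipped at zero and renormalized to sum to one, then
#' `S_conf = kB sum_i lambda_i ln(1/lambda_i)`. For a single dihedral this
#' reduces to the Shannon entropy of its conformer distribution; perfectly
#' correlated dihedrals are not double-counted.
#'
#' @param conformers list of `mcc_conformers`, one per flexible dihedral,
#'   with labels over the same frames
#' @return entropy in J K^-1 mol^-1 (attribute `kcal`; attribute
#'   `eigenvalues` holds the normalized spectrum)
#' @export
conformational_entropy <- function(conformers) {
  if (!length(conformers))
    return(structure(0, kcal = 0, eigenvalues = numeric(0)))
  if (inherits(conformers, "mcc_conformers")) conformers <- list(conformers)
  n_frames <- length(conformers[[1]]$labels)
  kcounts <- vapply(conformers, function(cs) cs$n_conformers, 0L)
  n_conf <- sum(kcounts)
  offset <- cumsum(c(0L, kcounts[-length(kcounts)]))
  M <- matrix(0, n_conf, n_conf)
  for (d in seq_along(conformers))
    for (a in seq_len(kcounts[d]))
      M[offset[d] + a, offset[d] + a] <- conformers[[d]]$p[a]
  if (length(conformers) > 1) {
    for (d1 in seq_len(length(conformers) - 1))
      for (d2 in (d1 + 1):length(conformers)) {
        l1 <- conformers[[d1]]$labels
        l2 <- conformers[[d2]]$labels
        joint <- table(factor(l1, levels = seq_len(kcounts[d1])),
                       factor(l2, levels = seq_len(kcounts[d2]))) / n_frames
        for (a in seq_len(kcounts[d1]))
          for (b in seq_len(kcounts[d2])) {
            M[offset[d1] + a, offset[d2] + b] <- joint[a, b]
            M[offset[d2] + b, offset[d1] + a] <- joint[a, b]
          }
      }
  }
  if (sum(diag(M)) <= 0) stop("unnormalizable conformer matrix")
  lam <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  lam <- lam / sum(lam)
  s_kcal <- KB_KCAL * sum(ifelse(lam > 0, lam * log(1 / lam), 0))
  structure(entropy_to_joules(s_kcal), kcal = s_kcal, eigenvalues = lam)
}
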