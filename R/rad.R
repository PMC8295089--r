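#' Per-molecule centres of mass under the minimum-image convention
#'
#' Atoms of each molecule are first unwrapped relative to the molecule's
#' first atom (each displacement mapped into `[-L/2, L/2)` per axis), then
#' mass-averaged; the result is wrapped back into the primary box `[0, L)`.
#'
#' @param coords `n_atoms x 3` coordinate matrix for one frame (Angstrom)
#' @param topology an [mcc_topology()]
#' @param box length-3 vector of box lengths (Angstrom)
#' @return `n_molecules x 3` matrix of COM positions
#' @export
centers_of_mass <- function(coords, topology, box) {
  if (any(topology$masses <= 0)) stop("masses must be positive")
  n_mol <- length(topology$molecules)
  out <- matrix(NA_real_, n_mol, 3)
  for (m in seq_len(n_mol)) {
    idx <- topology$molecules[[m]]
    un <- .unwrap_molecule(coords[idx, , drop = FALSE], box)
    w <- topology$masses[idx]
    out[m, ] <- colSums(un * w) / sum(w)
  }
  out %% matrix(box, n_mol, 3, byrow = TRUE)
}

## Unwrap a molecule's atoms relative to its first atom. Fails if any atom
## ends up more than half a box length from the reference on any axis.
.unwrap_molecule <- function(xyz, box) {
  ref <- xyz[1, ]
  d <- sweep(xyz, 2, ref)
  d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
  extent <- apply(d, 2, max) - apply(d, 2, min)
  if (any(extent > box / 2))
    stop("geometry error: molecule spans more than half the box")
  sweep(d, 2, ref, "+")
}

.min_image <- function(d, box) d - round(d / box) * box

#' First solvation shell by the Relative Angular Distance criterion
#'
#' Candidates are sorted by ascending minimum-image COM distance from the
#' central molecule. A candidate `j` is accepted into the shell unless some
#' already-accepted closer neighbour `k` blocks it, i.e. unless
#' `1/r_ij^2 < (1/r_ik^2) * cos(theta_jik)` where `theta_jik` is the angle at
#' the centre between the directions to `j` and `k`. The criterion is
#' parameter-free: nearer neighbours cast angular "shadows" on farther ones.
#'
#' @param com `n x 3` matrix of molecular COM positions
#' @param center 1-based row index of the central molecule
#' @param box length-3 box vector (Angstrom)
#' @param candidates optional integer vector restricting the neighbour pool
#'   (used as a distance pre-cut; must never exclude an acceptable neighbour)
#' @return sorted integer vector of first-shell molecule indices
#' @export
rad_shell <- function(com, center, box, candidates = NULL) {
  n <- nrow(com)
  if (is.null(candidates)) candidates <- setdiff(seq_len(n), center)
  candidates <- setdiff(candidates, center)
  if (!length(candidates)) stop("need at least one candidate neighbour")
  disp <- .min_image(sweep(com[candidates, , drop = FALSE], 2, com[center, ]),
                     matrix(box, length(candidates), 3, byrow = TRUE))
  r <- sqrt(rowSums(disp^2))
  if (any(r == 0)) stop("degenerate geometry: coincident centres of mass")
  ord <- order(r, candidates)                 # distance, ties by index
  disp <- disp[ord, , drop = FALSE]
  r <- r[ord]
  candidates <- candidates[ord]
  accepted <- integer(0)
  for (j in seq_along(candidates)) {
    blocked <- FALSE
    for (k in accepted) {
      cosang <- sum(disp[j, ] * disp[k, ]) / (r[j] * r[k])
      if (1 / r[j]^2 < cosang / r[k]^2) { blocked <- TRUE; break }
    }
    if (!blocked) accepted <- c(accepted, j)
  }
  sort(candidates[accepted])
}

## Distance pre-cut for rad_shell: everything within `cut` of the centre.
## Falls back to all molecules when fewer than 2 fall inside.
.rad_candidates <- function(com, center, box, cut = 12) {
  disp <- .min_image(sweep(com, 2, com[center, ]),
                     matrix(box, nrow(com), 3, byrow = TRUE))
  r2 <- rowSums(disp^2)
  idx <- setdiff(which(r2 <= cut^2), center)
  if (length(idx) < 2L) idx <- setdiff(seq_len(nrow(com)), center)
  idx
}

#' Coordination-number statistics over a trajectory
#'
#' Accumulates the RAD first-shell size `Nc` of the selected central
#' molecule(s) over all frames into the empirical distribution `p(Nc)`.
#' For a species selector, shells of every molecule of that species are
#' pooled over all frames (pure-liquid averaging over all molecules gives
#' better statistics than tracking a single one).
#'
#' @param frames an [mcc_frames()] object
#' @param topology an [mcc_topology()]
#' @param center `"solute"` (the unique solute molecule) or
#'   `"species:<label>"` (all molecules of a species), or an integer vector of
#'   molecule indices
#' @param precut candidate pre-cut radius in Angstrom (speed only; the shell
#'   itself is parameter-free)
#' @return object of class `mcc_shells`: list with `p_nc` (named probability
#'   vector over Nc), `mean_nc`, `per_frame` (list of shell index sets for a
#'   single-centre selector, else `NULL`), `n_obs`
#' @export
shell_statistics <- function(frames, topology, center = "solute", precut = 12) {
  if (frames$n_frames < 1L) stop("empty frame set")
  centers_fixed <- .resolve_centers(topology, center)
  single <- length(centers_fixed) == 1L
  counts <- integer(0)
  per_frame <- if (single) vector("list", frames$n_frames) else NULL
  for (f in seq_len(frames$n_frames)) {
    com <- centers_of_mass(frames$coords[, , f], topology, frames$box[f, ])
    for (cm in centers_fixed) {
      cand <- .rad_candidates(com, cm, frames$box[f, ], cut = precut)
      shell <- rad_shell(com, cm, frames$box[f, ], candidates = cand)
      nc <- length(shell)
      key <- as.character(nc)
      counts[key] <- if (is.na(counts[key])) 1L else counts[key] + 1L
      if (single) per_frame[[f]] <- shell
    }
  }
  nc_vals <- as.integer(names(counts))
  ord <- order(nc_vals)
  p <- counts[ord] / sum(counts)
  names(p) <- nc_vals[ord]
  structure(list(p_nc = p,
                 mean_nc = sum(nc_vals[ord] * p),
                 per_frame = per_frame,
                 n_obs = sum(counts)),
            class = "mcc_shells")
}

.resolve_centers <- function(topology, center) {
  if (is.numeric(center)) return(as.integer(center))
  if (identical(center, "solute")) {
    idx <- which(topology$species == "solute")
    if (length(idx) != 1L)
      stop("center='solute' requires exactly one solute molecule, found ",
           length(idx))
    return(idx)
  }
  if (startsWith(center, "species:")) {
    lab <- sub("^species:", "", center)
    idx <- which(topology$species == lab)
    if (!length(idx)) stop("no molecules of species '", lab, "'")
    return(idx)
  }
  stop("unknown center selector: ", center)
}

#' @export
print.mcc_shells <- function(x, ...) {
  cat(sprintf("mcc_shells: mean Nc = %.3f over %d observations\n",
              x$mean_nc, x$n_obs))
  print(round(x$p_nc, 4))
  invisible(x)
}
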