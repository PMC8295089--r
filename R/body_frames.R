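#' Molecule body frame from the inertia tensor
#'
#' The molecular reference frame has its origin at the centre of mass and its
#' axes along the principal axes of inertia, ordered by ascending moment.
#' Eigenvector signs are fixed by flipping each axis so its largest-magnitude
#' component is positive; the third axis is then replaced by the cross product
#' of the first two so the frame is always right-handed. When `prev_axes` is
#' supplied, the first two axes are additionally sign-matched to the previous
#' frame before the cross product, which prevents spurious covariance from
#' axis flips when two moments are nearly degenerate.
#'
#' @param xyz `n x 3` unwrapped coordinates of the molecule's atoms
#' @param masses atomic masses (amu)
#' @param prev_axes optional `3 x 3` axis matrix (columns) from the previous
#'   frame for continuity matching
#' @return list with `origin` (COM), `axes` (3x3, columns are unit axes),
#'   `moments` (amu Angstrom^2, ascending)
#' @export
molecule_frame <- function(xyz, masses, prev_axes = NULL) {
  com <- colSums(xyz * masses) / sum(masses)
  rel <- sweep(xyz, 2, com)
  ## collinearity check: rank of the centred coordinates
  if (nrow(xyz) < 3 || qr(rel)$rank < 2)
    stop("unsupported geometry: molecule is collinear (or fewer than 3 atoms)")
  r2 <- rowSums(rel^2)
  inertia <- diag(sum(masses * r2), 3) -
    t(rel * masses) %*% rel
  e <- eigen(inertia, symmetric = TRUE)
  ord <- order(e$values)                       # ascending moments
  moments <- pmax(e$values[ord], 0)
  axes <- e$vectors[, ord, drop = FALSE]
  for (i in 1:2) {
    if (axes[which.max(abs(axes[, i])), i] < 0) axes[, i] <- -axes[, i]
    if (!is.null(prev_axes) && sum(axes[, i] * prev_axes[, i]) < 0)
      axes[, i] <- -axes[, i]
  }
  axes[, 3] <- .cross3(axes[, 1], axes[, 2])
  list(origin = com, axes = axes, moments = moments)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Translational and rotational degrees of freedom of each united atom
#'
#' Every united atom translates in 3 dimensions. Its rotational degrees of
#' freedom are set by its hydrogen count: 3 when non-linear (two or more
#' hydrogens), 2 when linear (exactly one hydrogen), 0 when it is a point
#' (no hydrogens).
#'
#' @param topology an [mcc_topology()]
#' @param molecule molecule index
#' @return integer matrix with columns `n_trans`, `n_rot`, one row per UA
#' @export
united_atom_dof <- function(topology, molecule) {
  uas <- topology$united_atoms[[molecule]]
  n_h <- vapply(uas, function(u) sum(topology$elements[u[-1]] == "H"), 0L)
  cbind(n_trans = rep(3L, length(uas)),
        n_rot = ifelse(n_h >= 2L, 3L, ifelse(n_h == 1L, 2L, 0L)))
}

#' United-atom axes from covalent bonds to heavy atoms
#'
#' The UA origin is its heavy atom. With two or more heavy neighbours, the
#' first axis is the bisector of the two bond vectors (lowest atom indices),
#' the second lies in their plane orthogonal to the first, the third is their
#' cross product. With exactly one heavy neighbour the first axis is along
#' that bond and the second is a deterministic perpendicular built from the
#' least-aligned Cartesian axis. With none, the molecule frame is used.
#'
#' @param xyz `n_atoms x 3` unwrapped coordinates of the whole system or
#'   molecule (indexed by absolute atom index)
#' @param topology an [mcc_topology()]
#' @param molecule molecule index
#' @param ua UA index within the molecule
#' @param prev_axes optional previous-frame axes for sign continuity
#' @return list with `origin`, `axes` (3x3 columns)
#' @export
ua_axes <- function(xyz, topology, molecule, ua, prev_axes = NULL) {
  u <- topology$united_atoms[[molecule]][[ua]]
  heavy <- u[1]
  nbrs <- topology$adjacency[[heavy]]
  hn <- nbrs[topology$elements[nbrs] != "H"]
  origin <- xyz[heavy, ]
  if (length(hn) >= 2L) {
    b1 <- .unit(xyz[hn[1], ] - origin)
    b2 <- .unit(xyz[hn[2], ] - origin)
    a1 <- .unit(b1 + b2)
    a2 <- .unit(b1 - sum(b1 * a1) * a1)
    axes <- cbind(a1, a2, .cross3(a1, a2))
  } else if (length(hn) == 1L) {
    a1 <- .unit(xyz[hn[1], ] - origin)
    pick <- which.min(abs(a1))                 # least-aligned Cartesian axis
    e <- c(0, 0, 0); e[pick] <- 1
    a2 <- .unit(e - sum(e * a1) * a1)
    axes <- cbind(a1, a2, .cross3(a1, a2))
  } else {
    idx <- topology$molecules[[molecule]]
    mf <- molecule_frame(xyz[idx, , drop = FALSE], topology$masses[idx],
                         prev_axes = prev_axes)
    return(list(origin = mf$origin, axes = mf$axes))
  }
  if (!is.null(prev_axes)) {
    for (i in 1:2) if (sum(axes[, i] * prev_axes[, i]) < 0)
      axes[, i] <- -axes[, i]
    axes[, 3] <- .cross3(axes[, 1], axes[, 2])
  }
  dimnames(axes) <- NULL
  list(origin = origin, axes = axes)
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("degenerate geometry: zero-length axis vector")
  v / n
}

#' Net force and torque of a rigid unit in its body frame
#'
#' The net force is the sum of the unit's atomic forces rotated into the body
#' axes; the torque is `sum((r_atom - origin) x F_atom)` rotated likewise.
#' Mean-field halving is applied via `halve`: molecule-level forces and
#' torques and UA-level torques are halved; UA-level forces are not, because
#' UA correlations are carried explicitly in the molecule reference frame.
#'
#' @param xyz unwrapped coordinates of the unit's atoms (`n x 3`)
#' @param f forces on the unit's atoms (`n x 3`)
#' @param origin body-frame origin
#' @param axes `3 x 3` body axes (columns)
#' @param halve list with logical `force` and `torque`
#' @return list with `force` (3-vector), `torque` (3-vector), `halved`
#'   (the halving flags actually applied)
#' @export
net_force_torque <- function(xyz, f, origin, axes,
                             halve = list(force = TRUE, torque = TRUE)) {
  ftot <- colSums(f)
  rel <- sweep(xyz, 2, origin)
  tau <- c(sum(rel[, 2] * f[, 3] - rel[, 3] * f[, 2]),
           sum(rel[, 3] * f[, 1] - rel[, 1] * f[, 3]),
           sum(rel[, 1] * f[, 2] - rel[, 2] * f[, 1]))
  fb <- drop(crossprod(axes, ftot))
  tb <- drop(crossprod(axes, tau))
  if (isTRUE(halve$force)) fb <- fb / 2
  if (isTRUE(halve$torque)) tb <- tb / 2
  list(force = fb, torque = tb,
       halved = list(force = isTRUE(halve$force),
                     torque = isTRUE(halve$torque)))
}

#' Mean-field halving convention by level and motion
#'
#' @param level `"M"` (molecule) or `"UA"` (united atom)
#' @return list with logical `force` and `torque` flags
#' @export
halving_rule <- function(level = c("M", "UA")) {
  level <- match.arg(level)
  if (level == "M") list(force = TRUE, torque = TRUE)
  else list(force = FALSE, torque = TRUE)
}

## Rotational axes and moments used for UA torque weighting. For a non-linear
## UA (>= 2 H) the bond-derived ua_axes are used; for a linear UA (1 H) the
## rotation about the heavy-H axis carries no inertia, so the two torque axes
## are deterministic perpendiculars to that axis.
.ua_rot_frame <- function(xyz, topology, molecule, ua, n_rot,
                          prev_axes = NULL) {
  u <- topology$united_atoms[[molecule]][[ua]]
  heavy <- u[1]
  origin <- xyz[heavy, ]
  if (n_rot == 0L) return(NULL)
  if (n_rot == 2L) {
    hyd <- u[-1][topology$elements[u[-1]] == "H"]
    a1 <- .unit(xyz[hyd[1], ] - origin)
    pick <- which.min(abs(a1))
    e <- c(0, 0, 0); e[pick] <- 1
    a2 <- .unit(e - sum(e * a1) * a1)
    a3 <- .cross3(a1, a2)
    axes <- cbind(a2, a3)                      # both perpendicular to heavy-H
  } else {
    axes <- ua_axes(xyz, topology, molecule, ua, prev_axes = prev_axes)$axes
  }
  if (!is.null(prev_axes) && n_rot == 2L) {
    for (i in 1:2) if (sum(axes[, i] * prev_axes[, i]) < 0)
      axes[, i] <- -axes[, i]
  }
  rel <- sweep(xyz[u, , drop = FALSE], 2, origin)
  m <- topology$masses[u]
  moments <- apply(axes, 2, function(a)
    sum(m * (rowSums(rel^2) - (rel %*% a)^2)))
  list(origin = origin, axes = axes, moments = pmax(moments, 0))
}
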