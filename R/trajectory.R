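#' Trajectory frames with forces
#'
#' An `mcc_frames` object holds the per-frame Cartesian coordinates (Angstrom)
#' and forces (kcal mol^-1 Angstrom^-1) of every atom, the orthorhombic box
#' lengths (Angstrom) and the simulation temperature (K). Forces are
#' mandatory: the force/torque covariance entropies cannot be formed without
#' them.
#'
#' @param coords numeric array `n_atoms x 3 x n_frames`
#' @param forces numeric array of the same shape as `coords`
#' @param box numeric matrix `n_frames x 3` of box lengths, or a length-3
#'   vector recycled over frames
#' @param temperature simulation temperature in K
#' @return an object of class `mcc_frames`
#' @export
mcc_frames <- function(coords, forces, box, temperature) {
  if (is.null(forces)) stop("forces required for MCC")
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  if (length(dim(forces)) == 2L) forces <- array(forces, c(dim(forces), 1L))
  if (!identical(dim(coords), dim(forces)))
    stop("coordinates and forces must have identical shape")
  n_frames <- dim(coords)[3]
  if (n_frames < 1L) stop("need at least one frame")
  if (is.null(dim(box))) box <- matrix(box, n_frames, 3, byrow = TRUE)
  stopifnot(nrow(box) == n_frames, ncol(box) == 3)
  if (any(box <= 0)) stop("box lengths must be positive")
  stopifnot(is.numeric(temperature), temperature > 0)
  structure(list(coords = coords, forces = forces, box = box,
                 temperature = temperature,
                 n_frames = n_frames, n_atoms = dim(coords)[1]),
            class = "mcc_frames")
}

#' @export
print.mcc_frames <- function(x, ...) {
  cat(sprintf("mcc_frames: %d frames, %d atoms, T = %g K, box[1] = %s A\n",
              x$n_frames, x$n_atoms, x$temperature,
              paste(signif(x$box[1, ], 5), collapse = " x ")))
  invisible(x)
}

#' Read trajectory frames in the plain-text fixture dialect
#'
#' The dialect is line-oriented: a header `"natoms nframes"`, then for each
#' frame one box line (three lengths in Angstrom) followed by `natoms`
#' coordinate lines (x y z) and `natoms` force lines (fx fy fz). A trailing
#' comment `# T <kelvin>` on the header line carries the temperature.
#'
#' @param path trajectory file
#' @param topology an [mcc_topology()]; the frame atom count must match
#' @param temperature temperature in K; overrides any value in the file
#' @return an [mcc_frames()] object
#' @export
read_frames <- function(path, topology, temperature = NULL) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty trajectory file")
  head_tok <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n_atoms <- as.integer(head_tok[1])
  n_frames <- as.integer(head_tok[2])
  file_T <- if (length(head_tok) >= 5 && head_tok[3] == "#" && head_tok[4] == "T")
    as.numeric(head_tok[5]) else NA_real_
  if (is.null(temperature)) temperature <- file_T
  if (is.na(temperature))
    stop("temperature not given and not present in the trajectory header")
  if (n_atoms != length(topology$masses))
    stop(sprintf("atom-count mismatch: trajectory has %d atoms, topology %d",
                 n_atoms, length(topology$masses)))
  per_frame <- 1L + 2L * n_atoms
  if (length(lines) < 1L + n_frames * per_frame)
    stop("forces required for MCC: truncated frame block (expected ",
         1L + n_frames * per_frame, " lines, found ", length(lines), ")")

  body <- lines[-1]
  coords <- array(NA_real_, c(n_atoms, 3, n_frames))
  forces <- array(NA_real_, c(n_atoms, 3, n_frames))
  box <- matrix(NA_real_, n_frames, 3)
  parse_block <- function(blk) {
    m <- matrix(as.numeric(unlist(strsplit(trimws(blk), "\\s+"))),
                ncol = 3, byrow = TRUE)
    if (anyNA(m)) stop("non-numeric entry in trajectory frame")
    m
  }
  for (f in seq_len(n_frames)) {
    off <- (f - 1L) * per_frame
    bl <- as.numeric(strsplit(trimws(body[off + 1L]), "\\s+")[[1]])
    if (length(bl) != 3) stop("unsupported format: box line must hold exactly ",
                              "three orthorhombic lengths")
    box[f, ] <- bl
    coords[, , f] <- parse_block(body[off + 1L + seq_len(n_atoms)])
    forces[, , f] <- parse_block(body[off + 1L + n_atoms + seq_len(n_atoms)])
  }
  mcc_frames(coords, forces, box, temperature)
}

#' Write trajectory frames in the plain-text fixture dialect
#' @param frames an [mcc_frames()] object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_frames <- function(frames, path) {
  stopifnot(inherits(frames, "mcc_frames"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d # T %.10g", frames$n_atoms, frames$n_frames,
                     frames$temperature), con)
  fmt <- function(m) apply(m, 1, function(r) paste(sprintf("%.17g", r),
                                                   collapse = " "))
  for (f in seq_len(frames$n_frames)) {
    writeLines(paste(sprintf("%.17g", frames$box[f, ]), collapse = " "), con)
    writeLines(fmt(frames$coords[, , f]), con)
    writeLines(fmt(frames$forces[, , f]), con)
  }
  invisible(path)
}

#' Read a per-frame total-energy series
#'
#' Accepts either a two-column whitespace table `frame energy` (lines starting
#' with `#` ignored) or an AMBER mdout-style log, from which `Etot = <value>`
#' records are extracted.
#'
#' @param path input file
#' @param label box label, one of `"X(aq)"`, `"X(oct)"`, `"wat"`, `"oct"` or
#'   any identifying string
#' @return an object of class `mcc_energy`: list with `energy` (kcal mol^-1
#'   per frame) and `label`
#' @export
read_energy_series <- function(path, label) {
  if (!file.exists(path)) stop("energy file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  etot <- grepl("Etot\\s*=", lines)
  if (any(etot)) {
    vals <- as.numeric(sub(".*Etot\\s*=\\s*(-?[0-9.eE+]+).*", "\\1",
                           lines[etot]))
  } else {
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    if (!length(lines)) stop("empty energy series: ", path)
    toks <- strsplit(trimws(lines), "\\s+")
    if (any(vapply(toks, length, 0L) < 2))
      stop("energy table must have two columns (frame, energy)")
    vals <- suppressWarnings(as.numeric(vapply(toks, `[`, "", 2L)))
  }
  if (!length(vals)) stop("empty energy series: ", path)
  if (anyNA(vals) || any(!is.finite(vals)))
    stop("non-numeric or non-finite energy entry in ", path)
  mcc_energy(vals, label)
}

#' Construct an energy series in memory
#' @param energy numeric vector of per-frame total energies (kcal mol^-1)
#' @param label box label
#' @return an `mcc_energy` object
#' @export
mcc_energy <- function(energy, label) {
  if (!length(energy)) stop("empty energy series")
  if (anyNA(energy) || any(!is.finite(energy)))
    stop("energy series must be finite")
  structure(list(energy = as.numeric(energy), label = label),
            class = "mcc_energy")
}
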