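#' Streaming covariance accumulator for weighted forces and torques
#'
#' Accumulates the central covariance matrix of a weighted generalized-force
#' vector in a single pass (running sum and cross-moment). Weights
#' `1/sqrt(mass)` (translations) or `1/sqrt(moment of inertia)` (rotations)
#' are applied to each observation before accumulation, so the readout matrix
#' has elements `<F_a F_b>/sqrt(m_a m_b)` or `<tau_a tau_b>/sqrt(I_a I_b)`.
#'
#' @param dimension length of the observation vector
#' @param level `"M"` or `"UA"`
#' @param motion `"trans"` or `"rot"`
#' @return an `mcc_covariance` accumulator (environment-free list; update
#'   with [cov_accumulate()] and read with [cov_readout()])
#' @export
cov_accumulator <- function(dimension, level = "M", motion = "trans") {
  stopifnot(dimension >= 1)
  structure(list(dimension = as.integer(dimension),
                 level = level, motion = motion,
                 n = 0L,
                 sum = numeric(dimension),
                 cross = matrix(0, dimension, dimension)),
            class = "mcc_covariance")
}

#' Add one observation to a covariance accumulator
#' @param acc an accumulator from [cov_accumulator()]
#' @param x observation vector (already weighted, see [cov_accumulator()])
#' @param weights optional per-component weights `w`; the accumulated vector
#'   is `x * w` (pass `1/sqrt(mass)` or `1/sqrt(inertia)` here)
#' @return the updated accumulator
#' @export
cov_accumulate <- function(acc, x, weights = NULL) {
  if (length(x) != acc$dimension)
    stop("dimension mismatch: observation has length ", length(x),
         ", accumulator expects ", acc$dimension)
  if (!is.null(weights)) x <- x * weights
  acc$n <- acc$n + 1L
  acc$sum <- acc$sum + x
  acc$cross <- acc$cross + tcrossprod(x)
  acc
}

#' Add a block of observations to a covariance accumulator
#'
#' Equivalent to calling [cov_accumulate()] on every row of `x`, but in one
#' vectorized pass.
#'
#' @param acc an accumulator from [cov_accumulator()]
#' @param x matrix of observations, one per row
#' @param weights optional per-component weight vector applied to every row
#' @return the updated accumulator
#' @export
cov_accumulate_many <- function(acc, x, weights = NULL) {
  x <- as.matrix(x)
  if (ncol(x) != acc$dimension)
    stop("dimension mismatch: observations have ", ncol(x),
         " columns, accumulator expects ", acc$dimension)
  if (!is.null(weights)) x <- sweep(x, 2, weights, "*")
  acc$n <- acc$n + nrow(x)
  acc$sum <- acc$sum + colSums(x)
  acc$cross <- acc$cross + crossprod(x)
  acc
}

#' Read the central covariance matrix out of an accumulator
#' @param acc an accumulator with at least one observation
#' @return symmetric covariance matrix
#' @export
cov_readout <- function(acc) {
  if (acc$n < 1L) stop("no observations accumulated")
  mu <- acc$sum / acc$n
  cv <- acc$cross / acc$n - tcrossprod(mu)
  (cv + t(cv)) / 2
}

#' Vibrational frequencies from a weighted covariance matrix
#'
#' Eigenvalues `lambda_i` of the mass-weighted force (or inertia-weighted
#' torque) covariance matrix are converted to quasi-harmonic frequencies
#' `nu_i = (1/2pi) sqrt(lambda_i / (kB T))`. Internally `lambda/(kB T)` is in
#' kcal mol^-1 Angstrom^-2 amu^-1 (or kcal mol^-1 amu^-1 Angstrom^-2 for
#' torques, radians being dimensionless) and converts to s^-2 by the exact
#' factor 4.184e26.
#'
#' Slightly negative eigenvalues within `-1e-8 * trace/N` are clipped to
#' zero; eigenvalues below `1e-12 * trace/N` are treated as exact zero modes.
#'
#' @param covariance symmetric covariance matrix (internal units)
#' @param temperature temperature in K (> 0)
#' @param level,motion provenance tags carried into the spectrum
#' @return object of class `mcc_spectrum`: list with `nu` (s^-1, ascending),
#'   `level`, `motion`, `removed` (count of removed modes, 0 here)
#' @export
frequencies_from_covariance <- function(covariance, temperature,
                                        level = "M", motion = "trans") {
  if (temperature <= 0) stop("temperature must be positive")
  covariance <- (covariance + t(covariance)) / 2
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  n <- length(ev)
  scale <- sum(abs(ev)) / n
  if (scale > 0 && any(ev < -1e-8 * scale))
    stop("covariance matrix is not positive semi-definite")
  ev <- pmax(ev, 0)
  if (scale > 0) ev[ev < 1e-12 * scale] <- 0   # exact-constraint zero modes
  nu <- sqrt(ev * FREQ2_SI / (KB_KCAL * temperature)) / (2 * pi)
  mcc_spectrum(sort(nu), level = level, motion = motion)
}

#' Construct a mode spectrum
#' @param nu frequencies in s^-1 (non-negative)
#' @param level,motion provenance tags
#' @param removed number of removed low modes (0 or 6)
#' @return an `mcc_spectrum`
#' @export
mcc_spectrum <- function(nu, level = "M", motion = "trans", removed = 0L) {
  if (any(nu < 0)) stop("negative frequency")
  structure(list(nu = sort(as.numeric(nu)), level = level, motion = motion,
                 removed = as.integer(removed)),
            class = "mcc_spectrum")
}

#' Quantum harmonic oscillator entropy of a mode spectrum
#'
#' Each mode of frequency `nu` contributes
#' `kB * (x/(exp(x)-1) - log(1-exp(-x)))` with `x = h nu / kB T`. Zero-
#' frequency modes (from degenerate inputs or exact constraints) contribute
#' zero by convention rather than the divergent classical limit.
#'
#' @param spectrum an `mcc_spectrum` or numeric vector of frequencies (s^-1)
#' @param temperature temperature in K
#' @return entropy in J K^-1 mol^-1 (attribute `kcal` holds the
#'   kcal mol^-1 K^-1 view)
#' @export
qho_entropy <- function(spectrum, temperature) {
  if (temperature <= 0) stop("temperature must be positive")
  nu <- if (inherits(spectrum, "mcc_spectrum")) spectrum$nu else spectrum
  if (any(nu < 0)) stop("negative frequency")
  x <- H_KCAL_S * nu / (KB_KCAL * temperature)
  per <- ifelse(x == 0, 0, x / expm1(x) - log1p(-exp(-x)))
  s_kcal <- KB_KCAL * sum(per)
  structure(entropy_to_joules(s_kcal), kcal = s_kcal)
}

#' Drop the six lowest-frequency modes of a UA translational spectrum
#'
#' The six lowest UA translational vibrations duplicate the molecule-level
#' translational and rotational motion and are removed to avoid
#' double-counting entropy across levels.
#'
#' @param spectrum an `mcc_spectrum` with `level == "UA"`,
#'   `motion == "trans"` and at least `n` modes
#' @param n number of modes to drop (6)
#' @return the truncated spectrum with `removed` set
#' @export
remove_lowest_modes <- function(spectrum, n = 6L) {
  stopifnot(inherits(spectrum, "mcc_spectrum"))
  if (!(spectrum$level == "UA" && spectrum$motion == "trans"))
    stop("mode removal applies only to UA translational spectra")
  if (length(spectrum$nu) < n)
    stop("spectrum has fewer than ", n, " modes")
  mcc_spectrum(spectrum$nu[-seq_len(n)], level = spectrum$level,
               motion = spectrum$motion, removed = n)
}

#' @export
print.mcc_spectrum <- function(x, ...) {
  cat(sprintf("mcc_spectrum [%s/%s]: %d modes (%d removed)\n",
              x$level, x$motion, length(x$nu), x$removed))
  if (length(x$nu)) {
    cm1 <- x$nu / 2.99792458e10              # s^-1 -> cm^-1
    cat("  nu range:", sprintf("%.4g", min(x$nu)), "-",
        sprintf("%.4g", max(x$nu)), "s^-1  (",
        sprintf("%.4g", min(cm1)), "-", sprintf("%.4g", max(cm1)), "cm^-1 )\n")
  }
  invisible(x)
}
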