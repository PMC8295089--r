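#' Mean enthalpy of a simulation box
#'
#' The enthalpy is taken as the time average of the total (potential +
#' kinetic) energy; the pressure-volume term is negligible at ambient
#' pressure and cancels almost entirely in a transfer.
#'
#' @param energy an `mcc_energy` object or numeric energy vector
#'   (kcal mol^-1)
#' @return mean enthalpy (kcal mol^-1)
#' @export
mean_enthalpy <- function(energy) {
  e <- if (inherits(energy, "mcc_energy")) energy$energy else energy
  if (!length(e)) stop("empty energy series")
  if (anyNA(e)) stop("NaN in energy series")
  mean(e)
}

## Required entropy slots by solvent kind. Solute slots only when a solute is
## present; solvent slots are per-molecule and get multiplied by mean Nc.
.solute_slots <- c("X.M.transvib", "X.M.rovib", "X.pos", "X.or",
                   "X.UA.transvib", "X.UA.rovib", "X.conf")
.solvent_slots <- list(
  water = c("solv.M.transvib", "solv.M.rovib", "solv.or"),
  octanol = c("solv.M.transvib", "solv.M.rovib", "solv.or",
              "solv.UA.transvib", "solv.UA.rovib", "solv.conf"))

#' Bundle the results for one simulation box
#'
#' @param label box label: `"X(aq)"`, `"X(oct)"`, `"wat"` or `"oct"`
#' @param enthalpy mean enthalpy H (kcal mol^-1)
#' @param breakdown named numeric vector of entropy components in
#'   J K^-1 mol^-1. Solute slots: `X.M.transvib`, `X.M.rovib`, `X.pos`,
#'   `X.or`, `X.UA.transvib`, `X.UA.rovib`, `X.conf`. Per-solvent-molecule
#'   slots: `solv.M.transvib`, `solv.M.rovib`, `solv.or` and, for octanol,
#'   also `solv.UA.transvib`, `solv.UA.rovib`, `solv.conf`.
#' @param mean_nc mean first-shell coordination number multiplying the
#'   per-molecule solvent terms (the pure liquid uses the same count as the
#'   solute's shell to balance stoichiometry)
#' @param temperature temperature (K)
#' @param solvent `"water"` or `"octanol"`
#' @param has_solute whether the box contains the solute
#' @return an `mcc_system_result`
#' @export
mcc_system_result <- function(label, enthalpy, breakdown, mean_nc,
                              temperature, solvent = c("water", "octanol"),
                              has_solute = TRUE) {
  solvent <- match.arg(solvent)
  required <- c(if (has_solute) .solute_slots, .solvent_slots[[solvent]])
  missing <- setdiff(required, names(breakdown))
  if (length(missing))
    stop("missing entropy component(s): ", paste(missing, collapse = ", "))
  structure(list(label = label, enthalpy = enthalpy,
                 breakdown = breakdown[required], mean_nc = mean_nc,
                 temperature = temperature, solvent = solvent,
                 has_solute = has_solute),
            class = "mcc_system_result")
}

#' Total entropy of a simulation box from its component breakdown
#'
#' Solute components enter once; per-molecule solvent components are
#' multiplied by the mean coordination number, restricting the solvent
#' entropy to the first solvation shell (or the stoichiometrically matched
#' number of bulk molecules for a pure liquid).
#'
#' @param system an [mcc_system_result()]
#' @return total entropy in J K^-1 mol^-1 (attribute `kcal`)
#' @export
solution_entropy <- function(system) {
  stopifnot(inherits(system, "mcc_system_result"))
  b <- system$breakdown
  s_solute <- if (system$has_solute) sum(b[.solute_slots]) else 0
  s_solv <- sum(b[.solvent_slots[[system$solvent]]])
  total <- s_solute + system$mean_nc * s_solv
  structure(total, kcal = entropy_to_kcal(total))
}

#' logP from a transfer free energy
#' @param dg water-to-octanol transfer free energy (kcal mol^-1)
#' @param temperature temperature (K)
#' @return base-10 partition coefficient `logP = -dG / (ln(10) kB T)`
#' @export
logp_from_dg <- function(dg, temperature = 298) {
  -dg / (log(10) * KB_KCAL * temperature)
}

#' Water-to-octanol transfer thermodynamics from four simulation boxes
#'
#' Combines the solute-in-octanol, pure-water, pure-octanol and
#' solute-in-water boxes as
#' `dG = (G_X(oct) + G_wat) - (G_oct + G_X(aq))` with `G = H - T S`, and
#' converts to `logP`.
#'
#' @param x_oct,wat,oct,x_aq [mcc_system_result()] objects for the four boxes
#' @return an `mcc_transfer` object: list with `dH`, `TdS`, `dG`
#'   (kcal mol^-1), `logP`, `temperature`
#' @export
transfer <- function(x_oct, wat, oct, x_aq) {
  systems <- list(x_oct, wat, oct, x_aq)
  temps <- vapply(systems, `[[`, 0, "temperature")
  if (diff(range(temps)) > 0.5)
    stop("temperature mismatch between systems: ",
         paste(signif(temps, 6), collapse = ", "), " K")
  T <- mean(temps)
  sgn <- c(1, 1, -1, -1)
  dH <- sum(sgn * vapply(systems, `[[`, 0, "enthalpy"))
  dS_kcal <- sum(sgn * vapply(systems, function(s)
    attr(solution_entropy(s), "kcal"), 0))
  TdS <- T * dS_kcal
  dG <- dH - TdS
  structure(list(dH = dH, TdS = TdS, dG = dG,
                 logP = logp_from_dg(dG, T), temperature = T),
            class = "mcc_transfer")
}

#' @export
print.mcc_transfer <- function(x, ...) {
  cat(sprintf("water -> octanol transfer at %.1f K\n", x$temperature))
  cat(sprintf("  dH  = %8.3f kcal/mol\n", x$dH))
  cat(sprintf("  TdS = %8.3f kcal/mol\n", x$TdS))
  cat(sprintf("  dG  = %8.3f kcal/mol\n", x$dG))
  cat(sprintf("  logP = %7.3f\n", x$logP))
  invisible(x)
}

#' Mean absolute error and root-mean-square error versus experiment
#' @param predicted,experimental equal-length numeric vectors
#' @return list with `mae` and `rmse`
#' @export
performance_metrics <- function(predicted, experimental) {
  if (length(predicted) != length(experimental))
    stop("length mismatch between predicted and experimental values")
  if (!length(predicted)) stop("need at least one pair")
  d <- predicted - experimental
  list(mae = mean(abs(d)), rmse = sqrt(mean(d^2)))
}

#' Standard error of the mean over simulation replicates
#' @param values numeric vector of replicate values (n >= 2)
#' @return `sd(values)/sqrt(n)` with the n-1 denominator in the sd
#' @export
replicate_sem <- function(values) {
  n <- length(values)
  if (n < 2) stop("SEM requires at least two replicates")
  stats::sd(values) / sqrt(n)
}

#' Benchmark table: SAMPL7 N-acyl sulfonamide logP set
#'
#' Published per-solute transfer enthalpies, entropies, free energies,
#' computed and experimental logP values (with replicate SEMs) for the 22
#' SAMPL7 challenge solutes SM25-SM46, as shipped in `inst/extdata`. Useful
#' for exercising [performance_metrics()] and [replicate_sem()].
#'
#' @return data.frame with columns `solute`, `dH`, `TdS`, `dG`, `logP_calc`,
#'   `sem`, `logP_exp`, `abs_dlogP` (energies in kcal mol^-1)
#' @export
sampl7_table <- function() {
  path <- system.file("extdata", "sampl7_logp_table.csv", package = "eemcc")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
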