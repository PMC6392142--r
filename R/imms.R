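#' @include AllClasses.R AllGenerics.R
NULL

.PROTON <- 1.00728

#' Infer a neutral mass from an electrospray charge-state ladder
#'
#' Adjacent peaks m1 > m2 are assigned consecutive charges z, z + 1 with
#' `z = round((m2 - mp) / (m1 - m2))` (mp the proton mass); the neutral mass
#' is the mean over peaks of `z * (m/z - mp)`. The per-peak mass spread
#' diagnoses ladder consistency.
#'
#' @param peaks data.frame with column `mz` (two or more peaks), or a
#'   numeric vector of m/z values
#' @param assumedConsecutive logical; the ladder is interpreted as
#'   consecutive charge states (the only supported mode; non-consecutive
#'   ladders are rejected by the consistency check).
#' @param tol maximal relative disagreement of per-peak masses (default
#'   0.1 percent) before the ladder is rejected.
#' @return list with `mass` (Da), `charges` (one per peak, descending m/z ->
#'   ascending charge), `perPeakMass`, `spread`
#' @examples
#' inferMass(makeChargeLadder(149328, 21:24))
#' @export
inferMass <- function(peaks, assumedConsecutive = TRUE, tol = 1e-3) {
  mz <- if (is.data.frame(peaks)) peaks$mz else as.numeric(peaks)
  mz <- sort(mz, decreasing = TRUE)  # m1 > m2: ascending charge
  if (length(mz) < 2) stop("at least two peaks required to infer a mass")
  if (!assumedConsecutive)
    stop("only consecutive charge-state ladders are supported")
  z1 <- round((mz[2] - .PROTON) / (mz[1] - mz[2]))
  if (!is.finite(z1) || z1 < 1) stop("cannot assign a charge to the ladder")
  charges <- z1 + seq_along(mz) - 1
  perPeak <- charges * (mz - .PROTON)
  mass <- mean(perPeak)
  spread <- (max(perPeak) - min(perPeak)) / mass
  if (spread > tol)
    stop(sprintf(
      "inconsistent charge ladder: per-peak masses disagree by %.3g%% (> %.3g%%); masses: %s",
      100 * spread, 100 * tol, paste(sprintf("%.1f", perPeak), collapse = ", ")))
  list(mass = mass, charges = charges, perPeakMass = perPeak, spread = spread)
}

# reduced-mass/charge correction used throughout TWIMS calibration
.correctedCcs <- function(ccsValues, mass, charge, gasMass) {
  mu <- mass * gasMass / (mass + gasMass)
  ccsValues * sqrt(mu) / charge
}

#' Fit a travelling-wave IM power-law calibration
#'
#' Reference CCS values are corrected for reduced mass and charge
#' (`CCS' = CCS * sqrt(mu) / z`), drift times are dead-time corrected
#' (`t' = t - deadTime`), and `CCS' = A * t'^B` is fitted by least squares
#' in log-log space.
#'
#' @param calibrants data.frame with columns `ccs` (Angstrom^2), `drift`,
#'   `mass` (Da), `charge`
#' @param gasMass drift-gas mass in Da (default nitrogen, 28.006)
#' @param deadTime instrument dead time subtracted from drift times
#'   (default 0)
#' @return a [CalibrationFit]
#' @export
twimsCalibrate <- function(calibrants, gasMass = 28.006, deadTime = 0) {
  need <- c("ccs", "drift", "mass", "charge")
  stopifnot(all(need %in% names(calibrants)))
  if (nrow(calibrants) < 2)
    stop("at least two calibrants are required")
  tprime <- calibrants$drift - deadTime
  if (any(tprime <= 0)) stop("non-positive corrected drift times")
  ccsPrime <- .correctedCcs(calibrants$ccs, calibrants$mass,
                            calibrants$charge, gasMass)
  fit <- stats::lm(log(ccsPrime) ~ log(tprime))
  A <- exp(unname(stats::coef(fit)[1]))
  B <- unname(stats::coef(fit)[2])
  pred <- A * tprime^B
  new("CalibrationFit", A = A, B = B,
      residualRms = sqrt(mean(((ccsPrime - pred) / ccsPrime)^2)),
      nCalibrants = nrow(calibrants), gasMass = gasMass, deadTime = deadTime)
}

#' Apply a TWIMS calibration to analyte drift times
#'
#' Inverse of the corrected-CCS transform: `CCS = A * t'^B * z / sqrt(mu)`.
#' With `B > 0` the transform is monotone, so an arrival-time distribution
#' maps to a CCS distribution preserving order.
#'
#' @param fit a [CalibrationFit]
#' @param drift drift time(s), same unit as the calibrants
#' @param mass analyte mass, Da
#' @param charge analyte charge state
#' @return CCS value(s) in Angstrom^2
#' @export
applyCalibration <- function(fit, drift, mass, charge) {
  stopifnot(is(fit, "CalibrationFit"))
  tprime <- drift - fit@deadTime
  if (any(tprime <= 0)) stop("drift time at or below the dead time")
  mu <- mass * fit@gasMass / (mass + fit@gasMass)
  fit@A * tprime^fit@B * charge / sqrt(mu)
}

#' Average CCS measurements over wave velocities
#'
#' Arithmetic mean and sample (n - 1) standard deviation across the per-wave
#' CCS values; a single value yields sd 0 with a flag.
#'
#' @param values numeric vector of per-wave-velocity CCS values, Angstrom^2
#' @param waveVelocities optional labels (e.g. m/s values)
#' @return list with `mean`, `sd`, `n`, `values`, `singleValue` flag
#' @export
averageOverWaves <- function(values, waveVelocities = NULL) {
  stopifnot(length(values) >= 1)
  list(mean = mean(values),
       sd = if (length(values) > 1) stats::sd(values) else 0,
       n = length(values), values = values,
       waveVelocities = waveVelocities,
       singleValue = length(values) == 1)
}

#' Compare a model CCS to an experimental measurement
#'
#' Relative difference of model and experimental mean, with a within-band
#' verdict (band default 6 percent, a typical TWIMS calibration
#' uncertainty). Both denominator conventions are reported: relative to the
#' experimental mean (`relDiff`) and relative to the model
#' (`relDiffModelDenom`).
#'
#' @param modelCcs model CCS, Angstrom^2
#' @param experimentMean experimental mean CCS, Angstrom^2
#' @param experimentSd optional experimental standard deviation
#' @param band relative band half-width (default 0.06)
#' @return one-row data.frame: `modelCcs`, `experimentMean`, `relDiff`,
#'   `relDiffModelDenom`, `withinBand`
#' @examples
#' compareToExperiment(7180, 7173)
#' @export
compareToExperiment <- function(modelCcs, experimentMean, experimentSd = NA,
                                band = 0.06) {
  stopifnot(band > 0)
  rel <- (modelCcs - experimentMean) / experimentMean
  data.frame(modelCcs = modelCcs, experimentMean = experimentMean,
             experimentSd = experimentSd,
             relDiff = rel,
             relDiffModelDenom = (modelCcs - experimentMean) / modelCcs,
             band = band, withinBand = abs(rel) <= band)
}

#' Reference IM-MS observables for the four human IgG subclasses
#'
#' Returns the packaged table of published travelling-wave IM-MS and
#' modelling observables for human IgG1-4 (glycosylated and deglycosylated
#' experimental CCS averaged over T-wave velocities 550, 600 and 640 m/s,
#' masses, lowest observed charge states, hinge annotation counts and
#' stage-wise model CCS values). These serve as experimental inputs for
#' workflow comparisons.
#'
#' @return data.frame, one row per subclass
#' @export
igGReference <- function() {
  path <- system.file("extdata", "igg_imms_reference.csv", package = "abgas")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
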