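#' Medium glucose concentration from GOPOD absorbance
#'
#' Applies the plate-reader calibration
#' `Glucose (mM) = (Au_group - Au_blank) / (Au_standard - Au_blank) x standard_mM`.
#' A negative result (group reading below blank) is clamped to 0 and
#' flagged via a warning.
#'
#' @param auGroup,auBlank,auStandard absorbances at 505 nm (AU).
#' @param standardMM concentration of the glucose standard; the assay's
#'   control standard is 5.55 mM.
#' @return glucose concentration in mM.
#' @examples
#' glucoseConcentration(0.60, 0.10, 0.35, 5.55)  # 11.1 mM
#' @export
glucoseConcentration <- function(auGroup, auBlank, auStandard,
                                 standardMM = 5.55) {
  if (auStandard <= auBlank)
    stop("invalid standard: standard absorbance must exceed blank")
  conc <- (auGroup - auBlank) / (auStandard - auBlank) * standardMM
  if (any(conc < 0)) {
    warning("negative glucose concentration clamped to 0")
    conc <- pmax(conc, 0)
  }
  conc
}

#' Glucose depletion from the medium
#'
#' Depletion over one interval is the initial medium concentration minus
#' the measured concentration. The medium is replaced daily, so cumulative
#' depletion over the time course is the sum of per-24 h interval
#' depletions (`cumulative = TRUE` with a vector of per-interval measured
#' concentrations).
#'
#' @param initialMM medium glucose at the start of each interval (mM);
#'   default 5.5 mM, the formulated medium concentration.
#' @param measuredMM measured concentration(s) at interval end (mM).
#' @param cumulative if TRUE, return the running sum of per-interval
#'   depletions.
#' @return depletion in mM; negative values (apparent production) are
#'   returned as-is with a warning.
#' @examples
#' glucoseDepletion(20, 8.6)                       # 11.4
#' glucoseDepletion(5.5, c(1.5, 1.2, 1.4), cumulative = TRUE)
#' @export
glucoseDepletion <- function(initialMM = 5.5, measuredMM,
                             cumulative = FALSE) {
  if (any(initialMM < 0) || any(measuredMM < 0))
    stop("concentrations must be nonnegative")
  d <- initialMM - measuredMM
  if (any(d < 0))
    warning("negative depletion (measured exceeds initial medium glucose)")
  if (cumulative) cumsum(d) else d
}

#' Cell proliferation percent from CCK-8 absorbance
#'
#' `Cell proliferation (%) = A_group / A_control x 100`.
#'
#' @param aGroup,aControl absorbances at 450 nm (AU).
#' @return percent of control.
#' @examples
#' proliferationPercent(0.55, 0.50)  # 110
#' @export
proliferationPercent <- function(aGroup, aControl) {
  if (aControl <= 0) stop("control absorbance must be positive")
  aGroup / aControl * 100
}

#' Fold change of group mean over a reference mean
#'
#' Used for the Oil Red O lipid-accumulation readout (absorbance at
#' 490 nm): e.g. steatotic cells stain 1.6-fold the untreated control.
#'
#' @param groupMean,referenceMean mean absorbances (AU).
#' @return dimensionless fold change.
#' @examples
#' foldChange(0.80, 0.50)  # 1.6
#' @export
foldChange <- function(groupMean, referenceMean) {
  if (referenceMean <= 0) stop("reference mean must be positive")
  groupMean / referenceMean
}
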