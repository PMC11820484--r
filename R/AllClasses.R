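#' @import methods
NULL

#' FragmentDefinition: metadata for one monitored GC/MS fragment ion
#'
#' Describes the fragment ion monitored for one analyte: the nominal m/z of
#' the monoisotopic peak, how many carbons of the fragment skeleton can carry
#' tracer \eqn{^{13}}C, the elemental composition of the full derivatized
#' fragment (used to model the natural-isotope envelope), and the highest
#' mass-shift index recorded.
#'
#' @slot analyte character(1), e.g. "palmitate".
#' @slot monitoredMz integer(1), nominal m/z of the monoisotopic ion (Th).
#' @slot nSkeletonCarbons integer(1), carbons that can carry tracer label.
#' @slot elementalFormula named integer vector, element -> atom count for the
#'   whole derivatized fragment ion (including the skeleton carbons).
#' @slot maxShift integer(1), highest isotopomer index K recorded (m0..mK).
#'
#' @seealso [fragmentDefinition()] for the built-in fragment registry.
#' @export
setClass("FragmentDefinition",
  representation(
    analyte          = "character",
    monitoredMz      = "integer",
    nSkeletonCarbons = "integer",
    elementalFormula = "integer",
    maxShift         = "integer"
  )
)

setValidity("FragmentDefinition", function(object) {
  msg <- character()
  if (length(object@analyte) != 1L || !nzchar(object@analyte))
    msg <- c(msg, "'analyte' must be a non-empty string")
  if (length(object@nSkeletonCarbons) != 1L || object@nSkeletonCarbons < 1L)
    msg <- c(msg, "'nSkeletonCarbons' must be >= 1")
  if (length(object@maxShift) != 1L || object@maxShift < 2L)
    msg <- c(msg, "'maxShift' must be >= 2")
  ef <- object@elementalFormula
  if (length(ef)) {
    if (is.null(names(ef)) || any(!nzchar(names(ef))))
      msg <- c(msg, "'elementalFormula' must be a named vector")
    if (any(ef < 0L))
      msg <- c(msg, "atom counts must be nonnegative")
    nC <- if ("C" %in% names(ef)) ef[["C"]] else 0L
    if (nC < object@nSkeletonCarbons)
      msg <- c(msg, "formula carbon count below 'nSkeletonCarbons'")
  }
  if (length(msg)) msg else TRUE
})

#' MassIsotopomerDistribution: normalized isotopomer abundances of one fragment
#'
#' Fractional abundances a0..aK of one fragment ion in one sample, indexed by
#' mass shift relative to the monoisotopic monitored ion (shift 0 = m0). The
#' vector is normalized to sum to 1.
#'
#' @slot fragment a [FragmentDefinition-class].
#' @slot sampleId character(1).
#' @slot abundances numeric vector of length maxShift + 1, nonnegative,
#'   summing to 1 within 1e-9.
#'
#' @seealso [normalizeMid()], [correctNaturalAbundance()], [sigmn()]
#' @export
setClass("MassIsotopomerDistribution",
  representation(
    fragment   = "FragmentDefinition",
    sampleId   = "character",
    abundances = "numeric"
  )
)

setValidity("MassIsotopomerDistribution", function(object) {
  msg <- character()
  a <- object@abundances
  if (length(a) != object@fragment@maxShift + 1L)
    msg <- c(msg, sprintf("'abundances' must have length maxShift + 1 = %d",
                          object@fragment@maxShift + 1L))
  if (any(a < 0))
    msg <- c(msg, "abundances must be nonnegative")
  if (length(a) && abs(sum(a) - 1) > 1e-9)
    msg <- c(msg, sprintf("abundances must sum to 1 (got %.12f)", sum(a)))
  if (length(msg)) msg else TRUE
})

#' ExcessVector: isotopomer excess of a sample over a baseline
#'
#' Entries E1..EK are differences of fractional abundances (sample minus
#' baseline) at mass shifts >= 1. Small negative entries can arise from
#' noise; entries below -0.005 are flagged at construction.
#'
#' @slot fragment a [FragmentDefinition-class].
#' @slot sampleId character(1).
#' @slot excesses numeric vector E1..EK.
#' @slot flags character vector of quality flags.
#' @seealso [excessMid()]
#' @export
setClass("ExcessVector",
  representation(
    fragment = "FragmentDefinition",
    sampleId = "character",
    excesses = "numeric",
    flags    = "character"
  )
)

setValidity("ExcessVector", function(object) {
  if (length(object@excesses) != object@fragment@maxShift)
    return("'excesses' must have length maxShift (entries E1..EK)")
  TRUE
})

#' MidaResult: MIDA estimates for one fatty acid in one sample
#'
#' @slot fattyAcid character(1): "palmitate", "stearate" or "oleate".
#' @slot sampleId character(1).
#' @slot pPrecursor numeric(1), acetyl-CoA 13C2 labeling probability p.
#' @slot fns numeric(1), fraction of new synthesis in [0, 1].
#' @slot excessUsed the [ExcessVector-class] the estimates came from.
#' @slot diagnostics list: e4/e2 ratio, E4-based FNS cross-check, flags.
#' @export
setClass("MidaResult",
  representation(
    fattyAcid   = "character",
    sampleId    = "character",
    pPrecursor  = "numeric",
    fns         = "numeric",
    excessUsed  = "ExcessVector",
    diagnostics = "list"
  )
)

setValidity("MidaResult", function(object) {
  msg <- character()
  if (!is.na(object@pPrecursor) &&
      (object@pPrecursor < 0 || object@pPrecursor >= 1))
    msg <- c(msg, "'pPrecursor' must satisfy 0 <= p < 1")
  if (!is.na(object@fns) && (object@fns < 0 || object@fns > 1))
    msg <- c(msg, "'fns' must lie in [0, 1] (raw out-of-bound values are clipped and flagged)")
  if (length(msg)) msg else TRUE
})

#' PcPdhResult: pyruvate carboxylase / pyruvate dehydrogenase partitioning
#'
#' m2 fractions of the glutamate C2-C4 (m/z 152) and C2-C5 (m/z 198) TAB
#' fragments and the derived PC/PDH ratio
#' m2(152) / (m2(198) - m2(152)). The ratio is undefined (NA, with flag)
#' when the denominator is not positive.
#'
#' @slot sampleId character(1).
#' @slot m2_152,m2_198 numeric(1), corrected m2 fractions.
#' @slot ratio numeric(1); NA when undefined.
#' @slot defined logical(1).
#' @slot diagnostics list; carries the double-labeled isotopomers m3(152) and
#'   m4(198) and any flags.
#' @seealso [pcPdhRatio()]
#' @export
setClass("PcPdhResult",
  representation(
    sampleId    = "character",
    m2_152      = "numeric",
    m2_198      = "numeric",
    ratio       = "numeric",
    defined     = "logical",
    diagnostics = "list"
  )
)

#' EnrichmentResult: summed 13C molar enrichment (SIGmn) of one analyte
#'
#' SIGmn is the average number of labeled carbons per molecule,
#' \eqn{\Sigma_n n M_n}, bounded by the skeleton carbon count of the fragment.
#'
#' @slot analyte character(1).
#' @slot sampleId character(1).
#' @slot sigmn numeric(1) in [0, nSkeletonCarbons].
#' @seealso [sigmn()]
#' @export
setClass("EnrichmentResult",
  representation(
    analyte  = "character",
    sampleId = "character",
    sigmn    = "numeric"
  )
)

#' StudyDesign: sample-to-condition mapping for a group-structured study
#'
#' @slot samples data.frame with columns sample_id, group, timepoint_h,
#'   replicate_index.
#' @slot referenceControl character(1), the untreated control group.
#' @slot referenceSteatosis character(1), the steatosis (vehicle) control
#'   group used as the second reference in pairwise annotation.
#' @seealso [studyDesign()]
#' @export
setClass("StudyDesign",
  representation(
    samples            = "data.frame",
    referenceControl   = "character",
    referenceSteatosis = "character"
  )
)

setValidity("StudyDesign", function(object) {
  msg <- character()
  s <- object@samples
  need <- c("sample_id", "group", "timepoint_h", "replicate_index")
  if (!all(need %in% names(s)))
    msg <- c(msg, paste("'samples' must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(s$sample_id))
      msg <- c(msg, "sample ids must be unique")
    if (!(object@referenceControl %in% s$group))
      msg <- c(msg, sprintf("reference control group '%s' not present",
                            object@referenceControl))
    if (!(object@referenceSteatosis %in% s$group))
      msg <- c(msg, sprintf("reference steatosis group '%s' not present",
                            object@referenceSteatosis))
  }
  if (length(msg)) msg else TRUE
})
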