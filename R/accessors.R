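#' Accessors for midflux S4 classes
#'
#' Slot accessors for the core containers. Use these rather than `@`.
#'
#' @param x an object of the relevant class.
#' @return The slot value: a character scalar, numeric vector, integer scalar,
#'   data.frame, or embedded object, depending on the accessor.
#' @name accessors
NULL

#' @rdname accessors
setMethod("analyteName", "FragmentDefinition", function(x) x@analyte)
#' @rdname accessors
setMethod("analyteName", "MassIsotopomerDistribution",
          function(x) x@fragment@analyte)
#' @rdname accessors
setMethod("analyteName", "EnrichmentResult", function(x) x@analyte)

#' @rdname accessors
setMethod("maxShift", "FragmentDefinition", function(x) x@maxShift)
#' @rdname accessors
setMethod("maxShift", "MassIsotopomerDistribution",
          function(x) x@fragment@maxShift)

#' @rdname accessors
setMethod("nSkeletonCarbons", "FragmentDefinition",
          function(x) x@nSkeletonCarbons)
#' @rdname accessors
setMethod("nSkeletonCarbons", "MassIsotopomerDistribution",
          function(x) x@fragment@nSkeletonCarbons)

#' @rdname accessors
setMethod("elementalFormula", "FragmentDefinition",
          function(x) x@elementalFormula)

#' @rdname accessors
setMethod("fragmentOf", "MassIsotopomerDistribution", function(x) x@fragment)
#' @rdname accessors
setMethod("fragmentOf", "ExcessVector", function(x) x@fragment)

#' @rdname accessors
setMethod("sampleId", "MassIsotopomerDistribution", function(x) x@sampleId)
#' @rdname accessors
setMethod("sampleId", "ExcessVector", function(x) x@sampleId)
#' @rdname accessors
setMethod("sampleId", "MidaResult", function(x) x@sampleId)
#' @rdname accessors
setMethod("sampleId", "PcPdhResult", function(x) x@sampleId)
#' @rdname accessors
setMethod("sampleId", "EnrichmentResult", function(x) x@sampleId)

#' @rdname accessors
setMethod("abundances", "MassIsotopomerDistribution", function(x) {
  a <- x@abundances
  names(a) <- paste0("m", seq_along(a) - 1L)
  a
})

#' @rdname accessors
setMethod("excesses", "ExcessVector", function(x) {
  e <- x@excesses
  names(e) <- paste0("E", seq_along(e))
  e
})

#' @rdname accessors
setMethod("analyteName", "MidaResult", function(x) x@fattyAcid)
#' @rdname accessors
setMethod("precursorEnrichment", "MidaResult", function(x) x@pPrecursor)
#' @rdname accessors
setMethod("fns", "MidaResult", function(x) x@fns)
#' @rdname accessors
setMethod("diagnostics", "MidaResult", function(x) x@diagnostics)
#' @rdname accessors
setMethod("diagnostics", "PcPdhResult", function(x) x@diagnostics)

#' @rdname accessors
setMethod("pcPdh", "PcPdhResult", function(x) x@ratio)
#' @rdname accessors
setMethod("isDefined", "PcPdhResult", function(x) x@defined)

#' @rdname accessors
setMethod("sigmnValue", "EnrichmentResult", function(x) x@sigmn)

#' @rdname accessors
setMethod("samples", "StudyDesign", function(x) x@samples)
#' @rdname accessors
setMethod("groupNames", "StudyDesign", function(x) unique(x@samples$group))

setMethod("show", "FragmentDefinition", function(object) {
  f <- object@elementalFormula
  cat(sprintf("FragmentDefinition: %s (m/z %d)\n", object@analyte,
              object@monitoredMz))
  cat(sprintf("  skeleton carbons: %d | max shift: %d | formula: %s\n",
              object@nSkeletonCarbons, object@maxShift,
              paste0(names(f), f, collapse = " ")))
})

setMethod("show", "MassIsotopomerDistribution", function(object) {
  cat(sprintf("MassIsotopomerDistribution: %s [%s]\n",
              object@fragment@analyte, object@sampleId))
  print(round(abundances(object), 6))
})

setMethod("show", "ExcessVector", function(object) {
  cat(sprintf("ExcessVector: %s [%s]\n", object@fragment@analyte,
              object@sampleId))
  print(round(excesses(object), 6))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

setMethod("show", "MidaResult", function(object) {
  cat(sprintf("MidaResult: %s [%s]  p = %.4f  FNS = %.4f\n",
              object@fattyAcid, object@sampleId, object@pPrecursor,
              object@fns))
  fl <- object@diagnostics$flags
  if (length(fl)) cat("  flags:", paste(fl, collapse = "; "), "\n")
})

setMethod("show", "PcPdhResult", function(object) {
  cat(sprintf("PcPdhResult [%s]: m2(152) = %.4f, m2(198) = %.4f, PC/PDH = %s\n",
              object@sampleId, object@m2_152, object@m2_198,
              if (object@defined) sprintf("%.4f", object@ratio) else "undefined"))
})

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf("EnrichmentResult: %s [%s]  SIGmn = %.4f\n", object@analyte,
              object@sampleId, object@sigmn))
})

setMethod("show", "StudyDesign", function(object) {
  s <- object@samples
  cat(sprintf("StudyDesign: %d samples, %d groups\n", nrow(s),
              length(unique(s$group))))
  cat("  groups:", paste(unique(s$group), collapse = ", "), "\n")
  cat(sprintf("  references: control = '%s', steatosis = '%s'\n",
              object@referenceControl, object@referenceSteatosis))
})
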