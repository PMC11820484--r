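#' @rdname accessors
#' @export
setGeneric("analyteName", function(x) standardGeneric("analyteName"))

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname accessors
#' @export
setGeneric("excesses", function(x) standardGeneric("excesses"))

#' @rdname accessors
#' @export
setGeneric("maxShift", function(x) standardGeneric("maxShift"))

#' @rdname accessors
#' @export
setGeneric("nSkeletonCarbons", function(x) standardGeneric("nSkeletonCarbons"))

#' @rdname accessors
#' @export
setGeneric("elementalFormula", function(x) standardGeneric("elementalFormula"))

#' @rdname accessors
#' @export
setGeneric("fragmentOf", function(x) standardGeneric("fragmentOf"))

#' @rdname accessors
#' @export
setGeneric("precursorEnrichment", function(x) standardGeneric("precursorEnrichment"))

#' @rdname accessors
#' @export
setGeneric("fns", function(x) standardGeneric("fns"))

#' @rdname accessors
#' @export
setGeneric("diagnostics", function(x) standardGeneric("diagnostics"))

#' @rdname accessors
#' @export
setGeneric("pcPdh", function(x) standardGeneric("pcPdh"))

#' @rdname accessors
#' @export
setGeneric("isDefined", function(x) standardGeneric("isDefined"))

#' @rdname accessors
#' @export
setGeneric("sigmnValue", function(x) standardGeneric("sigmnValue"))

#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname accessors
#' @export
setGeneric("groupNames", function(x) standardGeneric("groupNames"))

#' Compute summed molar enrichment
#' @param mid a \linkS4class{MassIsotopomerDistribution}
#' @export
setGeneric("sigmn", function(mid) standardGeneric("sigmn"))
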