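#' Construct a FragmentDefinition
#'
#' @param analyte analyte name.
#' @param monitoredMz nominal m/z of the monoisotopic monitored ion (Th).
#' @param nSkeletonCarbons number of carbons that can carry tracer 13C.
#' @param elementalFormula named integer vector element -> atom count for the
#'   derivatized fragment ion, e.g. `c(C = 17, H = 34, O = 2)`. May be empty
#'   for idealized fragments in tests.
#' @param maxShift highest mass-shift index K recorded (m0..mK).
#' @return a \linkS4class{FragmentDefinition}
#' @examples
#' fragmentDefinition("palmitate")
#' FragmentDefinition("acetate", 60, 2, c(C = 2, H = 4, O = 2), maxShift = 3)
#' @export
FragmentDefinition <- function(analyte, monitoredMz, nSkeletonCarbons,
                               elementalFormula = integer(), maxShift) {
  ef <- elementalFormula
  if (length(ef)) {
    storage.mode(ef) <- "integer"
  } else {
    ef <- integer()
  }
  new("FragmentDefinition",
      analyte          = as.character(analyte),
      monitoredMz      = as.integer(monitoredMz),
      nSkeletonCarbons = as.integer(nSkeletonCarbons),
      elementalFormula = ef,
      maxShift         = as.integer(maxShift))
}

# Built-in registry of the monitored fragments. Elemental compositions are
# those of the derivatized fragment ions consistent with the nominal m/z
# (methyl esters for fatty acids, n-TFA n-butyl ester fragments for
# glutamate, aldononitrile acetate derivatives for the sugars); only the
# non-skeleton atom counts enter the natural-abundance model.
.fragmentRegistry <- list(
  palmitate = list(mz = 270L, nC = 16L, K = 8L,
                   formula = c(C = 17L, H = 34L, O = 2L)),
  stearate  = list(mz = 298L, nC = 18L, K = 8L,
                   formula = c(C = 19L, H = 38L, O = 2L)),
  oleate    = list(mz = 296L, nC = 18L, K = 8L,
                   formula = c(C = 19L, H = 36L, O = 2L)),
  glutamate_152 = list(mz = 152L, nC = 3L, K = 5L,   # C2-C4 fragment
                       formula = c(C = 5L, H = 5L, F = 3L, N = 1L, O = 1L)),
  glutamate_198 = list(mz = 198L, nC = 4L, K = 5L,   # C2-C5 fragment
                       formula = c(C = 7L, H = 11L, F = 3L, N = 1L, O = 2L)),
  glucose_glycogen = list(mz = 328L, nC = 6L, K = 7L,
                          formula = c(C = 13L, H = 14L, N = 1L, O = 9L)),
  ribose    = list(mz = 256L, nC = 5L, K = 6L,       # carbons 1-5
                   formula = c(C = 11L, H = 14L, N = 1L, O = 6L))
)

#' Built-in fragment definitions for the monitored ions
#'
#' Returns the registered [FragmentDefinition-class] for one of the analytes
#' monitored in the tracing experiment: fatty-acid methyl esters (palmitate
#' m/z 270, stearate m/z 298, oleate m/z 296), the glutamate TAB fragments
#' (`glutamate_152`, C2-C4; `glutamate_198`, C2-C5), the glycogen-derived
#' glucose derivative (`glucose_glycogen`, m/z 328, all six carbons) and the
#' ribose aldononitrile acetate fragment (`ribose`, m/z 256, carbons 1-5).
#'
#' @param analyte one of `supportedAnalytes()`.
#' @param maxShift override the default recorded mass-shift range (fatty
#'   acids 8, glutamate fragments 5, glucose 7, ribose 6).
#' @return a \linkS4class{FragmentDefinition}
#' @examples
#' fragmentDefinition("ribose")
#' supportedAnalytes()
#' @export
fragmentDefinition <- function(analyte, maxShift = NULL) {
  if (!analyte %in% names(.fragmentRegistry))
    stop("unknown analyte '", analyte, "'; supported analytes: ",
         paste(names(.fragmentRegistry), collapse = ", "))
  r <- .fragmentRegistry[[analyte]]
  FragmentDefinition(analyte, r$mz, r$nC, r$formula,
                     maxShift = if (is.null(maxShift)) r$K else maxShift)
}

#' @rdname fragmentDefinition
#' @export
supportedAnalytes <- function() names(.fragmentRegistry)

# analyte name for a (analyte, fragment_mz) pair from a MID table row
.resolveAnalyte <- function(analyte, fragment_mz) {
  if (analyte == "glutamate") {
    if (!fragment_mz %in% c(152, 198))
      stop("glutamate fragment m/z must be 152 or 198, got ", fragment_mz)
    return(paste0("glutamate_", fragment_mz))
  }
  analyte
}
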