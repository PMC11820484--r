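#' Polymerization models for the measured long-chain fatty acids
#'
#' In the MIDA framework a fatty acid is a polymer of N acetyl subunits,
#' each of which is either fully 13C2-labeled (derived from U-13C glucose
#' via pyruvate dehydrogenase) or unlabeled, so label incorporation moves
#' the molecular mass in steps of +2. Palmitate (C16) has N = 8 subunits;
#' stearate (C18) and oleate (C18, desaturation does not change the carbon
#' count) have N = 9.
#'
#' @param fattyAcid "palmitate", "stearate" or "oleate", or the number of
#'   acetyl subunits directly (8 or 9).
#' @return list with elements `fattyAcid`, `nSubunits`, `subunitMassShift`.
#' @examples
#' polymerModel("palmitate")$nSubunits  # 8
#' @export
polymerModel <- function(fattyAcid) {
  if (is.numeric(fattyAcid)) {
    n <- as.integer(fattyAcid)
    name <- paste0("polymer_N", n)
  } else {
    name <- match.arg(fattyAcid, c("palmitate", "stearate", "oleate"))
    n <- c(palmitate = 8L, stearate = 9L, oleate = 9L)[[name]]
  }
  if (!n %in% c(8L, 9L))
    stop("polymer model supports 8 or 9 acetyl subunits, got ", n)
  list(fattyAcid = name, nSubunits = n, subunitMassShift = 2L)
}

#' Estimate acetyl-CoA precursor enrichment from the excess doublet ratio
#'
#' The classical MIDA doublet-ratio estimator. For a polymer of N subunits
#' drawn i.i.d. with labeling probability p, the excesses at mass shifts 2
#' and 4 (one and two labeled subunits) satisfy
#' \deqn{r = E_4 / E_2 = \frac{N-1}{2}\,\frac{p}{1-p},}
#' which inverts in closed form to \eqn{p = r / ((N-1)/2 + r)}.
#'
#' @param excess an \linkS4class{ExcessVector} for the fatty acid (excesses
#'   at shifts 2 and 4 are used).
#' @param model a [polymerModel()].
#' @param noiseFloor negative-E4 magnitude attributed to noise; a negative
#'   E4 within the floor is clamped to 0 (p = 0), a larger violation is
#'   flagged and still clamped.
#' @return list with `p` (the enrichment), `ratio` (E4/E2), and `flags`.
#' @examples
#' # doublet ratio 0.8210 on palmitate (N = 8) gives p = 0.19
#' fr <- fragmentDefinition("palmitate", maxShift = 8)
#' e <- new("ExcessVector", fragment = fr, sampleId = "s",
#'          excesses = c(0, 0.10, 0, 0.0821, 0, 0, 0, 0), flags = character())
#' estimatePrecursorEnrichment(e, polymerModel("palmitate"))$p
#' @export
estimatePrecursorEnrichment <- function(excess, model, noiseFloor = 0.005) {
  e <- excess@excesses
  if (length(e) < 4L)
    stop("excess vector must extend at least to mass shift 4")
  E2 <- e[2L]; E4 <- e[4L]
  if (E2 <= 0)
    stop("no detectable new synthesis: excess at mass shift 2 is not positive")
  flags <- character()
  if (E4 < 0) {
    if (abs(E4) > noiseFloor)
      flags <- c(flags, sprintf(
        "negative E4 (%.4f) beyond noise floor; clamped to 0", E4))
    E4 <- 0
  }
  r <- E4 / E2
  halfNm1 <- (model$nSubunits - 1) / 2
  list(p = r / (halfNm1 + r), ratio = r, flags = flags)
}

#' Estimate the fraction of new synthesis (FNS)
#'
#' Given the precursor enrichment p, the fraction of the fatty-acid pool
#' newly synthesized during the labeling period is the observed
#' singly-labeled excess over its expectation for a fully new pool:
#' \deqn{FNS = E_2 / \left[ \binom{N}{1} p (1-p)^{N-1} \right].}
#' An independent estimate from E4 (the doubly-labeled excess) is carried
#' in the diagnostics; a relative discrepancy above 10\% is flagged.
#'
#' @param excess an \linkS4class{ExcessVector}.
#' @param p precursor enrichment in (0, 1), from
#'   [estimatePrecursorEnrichment()].
#' @param model a [polymerModel()].
#' @return list with `fns` (clipped to [0, 1]), `fnsFromE4`, `flags`.
#' @export
estimateFns <- function(excess, p, model) {
  e <- excess@excesses
  E2 <- e[2L]
  E4 <- if (length(e) >= 4L) e[4L] else NA_real_
  if (p == 0) {
    if (E2 > 0)
      stop("inconsistent enrichment: p = 0 but excess at shift 2 is positive")
    return(list(fns = 0, fnsFromE4 = 0, flags = character()))
  }
  if (p < 0 || p >= 1) stop("p must lie in [0, 1)")
  N <- model$nSubunits
  expected2 <- N * p * (1 - p)^(N - 1)
  fns <- E2 / expected2
  if (fns > 1.05)
    stop(sprintf(
      "model violation: raw FNS estimate %.3f exceeds 1.05; the binomial polymerization model does not describe these data", fns))
  flags <- character()
  if (fns > 1) {
    flags <- c(flags, sprintf("raw FNS %.4f above 1; clipped", fns))
    fns <- 1
  }
  if (fns < 0) {
    flags <- c(flags, sprintf("raw FNS %.4f below 0; clipped", fns))
    fns <- 0
  }
  expected4 <- choose(N, 2) * p^2 * (1 - p)^(N - 2)
  fnsFromE4 <- if (!is.na(E4) && expected4 > 0) E4 / expected4 else NA_real_
  if (!is.na(fnsFromE4) && fns > 0 &&
      abs(fnsFromE4 - fns) / fns > 0.10)
    flags <- c(flags,
               sprintf("E4-based FNS (%.4f) differs from E2-based (%.4f) by more than 10%%",
                       fnsFromE4, fns))
  list(fns = fns, fnsFromE4 = fnsFromE4, flags = flags)
}

#' Full MIDA analysis of one fatty-acid excess vector
#'
#' Chains [estimatePrecursorEnrichment()] and [estimateFns()] and packages
#' the result.
#'
#' @param excess an \linkS4class{ExcessVector}.
#' @param model a [polymerModel()]; defaults to the model registered for
#'   the fragment's analyte.
#' @return a \linkS4class{MidaResult}
#' @export
midaAnalysis <- function(excess, model = polymerModel(excess@fragment@analyte)) {
  pe <- estimatePrecursorEnrichment(excess, model)
  fe <- estimateFns(excess, pe$p, model)
  new("MidaResult",
      fattyAcid = model$fattyAcid, sampleId = excess@sampleId,
      pPrecursor = pe$p, fns = fe$fns, excessUsed = excess,
      diagnostics = list(e4_e2_ratio = pe$ratio, fnsFromE4 = fe$fnsFromE4,
                         flags = c(pe$flags, fe$flags)))
}

#' Desaturation and elongation precursor-to-product indices
#'
#' `desaturationIndex()` is the ratio of newly synthesized oleate to newly
#' synthesized stearate, a proxy for delta-9 desaturase activity over the
#' experiment. `elongationIndex()` is the ratio of newly synthesized
#' stearate to newly synthesized palmitate, a proxy for chain elongation.
#' Both are undefined (NA) when the denominator FNS is zero.
#'
#' @param fnsOleate,fnsStearate,fnsPalmitate fractions of new synthesis.
#' @return numeric(1) ratio, or NA when undefined.
#' @examples
#' desaturationIndex(0.306, 0.200)  # 1.53
#' elongationIndex(0.180, 0.250)    # 0.72
#' @export
desaturationIndex <- function(fnsOleate, fnsStearate) {
  if (is.na(fnsStearate) || fnsStearate == 0) return(NA_real_)
  fnsOleate / fnsStearate
}

#' @rdname desaturationIndex
#' @export
elongationIndex <- function(fnsStearate, fnsPalmitate) {
  if (is.na(fnsPalmitate) || fnsPalmitate == 0) return(NA_real_)
  fnsStearate / fnsPalmitate
}

#' Long-chain fatty-acid composition as percent of total
#'
#' Converts total (labeled + unlabeled) peak areas per fatty-acid species
#' into percent-of-total composition over the reported species set.
#'
#' @param totalAbundances named nonnegative numeric vector of peak areas,
#'   e.g. `c("16:0" = 2e6, "18:0" = 1e6, ...)`.
#' @return named numeric vector of percentages summing to 100.
#' @examples
#' fattyAcidProfile(c("16:0" = 2, "18:0" = 1, "18:1n-9" = 1))
#' @export
fattyAcidProfile <- function(totalAbundances) {
  if (any(totalAbundances < 0)) stop("peak areas must be nonnegative")
  tot <- sum(totalAbundances)
  if (tot == 0) stop("all peak areas are zero")
  100 * totalAbundances / tot
}
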