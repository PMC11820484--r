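#' Natural isotope abundances (IUPAC defaults)
#'
#' Per-element distributions of the mass shift contributed by one atom,
#' indexed from shift 0. Values are the IUPAC representative isotopic
#' compositions; override entries to model a different matrix or tracer
#' batch.
#'
#' @return named list, element -> numeric vector of shift probabilities
#'   (shift 0, 1, 2, ...), each summing to 1.
#' @examples
#' naturalAbundances()$C   # 12C, 13C
#' @export
naturalAbundances <- function() {
  list(
    C  = c(0.9893,   0.0107),
    H  = c(0.999885, 0.000115),
    N  = c(0.99636,  0.00364),
    O  = c(0.99757,  0.00038, 0.00205),
    F  = 1,
    Si = c(0.92223,  0.04685, 0.03092),
    S  = c(0.9499,   0.0075,  0.0425, 0, 0.0001)
  )
}

# convolve two shift distributions, truncating at maxLen entries
.convTrunc <- function(a, b, maxLen) {
  out <- numeric(min(length(a) + length(b) - 1L, maxLen))
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    jmax <- min(length(b), maxLen - i + 1L)
    if (jmax < 1L) break
    idx <- i:(i + jmax - 1L)
    out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
  }
  out
}

# n-fold self-convolution of a single-atom shift distribution
.convPower <- function(dist, n, maxLen) {
  out <- 1
  for (k in seq_len(n)) out <- .convTrunc(out, dist, maxLen)
  out
}

#' Normalize raw isotopomer intensities to a MID
#'
#' Converts a vector of nonnegative SIM peak intensities (m0..mK) into
#' fractional abundances summing to 1.
#'
#' @param rawIntensities nonnegative numeric vector, length maxShift + 1.
#' @param fragment a \linkS4class{FragmentDefinition}.
#' @param sampleId sample identifier carried on the result.
#' @return a \linkS4class{MassIsotopomerDistribution}
#' @examples
#' fr <- FragmentDefinition("test", 100, 2, c(C = 2), maxShift = 2)
#' abundances(normalizeMid(c(50, 25, 25), fr))
#' @export
normalizeMid <- function(rawIntensities, fragment, sampleId = "sample") {
  if (length(rawIntensities) != fragment@maxShift + 1L)
    stop("expected ", fragment@maxShift + 1L, " intensities (m0..m",
         fragment@maxShift, "), got ", length(rawIntensities))
  if (any(rawIntensities < 0))
    stop("negative intensity in spectrum")
  tot <- sum(rawIntensities)
  if (tot == 0)
    stop("empty spectrum: all intensities are zero")
  new("MassIsotopomerDistribution",
      fragment = fragment, sampleId = as.character(sampleId),
      abundances = as.numeric(rawIntensities) / tot)
}

# MID from a known abundance vector (internal; renormalizes tiny drift)
.midFromAbundances <- function(abund, fragment, sampleId = "sample") {
  new("MassIsotopomerDistribution",
      fragment = fragment, sampleId = as.character(sampleId),
      abundances = abund / sum(abund))
}

#' Build the natural-abundance correction matrix for a fragment
#'
#' Column j is the predicted measured MID (mass shifts 0..K) of a molecule
#' whose tracer skeleton carries exactly j labels: the convolution of (a) j
#' tracer positions at the stated isotopic purity, (b) the remaining
#' `nSkeletonCarbons - j` skeleton carbons at natural 13C abundance, and
#' (c) the natural isotope envelopes of all non-skeleton atoms in the
#' elemental formula. Mass shifts beyond K are truncated, so columns sum to
#' at most 1. Columns for label counts exceeding the skeleton carbon count
#' (possible when K > nSkeletonCarbons) are physically impossible and are
#' left as zero columns; the nonnegative solver in
#' [correctNaturalAbundance()] assigns them no weight.
#'
#' @param fragment a \linkS4class{FragmentDefinition}.
#' @param abundances per-element isotope shift distributions, as
#'   [naturalAbundances()].
#' @param tracerPurity isotopic enrichment of each tracer position
#'   (default 0.99, i.e. 99 atom-percent 13C).
#' @return (K+1) x (K+1) matrix, K = `maxShift(fragment)`.
#' @examples
#' fr <- FragmentDefinition("test", 100, 2, c(C = 2), maxShift = 2)
#' buildCorrectionMatrix(fr, list(C = c(0.989, 0.011)))
#' @export
buildCorrectionMatrix <- function(fragment, abundances = naturalAbundances(),
                                  tracerPurity = 0.99) {
  K <- fragment@maxShift
  if (K + 1L < 2L) stop("fragment must record at least shifts m0 and m1")
  for (el in names(abundances)) {
    s <- sum(abundances[[el]])
    if (abs(s - 1) > 1e-6)
      stop("natural abundance fractions for element '", el,
           "' must sum to 1 (got ", s, ")")
  }
  nSkel <- fragment@nSkeletonCarbons
  ef <- fragment@elementalFormula
  maxLen <- K + 1L

  # envelope of all non-skeleton atoms (fixed across columns)
  nonSkel <- 1
  for (el in names(ef)) {
    n <- ef[[el]]
    if (el == "C") n <- n - nSkel
    if (n <= 0L) next
    if (!el %in% names(abundances))
      stop("no natural abundance data for element '", el, "'")
    nonSkel <- .convTrunc(nonSkel, .convPower(abundances[[el]], n, maxLen),
                          maxLen)
  }
  cNat <- if ("C" %in% names(abundances)) abundances[["C"]] else c(1)
  tracer <- c(1 - tracerPurity, tracerPurity)

  M <- matrix(0, nrow = maxLen, ncol = maxLen)
  for (j in 0:K) {
    if (j > nSkel) next   # impossible label count: zero column
    col <- nonSkel
    if (nSkel - j > 0L)
      col <- .convTrunc(col, .convPower(cNat, nSkel - j, maxLen), maxLen)
    if (j > 0L)
      col <- .convTrunc(col, .convPower(tracer, j, maxLen), maxLen)
    M[seq_along(col), j + 1L] <- col
  }
  dimnames(M) <- list(paste0("m", 0:K), paste0("x", 0:K))
  M
}

#' Forward-convolve an ideal label distribution into a measured MID
#'
#' Applies the correction matrix in the forward direction: given the
#' distribution of true tracer-label counts, predicts the MID that would be
#' measured under natural isotope abundance. Inverse of
#' [correctNaturalAbundance()].
#'
#' @param mid a \linkS4class{MassIsotopomerDistribution} of true label
#'   counts.
#' @param matrix correction matrix from [buildCorrectionMatrix()] for the
#'   same fragment.
#' @return a \linkS4class{MassIsotopomerDistribution} (renormalized; the
#'   truncated tail beyond K is discarded).
#' @export
convolveNaturalAbundance <- function(mid, matrix) {
  .checkMatrixFragment(mid, matrix)
  meas <- as.numeric(matrix %*% mid@abundances)
  .midFromAbundances(meas, mid@fragment, mid@sampleId)
}

.checkMatrixFragment <- function(mid, matrix) {
  K <- mid@fragment@maxShift
  if (!is.matrix(matrix) || nrow(matrix) != K + 1L || ncol(matrix) != K + 1L)
    stop("correction matrix dimensions do not match fragment (expected ",
         K + 1L, " x ", K + 1L, ")")
}

#' Correct a measured MID for natural isotope abundance
#'
#' Solves `matrix %*% x = measured` for the distribution of true tracer
#' label counts by nonnegative least squares, then renormalizes x to sum
#' to 1. Nonnegative least squares (rather than a plain inverse) keeps the
#' solution stable under measurement noise and under the truncated,
#' rank-deficient matrices that arise when K exceeds the skeleton carbon
#' count.
#'
#' @param mid measured \linkS4class{MassIsotopomerDistribution}.
#' @param matrix correction matrix from [buildCorrectionMatrix()] for the
#'   same fragment.
#' @return corrected \linkS4class{MassIsotopomerDistribution}
#' @examples
#' fr <- FragmentDefinition("test", 100, 2, c(C = 2), maxShift = 2)
#' M <- buildCorrectionMatrix(fr, list(C = c(0.989, 0.011)))
#' ideal <- normalizeMid(c(0.7, 0.2, 0.1), fr)
#' meas <- convolveNaturalAbundance(ideal, M)
#' abundances(correctNaturalAbundance(meas, M))  # recovers (0.7, 0.2, 0.1)
#' @export
correctNaturalAbundance <- function(mid, matrix) {
  .checkMatrixFragment(mid, matrix)
  nz <- colSums(matrix) > 0   # drop impossible-label zero columns
  Mnz <- matrix[, nz, drop = FALSE]
  if (kappa(Mnz, exact = TRUE) > 1e8)
    stop("correction matrix is ill-conditioned (condition number > 1e8); ",
         "reduce maxShift (K) for this fragment")
  fit <- pracma::lsqnonneg(Mnz, mid@abundances)
  x <- numeric(ncol(matrix))
  x[nz] <- fit$x
  if (sum(x) == 0)
    stop("natural-abundance correction produced an empty distribution")
  .midFromAbundances(x, mid@fragment, mid@sampleId)
}

#' Theoretical baseline MIDs
#'
#' `naturalBaselineMid()` is the MID expected from a fully unlabeled
#' molecule under natural isotope abundance (column 0 of the correction
#' matrix, renormalized) — the default baseline for excess computation on
#' uncorrected data. `unlabeledBaselineMid()` is the point mass at shift 0,
#' the baseline appropriate after natural-abundance correction.
#'
#' @param fragment a \linkS4class{FragmentDefinition}.
#' @param abundances per-element isotope distributions, as
#'   [naturalAbundances()].
#' @return a \linkS4class{MassIsotopomerDistribution}
#' @export
naturalBaselineMid <- function(fragment, abundances = naturalAbundances()) {
  M <- buildCorrectionMatrix(fragment, abundances)
  .midFromAbundances(M[, 1L], fragment, "baseline")
}

#' @rdname naturalBaselineMid
#' @export
unlabeledBaselineMid <- function(fragment) {
  a <- numeric(fragment@maxShift + 1L)
  a[1L] <- 1
  new("MassIsotopomerDistribution", fragment = fragment,
      sampleId = "baseline", abundances = a)
}

#' Excess isotopomer vector of a sample over a baseline
#'
#' Computes E_i = sample a_i - baseline a_i for mass shifts i >= 1. Entries
#' below -0.005 (beyond what measurement noise explains) are flagged.
#'
#' @param sample,baseline \linkS4class{MassIsotopomerDistribution}s of the
#'   same fragment.
#' @return an \linkS4class{ExcessVector}
#' @examples
#' fr <- fragmentDefinition("ribose")
#' base <- unlabeledBaselineMid(fr)
#' excesses(excessMid(base, base))  # zero vector
#' @export
excessMid <- function(sample, baseline) {
  fs <- sample@fragment; fb <- baseline@fragment
  if (fs@analyte != fb@analyte || fs@maxShift != fb@maxShift)
    stop("fragment mismatch between sample ('", fs@analyte,
         "', K = ", fs@maxShift, ") and baseline ('", fb@analyte,
         "', K = ", fb@maxShift, ")")
  e <- (sample@abundances - baseline@abundances)[-1L]
  flags <- character()
  if (any(e < -0.005))
    flags <- sprintf("negative excess below -0.005 at shift(s) %s",
                     paste(which(e < -0.005), collapse = ", "))
  new("ExcessVector", fragment = fs, sampleId = sample@sampleId,
      excesses = e, flags = flags)
}
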