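# multiplicative log-normal noise on the intensity scale, then renormalize;
# cv is the coefficient of variation of the multiplicative factor
.noisyMid <- function(abund, cv) {
  if (cv <= 0) return(abund)
  sdlog <- sqrt(log(1 + cv^2))
  f <- exp(stats::rnorm(length(abund), -sdlog^2 / 2, sdlog))
  a <- abund * f
  a / sum(a)
}

.maybeSeed <- function(seed) if (!is.null(seed)) set.seed(seed)

# fragment used to simulate a fatty-acid MID: full binomial support (2N)
.faSimFragment <- function(model) {
  K <- 2L * model$nSubunits
  if (model$fattyAcid %in% names(.fragmentRegistry))
    fragmentDefinition(model$fattyAcid, maxShift = K)
  else
    FragmentDefinition(model$fattyAcid, 0L, 2L * model$nSubunits,
                       maxShift = K)
}

#' Simulate a fatty-acid mass isotopomer distribution
#'
#' Forward model of the MIDA inference: a polymer of N acetyl subunits,
#' each 13C2-labeled with probability p, gives a newly synthesized pool
#' with binomial isotopomer abundances on mass shifts 0, 2, 4, ...; the
#' sampled pool is the mixture `(1 - fns) * unlabeled + fns * new`.
#' Natural-isotope convolution and multiplicative log-normal noise are
#' optional.
#'
#' @param fns true fraction of new synthesis in [0, 1].
#' @param p true subunit (acetyl-CoA 13C2) labeling probability in [0, 1].
#' @param model a [polymerModel()].
#' @param noiseCv coefficient of variation of multiplicative intensity
#'   noise (0 = noiseless).
#' @param applyNaturalAbundance convolve with the fragment's natural
#'   isotope envelope (at `tracerPurity` per labeled position).
#' @param tracerPurity tracer 13C enrichment per position (default 0.99).
#' @param abundances per-element isotope distributions, as
#'   [naturalAbundances()].
#' @param sampleId sample identifier for the result.
#' @param seed optional RNG seed (set once; omit inside [simulateStudy()]).
#' @return a \linkS4class{MassIsotopomerDistribution} with
#'   `maxShift = 2 N` (full binomial support).
#' @examples
#' m <- simulateFattyAcidMid(0.4, 0.19, polymerModel("palmitate"))
#' midaAnalysis(excessMid(m, unlabeledBaselineMid(fragmentOf(m))))
#' @export
simulateFattyAcidMid <- function(fns, p, model, noiseCv = 0,
                                 applyNaturalAbundance = FALSE,
                                 tracerPurity = 0.99,
                                 abundances = naturalAbundances(),
                                 sampleId = "sim", seed = NULL) {
  stopifnot(fns >= 0, fns <= 1, p >= 0, p <= 1)
  .maybeSeed(seed)
  fr <- .faSimFragment(model)
  N <- model$nSubunits
  a <- numeric(fr@maxShift + 1L)
  newPool <- stats::dbinom(0:N, N, p)
  a[2L * (0:N) + 1L] <- fns * newPool
  a[1L] <- a[1L] + (1 - fns)
  mid <- .midFromAbundances(a, fr, sampleId)
  if (applyNaturalAbundance) {
    M <- buildCorrectionMatrix(fr, abundances, tracerPurity)
    mid <- convolveNaturalAbundance(mid, M)
  }
  .midFromAbundances(.noisyMid(mid@abundances, noiseCv), fr, sampleId)
}

#' Simulate the glutamate TAB fragment pair under the single-turn model
#'
#' PC and PDH labeling are independent per-molecule events: the C2-C3
#' carbon pair is 13C2-labeled with probability b (pyruvate carboxylase
#' entry) and the C4-C5 pair with probability a (pyruvate dehydrogenase
#' entry). The C2-C4 fragment (m/z 152) then has
#' m0 = (1-a)(1-b), m1 = a(1-b), m2 = b(1-a), m3 = ab (only C4 of the PDH
#' pair lies inside the fragment), and the C2-C5 fragment (m/z 198) has
#' m0 = (1-a)(1-b), m2 = a(1-b) + b(1-a), m4 = ab. Multi-turn TCA
#' scrambling is deliberately excluded; this is the minimal model behind
#' the PC/PDH ratio.
#'
#' @param aPdh,bPc labeling probabilities in [0, 1].
#' @inheritParams simulateFattyAcidMid
#' @return a [glutamateFragmentPair()]
#' @examples
#' pair <- simulateGlutamateFragments(0.300, 0.3665)
#' pcPdh(pcPdhRatio(pair))  # 1.35
#' @export
simulateGlutamateFragments <- function(aPdh, bPc, noiseCv = 0,
                                       applyNaturalAbundance = FALSE,
                                       tracerPurity = 0.99,
                                       abundances = naturalAbundances(),
                                       sampleId = "sim", seed = NULL) {
  stopifnot(aPdh >= 0, aPdh <= 1, bPc >= 0, bPc <= 1)
  .maybeSeed(seed)
  a <- aPdh; b <- bPc
  fr152 <- fragmentDefinition("glutamate_152")
  fr198 <- fragmentDefinition("glutamate_198")
  a152 <- c((1 - a) * (1 - b), a * (1 - b), b * (1 - a), a * b,
            numeric(fr152@maxShift - 3L))
  a198 <- c((1 - a) * (1 - b), 0, a * (1 - b) + b * (1 - a), 0, a * b,
            numeric(fr198@maxShift - 4L))
  mk <- function(abund, fr) {
    mid <- .midFromAbundances(abund, fr, sampleId)
    if (applyNaturalAbundance) {
      M <- buildCorrectionMatrix(fr, abundances, tracerPurity)
      mid <- convolveNaturalAbundance(mid, M)
    }
    .midFromAbundances(.noisyMid(mid@abundances, noiseCv), fr, sampleId)
  }
  glutamateFragmentPair(mk(a152, fr152), mk(a198, fr198))
}

#' Simulate a two-component unit-labeling MID (glycogen glucose, ribose)
#'
#' Forward model for units polymerized from either fully labeled or fully
#' unlabeled precursor: a fraction of molecules carries the label on all
#' skeleton carbons (mass shift = carbon count), the rest are unlabeled.
#'
#' @param labeledFraction fraction of fully labeled molecules in [0, 1].
#' @param nCarbons labeled-skeleton carbon count: 6 selects the
#'   glycogen-glucose fragment (m/z 328), 5 the ribose fragment (m/z 256).
#' @inheritParams simulateFattyAcidMid
#' @return a \linkS4class{MassIsotopomerDistribution}
#' @examples
#' sigmnValue(sigmn(simulateUnitLabeling(0.275, 6)))  # 1.65
#' @export
simulateUnitLabeling <- function(labeledFraction, nCarbons, noiseCv = 0,
                                 applyNaturalAbundance = FALSE,
                                 tracerPurity = 0.99,
                                 abundances = naturalAbundances(),
                                 sampleId = "sim", seed = NULL) {
  stopifnot(labeledFraction >= 0, labeledFraction <= 1)
  .maybeSeed(seed)
  fr <- if (nCarbons == 6L) fragmentDefinition("glucose_glycogen")
        else if (nCarbons == 5L) fragmentDefinition("ribose")
        else FragmentDefinition(paste0("unit_C", nCarbons), 0L, nCarbons,
                                maxShift = nCarbons + 1L)
  a <- numeric(fr@maxShift + 1L)
  a[1L] <- 1 - labeledFraction
  a[nCarbons + 1L] <- labeledFraction
  mid <- .midFromAbundances(a, fr, sampleId)
  if (applyNaturalAbundance) {
    M <- buildCorrectionMatrix(fr, abundances, tracerPurity)
    mid <- convolveNaturalAbundance(mid, M)
  }
  .midFromAbundances(.noisyMid(mid@abundances, noiseCv), fr, sampleId)
}

# per-group truth defaults emulating the six-arm steatosis study under 50%
# U-13C-glucose: FNS triples anchored to the printed precursor-to-product
# indices, (a, b) back-solved from the printed PC/PDH group means, labeled
# fractions = group SIGmn / carbon count
.defaultGroupTruth <- function() {
  g <- function(fnsP, fnsS, fnsO, pA, a, b, glyc, rib, oro,
                cck8 = 0.5, glucoseRemaining = c(1.8, 1.4, 1.6))
    list(fns = c(palmitate = fnsP, stearate = fnsS, oleate = fnsO),
         pAcetyl = pA, aPdh = a, bPc = b,
         glycogenLabeledFraction = glyc, riboseLabeledFraction = rib,
         oroAbsorbance = oro, cck8Absorbance = cck8,
         glucoseRemainingMM = glucoseRemaining)
  list(
    control      = g(0.250, 0.0975, 0.149175, 0.19, 0.300, 0.3665,
                     0.275000, 0.308, 0.50),
    oa_steatosis = g(0.250, 0.1800, 0.018000, 0.19, 0.400, 0.3852,
                     0.258333, 0.292, 0.80),
    naringenin   = g(0.220, 0.1430, 0.024310, 0.19, 0.400, 0.3671,
                     0.258333, 0.298, 0.80),
    morin        = g(0.300, 0.1770, 0.033630, 0.19, 0.300, 0.3991,
                     0.235000, 0.258, 0.80),
    topiramate   = g(0.220, 0.1300, 0.016900, 0.19, 0.300, 0.3560,
                     0.280000, 0.286, 0.65),
    silibinin    = g(0.220, 0.1210, 0.015730, 0.20, 0.300, 0.3359,
                     0.233333, 0.282, 0.65,
                     glucoseRemaining = c(1.8, 3.1, 1.6))
  )
}

#' Configuration for a synthetic tracing study
#'
#' The defaults emulate the six-arm hepatocyte steatosis experiment: an
#' untreated control, an oleic-acid steatosis (vehicle) control, and four
#' treatment arms, six replicates each, 72 h of 50\% U-13C-glucose
#' labeling. Group truth values are chosen so that the analysis pipeline,
#' run on noiseless output, reproduces the study's printed group-level
#' results (precursor enrichment 0.19, PC/PDH ratios, SIGmn enrichments,
#' desaturation/elongation indices, ORO fold changes).
#'
#' @param seed integer RNG seed; a fixed seed makes [simulateStudy()]
#'   bit-reproducible.
#' @param groups group names; must match names of `groupTruth`.
#' @param replicatesPerGroup biological replicates per group.
#' @param groupTruth named list of per-group truth lists (see
#'   `.defaultGroupTruth` in the source for the shape).
#' @param midMultiplicativeCv CV of multiplicative intensity noise on MIDs.
#' @param absorbanceCv CV of plate absorbance noise.
#' @param applyNaturalAbundance convolve simulated MIDs with natural
#'   isotope envelopes (the analysis must then correct them).
#' @param tracerPurity tracer 13C enrichment per position.
#' @param referenceControl,referenceSteatosis names of the two reference
#'   groups.
#' @param plateCalibration list: blankAu, standardAu, standardMM,
#'   initialMediumMM used by the glucose assay forward model.
#' @return list of class "midfluxSimulationConfig"
#' @export
simulationConfig <- function(seed = 1L,
                             groups = names(.defaultGroupTruth()),
                             replicatesPerGroup = 6L,
                             groupTruth = .defaultGroupTruth()[groups],
                             midMultiplicativeCv = 0.02,
                             absorbanceCv = 0.03,
                             applyNaturalAbundance = TRUE,
                             tracerPurity = 0.99,
                             referenceControl = groups[1L],
                             referenceSteatosis = if (length(groups) > 1L)
                               groups[2L] else groups[1L],
                             plateCalibration = list(
                               blankAu = 0.05, standardAu = 0.55,
                               standardMM = 5.55, initialMediumMM = 5.5)) {
  if (!setequal(names(groupTruth), groups))
    stop("'groupTruth' must have one entry per group")
  for (g in groups) {
    tr <- groupTruth[[g]]
    fr <- c(tr$fns, tr$pAcetyl, tr$aPdh, tr$bPc,
            tr$glycogenLabeledFraction, tr$riboseLabeledFraction)
    if (any(fr < 0 | fr > 1))
      stop("truth fractions for group '", g, "' must lie in [0, 1]")
  }
  if (replicatesPerGroup < 1L) stop("'replicatesPerGroup' must be >= 1")
  structure(list(
    seed = as.integer(seed), groups = groups,
    replicatesPerGroup = as.integer(replicatesPerGroup),
    groupTruth = groupTruth[groups],
    noise = list(midMultiplicativeCv = midMultiplicativeCv,
                 absorbanceCv = absorbanceCv),
    applyNaturalAbundance = applyNaturalAbundance,
    tracerPurity = tracerPurity,
    referenceControl = referenceControl,
    referenceSteatosis = referenceSteatosis,
    plateCalibration = plateCalibration
  ), class = "midfluxSimulationConfig")
}

#' Simulate a complete synthetic tracing study
#'
#' Generates the MID table and plate-reading table the analysis pipeline
#' consumes, together with a truth ledger recording every generator
#' parameter per sample so estimator output can be scored against truth.
#' Deterministic (bit-identical) under a fixed seed.
#'
#' @param config a [simulationConfig()].
#' @return list with `midTable` (data.frame in the CSV dialect of
#'   [readMidTable()]), `plateTable` (data.frame for [readPlateTable()]),
#'   `design` (a \linkS4class{StudyDesign}), and `truth` (list: `perSample`
#'   data.frame of true parameters, `config` echo).
#' @examples
#' study <- simulateStudy(simulationConfig(seed = 7, replicatesPerGroup = 2,
#'                                         midMultiplicativeCv = 0))
#' head(study$truth$perSample)
#' @export
simulateStudy <- function(config = simulationConfig()) {
  set.seed(config$seed)
  cv <- config$noise$midMultiplicativeCv
  acv <- config$noise$absorbanceCv
  na <- config$applyNaturalAbundance
  pur <- config$tracerPurity
  cal <- config$plateCalibration

  midRows <- list(); plateRows <- list(); truthRows <- list()
  designRows <- list()
  midRow <- function(mid, group) {
    a <- mid@abundances
    row <- c(list(sample_id = mid@sampleId, group = group,
                  analyte = sub("_(152|198)$", "", mid@fragment@analyte),
                  fragment_mz = mid@fragment@monitoredMz),
             as.list(a))
    names(row)[-(1:4)] <- paste0("m", seq_along(a) - 1L)
    row
  }
  noisyAu <- function(mu) {
    if (acv <= 0) return(mu)
    sdlog <- sqrt(log(1 + acv^2))
    mu * exp(stats::rnorm(1L, -sdlog^2 / 2, sdlog))
  }

  for (g in config$groups) {
    tr <- config$groupTruth[[g]]
    for (r in seq_len(config$replicatesPerGroup)) {
      sid <- sprintf("%s_r%02d", g, r)
      designRows[[sid]] <- data.frame(sample_id = sid, group = g,
                                      timepoint_h = 72L,
                                      replicate_index = r,
                                      stringsAsFactors = FALSE)
      for (fa in names(tr$fns)) {
        mid <- simulateFattyAcidMid(tr$fns[[fa]], tr$pAcetyl,
                                    polymerModel(fa), noiseCv = cv,
                                    applyNaturalAbundance = na,
                                    tracerPurity = pur, sampleId = sid)
        midRows[[length(midRows) + 1L]] <- midRow(mid, g)
      }
      pair <- simulateGlutamateFragments(tr$aPdh, tr$bPc, noiseCv = cv,
                                         applyNaturalAbundance = na,
                                         tracerPurity = pur, sampleId = sid)
      midRows[[length(midRows) + 1L]] <- midRow(pair$mid152, g)
      midRows[[length(midRows) + 1L]] <- midRow(pair$mid198, g)
      glc <- simulateUnitLabeling(tr$glycogenLabeledFraction, 6L,
                                  noiseCv = cv, applyNaturalAbundance = na,
                                  tracerPurity = pur, sampleId = sid)
      rib <- simulateUnitLabeling(tr$riboseLabeledFraction, 5L,
                                  noiseCv = cv, applyNaturalAbundance = na,
                                  tracerPurity = pur, sampleId = sid)
      midRows[[length(midRows) + 1L]] <- midRow(glc, g)
      midRows[[length(midRows) + 1L]] <- midRow(rib, g)

      tp <- c(24L, 48L, 72L)
      for (k in seq_along(tp)) {
        au <- cal$blankAu + (cal$standardAu - cal$blankAu) *
          tr$glucoseRemainingMM[k] / cal$standardMM
        plateRows[[length(plateRows) + 1L]] <- data.frame(
          sample_id = sid, group = g, assay = "glucose_GOPOD_505nm",
          timepoint_h = tp[k], absorbance = noisyAu(au),
          stringsAsFactors = FALSE)
        plateRows[[length(plateRows) + 1L]] <- data.frame(
          sample_id = sid, group = g, assay = "CCK8_450nm",
          timepoint_h = tp[k], absorbance = noisyAu(tr$cck8Absorbance),
          stringsAsFactors = FALSE)
      }
      plateRows[[length(plateRows) + 1L]] <- data.frame(
        sample_id = sid, group = g, assay = "ORO_490nm", timepoint_h = 48L,
        absorbance = noisyAu(tr$oroAbsorbance), stringsAsFactors = FALSE)

      truthRows[[length(truthRows) + 1L]] <- data.frame(
        sample_id = sid, group = g,
        fns_palmitate = tr$fns[["palmitate"]],
        fns_stearate = tr$fns[["stearate"]],
        fns_oleate = tr$fns[["oleate"]],
        p_acetyl = tr$pAcetyl, a_pdh = tr$aPdh, b_pc = tr$bPc,
        pc_pdh = tr$bPc * (1 - tr$aPdh) / (tr$aPdh * (1 - tr$bPc)),
        desaturation_index = tr$fns[["oleate"]] / tr$fns[["stearate"]],
        elongation_index = tr$fns[["stearate"]] / tr$fns[["palmitate"]],
        sigmn_glycogen = 6 * tr$glycogenLabeledFraction,
        sigmn_ribose = 5 * tr$riboseLabeledFraction,
        stringsAsFactors = FALSE)
    }
  }
  # calibration wells for the glucose assay, one blank + standard per plate
  for (t in c(24L, 48L, 72L)) {
    plateRows[[length(plateRows) + 1L]] <- data.frame(
      sample_id = "blank", group = "calibration",
      assay = "glucose_GOPOD_505nm", timepoint_h = t,
      absorbance = cal$blankAu, stringsAsFactors = FALSE)
    plateRows[[length(plateRows) + 1L]] <- data.frame(
      sample_id = "standard", group = "calibration",
      assay = "glucose_GOPOD_505nm", timepoint_h = t,
      absorbance = cal$standardAu, stringsAsFactors = FALSE)
  }

  # ragged K across analytes: pad every row to the widest shift range
  allCols <- unique(unlist(lapply(midRows, names)))
  mCols <- allCols[startsWith(allCols, "m")]
  mCols <- mCols[order(as.integer(sub("m", "", mCols)))]
  midTable <- do.call(rbind, lapply(midRows, function(row) {
    miss <- setdiff(mCols, names(row))
    row[miss] <- NA_real_
    as.data.frame(row[c("sample_id", "group", "analyte", "fragment_mz",
                        mCols)], stringsAsFactors = FALSE)
  }))
  design <- studyDesign(do.call(rbind, designRows),
                        referenceControl = config$referenceControl,
                        referenceSteatosis = config$referenceSteatosis)
  list(midTable = midTable,
       plateTable = do.call(rbind, plateRows),
       design = design,
       truth = list(perSample = do.call(rbind, truthRows),
                    config = config))
}
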