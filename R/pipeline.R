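#' Run the full carbon-flux analysis pipeline
#'
#' Orchestrates the complete analysis of one labeling study:
#' normalization, natural-abundance correction, MIDA estimation of
#' precursor enrichment and FNS for each fatty acid, desaturation and
#' elongation indices, the glutamate PC/PDH ratio, SIGmn enrichment of
#' glycogen-derived glucose and ribose, plate-assay readouts, and the
#' group-comparison report with a direction-of-change summary matrix.
#'
#' @param midTable path to a MID CSV, a data.frame in that dialect, or the
#'   list returned by [simulateStudy()] (in which case its plate table and
#'   design are used unless overridden).
#' @param plateTable optional path or data.frame of plate readings.
#' @param design optional \linkS4class{StudyDesign}; derived from the MID
#'   table when absent.
#' @param correctNA apply natural-abundance correction to every MID before
#'   analysis (set FALSE when the instrument software already corrected).
#' @param baseline excess baseline when `correctNA = FALSE`: the
#'   theoretical natural-abundance MID (default) or the pure-unlabeled
#'   point mass. After correction the pure-unlabeled baseline is always
#'   used.
#' @param abundances per-element isotope distributions, as
#'   [naturalAbundances()].
#' @param tracerPurity tracer 13C enrichment per position.
#' @param initialMediumMM medium glucose at the start of each 24 h
#'   interval, for depletion accounting.
#' @param referenceControl,referenceSteatosis reference groups (used when
#'   the design is derived from the table).
#' @return list with components `mida`, `indices`, `midaGroups`,
#'   `indicesGroups`, `pcPdh`, `pcPdhGroups`, `enrichment`,
#'   `enrichmentGroups`, `plate`, `outcomes`, `report`, `design`.
#' @examples
#' study <- simulateStudy(simulationConfig(seed = 1, replicatesPerGroup = 2,
#'                                         midMultiplicativeCv = 0,
#'                                         absorbanceCv = 0))
#' res <- runPipeline(study)
#' res$report$direction
#' @export
runPipeline <- function(midTable, plateTable = NULL, design = NULL,
                        correctNA = TRUE,
                        baseline = c("natural", "unlabeled"),
                        abundances = naturalAbundances(),
                        tracerPurity = 0.99,
                        initialMediumMM = 5.5,
                        referenceControl = "control",
                        referenceSteatosis = "oa_steatosis") {
  baseline <- match.arg(baseline)
  if (is.list(midTable) && !is.data.frame(midTable) &&
      all(c("midTable", "plateTable", "design") %in% names(midTable))) {
    study <- midTable
    midTable <- study$midTable
    if (is.null(plateTable)) plateTable <- study$plateTable
    if (is.null(design)) design <- study$design
  }
  if (is.character(midTable))
    midTable <- utils::read.csv(midTable, stringsAsFactors = FALSE)
  parsed <- .parseMidTable(midTable)
  if (is.null(design))
    design <- studyDesign(parsed$designDf, referenceControl,
                          referenceSteatosis)
  if (is.character(plateTable)) plateTable <- readPlateTable(plateTable)

  s <- samples(design)
  grpOf <- function(id) s$group[match(id, s$sample_id)]

  # --- correction and excess baselines, cached per fragment -------------
  matCache <- list(); baseCache <- list()
  prep <- function(mid) {
    an <- mid@fragment@analyte
    if (correctNA) {
      if (is.null(matCache[[an]]))
        matCache[[an]] <<- buildCorrectionMatrix(mid@fragment, abundances,
                                                 tracerPurity)
      mid <- correctNaturalAbundance(mid, matCache[[an]])
      if (is.null(baseCache[[an]]))
        baseCache[[an]] <<- unlabeledBaselineMid(mid@fragment)
    } else if (is.null(baseCache[[an]])) {
      baseCache[[an]] <<- if (baseline == "natural")
        naturalBaselineMid(mid@fragment, abundances)
      else unlabeledBaselineMid(mid@fragment)
    }
    mid
  }

  mids <- lapply(parsed$mids, prep)
  resolved <- parsed$resolved
  ids <- vapply(mids, sampleId, character(1))
  sampleIds <- unique(s$sample_id)

  pick <- function(sid, an) {
    i <- which(ids == sid & resolved == an)
    if (length(i) == 1L) mids[[i]] else NULL
  }

  # --- MIDA on the fatty acids -----------------------------------------
  midaRows <- list(); idxRows <- list()
  for (sid in sampleIds) {
    fnsOf <- c(palmitate = NA_real_, stearate = NA_real_,
               oleate = NA_real_)
    for (fa in c("palmitate", "stearate", "oleate")) {
      mid <- pick(sid, fa)
      if (is.null(mid)) next
      exc <- excessMid(mid, baseCache[[fa]])
      res <- midaAnalysis(exc, polymerModel(fa))
      fnsOf[[fa]] <- fns(res)
      midaRows[[length(midaRows) + 1L]] <- data.frame(
        sample_id = sid, group = grpOf(sid), fatty_acid = fa,
        p_precursor = precursorEnrichment(res), fns = fns(res),
        flags = paste(diagnostics(res)$flags, collapse = "; "),
        stringsAsFactors = FALSE)
    }
    idxRows[[length(idxRows) + 1L]] <- data.frame(
      sample_id = sid, group = grpOf(sid),
      desaturation_index = desaturationIndex(fnsOf[["oleate"]],
                                             fnsOf[["stearate"]]),
      elongation_index = elongationIndex(fnsOf[["stearate"]],
                                         fnsOf[["palmitate"]]),
      stringsAsFactors = FALSE)
  }
  midaTab <- do.call(rbind, midaRows)
  idxTab <- do.call(rbind, idxRows)

  groupMeanSd <- function(df, valueCol) {
    out <- do.call(rbind, lapply(split(df, df$group), function(d)
      data.frame(group = d$group[1], n = sum(!is.na(d[[valueCol]])),
                 mean = mean(d[[valueCol]], na.rm = TRUE),
                 sd = stats::sd(d[[valueCol]], na.rm = TRUE),
                 stringsAsFactors = FALSE)))
    rownames(out) <- NULL
    out
  }
  midaGroups <- if (!is.null(midaTab)) do.call(rbind, lapply(
    split(midaTab, midaTab$fatty_acid), function(d) {
      g <- groupMeanSd(d, "fns")
      g$fatty_acid <- d$fatty_acid[1]
      gp <- groupMeanSd(d, "p_precursor")
      g$p_mean <- gp$mean[match(g$group, gp$group)]
      g
    })) else NULL
  if (!is.null(midaGroups)) rownames(midaGroups) <- NULL
  indicesGroups <- if (!is.null(idxTab))
    list(desaturation = groupMeanSd(idxTab, "desaturation_index"),
         elongation = groupMeanSd(idxTab, "elongation_index")) else NULL

  # --- glutamate PC/PDH -------------------------------------------------
  pcResults <- list()
  for (sid in sampleIds) {
    m152 <- pick(sid, "glutamate_152"); m198 <- pick(sid, "glutamate_198")
    if (is.null(m152) || is.null(m198)) next
    pcResults[[length(pcResults) + 1L]] <-
      pcPdhRatio(glutamateFragmentPair(m152, m198))
  }
  pcTab <- if (length(pcResults)) do.call(rbind, lapply(pcResults, function(r)
    data.frame(sample_id = sampleId(r), group = grpOf(sampleId(r)),
               m2_152 = r@m2_152, m2_198 = r@m2_198, pc_pdh = pcPdh(r),
               defined = isDefined(r), stringsAsFactors = FALSE))) else NULL
  pcGroups <- if (length(pcResults) &&
                  all(table(grpOf(vapply(pcResults, sampleId,
                                         character(1)))) >= 2))
    pcPdhGroupSummary(pcResults, design) else NULL

  # --- SIGmn enrichment -------------------------------------------------
  enrRows <- list(); enrGroups <- list()
  for (an in c("glucose_glycogen", "ribose")) {
    res <- list()
    for (sid in sampleIds) {
      mid <- pick(sid, an)
      if (is.null(mid)) next
      res[[length(res) + 1L]] <- sigmn(mid)
    }
    if (!length(res)) next
    enrRows[[an]] <- do.call(rbind, lapply(res, function(r)
      data.frame(sample_id = sampleId(r), group = grpOf(sampleId(r)),
                 analyte = an, sigmn = sigmnValue(r),
                 stringsAsFactors = FALSE)))
    perGroup <- table(enrRows[[an]]$group)
    if (length(perGroup) == length(groupNames(design)) &&
        all(perGroup >= 2))
      enrGroups[[an]] <- enrichmentGroupTable(res, design)
  }
  enrTab <- if (length(enrRows)) do.call(rbind, enrRows) else NULL
  if (!is.null(enrTab)) rownames(enrTab) <- NULL

  # --- plate assays -----------------------------------------------------
  plate <- if (!is.null(plateTable))
    .analyzePlate(plateTable, design, initialMediumMM) else NULL

  # --- statistics and report -------------------------------------------
  outRows <- list()
  addOutcome <- function(df, valueCol, name) {
    if (is.null(df)) return()
    outRows[[length(outRows) + 1L]] <<- data.frame(
      sample_id = df$sample_id, outcome = name, value = df[[valueCol]],
      stringsAsFactors = FALSE)
  }
  if (!is.null(midaTab))
    for (fa in unique(midaTab$fatty_acid))
      addOutcome(midaTab[midaTab$fatty_acid == fa, ], "fns",
                 paste0("fns_", fa))
  addOutcome(idxTab, "desaturation_index", "desaturation_index")
  addOutcome(idxTab, "elongation_index", "elongation_index")
  if (!is.null(pcTab)) addOutcome(pcTab[pcTab$defined, ], "pc_pdh", "pc_pdh")
  if (!is.null(enrTab)) {
    addOutcome(enrTab[enrTab$analyte == "glucose_glycogen", ], "sigmn",
               "sigmn_glycogen")
    addOutcome(enrTab[enrTab$analyte == "ribose", ], "sigmn",
               "sigmn_ribose")
  }
  if (!is.null(plate)) {
    addOutcome(plate$oro, "absorbance", "oro_absorbance")
    pr <- plate$proliferation
    addOutcome(pr[pr$timepoint_h == max(pr$timepoint_h), ],
               "proliferation_pct", "proliferation")
  }
  outcomes <- do.call(rbind, outRows)
  report <- if (!is.null(outcomes)) buildReport(outcomes, design) else NULL

  list(mida = midaTab, indices = idxTab, midaGroups = midaGroups,
       indicesGroups = indicesGroups, pcPdh = pcTab, pcPdhGroups = pcGroups,
       enrichment = enrTab, enrichmentGroups = enrGroups, plate = plate,
       outcomes = outcomes, report = report, design = design)
}

# plate-reader arithmetic: glucose concentration/depletion, proliferation
# percent, ORO fold change
.analyzePlate <- function(plateTable, design, initialMediumMM) {
  df <- plateTable
  s <- samples(design)
  refC <- design@referenceControl

  glucose <- NULL
  g <- df[df$assay == "glucose_GOPOD_505nm", ]
  if (nrow(g)) {
    cal <- g[g$sample_id %in% c("blank", "standard"), ]
    gs <- g[!g$sample_id %in% c("blank", "standard"), ]
    rows <- list()
    for (tp in sort(unique(gs$timepoint_h))) {
      blank <- cal$absorbance[cal$sample_id == "blank" &
                              cal$timepoint_h == tp]
      std <- cal$absorbance[cal$sample_id == "standard" &
                            cal$timepoint_h == tp]
      if (length(blank) != 1L || length(std) != 1L)
        stop("glucose assay at ", tp,
             " h needs exactly one blank and one standard well")
      d <- gs[gs$timepoint_h == tp, ]
      conc <- glucoseConcentration(d$absorbance, blank, std)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = d$sample_id, group = d$group, timepoint_h = tp,
        glucose_mM = conc,
        depletion_mM = glucoseDepletion(initialMediumMM, conc),
        stringsAsFactors = FALSE)
    }
    glucose <- do.call(rbind, rows)
    glucose <- glucose[order(glucose$sample_id, glucose$timepoint_h), ]
    glucose$cumulative_depletion_mM <-
      stats::ave(glucose$depletion_mM, glucose$sample_id, FUN = cumsum)
    rownames(glucose) <- NULL
  }

  proliferation <- NULL
  p <- df[df$assay == "CCK8_450nm" & df$group %in% s$group, ]
  if (nrow(p)) {
    rows <- list()
    for (tp in sort(unique(p$timepoint_h))) {
      d <- p[p$timepoint_h == tp, ]
      ctrl <- mean(d$absorbance[d$group == refC])
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = d$sample_id, group = d$group, timepoint_h = tp,
        proliferation_pct = proliferationPercent(d$absorbance, ctrl),
        stringsAsFactors = FALSE)
    }
    proliferation <- do.call(rbind, rows)
    rownames(proliferation) <- NULL
  }

  oro <- NULL; oroFold <- NULL
  o <- df[df$assay == "ORO_490nm" & df$group %in% s$group, ]
  if (nrow(o)) {
    oro <- o[, c("sample_id", "group", "timepoint_h", "absorbance")]
    rownames(oro) <- NULL
    refMean <- mean(o$absorbance[o$group == refC])
    oroFold <- do.call(rbind, lapply(split(o, o$group), function(d)
      data.frame(group = d$group[1],
                 fold_vs_control = foldChange(mean(d$absorbance), refMean),
                 stringsAsFactors = FALSE)))
    rownames(oroFold) <- NULL
  }

  list(glucose = glucose, proliferation = proliferation, oro = oro,
       oroFoldChange = oroFold)
}
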