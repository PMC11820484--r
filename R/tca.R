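#' Pair the two glutamate TAB fragments of one sample
#'
#' @param mid152 corrected \linkS4class{MassIsotopomerDistribution} of the
#'   C2-C4 fragment (m/z 152).
#' @param mid198 corrected \linkS4class{MassIsotopomerDistribution} of the
#'   C2-C5 fragment (m/z 198).
#' @return list of class used by [pcPdhRatio()], with a `flags` element; a
#'   flag (not an error) is raised when m2(198) < m2(152), which under the
#'   single-turn labeling model can only arise from noise.
#' @export
glutamateFragmentPair <- function(mid152, mid198) {
  if (mid152@fragment@analyte != "glutamate_152")
    stop("'mid152' must carry the glutamate_152 (C2-C4) fragment")
  if (mid198@fragment@analyte != "glutamate_198")
    stop("'mid198' must carry the glutamate_198 (C2-C5) fragment")
  if (mid152@sampleId != mid198@sampleId)
    stop("both fragments must come from the same sample (got '",
         mid152@sampleId, "' and '", mid198@sampleId, "')")
  flags <- character()
  if (mid198@abundances[3L] < mid152@abundances[3L])
    flags <- "m2(198) < m2(152): expected only under noise"
  list(mid152 = mid152, mid198 = mid198, sampleId = mid152@sampleId,
       flags = flags)
}

#' PC/PDH ratio from the glutamate fragment m2 isotopomers
#'
#' Pyruvate enters the TCA cycle either by carboxylation to oxaloacetate
#' (pyruvate carboxylase, PC), which places 13C2 on glutamate carbons 2-3,
#' or by decarboxylation to acetyl-CoA (pyruvate dehydrogenase, PDH), which
#' labels carbons 4-5. The m2 isotopomer of the C2-C4 fragment (m/z 152)
#' therefore evidences PC entry alone, while m2 of the C2-C5 fragment
#' (m/z 198) accumulates both routes, giving
#' \deqn{PC/PDH = \frac{m_2(152)}{m_2(198) - m_2(152)}.}
#'
#' The double-labeled isotopomers m3(152) and m4(198) (both routes labeled
#' in the same molecule) are excluded from the ratio, exactly as the
#' formula dictates, but carried in the diagnostics.
#'
#' @param pair a [glutamateFragmentPair()].
#' @return a \linkS4class{PcPdhResult}; the ratio is NA with
#'   `isDefined(x) = FALSE` when the denominator is below 1e-6 (no PDH
#'   signal), and 0 with a flag when m2(152) = 0 (pure-PDH labeling).
#' @examples
#' fr152 <- fragmentDefinition("glutamate_152")
#' fr198 <- fragmentDefinition("glutamate_198")
#' a <- 0.300; b <- 0.3665
#' m152 <- normalizeMid(c((1-a)*(1-b), a*(1-b), b*(1-a), a*b, 0, 0), fr152, "s1")
#' m198 <- normalizeMid(c((1-a)*(1-b), 0, a*(1-b)+b*(1-a), 0, a*b, 0), fr198, "s1")
#' pcPdh(pcPdhRatio(glutamateFragmentPair(m152, m198)))  # 1.35
#' @export
pcPdhRatio <- function(pair) {
  m2_152 <- unname(pair$mid152@abundances[3L])
  m2_198 <- unname(pair$mid198@abundances[3L])
  m3_152 <- unname(pair$mid152@abundances[4L])
  m4_198 <- unname(pair$mid198@abundances[5L])
  denom <- m2_198 - m2_152
  flags <- pair$flags
  if (denom <= 1e-6) {
    flags <- c(flags, "undefined: no PDH signal (m2(198) - m2(152) <= 1e-6)")
    ratio <- NA_real_
    defined <- FALSE
  } else if (m2_152 == 0) {
    flags <- c(flags, "pure-PDH labeling: m2(152) = 0")
    ratio <- 0
    defined <- TRUE
  } else {
    ratio <- m2_152 / denom
    defined <- TRUE
  }
  new("PcPdhResult", sampleId = pair$sampleId,
      m2_152 = m2_152, m2_198 = m2_198, ratio = ratio, defined = defined,
      diagnostics = list(m3_152 = m3_152, m4_198 = m4_198, flags = flags))
}

#' Per-group summary of PC/PDH ratios
#'
#' Undefined ratios are excluded (with the exclusion count reported), never
#' zero-filled, so they do not bias the group means. Groups left with fewer
#' than two defined ratios are flagged.
#'
#' @param results list of \linkS4class{PcPdhResult} objects.
#' @param design a \linkS4class{StudyDesign} mapping sample ids to groups.
#' @return data.frame: group, n, n_excluded, mean, sd, flag.
#' @export
pcPdhGroupSummary <- function(results, design) {
  ids <- vapply(results, sampleId, character(1))
  ratios <- vapply(results, pcPdh, numeric(1))
  defined <- vapply(results, isDefined, logical(1))
  s <- samples(design)
  grp <- s$group[match(ids, s$sample_id)]
  if (anyNA(grp))
    stop("sample id(s) not in design: ",
         paste(ids[is.na(grp)], collapse = ", "))
  out <- do.call(rbind, lapply(unique(s$group), function(g) {
    sel <- grp == g
    ok <- sel & defined
    v <- ratios[ok]
    data.frame(group = g, n = sum(ok), n_excluded = sum(sel) - sum(ok),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               flag = if (sum(ok) < 2) "fewer than 2 defined ratios" else "",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
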