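#' Summed 13C molar enrichment (SIGmn)
#'
#' SIGmn is the average number of tracer-labeled carbons per molecule,
#' \eqn{\Sigma_{n\ge 1} n M_n} over the (corrected) mass isotopomer
#' distribution. It is linear in mixtures, bounded by the skeleton carbon
#' count of the fragment, and attains that bound only for a fully labeled
#' pool. Used here for glycogen-derived glucose (m/z 328, six carbons) and
#' RNA ribose (m/z 256, carbons 1-5).
#'
#' @param mid corrected \linkS4class{MassIsotopomerDistribution}.
#' @return an \linkS4class{EnrichmentResult}
#' @examples
#' fr <- fragmentDefinition("glucose_glycogen")
#' m <- normalizeMid(c(0.725, 0, 0, 0, 0, 0, 0.275, 0), fr)
#' sigmnValue(sigmn(m))  # 6 * 0.275 = 1.65
#' @export
setMethod("sigmn", "MassIsotopomerDistribution", function(mid) {
  a <- mid@abundances
  val <- sum(seq_along(a[-1L]) * a[-1L])
  new("EnrichmentResult", analyte = mid@fragment@analyte,
      sampleId = mid@sampleId, sigmn = val)
})

#' Per-group enrichment summary with one-way ANOVA
#'
#' Tabulates group mean and SD of SIGmn for one analyte and attaches the
#' one-way ANOVA p-value across groups.
#'
#' @param results list of \linkS4class{EnrichmentResult} objects for one
#'   analyte.
#' @param design a \linkS4class{StudyDesign}.
#' @return list with `table` (data.frame: group, n, mean, sd) and
#'   `anova` (list with F, p; NA when the decomposition is degenerate).
#' @export
enrichmentGroupTable <- function(results, design) {
  ids <- vapply(results, sampleId, character(1))
  vals <- vapply(results, sigmnValue, numeric(1))
  s <- samples(design)
  grp <- s$group[match(ids, s$sample_id)]
  if (anyNA(grp))
    stop("sample id(s) not in design: ",
         paste(ids[is.na(grp)], collapse = ", "))
  groups <- unique(s$group)
  counts <- vapply(groups, function(g) sum(grp == g), integer(1))
  if (any(counts == 0))
    stop("empty group(s): ", paste(groups[counts == 0], collapse = ", "))
  if (any(counts < 2))
    stop("each group needs at least 2 samples for the summary")
  tab <- data.frame(
    group = groups,
    n = counts,
    mean = vapply(groups, function(g) mean(vals[grp == g]), numeric(1)),
    sd = vapply(groups, function(g) stats::sd(vals[grp == g]), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  an <- oneWayAnova(split(vals, factor(grp, levels = groups)))
  list(table = tab, anova = an)
}
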