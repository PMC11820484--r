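#' Shapiro-Wilk normality check
#'
#' Thin wrapper over [stats::shapiro.test()] (Royston's approximation of
#' the W statistic) that flags degenerate input instead of erroring deep
#' in the test.
#'
#' @param values numeric vector, 3 <= n <= 2000.
#' @return list with `W`, `p`, and `degenerate` (TRUE when all values are
#'   identical, in which case W and p are NA).
#' @export
shapiroWilk <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3) stop("Shapiro-Wilk requires at least 3 observations")
  if (n > 2000) stop("Shapiro-Wilk supports at most 2000 observations")
  if (diff(range(values)) == 0)
    return(list(W = NA_real_, p = NA_real_, degenerate = TRUE))
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value, degenerate = FALSE)
}

.asGroupList <- function(groups) {
  if (is.data.frame(groups)) groups <- split(groups$value, groups$group)
  if (!is.list(groups)) stop("'groups' must be a list of numeric vectors")
  groups <- lapply(groups, function(v) v[!is.na(v)])
  if (length(groups) < 2) stop("at least 2 groups are required")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs at least 2 observations")
  groups
}

#' One-way ANOVA across groups
#'
#' Classical between/within variance decomposition via [stats::aov()].
#' When every observation is identical the decomposition is degenerate
#' (0/0) and the result is flagged instead of reporting a spurious F.
#'
#' @param groups list of numeric vectors (one per group), or a data.frame
#'   with columns `group` and `value`.
#' @return list with `F`, `p`, `df`, `degenerate`.
#' @export
oneWayAnova <- function(groups) {
  groups <- .asGroupList(groups)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (diff(range(y)) == 0)
    return(list(F = NA_real_, p = NA_real_,
                df = c(length(groups) - 1L, length(y) - length(groups)),
                degenerate = TRUE))
  fit <- stats::aov(y ~ g)
  s <- summary(fit)[[1]]
  list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1],
       df = s[["Df"]], degenerate = FALSE)
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range pairwise tests via [stats::TukeyHSD()], with
#' significance stars at 0.05 / 0.01 / 0.001 matching the usual
#' *, **, *** annotation convention.
#'
#' @param groups list of named numeric vectors, or a data.frame with
#'   columns `group` and `value`.
#' @return data.frame: group_a, group_b, diff (mean a - mean b), p_adj,
#'   significant (p_adj < 0.05), stars.
#' @export
tukeyHsd <- function(groups) {
  groups <- .asGroupList(groups)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (diff(range(y)) == 0) {
    cmb <- utils::combn(names(groups), 2)
    return(data.frame(group_a = cmb[2, ], group_b = cmb[1, ],
                      diff = 0, p_adj = NA_real_, significant = FALSE,
                      stars = "", stringsAsFactors = FALSE))
  }
  tk <- stats::TukeyHSD(stats::aov(y ~ g))$g
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  p <- unname(tk[, "p adj"])
  data.frame(
    group_a = vapply(pairs, `[`, character(1), 1L),
    group_b = vapply(pairs, `[`, character(1), 2L),
    diff = unname(tk[, "diff"]),
    p_adj = p,
    significant = !is.na(p) & p < 0.05,
    stars = vapply(p, .stars, character(1)),
    stringsAsFactors = FALSE)
}

.stars <- function(p) {
  if (is.na(p)) "" else if (p < 0.001) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else ""
}

#' Group-comparison report for a panel of outcomes
#'
#' For each outcome: per-group n / mean / SD, Shapiro-Wilk normality flag
#' on the pooled residuals, one-way ANOVA, and Tukey HSD pairwise tests.
#' A qualitative direction-of-change matrix (increased / decreased /
#' "no change") is derived from the Tukey tests against the designated
#' untreated-control reference (and, as a second annotation, against the
#' steatosis control), mirroring the dual-reference annotation convention
#' of the underlying assay panel. No correction is applied across
#' outcomes.
#'
#' @param outcomes data.frame with columns `sample_id`, `outcome`, `value`.
#' @param design a \linkS4class{StudyDesign}.
#' @return list with `comparisons` (per-outcome list: summary, shapiro,
#'   anova, tukey) and `direction` (outcome x group character matrix
#'   relative to the untreated control; reference column reads
#'   "reference").
#' @export
buildReport <- function(outcomes, design) {
  need <- c("sample_id", "outcome", "value")
  if (!all(need %in% names(outcomes)))
    stop("'outcomes' must have columns: ", paste(need, collapse = ", "))
  s <- samples(design)
  outcomes$group <- s$group[match(outcomes$sample_id, s$sample_id)]
  if (anyNA(outcomes$group))
    stop("sample id(s) not in design: ",
         paste(unique(outcomes$sample_id[is.na(outcomes$group)]),
               collapse = ", "))
  groups <- unique(s$group)
  refC <- design@referenceControl
  refS <- design@referenceSteatosis

  outcomeNames <- unique(outcomes$outcome)
  comparisons <- vector("list", length(outcomeNames))
  names(comparisons) <- outcomeNames
  direction <- matrix("no change", nrow = length(outcomeNames),
                      ncol = length(groups),
                      dimnames = list(outcomeNames, groups))
  direction[, refC] <- "reference"

  for (oc in outcomeNames) {
    d <- outcomes[outcomes$outcome == oc & !is.na(outcomes$value), ]
    gl <- split(d$value, factor(d$group, levels = groups))
    summ <- data.frame(
      group = groups,
      n = vapply(gl, length, integer(1)),
      mean = vapply(gl, function(v) if (length(v)) mean(v) else NA_real_,
                    numeric(1)),
      sd = vapply(gl, function(v) if (length(v) > 1) stats::sd(v)
                  else NA_real_, numeric(1)),
      stringsAsFactors = FALSE)
    rownames(summ) <- NULL
    resid <- unlist(lapply(gl, function(v) v - mean(v)), use.names = FALSE)
    sw <- if (length(resid) >= 3 && length(resid) <= 2000)
      shapiroWilk(resid) else list(W = NA_real_, p = NA_real_,
                                   degenerate = TRUE)
    an <- oneWayAnova(gl)
    tk <- tukeyHsd(gl)
    comparisons[[oc]] <- list(summary = summ, shapiro = sw, anova = an,
                              tukey = tk)
    for (g in setdiff(groups, refC)) {
      row <- tk[(tk$group_a == g & tk$group_b == refC) |
                (tk$group_a == refC & tk$group_b == g), ]
      if (nrow(row) != 1 || is.na(row$p_adj) || !row$significant) next
      delta <- summ$mean[summ$group == g] - summ$mean[summ$group == refC]
      direction[oc, g] <- if (delta > 0) "increased" else "decreased"
    }
  }
  list(comparisons = comparisons, direction = direction,
       references = c(control = refC, steatosis = refS))
}
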