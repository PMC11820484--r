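#' Construct a StudyDesign
#'
#' @param samples data.frame with columns sample_id, group, timepoint_h,
#'   replicate_index (the last two are filled in when missing).
#' @param referenceControl name of the untreated control group.
#' @param referenceSteatosis name of the steatosis (vehicle) control group.
#' @return a \linkS4class{StudyDesign}
#' @export
studyDesign <- function(samples, referenceControl = "control",
                        referenceSteatosis = "oa_steatosis") {
  if (!"timepoint_h" %in% names(samples)) samples$timepoint_h <- 72L
  if (!"replicate_index" %in% names(samples))
    samples$replicate_index <- stats::ave(seq_len(nrow(samples)),
                                          samples$group, FUN = seq_along)
  rownames(samples) <- NULL
  new("StudyDesign", samples = samples,
      referenceControl = referenceControl,
      referenceSteatosis = referenceSteatosis)
}

# parse a MID data.frame (CSV dialect: sample_id, group, analyte,
# fragment_mz, m0, m1, ...; blank cells are zeros; ragged K per analyte)
.parseMidTable <- function(df) {
  need <- c("sample_id", "group", "analyte", "fragment_mz", "m0", "m1", "m2")
  if (!all(need %in% names(df)))
    stop("MID table must have columns sample_id, group, analyte, ",
         "fragment_mz, m0, m1, m2, ...")
  mCols <- grep("^m[0-9]+$", names(df), value = TRUE)
  mCols <- mCols[order(as.integer(sub("m", "", mCols)))]
  intens <- as.matrix(df[, mCols, drop = FALSE])
  intens[is.na(intens)] <- 0

  resolved <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    line <- i + 1L  # header is line 1
    resolved[i] <- tryCatch(
      .resolveAnalyte(df$analyte[i], df$fragment_mz[i]),
      error = function(e) stop("line ", line, ": ", conditionMessage(e),
                               call. = FALSE))
    if (!resolved[i] %in% names(.fragmentRegistry))
      stop("line ", line, ": unknown analyte '", df$analyte[i],
           "'; supported analytes: ",
           paste(supportedAnalytes(), collapse = ", "), call. = FALSE)
    if (any(intens[i, ] < 0))
      stop("line ", line, ": negative intensity for sample '",
           df$sample_id[i], "', analyte '", df$analyte[i], "'",
           call. = FALSE)
    if (all(intens[i, ] == 0))
      stop("line ", line, ": empty spectrum for sample '", df$sample_id[i],
           "', analyte '", df$analyte[i], "'", call. = FALSE)
  }
  key <- paste(df$sample_id, resolved, sep = "|")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate (sample, fragment) rows: ", d, call. = FALSE)
  }

  # per-analyte recorded shift range: widest nonzero column, floored at
  # the registry default (blank trailing cells are padding, not data)
  mids <- vector("list", nrow(df)); names(mids) <- key
  for (an in unique(resolved)) {
    rows <- which(resolved == an)
    nz <- which(colSums(intens[rows, , drop = FALSE] > 0) > 0)
    K <- max(max(nz) - 1L, .fragmentRegistry[[an]]$K)
    K <- min(K, length(mCols) - 1L)
    fr <- fragmentDefinition(an, maxShift = K)
    for (i in rows)
      mids[[i]] <- normalizeMid(intens[i, seq_len(K + 1L)], fr,
                                df$sample_id[i])
  }
  designDf <- unique(df[, c("sample_id", "group")])
  list(mids = mids, resolved = resolved, table = df, designDf = designDf)
}

#' Read a MID table CSV
#'
#' Expected columns: `sample_id, group, analyte, fragment_mz, m0, m1, ...`,
#' with mass-shift indices relative to the monoisotopic monitored ion.
#' Blank cells are read as 0; the recorded shift range may differ per
#' analyte (ragged K). Row-level problems (negative intensity, unknown
#' analyte, empty spectrum, duplicated sample-fragment pairs) are reported
#' with the offending line number.
#'
#' @param path CSV file path.
#' @param referenceControl,referenceSteatosis reference group names for
#'   the extracted design.
#' @return list with `mids` (named list of
#'   \linkS4class{MassIsotopomerDistribution}, keyed `sample_id|analyte`),
#'   `design` (a \linkS4class{StudyDesign}) and `table` (the raw
#'   data.frame).
#' @export
readMidTable <- function(path, referenceControl = "control",
                         referenceSteatosis = "oa_steatosis") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  p <- .parseMidTable(df)
  list(mids = p$mids,
       design = studyDesign(p$designDf, referenceControl,
                            referenceSteatosis),
       table = p$table)
}

#' Write a MID or plate table CSV
#'
#' @param table data.frame (e.g. `simulateStudy()$midTable`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeMidTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeMidTable
#' @export
writePlateTable <- writeMidTable

#' Read a plate-reading table CSV
#'
#' Expected columns: `sample_id, group, assay, timepoint_h, absorbance`.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
readPlateTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "assay", "timepoint_h", "absorbance")
  if (!all(need %in% names(df)))
    stop("plate table must have columns: ", paste(need, collapse = ", "))
  bad <- which(df$absorbance < 0)
  if (length(bad))
    stop("line ", bad[1] + 1L, ": negative absorbance")
  known <- c("glucose_GOPOD_505nm", "CCK8_450nm", "ORO_490nm")
  unk <- setdiff(unique(df$assay), known)
  if (length(unk))
    stop("unknown assay(s): ", paste(unk, collapse = ", "),
         "; supported: ", paste(known, collapse = ", "))
  df
}
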