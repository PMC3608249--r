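# Replicate-level QC and assembly of the analysis-ready subject x unit
# methylation matrix: replicate-sd cell exclusion, calling-rate subject
# rejection, averaging of mass-colliding units, regional average.

#' Aggregate replicate measurements for one subject x unit cell
#'
#' The cell value is the mean over non-missing replicates unless their
#' sample standard deviation exceeds \code{max_sd}, in which case the cell
#' is excluded (missing).  A single surviving replicate has sd treated as 0
#' and is kept.
#'
#' @param fractions numeric vector of replicate fractions (NAs allowed).
#' @param max_sd exclusion threshold on the replicate standard deviation.
#' @return list with \code{value} (mean or \code{NA}), \code{sd}, and
#'   \code{excluded} (logical; TRUE only for sd-based exclusion).
#' @export
aggregate_replicates <- function(fractions, max_sd = 0.1) {
  x <- fractions[!is.na(fractions)]
  if (length(x) == 0L) {
    return(list(value = NA_real_, sd = NA_real_, excluded = FALSE))
  }
  if (any(x < 0 | x > 1)) stop("replicate fractions must lie in [0,1]")
  s <- if (length(x) > 1L) stats::sd(x) else 0
  if (s > max_sd) list(value = NA_real_, sd = s, excluded = TRUE)
  else list(value = mean(x), sd = s, excluded = FALSE)
}

#' Build a subject x unit methylation matrix from replicate records
#'
#' Applies the full QC chain in assay order: subjects are first rejected on
#' their measurement calling rate -- the fraction of panel columns
#' (regional average included) for which any replicate measurement exists
#' at all -- and only then are high-variance cells of the retained
#' subjects excluded by the replicate-sd rule, mass-colliding unit pairs
#' averaged, and the regional average appended.  Computing the calling
#' rate on raw measurement availability (not on post-exclusion cells)
#' keeps the two QC rules independent, so a subject is not rejected merely
#' for one noisy cell.
#'
#' @param records data.frame with columns \code{subject}, \code{unit},
#'   \code{replicate}, \code{fraction} (long format; \code{fraction} NA for
#'   failed measurements).
#' @param panel character vector of analysis unit labels defining the panel
#'   (order preserved); defaults to the units present in \code{records}
#'   after collision merging.
#' @param collisions optional list of character vectors, each a group of
#'   mass-colliding unit labels to be averaged into one analysis unit
#'   (labelled by their longest common prefix, stripped of trailing
#'   punctuation, or the labels joined by "+").
#' @param max_sd replicate-sd exclusion threshold.
#' @param min_calling_rate minimum fraction of called panel columns
#'   (including the regional average) a subject must reach; subjects
#'   strictly below are rejected.
#' @param avg_label column name for the regional average.
#' @return list with \code{matrix} (data.frame, rownames subject ids,
#'   columns panel units + regional average), \code{qc} (per-subject
#'   calling rate and rejection flag), and \code{cells} (per-cell sd and
#'   exclusion flag).
#' @export
build_methylation_matrix <- function(records, panel = NULL,
                                     collisions = NULL, max_sd = 0.1,
                                     min_calling_rate = 0.95,
                                     avg_label = "AVG") {
  req <- c("subject", "unit", "replicate", "fraction")
  if (!all(req %in% names(records))) {
    stop("records needs columns: ", paste(req, collapse = ", "))
  }
  records$subject <- as.character(records$subject)
  records$unit <- as.character(records$unit)
  subjects <- unique(records$subject)
  units <- unique(records$unit)
  key <- interaction(records$subject, records$unit, drop = TRUE)
  agg <- lapply(split(records$fraction, key), aggregate_replicates,
                max_sd = max_sd)
  cells <- data.frame(
    subject = vapply(split(records$subject, key), `[`, character(1), 1),
    unit = vapply(split(records$unit, key), `[`, character(1), 1),
    measured = !vapply(split(records$fraction, key),
                       function(x) all(is.na(x)), logical(1)),
    value = vapply(agg, `[[`, numeric(1), "value"),
    sd = vapply(agg, `[[`, numeric(1), "sd"),
    excluded = vapply(agg, `[[`, logical(1), "excluded"),
    row.names = NULL, stringsAsFactors = FALSE)
  idx <- cbind(match(cells$subject, subjects), match(cells$unit, units))
  wide <- matrix(NA_real_, length(subjects), length(units),
                 dimnames = list(subjects, units))
  wide[idx] <- cells$value
  meas <- matrix(FALSE, length(subjects), length(units),
                 dimnames = list(subjects, units))
  meas[idx] <- cells$measured
  # average mass-colliding units, merged column at the first member's slot
  merge_cols <- function(m, grp, combine) {
    merged <- apply(m[, grp, drop = FALSE], 1, combine)
    pos <- min(match(grp, colnames(m)))
    keep_idx <- setdiff(seq_len(ncol(m)), match(grp, colnames(m)))
    new <- cbind(m[, keep_idx[keep_idx < pos], drop = FALSE],
                 merged,
                 m[, keep_idx[keep_idx > pos], drop = FALSE])
    colnames(new)[sum(keep_idx < pos) + 1L] <- merge_label(grp)
    new
  }
  if (!is.null(collisions)) {
    for (grp in collisions) {
      grp <- intersect(grp, colnames(wide))
      if (length(grp) < 2L) next
      wide <- merge_cols(wide, grp, merge_ambiguous_units)
      meas <- merge_cols(meas, grp, any)
    }
  }
  if (!is.null(panel)) {
    missing_units <- setdiff(panel, colnames(wide))
    if (length(missing_units)) {
      stop("panel unit(s) absent from records: ",
           paste(missing_units, collapse = ", "))
    }
    wide <- wide[, panel, drop = FALSE]
    meas <- meas[, panel, drop = FALSE]
  }
  # calling rate over panel columns + regional average, on availability
  avail <- cbind(meas, rowSums(meas) > 0)
  rate <- rowMeans(avail)
  keep <- rate >= min_calling_rate
  report <- data.frame(subject = subjects, calling_rate = as.numeric(rate),
                       retained = as.logical(keep), row.names = NULL,
                       stringsAsFactors = FALSE)
  wide <- wide[keep, , drop = FALSE]
  ravg <- regional_average(wide)
  full <- cbind(as.data.frame(wide), stats::setNames(data.frame(ravg),
                                                     avg_label))
  list(matrix = full, qc = report, cells = cells)
}

#' Merge the values of mass-colliding units
#'
#' @param values numeric vector (one value per colliding unit; NAs allowed).
#' @return their mean over non-missing values, or \code{NA} when all are
#'   missing.
#' @export
merge_ambiguous_units <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) == 0L) NA_real_ else mean(v)
}

#' Label for a merged unit group
#'
#' "3a" + "3b" becomes "3"; labels without a common prefix are joined with
#' "+".
#' @param labels character vector of colliding unit labels.
#' @return single merged label.
#' @export
merge_label <- function(labels) {
  pre <- sub("[a-z]+$", "", labels)
  if (length(unique(pre)) == 1L && nzchar(pre[1])) pre[1]
  else paste(labels, collapse = "+")
}

#' Reject subjects with a low calling rate
#'
#' The calling rate is the fraction of non-missing columns; subjects
#' strictly below \code{min_calling_rate} are rejected.
#'
#' @param mat data.frame or matrix, subjects in rows, panel columns.
#' @param min_calling_rate threshold in (0,1].
#' @return list with \code{retained} (retained row subset of \code{mat})
#'   and \code{report} (subject, calling_rate, retained flag).
#' @export
subject_filter <- function(mat, min_calling_rate = 0.95) {
  m <- as.matrix(mat)
  rate <- rowMeans(!is.na(m))
  keep <- rate >= min_calling_rate
  report <- data.frame(subject = rownames(m) %||% as.character(seq_len(nrow(m))),
                       calling_rate = as.numeric(rate),
                       retained = as.logical(keep),
                       row.names = NULL, stringsAsFactors = FALSE)
  list(retained = mat[keep, , drop = FALSE], report = report)
}

#' Regional average methylation per subject
#'
#' Unweighted mean over non-missing unit values in each row.
#'
#' @param mat subjects x units matrix/data.frame.
#' @return numeric vector, \code{NA} where all units are missing.
#' @export
regional_average <- function(mat) {
  m <- as.matrix(mat)
  out <- rowMeans(m, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Calibrate a batch against the methylation control panel
#'
#' Fits the least-squares line of observed control means on expected
#' fractions (the assay runs 0/25/50/75/100 percent methylated controls)
#' and flags the batch when any control deviates beyond tolerance.
#'
#' @param observed observed control means.
#' @param expected expected control fractions.
#' @param tolerance maximum absolute deviation before flagging.
#' @return list: \code{slope}, \code{intercept}, \code{max_deviation},
#'   \code{flagged}.
#' @export
control_calibration <- function(observed,
                                expected = c(0, 0.25, 0.5, 0.75, 1),
                                tolerance = 0.1) {
  if (length(observed) != length(expected)) {
    stop("observed and expected must have equal length")
  }
  if (length(unique(expected)) < 2L) {
    stop("need at least 2 distinct expected control levels")
  }
  fit <- stats::lm(observed ~ expected)
  dev <- max(abs(observed - expected))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       max_deviation = dev, flagged = dev > tolerance)
}
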