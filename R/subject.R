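#' Create a subject record
#'
#' Bundles one participant's ROI time series with the per-frame nuisance
#' sources needed for post-processing: rigid-body motion parameters and
#' mean tissue signals.
#'
#' @param subject_id Character scalar.
#' @param timeseries T x R numeric matrix of ROI time series (arbitrary
#'   signal units); columns are ROIs.
#' @param motion T x 6 numeric matrix: three translations in mm followed by
#'   three rotations in radians.
#' @param tissue_signals T x 3 numeric matrix: mean white-matter, ventricle
#'   and gray-matter signals.
#' @param tr_seconds Repetition time in seconds (positive).
#' @param ls_score Numeric trait score for this subject (may be `NA` for
#'   unlabeled data).
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(subject_id, timeseries, motion, tissue_signals,
                           tr_seconds, ls_score = NA_real_) {
  timeseries <- as.matrix(timeseries)
  motion <- as.matrix(motion)
  tissue_signals <- as.matrix(tissue_signals)
  t_n <- nrow(timeseries)
  if (t_n < 1 || ncol(timeseries) < 2) {
    abort_param("timeseries must have at least 1 frame and 2 ROIs")
  }
  if (nrow(motion) != t_n || nrow(tissue_signals) != t_n) {
    abort_param(sprintf(
      "frame counts disagree: timeseries %d, motion %d, tissue %d",
      t_n, nrow(motion), nrow(tissue_signals)))
  }
  if (ncol(motion) != 6) abort_param("motion must have 6 columns")
  if (ncol(tissue_signals) != 3) abort_param("tissue_signals must have 3 columns")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1 || tr_seconds <= 0) {
    abort_param("tr_seconds must be a positive scalar")
  }
  structure(
    list(subject_id = as.character(subject_id), timeseries = timeseries,
         motion = motion, tissue_signals = tissue_signals,
         tr_seconds = tr_seconds, ls_score = ls_score),
    class = "subject_record"
  )
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record %s: %d frames x %d ROIs, TR = %g s, LS = %s>\n",
              x$subject_id, nrow(x$timeseries), ncol(x$timeseries),
              x$tr_seconds,
              ifelse(is.na(x$ls_score), "NA", format(x$ls_score))))
  invisible(x)
}
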