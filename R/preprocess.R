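#' Drop the initial seconds of a run
#'
#' Removes the first `ceiling(seconds / tr_seconds)` frames from the time
#' series, motion and tissue matrices of a subject record, so that early
#' non-equilibrium frames never enter the connectome.
#'
#' @param record A [subject_record()].
#' @param seconds Duration to remove from the start of the run (default 10 s).
#' @return A `subject_record` with the leading frames removed consistently
#'   from every per-frame array.
#' @export
#' @examples
#' rec <- subject_record("s1", matrix(rnorm(200), 100, 2),
#'                       matrix(0, 100, 6), matrix(0, 100, 3), tr_seconds = 1)
#' nrow(drop_initial(rec, 10)$timeseries)  # 90
drop_initial <- function(record, seconds = 10) {
  stopifnot(inherits(record, "subject_record"))
  if (seconds < 0) abort_param("seconds must be >= 0")
  n_drop <- ceiling(seconds / record$tr_seconds)
  t_n <- nrow(record$timeseries)
  if (n_drop >= t_n) {
    abort_param(sprintf(
      "dropping %d frames leaves nothing of a %d-frame run", n_drop, t_n))
  }
  if (n_drop == 0) return(record)
  keep <- seq.int(n_drop + 1, t_n)
  subject_record(record$subject_id,
                 record$timeseries[keep, , drop = FALSE],
                 record$motion[keep, , drop = FALSE],
                 record$tissue_signals[keep, , drop = FALSE],
                 record$tr_seconds, record$ls_score)
}

#' Build the nuisance regressor matrix
#'
#' Columns: intercept, centered linear trend, six motion parameters, three
#' tissue signals, and first-order temporal derivatives (backward
#' difference, zero first row) of the nine motion/tissue regressors —
#' 20 columns in total. Linear detrending is carried by the trend column so
#' nuisance removal is a single OLS pass.
#'
#' @param record A [subject_record()].
#' @return T x 20 numeric matrix with named columns.
#' @export
build_nuisance <- function(record) {
  stopifnot(inherits(record, "subject_record"))
  t_n <- nrow(record$motion)
  trend <- seq_len(t_n) - (t_n + 1) / 2
  signals <- cbind(record$motion, record$tissue_signals)
  colnames(signals) <- c(paste0("motion", 1:6), c("wm", "ventricle", "gm"))
  deriv <- rbind(0, diff(signals))
  colnames(deriv) <- paste0("d_", colnames(signals))
  cbind(intercept = rep(1, t_n), trend = trend, signals, deriv)
}

#' Regress nuisance signals out of a time-series matrix
#'
#' Per-ROI ordinary least-squares residualization. Residuals are orthogonal
#' to every regressor column. Rank-deficient designs are handled through
#' the pseudoinverse (with a warning) rather than failing.
#'
#' @param timeseries T x R numeric matrix.
#' @param regressors T x P numeric matrix, P < T.
#' @return T x R matrix of residuals.
#' @export
regress_nuisance <- function(timeseries, regressors) {
  timeseries <- as.matrix(timeseries)
  regressors <- as.matrix(regressors)
  if (nrow(timeseries) != nrow(regressors)) {
    abort_param("timeseries and regressors must share the number of frames")
  }
  if (nrow(regressors) <= ncol(regressors)) {
    abort_param("need more frames than nuisance regressors")
  }
  qr_x <- qr(regressors)
  if (qr_x$rank < ncol(regressors)) {
    warning(sprintf(
      "nuisance design is rank deficient (rank %d of %d); using pseudoinverse",
      qr_x$rank, ncol(regressors)), call. = FALSE)
    sv <- svd(regressors)
    pos <- sv$d > max(dim(regressors)) * .Machine$double.eps * sv$d[1]
    fitted <- sv$u[, pos, drop = FALSE] %*%
      crossprod(sv$u[, pos, drop = FALSE], timeseries)
    return(timeseries - fitted)
  }
  timeseries - regressors %*% qr.coef(qr_x, timeseries)
}

#' Zero-phase band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (zero phase) to each column. The default band (0.008-0.1 Hz) retains the
#' slow fluctuations that carry resting-state connectivity and removes
#' drift and respiratory/cardiac-aliased frequencies.
#'
#' @param timeseries T x R numeric matrix (columns filtered independently).
#' @param low_hz,high_hz Pass-band edges in Hz; `high_hz` must be below the
#'   Nyquist frequency `1 / (2 * tr_seconds)`.
#' @param tr_seconds Sampling interval in seconds.
#' @return Filtered matrix of the same shape.
#' @export
bandpass <- function(timeseries, low_hz = 0.008, high_hz = 0.1, tr_seconds) {
  timeseries <- as.matrix(timeseries)
  nyquist <- 1 / (2 * tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyquist)) {
    abort_param(sprintf(
      "band [%g, %g] Hz must satisfy 0 < low < high < Nyquist (%g Hz)",
      low_hz, high_hz, nyquist))
  }
  bf <- signal::butter(4, c(low_hz, high_hz) / nyquist, type = "pass")
  t_n <- nrow(timeseries)
  pad <- min(t_n - 1, 100)   # odd-symmetric reflection tames edge transients
  means <- colMeans(timeseries)
  out <- apply(sweep(timeseries, 2, means), 2, function(col) {
    ext <- c(2 * col[1] - col[(pad + 1):2],
             col,
             2 * col[t_n] - col[t_n - (1:pad)])
    signal::filtfilt(bf, ext)[pad + seq_len(t_n)]
  })
  matrix(out, nrow = t_n, dimnames = dimnames(timeseries))
}

#' Framewise displacement from motion parameters
#'
#' `FD_t = sum |delta translation| + head_radius * sum |delta rotation|`,
#' with rotations in radians converted to arc length on a sphere of
#' `head_radius_mm`. The first frame has FD 0 by convention.
#'
#' @param motion T x 6 matrix: translations (mm) then rotations (radians).
#' @param head_radius_mm Sphere radius used to convert rotations to mm
#'   (default 50).
#' @return Numeric vector of length T.
#' @export
#' @examples
#' m <- matrix(0, 5, 6); m[3, 1] <- 0.3
#' framewise_displacement(m)  # 0 0 0.3 0.3 0
framewise_displacement <- function(motion, head_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) abort_param("motion must be T x 6")
  if (!all(is.finite(motion))) {
    bad <- which(!apply(motion, 1, function(r) all(is.finite(r))))[1]
    abort_param(sprintf("non-finite motion parameters at frame %d", bad))
  }
  d <- abs(rbind(0, diff(motion)))
  rowSums(d[, 1:3, drop = FALSE]) +
    head_radius_mm * rowSums(d[, 4:6, drop = FALSE])
}

#' Scrub motion-contaminated frames
#'
#' Removes frames whose framewise displacement strictly exceeds the
#' threshold. Frames with FD exactly at the threshold are retained. If
#' fewer than `min_frames` survive, the subject is flagged for exclusion
#' (the censored data are still returned so callers can report).
#'
#' @param timeseries T x R matrix.
#' @param fd Numeric FD vector of length T (see [framewise_displacement()]).
#' @param threshold_mm Scrubbing threshold in mm (default 0.5).
#' @param min_frames Minimum retained frames before the subject is flagged
#'   (default 50).
#' @return List with `timeseries` (censored), `mask` (logical, TRUE =
#'   retained), `n_scrubbed`, and `excluded` (flag).
#' @export
scrub <- function(timeseries, fd, threshold_mm = 0.5, min_frames = 50) {
  timeseries <- as.matrix(timeseries)
  if (length(fd) != nrow(timeseries)) {
    abort_param("fd length must match the number of frames")
  }
  mask <- fd <= threshold_mm
  excluded <- sum(mask) < min_frames
  if (excluded) {
    warning(sprintf(
      "only %d of %d frames retained (min %d); subject flagged for exclusion",
      sum(mask), length(mask), min_frames), call. = FALSE)
  }
  list(timeseries = timeseries[mask, , drop = FALSE], mask = mask,
       n_scrubbed = sum(!mask), excluded = excluded)
}

#' Post-process one subject's time series
#'
#' Runs the fixed pipeline: drop initial seconds, nuisance regression
#' (motion, tissue, trend, derivatives), zero-phase band-pass, FD scrubbing.
#' Censored frames are removed, not interpolated.
#'
#' @param record A [subject_record()].
#' @param drop_seconds Seconds removed from the start of the run.
#' @param band Length-2 pass band in Hz.
#' @param fd_threshold_mm Scrubbing threshold.
#' @param min_frames Minimum retained frames before exclusion.
#' @return List with `timeseries` (clean, censored T' x R), `mask`, `fd`,
#'   `excluded`, `subject_id`, `ls_score`.
#' @export
preprocess_subject <- function(record, drop_seconds = 10,
                               band = c(0.008, 0.1), fd_threshold_mm = 0.5,
                               min_frames = 50) {
  rec <- drop_initial(record, drop_seconds)
  nuis <- build_nuisance(rec)
  resid <- regress_nuisance(rec$timeseries, nuis)
  filt <- bandpass(resid, band[1], band[2], rec$tr_seconds)
  fd <- framewise_displacement(rec$motion)
  sc <- scrub(filt, fd, fd_threshold_mm, min_frames)
  list(timeseries = sc$timeseries, mask = sc$mask, fd = fd,
       n_scrubbed = sc$n_scrubbed, excluded = sc$excluded,
       subject_id = rec$subject_id, ls_score = rec$ls_score)
}
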