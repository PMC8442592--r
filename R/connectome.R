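#' Canonical edge ordering for an R-ROI connectome
#'
#' Edges enumerate the strict lower triangle in row-major order: edge k
#' (1-based) pairs ROIs (i, j) with i > j, ordered (2,1), (3,1), (3,2),
#' (4,1), ... This ordering is identical across subjects and cohorts; all
#' vectorized connectomes in the package use it.
#'
#' @param n_rois Number of ROIs (>= 2).
#' @return Tibble with columns `edge` (1..E), `roi_i`, `roi_j` (1-based,
#'   `roi_i > roi_j`), where `E = n_rois * (n_rois - 1) / 2`.
#' @export
#' @examples
#' edge_index_table(3)  # pairs (2,1), (3,1), (3,2)
edge_index_table <- function(n_rois) {
  if (n_rois < 2) abort_param("n_rois must be >= 2")
  i <- rep(2:n_rois, times = 1:(n_rois - 1))
  j <- unlist(lapply(2:n_rois, function(k) seq_len(k - 1)), use.names = FALSE)
  tibble::tibble(edge = seq_along(i), roi_i = as.integer(i),
                 roi_j = as.integer(j))
}

#' Number of unique edges for a given ROI count
#' @param n_rois Number of ROIs.
#' @return `n_rois * (n_rois - 1) / 2`.
#' @export
n_edges <- function(n_rois) as.integer(n_rois * (n_rois - 1) / 2)

#' Fisher-z connectivity matrix from a clean time series
#'
#' Pearson correlations between all ROI pairs, Fisher r-to-z transformed
#' (`z = atanh(r)`). Requires at least 3 retained frames and nonzero
#' variance in every ROI. A correlation with `|r| >= 1 - 1e-12` off the
#' diagonal means two ROIs carry (numerically) identical signals and is
#' raised as a degenerate-correlation error rather than an infinite z.
#'
#' @param timeseries T x R numeric matrix of post-processed, censored data.
#' @return R x R symmetric matrix of Fisher-z values with zero diagonal.
#' @export
connectivity <- function(timeseries) {
  timeseries <- as.matrix(timeseries)
  if (nrow(timeseries) < 3) abort_param("need at least 3 retained frames")
  v <- apply(timeseries, 2, var)
  if (any(v <= 0)) {
    abort_param(sprintf("ROI %d has zero variance", which(v <= 0)[1]))
  }
  r <- cor(timeseries)
  off <- abs(r[upper.tri(r)])
  if (any(off >= 1 - 1e-12)) {
    abort_param("degenerate correlation |r| ~ 1 between distinct ROIs")
  }
  z <- atanh(r)
  diag(z) <- 0
  z
}

#' Vectorize a symmetric connectivity matrix to its canonical edge vector
#'
#' Extracts the strict lower triangle in the canonical row-major edge order
#' (see [edge_index_table()]); the diagonal is excluded.
#'
#' @param mat R x R symmetric numeric matrix.
#' @param tol Maximum allowed asymmetry `max |M - t(M)|`.
#' @return Numeric vector of length `R * (R - 1) / 2`.
#' @export
vectorize_connectivity <- function(mat, tol = 1e-8) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) abort_param("matrix must be square")
  if (max(abs(mat - t(mat))) > tol) {
    abort_param("matrix is asymmetric beyond tolerance")
  }
  # column-major upper triangle of a symmetric matrix equals the row-major
  # lower triangle: (2,1), (3,1), (3,2), ...
  mat[upper.tri(mat)]
}

#' Reconstruct a symmetric matrix from a canonical edge vector
#'
#' Inverse of [vectorize_connectivity()]: returns a symmetric R x R matrix
#' with zero diagonal whose canonical vectorization is `edges`.
#'
#' @param edges Numeric vector of length `R * (R - 1) / 2` for some R.
#' @return R x R symmetric matrix.
#' @export
inverse_vectorize <- function(edges) {
  e_n <- length(edges)
  r_n <- (1 + sqrt(1 + 8 * e_n)) / 2
  if (abs(r_n - round(r_n)) > 1e-9) {
    abort_param("edge vector length is not R*(R-1)/2 for any integer R")
  }
  r_n <- round(r_n)
  mat <- matrix(0, r_n, r_n)
  mat[upper.tri(mat)] <- edges
  mat + t(mat)
}

#' Assemble the cohort feature matrix of vectorized Fisher-z connectomes
#'
#' Post-processes every subject ([preprocess_subject()]), computes the
#' Fisher-z connectome, vectorizes it in the canonical edge order and
#' stacks subjects into an n x E feature matrix. Subjects flagged by the
#' scrubbing minimum are excluded from the matrix and reported.
#'
#' @param records List of [subject_record()] objects sharing the same ROI
#'   count.
#' @param drop_seconds,band,fd_threshold_mm,min_frames Passed to
#'   [preprocess_subject()].
#' @return An object of class `feature_matrix`: list with `features`
#'   (n x E matrix, rownames = subject ids), `edge_index` (tibble),
#'   `subjects` (tibble: subject_id, ls_score, n_scrubbed, excluded),
#'   `n_rois`.
#' @export
assemble_features <- function(records, drop_seconds = 10,
                              band = c(0.008, 0.1), fd_threshold_mm = 0.5,
                              min_frames = 50) {
  r_n <- unique(vapply(records, function(r) ncol(r$timeseries), integer(1)))
  if (length(r_n) != 1) {
    abort_param("all subjects must share the same number of ROIs")
  }
  pre <- purrr::map(records, preprocess_subject, drop_seconds = drop_seconds,
                    band = band, fd_threshold_mm = fd_threshold_mm,
                    min_frames = min_frames)
  subjects <- purrr::map_dfr(pre, function(p) tibble::tibble(
    subject_id = p$subject_id, ls_score = p$ls_score,
    n_scrubbed = p$n_scrubbed, excluded = p$excluded))
  kept <- pre[!subjects$excluded]
  features <- do.call(rbind, purrr::map(kept, function(p) {
    vectorize_connectivity(connectivity(p$timeseries))
  }))
  rownames(features) <- subjects$subject_id[!subjects$excluded]
  structure(
    list(features = features, edge_index = edge_index_table(r_n),
         subjects = subjects, n_rois = r_n),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix: %d subjects x %d edges (%d ROIs); %d excluded>\n",
    nrow(x$features), ncol(x$features), x$n_rois, sum(x$subjects$excluded)))
  invisible(x)
}
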