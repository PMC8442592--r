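#' Resting-state network labels
#'
#' The nine network labels used to partition ROIs: the seven canonical
#' cortical resting-state networks plus basal ganglia (BG) and cerebellar
#' (CER) networks.
#'
#' @format Character vector of length 9.
#' @export
rsn_labels <- c("Vis", "Somat", "DAN", "VAN", "Limb", "FP", "DMN", "BG", "CER")

#' Build the default synthetic 427-ROI atlas label table
#'
#' Returns a label table for a whole-brain parcellation with 400 cortical
#' ROIs, 17 subcortical ROIs and 10 cerebellar ROIs (427 total), each
#' assigned to one of nine resting-state networks. The cortical ROIs are
#' split over the seven cortical networks in proportions typical of a
#' 400-parcel cortical atlas; subcortical ROIs are labeled basal ganglia
#' (BG) and cerebellar ROIs CER.
#'
#' This table is *synthetic*: it reproduces the shape and network structure
#' of the published parcellations (parcel counts and the nine-network
#' partition), not their anatomy. Real analyses should supply their own
#' label table via [read_atlas_labels()].
#'
#' For ROI counts other than 427 (e.g. reduced synthetic cohorts), the ROIs
#' are split over the nine networks in the same proportions, each network
#' receiving at least one ROI when `n_rois >= 9`.
#'
#' @param n_rois Number of ROIs (default 427).
#' @return A tibble with columns `roi_index` (1-based), `roi_name`,
#'   `network` (one of [rsn_labels]).
#' @export
#' @examples
#' atlas <- default_atlas()
#' nrow(atlas)   # 427
#' table(atlas$network)
default_atlas <- function(n_rois = 427) {
  counts_427 <- c(Vis = 61, Somat = 77, DAN = 46, VAN = 47,
                  Limb = 26, FP = 52, DMN = 91, BG = 17, CER = 10)
  stopifnot(sum(counts_427) == 427)
  if (n_rois == 427) {
    counts <- counts_427
  } else {
    if (n_rois < 9) abort_param("default_atlas needs n_rois >= 9")
    counts <- round(counts_427 / 427 * n_rois)
    counts[counts < 1] <- 1
    # adjust the largest network so counts sum exactly to n_rois
    counts["DMN"] <- counts["DMN"] + (n_rois - sum(counts))
    if (counts["DMN"] < 1) abort_param("n_rois too small for nine networks")
  }
  network <- rep(names(counts), counts)
  tibble::tibble(
    roi_index = seq_along(network),
    roi_name = sprintf("ROI_%03d_%s", seq_along(network), network),
    network = network
  )
}

validate_atlas <- function(atlas) {
  req <- c("roi_index", "roi_name", "network")
  missing <- setdiff(req, names(atlas))
  if (length(missing) > 0) {
    abort_param(paste0("atlas table is missing column(s): ",
                       paste(missing, collapse = ", ")))
  }
  if (anyNA(atlas$network) || anyNA(atlas$roi_index)) {
    abort_param("atlas contains missing roi_index or network values")
  }
  bad <- setdiff(unique(atlas$network), rsn_labels)
  if (length(bad) > 0) {
    abort_param(paste0("atlas contains network label(s) outside the nine ",
                       "permitted: ", paste(bad, collapse = ", ")))
  }
  if (!identical(sort(as.integer(atlas$roi_index)), seq_len(nrow(atlas)))) {
    abort_param("atlas roi_index must be 1..R with every ROI labeled")
  }
  invisible(atlas)
}

#' Read an atlas label table
#'
#' Reads a tab-separated label table with columns `roi_index` (1-based),
#' `roi_name`, and `network`. Exactly nine network labels are permitted
#' (see [rsn_labels]); any other label is a validation error.
#'
#' @param path Path to a TSV file.
#' @return A validated tibble (see [default_atlas()] for the schema).
#' @export
read_atlas_labels <- function(path) {
  atlas <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  validate_atlas(atlas)
  atlas$roi_index <- as.integer(atlas$roi_index)
  dplyr::arrange(atlas, .data$roi_index)
}

#' Write an atlas label table
#' @param atlas Tibble as returned by [default_atlas()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_atlas_labels <- function(atlas, path) {
  validate_atlas(atlas)
  readr::write_tsv(atlas, path)
  invisible(path)
}
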