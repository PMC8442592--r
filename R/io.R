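read_tsv_strict <- function(path) {
  if (!file.exists(path)) abort_param(paste0("file not found: ", path))
  readr::read_tsv(path, show_col_types = FALSE, comment = "#")
}

#' Read a subject table
#'
#' TSV with columns `subject_id` and `ls_score`.
#'
#' @param path TSV path.
#' @return Tibble with `subject_id` (character) and `ls_score` (numeric).
#' @export
read_subject_table <- function(path) {
  tbl <- read_tsv_strict(path)
  missing <- setdiff(c("subject_id", "ls_score"), names(tbl))
  if (length(missing) > 0) {
    abort_param(paste0("subject table ", path, " missing column(s): ",
                       paste(missing, collapse = ", ")))
  }
  if (anyNA(tbl$ls_score)) {
    abort_param(sprintf("subject table %s: missing ls_score at line %d",
                        path, which(is.na(tbl$ls_score))[1] + 1L))
  }
  tibble::tibble(subject_id = as.character(tbl$subject_id),
                 ls_score = as.numeric(tbl$ls_score))
}

#' Read an ROI time-series table
#'
#' TSV with a header row of ROI names; each subsequent row is one frame.
#'
#' @param path TSV path.
#' @return T x R numeric matrix with ROI column names.
#' @export
read_timeseries <- function(path) {
  tbl <- read_tsv_strict(path)
  mat <- as.matrix(tbl)
  if (!is.numeric(mat)) abort_param(paste0("non-numeric entries in ", path))
  mat
}

#' Read a motion-parameter table
#'
#' TSV with six named columns (`trans_x/y/z` in mm, `rot_x/y/z` in
#' radians). The file must carry a unit declaration comment line
#' `# units: translations mm, rotations radians` — motion files with
#' undeclared units are rejected rather than silently misinterpreted.
#'
#' @param path TSV path.
#' @return T x 6 numeric matrix.
#' @export
read_motion <- function(path) {
  if (!file.exists(path)) abort_param(paste0("file not found: ", path))
  header <- readLines(path, n = 5)
  if (!any(grepl("^#\\s*units:.*mm.*radians", header))) {
    abort_param(paste0(
      "motion file ", path,
      " lacks the unit declaration '# units: translations mm, rotations radians'"))
  }
  tbl <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  req <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  missing <- setdiff(req, names(tbl))
  if (length(missing) > 0) {
    abort_param(paste0("motion file ", path, " missing column(s): ",
                       paste(missing, collapse = ", ")))
  }
  as.matrix(tbl[, req])
}

#' Read a tissue-signal table
#'
#' TSV with columns `wm`, `ventricle`, `gm` (mean white-matter, ventricle
#' and gray-matter signals per frame).
#'
#' @param path TSV path.
#' @return T x 3 numeric matrix.
#' @export
read_tissue <- function(path) {
  tbl <- read_tsv_strict(path)
  req <- c("wm", "ventricle", "gm")
  missing <- setdiff(req, names(tbl))
  if (length(missing) > 0) {
    abort_param(paste0("tissue file ", path, " missing column(s): ",
                       paste(missing, collapse = ", ")))
  }
  as.matrix(tbl[, req])
}

#' Read one subject's record from a cohort directory
#'
#' Expects `<id>_timeseries.tsv`, `<id>_motion.tsv`, `<id>_tissue.tsv` as
#' written by [write_cohort()]. Frame counts are cross-validated across the
#' three files.
#'
#' @param dir Cohort directory.
#' @param subject_id Subject identifier.
#' @param tr_seconds Repetition time.
#' @param ls_score Trait score (default `NA`).
#' @return A [subject_record()].
#' @export
read_subject_record <- function(dir, subject_id, tr_seconds,
                                ls_score = NA_real_) {
  ts <- read_timeseries(file.path(dir, paste0(subject_id, "_timeseries.tsv")))
  mo <- read_motion(file.path(dir, paste0(subject_id, "_motion.tsv")))
  ti <- read_tissue(file.path(dir, paste0(subject_id, "_tissue.tsv")))
  if (nrow(ts) != nrow(mo) || nrow(ts) != nrow(ti)) {
    abort_param(sprintf(
      "subject %s: frame counts disagree across files (ts %d, motion %d, tissue %d)",
      subject_id, nrow(ts), nrow(mo), nrow(ti)))
  }
  subject_record(subject_id, ts, mo, ti, tr_seconds, ls_score)
}

#' Write a synthetic time-series cohort to disk
#'
#' Writes, per subject, `<id>_timeseries.tsv` (T x R, ROI-name header),
#' `<id>_motion.tsv` (T x 6 with a unit declaration line) and
#' `<id>_tissue.tsv` (T x 3); plus `subjects.tsv` (subject_id, ls_score)
#' and `truth.json` (planted signal edge indices and effects).
#'
#' @param cohort Result of [generate_timeseries_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort$subjects) {
    ts <- tibble::as_tibble(rec$timeseries, .name_repair = "minimal")
    readr::write_tsv(ts, file.path(dir, paste0(rec$subject_id,
                                               "_timeseries.tsv")))
    mo_path <- file.path(dir, paste0(rec$subject_id, "_motion.tsv"))
    writeLines("# units: translations mm, rotations radians", mo_path)
    mo <- rec$motion
    colnames(mo) <- c("trans_x", "trans_y", "trans_z",
                      "rot_x", "rot_y", "rot_z")
    readr::write_tsv(tibble::as_tibble(mo), mo_path, append = TRUE,
                     col_names = TRUE)
    ti <- rec$tissue_signals
    colnames(ti) <- c("wm", "ventricle", "gm")
    readr::write_tsv(tibble::as_tibble(ti),
                     file.path(dir, paste0(rec$subject_id, "_tissue.tsv")))
  }
  readr::write_tsv(cohort$ls, file.path(dir, "subjects.tsv"))
  jsonlite::write_json(
    list(signal_edges = cohort$signal_edges, effects = cohort$effects,
         n_rois = cohort$spec$n_rois, seed = cohort$spec$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory containing `subjects.tsv` and per-subject
#'   files.
#' @param tr_seconds Repetition time of the stored runs.
#' @return List with `subjects` (list of [subject_record()]) and `ls`
#'   (tibble).
#' @export
read_cohort <- function(dir, tr_seconds) {
  ls_tbl <- read_subject_table(file.path(dir, "subjects.tsv"))
  subjects <- purrr::map2(ls_tbl$subject_id, ls_tbl$ls_score,
                          function(id, score) {
                            read_subject_record(dir, id, tr_seconds, score)
                          })
  list(subjects = subjects, ls = ls_tbl)
}
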