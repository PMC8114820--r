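#' Write a recording as delimited text plus JSON sidecar
#'
#' The on-disk exchange format: one tab-separated matrix per recording
#' (rows = samples, columns = channels, header row of channel ids) and a
#' JSON sidecar `<stem>.json` holding the sampling rate, channel metadata,
#' markers, subject and session.
#'
#' @param rec A [bci_recording].
#' @param stem Output path without extension; writes `<stem>.tsv` and
#'   `<stem>.json`.
#' @return The stem, invisibly.
#' @export
write_recording <- function(rec, stem) {
  stopifnot(inherits(rec, "bci_recording"))
  m <- t(rec$data)
  colnames(m) <- rec$channels$id
  utils::write.table(m, paste0(stem, ".tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  meta <- list(fs = rec$fs, modality = rec$modality,
               subject_id = rec$subject_id, session_id = rec$session_id,
               channels = rec$channels, markers = rec$markers)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(stem)
}

#' Read a recording written by [write_recording()]
#' @param stem Path stem (without extension).
#' @return A [bci_recording].
#' @export
read_recording <- function(stem) {
  m <- as.matrix(utils::read.table(paste0(stem, ".tsv"), header = TRUE,
                                   sep = "\t", check.names = FALSE))
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  channels <- as.data.frame(meta$channels, stringsAsFactors = FALSE)
  markers <- as.data.frame(meta$markers, stringsAsFactors = FALSE)
  if (nrow(markers) > 0) {
    markers$onset_sample <- as.integer(markers$onset_sample)
    markers$label <- as.integer(markers$label)
  }
  data <- t(m)
  dimnames(data) <- NULL
  bci_recording(data, meta$fs, channels, markers,
                meta$subject_id, meta$session_id, meta$modality)
}

#' Write a feature table as CSV
#'
#' Features in header-named columns followed by a final `label` column with
#' values 1/2.
#' @param table A [feature_table].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- as.data.frame(table$X)
  df$label <- table$y
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path.
#' @param set Provenance tag for the loaded table.
#' @return A [feature_table].
#' @export
read_feature_table <- function(path, set = "features") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"label" %in% names(df)) stop("no 'label' column in ", path)
  y <- as.integer(df$label)
  X <- as.matrix(df[, setdiff(names(df), "label"), drop = FALSE])
  feature_table(X, y, set = set)
}

#' Write class weights as CSV
#'
#' Rows are class 1 and class 2; columns are features.
#' @param cw A `class_weights` object.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_class_weights <- function(cw, path) {
  stopifnot(inherits(cw, "class_weights"))
  utils::write.csv(as.data.frame(cw$w), path, row.names = TRUE)
  invisible(path)
}

#' Write an evaluation report as JSON and CSV
#'
#' The JSON mirrors the nested cell structure (feature set -> classifier ->
#' weighting); the CSV is the flat grid with one row per cell and the
#' columns ACC %, SENS, FPR, PRC, Kappa and "error ± CI".
#'
#' @param report An `eval_report` from [run_experiment()].
#' @param stem Output path stem; writes `<stem>.json` and `<stem>.csv`.
#' @return The stem, invisibly.
#' @export
write_report <- function(report, stem) {
  stopifnot(inherits(report, "eval_report"))
  nested <- lapply(report$cells, function(by_clf)
    lapply(by_clf, function(by_wgt)
      lapply(by_wgt, function(res) {
        m <- res$metrics
        list(acc = m$acc, sens = m$sens, fpr = m$fpr, prc = m$prc,
             kappa = m$kappa, error = m$error, ci = m$ci, n = m$n,
             fold_acc = res$fold_acc,
             counts = unclass(m$counts))
      })))
  jsonlite::write_json(list(config = report$config, cells = nested),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  g <- report$grid
  g$classification_error <- sprintf("%.3f ± %.3f", g$error, g$ci)
  utils::write.csv(g, paste0(stem, ".csv"), row.names = FALSE)
  invisible(stem)
}
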