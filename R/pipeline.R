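#' Preprocess an optical-density recording to hemoglobin epoch inputs
#'
#' The fNIRS arm of the pipeline: modified Beer-Lambert inversion to
#' HbO/HbR, 3rd-order 0.01-0.09 Hz zero-phase Butterworth band-pass at the
#' acquisition rate, then polyphase downsampling to `fs_out` (default
#' 10 Hz).  Filtering before downsampling keeps the band edges far from the
#' design Nyquist; the order is configurable by calling the stages
#' ([od_to_hemo()], [filter_recording()], [resample_recording()]) directly.
#'
#' @param od_rec An optical-density [bci_recording].
#' @param p [mbll_params]; defaults to the recording's attached parameters.
#' @param low,high,order Band-pass settings.
#' @param fs_out Target sampling rate in Hz.
#' @return List with filtered, resampled `hbo` and `hbr` [bci_recording]s.
#' @export
preprocess_nirs <- function(od_rec, p = NULL, low = 0.01, high = 0.09,
                            order = 3, fs_out = 10) {
  hemo <- od_to_hemo(od_rec, p)
  lapply(hemo, function(rec)
    resample_recording(filter_recording(rec, low, high, order), fs_out))
}

#' Preprocess an EEG recording
#'
#' The EEG arm applies only the acquisition-protocol downsampling (default
#' 1000 Hz -> 200 Hz) with the anti-aliased polyphase resampler.
#'
#' @param rec An EEG [bci_recording].
#' @param fs_out Target sampling rate in Hz.
#' @return The resampled [bci_recording].
#' @export
preprocess_eeg <- function(rec, fs_out = 200) {
  resample_recording(rec, fs_out)
}

#' Simulate, preprocess and reduce a dataset to feature tables
#'
#' Streams the full synthetic pipeline one subject-session at a time:
#' generate the continuous recordings, preprocess each modality, segment
#' into `[-2, 10)` s trials, baseline-correct on the instruction window,
#' extract the seven per-channel statistics, and append the rows to the
#' accumulating feature tables.  Each session's raw data is discarded after
#' reduction, so the default 29-subject geometry runs in bounded memory.
#'
#' @param cfg A [sim_config].
#' @param modalities Subset of `c("od", "eeg")`; the returned list contains
#'   the feature sets computable from it (all six when both are present).
#' @param subjects Integer vector of subject indices (default all).
#' @param p [mbll_params] for the forward and inverse optical model.
#' @param fs_nirs_out,fs_eeg_out Post-downsampling rates.
#' @param verbose Print one line per session.
#' @return Named list of [feature_table]s (see [feature_tables()]), each
#'   with per-row `meta` (subject, session, trial).
#' @export
simulate_feature_tables <- function(cfg, modalities = c("od", "eeg"),
                                    subjects = NULL, p = mbll_params(),
                                    fs_nirs_out = 10, fs_eeg_out = 200,
                                    verbose = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  modalities <- match.arg(modalities, c("od", "eeg"), several.ok = TRUE)
  if (is.null(subjects)) subjects <- seq_len(cfg$n_subjects)
  window <- c(0, cfg$task_duration)
  context <- c(-cfg$baseline_duration, cfg$task_duration)

  acc <- list()
  append_tab <- function(name, tab) {
    acc[[name]] <<- if (is.null(acc[[name]])) tab else {
      feature_table(rbind(acc[[name]]$X, tab$X), c(acc[[name]]$y, tab$y),
                    set = tab$set, meta = rbind(acc[[name]]$meta, tab$meta))
    }
  }

  for (s in subjects)
    for (ss in seq_len(cfg$n_sessions)) {
      sess <- simulate_session(cfg, s, ss, modalities, p)
      n_tr <- nrow(sess[[1]]$markers)
      meta <- data.frame(subject = s, session = ss, trial = seq_len(n_tr))
      hbo_ep <- hbr_ep <- eeg_ep <- NULL
      if ("od" %in% modalities) {
        hemo <- preprocess_nirs(sess$od, p, fs_out = fs_nirs_out)
        hbo_ep <- baseline_correct(segment(hemo$hbo, window, context))
        hbr_ep <- baseline_correct(segment(hemo$hbr, window, context))
      }
      if ("eeg" %in% modalities) {
        eeg <- preprocess_eeg(sess$eeg, fs_out = fs_eeg_out)
        eeg_ep <- baseline_correct(segment(eeg, window, context))
      }
      tabs <- feature_tables(hbo = hbo_ep, hbr = hbr_ep, eeg = eeg_ep,
                             meta = meta)
      for (nm in names(tabs)) append_tab(nm, tabs[[nm]])
      if (verbose)
        message(sprintf("subject %d session %d: %d trials", s, ss, n_tr))
    }
  acc
}
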