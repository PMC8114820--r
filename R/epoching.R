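#' Stimulus-locked epochs
#'
#' Container for segmented trials: a `trials x channels x samples` array with
#' sampling rate, the time of the first sample relative to stimulus onset
#' (`t0`, seconds), per-trial class labels, channel ids and a modality tag.
#' Constructed by [segment()].
#'
#' @param data Numeric array `trials x channels x samples`.
#' @param fs Sampling rate in Hz.
#' @param t0 Time of the first retained sample relative to onset (s).
#' @param labels Integer vector of per-trial labels in `{1, 2}`.
#' @param channel_ids Character vector of channel identifiers.
#' @param modality Modality tag.
#' @param task_window Length-2 task window in seconds (kept so that
#'   [baseline_correct()] knows where to trim).
#' @return Object of class `bci_epochs`.
#' @export
bci_epochs <- function(data, fs, t0, labels, channel_ids, modality,
                       task_window = c(0, 10)) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (dim(data)[1] != length(labels))
    stop("one label per trial is required")
  if (length(unique(labels)) > 2 || !all(labels %in% c(1L, 2L)))
    stop("labels must take values in {1, 2}")
  structure(list(data = data, fs = fs, t0 = t0, labels = as.integer(labels),
                 channel_ids = channel_ids, modality = modality,
                 task_window = task_window),
            class = "bci_epochs")
}

#' @export
print.bci_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bci_epochs> %s: %d trials x %d channels x %d samples @ %g Hz (t0 = %g s)\n",
              x$modality, d[1], d[2], d[3], x$fs, x$t0))
  invisible(x)
}

#' Cut a continuous recording into stimulus-locked trials
#'
#' Extracts one trial per marker using half-open sample windows
#' `[round(onset + a * fs), round(onset + b * fs))`, ordered by onset.  The
#' wider `context` window (default `[-2, 10)` s) is retained so baseline
#' samples remain available to [baseline_correct()]; `window` records the
#' task span proper.
#'
#' @param rec A [bci_recording].
#' @param window Task window in seconds relative to onset (half-open).
#' @param context Retained window in seconds (must contain `window`).
#' @return A [bci_epochs] object with `t0 = context[1]`.
#' @examples
#' cfg <- sim_config(n_subjects = 1, n_sessions = 1, trials_per_session = 3,
#'                   n_nirs_channels = 2, n_eeg_channels = 2,
#'                   fs_eeg_raw = 100)
#' rec <- generate_dataset(cfg, modalities = "eeg")[[1]]$eeg
#' ep <- segment(rec, window = c(0, 10), context = c(-2, 10))
#' dim(ep$data)  # 3 trials x 2 channels x 1200 samples
#' @export
segment <- function(rec, window = c(0, 10), context = c(-2, 10)) {
  stopifnot(inherits(rec, "bci_recording"))
  if (context[1] > window[1] || context[2] < window[2])
    stop("context window must contain the task window")
  fs <- rec$fs
  markers <- rec$markers[order(rec$markers$onset_sample), , drop = FALSE]
  n_tr <- nrow(markers)
  if (n_tr == 0) stop("recording has no markers")
  a <- round(context[1] * fs)
  b <- round(context[2] * fs)
  n_samp <- b - a
  N <- ncol(rec$data)
  out <- array(0, dim = c(n_tr, nrow(rec$data), n_samp))
  for (k in seq_len(n_tr)) {
    start <- markers$onset_sample[k] + a
    end <- markers$onset_sample[k] + b - 1L
    if (start < 1 || end > N)
      stop(sprintf("marker %d (onset sample %d) lacks a full [%g, %g) s context window",
                   k, markers$onset_sample[k], context[1], context[2]))
    out[k, , ] <- rec$data[, seq(start, end), drop = FALSE]
  }
  bci_epochs(out, fs, context[1], markers$label, rec$channels$id,
             rec$modality, task_window = window)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline window
#' (default the 2-s instruction period `[-2, 0)` s before stimulation), then
#' trims the epochs to the task window.  Requires the epochs to still carry
#' baseline context; a second application on trimmed epochs therefore fails
#' with a precondition error.
#'
#' @param epochs A [bci_epochs] object whose `t0` covers the baseline.
#' @param baseline Baseline window in seconds (half-open).
#' @param trim Trim to the task window after correction (default `TRUE`);
#'   with `FALSE` the full context is kept, which is useful for checking
#'   that the post-correction baseline mean is zero.
#' @return A corrected [bci_epochs] object.
#' @export
baseline_correct <- function(epochs, baseline = c(-2, 0), trim = TRUE) {
  stopifnot(inherits(epochs, "bci_epochs"))
  fs <- epochs$fs
  if (epochs$t0 > baseline[1])
    stop(sprintf("epochs start at %g s; baseline window [%g, %g) s is not covered",
                 epochs$t0, baseline[1], baseline[2]))
  i0 <- round((baseline[1] - epochs$t0) * fs) + 1L
  i1 <- round((baseline[2] - epochs$t0) * fs)
  if (i1 < i0) stop("baseline window contains no samples")
  d <- dim(epochs$data)
  base_mean <- apply(epochs$data[, , seq(i0, i1), drop = FALSE], c(1, 2), mean)
  corrected <- sweep(epochs$data, c(1, 2), base_mean)
  if (trim) {
    tw <- epochs$task_window
    j0 <- round((tw[1] - epochs$t0) * fs) + 1L
    j1 <- round((tw[2] - epochs$t0) * fs)
    corrected <- corrected[, , seq(j0, j1), drop = FALSE]
    epochs$t0 <- tw[1]
  }
  epochs$data <- corrected
  epochs
}
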