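#' Multichannel continuous recording
#'
#' Container for one continuous multichannel time series: raw EEG (microvolts),
#' optical density (dimensionless), or derived hemoglobin concentration
#' changes (mM).  Channels are rows of `data`; stimulus onsets are stored as
#' 1-based sample indices in `markers` together with the binary class label.
#'
#' @param data Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz.
#' @param channels Data frame with one row per channel: `id`, `modality`
#'   (one of `"eeg"`, `"od"`, `"hbo"`, `"hbr"`), and for optical-density
#'   channels `wavelength` (nm), `pair_id` (links the two wavelengths of one
#'   source-detector pair) and `rho` (source-detector separation, cm).
#' @param markers Data frame with columns `onset_sample` (1-based index of
#'   stimulus onset) and `label` (1 or 2).
#' @param subject_id,session_id Identifiers.
#' @param modality Recording-level modality tag.
#'
#' @return An object of class `bci_recording`.
#' @export
bci_recording <- function(data, fs, channels, markers,
                          subject_id = 1L, session_id = 1L,
                          modality = channels$modality[1]) {
  stopifnot(is.matrix(data), is.numeric(data), fs > 0)
  if (nrow(channels) != nrow(data))
    stop("channels metadata must have one row per data row")
  if (nrow(markers) > 0) {
    if (!all(markers$label %in% c(1L, 2L)))
      stop("marker labels must be 1 or 2")
    if (any(markers$onset_sample < 1 | markers$onset_sample > ncol(data)))
      stop("marker onsets out of recording bounds")
  }
  if (identical(modality, "od")) {
    tab <- table(channels$pair_id)
    if (any(tab != 2))
      stop("every od pair_id must appear exactly twice (one channel per wavelength)")
    for (p in unique(channels$pair_id)) {
      wl <- channels$wavelength[channels$pair_id == p]
      if (length(unique(wl)) != 2)
        stop("the two channels of an od pair must have distinct wavelengths")
    }
  }
  structure(list(data = data, fs = fs, channels = channels, markers = markers,
                 subject_id = subject_id, session_id = session_id,
                 modality = modality),
            class = "bci_recording")
}

#' @export
print.bci_recording <- function(x, ...) {
  cat(sprintf("<bci_recording> %s: %d channels x %d samples @ %g Hz, %d markers (subject %s, session %s)\n",
              x$modality, nrow(x$data), ncol(x$data), x$fs, nrow(x$markers),
              x$subject_id, x$session_id))
  invisible(x)
}

#' Total recording duration in seconds
#' @param rec A `bci_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$fs
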