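#' Canonical double-gamma hemodynamic response function
#'
#' Unit-peak double-gamma curve used by the synthetic generator to give the
#' simulated HbO/HbR series a realistic task-locked shape: a positive lobe
#' peaking at `peak_time` followed by a small undershoot.  The curve starts
#' at exactly 0 and is normalized so its maximum is exactly 1.
#'
#' @param fs Sampling rate in Hz.
#' @param duration Curve length in seconds.
#' @param peak_time Time of the positive peak in seconds (default 6).
#' @param undershoot_time Time of the undershoot trough in seconds.
#' @param undershoot_ratio Relative undershoot amplitude.
#' @return Numeric vector of `round(duration * fs)` samples.
#' @examples
#' h <- make_hrf(10, 20)
#' length(h); max(h); which.max(h)  # 200 samples, peak 1 near t = 6 s
#' @export
make_hrf <- function(fs, duration, peak_time = 6, undershoot_time = 16,
                     undershoot_ratio = 1 / 6) {
  if (!is.finite(fs) || fs <= 0) stop("fs must be > 0")
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  n <- round(duration * fs)
  if (n < 2) stop("duration * fs must give at least 2 samples")
  t <- (seq_len(n) - 1) / fs
  # gamma densities with rate 1 peak at shape - 1
  h <- stats::dgamma(t, shape = peak_time + 1, rate = 1) -
    undershoot_ratio * stats::dgamma(t, shape = undershoot_time + 1, rate = 1)
  h / max(h)
}
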