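#' Butterworth band-pass filter
#'
#' Band-pass filters a series (or the rows of a channels x samples matrix)
#' with an order-`order` Butterworth design.  The default band 0.01-0.09 Hz
#' isolates the task-locked hemodynamic response of fNIRS hemoglobin series
#' while rejecting drift, respiration and cardiac components.
#'
#' By default filtering is zero-phase (forward-backward), because epoch
#' timing relative to stimulus onset must not be phase-shifted; this doubles
#' the effective magnitude order.  Edges are handled with odd-symmetric
#' padding of three filter orders plus DC-matched initial conditions, so a
#' constant input maps to (numerically) zero everywhere.  `zero_phase =
#' FALSE` gives a single causal pass.
#'
#' @param x Numeric vector, or matrix filtered along rows.
#' @param fs Sampling rate in Hz.
#' @param low,high Band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param order Butterworth order (per pass).
#' @param zero_phase Forward-backward filtering (default) or single pass.
#' @return Filtered series, same shape as `x`.
#' @examples
#' t <- seq(0, 600, by = 0.1)
#' x <- sin(2 * pi * 0.05 * t) + sin(2 * pi * 1 * t)
#' y <- bandpass(x, fs = 10)      # keeps 0.05 Hz, removes 1 Hz
#' @export
bandpass <- function(x, fs, low = 0.01, high = 0.09, order = 3,
                     zero_phase = TRUE) {
  if (!is.finite(fs) || fs <= 0) stop("fs must be > 0")
  if (!(low > 0 && high > low && high < fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2")
  if (order < 1 || order != round(order)) stop("order must be a positive integer")
  sos <- butter_bp_sos(order, c(low, high) / (fs / 2))
  if (is.matrix(x)) {
    out <- x
    for (i in seq_len(nrow(x)))
      out[i, ] <- filter_one(sos, x[i, ], order, zero_phase)
    return(out)
  }
  filter_one(sos, as.numeric(x), order, zero_phase)
}

# Butterworth band-pass as cascaded biquads, designed analytically: analog
# low-pass prototype poles -> low-pass-to-band-pass transform -> bilinear
# map, with the gain fixed to 1 at the band center.  Working pole-by-pole
# (never expanding the polynomial) keeps the design well conditioned at
# narrow normalized bands, where the expanded direct form loses ~6 digits.
butter_bp_sos <- function(order, w) {
  W1 <- tan(pi * w[1] / 2)          # prewarped edges
  W2 <- tan(pi * w[2] / 2)
  W0 <- sqrt(W1 * W2)
  BW <- W2 - W1
  theta <- pi * (2 * seq_len(order) - 1) / (2 * order)
  proto <- complex(real = -sin(theta), imaginary = cos(theta))
  s_poles <- unlist(lapply(proto, function(p) {
    t1 <- BW * p / 2
    rt <- sqrt(t1^2 - W0^2)
    c(t1 + rt, t1 - rt)
  }))
  zp <- (1 + s_poles) / (1 - s_poles)  # bilinear; zeros land on z = +/-1
  # greedy conjugate pairing into real-coefficient biquads
  sections <- list()
  used <- rep(FALSE, length(zp))
  for (i in seq_along(zp)) {
    if (used[i]) next
    used[i] <- TRUE
    cand <- which(!used)
    j <- cand[which.min(Mod(Conj(zp[i]) - zp[cand]))]
    used[j] <- TRUE
    sections[[length(sections) + 1]] <-
      list(b = c(1, 0, -1),
           a = c(1, -Re(zp[i] + zp[j]), Re(zp[i] * zp[j])))
  }
  # unit gain at the band center
  z0 <- exp(2i * atan(W0))
  resp <- prod(vapply(sections, function(s) {
    zz <- z0^-(0:2)
    Mod(sum(s$b * zz) / sum(s$a * zz))
  }, numeric(1)))
  sections[[1]]$b <- sections[[1]]$b / resp
  sections
}

# one channel: odd-symmetric padding + steady-state (DC-matched) initial
# conditions per section, optionally forward-backward
filter_one <- function(sos, x, order, zero_phase) {
  n <- length(x)
  pad <- min(3L * order, n - 1L)
  ext <- if (pad > 0)
    c(2 * x[1] - rev(x[seq(2, pad + 1)]), x,
      2 * x[n] - rev(x[seq(n - pad, n - 1)]))
  else x
  y <- causal_pass(sos, ext)
  if (zero_phase) y <- rev(causal_pass(sos, rev(y)))
  y[seq(pad + 1, pad + n)]
}

# cascaded IIR passes, each started from the steady state of a constant
# input equal to its first sample, so a DC signal produces its steady
# response from sample 1
causal_pass <- function(sos, x) {
  for (s in sos) {
    gdc <- sum(s$b) / sum(s$a)
    x <- as.numeric(signal::filter(s$b, s$a, x,
                                   init.x = rep(x[1], 2),
                                   init.y = rep(x[1] * gdc, 2)))
  }
  x
}

#' Polyphase rational-ratio resampling
#'
#' Downsamples a series from `fs_in` to `fs_out` (`fs_in >= fs_out`) with an
#' anti-aliasing FIR low-pass: the rate ratio is reduced to `p/q`, the input
#' is upsampled by `p`, filtered, and decimated by `q`.  The FIR is a
#' Hamming-windowed sinc whose polyphase branches are renormalized to unit
#' sum, so a constant series is preserved exactly, and the (odd) filter delay
#' is compensated so output sample `m` sits at time `(m-1)/fs_out`.  Output
#' length is `round(n * fs_out / fs_in)`.  Supports e.g. 12.5 -> 10 Hz
#' (ratio 4/5) and 1000 -> 200 Hz (ratio 1/5).
#'
#' @param x Numeric vector, or matrix resampled along rows.
#' @param fs_in,fs_out Input and output sampling rates in Hz.
#' @param half_order Half-length of each polyphase branch (filter length is
#'   `2 * half_order * max(p, q) + 1`).
#' @return Resampled series.
#' @export
resample_ts <- function(x, fs_in, fs_out, half_order = 10) {
  if (!is.finite(fs_in) || !is.finite(fs_out) || fs_out <= 0)
    stop("sampling rates must be > 0")
  if (fs_out > fs_in)
    stop("upsampling (fs_out > fs_in) is not supported")
  if (is.matrix(x)) {
    first <- resample_ts(x[1, ], fs_in, fs_out, half_order)
    out <- matrix(0, nrow(x), length(first))
    out[1, ] <- first
    if (nrow(x) > 1)
      for (i in 2:nrow(x)) out[i, ] <- resample_ts(x[i, ], fs_in, fs_out, half_order)
    return(out)
  }
  x <- as.numeric(x)
  n <- length(x)
  if (fs_in == fs_out) return(x)
  r <- rational_ratio(fs_out / fs_in)
  p <- r[1]; q <- r[2]
  len_out <- round(n * fs_out / fs_in)

  L <- 2L * half_order * max(p, q) + 1L       # odd tap count
  h <- p * signal::fir1(L - 1L, min(1 / p, 1 / q))
  # exact DC gain: each polyphase branch sums to 1
  for (k in seq_len(p)) {
    idx <- seq(k, L, by = p)
    h[idx] <- h[idx] / sum(h[idx])
  }
  D <- (L - 1L) / 2L                          # integer group delay
  E <- ceiling((D + q * len_out - (n - 1) * p) / p) + 1L  # right pad need
  Epad <- max(E, ceiling(D / p) + 1L)
  xp <- c(rep(x[1], Epad), x, rep(x[n], Epad))
  up <- numeric(length(xp) * p)
  up[seq(1, length(up), by = p)] <- xp
  yf <- signal::fftfilt(h, c(up, numeric(L)))  # linear conv head, length >= up+L
  # output m (1-based) at upsampled index j = (m-1)*q + 1 + Epad*p, delayed by D
  j <- (seq_len(len_out) - 1L) * q + 1L + Epad * p + D
  yf[j]
}

# smallest integer p/q with p/q == r (within tolerance)
rational_ratio <- function(r, max_q = 10000L, tol = 1e-9) {
  for (q in seq_len(max_q)) {
    p <- r * q
    if (abs(p - round(p)) < tol * q) {
      p <- as.integer(round(p))
      g <- gcd_int(p, q)
      return(c(p %/% g, as.integer(q) %/% g))
    }
  }
  stop("sampling-rate ratio is not a small rational number")
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Band-pass filter a recording
#'
#' Applies [bandpass()] to every channel of a [bci_recording]; markers and
#' metadata are unchanged.
#' @param rec A `bci_recording`.
#' @inheritParams bandpass
#' @return Filtered `bci_recording`.
#' @export
filter_recording <- function(rec, low = 0.01, high = 0.09, order = 3,
                             zero_phase = TRUE) {
  stopifnot(inherits(rec, "bci_recording"))
  rec$data <- bandpass(rec$data, rec$fs, low, high, order, zero_phase)
  rec
}

#' Resample a recording
#'
#' Applies [resample_ts()] to every channel and rescales marker onsets to the
#' new sampling grid (`onset' = round(t_onset * fs_out) + 1`).
#' @param rec A `bci_recording`.
#' @param fs_out Target sampling rate in Hz (`<=` current rate).
#' @return Resampled `bci_recording`.
#' @export
resample_recording <- function(rec, fs_out) {
  stopifnot(inherits(rec, "bci_recording"))
  if (rec$fs == fs_out) return(rec)
  data <- resample_ts(rec$data, rec$fs, fs_out)
  markers <- rec$markers
  if (nrow(markers) > 0)
    markers$onset_sample <-
      as.integer(round((markers$onset_sample - 1) * fs_out / rec$fs)) + 1L
  rec$data <- data
  rec$fs <- fs_out
  rec$markers <- markers
  rec
}
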