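#' Seven per-channel trial statistics
#'
#' Computes the feature vector used for every channel of every trial:
#' mean, maximum, slope, variance, skewness, kurtosis and median of the
#' epoch samples.
#'
#' Definitions: mean is the arithmetic average; maximum the largest
#' amplitude; slope the least-squares linear-regression slope over the whole
#' epoch in amplitude per second; variance uses the `N - 1` denominator;
#' skewness and kurtosis are the third and fourth standardized moments with
#' the population (biased) standard deviation in the denominator, and the
#' kurtosis is *not* excess (a Gaussian gives 3); median is the middle order
#' statistic (mean of the two middle values for even `N`).  For a constant
#' epoch the standardized moments are undefined; they are returned as 0 with
#' a warning so degenerate all-zero channels do not abort a run.
#'
#' The slope is computed over the whole epoch by default.  `slope_window`
#' switches to a windowed variant: the epoch is split into consecutive
#' windows of that length (seconds) and the per-window regression slopes are
#' averaged; for a noise-free linear trend both definitions agree.
#'
#' @param x Numeric vector of epoch samples (length >= 3).
#' @param fs Sampling rate in Hz (sets the slope's time unit).
#' @param slope_window Optional window length in seconds for the windowed
#'   slope variant (must contain at least 2 samples).
#' @return Named numeric vector
#'   `c(mean, max, slope, var, skew, kurt, median)`.
#' @examples
#' channel_features(c(1, 2, 3, 4), fs = 1)  # slope exactly 1
#' @export
channel_features <- function(x, fs = 1, slope_window = NULL) {
  n <- length(x)
  if (n < 3) stop("epoch must contain at least 3 samples")
  if (!is.finite(fs) || fs <= 0) stop("fs must be > 0")
  mu <- mean(x)
  d <- x - mu
  slope <- if (is.null(slope_window)) ls_slope(x, fs)
           else windowed_slope(x, fs, slope_window)
  m2 <- mean(d^2)  # population variance for the standardized moments
  if (m2 < .Machine$double.eps * max(1, mu^2)) {
    warning("constant epoch: skewness and kurtosis set to 0")
    skew <- 0
    kurt <- 0
  } else {
    skew <- mean(d^3) / m2^1.5
    kurt <- mean(d^4) / m2^2
  }
  c(mean = mu, max = max(x), slope = slope,
    var = sum(d^2) / (n - 1), skew = skew, kurt = kurt,
    median = stats::median(x))
}

ls_slope <- function(x, fs) {
  t <- (seq_along(x) - 1) / fs
  tc <- t - mean(t)
  sum(tc * (x - mean(x))) / sum(tc^2)
}

# mean of least-squares slopes over consecutive windows of slope_window s
windowed_slope <- function(x, fs, slope_window) {
  nw <- floor(slope_window * fs)
  if (nw < 2) stop("slope_window must contain at least 2 samples")
  starts <- seq(1, length(x) - nw + 1, by = nw)
  mean(vapply(starts, function(s) ls_slope(x[seq(s, s + nw - 1)], fs),
              numeric(1)))
}

feature_names <- function() c("mean", "max", "slope", "var", "skew", "kurt", "median")

#' Labeled feature table
#'
#' The unit of exchange between the feature-extraction and classification
#' stages: an observations x features matrix `X`, a label vector `y` in
#' `{1, 2}`, a provenance tag (`set`) naming which of the six feature sets it
#' is, and optional per-row metadata (subject, session, trial).
#'
#' @param X Numeric matrix with named columns.
#' @param y Integer labels, one per row.
#' @param set Provenance tag.
#' @param meta Optional data frame of per-row metadata.
#' @return Object of class `feature_table`.
#' @export
feature_table <- function(X, y, set = "features", meta = NULL) {
  stopifnot(is.matrix(X))
  if (nrow(X) != length(y)) stop("one label per row is required")
  if (!is.null(meta) && nrow(meta) != nrow(X))
    stop("meta must have one row per observation")
  structure(list(X = X, y = as.integer(y), set = set, meta = meta),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  tab <- table(x$y)
  cat(sprintf("<feature_table> %s: %d observations x %d features (classes: %s)\n",
              x$set, nrow(x$X), ncol(x$X),
              paste(sprintf("%s:%d", names(tab), as.integer(tab)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$X)

#' Build a feature table from epochs
#'
#' Computes the seven statistics of [channel_features()] for every channel
#' of every trial and lays them out channel-major: all seven features of
#' channel 1, then channel 2, and so on, giving `7 * n_channels` columns
#' (252 for 36 fNIRS channels, 224 for 32 EEG channels).  Labels form a
#' separate `y` vector; serialized as CSV the table gains a final `label`
#' column.
#'
#' @param epochs A [bci_epochs] object (typically baseline-corrected and
#'   trimmed to the task window).
#' @param set Provenance tag; defaults to the epochs' modality.
#' @param meta Optional per-trial metadata data frame.
#' @param slope_window Passed to [channel_features()].
#' @return A [feature_table].
#' @export
build_table <- function(epochs, set = epochs$modality, meta = NULL,
                        slope_window = NULL) {
  stopifnot(inherits(epochs, "bci_epochs"))
  d <- dim(epochs$data)
  n_tr <- d[1]; n_ch <- d[2]
  if (n_tr < 1) stop("epochs contain no trials")
  X <- matrix(0, n_tr, 7 * n_ch)
  for (c in seq_len(n_ch)) {
    cols <- (c - 1) * 7 + seq_len(7)
    for (k in seq_len(n_tr))
      X[k, cols] <- channel_features(epochs$data[k, c, ], epochs$fs,
                                     slope_window = slope_window)
  }
  colnames(X) <- as.vector(vapply(seq_len(n_ch), function(c)
    paste0(epochs$channel_ids[c], "_", feature_names()),
    character(7)))
  feature_table(X, epochs$labels, set = set, meta = meta)
}

#' Horizontally combine two feature tables
#'
#' Concatenates the feature blocks of two tables describing the same trials
#' in the same order (e.g. EEG + HbO -> 224 + 252 = 476 features).  The
#' label vectors must agree exactly; a mismatch signals a trial-ordering
#' bug upstream and raises an error.
#'
#' @param a,b [feature_table]s with identical row counts and labels.  `b`
#'   may have zero feature columns, in which case `a` is returned with the
#'   combined tag.
#' @return The combined [feature_table].
#' @export
combine_tables <- function(a, b) {
  stopifnot(inherits(a, "feature_table"), inherits(b, "feature_table"))
  if (nrow(a$X) != nrow(b$X))
    stop("tables describe different numbers of observations")
  if (!identical(a$y, b$y))
    stop("label vectors differ: trial ordering is inconsistent")
  feature_table(cbind(a$X, b$X), a$y,
                set = if (ncol(b$X) == 0) a$set else paste(a$set, b$set, sep = "+"),
                meta = a$meta %||% b$meta)
}

#' Assemble the six singular and hybrid feature sets
#'
#' Given HbO, HbR and EEG epoch sets describing the same trials, builds the
#' six labeled tables evaluated by the experiment: `hbo`, `hbr`, `eeg`,
#' `hbo+hbr`, `eeg+hbo` and `eeg+hbr`.
#'
#' @param hbo,hbr,eeg [bci_epochs] for the three signals (any may be `NULL`,
#'   in which case the sets requiring it are omitted).
#' @param meta Optional per-trial metadata attached to every table.
#' @return Named list of [feature_table]s.
#' @export
feature_tables <- function(hbo = NULL, hbr = NULL, eeg = NULL, meta = NULL) {
  singles <- list()
  if (!is.null(hbo)) singles$hbo <- build_table(hbo, "hbo", meta)
  if (!is.null(hbr)) singles$hbr <- build_table(hbr, "hbr", meta)
  if (!is.null(eeg)) singles$eeg <- build_table(eeg, "eeg", meta)
  out <- singles
  if (!is.null(singles$hbo) && !is.null(singles$hbr))
    out$`hbo+hbr` <- combine_tables(singles$hbo, singles$hbr)
  if (!is.null(singles$eeg) && !is.null(singles$hbo))
    out$`eeg+hbo` <- combine_tables(singles$eeg, singles$hbo)
  if (!is.null(singles$eeg) && !is.null(singles$hbr))
    out$`eeg+hbr` <- combine_tables(singles$eeg, singles$hbr)
  out
}
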