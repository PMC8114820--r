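#' @section Noise model:
#' Both modalities carry 1/f ("pink") noise plus white Gaussian noise,
#' scaled by modality-specific base amplitudes and the global `noise_sd`
#' dial.  Physiological artifacts (cardiac pulsation, Mayer waves, ocular
#' artifacts) are deliberately not simulated.
#' @keywords internal
#' @name synthgen-internals
NULL

# 1/f noise, unit variance per row (Kellet 3-pole pinking filter)
pink_noise <- function(nch, n) {
  b <- c(0.049922035, -0.095993537, 0.050612699, -0.004408786)
  a <- c(1, -2.494956002, 2.017265875, -0.522189400)
  h <- as.numeric(signal::filter(b, a, c(1, numeric(2047))))
  g <- sqrt(sum(h^2))  # output sd for unit-variance white input
  out <- matrix(stats::rnorm(nch * n), nch, n)
  for (i in seq_len(nch))
    out[i, ] <- as.numeric(signal::filter(b, a, out[i, ])) / g
  out
}

od_channel_table <- function(cfg, p) {
  pairs <- rep(seq_len(cfg$n_nirs_channels), each = 2)
  wl <- rep(p$lambda, cfg$n_nirs_channels)
  data.frame(id = sprintf("P%02d_W%d", pairs, wl),
             modality = "od", wavelength = wl, pair_id = pairs,
             rho = p$rho, stringsAsFactors = FALSE)
}

eeg_channel_table <- function(cfg) {
  data.frame(id = sprintf("EEG%02d", seq_len(cfg$n_eeg_channels)),
             modality = "eeg", wavelength = NA_real_, pair_id = NA_integer_,
             rho = NA_real_, stringsAsFactors = FALSE)
}

# channel subsets carrying class-dependent signal
active_nirs_channels <- function(cfg) seq_len(ceiling(cfg$n_nirs_channels / 3))
affected_eeg_channels <- function(cfg) seq_len(ceiling(cfg$n_eeg_channels / 4))

# trial timing in seconds, plus labels and rests; assumes RNG already seeded
session_layout <- function(cfg) {
  n <- cfg$trials_per_session
  labels <- sample(rep(c(1L, 2L), length.out = n))
  rests <- stats::runif(n, cfg$inter_trial_rest[1], cfg$inter_trial_rest[2])
  onsets <- numeric(n)
  t <- cfg$pre_task_rest
  for (k in seq_len(n)) {
    onsets[k] <- t + cfg$baseline_duration
    t <- onsets[k] + cfg$task_duration + rests[k]
  }
  list(labels = labels, rests = rests, onsets = onsets, t_end = t)
}

# per-trial HbO amplitude draw (mM), label-independent; class scaling applied
# afterwards so identical RNG draws give identical class-1/class-2 trials
# when hemo_effect_size = 1
draw_hbo_amps <- function(cfg, label) {
  amps <- cfg$hbo_peak * stats::runif(cfg$n_nirs_channels, 0.8, 1.2)
  if (label == 2L)
    amps[active_nirs_channels(cfg)] <-
      amps[active_nirs_channels(cfg)] * cfg$hemo_effect_size
  amps
}

draw_alpha_amps <- function(cfg, label) {
  amps <- cfg$alpha_amp * stats::runif(cfg$n_eeg_channels, 0.8, 1.2)
  if (label == 2L)
    amps[affected_eeg_channels(cfg)] <-
      amps[affected_eeg_channels(cfg)] * cfg$erd_effect_size
  amps
}

# Hann-ramped on/off envelope for the task oscillation
task_envelope <- function(n, fs, ramp = 0.5) {
  env <- rep(1, n)
  nr <- min(round(ramp * fs), floor(n / 2))
  if (nr > 0) {
    w <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    env[seq_len(nr)] <- w
    env[seq(n - nr + 1, n)] <- rev(w)
  }
  env
}

#' Simulate one trial of two-wavelength optical-density data
#'
#' Generates the `[-baseline, task]` segment of a single trial for all fNIRS
#' channels: a per-channel double-gamma HbO response (positive) and a
#' smaller, negative HbR response starting at stimulus onset, scaled on the
#' active channel subset by `hemo_effect_size` for class 2, converted to
#' optical density with the forward modified Beer-Lambert map, plus 1/f and
#' white noise.  The ground-truth concentration series are returned
#' alongside the OD data so that inversion round trips can be tested.
#'
#' @param cfg A [sim_config].
#' @param label Trial class, 1 or 2.
#' @param seed Optional integer seed (the caller's RNG state is restored).
#' @param p [mbll_params] used for the forward map.
#' @return List with `od` (2*n_nirs_channels x samples), ground truth `hbo`
#'   and `hbr` (n_nirs_channels x samples, mM), `channels`, `fs`, `label`.
#' @export
simulate_trial_od <- function(cfg, label, seed = NULL, p = mbll_params()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!label %in% c(1L, 2L)) stop("label must be 1 or 2")
  old <- local_seed(seed); on.exit(restore_seed(old))

  fs <- cfg$fs_nirs_raw
  n <- round((cfg$baseline_duration + cfg$task_duration) * fs)
  n_base <- round(cfg$baseline_duration * fs)
  nch <- cfg$n_nirs_channels

  amps <- draw_hbo_amps(cfg, label)
  resp_len <- n - n_base
  h <- make_hrf(fs, cfg$hrf_duration)[seq_len(resp_len)]
  hbo <- matrix(0, nch, n)
  hbo[, seq(n_base + 1, n)] <- amps %o% h
  hbr <- cfg$hbr_ratio * hbo

  od <- mbll_forward(hbo, hbr, p)
  data <- matrix(0, 2 * nch, n)
  data[seq(1, 2 * nch, by = 2), ] <- od$od1
  data[seq(2, 2 * nch, by = 2), ] <- od$od2
  if (cfg$noise_sd > 0)
    data <- data + cfg$noise_sd *
      (cfg$od_pink_sd * pink_noise(2 * nch, n) +
       cfg$od_white_sd * matrix(stats::rnorm(2 * nch * n), 2 * nch, n))

  list(od = data, hbo = hbo, hbr = hbr,
       channels = od_channel_table(cfg, p), fs = fs, label = as.integer(label))
}

#' Simulate one trial of EEG data
#'
#' Generates the `[-baseline, task]` EEG segment of a single trial:
#' background 1/f plus white noise on every channel, and an alpha-band
#' (default 10 Hz) oscillation during the task window whose amplitude on the
#' affected channel subset is multiplied by `erd_effect_size` for class 2
#' (values below 1 emulate event-related desynchronization).
#'
#' @inheritParams simulate_trial_od
#' @return Matrix `n_eeg_channels x samples` in microvolts.
#' @export
simulate_trial_eeg <- function(cfg, label, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!label %in% c(1L, 2L)) stop("label must be 1 or 2")
  old <- local_seed(seed); on.exit(restore_seed(old))

  fs <- cfg$fs_eeg_raw
  n <- round((cfg$baseline_duration + cfg$task_duration) * fs)
  n_base <- round(cfg$baseline_duration * fs)
  nch <- cfg$n_eeg_channels

  amps <- draw_alpha_amps(cfg, label)
  phase <- stats::runif(1, 0, 2 * pi)
  task_idx <- seq(n_base + 1, n)
  tt <- (task_idx - task_idx[1]) / fs
  osc <- sin(2 * pi * cfg$alpha_freq * tt + phase) *
    task_envelope(length(tt), fs)

  data <- matrix(0, nch, n)
  data[, task_idx] <- amps %o% osc
  if (cfg$noise_sd > 0)
    data <- data + cfg$noise_sd *
      (cfg$eeg_pink_sd * pink_noise(nch, n) +
       cfg$eeg_white_sd * matrix(stats::rnorm(nch * n), nch, n))
  data
}

# deterministic per-(subject, session, stream) seed below 2^31
session_seed <- function(seed, subject, session, stream) {
  as.integer((abs(seed) * 97 + subject * 1009 + session * 101 + stream * 7) %%
               2147483629)
}

# one continuous subject-session recording pair
simulate_session <- function(cfg, subject, session,
                             modalities = c("od", "eeg"),
                             p = mbll_params()) {
  old <- local_seed(session_seed(cfg$seed, subject, session, 0L))
  on.exit(restore_seed(old))
  lay <- session_layout(cfg)
  out <- list()

  if ("od" %in% modalities) {
    set.seed(session_seed(cfg$seed, subject, session, 1L))
    fs <- cfg$fs_nirs_raw
    N <- round(lay$t_end * fs)
    nch <- cfg$n_nirs_channels
    hbo <- matrix(0, nch, N)
    hlen <- round(cfg$hrf_duration * fs)
    h <- make_hrf(fs, cfg$hrf_duration)
    onset_samp <- as.integer(round(lay$onsets * fs)) + 1L
    for (k in seq_along(lay$onsets)) {
      amps <- draw_hbo_amps(cfg, lay$labels[k])
      idx <- seq(onset_samp[k], min(onset_samp[k] + hlen - 1L, N))
      hbo[, idx] <- hbo[, idx] + amps %o% h[seq_along(idx)]
    }
    hbr <- cfg$hbr_ratio * hbo
    od <- mbll_forward(hbo, hbr, p)
    data <- matrix(0, 2 * nch, N)
    data[seq(1, 2 * nch, by = 2), ] <- od$od1
    data[seq(2, 2 * nch, by = 2), ] <- od$od2
    if (cfg$noise_sd > 0)
      data <- data + cfg$noise_sd *
        (cfg$od_pink_sd * pink_noise(2 * nch, N) +
         cfg$od_white_sd * matrix(stats::rnorm(2 * nch * N), 2 * nch, N))
    rec <- bci_recording(data, fs, od_channel_table(cfg, p),
                         data.frame(onset_sample = onset_samp,
                                    label = lay$labels),
                         subject, session, "od")
    rec$ground_truth <- list(hbo = hbo, hbr = hbr)
    attr(rec, "mbll") <- p
    out$od <- rec
  }

  if ("eeg" %in% modalities) {
    set.seed(session_seed(cfg$seed, subject, session, 2L))
    fs <- cfg$fs_eeg_raw
    N <- round(lay$t_end * fs)
    nch <- cfg$n_eeg_channels
    data <- matrix(0, nch, N)
    onset_samp <- as.integer(round(lay$onsets * fs)) + 1L
    n_task <- round(cfg$task_duration * fs)
    for (k in seq_along(lay$onsets)) {
      amps <- draw_alpha_amps(cfg, lay$labels[k])
      phase <- stats::runif(1, 0, 2 * pi)
      idx <- seq(onset_samp[k], min(onset_samp[k] + n_task - 1L, N))
      tt <- (seq_along(idx) - 1) / fs
      osc <- sin(2 * pi * cfg$alpha_freq * tt + phase) *
        task_envelope(length(idx), fs)
      data[, idx] <- data[, idx] + amps %o% osc
    }
    if (cfg$noise_sd > 0)
      data <- data + cfg$noise_sd *
        (cfg$eeg_pink_sd * pink_noise(nch, N) +
         cfg$eeg_white_sd * matrix(stats::rnorm(nch * N), nch, N))
    out$eeg <- bci_recording(data, fs, eeg_channel_table(cfg),
                             data.frame(onset_sample = onset_samp,
                                        label = lay$labels),
                             subject, session, "eeg")
  }
  out
}

#' Generate a full synthetic hybrid dataset
#'
#' Produces one paired EEG + optical-density continuous recording per subject
#' and session, with the trial layout (balanced shuffled labels, uniform
#' inter-trial rests) drawn deterministically from `cfg$seed`.  Marker counts
#' total `n_subjects * n_sessions * trials_per_session` (1740 with defaults)
#' with equal class counts.  The trial layout depends only on
#' `(seed, subject, session)`, so the EEG and OD arms can be generated
#' independently (e.g. on different machines) and still align trial for
#' trial.
#'
#' With default geometry the EEG arm is large (about 150 MB per session at
#' 1000 Hz); for feature extraction at scale prefer the streaming
#' [simulate_feature_tables()], which discards each session after reducing it
#' to feature rows.
#'
#' @param cfg A [sim_config].
#' @param modalities Subset of `c("od", "eeg")` to generate.
#' @param subjects Integer vector of subject indices (default all).
#' @param p [mbll_params] for the forward optical-density model.
#' @return List with one element per subject-session (named
#'   `"s<subject>_<session>"`), each a list with the requested `od` and/or
#'   `eeg` [bci_recording]s.  The `od` recording carries the ground-truth
#'   concentration matrices in `$ground_truth` and its forward-model
#'   parameters in `attr(, "mbll")`.
#' @export
generate_dataset <- function(cfg, modalities = c("od", "eeg"),
                             subjects = NULL, p = mbll_params()) {
  stopifnot(inherits(cfg, "sim_config"))
  modalities <- match.arg(modalities, c("od", "eeg"), several.ok = TRUE)
  if (is.null(subjects)) subjects <- seq_len(cfg$n_subjects)
  out <- list()
  for (s in subjects)
    for (ss in seq_len(cfg$n_sessions))
      out[[sprintf("s%d_%d", s, ss)]] <-
        simulate_session(cfg, s, ss, modalities, p)
  attr(out, "cfg") <- cfg
  out
}

#' Count stimulus markers in a generated dataset
#' @param dataset Result of [generate_dataset()].
#' @return Named integer vector: total markers and per-class counts.
#' @export
count_markers <- function(dataset) {
  labs <- unlist(lapply(dataset, function(sess) {
    rec <- sess[[1]]
    rec$markers$label
  }))
  c(total = length(labs),
    class1 = sum(labs == 1L), class2 = sum(labs == 2L))
}
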