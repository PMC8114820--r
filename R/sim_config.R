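#' Simulation configuration for the synthetic hybrid EEG+fNIRS generator
#'
#' Bundles the geometry and signal parameters of the simulated recording
#' protocol: a binary-task experiment (e.g. left- vs right-hand motor imagery,
#' or mental arithmetic vs rest) recorded simultaneously with multichannel EEG
#' and two-wavelength fNIRS.  The defaults reproduce the geometry of a
#' 29-subject open hybrid BCI protocol: 3 sessions of 20 trials each
#' (29 x 3 x 20 = 1740 trials in total), 36 fNIRS source-detector channels
#' sampled at 12.5 Hz, 32 EEG channels sampled at 1000 Hz, 10-s task epochs
#' preceded by a 2-s instruction period, and 15-17 s of rest between trials.
#'
#' Class structure is injected through two dials.  `hemo_effect_size`
#' multiplies the task-locked hemodynamic response amplitude on the "active"
#' fNIRS channel subset for class 2; `erd_effect_size` multiplies the
#' amplitude of the 8-13 Hz task oscillation on the affected EEG channel
#' subset for class 2 (values < 1 emulate event-related desynchronization).
#' A value of 1 in either dial makes the two classes statistically identical
#' in that modality.
#'
#' @param n_subjects,n_sessions,trials_per_session Protocol counts (>= 1).
#' @param n_nirs_channels Number of fNIRS source-detector pairs; each pair
#'   yields two optical-density channels (one per wavelength).
#' @param n_eeg_channels Number of EEG channels.
#' @param fs_nirs_raw,fs_eeg_raw Acquisition sampling rates in Hz.
#' @param task_duration Task epoch length in seconds.
#' @param baseline_duration Instruction/baseline period before stimulus onset
#'   in seconds.
#' @param inter_trial_rest Length-2 numeric: rest duration between trials is
#'   drawn uniformly from this range (seconds).
#' @param pre_task_rest Initial rest before the first trial (seconds).
#' @param hemo_effect_size Class-2 / class-1 hemodynamic amplitude ratio on
#'   active fNIRS channels (dimensionless).
#' @param erd_effect_size Class-2 / class-1 alpha-band amplitude ratio on
#'   affected EEG channels (dimensionless).
#' @param noise_sd Dimensionless multiplier on both modality noise models
#'   (1/f plus white Gaussian); 0 gives noise-free recordings.
#' @param seed Integer seed; the full dataset is a deterministic function of
#'   the configuration including this seed.
#' @param hbo_peak Peak single-trial oxyhemoglobin excursion in mM on active
#'   channels (class 1).
#' @param hbr_ratio Ratio of the deoxyhemoglobin to the oxyhemoglobin
#'   response (negative and smaller in magnitude).
#' @param alpha_amp Alpha-oscillation amplitude in microvolts (class 1).
#' @param alpha_freq Alpha-oscillation frequency in Hz.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_subjects = 2, n_sessions = 1, trials_per_session = 4)
#' cfg$n_subjects * cfg$n_sessions * cfg$trials_per_session
#' @export
sim_config <- function(n_subjects = 29,
                       n_sessions = 3,
                       trials_per_session = 20,
                       n_nirs_channels = 36,
                       n_eeg_channels = 32,
                       fs_nirs_raw = 12.5,
                       fs_eeg_raw = 1000,
                       task_duration = 10,
                       baseline_duration = 2,
                       inter_trial_rest = c(15, 17),
                       pre_task_rest = 60,
                       hemo_effect_size = 1.5,
                       erd_effect_size = 0.5,
                       noise_sd = 1,
                       seed = 42L,
                       hbo_peak = 0.005,
                       hbr_ratio = -0.35,
                       alpha_amp = 4,
                       alpha_freq = 10) {
  counts <- c(n_subjects = n_subjects, n_sessions = n_sessions,
              trials_per_session = trials_per_session,
              n_nirs_channels = n_nirs_channels,
              n_eeg_channels = n_eeg_channels)
  if (any(!is.finite(counts)) || any(counts < 1) || any(counts != round(counts)))
    stop("all counts must be integers >= 1")
  durs <- c(task_duration = task_duration,
            baseline_duration = baseline_duration,
            fs_nirs_raw = fs_nirs_raw, fs_eeg_raw = fs_eeg_raw)
  if (any(!is.finite(durs)) || any(durs <= 0))
    stop("durations and sampling rates must be > 0")
  if (length(inter_trial_rest) != 2 || any(inter_trial_rest <= 0) ||
      inter_trial_rest[1] > inter_trial_rest[2])
    stop("inter_trial_rest must be an increasing positive range")
  if (pre_task_rest <= 0) stop("pre_task_rest must be > 0")
  if (hemo_effect_size < 0 || erd_effect_size < 0 || noise_sd < 0)
    stop("effect sizes and noise_sd must be >= 0")

  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_sessions = as.integer(n_sessions),
    trials_per_session = as.integer(trials_per_session),
    n_nirs_channels = as.integer(n_nirs_channels),
    n_eeg_channels = as.integer(n_eeg_channels),
    fs_nirs_raw = fs_nirs_raw,
    fs_eeg_raw = fs_eeg_raw,
    task_duration = task_duration,
    baseline_duration = baseline_duration,
    inter_trial_rest = as.numeric(inter_trial_rest),
    pre_task_rest = pre_task_rest,
    hemo_effect_size = hemo_effect_size,
    erd_effect_size = erd_effect_size,
    noise_sd = noise_sd,
    seed = as.integer(seed),
    hbo_peak = hbo_peak,
    hbr_ratio = hbr_ratio,
    alpha_amp = alpha_amp,
    alpha_freq = alpha_freq,
    # modality-specific base noise scales multiplied by noise_sd
    od_pink_sd = 0.02, od_white_sd = 0.005,   # optical-density units
    eeg_pink_sd = 10,  eeg_white_sd = 2,      # microvolts
    hrf_duration = 20                          # seconds of response modeled
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d subjects x %d sessions x %d trials = %d observations\n",
              x$n_subjects, x$n_sessions, x$trials_per_session,
              x$n_subjects * x$n_sessions * x$trials_per_session))
  cat(sprintf("  fNIRS: %d channels @ %g Hz | EEG: %d channels @ %g Hz\n",
              x$n_nirs_channels, x$fs_nirs_raw,
              x$n_eeg_channels, x$fs_eeg_raw))
  cat(sprintf("  epoch: [%g, %g] s; rest %g-%g s; effects hemo=%g erd=%g; noise_sd=%g; seed=%d\n",
              -x$baseline_duration, x$task_duration,
              x$inter_trial_rest[1], x$inter_trial_rest[2],
              x$hemo_effect_size, x$erd_effect_size, x$noise_sd, x$seed))
  invisible(x)
}

# restore the caller's RNG state on exit; set a local seed if given
local_seed <- function(seed) {
  if (is.null(seed)) return(invisible(NULL))
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  env <- globalenv()
  if (!is.null(old)) assign(".Random.seed", old, envir = env)
  invisible(NULL)
}
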