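#' Configuration for synthetic EEG generation
#'
#' Describes a trial-structured EEG recording session with a planted,
#' class-dependent band-power effect: background activity is 1/f^a Gaussian
#' noise plus low-amplitude narrowband oscillations in the five canonical
#' bands; for trials of the target class, the oscillation amplitude in
#' `effect_band` on `effect_channels` is multiplied by `effect_gain`.
#'
#' Two presets mirror the structure of the public emotion datasets this
#' package targets: `preset = "deap"` gives 32 channels at 128 Hz, 40 trials
#' of 63 s with a 3 s pre-stimulus baseline and binary labels;
#' `preset = "seed"` gives 62 channels at 200 Hz, 15 trials of ~4 min with
#' 3-class labels and no baseline.
#'
#' @param preset "deap", "seed", or NULL for a fully custom configuration.
#' @param n_subjects Number of subjects the configuration describes.
#' @param n_trials Trials per subject.
#' @param n_channels 32 or 62 for the shipped montages (any count with a
#'   custom `channel_names`).
#' @param fs Sampling rate in Hz; must exceed twice the upper gamma edge.
#' @param trial_len_s Trial length in seconds (including baseline).
#' @param baseline_len_s Leading pre-stimulus seconds (0 for SEED-like).
#' @param n_classes 2 or 3.
#' @param target_class Class code (1-based) receiving the planted effect.
#' @param effect_channels Channel names carrying the planted effect.
#' @param effect_band One of "delta","theta","alpha","beta","gamma".
#' @param effect_gain Multiplier (>= 1) on the narrowband amplitude for
#'   target-class trials.
#' @param noise_exponent Spectral slope a of the 1/f^a background.
#' @param osc_amplitude Baseline amplitude of each narrowband oscillation,
#'   in units of the background noise standard deviation.
#' @param channel_names Optional explicit channel name vector.
#' @param seed Integer seed; the generator is a pure function of the
#'   configuration including this seed.
#' @return A `synth_config` list.
#' @export
#' @examples
#' cfg <- synth_config("deap", seed = 1)
#' cfg$fs * cfg$trial_len_s   # samples per trial: 8064
synth_config <- function(preset = NULL,
                         n_subjects = 1L,
                         n_trials = NULL,
                         n_channels = NULL,
                         fs = NULL,
                         trial_len_s = NULL,
                         baseline_len_s = NULL,
                         n_classes = NULL,
                         target_class = 1L,
                         effect_channels = NULL,
                         effect_band = "alpha",
                         effect_gain = 3,
                         noise_exponent = 1,
                         osc_amplitude = 0.6,
                         channel_names = NULL,
                         seed = 1L) {
  defaults <- list(
    deap = list(n_trials = 40L, n_channels = 32L, fs = 128, trial_len_s = 63,
                baseline_len_s = 3, n_classes = 2L,
                effect_channels = c("F3", "F4", "T7", "T8")),
    seed = list(n_trials = 15L, n_channels = 62L, fs = 200, trial_len_s = 235,
                baseline_len_s = 0, n_classes = 3L,
                effect_channels = c("F3", "F4", "T7", "T8"))
  )
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("deap", "seed"))
    d <- defaults[[preset]]
    if (is.null(n_trials)) n_trials <- d$n_trials
    if (is.null(n_channels)) n_channels <- d$n_channels
    if (is.null(fs)) fs <- d$fs
    if (is.null(trial_len_s)) trial_len_s <- d$trial_len_s
    if (is.null(baseline_len_s)) baseline_len_s <- d$baseline_len_s
    if (is.null(n_classes)) n_classes <- d$n_classes
    if (is.null(effect_channels)) effect_channels <- d$effect_channels
  }
  if (is.null(fs) || fs <= 0) stop("`fs` must be a positive sampling rate", call. = FALSE)
  if (fs < 100) stop("`fs` must be at least 100 Hz (2 x upper gamma edge)", call. = FALSE)
  if (is.null(channel_names)) {
    if (n_channels == 32L) {
      channel_names <- montage_grid("deap32")$channels
    } else if (n_channels == 62L) {
      channel_names <- montage_grid("seed62")$channels
    } else {
      channel_names <- sprintf("CH%02d", seq_len(n_channels))
    }
  }
  if (length(channel_names) != n_channels)
    stop("`channel_names` length must equal `n_channels`", call. = FALSE)
  bad <- setdiff(effect_channels, channel_names)
  if (length(bad) > 0)
    stop("effect_channels not in the montage: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (effect_gain < 1) stop("`effect_gain` must be >= 1", call. = FALSE)
  effect_band <- match.arg(effect_band, names(eeg_bands()))
  if (abs(trial_len_s * fs - round(trial_len_s * fs)) > 1e-9)
    stop("trial_len_s * fs must be an integer sample count", call. = FALSE)
  if (!target_class %in% seq_len(n_classes))
    stop("`target_class` must be in 1..n_classes", call. = FALSE)
  structure(list(
    preset = preset %||% "custom",
    n_subjects = as.integer(n_subjects), n_trials = as.integer(n_trials),
    n_channels = as.integer(n_channels), fs = fs,
    trial_len_s = trial_len_s, baseline_len_s = baseline_len_s,
    n_classes = as.integer(n_classes), target_class = as.integer(target_class),
    effect_channels = effect_channels, effect_band = effect_band,
    effect_gain = effect_gain, noise_exponent = noise_exponent,
    osc_amplitude = osc_amplitude,
    channel_names = channel_names, seed = as.integer(seed)
  ), class = "synth_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical EEG frequency bands
#'
#' Delta (1-4), theta (4-8), alpha (8-13), beta (13-31), gamma (31-50) Hz.
#'
#' @return Named list of `c(low, high)` edges in Hz.
#' @export
eeg_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 31), gamma = c(31, 50))
}

# Seed for one subject's private random stream, derived from (seed, subject).
# Kept below 2^31 so it is a valid R integer.
subject_seed <- function(seed, subject_id) {
  s <- (as.numeric(seed) %% 1000003) * 1009 + 7919 * as.numeric(subject_id)
  as.integer(s %% 2147483647)
}

#' Generate a synthetic EEG recording for one subject
#'
#' Each trial is an independent realization of 1/f^a Gaussian noise (spectral
#' shaping in the frequency domain) plus one sinusoidal oscillation per band
#' with random in-band frequency and phase. Trials of
#' `cfg$target_class` have the `effect_band` oscillation amplitude multiplied
#' by `cfg$effect_gain` on `cfg$effect_channels`. Labels are a balanced,
#' seeded shuffle over the classes. Identical configuration (including seed)
#' gives bit-identical output; each subject has its own derived stream.
#'
#' @param cfg A [synth_config()].
#' @param subject_id Subject index (1-based).
#' @return A `raw_recording`: list with `data` (trials x channels x samples),
#'   `fs`, `channel_names`, `labels` (per-trial integer codes, 1-based),
#'   `baseline_samples`, `subject_id`.
#' @export
generate_recording <- function(cfg, subject_id = 1L) {
  stopifnot(inherits(cfg, "synth_config"))
  n_samp <- as.integer(round(cfg$trial_len_s * cfg$fs))
  C <- cfg$n_channels
  bands <- eeg_bands()
  eff_idx <- match(cfg$effect_channels, cfg$channel_names)

  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(subject_seed(cfg$seed, subject_id))

  # balanced labels, shuffled
  labels <- rep_len(seq_len(cfg$n_classes), cfg$n_trials)
  labels <- sample(labels)

  data <- array(0, dim = c(cfg$n_trials, C, n_samp))
  t_axis <- seq_len(n_samp) / cfg$fs
  for (tr in seq_len(cfg$n_trials)) {
    noise <- one_over_f_noise(C, n_samp, cfg$fs, cfg$noise_exponent)
    x <- noise
    for (b in names(bands)) {
      lo <- bands[[b]][1]; hi <- bands[[b]][2]
      f0 <- stats::runif(1, lo + 0.1 * (hi - lo), hi - 0.1 * (hi - lo))
      phase <- stats::runif(C, 0, 2 * pi)
      amp <- rep(cfg$osc_amplitude, C) * stats::runif(C, 0.9, 1.1)
      if (b == cfg$effect_band && labels[tr] == cfg$target_class)
        amp[eff_idx] <- amp[eff_idx] * cfg$effect_gain
      x <- x + amp * sin(outer(phase, 2 * pi * f0 * t_axis, `+`))
    }
    data[tr, , ] <- x
  }
  structure(list(
    subject_id = as.integer(subject_id), data = data, fs = cfg$fs,
    channel_names = cfg$channel_names, labels = labels,
    baseline_samples = as.integer(round(cfg$baseline_len_s * cfg$fs)),
    n_classes = cfg$n_classes
  ), class = "raw_recording")
}

# C x n matrix of Gaussian noise with a 1/f^a amplitude spectrum, unit sd.
one_over_f_noise <- function(C, n, fs, a) {
  freqs <- seq(0, fs / 2, length.out = floor(n / 2) + 1)
  shape <- c(0, freqs[-1]^(-a / 2))      # kill DC
  out <- matrix(0, C, n)
  for (ch in seq_len(C)) {
    spec <- stats::fft(stats::rnorm(n))
    # apply symmetric shaping: positive freqs then mirrored tail
    full <- c(shape, rev(shape[2:(n - length(shape) + 1)]))
    x <- Re(stats::fft(spec * full, inverse = TRUE)) / n
    out[ch, ] <- x / stats::sd(x)
  }
  out
}

#' @export
print.raw_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<raw_recording> subject %d: %d trials x %d channels x %d samples @ %g Hz\n",
              x$subject_id, d[1], d[2], d[3], x$fs))
  cat(sprintf("  labels: %s; baseline: %d samples\n",
              paste(table(x$labels), collapse = "/"), x$baseline_samples))
  invisible(x)
}

#' Remove the pre-stimulus baseline from every trial
#'
#' Drops the leading `baseline_samples` samples of each trial (e.g. the 3 s
#' pre-stimulus segment of a 63 s DEAP-style trial) and resets
#' `baseline_samples` to 0. Labels are unchanged.
#'
#' @param rec A `raw_recording`.
#' @return The trimmed `raw_recording`.
#' @export
split_baseline <- function(rec) {
  stopifnot(inherits(rec, "raw_recording"))
  nb <- rec$baseline_samples
  n_samp <- dim(rec$data)[3]
  if (nb > n_samp)
    stop("baseline_samples (", nb, ") exceeds trial length (", n_samp, ")",
         call. = FALSE)
  if (nb > 0) {
    rec$data <- rec$data[, , (nb + 1):n_samp, drop = FALSE]
    rec$baseline_samples <- 0L
  }
  rec
}

#' Save / load a recording container
#'
#' The on-disk layout is R serialization (RDS) of the `raw_recording` list;
#' [export_recording_csv()] provides a plain-text interchange format (one row
#' per trial x channel, samples as columns) for use outside R.
#'
#' @param rec A `raw_recording`.
#' @param path File path.
#' @return `read_recording` returns the `raw_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  saveRDS(rec, path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  rec <- readRDS(path)
  if (!inherits(rec, "raw_recording")) stop("not a recording file", call. = FALSE)
  rec
}

#' @rdname write_recording
#' @export
export_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  d <- dim(rec$data)
  m <- matrix(aperm(rec$data, c(3, 2, 1)), nrow = d[1] * d[2], byrow = TRUE)
  df <- data.frame(
    trial = rep(seq_len(d[1]), each = d[2]),
    channel = rep(rec$channel_names, d[1]),
    label = rep(rec$labels, each = d[2])
  )
  utils::write.csv(cbind(df, m), path, row.names = FALSE)
  invisible(path)
}
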