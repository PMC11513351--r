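#' Butterworth filterbank over the canonical EEG bands
#'
#' Third-order Butterworth bandpass filters for delta (1-4 Hz), theta (4-8),
#' alpha (8-13), beta (13-31) and gamma (31-50). Applied zero-phase
#' (forward-backward, effective order 6, no phase distortion) by default;
#' `zero_phase = FALSE` gives the causal single-pass filter.
#'
#' @param bands Named list of `c(low, high)` edges in Hz; defaults to
#'   [eeg_bands()].
#' @param order Filter order (default 3).
#' @param zero_phase Apply forward-backward filtering (default TRUE).
#' @return A `filter_bank` object.
#' @export
filter_bank <- function(bands = eeg_bands(), order = 3L, zero_phase = TRUE) {
  for (b in names(bands)) {
    e <- bands[[b]]
    if (length(e) != 2 || e[1] <= 0 || e[2] <= e[1])
      stop("band edges must be strictly increasing and positive: ", b,
           call. = FALSE)
  }
  structure(list(bands = bands, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_bank")
}

# design the band filters for a given sampling rate
design_filters <- function(fb, fs) {
  hi_max <- max(vapply(fb$bands, `[`, numeric(1), 2))
  if (fs < 2 * hi_max)
    stop("sampling rate ", fs, " Hz is below twice the upper band edge (",
         hi_max, " Hz)", call. = FALSE)
  lapply(fb$bands, function(e) signal::butter(fb$order, e / (fs / 2), type = "pass"))
}

# filter one trial (channels x samples matrix) into bands x channels x samples
filter_trial <- function(x, filts, zero_phase) {
  B <- length(filts); C <- nrow(x); S <- ncol(x)
  out <- array(0, dim = c(B, C, S))
  for (b in seq_len(B)) {
    for (ch in seq_len(C)) {
      out[b, ch, ] <- if (zero_phase) {
        signal::filtfilt(filts[[b]], x[ch, ])
      } else {
        as.numeric(signal::filter(filts[[b]], x[ch, ]))
      }
    }
  }
  out
}

#' Decompose a recording into frequency-band copies
#'
#' Applies the filterbank to every channel of every trial, returning one
#' filtered copy of the signal per band with unchanged length.
#'
#' @param rec A `raw_recording`.
#' @param fb A [filter_bank()].
#' @return Array trials x bands x channels x samples, with band and channel
#'   dimnames.
#' @export
bandpass_decompose <- function(rec, fb = filter_bank()) {
  stopifnot(inherits(rec, "raw_recording"), inherits(fb, "filter_bank"))
  if (anyNA(rec$data) || !all(is.finite(rec$data)))
    stop("recording contains non-finite samples", call. = FALSE)
  filts <- design_filters(fb, rec$fs)
  d <- dim(rec$data)
  out <- array(0, dim = c(d[1], length(filts), d[2], d[3]),
               dimnames = list(NULL, names(fb$bands), rec$channel_names, NULL))
  for (tr in seq_len(d[1]))
    out[tr, , , ] <- filter_trial(matrix(rec$data[tr, , ], d[2], d[3]),
                                  filts, fb$zero_phase)
  out
}

#' Segmentation plan: windows of T seconds, patches of 1 s
#'
#' Trials are cut into non-overlapping windows of `window_len_s` seconds
#' (8 for DEAP-like data, 11 for SEED-like); each window is split into
#' `window_len_s / patch_len_s` one-second patches. A trailing remainder
#' shorter than one window is discarded.
#'
#' @param window_len_s Window length in seconds.
#' @param patch_len_s Patch length in seconds (default 1).
#' @return A `segmentation_plan` object.
#' @export
segmentation_plan <- function(window_len_s, patch_len_s = 1) {
  if (window_len_s <= 0 || patch_len_s <= 0)
    stop("window and patch lengths must be positive", call. = FALSE)
  k <- window_len_s / patch_len_s
  if (abs(k - round(k)) > 1e-9)
    stop("window_len_s must be an integer multiple of patch_len_s",
         call. = FALSE)
  structure(list(window_len_s = window_len_s, patch_len_s = patch_len_s,
                 patches_per_window = as.integer(round(k)),
                 remainder_policy = "discard"),
            class = "segmentation_plan")
}

#' Segment a banded recording into windowed patches
#'
#' @param banded Array trials x bands x channels x samples from
#'   [bandpass_decompose()].
#' @param plan A [segmentation_plan()].
#' @param fs Sampling rate in Hz.
#' @return Array n_windows_total x T x bands x channels x patch_samples; the
#'   attribute `window_trial` maps each window to its source trial.
#' @export
segment_patches <- function(banded, plan, fs) {
  d <- dim(banded)  # trials x B x C x S
  usable_s <- d[4] / fs
  n_win <- floor(usable_s / plan$window_len_s)
  if (n_win < 1)
    stop("trial 1 is shorter than one window (", usable_s, " s < ",
         plan$window_len_s, " s)", call. = FALSE)
  Tn <- plan$patches_per_window
  ps <- as.integer(round(plan$patch_len_s * fs))
  out <- array(0, dim = c(d[1] * n_win, Tn, d[2], d[3], ps))
  for (tr in seq_len(d[1])) {
    for (w in seq_len(n_win)) {
      for (p in seq_len(Tn)) {
        s0 <- ((w - 1) * Tn + (p - 1)) * ps
        out[(tr - 1) * n_win + w, p, , , ] <- banded[tr, , , (s0 + 1):(s0 + ps)]
      }
    }
  }
  attr(out, "window_trial") <- rep(seq_len(d[1]), each = n_win)
  out
}

#' Differential entropy of a signal patch
#'
#' For a band-limited, approximately Gaussian patch the differential entropy
#' is `0.5 * log(2 * pi * e * sigma^2)` nats, where `sigma^2` is by default
#' the population variance of the samples (divide by n; `unbiased = TRUE`
#' divides by n - 1).
#'
#' @param x Numeric vector with at least 2 samples.
#' @param unbiased Use the n-1 variance estimator (default FALSE).
#' @return DE in nats.
#' @export
#' @examples
#' de_feature(rep(c(-1, 1), 32))  # variance 1: 0.5 * log(2 * pi * e)
de_feature <- function(x, unbiased = FALSE) {
  if (length(x) < 2) stop("patch must have at least 2 samples", call. = FALSE)
  v <- if (unbiased) stats::var(x) else mean((x - mean(x))^2)
  if (!is.finite(v) || v <= 0)
    stop("degenerate patch: zero or non-finite variance", call. = FALSE)
  0.5 * log(2 * pi * exp(1) * v)
}

#' Extract the per-patch differential-entropy feature tensor
#'
#' Composition of the preprocessing chain: baseline handling, band
#' decomposition, segmentation into T-second windows of 1-s patches, and DE
#' extraction per patch, band and channel. Each window inherits its trial's
#' label.
#'
#' @param rec A `raw_recording`.
#' @param fb A [filter_bank()].
#' @param plan A [segmentation_plan()].
#' @param baseline "drop" (remove the pre-stimulus segment, the default),
#'   "none" (keep it in the usable signal), or "subtract_mean" (drop it and
#'   subtract the mean per-second baseline DE from every stimulation patch).
#' @param unbiased Variance estimator switch passed to the DE computation.
#' @return A `patch_tensor`: `values` (n x T x B x C array of DE in nats),
#'   `band_names`, `channel_names`, `window_labels`, `window_trial`,
#'   `subject_id`.
#' @export
build_patch_tensor <- function(rec, fb = filter_bank(),
                               plan = segmentation_plan(8),
                               baseline = c("drop", "none", "subtract_mean"),
                               unbiased = FALSE) {
  stopifnot(inherits(rec, "raw_recording"))
  baseline <- match.arg(baseline)
  if (anyNA(rec$data) || !all(is.finite(rec$data)))
    stop("recording contains non-finite samples", call. = FALSE)
  filts <- design_filters(fb, rec$fs)
  nb <- rec$baseline_samples
  d <- dim(rec$data)
  ps <- as.integer(round(plan$patch_len_s * rec$fs))
  Tn <- plan$patches_per_window
  keep <- if (baseline == "none") seq_len(d[3]) else (nb + 1):d[3]
  usable_s <- length(keep) / rec$fs
  n_win <- floor(usable_s / plan$window_len_s)
  if (n_win < 1)
    stop("trials are shorter than one window (", usable_s, " s usable < ",
         plan$window_len_s, " s)", call. = FALSE)
  B <- length(fb$bands); C <- d[2]
  values <- array(0, dim = c(d[1] * n_win, Tn, B, C))
  for (tr in seq_len(d[1])) {
    banded <- filter_trial(matrix(rec$data[tr, , ], d[2], d[3]),
                           filts, fb$zero_phase)
    base_de <- NULL
    if (baseline == "subtract_mean" && nb >= ps) {
      n_bp <- floor(nb / ps)
      bd <- array(banded[, , seq_len(n_bp * ps)], dim = c(B, C, ps, n_bp))
      base_de <- apply(bd, c(1, 2), function(seg) {
        mean(de_cols(matrix(seg, nrow = ps), unbiased))
      })
    }
    sig <- banded[, , keep, drop = FALSE]
    n_pat <- n_win * Tn
    seg <- array(sig[, , seq_len(n_pat * ps)], dim = c(B, C, ps, n_pat))
    # DE over the sample axis, vectorized per (band, channel)
    for (b in seq_len(B)) for (ch in seq_len(C)) {
      de <- de_cols(matrix(seg[b, ch, , ], nrow = ps), unbiased)
      if (!is.null(base_de)) de <- de - base_de[b, ch]
      values[(tr - 1) * n_win + seq_len(n_win), , b, ch] <-
        matrix(de, nrow = n_win, ncol = Tn, byrow = TRUE)
    }
  }
  structure(list(
    values = values,
    band_names = names(fb$bands),
    channel_names = rec$channel_names,
    window_labels = rep(rec$labels, each = n_win),
    window_trial = rep(seq_along(rec$labels), each = n_win),
    subject_id = rec$subject_id,
    n_classes = rec$n_classes %||% length(unique(rec$labels))
  ), class = "patch_tensor")
}

# DE for every column of a matrix; population variance by default
de_cols <- function(m, unbiased = FALSE) {
  v <- colMeans(m^2) - colMeans(m)^2
  if (unbiased) v <- v * nrow(m) / (nrow(m) - 1)
  if (any(v <= 0 | !is.finite(v)))
    stop("degenerate patch: zero or non-finite variance", call. = FALSE)
  0.5 * log(2 * pi * exp(1) * v)
}

#' @export
print.patch_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<patch_tensor> %d windows x %d patches x %d bands x %d channels (DE, nats)\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Binarize continuous affective ratings at a threshold
#'
#' DEAP-style 1-9 ratings become class 2 ("high") when strictly above the
#' threshold and class 1 ("low") otherwise; 5 is the conventional cut.
#'
#' @param ratings Numeric vector.
#' @param threshold Cut point (default 5); ratings equal to it are "low".
#' @return Integer vector of class codes (1 = low, 2 = high).
#' @export
threshold_ratings <- function(ratings, threshold = 5) {
  as.integer(ratings > threshold) + 1L
}
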