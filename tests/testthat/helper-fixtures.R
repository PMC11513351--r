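# Shared fixtures, built in code and memoized across test files.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# a small DEAP-like subject: 10 trials of 19 s (16 s usable -> 2 windows
# each), strong planted alpha effect
small_subject_grid <- function() {
  fixture("small_subject_grid", function() {
    cfg <- synth_config("deap", n_trials = 10, trial_len_s = 19,
                        baseline_len_s = 3, effect_gain = 3, seed = 42)
    rec <- split_baseline(generate_recording(cfg))
    pt <- build_patch_tensor(rec, plan = segmentation_plan(8))
    gt <- map_to_grid(pt, montage_grid("deap32"))
    list(cfg = cfg, rec = rec, pt = pt, gt = gt)
  })
}

# hand-rolled recording container for filter tests
make_recording <- function(data, fs, channel_names = NULL, labels = NULL,
                           baseline_samples = 0L) {
  d <- dim(data)
  structure(list(
    subject_id = 1L, data = data, fs = fs,
    channel_names = channel_names %||% sprintf("CH%02d", seq_len(d[2])),
    labels = labels %||% rep(1L, d[1]),
    baseline_samples = as.integer(baseline_samples),
    n_classes = length(unique(labels %||% 1L))
  ), class = "raw_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent FFT periodogram band power (fraction of total power in band)
fft_band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  freqs <- (seq_len(n) - 1) * fs / n
  half <- freqs <= fs / 2
  sum(p[half & freqs >= lo & freqs <= hi]) / sum(p[half & freqs > 0])
}

# Welch-style band power estimate in absolute units (mean periodogram power)
welch_band_power <- function(x, fs, lo, hi, seg = 256) {
  n <- length(x)
  starts <- seq(1, n - seg + 1, by = seg %/% 2)
  ps <- sapply(starts, function(s) {
    y <- x[s:(s + seg - 1)] * 0.5 * (1 - cos(2 * pi * seq_len(seg) / seg))
    Mod(stats::fft(y))^2 / seg
  })
  p <- rowMeans(ps)
  freqs <- (seq_len(seg) - 1) * fs / seg
  mean(p[freqs >= lo & freqs <= hi & freqs <= fs / 2])
}

# rank-based AUC of score separating two classes
rank_auc <- function(score, is_pos) {
  r <- rank(score)
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# brute-force minimization of the attention energy over (w, b) for one
# position; independent of the closed-form path
numeric_min_energy <- function(fm, pos, lambda) {
  t_val <- fm[pos[1], pos[2]]
  others <- fm[-((pos[2] - 1) * nrow(fm) + pos[1])]
  energy <- function(par) {
    w <- par[1]; b <- par[2]
    mean((-1 - (w * others + b))^2) + (1 - (w * t_val + b))^2 + lambda * w^2
  }
  op <- stats::optim(c(0, 0), energy, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-14))
  list(value = op$value, par = op$par, energy = energy)
}

# naive per-head multi-head attention following the defining equations,
# for one window (Z: T1 x d)
naive_mha_window <- function(Z, cfg, w) {
  H <- cfg$n_heads; dk <- cfg$d_k
  Q <- sweep(Z %*% w$Wq, 2, w$bq, `+`)
  K <- sweep(Z %*% w$Wk, 2, w$bk, `+`)
  V <- sweep(Z %*% w$Wv, 2, w$bv, `+`)
  heads <- lapply(seq_len(H), function(h) {
    cols <- (h - 1) * dk + seq_len(dk)
    S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dk)
    A <- t(apply(S, 1, function(r) {e <- exp(r - max(r)); e / sum(e)}))
    if (nrow(S) == 1) A <- matrix(1, 1, 1)
    A %*% V[, cols, drop = FALSE]
  })
  cat_heads <- do.call(cbind, heads)
  sweep(cat_heads %*% w$Wo, 2, w$bo, `+`)
}
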