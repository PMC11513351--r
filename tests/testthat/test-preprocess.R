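test_that("a 10 Hz sinusoid lands in the alpha band copy", {
  fs <- 128
  x <- sin(2 * pi * 10 * seq_len(4 * fs) / fs)
  rec <- make_recording(array(x, dim = c(1, 1, length(x))), fs)
  banded <- bandpass_decompose(rec, filter_bank())
  pow <- function(band) sum(banded[1, band, 1, ]^2)
  total <- sum(x^2)
  expect_gt(pow("alpha") / total, 0.9)
  expect_lt(pow("delta") / total, 0.01)
  # oracle cross-check: the alpha copy's own spectrum still peaks at 10 Hz
  expect_gt(fft_band_power(banded[1, "alpha", 1, ], fs, 8, 13), 0.95)
})

test_that("filtering is linear: zero in, zero out", {
  rec <- make_recording(array(0, dim = c(1, 2, 256)), 128)
  banded <- bandpass_decompose(rec)
  expect_true(all(banded == 0))
})

test_that("sampling rates below the gamma Nyquist are rejected", {
  rec <- make_recording(array(rnorm(160), dim = c(1, 1, 160)), 80)
  expect_error(bandpass_decompose(rec), "twice the upper band edge")
  rec2 <- make_recording(array(c(NA, rnorm(255)), dim = c(1, 1, 256)), 128)
  expect_error(bandpass_decompose(rec2), "non-finite")
})

test_that("band energies of white noise do not exceed total energy", {
  set.seed(5)
  x <- rnorm(1024)
  rec <- make_recording(array(x, dim = c(1, 1, 1024)), 128)
  banded <- bandpass_decompose(rec)
  band_pow <- sum(apply(banded[1, , 1, ], 1, function(y) sum(y^2)))
  expect_lt(band_pow, sum(x^2) * 1.05)  # small transition-band leakage only
})

test_that("segmentation gives floor(usable / T) windows of T one-second patches", {
  # 60 s usable at 8 s windows -> 7 windows, 4 s discarded
  fs <- 32
  banded <- array(rnorm(2 * 5 * 3 * 60 * fs), dim = c(2, 5, 3, 60 * fs))
  seg <- segment_patches(banded, segmentation_plan(8), fs)
  expect_equal(dim(seg), c(2 * 7, 8, 5, 3, fs))
  expect_equal(attr(seg, "window_trial"), rep(1:2, each = 7))
  # 11-s windows hold 11 patches
  expect_equal(segmentation_plan(11)$patches_per_window, 11L)
  # a 7 s trial cannot fill an 8 s window
  short <- array(rnorm(1 * 5 * 3 * 7 * fs), dim = c(1, 5, 3, 7 * fs))
  expect_error(segment_patches(short, segmentation_plan(8), fs), "shorter than one window")
  # patches tile the used span exactly: reassemble and compare
  expect_equal(as.numeric(t(seg[1, , 1, 1, ])),
               banded[1, 1, 1, 1:(8 * fs)])
})

test_that("differential entropy matches its closed form", {
  # alternating -1/+1 has population variance exactly 1
  x <- rep(c(-1, 1), 32)
  expect_equal(de_feature(x), 0.5 * log(2 * pi * exp(1)), tolerance = 1e-12)
  # doubling the amplitude adds exactly ln 2
  set.seed(2)
  y <- rnorm(128)
  expect_equal(de_feature(2 * y) - de_feature(y), log(2), tolerance = 1e-12)
  # against a direct evaluation with the same variance estimator
  v <- mean((y - mean(y))^2)
  expect_equal(de_feature(y), 0.5 * log(2 * pi * exp(1) * v), tolerance = 1e-12)
  expect_equal(de_feature(y), 0.5 * log(2 * pi * exp(1)), tolerance = 0.2)
  vu <- stats::var(y)
  expect_equal(de_feature(y, unbiased = TRUE),
               0.5 * log(2 * pi * exp(1) * vu), tolerance = 1e-12)
  expect_error(de_feature(rep(1, 10)), "degenerate")
  expect_error(de_feature(1), "at least 2")
})

test_that("patch tensor has the composed shape and aligned labels", {
  fx <- small_subject_grid()
  pt <- fx$pt
  # 10 trials x 16 s usable -> 2 windows each
  expect_equal(dim(pt$values), c(20, 8, 5, 32))
  expect_true(all(is.finite(pt$values)))
  # every window carries its source trial's label
  expect_equal(pt$window_labels, fx$rec$labels[pt$window_trial])
  # total patches match the segmentation count
  expect_equal(sum(table(pt$window_trial)) * dim(pt$values)[2], 10 * 2 * 8)
})

test_that("target-class windows show higher effect-band DE on planted channels", {
  fx <- small_subject_grid()
  pt <- fx$pt
  b <- match("alpha", pt$band_names)
  eff <- match(fx$cfg$effect_channels, pt$channel_names)
  de_eff <- apply(pt$values[, , b, eff, drop = FALSE], 1, mean)
  tgt <- pt$window_labels == fx$cfg$target_class
  expect_gt(mean(de_eff[tgt]), mean(de_eff[!tgt]) + 0.5)
})

test_that("SEED-like segmentation yields 21 windows per 235 s trial", {
  plan <- segmentation_plan(11)
  expect_equal(floor(235 / plan$window_len_s), 21)
  cfg <- synth_config("seed", n_trials = 1, trial_len_s = 45, seed = 2)
  rec <- generate_recording(cfg)
  pt <- build_patch_tensor(rec, plan = plan)
  expect_equal(dim(pt$values), c(4, 11, 5, 62))
})

test_that("rating thresholds split at strictly-above-5", {
  expect_equal(threshold_ratings(c(1, 5, 5.1, 9)), c(1L, 1L, 2L, 2L))
})

test_that("baseline DE subtraction changes features but not shapes", {
  fx <- small_subject_grid()
  cfg <- fx$cfg
  rec <- generate_recording(cfg)  # with baseline attached
  pt_drop <- build_patch_tensor(rec, plan = segmentation_plan(8))
  pt_sub <- build_patch_tensor(rec, plan = segmentation_plan(8),
                               baseline = "subtract_mean")
  expect_equal(dim(pt_sub$values), dim(pt_drop$values))
  expect_false(isTRUE(all.equal(pt_sub$values, pt_drop$values)))
})
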