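const_grid <- function(value = 1, n = 2, Tn = 2) {
  mg <- montage_grid("deap32")
  v <- array(0, dim = c(n, Tn, 5, 9, 9))
  for (ch in mg$channels)
    v[, , , mg$rows[[ch]] + 1, mg$cols[[ch]] + 1] <- value
  structure(list(values = v, montage = mg, band_names = names(eeg_bands()),
                 window_labels = rep(1:2, length.out = n),
                 window_trial = seq_len(n), subject_id = 1L, n_classes = 2L),
            class = "grid_tensor")
}

test_that("a constant input grid yields the uniform weight sigmoid(1/2)", {
  gt <- const_grid(3)
  m <- extract_attention_map(gt, stage = "input")
  occ <- gt$montage$occupied
  expect_equal(as.numeric(m$values[occ]), rep(plogis(0.5), sum(occ)),
               tolerance = 1e-12)
  expect_true(all(is.na(m$values[!occ])))
})

test_that("attention maps stay within the sigmoid range", {
  fx <- small_subject_grid()
  m <- extract_attention_map(fx$gt, stage = "input")
  occ <- fx$gt$montage$occupied
  expect_true(all(m$values[occ] > 0 & m$values[occ] < 1))
  expect_equal(m$n_windows, dim(fx$gt$values)[1])
})

test_that("model-stage capture runs through the spatial extractor", {
  fx <- small_subject_grid()
  cfg <- hastf_config(T_seq = 8, n_classes = 2, scale = "desk",
                      filters = c(2, 3, 3, 2, 2), d = 8, n_heads = 2,
                      ffn_dim = 4, n_layers = 1)
  set.seed(61)
  p <- hastf_init(cfg)
  m <- extract_attention_map(fx$gt, cfg, p, stage = "uccf", windows = 1:4)
  occ <- fx$gt$montage$occupied
  expect_true(all(m$values[occ] > 0 & m$values[occ] < 1))
  expect_true(all(is.na(m$values[!occ])))
  # variants without an attention stage refuse
  cfg2 <- hastf_config(T_seq = 8, n_classes = 2, variant = "Wo-SA",
                       scale = "desk")
  expect_error(extract_attention_map(fx$gt, cfg2, p, stage = "uccf"),
               "no spatial attention")
})

test_that("map statistics are invariant to window batch order", {
  fx <- small_subject_grid()
  m1 <- extract_attention_map(fx$gt, stage = "input", windows = 1:8)
  m2 <- extract_attention_map(fx$gt, stage = "input", windows = 8:1)
  expect_equal(m1$values, m2$values, tolerance = 1e-12)
})

test_that("planted channels outrank the rest in the attention map", {
  fx <- small_subject_grid()
  mg <- fx$gt$montage
  tgt <- which(fx$gt$window_labels == fx$cfg$target_class)
  m <- extract_attention_map(fx$gt, stage = "input", windows = tgt)
  cellval <- function(chs)
    mean(sapply(chs, function(ch) m$values[mg$rows[[ch]] + 1, mg$cols[[ch]] + 1]))
  expect_gt(cellval(fx$cfg$effect_channels),
            cellval(setdiff(mg$channels, fx$cfg$effect_channels)))
})

test_that("class averaging is cellwise and subject-balanced", {
  gt <- const_grid()
  m0 <- extract_attention_map(gt, stage = "input")
  m1 <- m0
  m0$values[gt$montage$occupied] <- 0
  m1$values[gt$montage$occupied] <- 1
  avg <- average_by_class(list(m0, m1, m0, m1), labels = c(1, 1, 2, 2))
  expect_equal(unname(avg[["1"]]$values[gt$montage$occupied]),
               rep(0.5, 32))
  expect_equal(avg[["1"]]$class_label, 1)
  # identical maps average to themselves
  same <- average_by_class(list(m1, m1), labels = c(1, 1))
  expect_equal(same[["1"]]$values, m1$values)
  # subject weighting: subject A (two 1-maps), subject B (one 0-map)
  wavg <- average_by_class(list(m1, m1, m0), labels = c(1, 1, 1),
                           subjects = c("A", "A", "B"))
  expect_equal(unname(wavg[["1"]]$values[gt$montage$occupied]), rep(0.5, 32))
  expect_error(average_by_class(list(), labels = integer(0)), "no maps")
})

test_that("class-mean maps differ when the data carry class effects", {
  fx <- small_subject_grid()
  labs <- fx$gt$window_labels
  maps <- lapply(seq_along(labs), function(i)
    extract_attention_map(fx$gt, stage = "input", windows = i))
  avg <- average_by_class(maps, labs)
  delta <- abs(avg[[1]]$values - avg[[2]]$values)
  expect_gt(max(delta, na.rm = TRUE), 0)
})

test_that("minmax normalization pins the occupied range to [0, 1]", {
  fx <- small_subject_grid()
  m <- extract_attention_map(fx$gt, stage = "input", normalization = "minmax")
  expect_equal(range(m$values, na.rm = TRUE), c(0, 1))
})

test_that("rendering writes a deterministic raster with the full color range", {
  fx <- small_subject_grid()
  m <- extract_attention_map(fx$gt, stage = "input", normalization = "minmax")
  p1 <- file.path(tempdir(), "map1.png")
  p2 <- file.path(tempdir(), "map2.png")
  meta1 <- render_topomap(m, p1)
  meta2 <- render_topomap(m, p2)
  expect_gt(file.size(p1), 0)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  # a minmax map uses the full color scale
  expect_equal(meta1$zlim, c(0, 1))
  expect_error(render_topomap(m, "/nonexistent-dir/x.png"), "no such directory")
})
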