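test_that("constant feature maps have minimal energy exactly 2", {
  fm <- matrix(3.7, 5, 5)
  for (lam in c(1e-6, 1e-4, 1, 1e9)) {
    expect_equal(simam_energy(fm, c(2, 3), sa_params(lambda = lam)), 2,
                 tolerance = 1e-12)
  }
})

test_that("the closed-form energy matches brute-force minimization", {
  set.seed(11)
  fm <- matrix(rnorm(9), 3, 3)
  lam <- 1e-4
  e_star <- simam_energy(fm, c(2, 2), sa_params(lambda = lam))
  nm <- numeric_min_energy(fm, c(2, 2), lam)
  expect_lt(abs(e_star - nm$value), 1e-6)
  # the analytic minimizer agrees with the numeric one; with targets
  # +1 (target position) and -1 (others) the slope of the minimizer is
  # +2(t - u) / D -- the conventional printed form carries the opposite
  # sign, which corresponds to swapping the two targets and leaves the
  # minimal energy unchanged
  t_val <- fm[2, 2]
  others <- fm[-5]
  u <- mean(others); s2 <- mean((others - u)^2)
  w_t <- 2 * (t_val - u) / ((t_val - u)^2 + 2 * s2 + 2 * lam)
  b_t <- -0.5 * (t_val + u) * w_t
  expect_lt(max(abs(c(w_t, b_t) - nm$par)), 1e-5)
  expect_equal(e_star, nm$energy(c(w_t, b_t)), tolerance = 1e-10)
  # opposite-sign slope is not a minimizer unless t == u
  expect_gt(nm$energy(c(-w_t, 0.5 * (t_val + u) * w_t)), nm$value)
})

test_that("analytic energies track the numeric oracle over many maps and lambdas", {
  set.seed(12)
  worst <- 0
  for (lam in c(1e-6, 1e-4, 1e-2)) {
    for (i in 1:34) {
      fm <- matrix(rnorm(16, sd = sample(c(0.1, 1, 10), 1)), 4, 4)
      pos <- c(sample(4, 1), sample(4, 1))
      e_star <- simam_energy(fm, pos, sa_params(lambda = lam))
      nm <- numeric_min_energy(fm, pos, lam)
      worst <- max(worst, abs(e_star - nm$value) / abs(nm$value))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("very large lambda drives all weights to sigmoid(1/2)", {
  set.seed(13)
  x <- array(rnorm(9 * 9 * 2 * 3), dim = c(9, 9, 2, 3))
  sa <- spatial_attention(x, sa_params(lambda = 1e9))
  expect_equal(as.numeric(sa$attention$weights),
               rep(plogis(0.5), length(x)), tolerance = 1e-6)
})

test_that("attention refines a constant map uniformly by sigmoid(1/2)", {
  x <- array(2.5, dim = c(9, 9, 1, 1))
  sa <- spatial_attention(x, sa_params())
  expect_equal(as.numeric(sa$out), rep(plogis(0.5) * 2.5, 81),
               tolerance = 1e-12)
})

test_that("attention weights are a function of position values only (equivariance)", {
  set.seed(14)
  fm <- matrix(rnorm(81), 9, 9)
  perm <- sample(81)
  fmp <- matrix(fm[perm], 9, 9)
  w1 <- spatial_attention(fm)$attention$weights
  w2 <- spatial_attention(fmp)$attention$weights
  expect_equal(as.numeric(w2), as.numeric(w1)[perm], tolerance = 1e-12)
})

test_that("outlier positions receive above-median weights", {
  set.seed(15)
  hits <- 0
  for (i in 1:100) {
    fm <- matrix(rnorm(81), 9, 9)
    pos <- sample(81, 1)
    fm[pos] <- fm[pos] + 8  # large-magnitude outlier
    w <- spatial_attention(fm)$attention$weights
    if (w[pos] > stats::median(w)) hits <- hits + 1
  }
  expect_equal(hits, 100)
})

test_that("attention weights stay in (0,1) and preserve signs", {
  set.seed(16)
  x <- array(rnorm(9 * 9 * 4 * 5), dim = c(9, 9, 4, 5))
  sa <- spatial_attention(x, sa_params())
  w <- sa$attention$weights
  expect_true(all(w > 0 & w < 1))
  expect_true(all(sign(sa$out) == sign(x) | x == 0))
  expect_error(spatial_attention(array(NA_real_, c(9, 9, 1, 1))), "NA")
})

test_that("shared-statistics mode approximates leave-one-out", {
  set.seed(17)
  fm <- matrix(rnorm(81), 9, 9)
  w_loo <- spatial_attention(fm, sa_params())$attention$weights
  w_sh <- spatial_attention(fm, sa_params(statistics = "shared"))$attention$weights
  expect_gt(stats::cor(as.numeric(w_loo), as.numeric(w_sh)), 0.99)
})

test_that("UCCF preserves the 9x9 spatial size and wires skips by concatenation", {
  cfg <- uccf_config(c(4, 8, 8, 4, 4))
  expect_equal(cfg$in_ch, c(5L, 4L, 8L, 8L + 8L, 4L + 4L))
  set.seed(18)
  p <- uccf_init(cfg)
  x <- array(rnorm(9 * 9 * 3 * 5), dim = c(9, 9, 3, 5))
  out <- uccf_forward(x, cfg, p)$out
  expect_equal(dim(out), c(9, 9, 3, 4))
  # zero weights: rectifier(0) = 0 throughout
  p0 <- lapply(p, function(m) {m[] <- 0; m})
  expect_true(all(uccf_forward(x, cfg, p0)$out == 0))
  expect_error(uccf_forward(array(0, c(9, 9, 3, 4)), cfg, p), "UCCF expects")
})

test_that("gradients reach all five convolution layers", {
  cfg <- uccf_config(c(3, 4, 4, 3, 2))
  set.seed(19)
  p <- uccf_init(cfg)
  x <- array(rnorm(9 * 9 * 2 * 5), dim = c(9, 9, 2, 5))
  fw <- uccf_forward(x, cfg, p)
  g <- hastf:::uccf_backward(array(1, dim = dim(fw$out)), fw$cache)
  for (k in 1:5) {
    expect_gt(sum(abs(g[[paste0("conv", k, "_W")]])), 0)
  }
})

test_that("the spatial extractor produces d-dimensional features per patch", {
  cfg <- list(uccf = uccf_config(c(3, 4, 4, 3, 2)), sa = sa_params(),
              d = 7L, use_uccf = TRUE, use_sa = TRUE)
  set.seed(20)
  p <- safe_init(cfg)
  x <- array(rnorm(9 * 9 * 6 * 5), dim = c(9, 9, 6, 5))
  out <- safe_forward(x, cfg, p)
  expect_equal(dim(out$out), c(6, 7))
  # max pooling reduces 9x9 to 4x4 inside: flat dim is 16 * filters[5]
  expect_equal(nrow(p$proj_W), 16 * 2)
  # disabling attention changes the output
  cfg2 <- cfg; cfg2$use_sa <- FALSE
  out2 <- safe_forward(x, cfg2, p)
  expect_false(isTRUE(all.equal(out$out, out2$out)))
})
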