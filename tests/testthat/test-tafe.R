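tiny_cfg <- function(...) encoder_config(n_layers = 2L, n_heads = 2L, d = 8L,
                                         ffn_dim = 6L, ...)

test_that("qkv width must split evenly across heads", {
  expect_error(encoder_config(n_heads = 3L, d = 8L, qkv_dim = 8L),
               "divisible")
})

test_that("a single-token sequence attends only to itself", {
  cfg <- tiny_cfg()
  set.seed(31)
  p <- tafe_init(cfg, T_seq = 4, n_classes = 2)
  w <- hastf:::layer_weights(p, 1)
  Z <- matrix(rnorm(8), 1, 8)
  out <- multi_head_attention(Z, 1L, cfg, w)
  expect_equal(as.numeric(out$attn), rep(1, cfg$n_heads))
  # output equals the projection of V alone
  V <- sweep(Z %*% w$Wv, 2, w$bv, `+`)
  expect_equal(out$out, sweep(V %*% w$Wo, 2, w$bo, `+`), tolerance = 1e-12)
})

test_that("attention rows lie on the simplex", {
  cfg <- tiny_cfg()
  set.seed(32)
  p <- tafe_init(cfg, T_seq = 5, n_classes = 2)
  Z <- matrix(rnorm(6 * 3 * 8), 6 * 3, 8)   # 3 windows of 6 tokens
  out <- multi_head_attention(Z, 6L, cfg, hastf:::layer_weights(p, 1))
  expect_true(all(out$attn >= 0))
  sums <- apply(out$attn, c(1, 3, 4), sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-12)
})

test_that("batched attention equals the naive per-head loop", {
  set.seed(33)
  worst <- 0
  for (rep_i in 1:20) {
    heads <- sample(c(1L, 2L, 4L), 1)
    d <- heads * sample(c(2L, 4L), 1)
    T1 <- sample(3:9, 1)
    N <- sample(1:3, 1)
    cfg <- encoder_config(n_layers = 1L, n_heads = heads, d = d, ffn_dim = 4L)
    p <- tafe_init(cfg, T_seq = T1 - 1L, n_classes = 2)
    w <- hastf:::layer_weights(p, 1)
    Z <- matrix(rnorm(T1 * N * d), T1 * N, d)
    fast <- multi_head_attention(Z, T1, cfg, w)$out
    for (n in seq_len(N)) {
      rows <- (n - 1) * T1 + seq_len(T1)
      ref <- naive_mha_window(Z[rows, , drop = FALSE], cfg, w)
      worst <- max(worst, max(abs(fast[rows, ] - ref)))
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("encoder layers preserve shape and normalize rows", {
  cfg <- tiny_cfg()
  set.seed(34)
  p <- tafe_init(cfg, T_seq = 4, n_classes = 3)
  Z <- matrix(rnorm(5 * 2 * 8), 10, 8)
  out <- encoder_layer(Z, 5L, cfg, hastf:::layer_weights(p, 1))
  expect_equal(dim(out$out), dim(Z))
  # post-LayerNorm rows: mean ~ 0, unit variance (gamma = 1, beta = 0 at init)
  expect_equal(rowMeans(out$out), rep(0, 10), tolerance = 1e-5)
  expect_equal(apply(out$out, 1, function(r) mean(r^2)), rep(1, 10),
               tolerance = 1e-3)
})

test_that("without positional encoding, patch permutation commutes with encoding", {
  cfg <- tiny_cfg()
  set.seed(35)
  p <- tafe_init(cfg, T_seq = 6, n_classes = 2)
  p$pos_enc[] <- 0
  feats <- matrix(rnorm(6 * 8), 6, 8)
  perm <- sample(6)
  out1 <- tafe_forward(feats, 6L, cfg, p)
  out2 <- tafe_forward(feats[perm, , drop = FALSE], 6L, cfg, p)
  # the class-token logits are permutation invariant
  expect_equal(out1$logits, out2$logits, tolerance = 1e-10)
})

test_that("sequence length is T + 1 and logits match the class count", {
  cfg <- tiny_cfg()
  set.seed(36)
  # DEAP-like: 8 patches + class token = 9 tokens
  p8 <- tafe_init(cfg, T_seq = 8, n_classes = 2)
  out8 <- tafe_forward(matrix(rnorm(8 * 2 * 8), 16, 8), 8L, cfg, p8)
  expect_equal(dim(out8$attn)[1:2], c(9L, 9L))
  expect_equal(ncol(out8$logits), 2L)
  # SEED-like: 11 patches -> 12 tokens, 3 classes
  p11 <- tafe_init(cfg, T_seq = 11, n_classes = 3)
  out11 <- tafe_forward(matrix(rnorm(11 * 8), 11, 8), 11L, cfg, p11)
  expect_equal(dim(out11$attn)[1:2], c(12L, 12L))
  expect_equal(ncol(out11$logits), 3L)
  expect_error(tafe_forward(matrix(rnorm(7 * 8), 7, 8), 2L, cfg, p8),
               "ragged")
})

test_that("class token and positional encodings receive gradient", {
  cfg <- tiny_cfg()
  set.seed(37)
  p <- tafe_init(cfg, T_seq = 3, n_classes = 2)
  feats <- matrix(rnorm(3 * 4 * 8), 12, 8)
  fw <- tafe_forward(feats, 3L, cfg, p)
  ls <- hastf:::softmax_xent(fw$logits, c(1, 2, 1, 2))
  g <- hastf:::tafe_backward(ls$dlogits, fw$cache)
  expect_gt(sum(abs(g$class_token)), 0)
  expect_gt(sum(abs(g$pos_enc)), 0)
  expect_gt(sum(abs(g$dfeats)), 0)
})

test_that("token initialization is truncated standard normal in [0, 1]", {
  cfg <- encoder_config(n_layers = 1L, n_heads = 2L, d = 64L, ffn_dim = 4L)
  set.seed(38)
  p <- tafe_init(cfg, T_seq = 10, n_classes = 2)
  expect_true(all(p$pos_enc >= 0 & p$pos_enc <= 1))
  expect_true(all(p$class_token >= 0 & p$class_token <= 1))
  # plain-normal alternative
  cfg2 <- encoder_config(n_layers = 1L, n_heads = 2L, d = 64L, ffn_dim = 4L,
                         token_init = "norm")
  p2 <- tafe_init(cfg2, T_seq = 10, n_classes = 2)
  expect_true(any(p2$pos_enc < 0))
})
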