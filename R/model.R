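#' Configure the hybrid attention spatio-temporal network
#'
#' Combines the spatial extractor (UCCF + energy-based attention +
#' pooling + projection) with the class-token transformer temporal encoder
#' and a classification head. `variant` selects the ablation structure:
#'
#' * `"All"` — the full model.
#' * `"Wo-Sc"` — UCCF without its two skip concatenations.
#' * `"Wo-SA"` — spatial attention replaced by identity.
#' * `"Wo-UCCF"` — attention and pooling applied to the raw band maps,
#'   no convolutions.
#' * `"Wo-SAFE"` — flattened band maps affinely projected to width d and
#'   fed straight to the temporal encoder.
#' * `"Wo-TAFE"` — patch spatial features averaged over the window and
#'   classified by an affine head (no temporal encoder).
#'
#' @param T_seq Patches per window (8 for DEAP-like, 11 for SEED-like).
#' @param n_classes Number of emotion classes.
#' @param variant Ablation variant name (see above).
#' @param filters UCCF per-layer feature-map counts.
#' @param d Embedding width shared by the projection and the encoder.
#' @param n_layers,n_heads,qkv_dim,ffn_dim Encoder hyperparameters.
#' @param lambda Attention ridge constant.
#' @param scale "paper" keeps the published hyperparameters
#'   (64,128,128,64,32 filters, d = 256, 8 heads, 6 layers); "desk" is a
#'   reduced preset for CPU-scale experiments (4,8,8,4,4 filters, d = 32,
#'   4 heads, 2 layers). Explicit arguments override either.
#' @return An `hastf_config` list.
#' @export
hastf_config <- function(T_seq, n_classes,
                         variant = c("All", "Wo-Sc", "Wo-SA", "Wo-UCCF",
                                     "Wo-SAFE", "Wo-TAFE"),
                         scale = c("paper", "desk"),
                         filters = NULL, d = NULL, n_layers = NULL,
                         n_heads = NULL, qkv_dim = NULL, ffn_dim = NULL,
                         lambda = 1e-4) {
  variant <- match.arg(variant)
  scale <- match.arg(scale)
  def <- if (scale == "paper") {
    list(filters = c(64L, 128L, 128L, 64L, 32L), d = 256L, n_layers = 6L,
         n_heads = 8L, ffn_dim = 128L)
  } else {
    list(filters = c(4L, 8L, 8L, 4L, 4L), d = 32L, n_layers = 2L,
         n_heads = 4L, ffn_dim = 16L)
  }
  filters <- filters %||% def$filters
  d <- d %||% def$d
  n_layers <- n_layers %||% def$n_layers
  n_heads <- n_heads %||% def$n_heads
  ffn_dim <- ffn_dim %||% def$ffn_dim
  qkv_dim <- qkv_dim %||% d
  use_safe <- variant != "Wo-SAFE"
  structure(list(
    T_seq = as.integer(T_seq), n_classes = as.integer(n_classes),
    variant = variant, scale = scale,
    use_safe = use_safe,
    use_tafe = variant != "Wo-TAFE",
    safe = list(
      uccf = uccf_config(filters, skip = variant != "Wo-Sc"),
      sa = sa_params(lambda),
      d = as.integer(d),
      use_uccf = use_safe && variant != "Wo-UCCF",
      use_sa = use_safe && variant != "Wo-SA"
    ),
    tafe = encoder_config(n_layers, n_heads, d, qkv_dim, ffn_dim)
  ), class = "hastf_config")
}

#' Initialize all network weights
#'
#' Draws from the current RNG; call `set.seed()` first for reproducible
#' initialization.
#'
#' @param cfg An [hastf_config()].
#' @return Named list of parameter arrays.
#' @export
hastf_init <- function(cfg) {
  p <- list()
  if (cfg$use_safe) {
    p <- safe_init(cfg$safe)
  } else {
    p$proj_W <- init_weight(9L * 9L * 5L, cfg$safe$d)
    p$proj_b <- numeric(cfg$safe$d)
  }
  if (cfg$use_tafe) {
    p <- c(p, tafe_init(cfg$tafe, cfg$T_seq, cfg$n_classes))
  } else {
    p$head_W <- init_weight(cfg$safe$d, cfg$n_classes)
    p$head_b <- numeric(cfg$n_classes)
  }
  p
}

# rearrange grid windows (n x T x B x 9 x 9) into the channels-last patch
# stack (9, 9, T * n, B) with patch index fastest within each window
grid_to_patch_stack <- function(v) {
  d <- dim(v)
  out <- aperm(v, c(4, 5, 2, 1, 3))
  dim(out) <- c(d[4], d[5], d[2] * d[1], d[3])
  out
}

#' Full network forward pass
#'
#' @param x Grid windows: array n x T x 5 x 9 x 9 (a slice of a
#'   `grid_tensor`'s values).
#' @param cfg An [hastf_config()].
#' @param params Weights from [hastf_init()].
#' @return List with `logits` (n x n_classes), `attention` (spatial
#'   attention map or NULL), and `cache` for [hastf_backward()].
#' @export
hastf_forward <- function(x, cfg, params) {
  d <- dim(x)
  N <- d[1]; T_seq <- d[2]
  if (T_seq != cfg$T_seq)
    stop("window has ", T_seq, " patches; model expects ", cfg$T_seq,
         call. = FALSE)
  ps <- grid_to_patch_stack(x)
  cache <- list(cfg = cfg, N = N)
  att <- NULL
  if (cfg$use_safe) {
    sf <- safe_forward(ps, cfg$safe, params)
    feats <- sf$out
    att <- sf$attention
    cache$safe <- sf$cache
  } else {
    dm <- dim(ps)           # (9, 9, T*n, 5)
    flat <- aperm(ps, c(3, 1, 2, 4))
    dim(flat) <- c(dm[3], dm[1] * dm[2] * dm[4])
    pr <- linear_forward(flat, params$proj_W, params$proj_b)
    feats <- pr$out
    cache$proj <- pr$cache
    cache$flat_dims <- dm
  }
  if (cfg$use_tafe) {
    tf <- tafe_forward(feats, T_seq, cfg$tafe, params)
    logits <- tf$logits
    cache$tafe <- tf$cache
  } else {
    # mean over the T patch features of each window, then affine head
    fm <- array(feats, dim = c(T_seq, N, ncol(feats)))
    pooled <- colMeans(fm)                       # N x d
    hd <- linear_forward(pooled, params$head_W, params$head_b)
    logits <- hd$out
    cache$head <- hd$cache
    cache$T_seq <- T_seq
  }
  list(logits = logits, attention = att, cache = cache)
}

#' Backward pass of the full network
#'
#' @param dlogits Gradient of the loss with respect to the logits.
#' @param cache Cache from [hastf_forward()].
#' @return Named list of parameter gradients (same structure as the
#'   parameter list).
#' @export
hastf_backward <- function(dlogits, cache) {
  cfg <- cache$cfg
  grads <- list()
  if (cfg$use_tafe) {
    tg <- tafe_backward(dlogits, cache$tafe)
    dfeats <- tg$dfeats
    tg$dfeats <- NULL
    grads <- c(grads, tg)
  } else {
    hb <- linear_backward(dlogits, cache$head)
    grads$head_W <- hb$dW
    grads$head_b <- hb$db
    T_seq <- cache$T_seq
    # each of a window's T patch rows receives dlogits_row / T
    dfeats <- hb$dx[rep(seq_len(cache$N), each = T_seq), , drop = FALSE] / T_seq
  }
  if (cfg$use_safe) {
    sg <- safe_backward(dfeats, cache$safe)
    grads <- c(grads, sg)
  } else {
    pb <- linear_backward(dfeats, cache$proj)
    grads$proj_W <- pb$dW
    grads$proj_b <- pb$db
  }
  grads
}

#' Predict class labels for grid windows
#'
#' @inheritParams hastf_forward
#' @return Integer class codes (1-based).
#' @export
hastf_predict <- function(x, cfg, params) {
  max.col(hastf_forward(x, cfg, params)$logits, ties.method = "first")
}
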