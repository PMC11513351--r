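#' Configuration of the U-shaped continuous convolution fusion network
#'
#' Five convolution layers over the 9x9 band maps: a channel-expansion
#' branch (layers 1-3) and a channel-contraction branch (layers 4-5) joined
#' by concatenation skip connections — layer 4 consumes `CAT(Y3, Y2)` and
#' layer 5 consumes `CAT(Y4, Y1)`. Layers 1-4 use 3x3 kernels with stride 1
#' and padding 1; layer 5 uses a 1x1 kernel with padding 0, so the 9x9
#' spatial size is preserved throughout. Every layer is followed by a
#' rectifier.
#'
#' @param filters Per-layer feature-map counts (default 64,128,128,64,32).
#' @param skip Keep the two skip concatenations (FALSE gives the
#'   skip-connection ablation).
#' @return A `uccf_config` list with derived per-layer input channel counts.
#' @export
uccf_config <- function(filters = c(64L, 128L, 128L, 64L, 32L), skip = TRUE) {
  stopifnot(length(filters) == 5, all(filters >= 1))
  f <- as.integer(filters)
  in_ch <- c(5L, f[1], f[2],
             if (skip) f[3] + f[2] else f[3],
             if (skip) f[4] + f[1] else f[4])
  structure(list(filters = f, in_ch = in_ch, skip = isTRUE(skip),
                 kernels = c(3L, 3L, 3L, 3L, 1L)),
            class = "uccf_config")
}

#' Parameters of the energy-based spatial attention
#'
#' The attention is parameter-free: each position's weight is
#' `sigmoid(1 / e*)` where `e*` is the closed-form minimum of an energy
#' function measuring the position's linear separability from its peers
#' (binary targets +1 for the target position, -1 for the others, ridge
#' penalty `lambda` on the slope). With leave-one-out statistics
#' `u_t = mean(x[-t])`, `s2_t = popvar(x[-t])`,
#' `e* = 4 (s2_t + lambda) / ((t - u_t)^2 + 2 s2_t + 2 lambda)`.
#'
#' @param lambda Ridge constant (> 0, default 1e-4).
#' @param statistics "leave_one_out" (exact) or "shared" (channel-wide mean
#'   and variance including the target, a faster approximation).
#' @return An `sa_params` list.
#' @export
sa_params <- function(lambda = 1e-4,
                      statistics = c("leave_one_out", "shared")) {
  if (lambda <= 0) stop("`lambda` must be positive", call. = FALSE)
  structure(list(lambda = lambda, statistics = match.arg(statistics),
                 y_t = 1, y_o = -1),
            class = "sa_params")
}

#' Minimal energy of one position of a feature map
#'
#' Direct evaluation of the closed-form minimum energy for the position at
#' `pos`, using leave-one-out mean and population variance of the remaining
#' positions. Strictly positive for any input; equals exactly 2 on a
#' constant map.
#'
#' @param fm Numeric matrix (one 2D feature map with at least 2 positions).
#' @param pos `c(row, col)` of the target position.
#' @param params An [sa_params()].
#' @return The scalar minimal energy `e*`.
#' @export
simam_energy <- function(fm, pos, params = sa_params()) {
  fm <- as.matrix(fm)
  M <- length(fm)
  if (M < 2) stop("feature map needs at least 2 positions", call. = FALSE)
  t_val <- fm[pos[1], pos[2]]
  others <- fm[-((pos[2] - 1) * nrow(fm) + pos[1])]
  if (params$statistics == "leave_one_out") {
    u <- mean(others)
    s2 <- mean((others - u)^2)
  } else {
    u <- mean(fm)
    s2 <- mean((fm - u)^2)
  }
  4 * (s2 + params$lambda) / ((t_val - u)^2 + 2 * s2 + 2 * params$lambda)
}

# vectorized energies and weights for a stack of maps given as an
# (M x K) matrix (M spatial positions, K = maps); returns list(e, w, u, s2)
simam_stats <- function(xm, params) {
  M <- nrow(xm)
  lam <- params$lambda
  if (params$statistics == "leave_one_out") {
    s <- colSums(xm)
    ss <- colSums(xm^2)
    u <- sweep(-xm, 2, s, `+`) / (M - 1)           # (s - x) / (M-1)
    s2 <- sweep(-xm^2, 2, ss, `+`) / (M - 1) - u^2
    s2[s2 < 0] <- 0
  } else {
    u <- matrix(colMeans(xm), M, ncol(xm), byrow = TRUE)
    s2 <- matrix(colMeans(xm^2) - colMeans(xm)^2, M, ncol(xm), byrow = TRUE)
    s2[s2 < 0] <- 0
  }
  e <- 4 * (s2 + lam) / ((xm - u)^2 + 2 * s2 + 2 * lam)
  list(e = e, w = stats::plogis(1 / e), u = u, s2 = s2)
}

#' Apply energy-based spatial attention to a stack of feature maps
#'
#' Computes each position's minimal energy `e*` and refines the input as
#' `sigmoid(1/e*) * x`, elementwise per map. Contains no trainable
#' parameters; all weights lie strictly in (0, 1), so the refinement never
#' changes a value's sign. A constant map gets the uniform weight
#' `sigmoid(1/2)`.
#'
#' @param x Array (H, W, N, C) of feature maps (channels last: C maps per
#'   each of N items), or a single matrix.
#' @param params An [sa_params()].
#' @return List with `out` (refined features, same shape) and `attention`
#'   (an `attention_map`: `weights`, `energies`, `mean`, `variance`, all the
#'   same shape as the input).
#' @export
spatial_attention <- function(x, params = sa_params()) {
  single <- is.matrix(x)
  if (single) x <- array(x, dim = c(dim(x), 1, 1))
  d <- dim(x)
  if (anyNA(x)) stop("NA in attention input", call. = FALSE)
  if (d[1] * d[2] < 2) stop("feature map needs at least 2 positions", call. = FALSE)
  xm <- x
  dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  st <- simam_stats(xm, params)
  shape_back <- function(m) {dim(m) <- d; m}
  out <- shape_back(st$w * xm)
  att <- structure(list(weights = shape_back(st$w),
                        energies = shape_back(st$e),
                        mean = shape_back(st$u),
                        variance = shape_back(st$s2)),
                   class = "attention_map")
  if (single) {
    out <- out[, , 1, 1]
    att <- lapply(att, function(m) m[, , 1, 1])
    class(att) <- "attention_map"
  }
  list(out = out, attention = att)
}

# ---- UCCF forward/backward -------------------------------------------------

#' Initialize UCCF weights
#'
#' He-uniform draws using the current RNG state.
#'
#' @param cfg A [uccf_config()].
#' @return Named list of weight matrices `convk_W` ((kernel^2 * in) x out)
#'   and biases `convk_b`.
#' @export
uccf_init <- function(cfg) {
  p <- list()
  for (k in 1:5) {
    fan_in <- cfg$kernels[k]^2 * cfg$in_ch[k]
    p[[paste0("conv", k, "_W")]] <- init_weight(fan_in, cfg$filters[k])
    p[[paste0("conv", k, "_b")]] <- numeric(cfg$filters[k])
  }
  p
}

#' U-shaped convolution fusion forward pass
#'
#' @param x Array (9, 9, N, 5) of band maps (channels last).
#' @param cfg A [uccf_config()].
#' @param params Weights from [uccf_init()].
#' @return List with `out` (9, 9, N, filters[5]) and `cache` for the
#'   backward pass.
#' @export
uccf_forward <- function(x, cfg, params) {
  d <- dim(x)
  if (d[1] != 9 || d[2] != 9 || d[4] != cfg$in_ch[1])
    stop("UCCF expects (9, 9, N, ", cfg$in_ch[1], ") input, got (",
         paste(d, collapse = ", "), ")", call. = FALSE)
  caches <- vector("list", 5)
  ys <- vector("list", 5)
  inp <- x
  for (k in 1:5) {
    inp <- if (k == 1) x
      else if (cfg$skip && k == 4) abind4(ys[[3]], ys[[2]])
      else if (cfg$skip && k == 5) abind4(ys[[4]], ys[[1]])
      else ys[[k - 1]]
    cv <- conv2d_forward(inp, params[[paste0("conv", k, "_W")]],
                         params[[paste0("conv", k, "_b")]], cfg$kernels[k])
    rl <- relu_forward(cv$out)
    ys[[k]] <- rl$out
    caches[[k]] <- list(conv = cv$cache, relu = rl$cache)
  }
  list(out = ys[[5]], cache = list(layers = caches, cfg = cfg))
}

# concatenate two (H,W,N,C) arrays along the channel axis
abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

uccf_backward <- function(dout, cache) {
  cfg <- cache$cfg
  grads <- list()
  dy <- vector("list", 5)
  dy[[5]] <- dout
  for (k in 5:1) {
    dr <- relu_backward(dy[[k]], cache$layers[[k]]$relu)
    bk <- conv2d_backward(dr, cache$layers[[k]]$conv)
    grads[[paste0("conv", k, "_W")]] <- bk$dW
    grads[[paste0("conv", k, "_b")]] <- bk$db
    dx <- bk$dx
    add_dy <- function(idx, g) {
      dy[[idx]] <<- if (is.null(dy[[idx]])) g else dy[[idx]] + g
    }
    if (cfg$skip && k == 5) {
      f4 <- cfg$filters[4]
      add_dy(4, dx[, , , seq_len(f4), drop = FALSE])
      add_dy(1, dx[, , , f4 + seq_len(cfg$filters[1]), drop = FALSE])
    } else if (cfg$skip && k == 4) {
      f3 <- cfg$filters[3]
      add_dy(3, dx[, , , seq_len(f3), drop = FALSE])
      add_dy(2, dx[, , , f3 + seq_len(cfg$filters[2]), drop = FALSE])
    } else if (k > 1) {
      add_dy(k - 1, dx)
    } else {
      grads$dx <- dx
    }
  }
  grads
}

# ---- SAFE: UCCF -> attention -> max pooling -> flatten -> projection -------

#' Initialize SAFE weights
#'
#' @param cfg A `safe_config`-style list: `uccf` ([uccf_config()]), `sa`
#'   ([sa_params()]), `d` (embedding width), plus ablation switches
#'   `use_uccf`, `use_sa`.
#' @return Named parameter list (UCCF weights plus the projection).
#' @export
safe_init <- function(cfg) {
  p <- if (cfg$use_uccf) uccf_init(cfg$uccf) else list()
  cmaps <- if (cfg$use_uccf) cfg$uccf$filters[5] else 5L
  flat_dim <- 4L * 4L * cmaps
  p$proj_W <- init_weight(flat_dim, cfg$d)
  p$proj_b <- numeric(cfg$d)
  p
}

#' Spatial attention feature extractor forward pass
#'
#' UCCF convolutions, energy-based spatial attention, 2x2/stride-2 max
#' pooling (9x9 -> 4x4), flattening and an affine projection to the
#' embedding width `d`, producing one spatial feature vector per patch.
#' Ablation switches: `use_uccf = FALSE` applies attention and pooling to
#' the raw band maps; `use_sa = FALSE` replaces attention with identity.
#'
#' @param x Array (9, 9, N, 5) of per-patch band maps (channels last).
#' @param cfg SAFE configuration (see [safe_init()]).
#' @param params Weights from [safe_init()].
#' @return List with `out` (N x d matrix), `attention` (the attention map or
#'   NULL), and `cache`.
#' @export
safe_forward <- function(x, cfg, params) {
  cache <- list(cfg = cfg)
  h <- x
  if (cfg$use_uccf) {
    u <- uccf_forward(h, cfg$uccf, params)
    h <- u$out
    cache$uccf <- u$cache
  }
  att <- NULL
  if (cfg$use_sa) {
    sa <- spatial_attention(h, cfg$sa)
    att <- sa$attention
    cache$sa_w <- sa$attention$weights
    h <- sa$out
  }
  mp <- maxpool_forward(h)
  cache$mp <- mp$cache
  d <- dim(mp$out)          # (Ho, Wo, N, C)
  flat <- aperm(mp$out, c(3, 1, 2, 4))
  dim(flat) <- c(d[3], d[1] * d[2] * d[4])
  pr <- linear_forward(flat, params$proj_W, params$proj_b)
  cache$proj <- pr$cache
  cache$flat_dims <- d
  list(out = pr$out, attention = att, cache = cache)
}

safe_backward <- function(dout, cache) {
  pr <- linear_backward(dout, cache$proj)
  grads <- list(proj_W = pr$dW, proj_b = pr$db)
  d <- cache$flat_dims
  dflat <- pr$dx
  dim(dflat) <- c(d[3], d[1], d[2], d[4])
  dmp <- aperm(dflat, c(2, 3, 1, 4))
  dh <- maxpool_backward(dmp, cache$mp)
  if (!is.null(cache$sa_w)) dh <- dh * cache$sa_w  # attention as fixed gate
  if (!is.null(cache$uccf)) {
    ug <- uccf_backward(dh, cache$uccf)
    ug$dx <- NULL
    grads <- c(grads, ug)
  }
  grads
}
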