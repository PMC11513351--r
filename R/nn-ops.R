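# Low-level network operations with explicit forward caches and backward
# passes. Spatial arrays are channels-last, (H, W, N, C), so the im2col
# unfolding and all reshapes are plain dim changes without transposition;
# the 3x3 unfold/fold pair is compiled (src/conv.cpp). All dense algebra
# goes through BLAS matrix products.

# ---- initialization --------------------------------------------------------

# He-uniform fan-in initialization for conv / linear weights
init_weight <- function(fan_in, n_out) {
  lim <- sqrt(6 / fan_in)
  matrix(stats::runif(fan_in * n_out, -lim, lim), fan_in, n_out)
}

# standard-normal draws truncated (by redraw) to [0, 1]
init_trunc_norm01 <- function(n) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    z <- stats::rnorm(length(todo))
    ok <- z >= 0 & z <= 1
    out[todo[ok]] <- z[ok]
    todo <- todo[!ok]
  }
  out
}

# ---- 2D convolution (kernel 3 pad 1, or kernel 1 pad 0) --------------------
# input (H, W, N, Cin); weights (k^2*Cin) x Cout with kernel offsets fastest
# (column-major 3x3, centre-relative); bias length Cout. Spatial size is
# preserved (pad 1 for k = 3, pad 0 for k = 1).

conv2d_forward <- function(x, W, b, k) {
  d <- dim(x)
  cols <- if (k == 1) {
    dim(x) <- c(d[1] * d[2] * d[3], d[4])
    x
  } else {
    .im2col3(x, d[1], d[2], d[3], d[4])
  }
  out <- cols %*% W
  out <- out + rep(b, each = nrow(out))
  dim(out) <- c(d[1], d[2], d[3], ncol(W))
  list(out = out, cache = list(cols = cols, W = W, k = k, dims = d))
}

conv2d_backward <- function(dout, cache) {
  d <- cache$dims
  dm <- dout
  dim(dm) <- c(d[1] * d[2] * d[3], ncol(cache$W))
  dW <- crossprod(cache$cols, dm)
  db <- colSums(dm)
  dcols <- dm %*% t(cache$W)
  dx <- if (cache$k == 1) {
    dim(dcols) <- d
    dcols
  } else {
    .col2im3(dcols, d[1], d[2], d[3], d[4])
  }
  list(dx = dx, dW = dW, db = db)
}

# ---- elementwise -----------------------------------------------------------

relu_forward <- function(x) {
  out <- x
  out[out < 0] <- 0
  list(out = out, cache = x > 0)
}
relu_backward <- function(dout, cache) dout * cache

gelu_forward <- function(x) {
  # exact (error-function) form
  list(out = x * stats::pnorm(x), cache = x)
}
gelu_backward <- function(dout, cache) {
  dout * (stats::pnorm(cache) + cache * stats::dnorm(cache))
}

# ---- max pooling 2x2 stride 2 ---------------------------------------------

maxpool_forward <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  Ho <- H %/% 2; Wo <- W %/% 2
  r1 <- seq(1, by = 2, length.out = Ho); r2 <- r1 + 1
  c1 <- seq(1, by = 2, length.out = Wo); c2 <- c1 + 1
  a <- list(x[r1, c1, , , drop = FALSE], x[r2, c1, , , drop = FALSE],
            x[r1, c2, , , drop = FALSE], x[r2, c2, , , drop = FALSE])
  out <- pmax(a[[1]], a[[2]], a[[3]], a[[4]])
  idx <- ifelse(a[[1]] == out, 1L,
         ifelse(a[[2]] == out, 2L, ifelse(a[[3]] == out, 3L, 4L)))
  list(out = out, cache = list(idx = idx, dims = d, Ho = Ho, Wo = Wo,
                               r1 = r1, r2 = r2, c1 = c1, c2 = c2))
}

maxpool_backward <- function(dout, cache) {
  dx <- array(0, dim = cache$dims)
  for (q in 1:4) {
    g <- dout * (cache$idx == q)
    rr <- if (q %in% c(1, 3)) cache$r1 else cache$r2
    cc <- if (q <= 2) cache$c1 else cache$c2
    dx[rr, cc, , ] <- dx[rr, cc, , , drop = FALSE] + g
  }
  dx
}

# ---- dense -----------------------------------------------------------------

linear_forward <- function(x, W, b) {
  out <- x %*% W
  out <- sweep(out, 2, b, `+`)
  list(out = out, cache = list(x = x, W = W))
}
linear_backward <- function(dout, cache) {
  list(dx = dout %*% t(cache$W),
       dW = crossprod(cache$x, dout),
       db = colSums(dout))
}

# ---- LayerNorm over the feature axis of a (rows x d) matrix ----------------

layernorm_forward <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xn <- xc * inv
  out <- sweep(xn, 2, gamma, `*`)
  out <- sweep(out, 2, beta, `+`)
  list(out = out, cache = list(xn = xn, inv = inv, gamma = gamma))
}

layernorm_backward <- function(dout, cache) {
  xn <- cache$xn; inv <- cache$inv; d <- ncol(xn)
  dgamma <- colSums(dout * xn)
  dbeta <- colSums(dout)
  dxn <- sweep(dout, 2, cache$gamma, `*`)
  dx <- inv * (dxn - rowMeans(dxn) - xn * rowMeans(dxn * xn))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- softmax ---------------------------------------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# cross-entropy loss over logits (N x K), labels 1-based; returns mean loss
# and dlogits (already divided by N)
softmax_xent <- function(logits, labels) {
  p <- softmax_rows(logits)
  n <- nrow(logits)
  picked <- p[cbind(seq_len(n), labels)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  d <- p
  d[cbind(seq_len(n), labels)] <- d[cbind(seq_len(n), labels)] - 1
  list(loss = loss, dlogits = d / n)
}

# ---- AdamW -----------------------------------------------------------------

adamw_init <- function(params) {
  zero <- function(p) {dm <- p; dm[] <- 0; dm}
  list(m = lapply(params, zero), v = lapply(params, zero), t = 0L)
}

# decoupled weight decay: p <- p - lr * (mhat / (sqrt(vhat) + eps) + wd * p)
adamw_step <- function(params, grads, state, lr, weight_decay = 1e-4,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       no_decay = character()) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / b1t
    vhat <- state$v[[nm]] / b2t
    wd <- if (nm %in% no_decay) 0 else weight_decay
    params[[nm]] <- params[[nm]] - lr * (mhat / (sqrt(vhat) + eps) + wd * params[[nm]])
  }
  list(params = params, state = state)
}
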