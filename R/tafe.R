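#' Configuration of the temporal attention feature extractor
#'
#' A stack of pre-norm-free ("post-LN") transformer encoder layers over the
#' sequence of per-patch spatial features, with a learnable class token at
#' index 0 and learnable positional encodings. Each layer is
#' `Z_A = LN(MSA(Z) + Z)` followed by `LN(FFN(Z_A) + Z_A)`, where the FFN is
#' affine -> GELU -> affine (d -> ffn_dim -> d). The class token's final
#' state feeds the classification head.
#'
#' @param n_layers Encoder depth (default 6).
#' @param n_heads Attention heads (default 8).
#' @param d Model / embedding width (default 256).
#' @param qkv_dim Total width of the Q, K, V projections (default `d`);
#'   must be divisible by `n_heads`.
#' @param ffn_dim Hidden width of the FFN (default 128).
#' @param token_init "trunc_norm01" (standard-normal draws truncated to
#'   [0, 1]) or "norm" for the class token and positional encoding.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(n_layers = 6L, n_heads = 8L, d = 256L,
                           qkv_dim = d, ffn_dim = 128L,
                           token_init = c("trunc_norm01", "norm")) {
  if (qkv_dim %% n_heads != 0)
    stop("qkv_dim (", qkv_dim, ") must be divisible by n_heads (", n_heads,
         ")", call. = FALSE)
  structure(list(n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
                 d = as.integer(d), qkv_dim = as.integer(qkv_dim),
                 ffn_dim = as.integer(ffn_dim),
                 d_k = as.integer(qkv_dim / n_heads),
                 token_init = match.arg(token_init)),
            class = "encoder_config")
}

#' Initialize TAFE weights
#'
#' @param cfg An [encoder_config()].
#' @param T_seq Number of patch tokens per window.
#' @param n_classes Output classes of the head.
#' @return Named parameter list: class token, positional encoding,
#'   per-layer MSA / FFN / LayerNorm weights, and the classification head.
#' @export
tafe_init <- function(cfg, T_seq, n_classes) {
  draw <- if (cfg$token_init == "trunc_norm01") init_trunc_norm01 else stats::rnorm
  p <- list(
    class_token = matrix(draw(cfg$d), 1, cfg$d),
    pos_enc = matrix(draw((T_seq + 1) * cfg$d), T_seq + 1, cfg$d)
  )
  for (l in seq_len(cfg$n_layers)) {
    pre <- paste0("enc", l, "_")
    p[[paste0(pre, "Wq")]] <- init_weight(cfg$d, cfg$qkv_dim)
    p[[paste0(pre, "bq")]] <- numeric(cfg$qkv_dim)
    p[[paste0(pre, "Wk")]] <- init_weight(cfg$d, cfg$qkv_dim)
    p[[paste0(pre, "bk")]] <- numeric(cfg$qkv_dim)
    p[[paste0(pre, "Wv")]] <- init_weight(cfg$d, cfg$qkv_dim)
    p[[paste0(pre, "bv")]] <- numeric(cfg$qkv_dim)
    p[[paste0(pre, "Wo")]] <- init_weight(cfg$qkv_dim, cfg$d)
    p[[paste0(pre, "bo")]] <- numeric(cfg$d)
    p[[paste0(pre, "ln1_g")]] <- rep(1, cfg$d)
    p[[paste0(pre, "ln1_b")]] <- numeric(cfg$d)
    p[[paste0(pre, "W1")]] <- init_weight(cfg$d, cfg$ffn_dim)
    p[[paste0(pre, "b1")]] <- numeric(cfg$ffn_dim)
    p[[paste0(pre, "W2")]] <- init_weight(cfg$ffn_dim, cfg$d)
    p[[paste0(pre, "b2")]] <- numeric(cfg$d)
    p[[paste0(pre, "ln2_g")]] <- rep(1, cfg$d)
    p[[paste0(pre, "ln2_b")]] <- numeric(cfg$d)
  }
  p$head_W <- init_weight(cfg$d, n_classes)
  p$head_b <- numeric(n_classes)
  p
}

# ---- multi-head self-attention --------------------------------------------
# Token matrices are (T1 * N) x d with row index t + T1 * (n - 1), i.e. the
# T1 rows of window n are contiguous.

#' Multi-head self-attention over token sequences
#'
#' Per head: affine Q, K, V maps of the tokens, scores scaled by
#' `1 / sqrt(d_k)`, row softmax, value aggregation; heads are concatenated
#' and affinely mapped back to width d. Every attention row lies on the
#' simplex.
#'
#' @param Zm Token matrix ((T1 * N) x d), windows in contiguous row blocks.
#' @param T1 Tokens per window (sequence length).
#' @param cfg An [encoder_config()].
#' @param w Named list with `Wq, bq, Wk, bk, Wv, bv, Wo, bo`.
#' @return List with `out` ((T1 * N) x d), `attn` (T1 x T1 x heads x N
#'   array of attention weights), and `cache`.
#' @export
multi_head_attention <- function(Zm, T1, cfg, w) {
  N <- nrow(Zm) / T1
  H <- cfg$n_heads; dk <- cfg$d_k
  q <- linear_forward(Zm, w$Wq, w$bq)
  k <- linear_forward(Zm, w$Wk, w$bk)
  v <- linear_forward(Zm, w$Wv, w$bv)
  O <- matrix(0, nrow(Zm), cfg$qkv_dim)
  A <- array(0, dim = c(T1, T1, H, N))
  for (n in seq_len(N)) {
    rows <- (n - 1) * T1 + seq_len(T1)
    for (h in seq_len(H)) {
      cols <- (h - 1) * dk + seq_len(dk)
      S <- tcrossprod(q$out[rows, cols, drop = FALSE],
                      k$out[rows, cols, drop = FALSE]) / sqrt(dk)
      Ah <- softmax_rows(S)
      A[, , h, n] <- Ah
      O[rows, cols] <- Ah %*% v$out[rows, cols, drop = FALSE]
    }
  }
  pr <- linear_forward(O, w$Wo, w$bo)
  list(out = pr$out, attn = A,
       cache = list(q = q, k = k, v = v, A = A, O = O, pr = pr$cache,
                    T1 = T1, H = H, dk = dk, N = N))
}

mha_backward <- function(dout, cache) {
  T1 <- cache$T1; H <- cache$H; dk <- cache$dk; N <- cache$N
  pb <- linear_backward(dout, cache$pr)
  dO <- pb$dx
  dQ <- matrix(0, nrow(dO), H * dk)
  dK <- dQ; dV <- dQ
  for (n in seq_len(N)) {
    rows <- (n - 1) * T1 + seq_len(T1)
    for (h in seq_len(H)) {
      cols <- (h - 1) * dk + seq_len(dk)
      Ah <- cache$A[, , h, n]
      Vh <- cache$v$out[rows, cols, drop = FALSE]
      dOh <- dO[rows, cols, drop = FALSE]
      dA <- tcrossprod(dOh, Vh)
      dV[rows, cols] <- crossprod(Ah, dOh)
      dS <- Ah * (dA - rowSums(Ah * dA))
      dS <- dS / sqrt(dk)
      dQ[rows, cols] <- dS %*% cache$k$out[rows, cols, drop = FALSE]
      dK[rows, cols] <- crossprod(dS, cache$q$out[rows, cols, drop = FALSE])
    }
  }
  gq <- linear_backward(dQ, cache$q$cache)
  gk <- linear_backward(dK, cache$k$cache)
  gv <- linear_backward(dV, cache$v$cache)
  list(dx = gq$dx + gk$dx + gv$dx,
       Wq = gq$dW, bq = gq$db, Wk = gk$dW, bk = gk$db,
       Wv = gv$dW, bv = gv$db, Wo = pb$dW, bo = pb$db)
}

# ---- encoder layer ---------------------------------------------------------

#' One transformer encoder layer
#'
#' `Z_A = LayerNorm(MSA(Z) + Z)`, then
#' `out = LayerNorm(FFN(Z_A) + Z_A)` with FFN = affine -> GELU -> affine.
#'
#' @inheritParams multi_head_attention
#' @param w Named list of this layer's weights (see [tafe_init()], prefix
#'   stripped).
#' @return List with `out`, `attn`, `cache`.
#' @export
encoder_layer <- function(Zm, T1, cfg, w) {
  msa <- multi_head_attention(Zm, T1, cfg, w)
  ln1 <- layernorm_forward(msa$out + Zm, w$ln1_g, w$ln1_b)
  f1 <- linear_forward(ln1$out, w$W1, w$b1)
  g <- gelu_forward(f1$out)
  f2 <- linear_forward(g$out, w$W2, w$b2)
  ln2 <- layernorm_forward(f2$out + ln1$out, w$ln2_g, w$ln2_b)
  list(out = ln2$out, attn = msa$attn,
       cache = list(msa = msa$cache, ln1 = ln1$cache, f1 = f1$cache,
                    g = g$cache, f2 = f2$cache, ln2 = ln2$cache))
}

encoder_layer_backward <- function(dout, cache) {
  l2 <- layernorm_backward(dout, cache$ln2)
  db2 <- linear_backward(l2$dx, cache$f2)
  dg <- gelu_backward(db2$dx, cache$g)
  db1 <- linear_backward(dg, cache$f1)
  dZA <- db1$dx + l2$dx               # residual around the FFN
  l1 <- layernorm_backward(dZA, cache$ln1)
  mb <- mha_backward(l1$dx, cache$msa)
  dZ <- mb$dx + l1$dx                 # residual around the MSA
  grads <- list(ln2_g = l2$dgamma, ln2_b = l2$dbeta,
                W2 = db2$dW, b2 = db2$db, W1 = db1$dW, b1 = db1$db,
                ln1_g = l1$dgamma, ln1_b = l1$dbeta,
                Wq = mb$Wq, bq = mb$bq, Wk = mb$Wk, bk = mb$bk,
                Wv = mb$Wv, bv = mb$bv, Wo = mb$Wo, bo = mb$bo)
  list(dx = dZ, grads = grads)
}

# pull one layer's weights out of the flat parameter list
layer_weights <- function(params, l) {
  pre <- paste0("enc", l, "_")
  nm <- c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo",
          "ln1_g", "ln1_b", "W1", "b1", "W2", "b2", "ln2_g", "ln2_b")
  stats::setNames(lapply(nm, function(x) params[[paste0(pre, x)]]), nm)
}

# ---- TAFE forward / backward ----------------------------------------------

#' Temporal attention feature extractor forward pass
#'
#' Prepends the learnable class token to each window's T patch features,
#' adds the learnable positional encoding, applies the encoder stack, and
#' maps the class token's final state to class logits.
#'
#' @param feats Matrix (T * N) x d of spatial features, the T patches of
#'   each window in contiguous rows.
#' @param T_seq Patches per window.
#' @param cfg An [encoder_config()].
#' @param params Weights from [tafe_init()].
#' @return List with `logits` (N x n_classes), `attn` (last layer's
#'   attention array), and `cache`.
#' @export
tafe_forward <- function(feats, T_seq, cfg, params) {
  N <- nrow(feats) / T_seq
  if (N != round(N)) stop("ragged token count across windows", call. = FALSE)
  T1 <- T_seq + 1L
  Z <- matrix(0, T1 * N, cfg$d)
  cls_rows <- (seq_len(N) - 1) * T1 + 1L
  Z[cls_rows, ] <- matrix(params$class_token, N, cfg$d, byrow = TRUE)
  Z[-cls_rows, ] <- feats
  Z <- Z + params$pos_enc[rep(seq_len(T1), N), ]
  caches <- vector("list", cfg$n_layers)
  attn <- NULL
  for (l in seq_len(cfg$n_layers)) {
    el <- encoder_layer(Z, T1, cfg, layer_weights(params, l))
    Z <- el$out
    attn <- el$attn
    caches[[l]] <- el$cache
  }
  head <- linear_forward(Z[cls_rows, , drop = FALSE], params$head_W, params$head_b)
  list(logits = head$out, attn = attn,
       cache = list(layers = caches, head = head$cache, cls_rows = cls_rows,
                    T1 = T1, N = N, cfg = cfg))
}

tafe_backward <- function(dlogits, cache) {
  hb <- linear_backward(dlogits, cache$head)
  grads <- list(head_W = hb$dW, head_b = hb$db)
  dZ <- matrix(0, cache$T1 * cache$N, ncol(hb$dx))
  dZ[cache$cls_rows, ] <- hb$dx
  for (l in rev(seq_along(cache$layers))) {
    eb <- encoder_layer_backward(dZ, cache$layers[[l]])
    dZ <- eb$dx
    pre <- paste0("enc", l, "_")
    for (nm in names(eb$grads)) grads[[paste0(pre, nm)]] <- eb$grads[[nm]]
  }
  # positional encoding: sum over windows at each sequence index
  T1 <- cache$T1; N <- cache$N
  dpos <- matrix(0, T1, ncol(dZ))
  for (t in seq_len(T1))
    dpos[t, ] <- colSums(dZ[(seq_len(N) - 1) * T1 + t, , drop = FALSE])
  grads$pos_enc <- dpos
  grads$class_token <- matrix(colSums(dZ[cache$cls_rows, , drop = FALSE]), 1)
  grads$dfeats <- dZ[-cache$cls_rows, , drop = FALSE]
  grads
}
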