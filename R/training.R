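#' Training configuration
#'
#' Cross-entropy loss with the AdamW optimizer. Published settings:
#' learning rate 1e-4, weight decay 1e-4, batch size 32, 100 epochs. The
#' "desk" scale preset shortens training (20 epochs, learning rate 1e-3)
#' for CPU-scale runs.
#'
#' @param lr Initial learning rate.
#' @param weight_decay Decoupled weight decay.
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs per fold.
#' @param seed Integer seed controlling fold shuffling, weight
#'   initialization and batch order.
#' @param split_unit "trial" keeps all windows of a trial in one fold
#'   (leakage-safe default); "window" shuffles windows freely, which can
#'   inflate accuracy through within-trial correlation.
#' @param normalize Z-score grid values using training-fold statistics of
#'   the occupied cells (default TRUE).
#' @param scale "paper" or "desk" preset for unspecified arguments.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = NULL, weight_decay = 1e-4, batch_size = 32L,
                         epochs = NULL, seed = 1L,
                         split_unit = c("trial", "window"),
                         normalize = TRUE,
                         scale = c("paper", "desk")) {
  scale <- match.arg(scale)
  lr <- lr %||% if (scale == "paper") 1e-4 else 1e-3
  epochs <- epochs %||% if (scale == "paper") 100L else 20L
  if (epochs < 1 || batch_size < 1)
    stop("epochs and batch_size must be at least 1", call. = FALSE)
  split_unit <- match.arg(split_unit)
  if (split_unit == "window")
    warning("window-level folds let windows of one trial appear in both ",
            "train and test sets; reported accuracy will be inflated by ",
            "within-trial correlation", call. = FALSE)
  structure(list(lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 split_unit = split_unit,
                 normalize = isTRUE(normalize), scale = scale),
            class = "train_config")
}

#' Build the 5-fold cross-validation splits
#'
#' Seeded shuffle of the unit indices followed by a contiguous partition
#' into `k` near-equal subsets (sizes differ by at most one); each subset
#' serves as the test set exactly once.
#'
#' @param units Number of units (trials or windows).
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the shuffle.
#' @return List of `k` folds, each `list(fold_id, train, test)`.
#' @export
make_folds <- function(units, k = 5L, seed = 1L) {
  if (units < k)
    stop("need at least ", k, " units for ", k, "-fold CV, got ", units,
         call. = FALSE)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  idx <- sample.int(units)
  sizes <- rep(units %/% k, k)
  extra <- units %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  stops <- cumsum(sizes)
  starts <- c(1L, stops[-k] + 1L)
  lapply(seq_len(k), function(f) {
    test <- sort(idx[starts[f]:stops[f]])
    list(fold_id = f, train = sort(setdiff(seq_len(units), test)), test = test)
  })
}

#' Classification accuracy from confusion counts
#'
#' `100 * (TP + TN) / (TP + FP + TN + FN)`.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts.
#' @return Accuracy in percent.
#' @export
accuracy <- function(tp, tn, fp, fn) {
  total <- tp + tn + fp + fn
  if (any(c(tp, tn, fp, fn) < 0)) stop("negative count", call. = FALSE)
  if (total == 0) stop("undefined metric: zero total count", call. = FALSE)
  100 * (tp + tn) / total
}

#' Population standard deviation
#'
#' `sqrt(mean((x - mean(x))^2))` — divide by N, not N - 1, as used for the
#' fold-to-fold spread of cross-validation accuracies.
#'
#' @param x Numeric vector.
#' @return The population standard deviation.
#' @export
std_pop <- function(x) {
  if (length(x) < 1) stop("undefined metric: empty input", call. = FALSE)
  sqrt(mean((x - mean(x))^2))
}

# occupied-cell z-scoring statistics from training windows
grid_norm_stats <- function(v, occupied) {
  d <- dim(v)
  occ_idx <- which(occupied)
  vm <- matrix(aperm(v, c(4, 5, 1, 2, 3)), nrow = d[4] * d[5])
  vals <- vm[occ_idx, ]
  list(mu = mean(vals), sd = max(stats::sd(vals), 1e-8))
}

apply_grid_norm <- function(v, st, occupied) {
  d <- dim(v)
  mask <- aperm(array(occupied, dim = c(d[4], d[5], d[1], d[2], d[3])),
                c(3, 4, 5, 1, 2))
  v[mask] <- (v[mask] - st$mu) / st$sd
  v
}

#' Train and cross-validate one subject
#'
#' Subject-dependent 5-fold cross-validation: seeded shuffle of the units
#' (trials by default), then for each fold a fresh seeded initialization,
#' `epochs` epochs of mini-batch AdamW training with cross-entropy loss,
#' and evaluation on the held-out fold. Fully reproducible given the seed.
#'
#' @param gt A `grid_tensor` for one subject.
#' @param model_cfg An [hastf_config()].
#' @param tr_cfg A [train_config()].
#' @param k Number of folds (default 5).
#' @param verbose Print per-fold progress.
#' @return An `eval_result`: `fold_accuracy` (percent, length k), `mean`,
#'   `std` (population), `confusion` (summed over folds), `loss_history`
#'   (per fold x epoch mean training loss), `folds`.
#' @export
train_subject <- function(gt, model_cfg, tr_cfg = train_config(scale = "desk"),
                          k = 5L, verbose = FALSE) {
  stopifnot(inherits(gt, "grid_tensor"))
  labels <- gt$window_labels
  if (tr_cfg$split_unit == "trial") {
    trials <- sort(unique(gt$window_trial))
    folds <- make_folds(length(trials), k, tr_cfg$seed)
    unit_of <- match(gt$window_trial, trials)
  } else {
    folds <- make_folds(length(labels), k, tr_cfg$seed)
    unit_of <- seq_along(labels)
  }
  K <- model_cfg$n_classes
  fold_acc <- numeric(k)
  conf <- matrix(0L, K, K, dimnames = list(true = NULL, pred = NULL))
  loss_hist <- matrix(NA_real_, k, tr_cfg$epochs)
  for (f in seq_len(k)) {
    tr_idx <- which(unit_of %in% folds[[f]]$train)
    te_idx <- which(unit_of %in% folds[[f]]$test)
    if (length(unique(labels[tr_idx])) < 2)
      stop("training fold ", f, " contains a single class", call. = FALSE)
    xtr <- gt$values[tr_idx, , , , , drop = FALSE]
    xte <- gt$values[te_idx, , , , , drop = FALSE]
    if (tr_cfg$normalize) {
      st <- grid_norm_stats(xtr, gt$montage$occupied)
      xtr <- apply_grid_norm(xtr, st, gt$montage$occupied)
      xte <- apply_grid_norm(xte, st, gt$montage$occupied)
    }
    fit <- fit_hastf(xtr, labels[tr_idx], model_cfg, tr_cfg,
                     seed = tr_cfg$seed + 1000L * f)
    loss_hist[f, ] <- fit$loss
    pred <- hastf_predict(xte, model_cfg, fit$params)
    truth <- labels[te_idx]
    fold_acc[f] <- 100 * mean(pred == truth)
    for (i in seq_along(truth))
      conf[truth[i], pred[i]] <- conf[truth[i], pred[i]] + 1L
    if (verbose)
      message(sprintf("fold %d/%d: accuracy %.2f%%", f, k, fold_acc[f]))
  }
  structure(list(fold_accuracy = fold_acc, mean = mean(fold_acc),
                 std = std_pop(fold_acc), confusion = conf,
                 loss_history = loss_hist, folds = folds,
                 variant = model_cfg$variant, seed = tr_cfg$seed),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s: mean accuracy %.2f%% +/- %.2f%% over %d folds\n",
              x$variant, x$mean, x$std, length(x$fold_accuracy)))
  cat("  per fold:", paste(sprintf("%.1f", x$fold_accuracy), collapse = " "), "\n")
  invisible(x)
}

# one training run: seeded init + epochs of minibatch AdamW
fit_hastf <- function(x, labels, model_cfg, tr_cfg, seed) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  params <- hastf_init(model_cfg)
  state <- adamw_init(params)
  # biases, LayerNorm gains/offsets, class token and positional encoding
  # are exempt from weight decay
  no_decay <- grep("_b[qkvo12]?$|_g$|class_token|pos_enc",
                   names(params), value = TRUE)
  n <- length(labels)
  losses <- numeric(tr_cfg$epochs)
  for (ep in seq_len(tr_cfg$epochs)) {
    ord <- sample.int(n)
    batch_loss <- c()
    for (b0 in seq(1, n, by = tr_cfg$batch_size)) {
      sel <- ord[b0:min(b0 + tr_cfg$batch_size - 1, n)]
      fw <- hastf_forward(x[sel, , , , , drop = FALSE], model_cfg, params)
      ls <- softmax_xent(fw$logits, labels[sel])
      grads <- hastf_backward(ls$dlogits, fw$cache)
      upd <- adamw_step(params, grads, state, tr_cfg$lr, tr_cfg$weight_decay,
                        no_decay = no_decay)
      params <- upd$params
      state <- upd$state
      batch_loss <- c(batch_loss, ls$loss)
    }
    losses[ep] <- mean(batch_loss)
  }
  list(params = params, loss = losses)
}

#' Run the ablation experiment battery
#'
#' Trains each variant with identical fold splits and seeds (a paired
#' design: the index sets are bitwise identical across variants) and
#' collects per-fold accuracies.
#'
#' @param gt A `grid_tensor`.
#' @param variants Character vector of variant names (see
#'   [hastf_config()]).
#' @param tr_cfg A [train_config()].
#' @param scale Model scale preset passed to [hastf_config()].
#' @param k Folds.
#' @param verbose Print progress.
#' @return An `ablation_report`: `accuracy` (variants x folds matrix),
#'   `results` (named list of `eval_result`), `folds`.
#' @export
run_ablation <- function(gt, variants = c("All", "Wo-Sc", "Wo-SA",
                                          "Wo-UCCF", "Wo-SAFE"),
                         tr_cfg = train_config(scale = "desk"),
                         scale = "desk", k = 5L, verbose = FALSE) {
  T_seq <- dim(gt$values)[2]
  K <- gt$n_classes %||% length(unique(gt$window_labels))
  results <- list()
  acc <- matrix(NA_real_, length(variants), k,
                dimnames = list(variants, paste0("fold", seq_len(k))))
  for (v in variants) {
    cfg <- hastf_config(T_seq, K, variant = v, scale = scale)
    res <- train_subject(gt, cfg, tr_cfg, k = k, verbose = verbose)
    results[[v]] <- res
    acc[v, ] <- res$fold_accuracy
    if (verbose) message(sprintf("%-8s mean %.2f%%", v, res$mean))
  }
  structure(list(accuracy = acc, results = results,
                 folds = results[[1]]$folds, seed = tr_cfg$seed),
            class = "ablation_report")
}

#' @export
print.ablation_report <- function(x, ...) {
  cat("<ablation_report> mean accuracy per variant (%):\n")
  print(round(rowMeans(x$accuracy), 2))
  invisible(x)
}
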