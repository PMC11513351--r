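#' Extract a topographic attention map
#'
#' Summarizes the energy-based spatial attention as a 9x9 scalp map.
#' Two capture stages are available:
#'
#' * `"uccf"` — runs the spatial extractor forward on the selected windows
#'   and captures the attention applied to the UCCF output (statistics over
#'   all 81 grid positions per feature map); requires `cfg` and `params`.
#'   This is the view of what a trained model attends to.
#' * `"input"` — evaluates the attention operator directly on the DE band
#'   maps, with statistics over the occupied cells only (the map's
#'   "neurons" are then exactly the EEG channels of a frequency band).
#'   Needs no model and is deterministic in the data.
#'
#' Weights are averaged over feature maps (or bands) and patches onto the
#' grid; unoccupied montage cells are masked as NA and never contribute.
#'
#' @param gt A `grid_tensor`.
#' @param cfg,params Model configuration and weights (for stage "uccf").
#' @param stage "uccf" or "input"; defaults to "uccf" when `params` is
#'   given, else "input".
#' @param windows Integer window indices to include (default all).
#' @param quantity "weights" (mean attention weight per cell) or
#'   "refined" (mean absolute attended activation).
#' @param sa [sa_params()] for stage "input".
#' @param normalization "none" or "minmax" (rescale occupied cells to
#'   [0, 1]).
#' @return A `feature_map_grid`: `values` (9x9, NA at unoccupied cells),
#'   `montage`, `stage`, `quantity`, `normalization`, `n_windows`,
#'   `class_label`.
#' @export
extract_attention_map <- function(gt, cfg = NULL, params = NULL,
                                  stage = NULL, windows = NULL,
                                  quantity = c("weights", "refined"),
                                  sa = sa_params(),
                                  normalization = c("none", "minmax")) {
  stopifnot(inherits(gt, "grid_tensor"))
  quantity <- match.arg(quantity)
  normalization <- match.arg(normalization)
  if (is.null(stage)) stage <- if (!is.null(params)) "uccf" else "input"
  stage <- match.arg(stage, c("uccf", "input"))
  mg <- gt$montage
  if (is.null(windows)) windows <- seq_len(dim(gt$values)[1])
  v <- gt$values[windows, , , , , drop = FALSE]
  ps <- grid_to_patch_stack(v)             # (9, 9, T*n, B)
  if (stage == "uccf") {
    if (is.null(cfg) || is.null(params))
      stop("stage 'uccf' needs a model configuration and weights", call. = FALSE)
    if (!cfg$use_safe || !cfg$safe$use_sa)
      stop("this model variant has no spatial attention stage", call. = FALSE)
    h <- if (cfg$safe$use_uccf) uccf_forward(ps, cfg$safe$uccf, params)$out else ps
    at <- spatial_attention(h, cfg$safe$sa)
    m <- if (quantity == "weights") at$attention$weights else abs(at$out)
    map <- apply(m, c(1, 2), mean)
  } else {
    d <- dim(ps)
    vm <- ps
    dim(vm) <- c(d[1] * d[2], d[3] * d[4])
    occ <- which(mg$occupied)
    xo <- vm[occ, , drop = FALSE]          # channels x (bands * patches)
    st <- simam_stats(xo, sa)
    m <- if (quantity == "weights") st$w else abs(st$w * xo)
    map <- matrix(NA_real_, 9, 9)
    map[occ] <- rowMeans(m)
  }
  map[!mg$occupied] <- NA_real_
  if (normalization == "minmax") {
    rng <- range(map, na.rm = TRUE)
    if (diff(rng) > 0) map <- (map - rng[1]) / diff(rng) else map[] <- 0
    map[!mg$occupied] <- NA_real_
  }
  structure(list(values = map, montage = mg, stage = stage,
                 quantity = quantity, normalization = normalization,
                 n_windows = length(windows), class_label = NULL),
            class = "feature_map_grid")
}

#' Average attention maps by class
#'
#' Computes the cellwise mean map per class. When `subjects` is given,
#' each subject's maps are averaged first so every subject contributes
#' equally to the class mean.
#'
#' @param maps List of `feature_map_grid` objects (same montage).
#' @param labels Class code per map.
#' @param subjects Optional subject id per map.
#' @return Named list of `feature_map_grid`, one per class.
#' @export
average_by_class <- function(maps, labels, subjects = NULL) {
  stopifnot(length(maps) == length(labels))
  if (length(maps) == 0) stop("no maps", call. = FALSE)
  classes <- sort(unique(labels))
  out <- list()
  for (cl in classes) {
    sel <- which(labels == cl)
    if (length(sel) == 0) stop("empty class: ", cl, call. = FALSE)
    stack <- lapply(sel, function(i) maps[[i]]$values)
    if (!is.null(subjects)) {
      subj <- subjects[sel]
      stack <- lapply(unique(subj), function(s) {
        Reduce(`+`, stack[subj == s]) / sum(subj == s)
      })
    }
    avg <- Reduce(`+`, stack) / length(stack)
    tmpl <- maps[[sel[1]]]
    tmpl$values <- avg
    tmpl$class_label <- cl
    tmpl$n_windows <- NA_integer_
    out[[as.character(cl)]] <- tmpl
  }
  out
}

#' Render a topographic attention map to a raster image
#'
#' Draws the 9x9 map with a perceptually uniform (viridis) palette,
#' overlays channel labels at their montage positions, and leaves masked
#' cells blank. Rendering is deterministic: the same map and settings give
#' a byte-identical file.
#'
#' @param map A `feature_map_grid`.
#' @param path Output PNG path.
#' @param width,height Image size in pixels.
#' @param zlim Color limits (default the finite range of the map).
#' @param title Optional plot title.
#' @return Invisibly, a list with `path` and the `zlim` actually used.
#' @export
render_topomap <- function(map, path, width = 480, height = 480,
                           zlim = NULL, title = NULL) {
  stopifnot(inherits(map, "feature_map_grid"))
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop("cannot write to ", dir, ": no such directory", call. = FALSE)
  v <- map$values
  if (is.null(zlim)) zlim <- range(v, na.rm = TRUE)
  if (diff(zlim) == 0) zlim <- zlim + c(-0.5, 0.5)
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mar = c(1, 1, if (is.null(title)) 1 else 3, 1))
  # image() draws x along rows: transpose and flip so row 0 is at the top
  z <- t(v[nrow(v):1, ])
  graphics::image(x = 0:9, y = 0:9, z = z, zlim = zlim, axes = FALSE,
                  xlab = "", ylab = "", useRaster = FALSE,
                  col = grDevices::hcl.colors(64, "viridis"))
  if (!is.null(title)) graphics::title(main = title)
  mg <- map$montage
  for (ch in mg$channels) {
    r <- mg$rows[[ch]]; cc <- mg$cols[[ch]]
    graphics::text(cc + 0.5, 9 - r - 0.5, ch, cex = 0.7, col = "white")
  }
  graphics::par(op)
  invisible(list(path = path, zlim = zlim))
}
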