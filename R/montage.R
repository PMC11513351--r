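#' Scalp montage on a 9x9 grid
#'
#' Loads one of the shipped 10-20 electrode layouts ("deap32" for the
#' 32-channel Biosemi arrangement, "seed62" for the 62-channel ESI
#' arrangement) or a custom placement table. The grid preserves relative
#' scalp geometry: row 0 is anterior, column 0 is the left hemisphere.
#' Unoccupied cells take `fill_value`.
#'
#' @param name "deap32", "seed62", or a path to a placement file.
#' @param placement Optional data.frame `channel,row,col` (0-based indices)
#'   overriding `name`.
#' @param fill_value Value of unoccupied grid cells (default 0).
#' @return A `montage_grid`: list with `name`, `height`, `width`, `channels`
#'   (ordered names), `rows`, `cols` (0-based placements per channel), and
#'   `occupied` (logical 9x9 mask).
#' @export
#' @examples
#' mg <- montage_grid("deap32")
#' sum(mg$occupied)  # 32 occupied cells
montage_grid <- function(name = "deap32", placement = NULL, fill_value = 0) {
  if (is.null(placement)) {
    file <- if (name %in% c("deap32", "seed62")) {
      system.file("extdata", paste0("montage_", name, ".csv"), package = "hastf")
    } else name
    if (!nzchar(file) || !file.exists(file))
      stop("unknown montage: ", name, call. = FALSE)
    placement <- utils::read.csv(file, comment.char = "#",
                                 stringsAsFactors = FALSE)
  }
  stopifnot(all(c("channel", "row", "col") %in% names(placement)))
  h <- 9L; w <- 9L
  if (any(placement$row < 0 | placement$row >= h |
          placement$col < 0 | placement$col >= w))
    stop("placement indices out of the 9x9 grid", call. = FALSE)
  key <- placement$row * w + placement$col
  if (anyDuplicated(key))
    stop("two channels share a grid cell", call. = FALSE)
  if (anyDuplicated(placement$channel))
    stop("duplicated channel name in placement", call. = FALSE)
  occ <- matrix(FALSE, h, w)
  occ[cbind(placement$row + 1L, placement$col + 1L)] <- TRUE
  structure(list(
    name = if (is.null(name)) "custom" else name,
    height = h, width = w,
    channels = placement$channel,
    rows = stats::setNames(as.integer(placement$row), placement$channel),
    cols = stats::setNames(as.integer(placement$col), placement$channel),
    occupied = occ, fill_value = fill_value
  ), class = "montage_grid")
}

#' @export
print.montage_grid <- function(x, ...) {
  cat(sprintf("<montage_grid> %s: %d channels on a %dx%d grid\n",
              x$name, length(x$channels), x$height, x$width))
  invisible(x)
}

#' Map per-channel features onto the montage grid
#'
#' Places each channel's differential-entropy value at its scalp-grid cell,
#' producing per-patch band x 9 x 9 spatial maps. Unoccupied cells take the
#' montage fill value. The mapping is a bijection between channels and
#' occupied cells; [unmap_from_grid()] inverts it exactly.
#'
#' @param pt A `patch_tensor` from [build_patch_tensor()].
#' @param mg A [montage_grid()].
#' @return A `grid_tensor`: list with `values` (n x T x B x 9 x 9 array),
#'   `montage`, `band_names`, `window_labels`, `window_trial`, `subject_id`.
#' @export
map_to_grid <- function(pt, mg) {
  stopifnot(inherits(pt, "patch_tensor"), inherits(mg, "montage_grid"))
  missing <- setdiff(pt$channel_names, mg$channels)
  if (length(missing) > 0)
    stop("channels missing from montage: ", paste(missing, collapse = ", "),
         call. = FALSE)
  d <- dim(pt$values)  # n x T x B x C
  g <- array(mg$fill_value, dim = c(d[1], d[2], d[3], mg$height, mg$width))
  for (ci in seq_along(pt$channel_names)) {
    ch <- pt$channel_names[ci]
    g[, , , mg$rows[[ch]] + 1L, mg$cols[[ch]] + 1L] <- pt$values[, , , ci]
  }
  structure(list(
    values = g, montage = mg, band_names = pt$band_names,
    window_labels = pt$window_labels, window_trial = pt$window_trial,
    subject_id = pt$subject_id, n_classes = pt$n_classes
  ), class = "grid_tensor")
}

#' Recover per-channel features from a grid tensor
#'
#' Exact inverse of [map_to_grid()] on occupied cells. Nonzero values found
#' in unoccupied cells (a corrupted grid) are dropped with a warning giving
#' the count.
#'
#' @param gt A `grid_tensor`.
#' @return The `patch_tensor` it was mapped from.
#' @export
unmap_from_grid <- function(gt) {
  stopifnot(inherits(gt, "grid_tensor"))
  mg <- gt$montage
  if (!inherits(mg, "montage_grid"))
    stop("grid tensor carries no montage reference", call. = FALSE)
  d <- dim(gt$values)
  C <- length(mg$channels)
  v <- array(0, dim = c(d[1], d[2], d[3], C))
  for (ci in seq_len(C)) {
    ch <- mg$channels[ci]
    v[, , , ci] <- gt$values[, , , mg$rows[[ch]] + 1L, mg$cols[[ch]] + 1L]
  }
  # validation: unoccupied cells must hold the fill value
  n_bad <- 0L
  unocc <- which(!mg$occupied, arr.ind = TRUE)
  for (k in seq_len(nrow(unocc))) {
    cell <- gt$values[, , , unocc[k, 1], unocc[k, 2]]
    n_bad <- n_bad + sum(cell != mg$fill_value)
  }
  if (n_bad > 0)
    warning(n_bad, " nonzero values in unoccupied grid cells were dropped")
  structure(list(
    values = v, band_names = gt$band_names, channel_names = mg$channels,
    window_labels = gt$window_labels, window_trial = gt$window_trial,
    subject_id = gt$subject_id, n_classes = gt$n_classes
  ), class = "patch_tensor")
}
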