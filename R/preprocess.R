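# Normalization and tiling pipeline applied to every stack before training or
# inference.  A single extended-depth-of-field (EDF) reference image per stack
# drives triangle thresholding into foreground/background; the background mean
# is the shift factor and the 99th foreground percentile the scale factor.

#' Extended-depth-of-field reference image of a stack
#'
#' Per-pixel maximum-intensity projection across all planes.  A monotone,
#' parameter-free stand-in for wavelet-based EDF fusion: for thresholding and
#' normalization only the brightest in-focus content per pixel matters.
#'
#' @param stack an [image_stack].
#' @return an [image_plane] with `z = NA` (the EDF lives on no physical plane).
#' @export
compute_edf <- function(stack) {
  px <- stack$planes[[1L]]$pixels
  for (i in seq_along(stack$planes)[-1L]) px <- pmax(px, stack$planes[[i]]$pixels)
  image_plane(px, NA_real_)
}

#' Triangle threshold of an intensity image
#'
#' Standard triangle algorithm on an equal-width histogram: a line is drawn
#' from the histogram peak to the farthest non-empty tail bin, and the
#' threshold is the bin (between the two) whose count lies at maximal
#' perpendicular distance below that line.
#'
#' @param image an [image_plane] or numeric matrix/vector with at least two
#'   distinct values.
#' @param n_bins histogram bins; default 256 matches 8-bit display convention.
#' @return a single intensity threshold within the image's range.
#' @export
triangle_threshold <- function(image, n_bins = 256L) {
  v <- if (inherits(image, "image_plane")) as.vector(image$pixels) else as.vector(image)
  if (!is.numeric(v) || length(v) < 2L) stopf("`image` must hold at least 2 values")
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stopf("degenerate histogram: image is constant (value %g)", lo)
  check_number(n_bins, "n_bins", positive = TRUE)
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  counts <- tabulate(pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
                          n_bins), nbins = n_bins)
  centers <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  p <- which.max(counts)
  nonempty <- which(counts > 0L)
  e <- nonempty[which.max(abs(nonempty - p))]
  if (e == p) stopf("degenerate histogram: single occupied bin")
  span <- if (e > p) p:e else e:p
  # perpendicular distance from (i, counts[i]) to the peak--tail line
  x1 <- p; y1 <- counts[p]; x2 <- e; y2 <- counts[e]
  d <- abs((y2 - y1) * span - (x2 - x1) * counts[span] + x2 * y1 - y2 * x1) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  centers[span[which.max(d)]]
}

#' Normalize a stack by EDF-derived shift and scale factors
#'
#' The EDF image is triangle-thresholded into background and foreground; the
#' shift factor is the mean of the EDF background pixels and the scale factor
#' the linear-interpolation 99th percentile of the EDF foreground pixels.
#' Every plane is mapped to `(pixels - shift) / scale`.
#'
#' @param stack an [image_stack].
#' @param edf optional precomputed EDF [image_plane] for this stack; computed
#'   via [compute_edf] when missing.
#' @param n_bins histogram bins for the triangle threshold.
#' @return list with elements `stack` (the normalized [image_stack]) and
#'   `factors` (class `normalization_factors`: `shift`, `scale`, `threshold`),
#'   recorded so the affine map is invertible via [denormalize_stack].
#' @export
normalize_stack <- function(stack, edf = NULL, n_bins = 256L) {
  if (is.null(edf)) edf <- compute_edf(stack)
  thr <- triangle_threshold(edf, n_bins)
  fg <- edf$pixels[edf$pixels > thr]
  if (length(fg) == 0L) stopf("empty foreground after triangle thresholding")
  bg <- edf$pixels[edf$pixels <= thr]
  shift <- if (length(bg)) mean(bg) else min(edf$pixels)
  scale <- as.numeric(stats::quantile(fg, 0.99, type = 7))
  if (scale - shift > 1e-12 && abs(scale) < 1e-12) scale <- scale + 1e-12
  if (scale == 0) stopf("scale factor is zero")
  planes <- lapply(stack$planes, function(p)
    image_plane((p$pixels - shift) / scale, p$z))
  list(stack = image_stack(planes, stack$z_grid),
       factors = structure(list(shift = shift, scale = scale, threshold = thr),
                           class = "normalization_factors"))
}

#' Invert the normalization of [normalize_stack]
#'
#' @param stack a normalized [image_stack].
#' @param factors the `normalization_factors` recorded at normalization.
#' @return the [image_stack] on the original intensity scale.
#' @export
denormalize_stack <- function(stack, factors) {
  planes <- lapply(stack$planes, function(p)
    image_plane(p$pixels * factors$scale + factors$shift, p$z))
  image_stack(planes, stack$z_grid)
}

#' Crop a stack into non-overlapping square tiles
#'
#' All planes are cropped identically; margins that do not fill a whole tile
#' are discarded.
#'
#' @param stack an [image_stack] with planes of size m x n, both >= `tile`.
#' @param tile tile side in pixels (default 256).
#' @return list of `floor(m/tile) * floor(n/tile)` [image_stack] tiles, in
#'   row-major order of their top-left corners.
#' @export
crop_tiles <- function(stack, tile = 256L) {
  d <- dim(stack$planes[[1L]]$pixels)
  check_number(tile, "tile", positive = TRUE)
  if (tile > d[1L] || tile > d[2L])
    stopf("tile (%d) larger than image (%d x %d)", tile, d[1L], d[2L])
  nr <- d[1L] %/% tile; nc <- d[2L] %/% tile
  out <- vector("list", nr * nc)
  k <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    rows <- ((i - 1L) * tile + 1L):(i * tile)
    cols <- ((j - 1L) * tile + 1L):(j * tile)
    planes <- lapply(stack$planes, function(p)
      image_plane(p$pixels[rows, cols, drop = FALSE], p$z))
    k <- k + 1L
    out[[k]] <- image_stack(planes, stack$z_grid)
  }
  out
}
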