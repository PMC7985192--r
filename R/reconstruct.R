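# Volume inference: synthesize the image at any requested axial position from
# M acquired planes, assemble whole stacks, and choose M adaptively with a
# Frobenius-norm stopping rule.

# reflect-pad a matrix on the bottom/right to target dims
pad_reflect <- function(m, th, tw) {
  h <- nrow(m); w <- ncol(m)
  if (th > h) {
    extra <- th - h
    if (extra > h - 1L) stopf("cannot reflect-pad %d rows onto %d", extra, h)
    m <- rbind(m, m[h - seq_len(extra), , drop = FALSE])
  }
  if (tw > w) {
    extra <- tw - w
    if (extra > w - 1L) stopf("cannot reflect-pad %d cols onto %d", extra, w)
    m <- cbind(m, m[, w - seq_len(extra), drop = FALSE])
  }
  m
}

#' Reconstruct a single plane from M input planes
#'
#' Assembles the (image, DPM) sequence toward `z_out`, resets the recurrent
#' state and runs the generator in inference mode.  Images whose dimensions
#' are not divisible by `2^(K-1)` are reflect-padded to the next multiple and
#' cropped back.
#'
#' @param model a `vz_generator` (e.g. from [fit_refocus] or
#'   [load_checkpoint]).
#' @param planes non-empty list of [image_plane] inputs (any M >= 1).
#' @param z_out desired axial position (um).
#' @param ordering sequence ordering (default `"by_z"`, the training scheme).
#' @return an [image_plane] carrying `z = z_out`.
#' @export
infer_plane <- function(model, planes, z_out, ordering = "by_z") {
  stopifnot(inherits(model, "vz_generator"))
  if (length(planes) == 0L) stopf("need at least one input plane")
  sq <- assemble_sequence(planes, z_out, order = ordering,
                          scale_constant = model$config$scale_constant)
  frames <- sequence_frames(sq)
  d <- dim(frames[[1L]])
  div <- 2L^(model$config$K - 1L)
  th <- as.integer(ceiling(d[1L] / div) * div)
  tw <- as.integer(ceiling(d[2L] / div) * div)
  if (th != d[1L] || tw != d[2L]) {
    frames <- lapply(frames, function(fr) {
      out <- array(0, c(th, tw, dim(fr)[3L]))
      for (c in seq_len(dim(fr)[3L])) out[, , c] <- pad_reflect(fr[, , c], th, tw)
      out
    })
  }
  out <- gen_forward_(model, frames, train = FALSE, keep_cache = FALSE)$out
  image_plane(out[seq_len(d[1L]), seq_len(d[2L]), drop = FALSE], z_out)
}

#' Reconstruct a volume on a z grid
#'
#' One independent [infer_plane] call per grid point (there is no cross-plane
#' coupling at inference).
#'
#' @param model a `vz_generator`.
#' @param planes list of input [image_plane] objects.
#' @param z_grid strictly increasing output positions (um).
#' @param ordering sequence ordering.
#' @return an [image_stack] whose `z_grid` equals the request.
#' @export
infer_volume <- function(model, planes, z_grid, ordering = "by_z") {
  if (length(z_grid) == 0L) stopf("`z_grid` must be non-empty")
  if (length(z_grid) > 1L && any(diff(z_grid) <= 0))
    stopf("`z_grid` must be strictly increasing")
  out <- lapply(z_grid, function(z) infer_plane(model, planes, z, ordering))
  image_stack(out, z_grid)
}

#' Frobenius distance between two stacks
#'
#' @param a,b [image_stack] objects on the same grid.
#' @return `||a - b||_F` over all voxels.
#' @export
stack_frobenius <- function(a, b) {
  if (length(a$planes) != length(b$planes)) stopf("stacks differ in plane count")
  sqrt(sum(vapply(seq_along(a$planes), function(i)
    sum((a$planes[[i]]$pixels - b$planes[[i]]$pixels)^2), 0)))
}

#' Choose the number of input planes adaptively
#'
#' Reconstructs the volume after each additional input plane and stops at the
#' first M (>= 2) for which the Frobenius distance between successive volumes
#' drops to `epsilon` or below; if the bound is never met, all planes are
#' used.  Volumes are compared on the normalized-intensity scale, so
#' `epsilon` is in normalized units.
#'
#' @param model a `vz_generator`.
#' @param plane_stream list of [image_plane] objects, in acquisition order.
#' @param z_grid output grid (um).
#' @param epsilon stopping threshold (>= 0).
#' @param ordering sequence ordering.
#' @return list with `M` (chosen count), `volume` (the final [image_stack])
#'   and `distances` (Frobenius distance after each added plane).
#' @export
adaptive_M <- function(model, plane_stream, z_grid, epsilon,
                       ordering = "by_z") {
  if (length(plane_stream) == 0L) stopf("empty plane stream")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || is.na(epsilon) ||
      epsilon < 0)
    stopf("`epsilon` must be a single number >= 0 (Inf allowed)")
  prev <- infer_volume(model, plane_stream[1L], z_grid, ordering)
  if (length(plane_stream) == 1L)
    return(list(M = 1L, volume = prev, distances = numeric(0)))
  distances <- numeric(0)
  for (M in 2:length(plane_stream)) {
    cur <- infer_volume(model, plane_stream[seq_len(M)], z_grid, ordering)
    d <- stack_frobenius(cur, prev)
    distances <- c(distances, d)
    if (d <= epsilon)
      return(list(M = M, volume = cur, distances = distances))
    prev <- cur
  }
  list(M = length(plane_stream), volume = prev, distances = distances)
}
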