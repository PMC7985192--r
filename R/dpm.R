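# Digital propagation matrices (DPMs) and M-plane input sequences.  A DPM is a
# constant-valued matrix paired with an input image as its second channel; its
# value encodes the signed axial distance from that image's plane to the
# desired output plane.  Sign convention: dz = z_target - z_input (propagating
# towards larger z is positive).  Values are divided by `scale_constant`
# (default 10 um) when materialized so the DPM channel is O(1) alongside
# normalized images.

#' Construct a digital propagation matrix
#'
#' @param z_input axial position of the input plane (um).
#' @param z_target desired output plane (um).
#' @param dims (m, n) dimensions of the materialized matrix.
#' @param scale_constant normalizer (um) applied when materializing.
#' @return an object of class `dpm` with fields `value` (dz in um), `dims`,
#'   `scale_constant`.
#' @export
make_dpm <- function(z_input, z_target, dims, scale_constant = 10) {
  check_number(z_input, "z_input"); check_number(z_target, "z_target")
  check_number(scale_constant, "scale_constant", positive = TRUE)
  if (length(dims) != 2L || any(dims < 1)) stopf("`dims` must be (m, n)")
  structure(list(value = z_target - z_input, dims = as.integer(dims),
                 scale_constant = scale_constant), class = "dpm")
}

#' Materialize a DPM as its constant matrix
#'
#' @param dpm a [make_dpm] object.
#' @return an m x n matrix filled with `value / scale_constant`.
#' @export
materialize_dpm <- function(dpm) {
  matrix(dpm$value / dpm$scale_constant, dpm$dims[1L], dpm$dims[2L])
}

#' Assemble an M-plane input sequence for one target plane
#'
#' Pairs every input plane with a DPM toward `target_z` and orders the
#' entries.  `by_z` sorts ascending in z (the scheme used for training);
#' `by_abs_dz_desc` sorts by decreasing |dz| with ties broken by ascending z;
#' `given` preserves the supplied order.
#'
#' @param planes list of [image_plane] objects with identical dimensions.
#' @param target_z desired output plane (um).
#' @param order one of `"by_z"`, `"by_abs_dz_desc"`, `"given"`.
#' @param scale_constant DPM normalizer (um).
#' @return an object of class `input_sequence` with fields `entries` (list of
#'   `list(plane, dpm)`), `target_z`, `order`, `scale_constant`.
#' @export
assemble_sequence <- function(planes, target_z,
                              order = c("by_z", "by_abs_dz_desc", "given"),
                              scale_constant = 10) {
  order <- match.arg(order)
  if (length(planes) < 1L) stopf("need at least one input plane")
  check_number(target_z, "target_z")
  d1 <- dim(planes[[1L]]$pixels)
  for (p in planes) {
    if (!inherits(p, "image_plane")) stopf("all inputs must be image_plane objects")
    if (!identical(dim(p$pixels), d1)) stopf("input planes have mismatched dimensions")
  }
  zs <- vapply(planes, function(p) p$z, 0)
  idx <- switch(order,
    by_z = order(zs),
    by_abs_dz_desc = order(-abs(target_z - zs), zs),
    given = seq_along(planes))
  entries <- lapply(idx, function(i)
    list(plane = planes[[i]],
         dpm = make_dpm(zs[i], target_z, d1, scale_constant)))
  structure(list(entries = entries, target_z = target_z, order = order,
                 scale_constant = scale_constant), class = "input_sequence")
}

#' @export
print.input_sequence <- function(x, ...) {
  zs <- vapply(x$entries, function(e) e$plane$z, 0)
  cat(sprintf("<input_sequence M = %d, input z = (%s) um, target z = %g um>\n",
              length(x$entries), paste(format(zs), collapse = ", "), x$target_z))
  invisible(x)
}

#' Sequence tensor layout M x m x n x 2
#'
#' Channel 1 holds the image, channel 2 the materialized DPM.
#'
#' @param seq an `input_sequence`.
#' @return a numeric array of dimension `c(M, m, n, 2)`.
#' @export
sequence_tensor <- function(seq) {
  M <- length(seq$entries)
  d <- dim(seq$entries[[1L]]$plane$pixels)
  out <- array(0, c(M, d[1L], d[2L], 2L))
  for (t in seq_len(M)) {
    out[t, , , 1L] <- seq$entries[[t]]$plane$pixels
    out[t, , , 2L] <- materialize_dpm(seq$entries[[t]]$dpm)
  }
  out
}

# internal: list of M arrays [m, n, 2] (the network's preferred layout)
sequence_frames <- function(seq) {
  lapply(seq$entries, function(e) {
    d <- dim(e$plane$pixels)
    fr <- array(0, c(d, 2L))
    fr[, , 1L] <- e$plane$pixels
    fr[, , 2L] <- materialize_dpm(e$dpm)
    fr
  })
}

#' Inject axial-positioning noise into a sequence's DPMs
#'
#' Emulates uncontrolled stage drift: each input's DPM is shifted by a single
#' i.i.d. Gaussian scalar `z_d ~ N(0, sigma^2)` applied uniformly to the whole
#' matrix (the perturbation times an all-one matrix).  Images are untouched.
#'
#' @param seq an `input_sequence`.
#' @param sigma noise SD in um (>= 0); `sigma = 0` returns the input unchanged.
#' @param seed integer seed making the draw deterministic.
#' @return a new `input_sequence` with perturbed DPM values.
#' @export
inject_dpm_noise <- function(seq, sigma, seed = 1L) {
  check_number(sigma, "sigma")
  if (sigma < 0) stopf("`sigma` must be >= 0")
  if (sigma == 0) return(seq)
  draws <- with_seed(derive_seed(seed, "dpm-noise"),
                     stats::rnorm(length(seq$entries), 0, sigma))
  out <- seq
  for (t in seq_along(out$entries))
    out$entries[[t]]$dpm$value <- out$entries[[t]]$dpm$value + draws[t]
  out
}

#' Permute the entries of an input sequence
#'
#' Entries travel with their DPMs attached.
#'
#' @param seq an `input_sequence` of length M.
#' @param permutation a bijection on `1..M`.
#' @return the reordered `input_sequence` (order field becomes `"given"`).
#' @export
permute_sequence <- function(seq, permutation) {
  M <- length(seq$entries)
  if (length(permutation) != M || !setequal(permutation, seq_len(M)))
    stopf("`permutation` must be a bijection on 1..%d", M)
  out <- seq
  out$entries <- seq$entries[permutation]
  out$order <- "given"
  out
}

#' Repeat one plane into a length-M sequence
#'
#' Used by the repetition-invariance protocol: M identical (image, DPM) pairs
#' all pointing at the same target plane.
#'
#' @param plane an [image_plane].
#' @param M repetition count (>= 1).
#' @param target_z desired output plane (um).
#' @param scale_constant DPM normalizer (um).
#' @return an `input_sequence` of length M with identical entries.
#' @export
repeat_plane <- function(plane, M, target_z, scale_constant = 10) {
  check_number(M, "M", positive = TRUE)
  seq1 <- assemble_sequence(list(plane), target_z, order = "given",
                            scale_constant = scale_constant)
  out <- seq1
  out$entries <- rep(seq1$entries, M)
  out
}
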