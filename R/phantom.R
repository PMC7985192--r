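# Synthetic wide-field image formation: fluorophore phantoms rendered through
# a depth-dependent Gaussian defocus PSF, with optional shot + read noise.
# Every downstream module (preprocessing, training, metrics) is exercised on
# stacks produced here, so the forward model is kept simple and analytic.

#' Construct a 2D image plane with its axial position
#'
#' @param pixels numeric matrix (m x n) of non-negative-ish intensities.
#' @param z absolute axial position in micrometres.  The sentinel `NA` marks
#'   derived images that live on no physical plane (e.g. EDF projections).
#' @return an object of class `image_plane` with fields `pixels` and `z`.
#' @export
image_plane <- function(pixels, z) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stopf("`pixels` must be a numeric matrix")
  if (any(!is.finite(pixels))) stopf("`pixels` must be finite")
  if (nrow(pixels) < 16L || ncol(pixels) < 16L)
    stopf("image planes must be at least 16 x 16 pixels (got %d x %d)",
          nrow(pixels), ncol(pixels))
  if (!(length(z) == 1L && (is.na(z) || is.finite(z))))
    stopf("`z` must be a single number (or NA for derived images)")
  structure(list(pixels = pixels, z = as.numeric(z)), class = "image_plane")
}

#' @export
print.image_plane <- function(x, ...) {
  cat(sprintf("<image_plane %d x %d, z = %s um, range [%.4g, %.4g]>\n",
              nrow(x$pixels), ncol(x$pixels),
              ifelse(is.na(x$z), "NA", format(x$z)),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Construct an ordered z-stack of image planes
#'
#' @param planes list of [image_plane] objects, ordered to match `z_grid`.
#' @param z_grid strictly increasing axial positions (um), one per plane.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(planes, z_grid) {
  if (length(planes) == 0L) stopf("a stack needs at least one plane")
  if (length(planes) != length(z_grid))
    stopf("|planes| (%d) != |z_grid| (%d)", length(planes), length(z_grid))
  if (length(z_grid) > 1L && any(diff(z_grid) <= 0))
    stopf("`z_grid` must be strictly increasing")
  d1 <- dim(planes[[1L]]$pixels)
  for (i in seq_along(planes)) {
    if (!inherits(planes[[i]], "image_plane")) stopf("all planes must be image_plane objects")
    if (!identical(dim(planes[[i]]$pixels), d1)) stopf("all planes must share dimensions")
    if (!isTRUE(all.equal(planes[[i]]$z, z_grid[i])))
      stopf("plane %d has z = %g but z_grid says %g", i, planes[[i]]$z, z_grid[i])
  }
  structure(list(planes = planes, z_grid = as.numeric(z_grid)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$planes[[1L]]$pixels)
  cat(sprintf("<image_stack %d planes, %d x %d, z in [%g, %g] um>\n",
              length(x$planes), d[1L], d[2L], min(x$z_grid), max(x$z_grid)))
  invisible(x)
}

#' Wide-field optics model for the defocus simulator
#'
#' A separable Gaussian PSF whose width grows with defocus as
#' \deqn{\sigma(dz) = \sigma_0 \sqrt{1 + (dz / z_R)^2}.}
#' The axial scale `z_R` is the defocus at which the PSF variance doubles; the
#' default 0.2 um puts the +-z_R band at 0.4 um, emulating the shallow
#' depth-of-field of a 63x/1.4NA-class oil objective.  `sigma0 = 0.2` um gives
#' an in-focus FWHM of 2*sqrt(2 ln 2)*0.2 = 0.47 um, the scale observed for
#' sub-resolution beads through such a lens.
#'
#' @param sigma0 in-focus Gaussian PSF radius (um).
#' @param z_R axial blur length scale (um); the effective DOF is `2 * z_R`.
#' @param background mean background level (arbitrary intensity units).
#' @param read_noise_sd SD of additive Gaussian read noise.
#' @param photon_scale gain converting intensity units to expected photon
#'   counts for Poisson shot noise.
#' @param pixel_size lateral sampling (um / pixel); default 0.1 um matches
#'   63x-class magnification.
#' @return an object of class `optics_model`.
#' @export
optics_model <- function(sigma0 = 0.2, z_R = 0.2, background = 0.05,
                         read_noise_sd = 0.01, photon_scale = 200,
                         pixel_size = 0.1) {
  check_number(sigma0, "sigma0", positive = TRUE)
  check_number(z_R, "z_R", positive = TRUE)
  check_number(background, "background", nonneg = TRUE)
  check_number(read_noise_sd, "read_noise_sd", nonneg = TRUE)
  check_number(photon_scale, "photon_scale", positive = TRUE)
  check_number(pixel_size, "pixel_size", positive = TRUE)
  structure(list(sigma0 = sigma0, z_R = z_R, background = background,
                 read_noise_sd = read_noise_sd, photon_scale = photon_scale,
                 pixel_size = pixel_size),
            class = "optics_model")
}

#' Depth-of-field of an optics model
#'
#' The axial range over which the PSF variance is within a factor two of its
#' in-focus value, i.e. `2 * z_R`.
#' @param optics an [optics_model].
#' @return DOF in micrometres.
#' @export
depth_of_field <- function(optics) 2 * optics$z_R

#' Defocus-dependent PSF width
#'
#' @param dz signed axial distance from focus (um); the width is even in `dz`.
#' @param optics an [optics_model].
#' @return Gaussian radius sigma(dz) in micrometres.
#' @export
defocus_sigma <- function(dz, optics) {
  optics$sigma0 * sqrt(1 + (dz / optics$z_R)^2)
}

#' Generate a random bead phantom
#'
#' Point-like fluorophores (emulating sub-diffraction nanobeads) placed
#' uniformly at random inside a rectangular volume.
#'
#' @param n_beads number of beads (>= 0).
#' @param volume_extent numeric triple (X, Y, Z) in micrometres.
#' @param intensity_range (lo, hi) photon-scale intensities, lo > 0.
#' @param seed integer seed; placement is deterministic given the seed.
#' @param margin lateral margin (um) kept free of beads at the volume edge so
#'   that blurred spots stay inside the field of view.
#' @return an object of class `bead_phantom` with fields `positions`
#'   (n x 3 matrix of x, y, z in um), `intensities`, `volume_extent`,
#'   `pixel_size` placeholder (set when rendering) and `name`.
#' @export
generate_bead_phantom <- function(n_beads, volume_extent,
                                  intensity_range = c(0.5, 1),
                                  seed = 1L, margin = 0) {
  check_number(n_beads, "n_beads", nonneg = TRUE)
  if (length(volume_extent) != 3L || any(!is.finite(volume_extent)) ||
      any(volume_extent <= 0))
    stopf("`volume_extent` must be three positive numbers (X, Y, Z) in um")
  if (length(intensity_range) != 2L || intensity_range[1L] <= 0 ||
      diff(intensity_range) < 0)
    stopf("`intensity_range` must be (lo, hi) with 0 < lo <= hi")
  check_number(margin, "margin", nonneg = TRUE)
  pos <- with_seed(derive_seed(seed, "phantom"), {
    cbind(x = runif(n_beads, margin, volume_extent[1L] - margin),
          y = runif(n_beads, margin, volume_extent[2L] - margin),
          z = runif(n_beads, 0, volume_extent[3L]))
  })
  ints <- with_seed(derive_seed(seed, "phantom-intensity"),
                    runif(n_beads, intensity_range[1L], intensity_range[2L]))
  structure(list(positions = pos, intensities = ints,
                 volume_extent = as.numeric(volume_extent),
                 name = sprintf("beads-n%d-seed%d", n_beads, as.integer(seed))),
            class = "bead_phantom")
}

#' Generate a filament phantom (worm-like structures)
#'
#' Random cubic Bezier curves in 3D, densely sampled into point emitters so
#' the bead renderer can be reused.  Emulates filamentous / neuronal
#' structures; beads alone are used for the quantitative harness.
#'
#' @param n_filaments number of curves.
#' @param volume_extent (X, Y, Z) in um.
#' @param intensity_per_um fluorophore intensity per um of curve length.
#' @param seed integer seed.
#' @param step_um sampling step along each curve (um).
#' @return a `bead_phantom` whose emitters trace the filaments.
#' @export
generate_filament_phantom <- function(n_filaments, volume_extent,
                                      intensity_per_um = 2, seed = 1L,
                                      step_um = 0.05) {
  check_number(n_filaments, "n_filaments", nonneg = TRUE)
  if (length(volume_extent) != 3L || any(volume_extent <= 0))
    stopf("`volume_extent` must be three positive numbers")
  check_number(intensity_per_um, "intensity_per_um", positive = TRUE)
  pts <- with_seed(derive_seed(seed, "filament"), {
    out <- vector("list", n_filaments)
    for (f in seq_len(n_filaments)) {
      ctrl <- cbind(runif(4, 0.1, 0.9) * volume_extent[1L],
                    runif(4, 0.1, 0.9) * volume_extent[2L],
                    runif(4, 0.1, 0.9) * volume_extent[3L])
      tt <- seq(0, 1, length.out = 200L)
      bez <- outer((1 - tt)^3, ctrl[1L, ]) + outer(3 * (1 - tt)^2 * tt, ctrl[2L, ]) +
        outer(3 * (1 - tt) * tt^2, ctrl[3L, ]) + outer(tt^3, ctrl[4L, ])
      seg <- sqrt(rowSums(diff(bez)^2))
      arc <- c(0, cumsum(seg))
      s <- seq(0, max(arc), by = step_um)
      out[[f]] <- cbind(approx(arc, bez[, 1L], s)$y,
                        approx(arc, bez[, 2L], s)$y,
                        approx(arc, bez[, 3L], s)$y)
    }
    do.call(rbind, out)
  })
  if (is.null(pts)) pts <- matrix(numeric(0), 0L, 3L)
  colnames(pts) <- c("x", "y", "z")
  structure(list(positions = pts,
                 intensities = rep(intensity_per_um * step_um, nrow(pts)),
                 volume_extent = as.numeric(volume_extent),
                 name = sprintf("filaments-n%d-seed%d", n_filaments, as.integer(seed))),
            class = "bead_phantom")
}

#' Render one wide-field plane of a phantom
#'
#' Each emitter contributes a separable 2D Gaussian of radius
#' `defocus_sigma(z - z_bead)` whose integral equals the emitter intensity
#' (blur conserves energy; only boundary truncation loses signal).  With
#' `noise = TRUE`, Poisson shot noise at `photon_scale` and additive Gaussian
#' read noise are applied, deterministically for a given seed.
#'
#' @param phantom a `bead_phantom`.
#' @param z axial position of the focal plane (um).  A plane far outside the
#'   volume (beyond a margin of half the axial extent plus 2 um) triggers a
#'   warning and renders background only.
#' @param optics an [optics_model].
#' @param noise logical; add shot + read noise.
#' @param seed integer seed for the noise draw.
#' @return an [image_plane].
#' @export
render_plane <- function(phantom, z, optics, noise = FALSE, seed = 1L) {
  check_number(z, "z")
  ext <- phantom$volume_extent
  px <- optics$pixel_size
  n <- max(16L, round(ext[1L] / px))  # columns ~ x
  m <- max(16L, round(ext[2L] / px))  # rows ~ y
  img <- matrix(optics$background, m, n)
  margin <- 0.5 * ext[3L] + 2
  if (z < -margin || z > ext[3L] + margin) {
    warning(sprintf("plane z = %g um is far outside the volume [0, %g]; rendering background only",
                    z, ext[3L]))
  } else if (nrow(phantom$positions) > 0L) {
    xc <- (seq_len(n) - 0.5) * px
    yc <- (seq_len(m) - 0.5) * px
    for (b in seq_len(nrow(phantom$positions))) {
      bx <- phantom$positions[b, 1L]; by <- phantom$positions[b, 2L]
      bz <- phantom$positions[b, 3L]
      sig <- defocus_sigma(z - bz, optics)
      half <- max(5 * sig, 3 * px)
      jj <- which(abs(xc - bx) <= half)
      ii <- which(abs(yc - by) <= half)
      if (!length(jj) || !length(ii)) next
      amp <- phantom$intensities[b] * px^2 / (2 * pi * sig^2)
      gy <- exp(-(yc[ii] - by)^2 / (2 * sig^2))
      gx <- exp(-(xc[jj] - bx)^2 / (2 * sig^2))
      img[ii, jj] <- img[ii, jj] + amp * (gy %o% gx)
    }
  }
  if (noise) {
    img <- with_seed(derive_seed(seed, "render-noise"), {
      shot <- rpois(length(img), lambda = pmax(img, 0) * optics$photon_scale) /
        optics$photon_scale
      matrix(shot + rnorm(length(img), 0, optics$read_noise_sd), m, n)
    })
    img <- pmax(img, 0)
  }
  image_plane(img, z)
}

#' Render a full z-stack of a phantom
#'
#' @param phantom a `bead_phantom`.
#' @param z_grid strictly increasing focal positions (um).
#' @param optics an [optics_model].
#' @param noise logical; add noise per plane.
#' @param seed integer seed; per-plane noise streams are derived from it.
#' @return an [image_stack] with one plane per grid point.
#' @export
render_stack <- function(phantom, z_grid, optics, noise = FALSE, seed = 1L) {
  if (length(z_grid) == 0L) stopf("`z_grid` must be non-empty")
  if (length(z_grid) > 1L && any(diff(z_grid) <= 0))
    stopf("`z_grid` must be strictly increasing")
  planes <- lapply(seq_along(z_grid), function(i) {
    render_plane(phantom, z_grid[i], optics, noise = noise,
                 seed = derive_seed(seed, paste0("plane", i)))
  })
  image_stack(planes, z_grid)
}

# Stack IO -------------------------------------------------------------------

#' Write an image stack as multi-page TIFF plus CSV sidecar
#'
#' Intensities are mapped affinely into [0, 1] before float storage (the TIFF
#' writer clips outside that range); the mapping is recorded in the sidecar
#' columns `offset,scale` so [read_stack] restores the original values to
#' 32-bit float precision.
#'
#' @param stack an [image_stack].
#' @param tiff_path output TIFF file.
#' @param csv_path output CSV sidecar (`plane_index,z_um,offset,scale`).
#' @return invisibly, the sidecar data frame.
#' @export
write_stack <- function(stack, tiff_path, csv_path) {
  lo <- min(vapply(stack$planes, function(p) min(p$pixels), 0))
  hi <- max(vapply(stack$planes, function(p) max(p$pixels), 0))
  scale <- max(hi - lo, 1e-12)
  pages <- lapply(stack$planes, function(p) (p$pixels - lo) / scale)
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 32L)
  sidecar <- data.frame(plane_index = seq_along(stack$planes),
                        z_um = stack$z_grid, offset = lo, scale = scale)
  utils::write.csv(sidecar, csv_path, row.names = FALSE)
  invisible(sidecar)
}

#' Read an image stack written by [write_stack]
#'
#' @param tiff_path multi-page TIFF file.
#' @param csv_path CSV sidecar with `plane_index,z_um` and optional
#'   `offset,scale` columns (missing columns default to the identity map).
#' @return an [image_stack].
#' @export
read_stack <- function(tiff_path, csv_path) {
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  sidecar <- utils::read.csv(csv_path)
  if (length(pages) != nrow(sidecar))
    stopf("TIFF has %d pages but sidecar lists %d planes",
          length(pages), nrow(sidecar))
  off <- if ("offset" %in% names(sidecar)) sidecar$offset[1L] else 0
  sc <- if ("scale" %in% names(sidecar)) sidecar$scale[1L] else 1
  ord <- order(sidecar$z_um)
  planes <- lapply(ord, function(i) {
    px <- pages[[sidecar$plane_index[i]]]
    if (length(dim(px)) == 3L) px <- px[, , 1L]
    image_plane(px * sc + off, sidecar$z_um[i])
  })
  image_stack(planes, sidecar$z_um[ord])
}

# 3D array view of a stack: dims (m, n, n_planes)
stack_array <- function(stack) {
  d <- dim(stack$planes[[1L]]$pixels)
  arr <- array(0, c(d, length(stack$planes)))
  for (i in seq_along(stack$planes)) arr[, , i] <- stack$planes[[i]]$pixels
  arr
}
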