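# Quantitative evaluation: image-fidelity metrics (NRMSE, PSNR, ROI-RMSE),
# bead FWHM characterization with Gaussian fits and KL histogram comparison,
# axial-permutation statistics, and the DPM noise stability sweep.

as_pixels <- function(x) {
  if (inherits(x, "image_plane")) x$pixels else as.matrix(x)
}

#' Normalized root-mean-square error (percent)
#'
#' RMSE normalized by the reference dynamic range, times 100.
#'
#' @param x test image (matrix or [image_plane]).
#' @param y reference image of identical size.
#' @return NRMSE in percent.
#' @export
nrmse <- function(x, y) {
  x <- as_pixels(x); y <- as_pixels(y)
  if (!identical(dim(x), dim(y))) stopf("images differ in size")
  r <- max(y) - min(y)
  if (r <= 0) stopf("reference image has zero dynamic range")
  100 * sqrt(mean((x - y)^2)) / r
}

#' Peak signal-to-noise ratio (dB)
#'
#' `10 log10(R^2 / MSE)` with R the reference dynamic range.  Identical
#' images return `Inf`.
#'
#' @param x test image.
#' @param y reference image of identical size.
#' @return PSNR in decibels.
#' @export
psnr <- function(x, y) {
  x <- as_pixels(x); y <- as_pixels(y)
  if (!identical(dim(x), dim(y))) stopf("images differ in size")
  r <- max(y) - min(y)
  if (r <= 0) stopf("reference image has zero dynamic range")
  mse <- mean((x - y)^2)
  if (mse == 0) return(Inf)
  10 * log10(r^2 / mse)
}

#' RMSE over a region of interest on the 0-255 display scale
#'
#' Both images are mapped to the display scale with the reference's affine
#' map (`(v - min(y)) / range(y) * 255`) so that the two are compared in the
#' same display units, then the RMSE is taken over the ROI pixels.
#'
#' @param x test image.
#' @param y reference image.
#' @param roi logical mask of the same size, or `NULL` for the full image.
#' @return RMSE in display units (0-255 scale).
#' @export
roi_rmse <- function(x, y, roi = NULL) {
  x <- as_pixels(x); y <- as_pixels(y)
  if (!identical(dim(x), dim(y))) stopf("images differ in size")
  if (is.null(roi)) roi <- matrix(TRUE, nrow(x), ncol(x))
  if (!identical(dim(roi), dim(x))) stopf("`roi` mask must match image size")
  if (!any(roi)) stopf("empty ROI")
  r <- max(y) - min(y)
  if (r <= 0) stopf("reference image has zero dynamic range")
  to_display <- function(v) (v - min(y)) / r * 255
  sqrt(mean((to_display(x)[roi] - to_display(y)[roi])^2))
}

#' Measure bead FWHM distributions in a plane
#'
#' Detects isolated local maxima above a relative threshold, rejects beads
#' with a neighbor closer than the exclusion radius, fits 1D Gaussians to the
#' x and y line profiles through each peak, and reports per-bead FWHM
#' (`2 sqrt(2 ln 2) * sigma`, averaged over the two axes) in micrometres.
#'
#' @param plane an [image_plane] or matrix.
#' @param pixel_size um per pixel.
#' @param threshold_rel detection threshold as a fraction of the
#'   background-to-peak range (default 0.3).
#' @param exclusion_radius_px minimum allowed distance to the nearest other
#'   detection (default 10 px).
#' @param half_window half-width of the fitted line profile (default 7 px).
#' @return an object of class `fwhm_report`: `fwhm_um` (per-bead values),
#'   `mean_fwhm`, `centers` (n x 2 matrix), `count`.
#' @export
bead_fwhm <- function(plane, pixel_size = 0.1, threshold_rel = 0.3,
                      exclusion_radius_px = 10, half_window = 7L) {
  img <- as_pixels(plane)
  bg <- stats::median(img)
  thr <- bg + threshold_rel * (max(img) - bg)
  h <- nrow(img); w <- ncol(img)
  # strict local maxima over the 8-neighborhood, away from the border
  cand <- NULL
  pad <- half_window
  for (i in (pad + 1L):(h - pad)) for (j in (pad + 1L):(w - pad)) {
    v <- img[i, j]
    if (v <= thr) next
    nb <- img[(i - 1L):(i + 1L), (j - 1L):(j + 1L)]
    if (v >= max(nb) && sum(nb == v) == 1L) cand <- rbind(cand, c(i, j))
  }
  empty <- structure(list(fwhm_um = numeric(0), mean_fwhm = NA_real_,
                          centers = matrix(numeric(0), 0L, 2L), count = 0L),
                     class = "fwhm_report")
  if (is.null(cand)) {
    warning("no beads detected")
    return(empty)
  }
  keep <- rep(TRUE, nrow(cand))
  if (nrow(cand) > 1L) {
    dd <- as.matrix(stats::dist(cand))
    diag(dd) <- Inf
    keep <- apply(dd, 1L, min) > exclusion_radius_px
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) {
    warning("all detections rejected by the exclusion radius")
    return(empty)
  }
  fit_axis <- function(prof) {
    n <- length(prof)
    idx <- seq_len(n)
    st <- list(a = max(prof) - min(prof), mu = which.max(prof),
               s = max(1, sum(prof > (min(prof) + max(prof)) / 2) / 2.355),
               b = min(prof))
    fit <- try(minpack.lm::nlsLM(prof ~ b + a * exp(-(idx - mu)^2 / (2 * s^2)),
                                 start = st,
                                 lower = c(a = 0, mu = 1, s = 0.3, b = -Inf),
                                 upper = c(a = Inf, mu = n, s = n, b = Inf),
                                 control = minpack.lm::nls.lm.control(maxiter = 100)),
               silent = TRUE)
    if (inherits(fit, "try-error")) return(NA_real_)
    abs(stats::coef(fit)[["s"]])
  }
  fwhm <- rep(NA_real_, nrow(cand))
  for (b in seq_len(nrow(cand))) {
    i <- cand[b, 1L]; j <- cand[b, 2L]
    sx <- fit_axis(img[i, (j - half_window):(j + half_window)])
    sy <- fit_axis(img[(i - half_window):(i + half_window), j])
    fwhm[b] <- 2 * sqrt(2 * log(2)) * mean(c(sx, sy), na.rm = TRUE) * pixel_size
  }
  ok <- is.finite(fwhm) & fwhm > 0
  structure(list(fwhm_um = fwhm[ok], mean_fwhm = mean(fwhm[ok]),
                 centers = cand[ok, , drop = FALSE], count = sum(ok)),
            class = "fwhm_report")
}

#' Shared-bin histograms of two samples
#'
#' Equal-width bins spanning the pooled range of both samples, for KL
#' comparison of e.g. FWHM distributions.
#'
#' @param x,y numeric samples.
#' @param n_bins number of bins (default 30).
#' @return list with `p`, `q` (counts) and `edges`.
#' @export
shared_histogram <- function(x, y, n_bins = 30L) {
  rng <- range(c(x, y))
  if (diff(rng) <= 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  bin <- function(v) tabulate(pmin(pmax(findInterval(v, edges,
                                                     rightmost.closed = TRUE),
                                        1L), n_bins), nbins = n_bins)
  list(p = bin(x), q = bin(y), edges = edges)
}

#' Kullback-Leibler divergence between two histograms
#'
#' `sum p log(p / q)` in nats after add-epsilon smoothing and
#' renormalization.  Inputs may be counts or probabilities on shared bins.
#'
#' @param h_p,h_q numeric vectors of equal length (shared bin edges).
#' @param eps smoothing constant added to every bin before renormalization
#'   (default 1e-4).
#' @return KL divergence in nats (>= 0).
#' @export
histogram_kl <- function(h_p, h_q, eps = 1e-4) {
  if (length(h_p) != length(h_q)) stopf("histograms must share bins")
  if (any(h_p < 0) || any(h_q < 0)) stopf("histogram entries must be >= 0")
  p <- h_p / sum(h_p) + eps; p <- p / sum(p)
  q <- h_q / sum(h_q) + eps; q <- q / sum(q)
  sum(p * log(p / q))
}

# all permutations of 1..n (n small)
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_permutations(n - 1L)) {
      rest <- setdiff(seq_len(n), i)
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

#' Permutation statistics of a reconstruction
#'
#' Reconstructs the volume for every permutation of the M input planes (each
#' plane travelling with its DPM) and reports, per output plane, the mean and
#' population standard deviation of the ROI-RMSE against ground truth across
#' permutations, plus the pixel-wise SD map across permutations.
#'
#' @param model a `vz_generator`.
#' @param planes list of M input [image_plane] objects (M = 3 gives the six
#'   permutations of the standard protocol).
#' @param z_grid output grid (um).
#' @param ground_truth an [image_stack] on the same grid.
#' @param roi logical mask or `NULL` (full image).
#' @param max_permutations guard on M! (default 24); larger M errors,
#'   advising sampling.
#' @return list with `mu_rmse`, `sigma_rmse` (per grid point), `rmse`
#'   (permutations x planes matrix), `sd_map` (h x w x planes array) and
#'   `permutations`.
#' @export
permutation_stats <- function(model, planes, z_grid, ground_truth, roi = NULL,
                              max_permutations = 24L) {
  M <- length(planes)
  nperm <- factorial(M)
  if (nperm > max_permutations)
    stopf("M = %d gives %d permutations (> %d); sample a subset instead",
          M, nperm, max_permutations)
  if (length(ground_truth$planes) != length(z_grid))
    stopf("ground truth grid does not match `z_grid`")
  perms <- all_permutations(M)
  base <- assemble_sequence(planes, 0, order = "given")  # ordering template
  vols <- vector("list", nperm)
  R <- matrix(0, nperm, length(z_grid))
  for (p in seq_len(nperm)) {
    ordered <- planes[perms[[p]]]
    vols[[p]] <- infer_volume(model, ordered, z_grid, ordering = "given")
    for (i in seq_along(z_grid))
      R[p, i] <- roi_rmse(vols[[p]]$planes[[i]], ground_truth$planes[[i]], roi)
  }
  mu <- colMeans(R)
  sig <- sqrt(colMeans(sweep(R, 2L, mu)^2))
  d <- dim(planes[[1L]]$pixels)
  sd_map <- array(0, c(d, length(z_grid)))
  for (i in seq_along(z_grid)) {
    stackp <- vapply(vols, function(v) v$planes[[i]]$pixels,
                     matrix(0, d[1L], d[2L]))
    mu_map <- apply(stackp, c(1L, 2L), mean)
    sd_map[, , i] <- sqrt(apply(sweep(stackp, c(1L, 2L), mu_map)^2,
                                c(1L, 2L), mean))
  }
  list(mu_rmse = mu, sigma_rmse = sig, rmse = R, sd_map = sd_map,
       permutations = perms)
}

#' DPM axial-noise stability sweep
#'
#' For each noise level sigma, perturbs every input plane's recorded axial
#' position by an i.i.d. Gaussian draw (equivalently, shifts its DPM by a
#' constant), reconstructs the volume, and records the NRMSE per evaluated
#' plane against ground truth, over `n_trials` independent trials (50 in the
#' standard protocol).
#'
#' @param model a `vz_generator`.
#' @param planes list of input [image_plane] objects.
#' @param z_grid output grid (um).
#' @param ground_truth an [image_stack] on the same grid.
#' @param sigmas noise SDs in um (>= 0).
#' @param n_trials trials per sigma (default 50).
#' @param seed integer seed.
#' @return data frame with columns `sigma`, `trial`, `z`, `nrmse`.
#' @export
stability_sweep <- function(model, planes, z_grid, ground_truth,
                            sigmas = c(0, 0.25, 0.5, 1), n_trials = 50L,
                            seed = 1L) {
  if (any(sigmas < 0)) stopf("`sigmas` must be >= 0")
  check_number(n_trials, "n_trials", positive = TRUE)
  zs <- vapply(planes, function(p) p$z, 0)
  planes <- planes[order(zs)]
  zs <- sort(zs)
  out <- NULL
  for (s in sigmas) {
    for (tr in seq_len(n_trials)) {
      if (s == 0) {
        pert <- planes
      } else {
        zd <- with_seed(derive_seed(seed, sprintf("sweep-%g-%d", s, tr)),
                        stats::rnorm(length(planes), 0, s))
        # adding zd to the DPM equals subtracting it from the recorded z
        pert <- lapply(seq_along(planes), function(i)
          image_plane(planes[[i]]$pixels, zs[i] - zd[i]))
      }
      vol <- infer_volume(model, pert, z_grid, ordering = "given")
      for (i in seq_along(z_grid))
        out <- rbind(out, data.frame(sigma = s, trial = tr, z = z_grid[i],
                                     nrmse = nrmse(vol$planes[[i]],
                                                   ground_truth$planes[[i]])))
    }
  }
  out
}
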