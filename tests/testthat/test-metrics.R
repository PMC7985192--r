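# NRMSE/PSNR/ROI-RMSE, bead FWHM measurement, KL histogram divergence,
# permutation statistics, stability sweep.

test_that("nrmse and psnr follow the closed-form arithmetic", {
  x <- matrix(seq(0, 1, length.out = 64), 8, 8)  # unit-range reference
  expect_equal(nrmse(x, x), 0)
  expect_equal(psnr(x, x), Inf)
  # constant offset 0.1 on a range-1 image: MSE 0.01, PSNR 20 dB, NRMSE 10
  y <- x + 0.1
  expect_equal(psnr(y, x), 20)
  expect_equal(nrmse(y, x), 10)
  # symmetric when ranges agree
  a <- x; b <- 1 - x
  expect_equal(nrmse(a, b), nrmse(b, a))
  expect_error(nrmse(x, matrix(0.5, 8, 8)), "dynamic range")
  # invariance to a common affine rescaling (range-based normalization)
  s <- 7.3; o <- -2.1
  expect_equal(nrmse(s * y + o, s * x + o), nrmse(y, x))
  expect_equal(psnr(s * y + o, s * x + o), psnr(y, x))
})

test_that("roi_rmse works on the display scale", {
  y <- matrix(seq(0, 1, length.out = 16), 4, 4)
  expect_equal(roi_rmse(y, y), 0)
  # ROI of 4 pixels with display-scale differences (0, 0, 0, 2) -> RMSE 1
  x <- y
  x[2, 2] <- y[2, 2] + 2 / 255
  roi <- matrix(FALSE, 4, 4); roi[1:2, 1:2] <- TRUE
  expect_equal(roi_rmse(x, y, roi), 1)
  # full-image ROI equals plain display-scale RMSE
  x2 <- y + matrix(rnorm(16, 0, 0.01), 4, 4)
  expect_equal(roi_rmse(x2, y),
               sqrt(mean(((x2 - y) / (max(y) - min(y)) * 255)^2)))
  expect_error(roi_rmse(x, y, matrix(FALSE, 4, 4)), "empty ROI")
})

test_that("bead FWHM recovers planted Gaussian widths", {
  px <- 0.1
  mkplane <- function(sig_px, centers) {
    img <- matrix(0.05, 64, 64)
    for (k in seq_len(nrow(centers))) {
      i0 <- centers[k, 1]; j0 <- centers[k, 2]
      for (i in -10:10) for (j in -10:10)
        img[i0 + i, j0 + j] <- img[i0 + i, j0 + j] +
          exp(-(i^2 + j^2) / (2 * sig_px^2))
    }
    image_plane(img, 0)
  }
  # linearity across sigma = 1, 2, 3 px (linear-fit oracle)
  sig <- c(1, 2, 3)
  got <- vapply(sig, function(s) {
    bead_fwhm(mkplane(s, cbind(32, 32)), pixel_size = px)$mean_fwhm
  }, 0)
  want <- 2 * sqrt(2 * log(2)) * sig * px
  expect_true(all(abs(got - want) / want < 0.05))
  expect_gt(stats::cor(got, sig)^2, 0.99)

  # exclusion radius: two close beads both rejected, one far pair kept
  close2 <- mkplane(1.5, rbind(c(30, 30), c(30, 36), c(12, 50)))
  rep2 <- bead_fwhm(close2, pixel_size = px, exclusion_radius_px = 10)
  expect_equal(rep2$count, 1L)
  # brute-force pairwise-distance oracle agrees
  cen <- rbind(c(30, 30), c(30, 36), c(12, 50))
  dd <- as.matrix(dist(cen)); diag(dd) <- Inf
  expect_equal(sum(apply(dd, 1, min) > 10), 1L)

  expect_warning(e <- bead_fwhm(image_plane(matrix(0.1, 32, 32) +
                                              1e-6 * diag(32), 0)),
                 "no beads")
  expect_equal(e$count, 0L)
})

test_that("histogram KL matches hand arithmetic and the Gibbs bound", {
  expect_equal(histogram_kl(c(3, 7), c(3, 7)), 0)
  # hand case (0.5, 0.5) vs (0.9, 0.1), smoothing vanishes at this scale
  v <- histogram_kl(c(0.5, 0.5), c(0.9, 0.1))
  want <- 0.5 * log(0.5 / 0.9) + 0.5 * log(0.5 / 0.1)
  expect_lt(abs(v - want), 1e-3)
  set.seed(8)
  for (i in 1:50) {
    p <- rmultinom(1, 200, runif(10))[, 1]
    q <- rmultinom(1, 200, runif(10))[, 1]
    expect_gte(histogram_kl(p, q), 0)
  }
  expect_error(histogram_kl(1:3, 1:4), "share bins")
  # smoothing sensitivity vanishes on well-populated histograms
  p <- rmultinom(1, 5000, runif(10) + 0.5)[, 1]
  q <- rmultinom(1, 5000, runif(10) + 0.5)[, 1]
  k1 <- histogram_kl(p, q, eps = 1e-4)
  k2 <- histogram_kl(p, q, eps = 1e-5)
  expect_lt(abs(k1 - k2) / max(k1, 1e-12), 0.01)
})

test_that("shared histograms bin both samples on pooled edges", {
  h <- shared_histogram(c(1, 2, 3), c(2, 3, 4), n_bins = 3)
  expect_equal(sum(h$p), 3); expect_equal(sum(h$q), 3)
  expect_equal(length(h$edges), 4L)
  expect_equal(range(h$edges), c(1, 4))
})

test_that("permutation statistics match an enumeration oracle and vanish for
           a permutation-blind model", {
  gen <- tiny_gen(K = 2, base = 2)
  set.seed(21)
  pl <- lapply(c(0, 1, 2), function(z)
    image_plane(matrix(runif(256), 16, 16), z))
  zg <- c(0.5, 1.5)
  gt <- image_stack(lapply(zg, function(z)
    image_plane(matrix(runif(256), 16, 16), z)), zg)
  ps <- permutation_stats(gen, pl, zg, gt)
  expect_equal(dim(ps$rmse), c(6L, 2L))
  expect_length(ps$permutations, 6L)
  # independent loop oracle over an explicitly enumerated permutation list
  perml <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  R <- matrix(0, 6, 2)
  for (p in seq_along(perml)) {
    vol <- infer_volume(gen, pl[perml[[p]]], zg, ordering = "given")
    for (i in 1:2) R[p, i] <- roi_rmse(vol$planes[[i]], gt$planes[[i]])
  }
  # same multiset of rows (permutation enumeration order may differ)
  expect_equal(sort(ps$rmse[, 1]), sort(R[, 1]), tolerance = 1e-10)
  mu <- colMeans(R); sig <- sqrt(colMeans(sweep(R, 2, mu)^2))
  expect_lt(max(abs(ps$mu_rmse - mu)), 1e-10)
  expect_lt(max(abs(ps$sigma_rmse - sig)), 1e-10)

  # a permutation-blind stub (constant output) gives sigma_rmse exactly 0:
  # feed M identical planes so every permutation is the same sequence
  pl_same <- lapply(c(0, 1, 2), function(z) image_plane(pl[[1]]$pixels, z))
  # constant-output stub: zero all weights including the head
  stub <- tiny_gen(K = 2, base = 2)
  stub$params <- vrefocus:::zero_like_tree(stub$params)
  ps0 <- permutation_stats(stub, pl, zg, gt)
  expect_lt(max(ps0$sigma_rmse), 1e-12)
  expect_lt(max(ps0$sd_map), 1e-12)

  expect_error(permutation_stats(gen, c(pl, pl), zg, gt), "permutations")
})

test_that("stability sweep at sigma 0 reproduces the baseline bit-exactly", {
  gen <- tiny_gen(K = 2, base = 2)
  set.seed(31)
  pl <- lapply(c(0, 1, 2), function(z)
    image_plane(matrix(runif(256), 16, 16), z))
  zg <- c(0.6, 1.4)
  gt <- image_stack(lapply(zg, function(z)
    image_plane(matrix(runif(256), 16, 16), z)), zg)
  base_vol <- infer_volume(gen, pl, zg, ordering = "given")
  sw <- stability_sweep(gen, pl, zg, gt, sigmas = 0, n_trials = 3, seed = 1)
  for (i in seq_along(zg)) {
    want <- nrmse(base_vol$planes[[i]], gt$planes[[i]])
    expect_identical(unique(sw$nrmse[sw$z == zg[i]]), want)
  }
  # default protocol size: 50 trials per sigma
  expect_equal(formals(stability_sweep)$n_trials, 50L)
  # seeded determinism of the noisy branch
  s1 <- stability_sweep(gen, pl, zg, gt, sigmas = 0.5, n_trials = 2, seed = 9)
  s2 <- stability_sweep(gen, pl, zg, gt, sigmas = 0.5, n_trials = 2, seed = 9)
  expect_identical(s1, s2)
})
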