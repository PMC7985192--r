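# Composite training objective: reverse-Huber (BerHu) pixel loss, multi-scale
# structural similarity, and least-squares adversarial terms, plus the
# discriminator's own loss.  Each term is evaluated exactly (no stochastic
# approximation) and carries an analytic gradient used by the trainer.

#' Loss weights and constants
#'
#' @param alpha weight of the BerHu term (default 3).
#' @param beta weight of the structural term `1 - MSSSIM` (default 1).
#' @param gamma weight of the adversarial term (default 0.5).
#' @param berhu_c BerHu threshold on the per-pixel residual (default 0.1 on
#'   the normalized intensity scale).
#' @param msssim_levels number of dyadic scales (default 5).
#' @param data_range dynamic range L entering the SSIM stability constants
#'   `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`, `C3 = C2 / 2` (default 1, the
#'   normalized scale).
#' @return a list of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 3, beta = 1, gamma = 0.5, berhu_c = 0.1,
                         msssim_levels = 5L, data_range = 1) {
  for (nm in c("alpha", "beta", "gamma"))
    check_number(get(nm), nm, nonneg = TRUE)
  check_number(berhu_c, "berhu_c", positive = TRUE)
  check_number(msssim_levels, "msssim_levels", positive = TRUE)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, berhu_c = berhu_c,
                 msssim_levels = as.integer(msssim_levels),
                 data_range = data_range),
            class = "loss_weights")
}

# canonical 5-level exponents; for fewer levels the leading ones are
# renormalized to sum to 1 (the luminance exponent is the coarsest weight)
msssim_weights <- function(levels) {
  w5 <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)
  if (levels > 5L) stopf("at most 5 scales are supported")
  w <- w5[seq_len(levels)]
  w / sum(w)
}

#' Reverse-Huber (BerHu) loss
#'
#' Per-pixel: `|e|` when `|e| <= c`, `(e^2 + c^2) / (2c)` otherwise; the two
#' branches agree at `|e| = c`, so the penalty is continuous (and convex).
#'
#' @param x,y numeric arrays of identical shape (prediction, reference).
#' @param c threshold on the per-pixel residual (> 0).
#' @param reduction `"sum"` (the printed form) or `"mean"` (per-pixel
#'   normalized, used inside the training objective so `c` and the term
#'   weights are crop-size independent).
#' @return a non-negative scalar.
#' @export
berhu <- function(x, y, c = 0.1, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  if (c <= 0) stopf("`c` must be > 0")
  if (!identical(dim(x), dim(y)) || length(x) != length(y))
    stopf("`x` and `y` must have identical shape")
  e <- abs(x - y)
  v <- ifelse(e <= c, e, (e^2 + c^2) / (2 * c))
  if (reduction == "sum") sum(v) else mean(v)
}

# gradient of berhu wrt x
berhu_grad <- function(x, y, c = 0.1, reduction = "sum") {
  e <- x - y
  g <- ifelse(abs(e) <= c, sign(e), e / c)
  if (reduction == "mean") g <- g / length(e)
  g
}

# Gaussian window used for local SSIM statistics (sums to 1)
ssim_window <- function(size = 11L, sigma = 1.5) {
  r <- seq_len(size) - (size + 1) / 2
  g <- exp(-r^2 / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

gfilter <- function(x, w) EBImage::filter2(x, w, boundary = "replicate")

# 2x2 average-pool downsampling (odd trailing row/col cropped)
avgpool2 <- function(x) {
  h <- nrow(x) - nrow(x) %% 2L; w <- ncol(x) - ncol(x) %% 2L
  x <- x[seq_len(h), seq_len(w), drop = FALSE]
  (x[seq(1L, h, 2L), seq(1L, w, 2L)] + x[seq(2L, h, 2L), seq(1L, w, 2L)] +
     x[seq(1L, h, 2L), seq(2L, w, 2L)] + x[seq(2L, h, 2L), seq(2L, w, 2L)]) / 4
}

# adjoint of avgpool2 into an image of size (h, w)
avgpool2_bwd <- function(d, h, w) {
  out <- matrix(0, h, w)
  h2 <- nrow(d) * 2L; w2 <- ncol(d) * 2L
  q <- d / 4
  out[seq(1L, h2, 2L), seq(1L, w2, 2L)] <- q
  out[seq(2L, h2, 2L), seq(1L, w2, 2L)] <- out[seq(2L, h2, 2L), seq(1L, w2, 2L)] + q
  out[seq(1L, h2, 2L), seq(2L, w2, 2L)] <- out[seq(1L, h2, 2L), seq(2L, w2, 2L)] + q
  out[seq(2L, h2, 2L), seq(2L, w2, 2L)] <- out[seq(2L, h2, 2L), seq(2L, w2, 2L)] + q
  out
}

# Multi-scale SSIM with optional gradient wrt x.  Local statistics use an
# 11 x 11 Gaussian window (sigma 1.5); means are taken over the window-valid
# interior so boundary handling cancels exactly in the gradient.  With
# C3 = C2 / 2 the contrast * structure product collapses to the standard
# cs = (2 cov + C2) / (varx + vary + C2) term.
msssim_ <- function(x, y, levels, data_range, grad = FALSE) {
  win <- ssim_window()
  half <- (nrow(win) - 1L) %/% 2L
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  minside <- 2L^(levels - 1L) * nrow(win)
  if (min(dim(x)) < minside)
    stopf("image too small for %d scales (needs >= %d px per side); use fewer levels",
          levels, minside)
  wts <- msssim_weights(levels)
  xs <- vector("list", levels); ys <- vector("list", levels)
  xs[[1L]] <- x; ys[[1L]] <- y
  for (j in seq_len(levels - 1L)) {
    xs[[j + 1L]] <- avgpool2(xs[[j]])
    ys[[j + 1L]] <- avgpool2(ys[[j]])
  }
  terms <- numeric(levels + 1L)   # cs_1..cs_L, then luminance
  stats <- vector("list", levels)
  for (j in seq_len(levels)) {
    xj <- xs[[j]]; yj <- ys[[j]]
    mx <- gfilter(xj, win); my <- gfilter(yj, win)
    vx <- gfilter(xj^2, win) - mx^2
    vy <- gfilter(yj^2, win) - my^2
    cxy <- gfilter(xj * yj, win) - mx * my
    B <- vx + vy + C2
    cs <- (2 * cxy + C2) / B
    mask <- matrix(0, nrow(xj), ncol(xj))
    mask[(half + 1L):(nrow(xj) - half), (half + 1L):(ncol(xj) - half)] <- 1
    N <- sum(mask)
    terms[j] <- sum(cs * mask) / N
    if (grad) stats[[j]] <- list(mx = mx, my = my, B = B, cs = cs,
                                 mask = mask, N = N)
    if (j == levels) {
      Bl <- mx^2 + my^2 + C1
      l <- (2 * mx * my + C1) / Bl
      terms[levels + 1L] <- sum(l * mask) / N
      if (grad) stats[[j]]$lum <- list(Bl = Bl, l = l)
    }
  }
  eps <- 1e-6
  tcl <- pmax(terms, eps)   # clamp: powers of near-zero/negative terms
  value <- prod(tcl[seq_len(levels)]^wts) * tcl[levels + 1L]^wts[levels]
  if (!grad) return(list(value = value))
  # dvalue/dterm_j = value * w_j / term_j (zero where clamped)
  dterm <- numeric(levels + 1L)
  for (j in seq_len(levels))
    dterm[j] <- if (terms[j] > eps) value * wts[j] / tcl[j] else 0
  dterm[levels + 1L] <- if (terms[levels + 1L] > eps)
    value * wts[levels] / tcl[levels + 1L] else 0
  glev <- vector("list", levels)
  for (j in seq_len(levels)) {
    st <- stats[[j]]
    xj <- xs[[j]]; yj <- ys[[j]]
    mB <- st$mask / st$B
    gj <- (2 / st$N) * (yj * gfilter(mB, win) - gfilter(mB * st$my, win) -
                          xj * gfilter(mB * st$cs, win) +
                          gfilter(mB * st$cs * st$mx, win)) * dterm[j]
    if (j == levels) {
      lu <- st$lum
      mBl <- st$mask / lu$Bl
      gj <- gj + (2 / st$N) * (gfilter(mBl * st$my, win) -
                                 gfilter(mBl * lu$l * st$mx, win)) *
        dterm[levels + 1L]
    }
    glev[[j]] <- gj
  }
  g <- glev[[levels]]
  for (j in rev(seq_len(levels - 1L)))
    g <- glev[[j]] + avgpool2_bwd(g, nrow(xs[[j]]), ncol(xs[[j]]))
  list(value = value, grad = g)
}

#' Multi-scale structural similarity index
#'
#' Product of window-averaged contrast-structure terms over dyadically
#' down-sampled scales with a luminance term at the coarsest scale, using the
#' canonical 5-level exponents (renormalized when fewer levels are used).
#'
#' @param x,y numeric matrices of identical size.
#' @param levels number of dyadic scales (each side must be at least
#'   `2^(levels-1) * 11` pixels).
#' @param data_range dynamic range for the stability constants.
#' @return a scalar in (0, 1]; 1 iff `x == y`.
#' @export
msssim <- function(x, y, levels = 5L, data_range = 1) {
  if (!identical(dim(x), dim(y))) stopf("`x` and `y` must have identical size")
  msssim_(as.matrix(x), as.matrix(y), as.integer(levels), data_range)$value
}

#' Composite generator loss
#'
#' `alpha * BerHu + beta * (1 - MSSSIM) + gamma * (D(y_hat) - 1)^2`.  The
#' structural similarity enters as a dissimilarity `1 - MSSSIM` so that
#' minimizing the loss maximizes similarity; the BerHu term uses the mean
#' reduction so the weights are crop-size independent.
#'
#' @param y_hat predicted image (matrix).
#' @param y ground-truth image (matrix).
#' @param d_score discriminator score of `y_hat`, in (0, 1); use 1 to switch
#'   the adversarial term off.
#' @param weights a [loss_weights].
#' @return list with `total` and the individual `berhu`, `msssim`, `adv`
#'   components.
#' @export
generator_loss <- function(y_hat, y, d_score = 1, weights = loss_weights()) {
  lb <- berhu(y_hat, y, weights$berhu_c, reduction = "mean")
  lm <- msssim(y_hat, y, weights$msssim_levels, weights$data_range)
  la <- (d_score - 1)^2
  list(total = weights$alpha * lb + weights$beta * (1 - lm) + weights$gamma * la,
       berhu = lb, msssim = lm, adv = la)
}

#' Least-squares discriminator loss
#'
#' `0.5 * D(y_hat)^2 + 0.5 * (D(y) - 1)^2`: zero exactly at perfect
#' discrimination (fake -> 0, real -> 1).
#'
#' @param d_fake discriminator score of the generated image.
#' @param d_real discriminator score of the ground truth.
#' @return a non-negative scalar.
#' @export
discriminator_loss <- function(d_fake, d_real) {
  0.5 * d_fake^2 + 0.5 * (d_real - 1)^2
}
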