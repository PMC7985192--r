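# Independent straight-from-formula loss oracles (no code shared with the
# package implementation): explicit window-offset accumulation for local
# statistics, separate contrast and structure terms, loop-based downsampling.

# literal zero-padded same-convolution by explicit loops (independent oracle)
naive_conv <- function(x, Wmat, b = NULL) {
  ks <- attr(Wmat, "kshape")
  kh <- ks[1]; kw <- ks[2]; cin <- ks[3]; cout <- ks[4]
  d <- dim(x); h <- d[1]; w <- d[2]
  out <- array(0, c(h, w, cout))
  for (u in seq_len(cout)) {
    for (i in seq_len(h)) for (j in seq_len(w)) {
      acc <- 0
      for (di in seq_len(kh)) for (dj in seq_len(kw)) for (c in seq_len(cin)) {
        ii <- i + di - (kh + 1) / 2; jj <- j + dj - (kw + 1) / 2
        if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) {
          # rows of Wmat are ordered channel-fastest within each offset
          r <- ((dj - 1) * kh + (di - 1)) * cin + c
          acc <- acc + x[ii, jj, c] * Wmat[r, u]
        }
      }
      out[i, j, u] <- acc + if (is.null(b)) 0 else b[u]
    }
  }
  out
}

berhu_oracle <- function(x, y, c) {
  tot <- 0
  for (i in seq_along(x)) {
    e <- abs(x[i] - y[i])
    tot <- tot + if (e <= c) e else (e^2 + c^2) / (2 * c)
  }
  tot
}

msssim_oracle <- function(x, y, levels, data_range = 1) {
  size <- 11L; sigma <- 1.5
  r <- seq_len(size) - (size + 1) / 2
  g <- exp(-r^2 / (2 * sigma^2))
  win <- outer(g, g); win <- win / sum(win)
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  C3 <- C2 / 2
  w5 <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)
  wts <- w5[seq_len(levels)]; wts <- wts / sum(wts)
  down2 <- function(m) {
    h <- nrow(m) - nrow(m) %% 2L; w <- ncol(m) - ncol(m) %% 2L
    out <- matrix(0, h / 2, w / 2)
    for (i in seq_len(h / 2)) for (j in seq_len(w / 2))
      out[i, j] <- mean(m[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
    out
  }
  local_stats <- function(a, b) {
    h <- nrow(a); w <- ncol(a); half <- (size - 1L) / 2L
    ma <- matrix(0, h, w); mb <- ma; maa <- ma; mbb <- ma; mab <- ma
    for (di in -half:half) for (dj in -half:half) {
      wt <- win[di + half + 1L, dj + half + 1L]
      ri <- (half + 1L):(h - half); rj <- (half + 1L):(w - half)
      ma[ri, rj] <- ma[ri, rj] + wt * a[ri + di, rj + dj]
      mb[ri, rj] <- mb[ri, rj] + wt * b[ri + di, rj + dj]
      maa[ri, rj] <- maa[ri, rj] + wt * a[ri + di, rj + dj]^2
      mbb[ri, rj] <- mbb[ri, rj] + wt * b[ri + di, rj + dj]^2
      mab[ri, rj] <- mab[ri, rj] + wt * a[ri + di, rj + dj] * b[ri + di, rj + dj]
    }
    ri <- (half + 1L):(h - half); rj <- (half + 1L):(w - half)
    list(mx = ma[ri, rj], my = mb[ri, rj],
         vx = maa[ri, rj] - ma[ri, rj]^2, vy = mbb[ri, rj] - mb[ri, rj]^2,
         cxy = mab[ri, rj] - ma[ri, rj] * mb[ri, rj])
  }
  val <- 1
  for (j in seq_len(levels)) {
    st <- local_stats(x, y)
    sx <- sqrt(pmax(st$vx, 0)); sy <- sqrt(pmax(st$vy, 0))
    contrast <- (2 * sx * sy + C2) / (st$vx + st$vy + C2)
    structure_ <- (st$cxy + C3) / (sx * sy + C3)
    val <- val * mean(contrast * structure_)^wts[j]
    if (j == levels) {
      lum <- (2 * st$mx * st$my + C1) / (st$mx^2 + st$my^2 + C1)
      val <- val * mean(lum)^wts[levels]
    }
    if (j < levels) { x <- down2(x); y <- down2(y) }
  }
  val
}
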