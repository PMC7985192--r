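# Least-squares GAN discriminator: five convolutional blocks (two 3x3 conv
# layers of width base * 2^k each, ReLU, 2x2 max-pool), global average
# pooling, a 20-unit ReLU dense layer and a sigmoid output unit.

#' Discriminator architecture configuration
#'
#' @param n_blocks convolutional blocks; default 5.
#' @param base_channels width multiplier; block k has `base * 2^k` channels
#'   (default 20 gives 40..640).
#' @param hidden_units width of the first dense layer; default 20.
#' @param input_channels input image channels; default 1.
#' @return a list of class `vz_disc_config`.
#' @export
disc_config <- function(n_blocks = 5L, base_channels = 20L, hidden_units = 20L,
                        input_channels = 1L) {
  check_number(n_blocks, "n_blocks", positive = TRUE)
  check_number(base_channels, "base_channels", positive = TRUE)
  structure(list(n_blocks = as.integer(n_blocks),
                 base_channels = as.integer(base_channels),
                 hidden_units = as.integer(hidden_units),
                 input_channels = as.integer(input_channels)),
            class = "vz_disc_config")
}

#' Initialize a discriminator with random weights
#'
#' @param config a [disc_config].
#' @param seed integer seed.
#' @return an object of class `vz_discriminator`.
#' @export
init_discriminator <- function(config, seed = 1L) {
  stopifnot(inherits(config, "vz_disc_config"))
  with_seed(derive_seed(seed, "disc-init"), {
    blocks <- vector("list", config$n_blocks)
    cin <- config$input_channels
    for (k in seq_len(config$n_blocks)) {
      ck <- config$base_channels * 2L^k
      blocks[[k]] <- list(conv1 = conv_param(3L, 3L, cin, ck),
                          conv2 = conv_param(3L, 3L, ck, ck))
      cin <- ck
    }
    names(blocks) <- paste0("k", seq_len(config$n_blocks))
    dense1 <- list(W = matrix(stats::rnorm(cin * config$hidden_units, 0,
                                           sqrt(2 / cin)),
                              cin, config$hidden_units),
                   b = numeric(config$hidden_units))
    dense2 <- list(W = matrix(stats::rnorm(config$hidden_units, 0,
                                           sqrt(1 / config$hidden_units)),
                              config$hidden_units, 1L),
                   b = numeric(1L))
    structure(list(config = config,
                   params = list(blocks = blocks, dense1 = dense1,
                                 dense2 = dense2)),
              class = "vz_discriminator")
  })
}

disc_forward_ <- function(model, x, keep_cache = FALSE) {
  cfg <- model$config; P <- model$params
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  d <- dim(x)
  if (d[1L] < 2L^cfg$n_blocks || d[2L] < 2L^cfg$n_blocks)
    stopf("discriminator input must be at least %d pixels per side",
          2L^cfg$n_blocks)
  caches <- if (keep_cache) vector("list", cfg$n_blocks)
  for (k in seq_len(cfg$n_blocks)) {
    a1 <- conv_fwd(x, P$blocks[[k]]$conv1)
    r1 <- relu_fwd(a1)
    a2 <- conv_fwd(r1, P$blocks[[k]]$conv2)
    r2 <- relu_fwd(a2)
    mp <- maxpool_fwd(r2)
    if (keep_cache)
      caches[[k]] <- list(x = x, a1 = a1, r1 = r1, a2 = a2, r2 = r2,
                          pool = mp$cache)
    x <- mp$out
  }
  dpool <- dim(x)
  gap <- colMeans(matrix(x, dpool[1L] * dpool[2L], dpool[3L]))
  z1 <- as.vector(gap %*% P$dense1$W) + P$dense1$b
  h1 <- pmax(z1, 0)
  z2 <- sum(h1 * P$dense2$W) + P$dense2$b
  score <- sigmoid(z2)
  cache <- if (keep_cache)
    list(blocks = caches, gap = gap, z1 = z1, h1 = h1, z2 = z2,
         score = score, dpool = dpool)
  list(score = as.numeric(score), cache = cache)
}

# backward: dscore is dLoss/dscore; returns grads tree and dLoss/dinput
disc_backward_ <- function(model, cache, dscore) {
  P <- model$params; cfg <- model$config
  G <- zero_like_tree(P)
  dz2 <- dscore * cache$score * (1 - cache$score)
  G$dense2$W <- matrix(cache$h1 * dz2, ncol = 1L)
  G$dense2$b <- dz2
  dh1 <- as.vector(P$dense2$W) * dz2
  dz1 <- dh1 * (cache$z1 > 0)
  G$dense1$W <- outer(cache$gap, dz1)
  G$dense1$b <- dz1
  dgap <- as.vector(P$dense1$W %*% dz1)
  dp <- cache$dpool
  npix <- dp[1L] * dp[2L]
  dx <- array(rep(dgap / npix, each = npix), dp)
  for (k in rev(seq_len(cfg$n_blocks))) {
    ck <- cache$blocks[[k]]
    dr2 <- maxpool_bwd(dx, ck$pool)
    da2 <- relu_bwd(dr2, ck$a2)
    c2 <- conv_bwd(da2, ck$r1, P$blocks[[k]]$conv2)
    G$blocks[[k]]$conv2$W <- c2$dW; G$blocks[[k]]$conv2$b <- c2$db
    da1 <- relu_bwd(c2$dx, ck$a1)
    c1 <- conv_bwd(da1, ck$x, P$blocks[[k]]$conv1)
    G$blocks[[k]]$conv1$W <- c1$dW; G$blocks[[k]]$conv1$b <- c1$db
    dx <- c1$dx
  }
  list(grads = G, dinput = dx[, , 1L])
}

#' Discriminator score for an image
#'
#' @param model a `vz_discriminator`.
#' @param image numeric matrix (or (h, w, 1) array), at least `2^n_blocks`
#'   pixels per side.
#' @return a score strictly in (0, 1).
#' @export
discriminator_forward <- function(model, image) {
  stopifnot(inherits(model, "vz_discriminator"))
  if (inherits(image, "image_plane")) image <- image$pixels
  disc_forward_(model, image)$score
}
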