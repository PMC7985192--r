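# Shared fixtures: tiny architectures and phantoms built in code.

tiny_gen <- function(K = 3L, base = 2L, seed = 3L) {
  init_generator(gen_config(K = K, base_channels = base), seed = seed)
}

tiny_frames <- function(M, side = 16L, seed = 1L, channels = 2L) {
  set.seed(seed)
  lapply(seq_len(M), function(t) array(rnorm(side * side * channels),
                                       c(side, side, channels)))
}

tiny_disc <- function(n_blocks = 3L, base = 2L, seed = 5L) {
  init_discriminator(disc_config(n_blocks = n_blocks, base_channels = base),
                     seed = seed)
}

# small single-bead phantom near the lateral centre, on a pixel centre
# (0.1 um sampling) so the rendered peak is a strict local maximum
one_bead_phantom <- function(z_bead, extent = c(3.2, 3.2, 2), intensity = 1) {
  structure(list(positions = cbind(x = extent[1] / 2 + 0.05,
                                   y = extent[2] / 2 + 0.05,
                                   z = z_bead),
                 intensities = intensity,
                 volume_extent = extent, name = "one-bead"),
            class = "bead_phantom")
}

# a quick 16x16-plane stack with a clean foreground/background split
toy_stack <- function(n_planes = 3L, side = 32L, fg = 10, bg = 1) {
  planes <- lapply(seq_len(n_planes), function(i) {
    px <- matrix(bg, side, side)
    px[(4 * i):(4 * i + 3), 5:10] <- fg + i
    image_plane(px, i)
  })
  image_stack(planes, seq_len(n_planes))
}

# numeric gradient of f at x (arrays), central differences on a few entries
num_grad_at <- function(f, x, idx, eps = 1e-6) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, 0)
}
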