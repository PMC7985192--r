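# The recurrent generator: cascaded encoder blocks -> per-scale convolutional
# GRU recurrent blocks -> decoder blocks.  The M (image, DPM) input frames
# pass one by one through the shared encoder, each updating the per-scale GRU
# hidden states; after the last frame the decoder consumes the aggregated
# features and a linear 1x1 head emits the refocused image.  The weight count
# is independent of M by construction: M never appears in the architecture.

#' Generator architecture configuration
#'
#' Channel widths follow `base * 2^(k-2)` and `base * 2^(k-1)` for the two
#' convolutions of encoder block k >= 2; the stem (k = 1) uses `base` for both
#' and applies no pooling, so a K-scale network pools K - 1 times.  The GRU at
#' scale k has hidden width equal to that scale's feature width, which the
#' residual aggregation `s_k = x_k + Conv1x1(GRU(x_k))` requires.
#'
#' @param K number of scales (>= 2); default 5.
#' @param base_channels stem width; default 20.
#' @param input_channels input channels (image + DPM = 2).
#' @param scale_constant DPM normalizer in um carried with the model so
#'   inference builds DPMs exactly as training did.
#' @return a list of class `vz_gen_config`.
#' @export
gen_config <- function(K = 5L, base_channels = 20L, input_channels = 2L,
                       scale_constant = 10) {
  check_number(K, "K"); check_number(base_channels, "base_channels", positive = TRUE)
  if (K < 2L) stopf("`K` must be >= 2")
  structure(list(K = as.integer(K), base_channels = as.integer(base_channels),
                 input_channels = as.integer(input_channels),
                 scale_constant = scale_constant),
            class = "vz_gen_config")
}

# feature width at scale k
scale_channels <- function(cfg, k) cfg$base_channels * 2L^(k - 1L)

#' Initialize a generator with random weights
#'
#' @param config a [gen_config].
#' @param seed integer seed for the weight draw (He-scaled normals).
#' @return an object of class `vz_generator` with fields `config` and `params`.
#' @export
init_generator <- function(config, seed = 1L) {
  stopifnot(inherits(config, "vz_gen_config"))
  K <- config$K; base <- config$base_channels
  with_seed(derive_seed(seed, "gen-init"), {
    enc <- vector("list", K); gru <- vector("list", K); mix <- vector("list", K)
    cin <- config$input_channels
    for (k in seq_len(K)) {
      w1 <- if (k == 1L) base else base * 2L^(k - 2L)
      w2 <- scale_channels(config, k)
      enc[[k]] <- list(conv1 = conv_param(3L, 3L, cin, w1), bn1 = bn_param(w1),
                       conv2 = conv_param(3L, 3L, w1, w2), bn2 = bn_param(w2))
      gru[[k]] <- list(Wf = conv_param(3L, 3L, w2, w2),
                       Uf = conv_param(3L, 3L, w2, w2),
                       Wh = conv_param(3L, 3L, w2, w2),
                       Uh = conv_param(3L, 3L, w2, w2))
      gru[[k]]$Uf$b <- NULL  # bias lives on the W path only
      gru[[k]]$Uh$b <- NULL
      mix[[k]] <- conv_param(1L, 1L, w2, w2)
      cin <- w2
    }
    dec <- vector("list", K - 1L)
    for (k in seq_len(K - 1L)) {
      ck <- scale_channels(config, k); cup <- scale_channels(config, k + 1L)
      dec[[k]] <- list(conv1 = conv_param(3L, 3L, cup + ck, ck), bn1 = bn_param(ck),
                       conv2 = conv_param(3L, 3L, ck, ck), bn2 = bn_param(ck))
    }
    head <- conv_param(1L, 1L, base, 1L, gain = 1)
    names(enc) <- paste0("k", seq_len(K)); names(gru) <- names(enc); names(mix) <- names(enc)
    names(dec) <- paste0("k", seq_len(K - 1L))
    structure(list(config = config,
                   params = list(enc = enc, gru = gru, mix = mix, dec = dec,
                                 head = head)),
              class = "vz_generator")
  })
}

#' Count trainable parameters of a model
#'
#' Convolution kernels, biases and batch-norm gamma/beta; running statistics
#' are excluded.  The count does not depend on the sequence length M.
#'
#' @param model a `vz_generator` or `vz_discriminator`.
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  leaves <- tree_leaves(model$params)
  sum(vapply(seq_along(leaves), function(i) {
    if (is_trainable_leaf(names(leaves)[i])) length(leaves[[i]]) else 0L
  }, 0L))
}

# conv-GRU cell update: f = sigma(Wf*x + Uf*h + bf);
# hcand = tanh(Wh*x + Uh*(f.h) + bh); h' = (1-f).h + f.hcand.
# The patch matrices of x, h and f.h are gathered once and shared between the
# gate and candidate convolutions (and cached for the backward pass).
conv_gru_step_ <- function(x, h, w) {
  d <- dim(x); n <- d[1L] * d[2L]; c <- d[3L]
  Xc <- im2col(x, 3L, 3L)
  Hc <- im2col(h, 3L, 3L)
  f <- Xc %*% w$Wf$W + Hc %*% w$Uf$W + rep(w$Wf$b, each = n)
  dim(f) <- d
  f <- sigmoid(f)
  fh <- f * h
  FHc <- im2col(fh, 3L, 3L)
  hc <- Xc %*% w$Wh$W + FHc %*% w$Uh$W + rep(w$Wh$b, each = n)
  dim(hc) <- d
  hc <- tanh(hc)
  hn <- (1 - f) * h + f * hc
  list(h = hn, cache = list(h_prev = h, f = f, hc = hc, dims = d,
                            Xc = Xc, Hc = Hc, FHc = FHc))
}

#' One convolutional GRU update
#'
#' Exposes the recurrent cell used at every scale: given the scale features
#' `x_t` and the previous hidden map `h_{t-1}`, computes the forget map, the
#' candidate state and the convex-combination update.
#'
#' @param x_t feature array (h, w, c).
#' @param h_prev hidden array (h, w, c), spatially aligned with `x_t`.
#' @param weights list with conv parameters `Wf`, `Uf`, `Wh`, `Uh` (biases on
#'   the `Wf`/`Wh` path), as stored in `model$params$gru[[k]]`.
#' @return the updated hidden array `h_t`.
#' @export
conv_gru_step <- function(x_t, h_prev, weights) {
  if (!identical(dim(x_t), dim(h_prev)))
    stopf("`x_t` and `h_prev` must have identical shapes")
  conv_gru_step_(x_t, h_prev, weights)$h
}

# backward of the GRU cell; dh is the gradient on h_t.  The patch matrix of
# each pre-activation gradient is gathered once and shared between the two
# kernels it feeds (W and U paths).
conv_gru_bwd_ <- function(dh, cache, w) {
  f <- cache$f; hc <- cache$hc; h_prev <- cache$h_prev
  d <- cache$dims; n <- d[1L] * d[2L]; c <- d[3L]
  df <- dh * (hc - h_prev)
  dhc <- dh * f
  dh_prev <- dh * (1 - f)
  dtan <- dhc * (1 - hc^2)
  dTm <- dtan; dim(dTm) <- c(n, c)
  dWh <- crossprod(cache$Xc, dTm); attr(dWh, "kshape") <- attr(w$Wh$W, "kshape")
  dUh <- crossprod(cache$FHc, dTm); attr(dUh, "kshape") <- attr(w$Uh$W, "kshape")
  dbh <- colSums(dTm)
  Tc <- im2col(dtan, 3L, 3L)
  dx <- Tc %*% flip_kernel(w$Wh$W)
  dfh <- Tc %*% flip_kernel(w$Uh$W)
  dim(dfh) <- d
  df <- df + dfh * h_prev
  dh_prev <- dh_prev + dfh * f
  dsig <- df * f * (1 - f)
  dSm <- dsig; dim(dSm) <- c(n, c)
  dWf <- crossprod(cache$Xc, dSm); attr(dWf, "kshape") <- attr(w$Wf$W, "kshape")
  dUf <- crossprod(cache$Hc, dSm); attr(dUf, "kshape") <- attr(w$Uf$W, "kshape")
  dbf <- colSums(dSm)
  Sc <- im2col(dsig, 3L, 3L)
  dx <- dx + Sc %*% flip_kernel(w$Wf$W)
  dim(dx) <- d
  dhp <- Sc %*% flip_kernel(w$Uf$W)
  dim(dhp) <- d
  dh_prev <- dh_prev + dhp
  list(dx = dx, dh_prev = dh_prev,
       grads = list(Wf = list(W = dWf, b = dbf),
                    Uf = list(W = dUf),
                    Wh = list(W = dWh, b = dbh),
                    Uh = list(W = dUh)))
}

# conv + BN + ReLU (+ conv + BN + ReLU) block used by encoder and decoder
double_conv_fwd <- function(x, par, train) {
  c1 <- conv_fwd_cache(x, par$conv1)
  b1 <- bn_fwd(c1$out, par$bn1, train); par$bn1 <- b1$par
  r1 <- relu_fwd(b1$out)
  c2 <- conv_fwd_cache(r1, par$conv2)
  b2 <- bn_fwd(c2$out, par$bn2, train); par$bn2 <- b2$par
  out <- relu_fwd(b2$out)
  list(out = out, par = par,
       cache = list(x = x, X1 = c1$X, bn1 = b1$cache, r1 = r1, X2 = c2$X,
                    bn2 = b2$cache, pre2 = b2$out, pre1 = b1$out))
}

double_conv_bwd <- function(dy, cache, par) {
  d2 <- relu_bwd(dy, cache$pre2)
  bb2 <- bn_bwd(d2, cache$bn2, par$bn2)
  cc2 <- conv_bwd(bb2$dx, cache$r1, par$conv2, X = cache$X2)
  d1 <- relu_bwd(cc2$dx, cache$pre1)
  bb1 <- bn_bwd(d1, cache$bn1, par$bn1)
  cc1 <- conv_bwd(bb1$dx, cache$x, par$conv1, X = cache$X1)
  list(dx = cc1$dx,
       grads = list(conv1 = list(W = cc1$dW, b = cc1$db),
                    bn1 = list(gamma = bb1$dgamma, beta = bb1$dbeta,
                               rmean = par$bn1$rmean * 0, rvar = par$bn1$rvar * 0),
                    conv2 = list(W = cc2$dW, b = cc2$db),
                    bn2 = list(gamma = bb2$dgamma, beta = bb2$dbeta,
                               rmean = par$bn2$rmean * 0, rvar = par$bn2$rvar * 0)))
}

# Full generator forward.  `frames` is a list of M arrays (h, w, 2).
# Returns the output matrix plus (when train = TRUE or keep_cache) everything
# the backward pass needs, and the model with updated BN running statistics.
gen_forward_ <- function(model, frames, train = FALSE, keep_cache = train) {
  cfg <- model$config; K <- cfg$K; P <- model$params
  M <- length(frames)
  if (M < 1L) stopf("empty input sequence")
  d <- dim(frames[[1L]])
  if (is.null(d) || length(d) != 3L || d[3L] != cfg$input_channels)
    stopf("each frame must be an (h, w, %d) array", cfg$input_channels)
  if (d[1L] %% 2L^(K - 1L) || d[2L] %% 2L^(K - 1L))
    stopf("input dims (%d x %d) must be divisible by 2^(K-1) = %d",
          d[1L], d[2L], 2L^(K - 1L))
  h_state <- vector("list", K)   # fresh state: no leakage across sequences
  enc_cache <- if (keep_cache) vector("list", M)
  gru_cache <- if (keep_cache) vector("list", M)
  pool_cache <- if (keep_cache) vector("list", M)
  x_last <- vector("list", K)
  for (t in seq_len(M)) {
    x <- frames[[t]]
    if (keep_cache) {
      enc_cache[[t]] <- vector("list", K)
      gru_cache[[t]] <- vector("list", K)
      pool_cache[[t]] <- vector("list", K)
    }
    for (k in seq_len(K)) {
      if (k > 1L) {
        mp <- maxpool_fwd(x)
        x <- mp$out
        if (keep_cache) pool_cache[[t]][[k]] <- mp$cache
      }
      dc <- double_conv_fwd(x, P$enc[[k]], train)
      P$enc[[k]] <- dc$par
      xk <- dc$out
      if (is.null(h_state[[k]])) h_state[[k]] <- array(0, dim(xk))
      g <- conv_gru_step_(xk, h_state[[k]], P$gru[[k]])
      h_state[[k]] <- g$h
      if (keep_cache) {
        enc_cache[[t]][[k]] <- dc$cache
        gru_cache[[t]][[k]] <- g$cache
      }
      if (t == M) x_last[[k]] <- xk
      x <- xk
    }
  }
  s <- vector("list", K)
  mix_cache <- vector("list", K)
  for (k in seq_len(K)) {
    s[[k]] <- x_last[[k]] + conv_fwd(h_state[[k]], P$mix[[k]])
    mix_cache[[k]] <- h_state[[k]]
  }
  y <- s[[K]]
  dec_cache <- vector("list", K - 1L)
  for (k in rev(seq_len(K - 1L))) {
    u <- upsample_fwd(y)
    cc <- concat_channels(u, s[[k]])
    dc <- double_conv_fwd(cc, P$dec[[k]], train)
    P$dec[[k]] <- dc$par
    if (keep_cache) dec_cache[[k]] <- c(dc$cache, list(ch_up = dim(u)[3L]))
    y <- dc$out
  }
  out <- conv_fwd(y, P$head)
  model$params <- P
  cache <- if (keep_cache)
    list(enc = enc_cache, gru = gru_cache, pool = pool_cache,
         mix = mix_cache, dec = dec_cache, head_in = y, M = M, K = K)
  list(out = out[, , 1L], cache = cache, model = model)
}

# Full generator backward: dout is the gradient on the output matrix.
gen_backward_ <- function(model, cache, dout) {
  P <- model$params; K <- cache$K; M <- cache$M
  G <- zero_like_tree(P)
  ddy <- array(dout, c(dim(dout), 1L))
  ch <- conv_bwd(ddy, cache$head_in, P$head)
  G$head$W <- ch$dW; G$head$b <- ch$db
  dy <- ch$dx
  ds <- vector("list", K)
  for (k in seq_len(K - 1L)) {
    db <- double_conv_bwd(dy, cache$dec[[k]], P$dec[[k]])
    G$dec[[k]] <- tree_map2(`+`, G$dec[[k]], db$grads)
    cup <- cache$dec[[k]]$ch_up
    dcc <- db$dx
    du <- dcc[, , seq_len(cup), drop = FALSE]
    ds[[k]] <- dcc[, , cup + seq_len(dim(dcc)[3L] - cup), drop = FALSE]
    dy <- upsample_bwd(du)
  }
  ds[[K]] <- dy
  dh <- vector("list", K)      # gradient on h_k after step M
  dres <- vector("list", K)    # gradient on x_k at t = M via the residual
  for (k in seq_len(K)) {
    cm <- conv_bwd(ds[[k]], cache$mix[[k]], P$mix[[k]])
    G$mix[[k]]$W <- G$mix[[k]]$W + cm$dW
    G$mix[[k]]$b <- G$mix[[k]]$b + cm$db
    dh[[k]] <- cm$dx
    dres[[k]] <- ds[[k]]
  }
  for (t in rev(seq_len(M))) {
    carry <- NULL   # gradient flowing into x_k from the encoder block above
    for (k in rev(seq_len(K))) {
      gb <- conv_gru_bwd_(dh[[k]], cache$gru[[t]][[k]], P$gru[[k]])
      G$gru[[k]] <- tree_map2(`+`, G$gru[[k]], gb$grads)
      dh[[k]] <- gb$dh_prev
      dxk <- gb$dx
      if (t == M) dxk <- dxk + dres[[k]]
      if (!is.null(carry)) dxk <- dxk + carry
      eb <- double_conv_bwd(dxk, cache$enc[[t]][[k]], P$enc[[k]])
      G$enc[[k]] <- tree_map2(`+`, G$enc[[k]], eb$grads)
      if (k > 1L) {
        carry <- maxpool_bwd(eb$dx, cache$pool[[t]][[k]])
      } else {
        carry <- NULL  # gradient on the data frame; not needed
      }
    }
  }
  G
}

#' Run the generator on an input sequence
#'
#' Inference entry point: recurrent state is freshly initialized, batch norm
#' uses its running statistics, and the output carries the sequence's target
#' z.  The same weights accept any sequence length M >= 1.
#'
#' @param model a `vz_generator`.
#' @param seq an `input_sequence` (from [assemble_sequence]) or a list of
#'   (h, w, 2) arrays.
#' @param train logical; `TRUE` switches batch norm to batch statistics and
#'   updates running averages (used internally by the training loop).
#' @return an [image_plane] at the sequence's target z (or a plain matrix when
#'   `seq` is a raw frame list).
#' @export
generator_forward <- function(model, seq, train = FALSE) {
  stopifnot(inherits(model, "vz_generator"))
  if (inherits(seq, "input_sequence")) {
    res <- gen_forward_(model, sequence_frames(seq), train = train,
                        keep_cache = FALSE)
    image_plane(res$out, seq$target_z)
  } else {
    gen_forward_(model, seq, train = train, keep_cache = FALSE)$out
  }
}
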