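# Low-level differentiable operations on (h, w, channels) arrays.
# Convolutions use an im2col layout: a kernel is stored as a matrix of shape
# (kh*kw*cin, cout) whose rows are grouped by kernel offset (row offset
# fastest) with `cin` consecutive columns per offset; the patch matrix built
# by im2col() uses the same ordering, so a convolution is one matrix product.
# Every *_fwd returns what its matching *_bwd needs; nothing is re-derived by
# a framework.

conv_param <- function(kh, kw, cin, cout, gain = sqrt(2)) {
  W <- matrix(stats::rnorm(kh * kw * cin * cout, 0, gain / sqrt(kh * kw * cin)),
              kh * kw * cin, cout)
  attr(W, "kshape") <- c(kh, kw, cin, cout)
  list(W = W, b = numeric(cout))
}

bn_param <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c), rmean = numeric(c), rvar = rep(1, c))
}

# gather-index cache: one linear-index vector per (h, w, cin, kh, kw) shape
.im2col_cache <- new.env(parent = emptyenv())

im2col_index <- function(h, w, cin, kh, kw) {
  key <- paste(h, w, cin, kh, kw, sep = "x")
  idx <- .im2col_cache[[key]]
  if (!is.null(idx)) return(idx)
  H <- h + kh - 1L; W <- w + kw - 1L
  base <- as.vector(outer(seq_len(h), (seq_len(w) - 1L) * H, "+"))
  offs <- integer(kh * kw * cin)
  o <- 0L
  for (dj in 0:(kw - 1L)) for (di in 0:(kh - 1L)) {
    offs[o * cin + seq_len(cin)] <- di + H * dj + H * W * (seq_len(cin) - 1L)
    o <- o + 1L
  }
  idx <- as.integer(rep(base, times = length(offs)) +
                      rep(offs, each = length(base)))
  .im2col_cache[[key]] <- idx
  idx
}

im2col <- function(x, kh, kw) {
  d <- dim(x); h <- d[1L]; w <- d[2L]; cin <- d[3L]
  if (kh == 1L && kw == 1L) {
    X <- x; dim(X) <- c(h * w, cin)
    return(X)
  }
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  P <- array(0, c(h + kh - 1L, w + kw - 1L, cin))
  P[ph + seq_len(h), pw + seq_len(w), ] <- x
  X <- P[im2col_index(h, w, cin, kh, kw)]
  dim(X) <- c(h * w, kh * kw * cin)
  X
}

# spatially flipped, in/out-transposed kernel: the adjoint of a zero-padded
# same-convolution is a same-convolution with this kernel
flip_kernel <- function(W) {
  ks <- attr(W, "kshape"); kh <- ks[1L]; kw <- ks[2L]; cin <- ks[3L]; cout <- ks[4L]
  Wf <- matrix(0, kh * kw * cout, cin)
  o <- 0L
  for (dj in 0:(kw - 1L)) for (di in 0:(kh - 1L)) {
    of <- (kh - 1L - di) + kh * (kw - 1L - dj)
    Wf[o * cout + seq_len(cout), ] <-
      t(W[of * cin + seq_len(cin), , drop = FALSE])
    o <- o + 1L
  }
  attr(Wf, "kshape") <- c(kh, kw, cout, cin)
  Wf
}

conv_fwd <- function(x, par) {
  ks <- attr(par$W, "kshape")
  d <- dim(x)
  stopifnot(d[3L] == ks[3L])
  X <- im2col(x, ks[1L], ks[2L])
  Y <- X %*% par$W
  if (any(par$b != 0)) Y <- Y + rep(par$b, each = nrow(Y))
  dim(Y) <- c(d[1L], d[2L], ks[4L])
  Y
}

# forward that also returns the patch matrix, reused by the backward pass
conv_fwd_cache <- function(x, par) {
  ks <- attr(par$W, "kshape")
  d <- dim(x)
  X <- im2col(x, ks[1L], ks[2L])
  Y <- X %*% par$W
  if (any(par$b != 0)) Y <- Y + rep(par$b, each = nrow(Y))
  dim(Y) <- c(d[1L], d[2L], ks[4L])
  list(out = Y, X = X, dims = d)
}

# gradient wrt the input of a zero-padded same-convolution
conv_input_grad <- function(dy, W) {
  ks <- attr(W, "kshape")
  if (ks[1L] == 1L && ks[2L] == 1L) {
    d <- dim(dy)
    dY <- dy; dim(dY) <- c(d[1L] * d[2L], ks[4L])
    dx <- tcrossprod(dY, W)
    dim(dx) <- c(d[1L], d[2L], ks[3L])
    return(dx)
  }
  d <- dim(dy)
  dx <- im2col(dy, ks[1L], ks[2L]) %*% flip_kernel(W)
  dim(dx) <- c(d[1L], d[2L], ks[3L])
  dx
}

# `X` is the patch matrix cached by conv_fwd_cache (rebuilt when absent)
conv_bwd <- function(dy, x, par, X = NULL) {
  ks <- attr(par$W, "kshape"); kh <- ks[1L]; kw <- ks[2L]; cin <- ks[3L]; cout <- ks[4L]
  d <- dim(x)
  h <- d[1L]; w <- d[2L]
  dY <- dy; dim(dY) <- c(h * w, cout)
  if (is.null(X)) X <- im2col(x, kh, kw)
  dW <- crossprod(X, dY)
  attr(dW, "kshape") <- ks
  db <- colSums(dY)
  dim(dY) <- c(h, w, cout)
  list(dx = conv_input_grad(dY, par$W), dW = dW, db = db)
}

relu_fwd <- function(x) x * (x > 0)
relu_bwd <- function(dy, x) dy * (x > 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

BN_EPS <- 1e-3
BN_MOMENTUM <- 0.99

# Batch-norm over the spatial dimensions of one example (per channel).
# Returns the output, a cache for the backward pass, and the parameter list
# with updated running statistics (train mode only).
bn_fwd <- function(x, par, train) {
  d <- dim(x); n <- d[1L] * d[2L]; c <- d[3L]
  X <- x; dim(X) <- c(n, c)
  if (train) {
    mu <- colMeans(X)
    va <- colMeans(X^2) - mu^2
    par$rmean <- BN_MOMENTUM * par$rmean + (1 - BN_MOMENTUM) * mu
    par$rvar <- BN_MOMENTUM * par$rvar + (1 - BN_MOMENTUM) * va
  } else {
    mu <- par$rmean
    va <- par$rvar
  }
  inv <- 1 / sqrt(va + BN_EPS)
  xhat <- (X - rep(mu, each = n)) * rep(inv, each = n)
  Y <- xhat * rep(par$gamma, each = n) + rep(par$beta, each = n)
  dim(xhat) <- c(n, c)
  dim(Y) <- d
  list(out = Y, cache = list(xhat = xhat, inv = inv, dims = d, train = train),
       par = par)
}

bn_bwd <- function(dy, cache, par) {
  d <- cache$dims; n <- d[1L] * d[2L]; c <- d[3L]
  dY <- dy; dim(dY) <- c(n, c)
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(par$gamma, each = n)
  if (cache$train) {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * xhat)
    dX <- (dxhat - rep(s1 / n, each = n) - xhat * rep(s2 / n, each = n)) *
      rep(cache$inv, each = n)
  } else {
    dX <- dxhat * rep(cache$inv, each = n)
  }
  dim(dX) <- c(n, c)
  dim(dX) <- d
  list(dx = dX, dgamma = dgamma, dbeta = dbeta)
}

maxpool_fwd <- function(x) {
  d <- dim(x); h <- d[1L]; w <- d[2L]; c <- d[3L]
  if (h %% 2L || w %% 2L) stopf("max-pooling needs even spatial dims, got %d x %d", h, w)
  h2 <- h %/% 2L; w2 <- w %/% 2L
  m4 <- matrix(0, h2 * w2 * c, 4L)
  q <- 0L
  for (dj in 0:1) for (di in 0:1) {
    q <- q + 1L
    m4[, q] <- x[seq(1L + di, h, 2L), seq(1L + dj, w, 2L), ]
  }
  amax <- max.col(m4, ties.method = "first")
  y <- m4[cbind(seq_len(nrow(m4)), amax)]
  dim(y) <- c(h2, w2, c)
  list(out = y, cache = list(amax = amax, dims = d))
}

maxpool_bwd <- function(dy, cache) {
  d <- cache$dims; h <- d[1L]; w <- d[2L]; c <- d[3L]
  dv <- as.vector(dy)
  dx <- array(0, d)
  q <- 0L
  for (dj in 0:1) for (di in 0:1) {
    q <- q + 1L
    g <- dv * (cache$amax == q)
    dim(g) <- c(h %/% 2L, w %/% 2L, c)
    dx[seq(1L + di, h, 2L), seq(1L + dj, w, 2L), ] <- g
  }
  dx
}

upsample_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), , drop = FALSE]
}

upsample_bwd <- function(dy) {
  d <- dim(dy); h <- d[1L]; w <- d[2L]
  dy[seq(1L, h, 2L), seq(1L, w, 2L), , drop = FALSE] +
    dy[seq(2L, h, 2L), seq(1L, w, 2L), , drop = FALSE] +
    dy[seq(1L, h, 2L), seq(2L, w, 2L), , drop = FALSE] +
    dy[seq(2L, h, 2L), seq(2L, w, 2L), , drop = FALSE]
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(da[1L] == db[1L], da[2L] == db[2L])
  array(c(a, b), c(da[1L], da[2L], da[3L] + db[3L]))
}

# Parameter-tree utilities ---------------------------------------------------

# leaves named rmean/rvar are running statistics, not trainable parameters
tree_leaves <- function(tree, path = character()) {
  if (is.list(tree)) {
    out <- list()
    for (nm in names(tree))
      out <- c(out, tree_leaves(tree[[nm]], c(path, nm)))
    out
  } else {
    stats::setNames(list(tree), paste(path, collapse = "/"))
  }
}

is_trainable_leaf <- function(name) {
  leaf <- sub(".*/", "", name)
  !(leaf %in% c("rmean", "rvar"))
}

tree_map <- function(f, tree) {
  if (is.list(tree)) {
    for (nm in names(tree)) tree[[nm]] <- tree_map(f, tree[[nm]])
    tree
  } else f(tree)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- tree_map2(f, a[[nm]], b[[nm]])
    a
  } else f(a, b)
}

zero_like_tree <- function(tree) tree_map(function(x) x * 0, tree)

# accumulate `delta` (a partial grad tree with matching names) into `grads`
tree_add_at <- function(grads, path, delta) {
  if (length(path) == 1L) {
    grads[[path]] <- grads[[path]] + delta
  } else {
    grads[[path[1L]]] <- tree_add_at(grads[[path[1L]]], path[-1L], delta)
  }
  grads
}

# Adam optimizer over a parameter tree; running BN statistics are skipped.
adam_init <- function(params) {
  list(m = zero_like_tree(params), v = zero_like_tree(params), t = 0L)
}

adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v, path) {
    if (is.list(p)) {
      for (nm in names(p)) {
        res <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]], c(path, nm))
        p[[nm]] <- res$p; m[[nm]] <- res$m; v[[nm]] <- res$v
      }
      return(list(p = p, m = m, v = v))
    }
    if (!is_trainable_leaf(paste(path, collapse = "/")))
      return(list(p = p, m = m, v = v))
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    p <- p - lr * mhat / (sqrt(vhat) + eps)
    list(p = p, m = m, v = v)
  }
  res <- walk(params, grads, state$m, state$v, character())
  list(params = res$p, state = list(m = res$m, v = res$v, t = t))
}
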