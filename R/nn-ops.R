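# Internal neural-network primitives. All backward passes are hand-derived
# and covered by finite-difference gradient tests.

relu_fwd <- function(x) x * (x > 0)

# --- batch normalisation over a 2D matrix: rows = observations, cols = channels

bn_fwd <- function(xm, bn, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2 # biased, as used for normalisation
    v <- pmax(v, 0)
    bn$run_mean <- (1 - momentum) * bn$run_mean + momentum * mu
    bn$run_var <- (1 - momentum) * bn$run_var + momentum * v
  } else {
    mu <- bn$run_mean
    v <- bn$run_var
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu, "-"), 2, ivar, "*")
  y <- sweep(sweep(xhat, 2, bn$gamma, "*"), 2, bn$beta, "+")
  list(y = y, bn = bn,
       cache = if (training) list(xhat = xhat, ivar = ivar, gamma = bn$gamma))
}

bn_bwd <- function(gy, cache) {
  m <- nrow(gy)
  dgamma <- colSums(gy * cache$xhat)
  dbeta <- colSums(gy)
  dxhat <- sweep(gy, 2, cache$gamma, "*")
  t1 <- colSums(dxhat) / m
  t2 <- colSums(dxhat * cache$xhat) / m
  dx <- sweep(sweep(dxhat, 2, t1, "-") - sweep(cache$xhat, 2, t2, "*"),
              2, cache$ivar, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# --- dropout (inverted scaling, active only in training)

dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  mask <- (runif(length(x)) >= rate) / (1 - rate)
  y <- x * mask
  attributes(y) <- attributes(x)
  list(y = y, mask = mask)
}

dropout_bwd <- function(gy, mask) {
  if (is.null(mask)) return(gy)
  g <- gy * mask
  attributes(g) <- attributes(gy)
  g
}

# --- fully connected layer: x (N, in) -> x W + b, W (in, out)

dense_fwd <- function(x, W, b) sweep(x %*% W, 2, b, "+")

dense_bwd <- function(x, W, gy) {
  list(gx = gy %*% t(W), gW = crossprod(x, gy), gb = colSums(gy))
}

# --- softmax cross-entropy (mean over the batch), numerically stable

softmax_probs <- function(scores) {
  z <- scores - apply(scores, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

softmax_ce_fwd <- function(scores, labels) {
  z <- scores - apply(scores, 1, max)
  lse <- log(rowSums(exp(z)))
  picked <- z[cbind(seq_len(nrow(z)), labels)]
  mean(lse - picked)
}

softmax_ce_bwd <- function(scores, labels) {
  p <- softmax_probs(scores)
  p[cbind(seq_len(nrow(p)), labels)] <- p[cbind(seq_len(nrow(p)), labels)] - 1
  p / nrow(p)
}

# --- He-uniform initialisation

init_uniform <- function(dims, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(runif(prod(dims), -lim, lim), dim = dims)
}

# --- Adam over nested parameter lists -----------------------------------
# Parameters live in named nested lists; gradients come back in an identical
# structure. Fields named W/Wproj receive L2 weight decay; b/gamma/beta do not.

DECAYED <- c("W", "Wproj") # fields that receive weight decay

adam_init <- function(params) {
  if (is.numeric(params)) return(list(m = params * 0, v = params * 0))
  if (is.list(params)) return(lapply(params, adam_init))
  NULL
}

adam_step <- function(params, grads, state, t, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, s, decay_ok) {
    if (is.numeric(p)) {
      if (is.null(g)) return(list(p = p, s = s))
      if (decay_ok && weight_decay > 0) g <- g + weight_decay * p
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g^2
      mhat <- s$m / (1 - beta1^t)
      vhat <- s$v / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), s = s)
    } else if (is.list(p)) {
      keys <- names(p) %||% seq_along(p) # unnamed lists walk by position
      for (nm in keys) {
        r <- walk(p[[nm]], g[[nm]], s[[nm]], is.character(nm) && nm %in% DECAYED)
        p[[nm]] <- r$p
        s[[nm]] <- r$s
      }
      list(p = p, s = s)
    } else {
      list(p = p, s = s) # non-numeric leaf (config strings etc.)
    }
  }
  walk(params, grads, state, FALSE)
}

# sum two grad structures of identical shape (NULL-tolerant)
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.numeric(a)) return(a + b)
  for (nm in names(a)) a[[nm]] <- grads_add(a[[nm]], b[[nm]])
  a
}

# --- convolution dispatch --------------------------------------------------
# Small problems go through im2col + one GEMM against OpenBLAS; large
# single-sample problems (e.g. a full-resolution forward pass) use the
# direct loop kernel to avoid materialising a huge unfolded matrix.
IM2COL_LIMIT <- 2e7 # max elements of the unfolded matrix (~160 MB)

conv_dims <- function(xd, kernel, stride) {
  ov <- (xd[1:3] - kernel) %/% stride + 1L
  list(ov = ov, K = prod(kernel) * xd[4], M = prod(ov) * xd[5])
}

conv_fwd <- function(x5, W, b, stride, cache_col = FALSE) {
  xd <- dim(x5)
  wd <- dim(W)
  cd <- conv_dims(xd, wd[1:3], stride)
  co <- wd[5]
  if (cd$K * cd$M <= IM2COL_LIMIT) {
    xcol <- im2col3d_cpp(x5, wd[1:3], stride)
    wm <- matrix(W, cd$K, co)
    ym <- crossprod(xcol, wm) # (M, Co)
    ym <- sweep(ym, 2, b, "+")
    dim(ym) <- c(prod(cd$ov), xd[5], co)
    y <- aperm(ym, c(1L, 3L, 2L))
    dim(y) <- c(cd$ov, co, xd[5])
    list(y = y, xcol = if (cache_col) xcol)
  } else {
    list(y = conv3d_fwd_cpp(x5, W, b, stride), xcol = NULL)
  }
}

conv_bwd <- function(x5, W, gy, stride, want_gx = TRUE, xcol = NULL) {
  xd <- dim(x5)
  wd <- dim(W)
  cd <- conv_dims(xd, wd[1:3], stride)
  co <- wd[5]
  if (!is.null(xcol) || cd$K * cd$M <= IM2COL_LIMIT) {
    if (is.null(xcol)) xcol <- im2col3d_cpp(x5, wd[1:3], stride)
    g <- aperm(array(gy, c(prod(cd$ov), co, xd[5])), c(1L, 3L, 2L))
    dim(g) <- c(cd$M, co) # (M, Co), columns match xcol columns
    gw <- xcol %*% g
    dim(gw) <- wd
    gb <- colSums(g)
    gx <- NULL
    if (want_gx) {
      gcol <- matrix(W, cd$K, co) %*% t(g)
      gx <- col2im3d_cpp(gcol, xd, wd[1:3], stride)
    }
    list(gx = gx, gw = gw, gb = gb)
  } else {
    out <- conv3d_bwd_cpp(x5, W, gy, stride, want_gx)
    if (!want_gx) out$gx <- NULL
    out
  }
}

# --- batch normalisation on 5D activations in native (X,Y,Z,C,N) layout ----
# Channel statistics via column sums on a (S, C*N) view and rep-based
# broadcasting; avoids the array permutations a matrix-layout BN would need.

bn5_fwd <- function(a, bn, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(a)
  S <- prod(d[1:3]); C <- d[4]; N <- d[5]; M <- S * N
  am <- a; dim(am) <- c(S, C * N)
  if (training) {
    mu <- rowSums(matrix(.colSums(am, S, C * N), C, N)) / M
    ex2 <- rowSums(matrix(.colSums(am * am, S, C * N), C, N)) / M
    v <- pmax(ex2 - mu^2, 0)
    bn$run_mean <- (1 - momentum) * bn$run_mean + momentum * mu
    bn$run_var <- (1 - momentum) * bn$run_var + momentum * v
  } else {
    mu <- bn$run_mean
    v <- bn$run_var
  }
  ivar <- 1 / sqrt(v + eps)
  sc <- bn$gamma * ivar
  off <- bn$beta - mu * sc
  y <- a * rep(sc, each = S) + rep(off, each = S) # recycles over N
  list(y = y, bn = bn, mu = mu, ivar = ivar)
}

bn5_bwd <- function(gy, z, mu, ivar, gamma) {
  d <- dim(z)
  S <- prod(d[1:3]); C <- d[4]; N <- d[5]; M <- S * N
  xhat <- (z - rep(mu, each = S)) * rep(ivar, each = S)
  chan_sum <- function(x) {
    dim(x) <- c(S, C * N)
    rowSums(matrix(.colSums(x, S, C * N), C, N))
  }
  dgamma <- chan_sum(gy * xhat)
  dbeta <- chan_sum(gy)
  dxhat <- gy * rep(gamma, each = S)
  t1 <- chan_sum(dxhat) / M
  t2 <- chan_sum(dxhat * xhat) / M
  dx <- (dxhat - rep(t1, each = S) - xhat * rep(t2, each = S)) *
    rep(ivar, each = S)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}
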