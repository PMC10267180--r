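# Minimal neural-network engine for 1-D time-series classification.
#
# Tensors are base-R arrays laid out (channels, time, batch); dense parts use
# (features, batch) matrices. Every layer implements a forward pass returning
# (output, cache, possibly-updated layer) and a backward pass returning the
# input gradient plus parameter gradients. Correctness is pinned by a
# numerical-gradient test rather than by construction-time cleverness, so the
# implementations below favour clarity over micro-optimisation.

EPS_NORM <- 1e-5

## ---- parameter initialisation -------------------------------------------

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

layer_conv <- function(cin, cout, k) {
  list(type = "conv", cin = cin, cout = cout, k = k,
       params = list(W = he_init(cin * k, cout, cin * k), b = numeric(cout)))
}
layer_dense <- function(din, dout) {
  list(type = "dense", din = din, dout = dout,
       params = list(W = he_init(din, dout, din), b = numeric(dout)))
}
layer_bnorm <- function(C) {
  list(type = "bnorm", C = C,
       params = list(gamma = rep(1, C), beta = numeric(C)),
       running_mean = numeric(C), running_var = rep(1, C), momentum = 0.9)
}
layer_inorm <- function(C) {
  list(type = "inorm", C = C,
       params = list(gamma = rep(1, C), beta = numeric(C)))
}
layer_prelu <- function(C) {
  list(type = "prelu", C = C, params = list(a = rep(0.25, C)))
}
layer_relu <- function() list(type = "relu", params = list())
layer_dropout <- function(rate) list(type = "dropout", rate = rate,
                                     params = list())
layer_maxpool <- function(factor = 2) list(type = "maxpool", factor = factor,
                                           params = list())
layer_flatten <- function() list(type = "flatten", params = list())
layer_gap <- function() list(type = "gap", params = list())
layer_attention <- function(C) {
  if (C %% 2 != 0)
    config_error("attention needs an even channel count (it splits in half)")
  list(type = "attention", C = C, params = list())
}
layer_resblock <- function(cin, cout, kernels = c(8, 5, 3)) {
  convs <- list(layer_conv(cin, cout, kernels[1]),
                layer_conv(cout, cout, kernels[2]),
                layer_conv(cout, cout, kernels[3]))
  bns <- list(layer_bnorm(cout), layer_bnorm(cout), layer_bnorm(cout))
  shortcut <- if (cin != cout)
    list(conv = layer_conv(cin, cout, 1), bn = layer_bnorm(cout)) else NULL
  list(type = "resblock", cin = cin, cout = cout, params = list(),
       convs = convs, bns = bns, shortcut = shortcut)
}

## ---- forward passes ------------------------------------------------------

conv_im2col <- function(x, k) {
  d <- dim(x); C <- d[1]; Tt <- d[2]; B <- d[3]
  pl <- (k - 1) %/% 2
  P <- array(0, c(C, Tt + k - 1, B))
  P[, (pl + 1):(pl + Tt), ] <- x
  Xcol <- array(0, c(C * k, Tt, B))
  for (j in 0:(k - 1))
    Xcol[(j * C + 1):((j + 1) * C), , ] <- P[, (1 + j):(Tt + j), , drop = FALSE]
  dim(Xcol) <- c(C * k, Tt * B)
  Xcol
}

fw_conv <- function(layer, x, train) {
  d <- dim(x); Tt <- d[2]; B <- d[3]
  Xcol <- conv_im2col(x, layer$k)
  Y <- crossprod(layer$params$W, Xcol) + layer$params$b
  dim(Y) <- c(layer$cout, Tt, B)
  list(y = Y, cache = list(Xcol = Xcol, dims = d), layer = layer)
}

bw_conv <- function(layer, cache, dy) {
  d <- cache$dims; C <- d[1]; Tt <- d[2]; B <- d[3]
  k <- layer$k
  dim(dy) <- c(layer$cout, Tt * B)
  dW <- cache$Xcol %*% t(dy)
  db <- rowSums(dy)
  dXcol <- layer$params$W %*% dy
  dim(dXcol) <- c(C, k, Tt, B)
  pl <- (k - 1) %/% 2
  dP <- array(0, c(C, Tt + k - 1, B))
  for (j in 0:(k - 1)) {
    slice <- dXcol[, j + 1, , , drop = FALSE]
    dim(slice) <- c(C, Tt, B)
    dP[, (1 + j):(Tt + j), ] <- dP[, (1 + j):(Tt + j), , drop = FALSE] + slice
  }
  dx <- dP[, (pl + 1):(pl + Tt), , drop = FALSE]
  dim(dx) <- d
  list(dx = dx, grads = list(W = dW, b = db))
}

fw_dense <- function(layer, x, train) {
  list(y = crossprod(layer$params$W, x) + layer$params$b,
       cache = list(x = x), layer = layer)
}
bw_dense <- function(layer, cache, dy) {
  list(dx = layer$params$W %*% dy,
       grads = list(W = cache$x %*% t(dy), b = rowSums(dy)))
}

# helper: move (C,T,B) into (T, C*B) and back (channel index fastest in C*B)
to_tcb <- function(x) {
  d <- dim(x)
  m <- aperm(x, c(2, 1, 3))
  dim(m) <- c(d[2], d[1] * d[3])
  m
}
from_tcb <- function(m, d) {
  dim(m) <- c(d[2], d[1], d[3])
  aperm(m, c(2, 1, 3))
}

# group normalisation core shared by inorm (groups = (c,b) pairs over time)
norm_forward <- function(m, gamma_g, beta_g) {
  Tt <- nrow(m)
  mu <- colMeans(m)
  xc <- m - matrix(mu, Tt, ncol(m), byrow = TRUE)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + EPS_NORM)
  xhat <- xc * matrix(istd, Tt, ncol(m), byrow = TRUE)
  y <- xhat * matrix(gamma_g, Tt, ncol(m), byrow = TRUE) +
    matrix(beta_g, Tt, ncol(m), byrow = TRUE)
  list(y = y, xhat = xhat, istd = istd)
}
norm_backward <- function(dy, xhat, istd, gamma_g) {
  Tt <- nrow(dy)
  n <- ncol(dy)
  dgamma_g <- colSums(dy * xhat)
  dbeta_g <- colSums(dy)
  dxhat <- dy * matrix(gamma_g, Tt, n, byrow = TRUE)
  t1 <- matrix(colMeans(dxhat), Tt, n, byrow = TRUE)
  t2 <- xhat * matrix(colMeans(dxhat * xhat), Tt, n, byrow = TRUE)
  dx <- (dxhat - t1 - t2) * matrix(istd, Tt, n, byrow = TRUE)
  list(dx = dx, dgamma_g = dgamma_g, dbeta_g = dbeta_g)
}

fw_inorm <- function(layer, x, train) {
  d <- dim(x); C <- d[1]; B <- d[3]
  m <- to_tcb(x)
  gcb <- rep(layer$params$gamma, times = B)
  bcb <- rep(layer$params$beta, times = B)
  nf <- norm_forward(m, gcb, bcb)
  list(y = from_tcb(nf$y, d),
       cache = list(xhat = nf$xhat, istd = nf$istd, d = d), layer = layer)
}
bw_inorm <- function(layer, cache, dy) {
  d <- cache$d; C <- d[1]; B <- d[3]
  gcb <- rep(layer$params$gamma, times = B)
  nb <- norm_backward(to_tcb(dy), cache$xhat, cache$istd, gcb)
  # fold (c,b) group gradients back to per-channel parameters
  dgamma <- rowSums(matrix(nb$dgamma_g, C, B))
  dbeta <- rowSums(matrix(nb$dbeta_g, C, B))
  list(dx = from_tcb(nb$dx, d), grads = list(gamma = dgamma, beta = dbeta))
}

fw_bnorm <- function(layer, x, train) {
  d <- dim(x); C <- d[1]; Tt <- d[2]; B <- d[3]
  xm <- matrix(aperm(x, c(2, 3, 1)), Tt * B, C)   # rows = (t,b), cols = c
  if (train) {
    mu <- colMeans(xm)
    xc <- xm - matrix(mu, nrow(xm), C, byrow = TRUE)
    v <- colMeans(xc^2)
    layer$running_mean <- layer$momentum * layer$running_mean +
      (1 - layer$momentum) * mu
    layer$running_var <- layer$momentum * layer$running_var +
      (1 - layer$momentum) * v
  } else {
    mu <- layer$running_mean
    v <- layer$running_var
    xc <- xm - matrix(mu, nrow(xm), C, byrow = TRUE)
  }
  istd <- 1 / sqrt(v + EPS_NORM)
  xhat <- xc * matrix(istd, nrow(xm), C, byrow = TRUE)
  ym <- xhat * matrix(layer$params$gamma, nrow(xm), C, byrow = TRUE) +
    matrix(layer$params$beta, nrow(xm), C, byrow = TRUE)
  y <- aperm(array(ym, c(Tt, B, C)), c(3, 1, 2))
  list(y = y, cache = list(xhat = xhat, istd = istd, d = d, train = train),
       layer = layer)
}
bw_bnorm <- function(layer, cache, dy) {
  d <- cache$d; C <- d[1]; Tt <- d[2]; B <- d[3]
  dym <- matrix(aperm(dy, c(2, 3, 1)), Tt * B, C)
  xhat <- cache$xhat
  n <- nrow(dym)
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- dym * matrix(layer$params$gamma, n, C, byrow = TRUE)
  if (cache$train) {
    t1 <- matrix(colMeans(dxhat), n, C, byrow = TRUE)
    t2 <- xhat * matrix(colMeans(dxhat * xhat), n, C, byrow = TRUE)
    dxm <- (dxhat - t1 - t2) * matrix(cache$istd, n, C, byrow = TRUE)
  } else {
    dxm <- dxhat * matrix(cache$istd, n, C, byrow = TRUE)
  }
  dx <- aperm(array(dxm, c(Tt, B, C)), c(3, 1, 2))
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

fw_prelu <- function(layer, x, train) {
  d <- dim(x)
  a_full <- array(layer$params$a, d)   # channel index fastest: recycles right
  neg <- x < 0
  y <- x
  y[neg] <- a_full[neg] * x[neg]
  list(y = y, cache = list(x = x, neg = neg), layer = layer)
}
bw_prelu <- function(layer, cache, dy) {
  d <- dim(cache$x); C <- d[1]
  a_full <- array(layer$params$a, d)
  dx <- dy
  dx[cache$neg] <- dy[cache$neg] * a_full[cache$neg]
  contrib <- array(0, d)
  contrib[cache$neg] <- dy[cache$neg] * cache$x[cache$neg]
  da <- rowSums(matrix(contrib, C))
  list(dx = dx, grads = list(a = da))
}

fw_relu <- function(layer, x, train) {
  mask <- x > 0
  y <- x * mask
  list(y = y, cache = list(mask = mask), layer = layer)
}
bw_relu <- function(layer, cache, dy) list(dx = dy * cache$mask, grads = list())

fw_dropout <- function(layer, x, train) {
  if (!train || layer$rate <= 0)
    return(list(y = x, cache = list(mask = NULL), layer = layer))
  keep <- 1 - layer$rate
  mask <- array(stats::rbinom(length(x), 1, keep) / keep, dim(x) %||% length(x))
  list(y = x * mask, cache = list(mask = mask), layer = layer)
}
bw_dropout <- function(layer, cache, dy) {
  if (is.null(cache$mask)) list(dx = dy, grads = list())
  else list(dx = dy * cache$mask, grads = list())
}

fw_maxpool <- function(layer, x, train) {
  d <- dim(x); C <- d[1]; Tt <- d[2]; B <- d[3]
  m <- layer$factor
  T2 <- Tt %/% m
  x2 <- x[, seq_len(T2 * m), , drop = FALSE]
  dim(x2) <- c(C, m, T2, B)
  y <- x2[, 1, , , drop = FALSE]
  dim(y) <- c(C, T2, B)
  amax <- array(1L, c(C, T2, B))
  for (j in 2:m) {
    xj <- x2[, j, , , drop = FALSE]
    dim(xj) <- c(C, T2, B)
    upd <- xj > y
    y[upd] <- xj[upd]
    amax[upd] <- j
  }
  list(y = y, cache = list(d = d, amax = amax, T2 = T2), layer = layer)
}
bw_maxpool <- function(layer, cache, dy) {
  d <- cache$d; C <- d[1]; Tt <- d[2]; B <- d[3]
  m <- layer$factor; T2 <- cache$T2
  dx2 <- array(0, c(C, m, T2, B))
  for (j in seq_len(m)) {
    sel <- cache$amax == j
    slice <- array(0, c(C, T2, B))
    slice[sel] <- dy[sel]
    dx2[, j, , ] <- slice
  }
  dim(dx2) <- c(C, m * T2, B)
  dx <- array(0, d)
  dx[, seq_len(m * T2), ] <- dx2
  list(dx = dx, grads = list())
}

fw_flatten <- function(layer, x, train) {
  d <- dim(x)
  y <- x
  dim(y) <- c(d[1] * d[2], d[3])
  list(y = y, cache = list(d = d), layer = layer)
}
bw_flatten <- function(layer, cache, dy) {
  dim(dy) <- cache$d
  list(dx = dy, grads = list())
}

fw_gap <- function(layer, x, train) {
  d <- dim(x)
  m <- to_tcb(x)                      # (T, C*B)
  y <- matrix(colMeans(m), d[1], d[3])
  list(y = y, cache = list(d = d), layer = layer)
}
bw_gap <- function(layer, cache, dy) {
  d <- cache$d
  m <- matrix(rep(as.numeric(dy) / d[2], each = d[2]), d[2], d[1] * d[3])
  list(dx = from_tcb(m, d), grads = list())
}

fw_attention <- function(layer, x, train) {
  d <- dim(x); C <- d[1]; Tt <- d[2]; B <- d[3]
  h <- C %/% 2
  A <- x[seq_len(h), , , drop = FALSE]
  Bv <- x[(h + 1):C, , , drop = FALSE]
  bm <- to_tcb(Bv)                    # (T, h*B)
  mx <- apply(bm, 2, max)
  e <- exp(bm - matrix(mx, Tt, ncol(bm), byrow = TRUE))
  Sm <- e / matrix(colSums(e), Tt, ncol(bm), byrow = TRUE)
  S <- from_tcb(Sm, c(h, Tt, B))
  y <- A * S
  list(y = y, cache = list(A = A, S = S, d = d), layer = layer)
}
bw_attention <- function(layer, cache, dy) {
  d <- cache$d; C <- d[1]; Tt <- d[2]; B <- d[3]
  h <- C %/% 2
  dA <- dy * cache$S
  dS <- dy * cache$A
  Sm <- to_tcb(cache$S)
  dSm <- to_tcb(dS)
  dBm <- Sm * (dSm - matrix(colSums(dSm * Sm), Tt, ncol(Sm), byrow = TRUE))
  dx <- array(0, d)
  dx[seq_len(h), , ] <- dA
  dx[(h + 1):C, , ] <- from_tcb(dBm, c(h, Tt, B))
  list(dx = dx, grads = list())
}

fw_resblock <- function(layer, x, train) {
  caches <- list()
  h <- x
  for (i in 1:3) {
    r <- fw_conv(layer$convs[[i]], h, train)
    caches[[paste0("c", i)]] <- r$cache; h <- r$y
    r <- fw_bnorm(layer$bns[[i]], h, train)
    layer$bns[[i]] <- r$layer
    caches[[paste0("b", i)]] <- r$cache; h <- r$y
    if (i < 3) {
      r <- fw_relu(NULL, h, train)
      caches[[paste0("r", i)]] <- r$cache; h <- r$y
    }
  }
  if (!is.null(layer$shortcut)) {
    r <- fw_conv(layer$shortcut$conv, x, train)
    caches$sc <- r$cache; s <- r$y
    r <- fw_bnorm(layer$shortcut$bn, s, train)
    layer$shortcut$bn <- r$layer
    caches$sb <- r$cache; s <- r$y
  } else s <- x
  sum_ <- h + s
  r <- fw_relu(NULL, sum_, train)
  caches$rout <- r$cache
  list(y = r$y, cache = caches, layer = layer)
}
bw_resblock <- function(layer, cache, dy) {
  grads <- list()
  r <- bw_relu(NULL, cache$rout, dy)
  dsum <- r$dx
  # main path
  d <- dsum
  for (i in 3:1) {
    r <- bw_bnorm(layer$bns[[i]], cache[[paste0("b", i)]], d)
    grads[[paste0("bn", i)]] <- r$grads; d <- r$dx
    r <- bw_conv(layer$convs[[i]], cache[[paste0("c", i)]], d)
    grads[[paste0("conv", i)]] <- r$grads; d <- r$dx
    if (i > 1) {
      r <- bw_relu(NULL, cache[[paste0("r", i - 1)]], d)
      d <- r$dx
    }
  }
  # shortcut path
  if (!is.null(layer$shortcut)) {
    r <- bw_bnorm(layer$shortcut$bn, cache$sb, dsum)
    grads$sbn <- r$grads
    r <- bw_conv(layer$shortcut$conv, cache$sc, r$dx)
    grads$sconv <- r$grads
    d <- d + r$dx
  } else d <- d + dsum
  list(dx = d, grads = grads)
}

## ---- dispatch ------------------------------------------------------------

layer_forward <- function(layer, x, train) {
  switch(layer$type,
         conv = fw_conv(layer, x, train),
         dense = fw_dense(layer, x, train),
         bnorm = fw_bnorm(layer, x, train),
         inorm = fw_inorm(layer, x, train),
         prelu = fw_prelu(layer, x, train),
         relu = fw_relu(layer, x, train),
         dropout = fw_dropout(layer, x, train),
         maxpool = fw_maxpool(layer, x, train),
         flatten = fw_flatten(layer, x, train),
         gap = fw_gap(layer, x, train),
         attention = fw_attention(layer, x, train),
         resblock = fw_resblock(layer, x, train),
         stop("unknown layer type ", layer$type))
}
layer_backward <- function(layer, cache, dy) {
  switch(layer$type,
         conv = bw_conv(layer, cache, dy),
         dense = bw_dense(layer, cache, dy),
         bnorm = bw_bnorm(layer, cache, dy),
         inorm = bw_inorm(layer, cache, dy),
         prelu = bw_prelu(layer, cache, dy),
         relu = bw_relu(layer, cache, dy),
         dropout = bw_dropout(layer, cache, dy),
         maxpool = bw_maxpool(layer, cache, dy),
         flatten = bw_flatten(layer, cache, dy),
         gap = bw_gap(layer, cache, dy),
         attention = bw_attention(layer, cache, dy),
         resblock = bw_resblock(layer, cache, dy),
         stop("unknown layer type ", layer$type))
}

# Forward through a layer list. Returns logits, per-layer caches and the
# (state-updated) layers.
net_forward <- function(layers, x, train = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x, train)
    caches[[i]] <- r$cache
    layers[[i]] <- r$layer
    x <- r$y
  }
  list(logits = x, caches = caches, layers = layers)
}

net_backward <- function(layers, caches, dlogits) {
  grads <- vector("list", length(layers))
  dy <- dlogits
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], caches[[i]], dy)
    grads[[i]] <- r$grads
    dy <- r$dx
  }
  grads
}

## ---- loss and optimiser --------------------------------------------------

softmax_cols <- function(z) {
  z <- z - matrix(apply(z, 2, max), nrow(z), ncol(z), byrow = TRUE)
  e <- exp(z)
  e / matrix(colSums(e), nrow(z), ncol(z), byrow = TRUE)
}

# Weighted cross-entropy. `y` holds 1-based class indices; `w` a per-class
# weight vector (inverse class frequency for imbalance).
ce_loss <- function(logits, y, w) {
  B <- ncol(logits)
  P <- softmax_cols(logits)
  py <- P[cbind(y, seq_len(B))]
  wy <- w[y]
  loss <- sum(-wy * log(pmax(py, 1e-12))) / B
  dZ <- P
  dZ[cbind(y, seq_len(B))] <- dZ[cbind(y, seq_len(B))] - 1
  dZ <- dZ * matrix(wy, nrow(logits), B, byrow = TRUE) / B
  list(loss = loss, dlogits = dZ)
}

# Adam over nested parameter lists; `state` mirrors the gradient structure.
adam_update_params <- function(params, grads, state, lr, t,
                               b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.list(g)) {
      r <- adam_update_params(params[[nm]], g, state[[nm]] %||% list(),
                              lr, t, b1, b2, eps)
      params[[nm]] <- r$params
      state[[nm]] <- r$state
    } else {
      st <- state[[nm]] %||% list(m = 0 * g, v = 0 * g)
      st$m <- b1 * st$m + (1 - b1) * g
      st$v <- b2 * st$v + (1 - b2) * g^2
      mhat <- st$m / (1 - b1^t)
      vhat <- st$v / (1 - b2^t)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      state[[nm]] <- st
    }
  }
  list(params = params, state = state)
}

# Map a layer's (possibly nested, for resblocks) parameters to/from the flat
# update routine.
layer_get_params <- function(layer) {
  if (layer$type == "resblock") {
    p <- list()
    for (i in 1:3) {
      p[[paste0("conv", i)]] <- layer$convs[[i]]$params
      p[[paste0("bn", i)]] <- layer$bns[[i]]$params
    }
    if (!is.null(layer$shortcut)) {
      p$sconv <- layer$shortcut$conv$params
      p$sbn <- layer$shortcut$bn$params
    }
    p
  } else layer$params
}
layer_set_params <- function(layer, p) {
  if (layer$type == "resblock") {
    for (i in 1:3) {
      layer$convs[[i]]$params <- p[[paste0("conv", i)]]
      layer$bns[[i]]$params <- p[[paste0("bn", i)]]
    }
    if (!is.null(layer$shortcut)) {
      layer$shortcut$conv$params <- p$sconv
      layer$shortcut$bn$params <- p$sbn
    }
  } else layer$params <- p
  layer
}

count_params <- function(x) {
  if (is.list(x)) sum(vapply(x, count_params, numeric(1))) else length(x)
}
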