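# Low-level layers for the 3D classification network.
#
# Layout conventions:
#   * one sample  : array dim (D, H, W, C)
#   * a mini-batch: array dim (D, H, W, C, N)
#   * conv weights: array dim (k, k, k, C_in, C_out); the column-major
#     flattening matches the row order produced by im2col3d(), so a 3D
#     convolution is a single BLAS GEMM per sample.
#
# Every *_fw returns list(out, cache); every *_bw consumes (cache, dout)
# and returns list(dx, grads). Gradients are verified against central
# finite differences in the test suite.

.sigmoid <- function(x) 1 / (1 + exp(-x))

.sample4 <- function(x5, n) {
  d <- dim(x5)
  a <- x5[, , , , n, drop = FALSE]
  dim(a) <- d[1:4]
  a
}

# per-channel mean / sum over spatial dims and batch
.ch_reduce <- function(x5, fun = colMeans) {
  d <- dim(x5)
  m <- matrix(x5, prod(d[1:3]), d[4] * d[5])
  v <- matrix(fun(m), d[4], d[5])
  if (identical(fun, colMeans)) rowMeans(v) else rowSums(v)
}

# im2col matrices are kept in the cache during training (so the backward
# pass reuses them) unless the unrolled size is large, as in a full-size
# 64^3 forward pass, where recomputation is cheaper than the memory.
.conv_cache_budget <- 8e6   # doubles per sample

conv_fw <- function(x5, w, b, stride, pad, keep_cols = FALSE) {
  d <- dim(x5); k <- dim(w)[1]; outC <- dim(w)[5]; N <- d[5]
  od <- (d[1:3] + 2L * pad - k) %/% stride + 1L
  K <- k^3 * d[4]
  wmat <- matrix(w, nrow = K)
  out <- array(0, c(od, outC, N))
  keep <- keep_cols && K * prod(od) <= .conv_cache_budget
  saved <- if (keep) vector("list", N)
  for (n in seq_len(N)) {
    cols <- im2col3d(.sample4(x5, n), d[1:4], k, stride, pad)
    if (keep) saved[[n]] <- cols
    om <- crossprod(cols, wmat)
    om <- om + rep(b, each = nrow(om))
    out[, , , , n] <- om
  }
  list(out = out, cache = list(x = x5, w = w, stride = stride, pad = pad,
                               cols = saved))
}

conv_bw <- function(cache, dout) {
  x5 <- cache$x; w <- cache$w
  d <- dim(x5); k <- dim(w)[1]; outC <- dim(w)[5]; N <- d[5]
  K <- k^3 * d[4]
  wmat <- matrix(w, nrow = K)
  dW <- matrix(0, K, outC); db <- numeric(outC)
  dx <- array(0, d)
  nvox <- prod(dim(dout)[1:3])
  for (n in seq_len(N)) {
    cols <- if (!is.null(cache$cols)) cache$cols[[n]] else
      im2col3d(.sample4(x5, n), d[1:4], k, stride = cache$stride,
               pad = cache$pad)
    dom <- matrix(.sample4(dout, n), nvox, outC)
    dW <- dW + cols %*% dom
    db <- db + colSums(dom)
    dx[, , , , n] <- col2im3d(wmat %*% t(dom), d[1:4], k, cache$stride,
                              cache$pad)
  }
  list(dx = dx, grads = list(w = array(dW, dim(w)), b = db))
}

bn_fw <- function(x5, gamma, beta, rm, rv, training, momentum = 0.1,
                  eps = 1e-5) {
  if (training) {
    mu <- .ch_reduce(x5, colMeans)
    va <- .ch_reduce(x5^2, colMeans) - mu^2
    rm <- (1 - momentum) * rm + momentum * mu
    rv <- (1 - momentum) * rv + momentum * va
  } else {
    mu <- rm; va <- rv
  }
  inv_std <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(x5, 4, mu), 4, inv_std, "*")
  out <- sweep(sweep(xhat, 4, gamma, "*"), 4, beta, "+")
  list(out = out,
       cache = list(xhat = xhat, inv_std = inv_std, gamma = gamma),
       rm = rm, rv = rv)
}

bn_bw <- function(cache, dout) {
  xhat <- cache$xhat
  d <- dim(xhat)
  m <- prod(d[c(1, 2, 3, 5)])
  dgamma <- .ch_reduce(dout * xhat, colSums)
  dbeta <- .ch_reduce(dout, colSums)
  scale <- cache$gamma * cache$inv_std
  dx <- sweep(dout, 4, dbeta / m) - sweep(xhat, 4, dgamma / m, "*")
  dx <- sweep(dx, 4, scale, "*")
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

relu_fw <- function(x) list(out = x * (x > 0), cache = x > 0)
relu_bw <- function(cache, dout) dout * cache

linear_fw <- function(X, w, b) {
  out <- X %*% w
  out <- sweep(out, 2, b, "+")
  list(out = out, cache = list(X = X, w = w))
}

linear_bw <- function(cache, dout) {
  list(dx = dout %*% t(cache$w),
       grads = list(w = crossprod(cache$X, dout), b = colSums(dout)))
}

# softmax cross-entropy over rows of an N x n_classes logit matrix;
# y is an integer class index vector (1-based)
softmax_ce <- function(logits, y = NULL) {
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  probs <- ez / rowSums(ez)
  out <- list(probs = probs)
  if (!is.null(y)) {
    N <- nrow(logits)
    out$loss <- -mean(log(pmax(probs[cbind(seq_len(N), y)], 1e-12)))
    dlogits <- probs
    dlogits[cbind(seq_len(N), y)] <- dlogits[cbind(seq_len(N), y)] - 1
    out$dlogits <- dlogits / N
  }
  out
}

# ---- CBAM: channel attention then spatial attention ------------------------

cbam_fw <- function(x5, p, gate = "sigmoid", channel = TRUE, spatial = TRUE,
                    bypass = FALSE, training = FALSE) {
  d <- dim(x5)
  if (bypass || (!channel && !spatial))
    return(list(out = x5, cache = list(bypass = TRUE, d = d)))
  DHW <- prod(d[1:3]); C <- d[4]; N <- d[5]
  cache <- list(bypass = FALSE, d = d, x = x5, gate = gate,
                channel = channel, spatial = spatial)

  y <- x5
  if (channel) {
    m <- matrix(x5, DHW, C * N)
    s_a <- matrix(colMeans(m), C, N)
    amax <- vapply(seq_len(C * N), function(j) {
      w <- which.max(m[, j])   # length 0 on all-NaN (diverged) input
      if (length(w)) w else 1L
    }, 1L)
    s_m <- matrix(m[cbind(amax, seq_len(C * N))], C, N)
    h_a <- p$w1 %*% s_a + p$b1; r_a <- h_a * (h_a > 0)
    h_m <- p$w1 %*% s_m + p$b1; r_m <- h_m * (h_m > 0)
    logits <- p$w2 %*% (r_a + r_m) + 2 * p$b2
    a <- if (gate == "sigmoid") .sigmoid(logits) else {
      e <- exp(sweep(logits, 2, apply(logits, 2, max)))
      sweep(e, 2, colSums(e), "/")
    }
    y <- x5 * array(rep(as.vector(a), each = DHW), d)
    cache[c("s_a", "s_m", "amax", "h_a", "h_m", "r_a", "r_m", "a")] <-
      list(s_a, s_m, amax, h_a, h_m, r_a, r_m, a)
  }

  out <- y
  if (spatial) {
    m2 <- matrix(y, DHW, C * N)
    p_a <- matrix(0, DHW, N); p_m <- matrix(-Inf, DHW, N)
    argc <- matrix(1L, DHW, N)
    for (n in seq_len(N)) {
      cols <- (n - 1L) * C + seq_len(C)
      blk <- m2[, cols, drop = FALSE]
      p_a[, n] <- rowMeans(blk)
      for (cc in seq_len(C)) {
        upd <- which(blk[, cc] > p_m[, n])   # which() drops NaN comparisons
        argc[upd, n] <- cc
        p_m[upd, n] <- blk[upd, cc]
      }
    }
    s2 <- array(0, c(d[1:3], 2L, N))
    s2[, , , 1, ] <- p_a; s2[, , , 2, ] <- p_m
    ks <- dim(p$sw)[1]
    cv <- conv_fw(s2, p$sw, p$sb, stride = 1L, pad = (ks - 1L) %/% 2L,
                  keep_cols = training)
    sg <- .sigmoid(cv$out)                       # (D,H,W,1,N)
    out <- array(0, d)
    for (cc in seq_len(C)) out[, , , cc, ] <- y[, , , cc, ] * sg[, , , 1, ]
    cache[c("y", "argc", "conv_cache", "sg")] <-
      list(y, argc, cv$cache, sg)
  }
  list(out = out, cache = cache)
}

cbam_bw <- function(p, cache, dout) {
  if (cache$bypass)
    return(list(dx = dout, grads = lapply(p, function(a) a * 0)))
  d <- cache$d; DHW <- prod(d[1:3]); C <- d[4]; N <- d[5]
  x5 <- cache$x
  grads <- lapply(p, function(a) a * 0)

  if (cache$spatial) {
    y <- cache$y; sg <- cache$sg
    dsg <- array(0, c(d[1:3], 1L, N))
    dy <- array(0, d)
    for (cc in seq_len(C)) {
      dsg[, , , 1, ] <- dsg[, , , 1, ] + dout[, , , cc, ] * y[, , , cc, ]
      dy[, , , cc, ] <- dout[, , , cc, ] * sg[, , , 1, ]
    }
    dL <- dsg * sg * (1 - sg)
    cbw <- conv_bw(cache$conv_cache, dL)
    grads$sw <- cbw$grads$w; grads$sb <- cbw$grads$b
    ds2 <- cbw$dx
    dpa <- matrix(ds2[, , , 1, ], DHW, N)
    dpm <- matrix(ds2[, , , 2, ], DHW, N)
    dym <- matrix(0, DHW, C * N)
    for (n in seq_len(N)) {
      cols <- (n - 1L) * C + seq_len(C)
      dym[, cols] <- dym[, cols] + dpa[, n] / C
      idx <- cbind(seq_len(DHW), (n - 1L) * C + cache$argc[, n])
      dym[idx] <- dym[idx] + dpm[, n]
    }
    dy <- dy + array(dym, d)
  } else {
    dy <- dout
  }

  if (cache$channel) {
    a <- cache$a
    mx <- matrix(x5, DHW, C * N); mdy <- matrix(dy, DHW, C * N)
    da <- matrix(colSums(mx * mdy), C, N)
    dx <- dy * array(rep(as.vector(a), each = DHW), d)
    dlog <- if (cache$gate == "sigmoid") da * a * (1 - a) else
      a * sweep(da, 2, colSums(da * a))
    # shared two-layer MLP, summed over the avg- and max-pool branches
    grads$w2 <- dlog %*% t(cache$r_a + cache$r_m)
    grads$b2 <- rowSums(dlog) * 2
    dr <- t(p$w2) %*% dlog
    dh_a <- dr * (cache$h_a > 0); dh_m <- dr * (cache$h_m > 0)
    grads$w1 <- dh_a %*% t(cache$s_a) + dh_m %*% t(cache$s_m)
    grads$b1 <- rowSums(dh_a + dh_m)
    ds_a <- t(p$w1) %*% dh_a
    ds_m <- t(p$w1) %*% dh_m
    dxm <- matrix(dx, DHW, C * N)
    dxm <- sweep(dxm, 2, as.vector(ds_a) / DHW, "+")
    idx <- cbind(cache$amax, seq_len(C * N))
    dxm[idx] <- dxm[idx] + as.vector(ds_m)
    dx <- array(dxm, d)
  } else {
    dx <- dy
  }
  list(dx = dx, grads = grads)
}

# ---- residual block: x + ReLU(BN2(conv2(ReLU(BN1(conv1(x)))))) -------------

resblock_fw <- function(x5, p, st, training) {
  c1 <- conv_fw(x5, p$conv1$w, p$conv1$b, 1L, 1L, keep_cols = training)
  b1 <- bn_fw(c1$out, p$bn1$gamma, p$bn1$beta, st$bn1$rm, st$bn1$rv, training)
  r1 <- relu_fw(b1$out)
  c2 <- conv_fw(r1$out, p$conv2$w, p$conv2$b, 1L, 1L, keep_cols = training)
  b2 <- bn_fw(c2$out, p$bn2$gamma, p$bn2$beta, st$bn2$rm, st$bn2$rv, training)
  r2 <- relu_fw(b2$out)
  list(out = x5 + r2$out,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                    c2 = c2$cache, b2 = b2$cache, r2 = r2$cache),
       state = list(bn1 = list(rm = b1$rm, rv = b1$rv),
                    bn2 = list(rm = b2$rm, rv = b2$rv)))
}

resblock_bw <- function(cache, dout) {
  dr2 <- relu_bw(cache$r2, dout)
  b2 <- bn_bw(cache$b2, dr2)
  c2 <- conv_bw(cache$c2, b2$dx)
  dr1 <- relu_bw(cache$r1, c2$dx)
  b1 <- bn_bw(cache$b1, dr1)
  c1 <- conv_bw(cache$c1, b1$dx)
  list(dx = dout + c1$dx,
       grads = list(conv1 = c1$grads, bn1 = b1$grads,
                    conv2 = c2$grads, bn2 = b2$grads))
}

# ---- Adam over an arbitrarily nested parameter list ------------------------

adam_init <- function(params) {
  zero <- function(x) if (is.list(x)) lapply(x, zero) else x * 0
  list(m = zero(params), v = zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (k in seq_along(p)) {
        if (is.null(p[[k]])) next
        r <- upd(p[[k]], g[[k]], m[[k]], v[[k]])
        out$p[[k]] <- r$p; out$m[[k]] <- r$m; out$v[[k]] <- r$v
      }
      out
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
    }
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}
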