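# Primitive differentiable ops of the conv-net engine. Every *Fwd returns
# list(out, cache); every *Bwd takes (d_out, cache) and returns d_in (plus
# parameter gradients where applicable). Arrays are (H, W, C, N).

convFwd <- function(x, w, b, stride, pad) {
  y <- cpp_conv_forward(x, w, as.integer(stride), as.integer(pad))
  if (!is.null(b)) {
    d <- dim(y)
    y <- y + rep(rep(b, each = d[1] * d[2]), times = d[4])
  }
  list(out = y, cache = list(x = x, w = w, stride = stride, pad = pad,
                             has_b = !is.null(b)))
}

convBwd <- function(dy, cache) {
  g <- cpp_conv_backward(cache$x, cache$w, dy,
                         as.integer(cache$stride), as.integer(cache$pad))
  db <- NULL
  if (cache$has_b) db <- apply(dy, 3, sum)
  list(dx = g$dx, dw = g$dw, db = db)
}

# per-channel sum over (H, W, N) via reshape + colSums (fast path for apply)
chSum3 <- function(x, d) {
  s <- colSums(matrix(x, d[1] * d[2], d[3] * d[4]))
  if (d[4] > 1L) rowSums(matrix(s, d[3], d[4])) else s
}

# per-(channel, sample) mean / sum, returned as C x N matrices
chMean34 <- function(x, d) {
  matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
}
chSum34 <- function(x, d) {
  matrix(colSums(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
}

# Batch normalization over (H, W, N) per channel; v5-style eps/momentum.
bnFwd <- function(x, gamma, beta, rmean, rvar, train, eps = 1e-3, momentum = 0.03) {
  d <- dim(x); hw <- d[1] * d[2]
  if (train) {
    mom <- cpp_channel_moments(x)
    mu <- mom$mean
    vr <- pmax(mom$meansq - mu^2, 0)
    new_rmean <- (1 - momentum) * rmean + momentum * mu
    m <- hw * d[4]
    new_rvar <- (1 - momentum) * rvar + momentum * vr * m / max(1, m - 1)
  } else {
    mu <- rmean; vr <- rvar
    new_rmean <- rmean; new_rvar <- rvar
  }
  istd <- 1 / sqrt(vr + eps)
  xhat <- cpp_affine_ch(x, istd, -mu * istd)
  y <- cpp_affine_ch(xhat, gamma, beta)
  list(out = y,
       cache = list(xhat = xhat, istd = istd, gamma = gamma, train = train, d = d),
       rmean = new_rmean, rvar = new_rvar)
}

bnBwd <- function(dy, cache) {
  d <- cache$d
  m <- d[1] * d[2] * d[4]
  dgamma <- chSum3(dy * cache$xhat, d)
  dbeta <- chSum3(dy, d)
  if (cache$train) {
    # standard BN backward through the batch statistics
    dx <- cpp_bn_backward_dx(dy, cache$xhat, dbeta / m, dgamma / m,
                             cache$gamma * cache$istd)
  } else {
    dx <- cpp_affine_ch(dy, cache$gamma * cache$istd, numeric(cache$d[3]))
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# broadcast a per-channel vector over an (H, W, C, N) shape
rep_ch <- function(v, d) rep(rep(v, each = d[1] * d[2]), times = d[4])

siluFwd <- function(x) {
  s <- sigmoid(x)
  list(out = x * s, cache = list(x = x, s = s))
}

siluBwd <- function(dy, cache) {
  s <- cache$s
  dy * (s * (1 + cache$x * (1 - s)))
}

maxpoolFwd <- function(x, k, stride = 1L, pad = NULL) {
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  r <- cpp_maxpool_forward(x, as.integer(k), as.integer(stride), as.integer(pad))
  list(out = r$y, cache = list(idx = r$idx, xdim = dim(x)))
}

maxpoolBwd <- function(dy, cache) {
  cpp_maxpool_backward(dy, cache$idx, as.integer(cache$xdim))
}

upsample2Fwd <- function(x) {
  d <- dim(x)
  ih <- rep(seq_len(d[1]), each = 2)
  iw <- rep(seq_len(d[2]), each = 2)
  list(out = x[ih, iw, , , drop = FALSE], cache = d)
}

upsample2Bwd <- function(dy, d) {
  dd <- dim(dy)
  # sum each 2x2 block back to the source cell
  y1 <- dy[seq(1, dd[1], 2), , , , drop = FALSE] + dy[seq(2, dd[1], 2), , , , drop = FALSE]
  y1[, seq(1, dd[2], 2), , , drop = FALSE] + y1[, seq(2, dd[2], 2), , , drop = FALSE]
}

# --- Shuffle Attention with backward ------------------------------------

channelBranchFwd <- function(x, scale, shift) {
  d <- dim(x); hw <- d[1] * d[2]
  s <- chMean34(x, d)                                # C x N
  gate <- sigmoid(scale * s + shift)
  gb <- rep(gate, each = hw)
  list(out = x * gb,
       cache = list(x = x, s = s, gate = gate, scale = scale, d = d))
}

channelBranchBwd <- function(dy, cache) {
  d <- cache$d; hw <- d[1] * d[2]
  gate <- cache$gate
  dgate <- chSum34(dy * cache$x, d)                  # C x N
  dpre <- dgate * gate * (1 - gate)                  # through sigmoid
  dx <- dy * rep(gate, each = hw) +
    rep(dpre * cache$scale / hw, each = hw)
  dscale <- rowSums(dpre * cache$s)
  dshift <- rowSums(dpre)
  list(dx = dx, dscale = dscale, dshift = dshift)
}

spatialBranchFwd <- function(x, scale, shift, eps = 1e-5) {
  d <- dim(x); hw <- d[1] * d[2]
  mu <- chMean34(x, d)
  vr <- pmax(chMean34(x * x, d) - mu^2, 0)
  istd <- 1 / sqrt(vr + eps)
  xn <- (x - rep(mu, each = hw)) * rep(istd, each = hw)
  scb <- as.vector(rep(scale, each = hw))
  shb <- as.vector(rep(shift, each = hw))
  gate <- sigmoid(xn * scb + shb)
  list(out = x * gate,
       cache = list(x = x, xn = xn, istd = istd, gate = gate,
                    scale = scale, d = d))
}

spatialBranchBwd <- function(dy, cache) {
  d <- cache$d; hw <- d[1] * d[2]
  gate <- cache$gate; xn <- cache$xn
  scb <- as.vector(rep(cache$scale, each = hw))
  dgate <- dy * cache$x
  dpre <- dgate * gate * (1 - gate)
  dscale <- chSum3(dpre * xn, d)
  dshift <- chSum3(dpre, d)
  dxn <- dpre * scb
  # instance-norm backward per (channel, sample)
  mean_dxn <- chMean34(dxn, d)
  mean_dxn_xn <- chMean34(dxn * xn, d)
  dx_norm <- (dxn - rep(mean_dxn, each = hw) -
                xn * rep(mean_dxn_xn, each = hw)) * rep(cache$istd, each = hw)
  dx <- dy * gate + dx_norm
  list(dx = dx, dscale = dscale, dshift = dshift)
}

saFwd <- function(x, params, groups) {
  d <- dim(x); C <- d[3]
  m <- C / (2 * groups)
  y <- x
  caches <- vector("list", groups)
  for (g in seq_len(groups)) {
    i0 <- (g - 1) * 2 * m
    ci <- i0 + seq_len(m); si <- i0 + m + seq_len(m)
    cb <- channelBranchFwd(x[, , ci, , drop = FALSE],
                           params$cb_scale[, g], params$cb_shift[, g])
    sb <- spatialBranchFwd(x[, , si, , drop = FALSE],
                           params$sb_scale[, g], params$sb_shift[, g])
    y[, , ci, ] <- cb$out
    y[, , si, ] <- sb$out
    caches[[g]] <- list(cb = cb$cache, sb = sb$cache, ci = ci, si = si)
  }
  perm <- channelShufflePerm(C, groups)
  list(out = y[, , perm, , drop = FALSE],
       cache = list(caches = caches, perm = perm, groups = groups, m = m, d = d))
}

saBwd <- function(dy, cache, params) {
  inv <- order(cache$perm)
  dz <- dy[, , inv, , drop = FALSE]   # undo the shuffle: out = y[perm]
  dx <- dz
  g_ <- cache$groups
  grads <- list(cb_scale = params$cb_scale * 0, cb_shift = params$cb_shift * 0,
                sb_scale = params$sb_scale * 0, sb_shift = params$sb_shift * 0)
  for (g in seq_len(g_)) {
    cc <- cache$caches[[g]]
    bc <- channelBranchBwd(dz[, , cc$ci, , drop = FALSE], cc$cb)
    bs <- spatialBranchBwd(dz[, , cc$si, , drop = FALSE], cc$sb)
    dx[, , cc$ci, ] <- bc$dx
    dx[, , cc$si, ] <- bs$dx
    grads$cb_scale[, g] <- bc$dscale; grads$cb_shift[, g] <- bc$dshift
    grads$sb_scale[, g] <- bs$dscale; grads$sb_shift[, g] <- bs$dshift
  }
  list(dx = dx, grads = grads)
}
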