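#' Channel shuffle permutation
#'
#' Reorders the channel axis of a feature map by the
#' reshape(groups, C/groups) -> transpose -> flatten permutation, so that
#' channels from different groups become interleaved. Values are untouched;
#' applying the inverse permutation ([channelShuffleInverse()]) restores the
#' input exactly.
#'
#' @param x numeric array with axes (height, width, channel, batch).
#' @param groups positive integer dividing the channel count.
#' @return array of the same shape with channels permuted.
#' @examples
#' x <- array(seq_len(4), c(1, 1, 4, 1))
#' drop(channelShuffle(x, 2))  # 1 3 2 4
#' @export
channelShuffle <- function(x, groups) {
  perm <- channelShufflePerm(dim(x)[3], groups)
  x[, , perm, , drop = FALSE]
}

channelShufflePerm <- function(C, groups) {
  if (groups < 1 || C %% groups != 0)
    stop(sprintf("shape error: %d channels not divisible by %d groups", C, groups))
  as.vector(matrix(seq_len(C), nrow = groups, byrow = TRUE))
}

#' @rdname channelShuffle
#' @export
channelShuffleInverse <- function(x, groups) {
  perm <- channelShufflePerm(dim(x)[3], groups)
  inv <- order(perm)
  x[, , inv, , drop = FALSE]
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Channel-attention branch of the Shuffle Attention unit
#'
#' Gates each channel of a sub-feature by
#' `sigmoid(scale * GAP(x) + shift)` where GAP is the global average pool
#' over the spatial axes, broadcast back over space.
#'
#' @param x numeric array (H, W, C, N) — one group's channel half.
#' @param scale,shift per-channel affine parameters, length `dim(x)[3]`.
#' @return gated array of the same shape.
#' @export
channelBranch <- function(x, scale, shift) {
  d <- dim(x)
  if (length(scale) != d[3] || length(shift) != d[3])
    stop("shape error: affine parameter length must equal channel count")
  s <- apply(x, c(3, 4), mean)                     # C x N
  gate <- sigmoid(scale * s + shift)               # recycled per channel
  x * rep(gate, each = d[1] * d[2])
}

#' Spatial-attention branch of the Shuffle Attention unit
#'
#' Normalizes each channel of the sub-feature over its spatial extent
#' (per-sample, per-channel statistics with epsilon `eps`), then gates
#' elementwise by `sigmoid(scale * norm(x) + shift)`.
#'
#' @inheritParams channelBranch
#' @param eps variance floor of the normalization.
#' @export
spatialBranch <- function(x, scale, shift, eps = 1e-5) {
  d <- dim(x)
  if (length(scale) != d[3] || length(shift) != d[3])
    stop("shape error: affine parameter length must equal channel count")
  hw <- d[1] * d[2]
  mu <- apply(x, c(3, 4), mean)
  vr <- apply(x, c(3, 4), function(v) mean((v - mean(v))^2))
  xn <- (x - rep(mu, each = hw)) / rep(sqrt(vr + eps), each = hw)
  sc <- rep(scale, each = hw)   # recycles over the batch axis
  sh <- rep(shift, each = hw)
  gate <- sigmoid(xn * as.vector(sc) + as.vector(sh))
  x * gate
}

#' Initialize Shuffle Attention parameters
#'
#' One SA block splits `C` channels into `groups` groups; each group is
#' halved into a channel-attention and a spatial-attention sub-feature of
#' `C/(2*groups)` channels, each with its own per-channel scale and shift.
#' Scales start at 1 and shifts at 0 so the block initially passes a
#' half-gated signal without distorting channel balance.
#'
#' @param channels channel count `C` (must be divisible by `2 * groups`).
#' @param groups number of groups `G`.
#' @return list of four `C/(2G) x G` matrices: `cb_scale`, `cb_shift`,
#'   `sb_scale`, `sb_shift`.
#' @export
saParams <- function(channels, groups) {
  if (channels %% (2 * groups) != 0)
    stop(sprintf("shape error: %d channels not divisible by 2 x %d groups",
                 channels, groups))
  m <- channels / (2 * groups)
  list(cb_scale = matrix(1, m, groups), cb_shift = matrix(0, m, groups),
       sb_scale = matrix(1, m, groups), sb_shift = matrix(0, m, groups))
}

#' Trainable parameter count of one SA block
#'
#' Four per-channel affine vectors of length `C/(2G)` for each of the `G`
#' groups: `4 * G * C/(2G) = 2C` parameters regardless of `G`.
#'
#' @inheritParams saParams
#' @export
saParamCount <- function(channels, groups) {
  m <- channels / (2 * groups)
  4 * groups * m
}

#' Shuffle Attention forward transform
#'
#' Splits the channels into `groups` groups, halves each group into a
#' channel-attention and a spatial-attention sub-feature, applies the two
#' gating branches, concatenates all groups back and finally mixes them with
#' a channel shuffle. Shape-preserving; with all affine parameters zero the
#' output is exactly `0.5 * channelShuffle(x, groups)`.
#'
#' @param x numeric array (H, W, C, N), `C` divisible by `2 * groups`.
#' @param params parameter list from [saParams()].
#' @param groups number of groups `G`.
#' @return array of the same shape as `x`.
#' @export
saForward <- function(x, params, groups) {
  d <- dim(x)
  C <- d[3]
  if (C %% (2 * groups) != 0)
    stop(sprintf("shape error: %d channels not divisible by 2 x %d groups", C, groups))
  m <- C / (2 * groups)
  y <- x
  for (g in seq_len(groups)) {
    i0 <- (g - 1) * 2 * m
    ci <- i0 + seq_len(m)          # channel-attention half
    si <- i0 + m + seq_len(m)      # spatial-attention half
    y[, , ci, , drop = FALSE] -> xc
    y[, , si, , drop = FALSE] -> xs
    y[, , ci, ] <- channelBranch(xc, params$cb_scale[, g], params$cb_shift[, g])
    y[, , si, ] <- spatialBranch(xs, params$sb_scale[, g], params$sb_shift[, g])
  }
  channelShuffle(y, groups)
}
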