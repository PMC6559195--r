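# Separable Gaussian filtering and interpolation helpers shared by the
# pre-processing, registration and fMRI stages. All kernels are normalized
# and edges are handled by renormalized (truncated-kernel) convolution, so
# a constant image is exactly invariant.

gauss_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Convolve `arr` along `axis` with 1-D kernel `k` (odd length), truncated and
# renormalized at the edges. Works for any array dimensionality.
convolve_axis <- function(arr, k, axis) {
  if (length(k) == 1L) return(arr)
  d <- dim(arr)
  nd <- length(d)
  n <- d[axis]
  r <- (length(k) - 1L) %/% 2L
  # dense banded operator with per-row renormalization
  K <- matrix(0, n, n)
  for (j in seq_along(k)) {
    off <- j - r - 1L
    rows <- seq_len(n)[seq_len(n) + off >= 1 & seq_len(n) + off <= n]
    K[cbind(rows, rows + off)] <- k[j]
  }
  K <- K / rowSums(K)
  perm <- c(axis, seq_len(nd)[-axis])
  a <- aperm(arr, perm)
  a <- matrix(a, nrow = n)
  a <- K %*% a
  dim(a) <- d[perm]
  aperm(a, order(perm))
}

# sigma: one value per requested axis (in voxels); axes: which array axes.
gauss_smooth <- function(arr, sigma, axes = seq_along(sigma)) {
  for (i in seq_along(axes)) {
    if (sigma[i] > 0) arr <- convolve_axis(arr, gauss_kernel_1d(sigma[i]), axes[i])
  }
  arr
}

# ---- interpolation ------------------------------------------------------

# Sample 3D array at fractional 0-based voxel coordinates (n x 3 matrix).
# Out-of-field samples return `outside`.
sample_trilinear <- function(arr, idx, outside = 0) {
  d <- dim(arr)
  x <- idx[, 1]; y <- idx[, 2]; z <- idx[, 3]
  inside <- x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1 & z >= 0 & z <= d[3] - 1
  out <- rep(outside, nrow(idx))
  if (!any(inside)) return(out)
  x <- x[inside]; y <- y[inside]; z <- z[inside]
  x0 <- pmin(floor(x), d[1] - 2); y0 <- pmin(floor(y), d[2] - 2); z0 <- pmin(floor(z), d[3] - 2)
  x0 <- pmax(x0, 0); y0 <- pmax(y0, 0); z0 <- pmax(z0, 0)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  base <- function(i, j, k) arr[cbind(i + 1, j + 1, k + 1)]
  v <- (1 - fx) * (1 - fy) * (1 - fz) * base(x0, y0, z0) +
    fx * (1 - fy) * (1 - fz) * base(x0 + 1, y0, z0) +
    (1 - fx) * fy * (1 - fz) * base(x0, y0 + 1, z0) +
    (1 - fx) * (1 - fy) * fz * base(x0, y0, z0 + 1) +
    fx * fy * (1 - fz) * base(x0 + 1, y0 + 1, z0) +
    fx * (1 - fy) * fz * base(x0 + 1, y0, z0 + 1) +
    (1 - fx) * fy * fz * base(x0, y0 + 1, z0 + 1) +
    fx * fy * fz * base(x0 + 1, y0 + 1, z0 + 1)
  out[inside] <- v
  out
}

sample_nearest <- function(arr, idx, outside = 0) {
  d <- dim(arr)
  i <- round(idx[, 1]); j <- round(idx[, 2]); k <- round(idx[, 3])
  inside <- i >= 0 & i <= d[1] - 1 & j >= 0 & j <= d[2] - 1 & k >= 0 & k <= d[3] - 1
  out <- rep(outside, nrow(idx))
  out[inside] <- arr[cbind(i[inside] + 1, j[inside] + 1, k[inside] + 1)]
  out
}

# Trilinear sample plus the exact gradient of the interpolant w.r.t. the
# continuous (0-based) voxel coordinates; value/gradient are 0 outside.
sample_trilinear_grad <- function(arr, idx) {
  d <- dim(arr)
  n <- nrow(idx)
  x <- idx[, 1]; y <- idx[, 2]; z <- idx[, 3]
  inside <- x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1 & z >= 0 & z <= d[3] - 1
  val <- gx <- gy <- gz <- numeric(n)
  if (!any(inside)) return(list(value = val, gx = gx, gy = gy, gz = gz))
  x <- x[inside]; y <- y[inside]; z <- z[inside]
  x0 <- pmax(pmin(floor(x), d[1] - 2), 0)
  y0 <- pmax(pmin(floor(y), d[2] - 2), 0)
  z0 <- pmax(pmin(floor(z), d[3] - 2), 0)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  c000 <- arr[cbind(x0 + 1, y0 + 1, z0 + 1)]
  c100 <- arr[cbind(x0 + 2, y0 + 1, z0 + 1)]
  c010 <- arr[cbind(x0 + 1, y0 + 2, z0 + 1)]
  c001 <- arr[cbind(x0 + 1, y0 + 1, z0 + 2)]
  c110 <- arr[cbind(x0 + 2, y0 + 2, z0 + 1)]
  c101 <- arr[cbind(x0 + 2, y0 + 1, z0 + 2)]
  c011 <- arr[cbind(x0 + 1, y0 + 2, z0 + 2)]
  c111 <- arr[cbind(x0 + 2, y0 + 2, z0 + 2)]
  # interpolate along x first
  a00 <- c000 + fx * (c100 - c000)
  a10 <- c010 + fx * (c110 - c010)
  a01 <- c001 + fx * (c101 - c001)
  a11 <- c011 + fx * (c111 - c011)
  b0 <- a00 + fy * (a10 - a00)
  b1 <- a01 + fy * (a11 - a01)
  val[inside] <- b0 + fz * (b1 - b0)
  dx00 <- c100 - c000; dx10 <- c110 - c010; dx01 <- c101 - c001; dx11 <- c111 - c011
  gx[inside] <- (dx00 + fy * (dx10 - dx00)) * (1 - fz) +
    (dx01 + fy * (dx11 - dx01)) * fz
  gy[inside] <- (a10 - a00) * (1 - fz) + (a11 - a01) * fz
  gz[inside] <- b1 - b0
  list(value = val, gx = gx, gy = gy, gz = gz)
}

# 0-based voxel index grid of a 3D volume as an n x 3 matrix (x fastest).
voxel_index_grid <- function(d) {
  cbind(
    rep.int(seq_len(d[1]) - 1, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  )
}

# Bilinear sampling of a 2D array at fractional 0-based coords.
sample_bilinear_2d <- function(arr, idx, outside = 0) {
  d <- dim(arr)
  x <- idx[, 1]; y <- idx[, 2]
  inside <- x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1
  out <- rep(outside, nrow(idx))
  if (!any(inside)) return(out)
  x <- x[inside]; y <- y[inside]
  x0 <- pmax(pmin(floor(x), d[1] - 2), 0)
  y0 <- pmax(pmin(floor(y), d[2] - 2), 0)
  fx <- x - x0; fy <- y - y0
  v <- (1 - fx) * (1 - fy) * arr[cbind(x0 + 1, y0 + 1)] +
    fx * (1 - fy) * arr[cbind(x0 + 2, y0 + 1)] +
    (1 - fx) * fy * arr[cbind(x0 + 1, y0 + 2)] +
    fx * fy * arr[cbind(x0 + 2, y0 + 2)]
  out[inside] <- v
  out
}

# Downsample a 3D array by 2 along each axis by block averaging (used by the
# multi-resolution registration pyramid).
downsample2 <- function(arr) {
  d <- dim(arr)
  dn <- pmax(d %/% 2L, 1L)
  arr <- arr[seq_len(dn[1] * 2), seq_len(dn[2] * 2), seq_len(dn[3] * 2), drop = FALSE]
  idx <- function(n) rep(seq_len(n), each = 2L)
  out <- array(0, dn)
  acc <- arr
  # average pairs along each axis in turn
  acc <- (acc[seq(1, 2 * dn[1], 2), , , drop = FALSE] +
            acc[seq(2, 2 * dn[1], 2), , , drop = FALSE]) / 2
  acc <- (acc[, seq(1, 2 * dn[2], 2), , drop = FALSE] +
            acc[, seq(2, 2 * dn[2], 2), , drop = FALSE]) / 2
  acc <- (acc[, , seq(1, 2 * dn[3], 2), drop = FALSE] +
            acc[, , seq(2, 2 * dn[3], 2), drop = FALSE]) / 2
  acc
}

# Run an expression with a private, restored RNG state.
with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
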