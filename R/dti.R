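# Diffusion pipeline: gradient schemes, slice-wise rigid motion
# correction, log-linear tensor estimation, and the FA/MD/RD/AD scalar
# maps derived from the tensor eigenvalues.

#' Diffusion gradient scheme
#'
#' @param b_values numeric vector of b-values (s/mm^2), one per volume.
#' @param b_vectors matrix (n x 3) of gradient directions; unit length for
#'   b > 0 (b0 rows may be zero).
#' @param b0_threshold b-values at or below this count as b0.
#' @return A `gradient_scheme` with `n_b0` and the diffusion-weighted
#'   direction count.
#' @export
gradient_scheme <- function(b_values, b_vectors, b0_threshold = 10) {
  b_values <- as.numeric(b_values)
  b_vectors <- as.matrix(b_vectors)
  if (nrow(b_vectors) != length(b_values) || ncol(b_vectors) != 3) {
    stop("'b_vectors' must be an n x 3 matrix matching length(b_values)")
  }
  is_b0 <- b_values <= b0_threshold
  if (!any(is_b0)) stop("scheme needs at least one b0 volume")
  nrm <- sqrt(rowSums(b_vectors^2))
  if (any(abs(nrm[!is_b0] - 1) > 1e-3)) {
    stop("b > 0 gradient vectors must be unit length")
  }
  dirs <- unique(round(b_vectors[!is_b0, , drop = FALSE], 6))
  if (nrow(dirs) < 6) stop("need >= 6 unique gradient directions for a tensor fit")
  structure(list(b_values = b_values, b_vectors = b_vectors, is_b0 = is_b0,
                 n_b0 = sum(is_b0)),
            class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat("<gradient_scheme> ", length(x$b_values), " volumes: ", x$n_b0,
      " b0 + ", sum(!x$is_b0), " diffusion-weighted (b up to ",
      max(x$b_values), " s/mm^2)\n", sep = "")
  invisible(x)
}

#' Read FSL-style bval/bvec text files
#'
#' @param bval_path,bvec_path whitespace-delimited text files: one row of
#'   b-values; three rows (x, y, z) of direction components.
#' @return A [gradient_scheme()].
#' @export
read_gradient_scheme <- function(bval_path, bvec_path) {
  bv <- scan(bval_path, quiet = TRUE)
  vecs <- as.matrix(read.table(bvec_path))
  if (nrow(vecs) == 3) vecs <- t(vecs)
  gradient_scheme(bv, vecs)
}

# ---- slice-wise motion correction --------------------------------------

# 2D rigid resampling: rotate by theta (deg) about the slice centre then
# translate by (tx, ty) in voxels; bilinear.
rigid_resample_2d <- function(slice, tx, ty, theta_deg) {
  d <- dim(slice)
  th <- theta_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  cx <- (d[1] - 1) / 2; cy <- (d[2] - 1) / 2
  g <- cbind(rep.int(seq_len(d[1]) - 1, d[2]),
             rep(seq_len(d[2]) - 1, each = d[1]))
  x <- g[, 1] - cx; y <- g[, 2] - cy
  xs <- ct * x - st * y + cx + tx
  ys <- st * x + ct * y + cy + ty
  array(sample_bilinear_2d(slice, cbind(xs, ys)), d)
}

# Integer-shift initialization: brute-force SSD over a +/- `radius` voxel
# window (overlap-normalized), evaluated by pure index offsetting.
int_shift_init_2d <- function(ref, mov, radius = 5L) {
  d <- dim(ref)
  best <- c(0, 0)
  best_v <- Inf
  for (sx in -radius:radius) {
    xs_m <- max(1, 1 - sx):min(d[1], d[1] - sx)
    for (sy in -radius:radius) {
      ys_m <- max(1, 1 - sy):min(d[2], d[2] - sy)
      dd <- mov[xs_m + sx, ys_m + sy] - ref[xs_m, ys_m]
      v <- mean(dd^2)
      if (v < best_v) {
        best_v <- v
        best <- c(sx, sy)
      }
    }
  }
  best
}

#' Slice-wise rigid motion correction of a 4D series
#'
#' Head motion in fast rodent EPI shows up as in-plane displacements that
#' differ between slices, which volume-wise correction cannot model. Each
#' z-slice is therefore treated as its own 2D time series: every time
#' frame is rigidly aligned (in-plane translation + rotation, 3 DOF) to
#' the middle frame of the series, and the corrected slices are merged
#' back into one 4D data set.
#'
#' @param series a 4D [mri_volume()] with >= 3 frames.
#' @return List with `corrected` (4D `mri_volume`) and `parameters`: array
#'   `(z, t, 3)` of per-slice, per-frame (tx mm, ty mm, theta deg)
#'   estimates (the motion, i.e. minus the applied correction), plus a
#'   logical `flat_slices` flag vector for slices with no signal.
#' @export
motion_correct_slicewise <- function(series) {
  stopifnot(inherits(series, "mri_volume"))
  if (!is_4d(series)) stop("motion correction requires a 4D series")
  d <- dim(series$data)
  nt <- d[4]
  if (nt < 3) stop("need >= 3 volumes")
  ref_t <- ceiling(nt / 2)
  out <- series$data
  pars <- array(0, c(d[3], nt, 3),
                dimnames = list(NULL, NULL, c("tx_mm", "ty_mm", "theta_deg")))
  flat <- logical(d[3])
  vx <- series$voxel_size
  for (z in seq_len(d[3])) {
    ref <- series$data[, , z, ref_t]
    if (sd(ref) == 0) {
      flat[z] <- TRUE
      next
    }
    for (t in seq_len(nt)) {
      if (t == ref_t) next
      mov <- series$data[, , z, t]
      if (sd(mov) == 0) next
      init <- int_shift_init_2d(ref, mov)
      cost <- function(p) {
        r <- rigid_resample_2d(mov, p[1], p[2], p[3])
        mean((r - ref)^2)
      }
      # translation-only first: the rotation DOF otherwise trades off
      # against translation on smooth low-contrast slices
      ct <- function(q) cost(c(q, 0))
      q <- optim(c(init[1], init[2]), ct, method = "Nelder-Mead",
                 control = list(maxit = 200, reltol = 1e-12))$par
      q <- optim(q, ct, method = "Nelder-Mead",
                 control = list(maxit = 200, reltol = 1e-12))$par
      p <- c(q, 0)
      for (round in 1:2) {
        p <- optim(p, cost, method = "Nelder-Mead",
                   control = list(maxit = 300, reltol = 1e-12,
                                  parscale = c(1, 1, 2)))$par
      }
      if (cost(p) > cost(c(q, 0))) p <- c(q, 0)
      out[, , z, t] <- rigid_resample_2d(mov, p[1], p[2], p[3])
      # report the *motion* (inverse of the applied correction), in mm/deg
      pars[z, t, ] <- c(-p[1] * vx[1], -p[2] * vx[2], -p[3])
    }
  }
  corrected <- series
  corrected$data <- out
  list(corrected = corrected, parameters = pars, flat_slices = flat)
}

# ---- tensor fitting -----------------------------------------------------

#' Fit diffusion tensors by log-linear least squares
#'
#' Per masked voxel, solves `ln S(g, b) = ln S0 - b g' D g` for the six
#' unique tensor elements and ln S0 by ordinary least squares. Non-positive
#' signals are floored at machine epsilon (flagged); negative eigenvalues
#' are clamped to zero with a clamp count reported.
#'
#' @param dwi 4D [mri_volume()]; 4th axis matches the scheme.
#' @param scheme a [gradient_scheme()].
#' @param mask binary `mri_volume`.
#' @return A `tensor_field`: per-voxel tensors (`d6`, order xx yy zz xy xz
#'   yz), eigenvalues `l1 >= l2 >= l3`, principal directions `e1`, `s0`,
#'   the `mask`, and counts `n_clamped`, `n_floored`.
#' @export
fit_tensor <- function(dwi, scheme, mask) {
  stopifnot(inherits(dwi, "mri_volume"), inherits(scheme, "gradient_scheme"),
            inherits(mask, "mri_volume"))
  d <- dim(dwi$data)
  if (d[4] != length(scheme$b_values)) {
    stop("scheme length does not match the number of volumes")
  }
  m <- mask$data != 0
  if (!any(m)) stop("empty mask")
  b <- scheme$b_values
  g <- scheme$b_vectors
  X <- cbind(-b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3], 1)
  if (qr(X)$rank < 7) stop("rank-deficient design matrix: directions are degenerate")
  Xp <- solve(crossprod(X), t(X))
  S <- matrix(aperm(dwi$data, c(4, 1, 2, 3)), nrow = d[4])[, as.vector(m), drop = FALSE]
  n_floored <- sum(S <= 0)
  S[S <= 0] <- .Machine$double.eps
  beta <- Xp %*% log(S)                       # 7 x n_mask
  nmask <- ncol(beta)
  l <- matrix(0, nmask, 3)
  e1 <- matrix(0, nmask, 3)
  n_clamped <- 0L
  for (i in seq_len(nmask)) {
    Dm <- matrix(c(beta[1, i], beta[4, i], beta[5, i],
                   beta[4, i], beta[2, i], beta[6, i],
                   beta[5, i], beta[6, i], beta[3, i]), 3, 3)
    eg <- eigen(Dm, symmetric = TRUE)
    ev <- eg$values
    if (any(ev < 0)) {
      n_clamped <- n_clamped + 1L
      ev <- pmax(ev, 0)
    }
    l[i, ] <- ev
    e1[i, ] <- eg$vectors[, 1]
  }
  dims3 <- d[1:3]
  pack <- function(vals) {
    a <- array(0, c(dims3, ncol(vals)))
    for (j in seq_len(ncol(vals))) {
      tmp <- array(0, dims3)
      tmp[m] <- vals[, j]
      a[, , , j] <- tmp
    }
    a
  }
  structure(
    list(d6 = pack(t(beta[1:6, , drop = FALSE])),
         s0 = {tmp <- array(0, dims3); tmp[m] <- exp(beta[7, ]); tmp},
         eigenvalues = pack(l), e1 = pack(e1),
         mask = m, voxel_size = dwi$voxel_size,
         n_clamped = n_clamped, n_floored = n_floored),
    class = "tensor_field"
  )
}

#' @export
print.tensor_field <- function(x, ...) {
  cat("<tensor_field> ", sum(x$mask), " voxels fitted (grid ",
      paste(dim(x$s0), collapse = " x "), ")\n", sep = "")
  cat("  clamped eigenvalue voxels: ", x$n_clamped,
      ", floored signals: ", x$n_floored, "\n", sep = "")
  invisible(x)
}

#' Scalar diffusion maps from a tensor field
#'
#' Axial diffusivity AD = l1, radial RD = (l2 + l3)/2, mean
#' MD = (l1 + l2 + l3)/3 and fractional anisotropy
#' FA = sqrt(3/2) * ||lambda - MD|| / ||lambda|| (0 for an all-zero
#' tensor). FA lies in [0, 1].
#'
#' @param tf a `tensor_field` from [fit_tensor()].
#' @return Named list of `mri_volume`s: `FA`, `MD`, `RD`, `AD`.
#' @export
scalar_maps <- function(tf) {
  stopifnot(inherits(tf, "tensor_field"))
  d3 <- dim(tf$s0)
  l1 <- array(tf$eigenvalues[, , , 1], d3)
  l2 <- array(tf$eigenvalues[, , , 2], d3)
  l3 <- array(tf$eigenvalues[, , , 3], d3)
  md <- (l1 + l2 + l3) / 3
  nrm <- sqrt(l1^2 + l2^2 + l3^2)
  dev <- sqrt((l1 - md)^2 + (l2 - md)^2 + (l3 - md)^2)
  fa <- ifelse(nrm > 0, sqrt(1.5) * dev / nrm, 0)
  mk <- function(a, tag) mri_volume(a, tf$voxel_size, modality = "t2map")
  list(FA = mk(fa), MD = mk(md), RD = mk((l2 + l3) / 2), AD = mk(l1))
}
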