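# Multi-step registration: histogram-divergence similarity metrics, a
# multi-resolution derivative-free affine stage (6 or 12 DOF) and a
# B-spline free-form deformation stage with an analytic-gradient data term,
# a hinge penalty on negative Jacobian determinants and a bending-energy
# regularizer.
#
# Metrics. kl_similarity() is the divergence between the two images'
# *marginal* intensity histograms — useful as a validation/report metric.
# The registration objective itself is the joint-histogram form of the same
# divergence: the negative mutual information -MI(F, M), where MI is the
# Kullback-Leibler divergence between the joint intensity distribution and
# the product of its marginals. The marginal form is blind to spatial
# rearrangement (translating an object inside the field of view leaves both
# histograms unchanged), so it cannot drive a transform search; the joint
# form can, and reduces to the same divergence family.

#' Kullback-Leibler divergence between intensity histograms
#'
#' D_KL(p || q) of the normalized intensity histograms of the fixed and
#' moving images over their common (overlap) domain, with additive
#' smoothing. Non-negative; zero iff the histograms coincide. Not
#' symmetric.
#'
#' @param fixed,moving [mri_volume()]s (or arrays) of identical shape; the
#'   moving image is expected to be already resampled onto the fixed grid,
#'   with `NA` marking voxels outside the overlap.
#' @param bins number of histogram bins (>= 8).
#' @return The divergence (nats).
#' @export
kl_similarity <- function(fixed, moving, bins = 64L) {
  fa <- if (inherits(fixed, "mri_volume")) fixed$data else as.array(fixed)
  ma <- if (inherits(moving, "mri_volume")) moving$data else as.array(moving)
  if (!identical(dim(fa), dim(ma))) stop("fixed/moving shapes differ")
  if (bins < 8) stop("'bins' must be >= 8")
  ok <- is.finite(fa) & is.finite(ma)
  if (!any(ok)) stop("empty overlap between fixed and moving")
  f <- fa[ok]; m <- ma[ok]
  rng <- range(c(f, m))
  if (diff(rng) == 0) return(0)
  brks <- seq(rng[1], rng[2], length.out = bins + 1L)
  p <- tabulate(pmin(findInterval(f, brks, all.inside = TRUE), bins), bins) + 1e-8
  q <- tabulate(pmin(findInterval(m, brks, all.inside = TRUE), bins), bins) + 1e-8
  p <- p / sum(p)
  q <- q / sum(q)
  sum(p * log(p / q))
}

# Negative mutual information between two equally-shaped arrays over the
# voxels where `inside` is TRUE. Bin edges for each image over its own
# range. Returns -MI (nats); lower is better.
neg_mutual_information <- function(f, m, inside = NULL, bins = 32L) {
  if (!is.null(inside)) {
    f <- f[inside]; m <- m[inside]
  }
  n <- length(f)
  if (n < 100) return(0)  # degenerate overlap: no signal
  rf <- range(f); rm_ <- range(m)
  if (diff(rf) == 0 || diff(rm_) == 0) return(0)
  fi <- pmin(pmax(floor((f - rf[1]) / diff(rf) * bins) + 1, 1), bins)
  mi <- pmin(pmax(floor((m - rm_[1]) / diff(rm_) * bins) + 1, 1), bins)
  joint <- tabulate(fi + bins * (mi - 1L), bins * bins) / n
  pf <- rowSums(matrix(joint, bins))
  pm <- colSums(matrix(joint, bins))
  nz <- joint > 0
  mi_val <- sum(joint[nz] * log(joint[nz] /
                                  (outer(pf, pm)[nz] + 1e-300)))
  -mi_val
}

# Resample `marr` at affine-mapped fixed-grid points; returns sampled
# values and inside flags.
resample_affine <- function(marr, mvox, M, fixed_dims, fvox) {
  pts <- sweep(voxel_index_grid(fixed_dims), 2, fvox, `*`)
  pts <- sweep(pts %*% t(M[1:3, 1:3]), 2, M[1:3, 4], `+`)
  idx <- sweep(pts, 2, mvox, `/`)
  d <- dim(marr)
  inside <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
    idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
    idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
  list(values = sample_trilinear(marr, idx), inside = inside)
}

affine_metric <- function(p, farr, fvox, marr, mvox, center, bins) {
  M <- affine_params_to_matrix(p, center)
  rs <- resample_affine(marr, mvox, M, dim(farr), fvox)
  if (mean(rs$inside) < 0.1) return(10)  # essentially no overlap
  neg_mutual_information(as.vector(farr), rs$values, rs$inside, bins)
}

#' Affine registration by multi-resolution metric optimization
#'
#' Finds the affine map from the fixed grid to the moving image that
#' minimizes the joint-histogram divergence metric (negative mutual
#' information), by derivative-free (Nelder-Mead) optimization over a
#' coarse-to-fine image pyramid with a few deterministic restarts at the
#' coarsest level. With `dof = 6` the result is rigid (orthonormal rotation
#' block) by construction.
#'
#' @param fixed,moving 3D [mri_volume()]s.
#' @param dof 6 (rigid) or 12 (full affine).
#' @param levels number of pyramid octaves (>= 1).
#' @param bins histogram bins for the metric.
#' @param session provenance tag for the returned transform.
#' @return An `affine_transform` with attributes `metric_initial`,
#'   `metric_final` (full-resolution metric before/after), `params` and
#'   `warning_flag` (TRUE when the optimizer failed to improve on the
#'   identity, in which case the identity is returned).
#' @export
register_affine <- function(fixed, moving, dof = c(6, 12), levels = 3L,
                            bins = 32L, session = "default") {
  dof <- match.arg(as.character(dof[1]), c("6", "12"))
  dof <- as.integer(dof)
  stopifnot(inherits(fixed, "mri_volume"), inherits(moving, "mri_volume"))
  if (is_4d(fixed) || is_4d(moving)) stop("affine registration requires 3D volumes")
  np <- if (dof == 6) 6L else 12L
  # pyramids, fine -> coarse (light smoothing before each decimation)
  pyr <- list(list(f = fixed$data, fv = fixed$voxel_size,
                   m = moving$data, mv = moving$voxel_size))
  for (l in seq_len(max(levels - 1L, 0L))) {
    prev <- pyr[[l]]
    if (min(dim(prev$f)) < 12 || min(dim(prev$m)) < 12) break
    pyr[[l + 1L]] <- list(
      f = downsample2(gauss_smooth(prev$f, rep(0.8, 3))), fv = prev$fv * 2,
      m = downsample2(gauss_smooth(prev$m, rep(0.8, 3))), mv = prev$mv * 2)
  }
  center <- (dim(fixed$data)[1:3] - 1) * fixed$voxel_size / 2
  parscale <- c(rep(5 * max(fixed$voxel_size), 3), rep(10, 3),
                if (np == 12) rep(0.1, 6))
  polish <- function(p, fn, maxit) {
    # repeated Nelder-Mead rounds: each restart re-inflates the simplex,
    # which escapes the plateaus of the binned histogram metric
    for (round in 1:3) {
      p <- optim(p, fn, method = "Nelder-Mead",
                 control = list(maxit = maxit, parscale = parscale,
                                reltol = 1e-9))$par
    }
    p
  }
  sweep_rotations <- function(p, fn, range_deg = 20, step_deg = 2.5) {
    # greedy 1-D grid search per rotation axis; escapes the local minima a
    # simplex search cannot leave when the coarse levels are
    # rotation-insensitive
    for (axis in 4:6) {
      cand <- p[axis] + seq(-range_deg, range_deg, by = step_deg)
      vals <- vapply(cand, function(a) {
        q <- p
        q[axis] <- a
        fn(q)
      }, numeric(1))
      p[axis] <- cand[which.min(vals)]
    }
    p
  }
  p <- rep(0, np)
  for (l in rev(seq_along(pyr))) {
    lev <- pyr[[l]]
    fn <- function(p) affine_metric(p, lev$f, lev$fv, lev$m, lev$mv, center, bins)
    p <- sweep_rotations(p, fn)
    if (l == length(pyr)) {
      # deterministic restarts at the coarsest level
      starts <- list(p)
      perturb <- with_private_seed(42L, lapply(1:3, function(i) {
        dp <- rep(0, np)
        dp[1:3] <- runif(3, -2, 2) * max(lev$fv)
        dp[4:6] <- runif(3, -8, 8)
        p + dp
      }))
      starts <- c(starts, perturb)
      fits <- lapply(starts, function(s)
        optim(s, fn, method = "Nelder-Mead",
              control = list(maxit = 400, parscale = parscale, reltol = 1e-8)))
      p <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]$par
      p <- polish(p, fn, 400)
    } else {
      p <- polish(p, fn, 300)
    }
  }
  full_fn <- function(p) affine_metric(p, fixed$data, fixed$voxel_size,
                                       moving$data, moving$voxel_size, center, bins)
  metric0 <- full_fn(rep(0, np))
  metric1 <- full_fn(p)
  warn <- metric1 > metric0 + 1e-3 * abs(metric0)
  if (metric1 > metric0 && !warn) {
    # numerically tied with the identity (e.g. self-registration)
    metric1 <- metric0
  }
  if (warn) {
    warning("affine optimizer failed to improve on the identity; ",
            "returning identity transform")
    p <- rep(0, np)
    metric1 <- metric0
  }
  out <- affine_transform(affine_params_to_matrix(p, center), dof = dof,
                          session = session)
  attr(out, "params") <- p
  attr(out, "metric_initial") <- metric0
  attr(out, "metric_final") <- metric1
  attr(out, "warning_flag") <- warn
  out
}

# ---- non-linear ---------------------------------------------------------

# Analytic gradient pieces for the FFD objective. `basis` holds per-axis
# j0/weight tables for the fixed voxel grid.
ffd_basis <- function(dims, voxel_size, spacing) {
  list(x = bspline_weights_1d((seq_len(dims[1]) - 1) * voxel_size[1] / spacing[1]),
       y = bspline_weights_1d((seq_len(dims[2]) - 1) * voxel_size[2] / spacing[2]),
       z = bspline_weights_1d((seq_len(dims[3]) - 1) * voxel_size[3] / spacing[3]))
}

ffd_dense_from_control <- function(C, basis, dims) {
  out <- vector("list", 3)
  for (comp in 1:3) {
    acc <- array(0, dims)
    for (l1 in 1:4) for (l2 in 1:4) for (l3 in 1:4) {
      W <- outer(outer(basis$x$w[, l1], basis$y$w[, l2]), basis$z$w[, l3])
      acc <- acc + W * C[basis$x$j0 + l1, basis$y$j0 + l2, basis$z$j0 + l3, comp]
    }
    out[[comp]] <- acc
  }
  names(out) <- c("ux", "uy", "uz")
  out
}

# Scatter voxelwise dE/du back to control points through the basis.
ffd_backproject <- function(dEdu, basis, dims, ctrl_dims) {
  ncp <- prod(ctrl_dims[1:3])
  lin_x <- lapply(1:4, function(l) basis$x$j0 + l)
  lin_y <- lapply(1:4, function(l) (basis$y$j0 + l - 1L) * ctrl_dims[1])
  lin_z <- lapply(1:4, function(l) (basis$z$j0 + l - 1L) * ctrl_dims[1] * ctrl_dims[2])
  grad <- array(0, ctrl_dims)
  for (comp in 1:3) {
    g <- numeric(ncp)
    dcomp <- dEdu[[comp]]
    for (l1 in 1:4) for (l2 in 1:4) for (l3 in 1:4) {
      W <- outer(outer(basis$x$w[, l1], basis$y$w[, l2]), basis$z$w[, l3])
      lin <- outer(outer(lin_x[[l1]], lin_y[[l2]], `+`), lin_z[[l3]], `+`)
      contrib <- rowsum(as.vector(W * dcomp), as.vector(lin))
      g[as.integer(rownames(contrib))] <-
        g[as.integer(rownames(contrib))] + contrib
    }
    grad[, , , comp] <- array(g, ctrl_dims[1:3])
  }
  grad
}

# Bending energy on the control lattice: mean squared second difference
# along each axis, all components (normalized by the number of terms so
# the weight is independent of grid size). Returns list(value, grad).
bending_energy <- function(C) {
  d <- dim(C)
  val <- 0
  grad <- array(0, d)
  n_terms <- 0
  for (axis in 1:3) {
    n <- d[axis]
    if (n < 3) next
    idx <- function(k) {
      ix <- rep(list(quote(expr = )), 4)
      ix[[axis]] <- k
      ix
    }
    get <- function(k) do.call(`[`, c(list(C), idx(k), list(drop = FALSE)))
    D2 <- get(3:n) - 2 * get(2:(n - 1)) + get(1:(n - 2))
    val <- val + sum(D2^2)
    n_terms <- n_terms + length(D2)
    add <- function(k, v) {
      cur <- do.call(`[`, c(list(grad), idx(k), list(drop = FALSE)))
      grad <<- do.call(`[<-`, c(list(grad), idx(k), list(value = cur + v)))
    }
    add(3:n, 2 * D2)
    add(2:(n - 1), -4 * D2)
    add(1:(n - 2), 2 * D2)
  }
  if (n_terms > 0) {
    val <- val / n_terms
    grad <- grad / n_terms
  }
  list(value = val, grad = grad)
}

# Hinge penalty on negative Jacobian determinants of x + u(x), evaluated on
# the interior control lattice with central differences over `spacing`.
# Returns list(value, grad) with analytic gradient via cofactors.
jacobian_hinge <- function(C, spacing) {
  d <- dim(C)
  if (any(d[1:3] < 3)) return(list(value = 0, grad = array(0, d)))
  int <- lapply(1:3, function(a) 2:(d[a] - 1))
  # G[a, b] = dC_a / dx_b at interior nodes
  G <- vector("list", 9)
  dim(G) <- c(3, 3)
  slice <- function(comp, off) {
    ix <- lapply(1:3, function(a) int[[a]] + off[a])
    C[ix[[1]], ix[[2]], ix[[3]], comp, drop = FALSE]
  }
  for (a in 1:3) for (b in 1:3) {
    off <- c(0, 0, 0)
    off[b] <- 1
    G[[a, b]] <- (slice(a, off) - slice(a, -off)) / (2 * spacing[b])
  }
  A <- function(a, b) (a == b) + G[[a, b]]
  J <- A(1, 1) * (A(2, 2) * A(3, 3) - A(2, 3) * A(3, 2)) -
    A(1, 2) * (A(2, 1) * A(3, 3) - A(2, 3) * A(3, 1)) +
    A(1, 3) * (A(2, 1) * A(3, 2) - A(2, 2) * A(3, 1))
  neg <- J < 0
  val <- -sum(J[neg])
  grad <- array(0, d)
  if (any(neg)) {
    cof <- vector("list", 9)
    dim(cof) <- c(3, 3)
    ix3 <- function(a) setdiff(1:3, a)
    for (a in 1:3) for (b in 1:3) {
      r <- ix3(a); cc <- ix3(b)
      minor <- A(r[1], cc[1]) * A(r[2], cc[2]) - A(r[1], cc[2]) * A(r[2], cc[1])
      cof[[a, b]] <- (-1)^(a + b) * minor
    }
    for (a in 1:3) for (b in 1:3) {
      dPdG <- -cof[[a, b]] * neg   # d(-J)/dG_ab where J < 0
      off <- c(0, 0, 0)
      off[b] <- 1
      for (sgn in c(1, -1)) {
        ix <- lapply(1:3, function(k) int[[k]] + sgn * off[k])
        cur <- grad[ix[[1]], ix[[2]], ix[[3]], a, drop = FALSE]
        grad[ix[[1]], ix[[2]], ix[[3]], a] <-
          cur + sgn * dPdG / (2 * spacing[b])
      }
    }
  }
  list(value = val, grad = grad)
}

#' Non-linear (B-spline FFD) registration
#'
#' Estimates a free-form deformation `x -> x + u(x)` on a regular B-spline
#' control grid so that the moving image sampled at the deformed fixed-grid
#' points matches the fixed image. The objective is a sum-of-squares data
#' term on intensity-normalized images plus `penalty` times a hinge on
#' negative Jacobian determinants (discouraging folding) and a small
#' bending-energy regularizer; it is minimized by L-BFGS with an analytic
#' gradient. The joint-histogram divergence metric is evaluated before and
#' after for the descent contract. Affine pre-alignment is assumed.
#'
#' @param fixed,moving 3D [mri_volume()]s on compatible grids.
#' @param grid_spacing control-point spacing in mm, between 1 and 5.
#' @param penalty weight of the negative-Jacobian hinge (default 0.3).
#' @param bending bending-energy weight (control-lattice units).
#' @param max_iter L-BFGS iteration cap.
#' @param session provenance tag.
#' @return A `bspline_field` with attributes `metric_initial`,
#'   `metric_final` (joint-histogram metric), `objective_trace`,
#'   `folding_fraction` (share of voxels with non-positive Jacobian) and
#'   `displacement_rms_mm`. A folding fraction above 0.5% raises a warning.
#' @export
register_nonlinear <- function(fixed, moving, grid_spacing = 2.5, penalty = 0.3,
                               bending = 0.005, max_iter = 150L,
                               session = "default") {
  stopifnot(inherits(fixed, "mri_volume"), inherits(moving, "mri_volume"))
  if (grid_spacing < 1 || grid_spacing > 5) {
    stop("'grid_spacing' must lie in [1, 5] mm")
  }
  dims <- dim(fixed$data)
  fvox <- fixed$voxel_size
  zs <- function(a) (a - mean(a)) / max(sd(a), 1e-12)
  Fn <- zs(fixed$data)
  Mn <- zs(moving$data)
  spacing <- rep(grid_spacing, 3)
  nc <- vapply(1:3, function(a) n_control_points((dims[a] - 1) * fvox[a], spacing[a]),
               integer(1))
  ctrl_dims <- c(nc, 3L)
  basis <- ffd_basis(dims, fvox, spacing)
  grid_mm <- lapply(1:3, function(a) (seq_len(dims[a]) - 1) * fvox[a])
  base_pts <- sweep(voxel_index_grid(dims), 2, fixed$voxel_size, `*`)
  mvox <- moving$voxel_size
  nvox <- prod(dims)
  trace_env <- new.env()
  trace_env$trace <- numeric(0)
  objective <- function(par, want_grad = FALSE) {
    C <- array(par, ctrl_dims)
    dense <- ffd_dense_from_control(C, basis, dims)
    pts <- base_pts + cbind(as.vector(dense$ux), as.vector(dense$uy),
                            as.vector(dense$uz))
    idx <- sweep(pts, 2, mvox, `/`)
    sg <- sample_trilinear_grad(Mn, idx)
    resid <- sg$value - as.vector(Fn)
    data_term <- mean(resid^2)
    be <- bending_energy(C)
    jh <- jacobian_hinge(C, spacing)
    val <- data_term + bending * be$value + penalty * jh$value
    if (!want_grad) return(val)
    w <- 2 * resid / nvox
    dEdu <- list(array(w * sg$gx / mvox[1], dims),
                 array(w * sg$gy / mvox[2], dims),
                 array(w * sg$gz / mvox[3], dims))
    grad <- ffd_backproject(dEdu, basis, dims, ctrl_dims) +
      bending * be$grad + penalty * jh$grad
    list(value = val, grad = as.vector(grad))
  }
  fn <- function(par) {
    v <- objective(par, want_grad = FALSE)
    trace_env$trace <- c(trace_env$trace, v)
    v
  }
  gr <- function(par) objective(par, want_grad = TRUE)$grad
  par <- numeric(prod(ctrl_dims))
  iters_left <- max_iter
  for (round in 1:4) {
    fit <- optim(par, fn, gr, method = "L-BFGS-B",
                 control = list(maxit = iters_left, factr = 1e7))
    par <- fit$par
    if (fit$convergence == 0) break   # restart after line-search aborts
  }
  C <- array(par, ctrl_dims)
  field <- bspline_field(C, spacing, session = session)
  dense <- ffd_dense_from_control(C, basis, dims)
  idx <- sweep(base_pts + cbind(as.vector(dense$ux), as.vector(dense$uy),
                                as.vector(dense$uz)), 2, mvox, `/`)
  warped <- array(sample_trilinear(moving$data, idx, outside = NA), dims)
  metric0 <- neg_mutual_information(as.vector(fixed$data),
                                    as.vector(moving$data),
                                    rep(TRUE, nvox))
  ok <- is.finite(warped)
  metric1 <- neg_mutual_information(fixed$data[ok], warped[ok])
  J <- jacobian_determinant_dense(dense, fvox)
  fold <- mean(J <= 0)
  if (fold > 0.005) {
    warning(sprintf("deformation folds at %.2f%% of voxels", 100 * fold))
  }
  u2 <- dense$ux^2 + dense$uy^2 + dense$uz^2
  attr(field, "metric_initial") <- metric0
  attr(field, "metric_final") <- metric1
  attr(field, "objective_trace") <- trace_env$trace
  attr(field, "folding_fraction") <- fold
  attr(field, "displacement_rms_mm") <- sqrt(mean(u2))
  attr(field, "convergence") <- fit$convergence
  field
}
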