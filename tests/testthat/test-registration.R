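# Histogram metrics, affine and B-spline registration recovery, transform
# chains and serialization. The known-transform recoveries here are the
# module's core validation surface.

reg_phantom <- function(snr = 30, seed = 5) {
  make_tissue_phantom(shape = c(32, 32, 24), voxel_size = c(0.2, 0.2, 0.2),
                      intensities = c(60, 100, 140), snr = snr, seed = seed)
}

test_that("marginal-histogram KL divergence behaves as defined", {
  set.seed(4)
  f <- array(runif(1000), c(10, 10, 10))
  g <- array(0.5, c(10, 10, 10))

  expect_lt(kl_similarity(f, f, bins = 16), 1e-6)

  # hand-computed divergence of the two binned distributions
  brks <- seq(min(c(f, g)), max(c(f, g)), length.out = 17)
  p <- tabulate(pmin(findInterval(f, brks, all.inside = TRUE), 16), 16) + 1e-8
  q <- tabulate(pmin(findInterval(g, brks, all.inside = TRUE), 16), 16) + 1e-8
  p <- p / sum(p); q <- q / sum(q)
  expect_equal(kl_similarity(f, g, bins = 16), sum(p * log(p / q)))

  # not symmetric
  expect_false(isTRUE(all.equal(kl_similarity(f, g, bins = 16),
                                kl_similarity(g, f, bins = 16))))
  expect_gte(kl_similarity(g, f, bins = 16), 0)

  expect_error(kl_similarity(f, g, bins = 4), ">= 8")
  expect_error(kl_similarity(f, array(0, c(2, 2, 2))), "differ")
})

test_that("affine registration recovers identity, shift and rotation", {
  ph <- reg_phantom()
  fixed <- ph$volume
  vs <- fixed$voxel_size
  d <- dim(fixed$data)

  # self-registration stays at the identity
  self <- register_affine(fixed, fixed, dof = 6, levels = 3)
  p0 <- attr(self, "params")
  expect_lt(max(abs(p0[1:3]) / vs), 0.1)    # < 0.1 voxel
  expect_lt(max(abs(p0[4:6])), 0.5)         # < 0.5 degree
  expect_lte(attr(self, "metric_final"), attr(self, "metric_initial"))

  # known integer shift (3, -2, 1) voxels
  mov <- array(0, d)
  mov[4:d[1], 1:(d[2] - 2), 2:d[3]] <- fixed$data[1:(d[1] - 3), 3:d[2], 1:(d[3] - 1)]
  shift_fit <- register_affine(fixed, mri_volume(mov, vs), dof = 6, levels = 3)
  ps <- attr(shift_fit, "params")
  expect_lt(max(abs(ps[1:3] / vs - c(3, -2, 1))), 0.5)
  expect_lte(attr(shift_fit, "metric_final"), attr(shift_fit, "metric_initial"))

  # dof = 6 gives a rigid matrix: orthonormal rotation block
  R <- shift_fit$matrix[1:3, 1:3]
  expect_equal(crossprod(R), diag(3), tolerance = 1e-6)

  # known 10-degree rotation about z
  ctr <- (d - 1) * vs / 2
  rotM <- murimap:::affine_params_to_matrix(c(0, 0, 0, 0, 0, 10), center = ctr)
  moving <- apply_chain(affine_transform(rotM), fixed, fixed)
  rot_fit <- register_affine(fixed, moving, dof = 6, levels = 3)
  pr <- attr(rot_fit, "params")
  expect_lt(abs(pr[6] - (-10)), 1)
  expect_lt(max(abs(pr[4:5])), 1)
  expect_lte(attr(rot_fit, "metric_final"), attr(rot_fit, "metric_initial"))
})

test_that("B-spline registration recovers a known sinusoidal warp", {
  ph <- reg_phantom()
  wp <- sinusoidal_warp_pair(ph$volume, amplitude_vox = 2)
  nl <- register_nonlinear(ph$volume, wp$moving, grid_spacing = 1.5,
                           penalty = 0.3, max_iter = 200)
  d <- dim(ph$volume$data)
  vs <- ph$volume$voxel_size
  dense <- murimap:::bspline_dense_field(nl, d, vs)
  u <- cbind(as.vector(dense$ux), as.vector(dense$uy), as.vector(dense$uz))
  m <- as.vector(ph$brain_mask$data != 0)
  rms_vox <- sqrt(mean(rowSums((u - wp$inverse_truth)^2)[m])) / vs[1]
  expect_lt(rms_vox, 0.5)

  # metric descent and a non-folding deformation
  expect_lte(attr(nl, "metric_final"), attr(nl, "metric_initial"))
  expect_lt(attr(nl, "folding_fraction"), 0.005)
})

test_that("self non-linear registration keeps displacements tiny", {
  ph <- reg_phantom()
  nl <- register_nonlinear(ph$volume, ph$volume, grid_spacing = 2.5,
                           max_iter = 60)
  expect_lt(attr(nl, "displacement_rms_mm") / ph$volume$voxel_size[1], 0.1)
})

test_that("the Jacobian hinge reduces folding on an aggressive warp", {
  ph <- reg_phantom(seed = 12)
  wp <- sinusoidal_warp_pair(ph$volume, amplitude_vox = 4)
  folds <- sapply(c(0, 0.3), function(pen) {
    nl <- suppressWarnings(
      register_nonlinear(ph$volume, wp$moving, grid_spacing = 1.2,
                         penalty = pen, bending = 0, max_iter = 120))
    attr(nl, "folding_fraction")
  })
  expect_gte(folds[1], folds[2])   # weakly larger without the penalty
})

test_that("grid spacing is restricted to the supported range", {
  ph <- reg_phantom()
  expect_error(register_nonlinear(ph$volume, ph$volume, grid_spacing = 0.5),
               "\\[1, 5\\]")
  expect_error(register_nonlinear(ph$volume, ph$volume, grid_spacing = 7),
               "\\[1, 5\\]")
})

test_that("session chains compose, reuse the non-linear field and validate provenance", {
  ph <- make_tissue_phantom(shape = c(20, 20, 16), snr = Inf, seed = 9)
  v <- ph$volume
  v$data <- murimap:::gauss_smooth(v$data, c(1.5, 1.5, 1.5))
  aff <- affine_transform(murimap:::affine_params_to_matrix(c(0.3, -0.2, 0.1, 4, 0, 0)),
                          session = "s1")
  ctrl <- array(0, c(7, 7, 6, 3))
  ctrl[, , , 1] <- 0.15
  bs <- bspline_field(ctrl, spacing = 1.0, session = "s1")

  # identity modality affine: chain equals the T2 chain voxel for voxel
  id <- affine_transform(session = "s1")
  ch_t2 <- build_session_chain(aff, bs)
  ch_id <- build_session_chain(aff, bs, id)
  expect_equal(apply_chain(ch_id, v, v)$data, apply_chain(ch_t2, v, v)$data)

  # chain application equals sequential application (smooth image)
  ch <- transform_chain(list(aff, bs))
  r_chain <- apply_chain(ch, v, v)
  r_seq <- apply_chain(aff, apply_chain(bs, v, v), v)
  interior <- array(FALSE, dim(v$data))
  interior[3:18, 3:18, 3:14] <- TRUE
  rms <- sqrt(mean((r_chain$data - r_seq$data)[interior]^2))
  expect_lt(rms / sd(v$data), 0.05)

  # affine followed by its inverse is the identity within interpolation
  ri <- apply_chain(transform_chain(list(aff, invert_affine(aff))), v, v)
  expect_lt(max(abs(ri$data - v$data)[interior]), 1e-9)

  # mixing sessions is a provenance error
  expect_error(build_session_chain(aff, bs, affine_transform(session = "s2")),
               "provenance")
})

test_that("chains resample labels conservatively", {
  ph <- make_tissue_phantom(shape = c(20, 20, 16), snr = Inf, seed = 9)
  v <- ph$volume
  set.seed(2)
  lab <- label_volume(array(sample(0:3, prod(dim(v$data)), TRUE), dim(v$data)),
                      voxel_size = v$voxel_size)

  # identity chain: bit-identical label values
  idch <- transform_chain(list(affine_transform(session = "s1")))
  expect_true(all(apply_chain(idch, lab, v)$data == lab$data))

  # integer-voxel translation with nearest = pure index shift
  M <- diag(4)
  M[1, 4] <- 2 * v$voxel_size[1]
  sh <- apply_chain(affine_transform(M, session = "s1"), lab, v)
  expect_true(all(sh$data[1:18, , ] == lab$data[3:20, , ]))
  expect_true(all(sh$data[19:20, , ] == 0))

  # the label set never grows under warping
  aff <- affine_transform(murimap:::affine_params_to_matrix(c(0.3, -0.2, 0.1, 4, 0, 0)),
                          session = "s1")
  wl <- apply_chain(aff, lab, v)
  expect_true(all(unique(as.vector(wl$data)) %in% unique(as.vector(lab$data))))

  expect_error(apply_chain(aff, lab, v, interpolation = "linear"),
               "nearest-neighbour")
})

test_that("transforms and chains round-trip through JSON", {
  aff <- affine_transform(murimap:::affine_params_to_matrix(c(1, 2, -1, 5, -3, 8)),
                          dof = 6, session = "sx")
  ctrl <- array(rnorm(5 * 4 * 4 * 3, sd = 0.1), c(5, 4, 4, 3))
  bs <- bspline_field(ctrl, spacing = c(2, 2.5, 3), session = "sx")
  ch <- transform_chain(list(aff, bs))
  path <- tempfile(fileext = ".json")
  save_transform(ch, path)
  back <- load_transform(path)
  expect_equal(back$transforms[[1]]$matrix, aff$matrix)
  expect_equal(back$transforms[[1]]$dof, 6L)
  expect_equal(back$transforms[[2]]$control, ctrl)
  expect_equal(back$transforms[[2]]$spacing, c(2, 2.5, 3))
  expect_equal(back$session, "sx")
})

test_that("the FFD objective gradient matches finite differences", {
  set.seed(2)
  C <- array(rnorm(5 * 5 * 4 * 3, sd = 1.2), c(5, 5, 4, 3))
  be <- murimap:::bending_energy(C)
  jh <- murimap:::jacobian_hinge(C, c(1, 1, 1))
  expect_gt(jh$value, 0)   # this configuration folds
  idx <- sample(length(C), 25)
  eps <- 1e-6
  for (k in idx) {
    C2 <- C
    C2[k] <- C2[k] + eps
    expect_equal((murimap:::bending_energy(C2)$value - be$value) / eps,
                 be$grad[k], tolerance = 1e-3)
    expect_equal((murimap:::jacobian_hinge(C2, c(1, 1, 1))$value - jh$value) / eps,
                 jh$grad[k], tolerance = 1e-3)
  }
})
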