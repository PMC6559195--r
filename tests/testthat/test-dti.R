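# Gradient schemes, slice-wise motion correction, tensor fitting and the
# scalar eigenvalue maps.

test_that("gradient schemes validate their invariants", {
  dirs <- jones_directions(12, seed = 1, iters = 200)
  sch <- gradient_scheme(c(0, rep(1000, 12)), rbind(c(0, 0, 0), dirs))
  expect_equal(sch$n_b0, 1L)

  expect_error(gradient_scheme(rep(1000, 12), dirs), "b0")
  expect_error(gradient_scheme(c(0, rep(1000, 12)),
                               rbind(c(0, 0, 0), dirs * 2)), "unit length")
  expect_error(gradient_scheme(c(0, rep(1000, 4)),
                               rbind(c(0, 0, 0), dirs[c(1, 1, 2, 2), ])),
               "6 unique")
})

test_that("bval/bvec text files round-trip through the FSL dialect", {
  dirs <- jones_directions(8, seed = 2, iters = 200)
  bv <- c(0, rep(1000, 8))
  vecs <- rbind(c(0, 0, 0), dirs)
  fb <- tempfile(); fv <- tempfile()
  writeLines(paste(bv, collapse = " "), fb)
  write.table(t(vecs), fv, row.names = FALSE, col.names = FALSE)
  sch <- read_gradient_scheme(fb, fv)
  expect_equal(sch$b_values, bv)
  expect_equal(unname(sch$b_vectors), unname(vecs), tolerance = 1e-12)
})

test_that("noiseless tensors are recovered exactly (property over random SPD)", {
  set.seed(10)
  n <- 100
  dirs <- jones_directions(30, seed = 7)
  bvals <- c(0, rep(1000, 30))
  bvecs <- rbind(c(0, 0, 0), dirs)
  scheme <- gradient_scheme(bvals, bvecs)
  # random SPD tensors at physiological scale
  D6 <- t(sapply(seq_len(n), function(i) {
    A <- matrix(rnorm(9, sd = 1), 3, 3)
    D <- crossprod(A)
    D <- D / max(eigen(D, symmetric = TRUE)$values) * runif(1, 0.5e-3, 2e-3)
    c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
  }))
  s0 <- 100
  sig <- sapply(seq_len(31), function(v) {
    g <- bvecs[v, ]
    quad <- D6[, 1] * g[1]^2 + D6[, 2] * g[2]^2 + D6[, 3] * g[3]^2 +
      2 * (D6[, 4] * g[1] * g[2] + D6[, 5] * g[1] * g[3] + D6[, 6] * g[2] * g[3])
    s0 * exp(-bvals[v] * quad)
  })
  dwi <- mri_volume(array(sig, c(n, 1, 1, 31)), c(1, 1, 1), t_step = 3,
                    modality = "dwi")
  mask <- mri_volume(array(1, c(n, 1, 1)), c(1, 1, 1), modality = "mask")
  tf <- fit_tensor(dwi, scheme, mask)
  fitted <- sapply(1:6, function(j) tf$d6[, 1, 1, j])
  expect_lt(max(abs(fitted - D6)) / max(abs(D6)), 1e-6)

  # scalar maps match the closed-form eigenvalue expressions
  maps <- scalar_maps(tf)
  for (i in seq_len(n)) {
    D <- matrix(c(D6[i, 1], D6[i, 4], D6[i, 5],
                  D6[i, 4], D6[i, 2], D6[i, 6],
                  D6[i, 5], D6[i, 6], D6[i, 3]), 3, 3)
    ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
    md <- mean(ev)
    fa <- sqrt(1.5) * sqrt(sum((ev - md)^2)) / sqrt(sum(ev^2))
    expect_equal(maps$FA$data[i, 1, 1], fa, tolerance = 1e-6)
    expect_equal(maps$MD$data[i, 1, 1], md, tolerance = 1e-9)
    expect_equal(maps$AD$data[i, 1, 1], ev[1], tolerance = 1e-9)
    expect_equal(maps$RD$data[i, 1, 1], (ev[2] + ev[3]) / 2, tolerance = 1e-9)
  }
})

test_that("isotropic tensors give equal eigenvalues and zero FA", {
  dw <- make_dwi(shape = c(10, 10, 6), layout = "tube", snr = Inf, seed = 7)
  tf <- fit_tensor(dw$dwi, dw$scheme, dw$brain_mask)
  bg <- dw$brain_mask$data != 0 & dw$tube_mask$data == 0
  l <- sapply(1:3, function(j) tf$eigenvalues[, , , j][bg])
  expect_lt(max(abs(l - dw$iso_diffusivity)), 1e-9)
  maps <- scalar_maps(tf)
  expect_lt(max(maps$FA$data[bg]), 1e-6)

  # stick limit: lambda = (1, 0, 0) has FA 1, MD 1/3
  stick <- tf
  stick$eigenvalues[, , , 1][bg] <- 1
  stick$eigenvalues[, , , 2][bg] <- 0
  stick$eigenvalues[, , , 3][bg] <- 0
  ms <- scalar_maps(stick)
  expect_equal(unique(ms$FA$data[bg]), 1)
  expect_equal(unique(ms$MD$data[bg]), 1 / 3)
  expect_equal(unique(ms$RD$data[bg]), 0)
})

test_that("Rician noise induces only a small median FA bias", {
  dw <- make_dwi(shape = c(12, 12, 6), layout = "tube", snr = 20, seed = 15,
                 tube_radius_vox = 4)
  tf <- fit_tensor(dw$dwi, dw$scheme, dw$tube_mask)
  maps <- scalar_maps(tf)
  m <- dw$tube_mask$data != 0
  lam <- dw$eigenvalues_true
  md <- mean(lam)
  fa_true <- sqrt(1.5) * sqrt(sum((lam - md)^2)) / sqrt(sum(lam^2))
  expect_gte(sum(m), 400)
  expect_lt(abs(median(maps$FA$data[m]) - fa_true), 0.03)
})

test_that("slice-wise motion correction recovers per-slice shifts", {
  series <- moco_series()
  vs <- series$voxel_size

  # an already-aligned series yields near-zero parameters
  mc0 <- motion_correct_slicewise(series)
  expect_lt(max(abs(mc0$parameters[, , 1:2])) / vs[1], 0.05)

  # frame 5 shifted +2 voxels in x on every slice: motion -2 recovered
  sh <- shift_frame_x(series, frame = 5, shift_vox = 2)
  mc <- motion_correct_slicewise(sh)
  tx <- mc$parameters[, 5, 1] / vs[1]
  expect_true(all(abs(tx - (-2)) <= 0.25))
  expect_lt(max(abs(mc$parameters[, -5, 1:2])) / vs[1], 0.05)

  # a shift on exactly one slice is found on that slice only — the
  # behaviour a volume-wise correction cannot produce
  sh2 <- shift_frame_x(series, frame = 6, shift_vox = 1, slice = 3)
  mc2 <- motion_correct_slicewise(sh2)
  expect_lt(abs(mc2$parameters[3, 6, 1] / vs[1] - (-1)), 0.25)
  expect_lt(max(abs(mc2$parameters[-3, 6, 1:2])) / vs[1], 0.05)

  # corrected series aligns the shifted frame again
  resid <- mc$corrected$data[, , , 5] - series$data[, , , 5]
  interior <- array(FALSE, dim(resid))
  interior[5:20, 5:20, ] <- TRUE
  expect_lt(sqrt(mean(resid[interior]^2)) / sd(series$data), 0.2)

  expect_error(motion_correct_slicewise(series$data), "mri_volume|inherits")
  short <- mri_volume(series$data[, , , 1:2], vs, t_step = 1.42, modality = "bold")
  expect_error(motion_correct_slicewise(short), ">= 3")

  # a slice with no signal is flagged, not fitted
  flat <- series
  flat$data[, , 2, ] <- 0
  mcf <- motion_correct_slicewise(flat)
  expect_true(mcf$flat_slices[2])
  expect_true(all(mcf$parameters[2, , ] == 0))
})
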