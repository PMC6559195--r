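# Slice timing, in-plane smoothing, temporal high-pass, respiration
# regressors, regional extraction and functional connectivity.

test_that("slice timing correction aligns slice phases", {
  nz <- 6; nt <- 60; tr <- 1.0
  ordr <- c(1, 3, 5, 2, 4, 6)                  # interleaved acquisition
  frac <- (match(1:nz, ordr) - 1) / nz
  ser <- array(0, c(4, 4, nz, nt))
  for (z in 1:nz) for (t in 1:nt) ser[, , z, t] <- sin(2 * pi * 0.05 * (t + frac[z]))
  sv <- mri_volume(ser, c(1, 1, 1), t_step = tr, modality = "bold")

  fixed <- slice_timing_correct(sv, ordr)
  ph_err <- sapply(2:nz, function(z) {
    a <- fixed$data[1, 1, 1, 10:50]
    b <- fixed$data[1, 1, z, 10:50]
    acos(pmin(sum(a * b) / sqrt(sum(a^2) * sum(b^2)), 1)) / (2 * pi * 0.05)
  })
  expect_lt(max(ph_err) / tr, 0.05)            # < 5% of one TR

  # disabled switch is the identity; constant voxels are unaffected
  expect_identical(slice_timing_correct(sv, ordr, enabled = FALSE), sv)
  const <- mri_volume(array(3, c(4, 4, nz, nt)), c(1, 1, 1), t_step = tr,
                      modality = "bold")
  expect_equal(slice_timing_correct(const, ordr)$data, const$data)

  expect_error(slice_timing_correct(sv, c(1, 2, 3)), "permutation")
})

test_that("in-plane smoothing never mixes slices or frames", {
  imp <- array(0, c(9, 9, 5, 3))
  imp[5, 5, 3, 2] <- 1
  v <- mri_volume(imp, c(0.141, 0.141, 0.4), t_step = 1.42, modality = "bold")
  sm <- smooth_inplane(v, 3.0)
  expect_equal(sum(abs(sm$data[, , c(1, 2, 4, 5), ])), 0)
  expect_equal(sum(abs(sm$data[, , , c(1, 3)])), 0)

  # impulse response equals the separable 2D Gaussian kernel (interior
  # impulse on a grid wide enough that no edge renormalization applies)
  big <- array(0, c(31, 31, 3, 2))
  big[16, 16, 2, 1] <- 1
  vb <- mri_volume(big, c(1, 1, 4), t_step = 1.42, modality = "bold")
  smb <- smooth_inplane(vb, 3.0)
  sigma_vox <- 3.0 / (2 * sqrt(2 * log(2)))
  k <- murimap:::gauss_kernel_1d(sigma_vox)
  r <- (length(k) - 1) / 2
  oracle <- array(0, c(31, 31))
  for (i in seq_along(k)) for (j in seq_along(k)) {
    oracle[16 + i - r - 1, 16 + j - r - 1] <- k[i] * k[j]
  }
  expect_equal(smb$data[, , 2, 1], oracle, tolerance = 1e-12)

  # a constant image is invariant
  const <- mri_volume(array(2, c(9, 9, 5, 3)), c(0.141, 0.141, 0.4),
                      t_step = 1.42, modality = "bold")
  expect_equal(smooth_inplane(const, 3.0)$data, const$data, tolerance = 1e-12)

  expect_warning(smooth_inplane(v, 0.05), "below one voxel")
  expect_error(smooth_inplane(v, -1), "positive")
})

test_that("the 0.01 Hz high-pass removes drift and passes fluctuations", {
  tr <- 1.42; nt <- 600
  tt <- (0:(nt - 1)) * tr
  rms <- function(x) sqrt(mean(x^2))

  s_stop <- sin(2 * pi * 0.002 * tt)
  s_pass <- sin(2 * pi * 0.05 * tt)
  o_stop <- highpass_temporal(s_stop, 0.01, t_step = tr)
  o_pass <- highpass_temporal(s_pass, 0.01, t_step = tr)
  expect_lt(rms(o_stop) / rms(s_stop), 0.1)              # >= 90% attenuation
  expect_lt(abs(rms(o_pass) / rms(s_pass) - 1), 0.1)     # within 10%

  # constant series maps to zero (mean removal)
  expect_equal(highpass_temporal(rep(5, 64), 0.01, t_step = tr), rep(0, 64),
               tolerance = 1e-9)

  # 4D volumes are filtered voxelwise
  arr <- array(rep(s_stop, each = 8), c(2, 2, 2, nt))
  v <- mri_volume(arr, c(1, 1, 1), t_step = tr, modality = "bold")
  hv <- highpass_temporal(v, 0.01)
  expect_lt(rms(hv$data[1, 1, 1, ]) / rms(s_stop), 0.1)

  expect_error(highpass_temporal(s_stop[1:8], 0.01, t_step = tr), "too short")
  expect_error(highpass_temporal(s_stop, 0.4, t_step = tr), "Nyquist")
  expect_error(highpass_temporal(s_stop, 0.01), "t_step")
})

test_that("respiration regressors track the breathing rate", {
  fs <- 50; n <- 30000
  t <- (0:(n - 1)) / fs
  trig <- round(seq(1, n - 100, length.out = 400))

  # steady 2 Hz breathing
  pt <- physio_trace(sin(2 * pi * 2 * t) + 0.2, fs, trig)
  reg <- respiration_regressor(pt, 400)
  expect_true(all(abs(reg - 2) / 2 < 0.05))
  # the constructed trace holds 2 inspirations per second
  expect_lte(abs(length(attr(reg, "peaks")) - 2 * n / fs), 2)

  # amplitude scaling leaves the regressor unchanged
  pt_big <- physio_trace(17 * (sin(2 * pi * 2 * t) + 0.2), fs, trig)
  expect_equal(as.numeric(respiration_regressor(pt_big, 400)),
               as.numeric(reg))

  # a 2 -> 3 Hz step appears at the right volume
  tr2 <- c(sin(2 * pi * 2 * t[t < 300]), sin(2 * pi * 3 * (t[t >= 300] - 300)))
  reg2 <- respiration_regressor(physio_trace(tr2, fs, trig), 400)
  vol_times <- (trig - 1) / fs
  expected_vol <- which(vol_times >= 300)[1]
  found <- which(reg2 > 2.5)[1]
  expect_lte(abs(found - expected_vol), 1)

  # flat trace: warning and zero regressor
  expect_warning(flatreg <- respiration_regressor(
    physio_trace(rep(0.1, 2000), fs, c(10, 500, 1000)), 3), "no inspiration")
  expect_equal(as.numeric(flatreg), c(0, 0, 0))

  expect_error(physio_trace(1:10, fs, c(5, 5)), "strictly increasing")
  expect_error(physio_trace(1:10, fs, c(5, 50)), "outside")
})

test_that("regional extraction averages in-region voxels per frame", {
  d <- c(6, 4, 2); nt <- 20
  lab_arr <- array(0L, d)
  lab_arr[1:2, , ] <- 3L
  lab_arr[3:4, , ] <- 7L
  lab <- label_volume(lab_arr)
  set.seed(5)
  arr <- array(rnorm(prod(d) * nt), c(d, nt))
  v <- mri_volume(arr, c(1, 1, 1), t_step = 1, modality = "bold")
  ts_ <- extract_regional_timeseries(v, lab)
  expect_equal(ts_$label_ids, c(3L, 7L))

  # oracle: per-voxel averaging
  for (t in 1:nt) {
    expect_equal(ts_$series[1, t], mean(arr[, , , t][lab_arr == 3]))
    expect_equal(ts_$series[2, t], mean(arr[, , , t][lab_arr == 7]))
  }

  # two-voxel region with values 4 and 6 averages to 5
  small <- array(0, c(2, 1, 1, 1))
  small[, 1, 1, 1] <- c(4, 6)
  lv <- label_volume(array(1L, c(2, 1, 1)))
  one <- extract_regional_timeseries(
    mri_volume(small, c(1, 1, 1), t_step = 1, modality = "bold"), lv)
  expect_equal(as.vector(one$series), 5)

  # the exported mask stack is one binary mask per region
  stack <- attr(ts_, "mask_stack")
  expect_equal(dim(stack), c(d, 2))
  expect_equal(stack[, , , 1], (lab_arr == 3) * 1)

  expect_error(extract_regional_timeseries(v, label_volume(array(0L, d))),
               "no region")
})

test_that("functional connectivity has unit diagonal, symmetry and bounds", {
  set.seed(6)
  x <- rnorm(100)
  ser <- rbind(x, -x, rnorm(100))
  ts_ <- regional_timeseries(ser, c(1L, 2L, 3L), 1.42)
  fc <- functional_connectivity(ts_)
  expect_equal(diag(unclass(fc)), c(`1` = 1, `2` = 1, `3` = 1))
  expect_equal(fc["1", "2"], -1)
  expect_true(isSymmetric(unclass(fc)))
  expect_true(all(fc >= -1 & fc <= 1))

  # invariant under per-region affine rescaling (Pearson property)
  ser2 <- ser * c(3, 0.5, 10) + c(100, -4, 0)
  fc2 <- functional_connectivity(regional_timeseries(ser2, 1:3, 1.42))
  expect_equal(unclass(fc2), unclass(fc), tolerance = 1e-12)

  # nuisance residualization removes a shared confound
  conf <- sin(2 * pi * (1:100) / 25)
  serc <- rbind(rnorm(100) + 3 * conf, rnorm(100) + 3 * conf)
  tsc <- regional_timeseries(serc, 1:2, 1.42)
  r_raw <- functional_connectivity(tsc)["1", "2"]
  r_res <- functional_connectivity(tsc, nuisance = conf)["1", "2"]
  expect_lt(abs(r_res), abs(r_raw))

  # zero-variance regions are flagged and zeroed off-diagonal
  serz <- rbind(rnorm(100), rep(1, 100))
  fcz <- functional_connectivity(regional_timeseries(serz, c(5L, 9L), 1.42))
  expect_equal(attr(fcz, "zero_variance"), 9L)
  expect_equal(fcz["5", "9"], 0)
  expect_equal(fcz["9", "9"], 1)

  # Fisher z option
  fz <- functional_connectivity(ts_, fisher_z = TRUE)
  expect_equal(diag(unclass(fz)), c(`1` = 0, `2` = 0, `3` = 0))

  expect_error(functional_connectivity(
    regional_timeseries(ser[, 1:10], 1:3, 1.42)), ">= 16")
})

test_that("block-structured BOLD phantom yields the designed contrast", {
  bn <- make_bold_network(seed = 11)
  reg <- respiration_regressor(bn$physio, 600)
  proc <- highpass_temporal(smooth_inplane(bn$bold, 3.0), 0.01)
  ts_ <- extract_regional_timeseries(proc, bn$labels)
  fc <- functional_connectivity(ts_, nuisance = as.numeric(reg))
  blk <- bn$truth$block
  within <- outer(blk, blk, `==`) & upper.tri(fc)
  between <- (!outer(blk, blk, `==`)) & upper.tri(fc)
  expect_gt(mean(fc[within]) - mean(fc[between]), 0.3)
})
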