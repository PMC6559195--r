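# Shared fixture builders. Everything is generated in code at test time;
# no data files are read.

# Smooth, edge-windowed 4D test series for motion-correction tests: the
# pattern vanishes near the x/y borders so integer shifts lose no content.
moco_series <- function(d = c(24, 24, 6), nt = 8, noise_sd = 0.05, seed = 3) {
  withr_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed(seed, {
    base <- murimap:::gauss_smooth(array(rnorm(prod(d)), d), c(1.2, 1.2, 0.5))
    wx <- pmin(1, pmax(0, (pmin(seq_len(d[1]) - 1, d[1] - seq_len(d[1])) - 2) / 4))
    wy <- pmin(1, pmax(0, (pmin(seq_len(d[2]) - 1, d[2] - seq_len(d[2])) - 2) / 4))
    base <- base * outer(outer(wx, wy), rep(1, d[3])) * 10
    arr <- array(rep(base, nt), c(d, nt)) +
      array(rnorm(prod(d) * nt, sd = noise_sd), c(d, nt))
    mri_volume(arr, c(0.141, 0.141, 0.4), t_step = 1.42, modality = "bold")
  })
}

# Integer x-shift of one frame (all slices) or one slice of one frame.
shift_frame_x <- function(series, frame, shift_vox, slice = NULL) {
  arr <- series$data
  d <- dim(arr)
  src <- 1:(d[1] - shift_vox)
  dst <- (1 + shift_vox):d[1]
  if (is.null(slice)) {
    new <- array(0, d[1:3])
    new[dst, , ] <- arr[src, , , frame]
    arr[, , , frame] <- new
  } else {
    new <- matrix(0, d[1], d[2])
    new[dst, ] <- arr[src, , slice, frame]
    arr[, , slice, frame] <- new
  }
  series$data <- arr
  series
}

# Sinusoidal displacement field (mm) and the moving image obtained by
# resampling `fixed` through it: moving(x) = fixed(x + d(x)).
sinusoidal_warp_pair <- function(fixed, amplitude_vox = 2) {
  d <- dim(fixed$data)
  vs <- fixed$voxel_size
  ext <- (d - 1) * vs
  pts <- sweep(murimap:::voxel_index_grid(d), 2, vs, `*`)
  amp <- amplitude_vox * vs[1]
  dfun <- function(P) cbind(amp * sin(2 * pi * P[, 2] / ext[2]),
                            amp * sin(2 * pi * P[, 3] / ext[3]),
                            amp * sin(2 * pi * P[, 1] / ext[1]))
  dfield <- dfun(pts)
  idx <- sweep(pts + dfield, 2, vs, `/`)
  moving <- mri_volume(array(murimap:::sample_trilinear(fixed$data, idx), d), vs)
  # the registration recovers the *inverse* displacement; compute it by
  # fixed-point iteration as the independent truth
  ut <- -dfield
  for (it in 1:40) ut <- -dfun(pts + ut)
  list(moving = moving, displacement = dfield, inverse_truth = ut, pts = pts,
       dfun = dfun)
}

# Brute-force ancestor walk used as the oracle for aggregation tests.
oracle_nearest_ancestor <- function(ont, id, parent_set) {
  parent <- stats::setNames(ont$parent_id, ont$id)
  cur <- id
  while (!is.na(cur)) {
    if (cur %in% parent_set) return(cur)
    cur <- parent[[as.character(cur)]]
  }
  0L
}

expect_volume_equal <- function(a, b, tol = 1e-12) {
  expect_equal(as.vector(a$data), as.vector(b$data), tolerance = tol)
}
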