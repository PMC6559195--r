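# Deterministic Euler tractography and structural connectivity.

tube_setup <- function() {
  dw <- make_dwi(layout = "tube", snr = Inf, seed = 7)
  tf <- fit_tensor(dw$dwi, dw$scheme, dw$brain_mask)
  list(dw = dw, tf = tf)
}

test_that("streamlines span a straight tube and respect the length window", {
  ts <- tube_setup()
  fib <- track_deterministic(ts$tf, ts$dw$tube_mask, fiber_cap = 2000, seed = 42)
  expect_equal(length(fib$n_points), 2000)

  len <- streamline_lengths(fib)
  ys <- which(apply(ts$dw$tube_mask$data, 2, sum) > 0)
  tube_len <- (max(ys) - min(ys)) * ts$dw$dwi$voxel_size[2]
  expect_gte(mean(len >= 0.9 * tube_len), 0.95)
  expect_true(all(len >= 0.5 & len <= 12))

  # consecutive points are exactly one step apart
  p <- get_streamline(fib, 1)
  steps <- sqrt(rowSums(diff(p)^2))
  expect_equal(steps, rep(fib$step_mm, nrow(p) - 1), tolerance = 1e-9)
})

test_that("tracking terminates at a sharp elbow and on low FA", {
  dw <- make_dwi(layout = "bent_tube", elbow_deg = 80, snr = Inf, seed = 7)
  tf <- fit_tensor(dw$dwi, dw$scheme, dw$brain_mask)
  fib <- track_deterministic(tf, dw$tube_mask, fiber_cap = 1000, seed = 42)
  d <- dim(dw$tube_mask$data)
  ctr <- (d - 1) / 2
  vs <- dw$dwi$voxel_size
  fid <- rep(seq_along(fib$n_points), fib$n_points)
  arm1 <- fib$points[, 2] / vs[2] < ctr[2] - 3          # first arm (along y)
  arm2 <- (fib$points[, 1] / vs[1] - ctr[1]) > 3        # second arm (bent off)
  crosses <- tapply(arm1, fid, any) & tapply(arm2, fid, any)
  expect_equal(sum(crosses), 0L)

  # fa_stop above the tube FA leaves nothing to track
  expect_error(track_deterministic(tf, dw$tube_mask, fiber_cap = 10,
                                   fa_stop = 0.95, seed = 1),
               "no streamlines")
})

test_that("tracking is bit-identical under a fixed seed and stops at the cap", {
  ts <- tube_setup()
  a <- track_deterministic(ts$tf, ts$dw$tube_mask, fiber_cap = 500, seed = 9)
  b <- track_deterministic(ts$tf, ts$dw$tube_mask, fiber_cap = 500, seed = 9)
  expect_identical(a, b)
  c_ <- track_deterministic(ts$tf, ts$dw$tube_mask, fiber_cap = 500, seed = 10)
  expect_false(identical(a$points, c_$points))

  expect_equal(length(a$n_points), 500)   # exactly the cap, in seed order
  expect_equal(nrow(a$points), sum(a$n_points))
})

test_that("structural connectivity counts distinct region pairs per fiber", {
  # hand-built streamline set crossing labelled slabs
  vs <- c(1, 1, 1)
  lab_arr <- array(0L, c(12, 4, 4))
  lab_arr[1:4, , ] <- 1L
  lab_arr[5:8, , ] <- 2L
  lab_arr[9:12, , ] <- 3L
  lab <- label_volume(lab_arr, voxel_size = vs)
  mkset <- function(points_list) {
    np <- vapply(points_list, nrow, integer(1))
    structure(list(points = do.call(rbind, points_list), n_points = np,
                   offsets = cumsum(np) - np, step_mm = 1, seed = 1L,
                   n_attempted = length(np),
                   params = list(), voxel_size = vs, dims = dim(lab_arr)),
              class = "streamline_set")
  }
  line <- function(x0, x1) cbind(seq(x0, x1, by = 1), 1.5, 1.5)

  # one fiber crossing regions 1 -> 2
  s1 <- mkset(list(line(2, 6)))
  M1 <- structural_connectivity(s1, lab)
  expect_equal(M1["1", "2"], 1)
  expect_equal(M1["2", "1"], 1)
  expect_equal(sum(M1), 2)

  # a fiber touching three regions increments C(3,2) = 3 pairs
  s2 <- mkset(list(line(2, 10)))
  M2 <- structural_connectivity(s2, lab)
  expect_equal(sum(M2 > 0), 6)
  expect_equal(sum(M2), 6)

  # a fiber confined to one region counts on the diagonal
  s3 <- mkset(list(line(1, 3)))
  M3 <- structural_connectivity(s3, lab)
  expect_equal(M3["1", "1"], 1)
  expect_equal(sum(M3), 1)

  # endpoints-only mode ignores pass-through regions
  Me <- structural_connectivity(s2, lab, count = "end")
  expect_equal(Me["1", "3"], 1)
  expect_equal(sum(Me), 2)

  # fibers outside the labelled field go to background
  s4 <- mkset(list(cbind(seq(2, 6), 1.5, 20)))
  M4 <- structural_connectivity(s4, lab)
  expect_equal(sum(M4), 0)
  expect_equal(attr(M4, "n_background"), 1L)

  # permuting label codes permutes the matrix identically
  perm_arr <- lab_arr
  perm_arr[lab_arr == 1L] <- 7L
  Mp <- structural_connectivity(s1, label_volume(perm_arr, voxel_size = vs))
  expect_equal(Mp["7", "2"], M1["1", "2"])
})

test_that("connectivity totals match the per-fiber combinatorial identity", {
  ts <- tube_setup()
  # split the tube into slabs so fibers traverse several regions
  d <- dim(ts$dw$tube_mask$data)
  lab_arr <- array(0L, d)
  thirds <- floor(seq(1, d[2] + 1, length.out = 4))
  for (r in 1:3) {
    lab_arr[, thirds[r]:(thirds[r + 1] - 1), ] <- r
  }
  lab_arr[ts$dw$tube_mask$data == 0] <- 0L
  lab <- label_volume(lab_arr, voxel_size = ts$dw$dwi$voxel_size)
  fib <- track_deterministic(ts$tf, ts$dw$tube_mask, fiber_cap = 300, seed = 4)
  M <- structural_connectivity(fib, lab)
  expect_true(isSymmetric(unclass(M)))

  # direct enumeration over fibers
  total <- 0
  for (i in seq_along(fib$n_points)) {
    p <- get_streamline(fib, i)
    idx <- round(sweep(p, 2, ts$dw$dwi$voxel_size, `/`)) + 1
    ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 & idx[, 2] <= d[2] &
      idx[, 3] >= 1 & idx[, 3] <= d[3]
    labs <- unique(lab_arr[idx[ok, , drop = FALSE]])
    labs <- labs[labs != 0]
    k <- length(labs)
    total <- total + if (k <= 1) k else 2 * choose(k, 2)
  }
  expect_equal(sum(M), total)
})

test_that("TrackVis output round-trips", {
  ts <- tube_setup()
  fib <- track_deterministic(ts$tf, ts$dw$tube_mask, fiber_cap = 50, seed = 3)
  path <- tempfile(fileext = ".trk")
  write_trk(fib, path)
  back <- read_trk(path)
  expect_equal(back$n_points, fib$n_points)
  expect_equal(back$points, fib$points, tolerance = 1e-6)
  expect_equal(back$voxel_size, fib$voxel_size, tolerance = 1e-6)
})
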