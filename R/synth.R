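# Synthetic phantom generators: every pipeline stage is testable with no
# external data. All generators are pure functions of their arguments
# (fixed seed => bit-identical output). Rician noise is built from two
# Gaussian channels; SNR is defined as class-mean / Gaussian sigma.

add_rician_noise <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  d <- dim(arr)
  n <- prod(d)
  re <- arr + array(rnorm(n, sd = sigma), d)
  im <- array(rnorm(n, sd = sigma), d)
  sqrt(re^2 + im^2)
}

#' Tissue-class phantom
#'
#' An ellipsoidal "brain" of nested intensity classes (emulating CSF, grey
#' and white matter compartments of a T2-weighted scan) on an air
#' background, with optional Rician noise. Ground-truth class masks are
#' returned for bias-correction and masking tests.
#'
#' @param shape voxel dimensions (default `c(48, 48, 32)`).
#' @param voxel_size mm (default 0.2 isotropic).
#' @param intensities per-class intensity, innermost class last; its
#'   length sets the number of classes (default `c(60, 100, 140)`).
#' @param snr class-mean / Gaussian-sigma noise level; `Inf` = noiseless.
#' @param seed RNG seed for the noise field.
#' @return List: `volume` (`mri_volume`), `class_masks` (list of binary
#'   `mri_volume`s, outermost first), `brain_mask`, `sigma` (noise SD).
#' @export
make_tissue_phantom <- function(shape = c(48, 48, 32), voxel_size = c(0.2, 0.2, 0.2),
                                intensities = c(60, 100, 140), snr = Inf,
                                seed = 1L) {
  if (any(shape < 8)) stop("degenerate phantom shape")
  K <- length(intensities)
  d <- as.integer(shape)
  ctr <- (d - 1) / 2
  idx <- voxel_index_grid(d)
  # unequal in-plane semi-axes and posteriorly offset inner classes keep
  # the phantom rotationally asymmetric, like real anatomy
  semi_out <- c(0.36, 0.44, 0.40) * (d - 1)
  r2 <- function(scale, k) {
    ck <- ctr - c(0, 0.08, 0) * (k - 1) * (d - 1)
    rowSums(sweep(sweep(idx, 2, ck, `-`), 2, semi_out * scale, `/`)^2)
  }
  scales <- seq(1, 0.35, length.out = K + 1)[-1]  # shrinking nested shells
  vol <- array(0, d)
  masks <- vector("list", K)
  inside <- lapply(seq_len(K), function(k) r2(scales[k], k) <= 1)
  for (k in seq_len(K)) {
    shell <- if (k < K) inside[[k]] & !inside[[k + 1]] else inside[[k]]
    vol[array(shell, d)] <- intensities[k]
    masks[[k]] <- array(as.numeric(shell), d)
  }
  sigma <- if (is.finite(snr)) mean(intensities) / snr else 0
  noisy <- with_private_seed(as.integer(seed), add_rician_noise(vol, sigma))
  mk <- function(a, mod) mri_volume(a, voxel_size, modality = mod)
  list(
    volume = mk(noisy, "t2"),
    class_masks = lapply(masks, mk, mod = "mask"),
    brain_mask = mk(array(as.numeric(inside[[1]]), d), "mask"),
    sigma = sigma
  )
}

#' Smooth positive multiplicative bias field
#'
#' A random polynomial field of the given order, rescaled so its values
#' stay inside `amplitude` and its mean is exactly 1.
#'
#' @param shape voxel dimensions.
#' @param voxel_size mm.
#' @param order polynomial order (0 gives the constant 1).
#' @param amplitude length-2 range the field must stay within.
#' @param mask optional binary `mri_volume`/array: normalize mean and
#'   realize the amplitude range over this region (e.g. the brain) instead
#'   of the whole field of view.
#' @param seed RNG seed for the coefficients.
#' @return An `mri_volume` (modality `t2map`).
#' @export
make_bias_field <- function(shape = c(48, 48, 32), voxel_size = c(0.2, 0.2, 0.2),
                            order = 2L, amplitude = c(0.8, 1.2), mask = NULL,
                            seed = 1L) {
  d <- as.integer(shape)
  if (order == 0) {
    return(mri_volume(array(1, d), voxel_size, modality = "t2map"))
  }
  idx <- voxel_index_grid(d)
  G <- poly_basis(idx, voxel_size, order)
  w <- with_private_seed(as.integer(seed), rnorm(ncol(G)))
  w[1] <- 0
  f <- as.vector(G %*% w)
  sel <- if (is.null(mask)) rep(TRUE, length(f)) else {
    as.vector((if (inherits(mask, "mri_volume")) mask$data else as.array(mask)) != 0)
  }
  # centre on its (in-mask) mean, then scale so the in-mask range fills
  # `amplitude` around 1 while the in-mask mean stays exactly 1
  f <- f - mean(f[sel])
  lo <- min(f[sel]); hi <- max(f[sel])
  s <- min((amplitude[2] - 1) / max(hi, 1e-12),
           (1 - amplitude[1]) / max(-lo, 1e-12)) * 0.999
  f <- 1 + f * s
  mri_volume(array(f, d), voxel_size, modality = "t2map")
}

#' Electrostatically optimized gradient directions
#'
#' Spreads `n` directions over the half-sphere by minimizing a pairwise
#' inverse-squared-angle repulsion with antipodal symmetry (the classic
#' electrostatic design of multi-direction diffusion protocols).
#'
#' @param n number of directions (default 30).
#' @param seed RNG seed for the initial configuration.
#' @param iters optimization iterations (default 500).
#' @return `n` x 3 matrix of unit vectors.
#' @export
jones_directions <- function(n = 30L, seed = 7L, iters = 500L) {
  V <- with_private_seed(as.integer(seed), {
    v <- matrix(rnorm(3 * n), n, 3)
    v / sqrt(rowSums(v^2))
  })
  step <- 0.05
  for (it in seq_len(iters)) {
    Fm <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      Vi <- matrix(V[i, ], n, 3, byrow = TRUE)
      diffs <- Vi - V                      # V[i] - V[j]
      sums <- Vi + V                       # V[i] - (-V[j]): antipodal term
      dd <- rowSums(diffs^2); ds <- rowSums(sums^2)
      dd[i] <- Inf; ds[i] <- Inf
      Fm[i, ] <- colSums(diffs / (dd^1.5 + 1e-9)) + colSums(sums / (ds^1.5 + 1e-9))
    }
    V <- V + step * Fm
    V <- V / sqrt(rowSums(V^2))
    step <- step * 0.995
  }
  V
}

#' Synthetic diffusion-weighted series with known tensors
#'
#' Builds a tensor field with a known fiber geometry (a straight tube, a
#' tube bent at a configurable elbow angle, or two 90-degree crossing
#' tubes) in an isotropic background, simulates the signal
#' `S = S0 * exp(-b g' D g)` for an electrostatic direction scheme, and
#' returns signal, scheme and ground truth.
#'
#' @param shape voxel dimensions (default `c(24, 24, 12)`).
#' @param voxel_size mm (default 0.4 isotropic).
#' @param layout `"tube"`, `"bent_tube"` or `"crossing"`.
#' @param elbow_deg bend angle of the `bent_tube` layout (degrees).
#' @param n_directions diffusion directions (default 30).
#' @param b b-value for weighted volumes (s/mm^2, default 1000).
#' @param s0 unweighted signal level.
#' @param snr Rician noise level (`Inf` = noiseless).
#' @param tube_radius_vox tube radius in voxels.
#' @param seed RNG seed (directions and noise).
#' @return List: `dwi` (4D `mri_volume`), `scheme`
#'   ([gradient_scheme()]), `tube_mask`, `brain_mask`, `eigenvalues_true`
#'   (length 3), `e1_true` (array dims x 3), `d6_true` (array dims x 6).
#' @export
make_dwi <- function(shape = c(24, 24, 12), voxel_size = c(0.4, 0.4, 0.4),
                     layout = c("tube", "bent_tube", "crossing"),
                     elbow_deg = 80, n_directions = 30L, b = 1000,
                     s0 = 100, snr = Inf, tube_radius_vox = 2.2, seed = 7L) {
  layout <- match.arg(layout)
  d <- as.integer(shape)
  lam <- c(1.5e-3, 0.5e-3, 0.5e-3)
  iso <- 0.7e-3
  idx <- voxel_index_grid(d)
  ctr <- (d - 1) / 2
  dir_field <- matrix(0, prod(d), 3)
  in_tube <- rep(FALSE, prod(d))
  dist_point_seg <- function(p, a, bseg) {
    ab <- bseg - a
    t <- pmin(pmax((sweep(p, 2, a, `-`) %*% ab) / sum(ab^2), 0), 1)
    dd <- p - (matrix(a, nrow(p), 3, byrow = TRUE) + t %*% t(ab))
    sqrt(rowSums(dd^2))
  }
  if (layout == "tube") {
    # flat-ended cylinder along y: every fiber can run the full length
    rad <- sqrt((idx[, 1] - ctr[1])^2 + (idx[, 3] - ctr[3])^2)
    in_tube <- rad <= tube_radius_vox & idx[, 2] >= 1 & idx[, 2] <= d[2] - 2
    dir_field[in_tube, ] <- matrix(c(0, 1, 0), sum(in_tube), 3, byrow = TRUE)
  } else if (layout == "bent_tube") {
    th <- elbow_deg * pi / 180
    elbow <- c(ctr[1], ctr[2], ctr[3])
    a <- c(ctr[1], 1, ctr[3])
    arm2 <- c(sin(th), cos(th), 0)                  # rotated by elbow angle
    bseg <- elbow + arm2 * (ctr[2] - 1)
    d1 <- dist_point_seg(idx, a, elbow)
    d2 <- dist_point_seg(idx, elbow, bseg)
    seg1 <- d1 <= tube_radius_vox
    seg2 <- d2 <= tube_radius_vox & !seg1
    in_tube <- seg1 | seg2
    dir_field[seg1, ] <- matrix(c(0, 1, 0), sum(seg1), 3, byrow = TRUE)
    dir_field[seg2, ] <- matrix(arm2, sum(seg2), 3, byrow = TRUE)
  } else {
    a1 <- c(ctr[1], 1, ctr[3]); b1 <- c(ctr[1], d[2] - 2, ctr[3])
    a2 <- c(1, ctr[2], ctr[3]); b2 <- c(d[1] - 2, ctr[2], ctr[3])
    s1 <- dist_point_seg(idx, a1, b1) <= tube_radius_vox
    s2 <- dist_point_seg(idx, a2, b2) <= tube_radius_vox & !s1
    in_tube <- s1 | s2
    dir_field[s1, ] <- matrix(c(0, 1, 0), sum(s1), 3, byrow = TRUE)
    dir_field[s2, ] <- matrix(c(1, 0, 0), sum(s2), 3, byrow = TRUE)
  }
  # brain = everything inside an ellipsoid margin; background isotropic
  in_brain <- rowSums(sweep(sweep(idx, 2, ctr, `-`), 2, 0.48 * (d - 1), `/`)^2) <= 1
  in_brain <- in_brain | in_tube
  # per-voxel tensors
  n <- prod(d)
  D6 <- matrix(0, n, 6)                      # xx yy zz xy xz yz
  bg <- in_brain & !in_tube
  D6[bg, 1:3] <- iso
  if (any(in_tube)) {
    e1 <- dir_field[in_tube, , drop = FALSE]
    # D = (l1 - l23) e1 e1' + l23 I
    l23 <- lam[2]
    dl <- lam[1] - l23
    D6[in_tube, 1] <- dl * e1[, 1]^2 + l23
    D6[in_tube, 2] <- dl * e1[, 2]^2 + l23
    D6[in_tube, 3] <- dl * e1[, 3]^2 + l23
    D6[in_tube, 4] <- dl * e1[, 1] * e1[, 2]
    D6[in_tube, 5] <- dl * e1[, 1] * e1[, 3]
    D6[in_tube, 6] <- dl * e1[, 2] * e1[, 3]
  }
  dirs <- jones_directions(n_directions, seed = seed)
  bvals <- c(0, rep(b, n_directions))
  bvecs <- rbind(c(0, 0, 0), dirs)
  # signal: S = S0 exp(-b g' D g); vectorized over voxels per volume
  nt <- length(bvals)
  sig <- matrix(0, n, nt)
  sig[in_brain, 1] <- s0
  for (v in 2:nt) {
    g <- bvecs[v, ]
    quad <- D6[, 1] * g[1]^2 + D6[, 2] * g[2]^2 + D6[, 3] * g[3]^2 +
      2 * (D6[, 4] * g[1] * g[2] + D6[, 5] * g[1] * g[3] + D6[, 6] * g[2] * g[3])
    sig[, v] <- s0 * exp(-b * quad) * in_brain
  }
  arr <- array(sig, c(d, nt))
  sigma <- if (is.finite(snr)) s0 / snr else 0
  if (sigma > 0) {
    arr <- with_private_seed(as.integer(seed) + 1L, add_rician_noise(arr, sigma))
  }
  mk <- function(a, mod) mri_volume(array(as.numeric(a), d), voxel_size, modality = mod)
  list(
    dwi = mri_volume(arr, voxel_size, t_step = 3, modality = "dwi"),
    scheme = gradient_scheme(bvals, bvecs),
    tube_mask = mk(in_tube, "mask"),
    brain_mask = mk(in_brain, "mask"),
    eigenvalues_true = lam, iso_diffusivity = iso,
    e1_true = array(dir_field, c(d, 3)),
    d6_true = array(D6, c(d, 6))
  )
}

#' Block-structured resting-state BOLD phantom
#'
#' Regional signals are built as shared within-block factors plus
#' idiosyncratic noise plus a sinusoidal respiration confound common to
#' all regions; voxel series add voxel-level noise on top of their
#' region's signal. A breathing trace with per-TR trigger marks and the
#' designed (truth) correlation structure are returned alongside.
#'
#' @param n_regions number of regions (default 10).
#' @param n_blocks number of correlation blocks (default 2).
#' @param frames time points (default 600).
#' @param tr repetition time in seconds (default 1.42).
#' @param shared_sd SD of the within-block shared factor.
#' @param noise_sd SD of the idiosyncratic regional noise.
#' @param resp_amp amplitude of the respiration confound in the BOLD
#'   series.
#' @param respiration_hz breathing rate (default 2 Hz).
#' @param voxels_per_region voxels painted per region.
#' @param voxel_noise_sd voxel-level noise SD.
#' @param physio_rate_hz sampling rate of the breathing trace.
#' @param seed RNG seed.
#' @return List: `bold` (4D `mri_volume`), `labels` (label `mri_volume`),
#'   `physio` ([physio_trace()]), `truth` (block membership vector and
#'   designed correlation matrix), `regional_truth` (regions x frames
#'   noiseless regional signals).
#' @export
make_bold_network <- function(n_regions = 10L, n_blocks = 2L, frames = 600L,
                              tr = 1.42, shared_sd = 1, noise_sd = 1,
                              resp_amp = 0.5, respiration_hz = 2,
                              voxels_per_region = 24L, voxel_noise_sd = 0.3,
                              physio_rate_hz = 50, seed = 11L) {
  block <- rep(seq_len(n_blocks), length.out = n_regions)
  block <- sort(block)
  tt <- (seq_len(frames) - 1) * tr
  out <- with_private_seed(as.integer(seed), {
    shared <- matrix(rnorm(n_blocks * frames, sd = shared_sd), n_blocks)
    idio <- matrix(rnorm(n_regions * frames, sd = noise_sd), n_regions)
    resp_phase <- runif(1, 0, 2 * pi)
    resp_reg <- sin(2 * pi * respiration_hz * tt + resp_phase)
    regional <- shared[block, , drop = FALSE] + idio +
      resp_amp * matrix(resp_reg, n_regions, frames, byrow = TRUE)
    # voxel layout: regions as consecutive x-slabs in a thin slab volume
    nx <- n_regions * 4L
    d <- c(nx, 6L, 4L)
    lab <- array(0L, d)
    for (r in seq_len(n_regions)) lab[(r - 1) * 4 + 1:4, 2:5, 2:3] <- r
    vox_region <- as.vector(lab)
    series <- array(0, c(d, frames))
    mat <- matrix(0, prod(d), frames)
    in_r <- vox_region > 0
    mat[in_r, ] <- regional[vox_region[in_r], , drop = FALSE] +
      matrix(rnorm(sum(in_r) * frames, sd = voxel_noise_sd), sum(in_r))
    series <- array(mat, c(d, frames))
    # breathing trace with triggers at each TR
    ns <- ceiling(frames * tr * physio_rate_hz) + 10L
    ts_ <- (seq_len(ns) - 1) / physio_rate_hz
    trace <- sin(2 * pi * respiration_hz * ts_ + resp_phase) +
      rnorm(ns, sd = 0.05)
    trig <- round(tt * physio_rate_hz) + 1L
    list(regional = regional, lab = lab, series = series, trace = trace,
         trig = trig, d = d)
  })
  r_within <- shared_sd^2 / (shared_sd^2 + noise_sd^2 + resp_amp^2 / 2)
  r_between <- (resp_amp^2 / 2) / (shared_sd^2 + noise_sd^2 + resp_amp^2 / 2)
  truth_cor <- matrix(r_between, n_regions, n_regions)
  same <- outer(block, block, `==`)
  truth_cor[same] <- r_within
  diag(truth_cor) <- 1
  list(
    bold = mri_volume(out$series, c(0.141, 0.141, 0.4), t_step = tr,
                      modality = "bold"),
    labels = label_volume(out$lab, voxel_size = c(0.141, 0.141, 0.4)),
    physio = physio_trace(out$trace, physio_rate_hz, out$trig),
    truth = list(block = block, correlation = truth_cor),
    regional_truth = out$regional
  )
}

#' Toy hierarchical atlas
#'
#' A complete tree ontology of the given depth and branching factor with
#' leaf labels painted as contiguous blocks in the left hemisphere and
#' mirrored to the right, for exercising parental aggregation and
#' hemisphere-split logic.
#'
#' @param depth tree depth below the root (default 2).
#' @param branching children per node (default 3).
#' @param shape label-volume dimensions; x is the left-right axis.
#' @param voxel_size mm.
#' @return List: `ontology` ([ontology_table()]), `labels` (label
#'   `mri_volume`), `leaf_ids`, `parent_ids` (ids one level above the
#'   leaves).
#' @export
make_toy_atlas <- function(depth = 2L, branching = 3L, shape = c(24, 18, 10),
                           voxel_size = c(0.2, 0.2, 0.2)) {
  stopifnot(depth >= 1, branching >= 1)
  rows <- list(data.frame(id = 1L, acronym = "root", name = "root",
                          parent_id = NA_integer_))
  level_ids <- list(1L)
  next_id <- 2L
  for (lv in seq_len(depth)) {
    prev <- level_ids[[lv]]
    ids <- integer(0)
    for (p in prev) {
      kid <- next_id - 1L + seq_len(branching)
      next_id <- next_id + branching
      ids <- c(ids, kid)
      rows[[length(rows) + 1L]] <- data.frame(
        id = kid,
        acronym = sprintf("n%d", kid),
        name = sprintf("node %d (level %d)", kid, lv),
        parent_id = p
      )
    }
    level_ids[[lv + 1L]] <- ids
  }
  ont <- ontology_table(do.call(rbind, rows))
  leaves <- level_ids[[depth + 1L]]
  d <- as.integer(shape)
  half <- d[1] %/% 2
  lab <- array(0L, d)
  # paint leaves as y-slabs in the left half, mirrored into the right half
  nl <- length(leaves)
  yb <- floor(seq(1, d[2] + 1, length.out = nl + 1))
  for (i in seq_len(nl)) {
    ys <- yb[i]:(yb[i + 1] - 1)
    lab[1:half, ys, ] <- leaves[i]
  }
  lab[(d[1] - half + 1):d[1], , ] <- lab[half:1, , ]
  list(
    ontology = ont,
    labels = label_volume(lab, voxel_size = voxel_size),
    leaf_ids = leaves,
    parent_ids = if (depth >= 1) level_ids[[depth]] else 1L
  )
}
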