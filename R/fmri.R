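# Resting-state fMRI pipeline: optional slice-timing correction, in-plane
# smoothing, temporal high-pass filtering, respiration regressors from a
# breathing trace with scanner triggers, regional time-series extraction
# and Pearson functional connectivity.

#' Physiological (respiration) trace with scanner triggers
#'
#' @param samples breathing amplitude samples at a fixed rate.
#' @param rate_hz sampling rate in Hz.
#' @param trigger_indices strictly increasing sample indices (1-based) at
#'   which image volumes were acquired.
#' @return A `physio_trace`.
#' @export
physio_trace <- function(samples, rate_hz, trigger_indices) {
  samples <- as.numeric(samples)
  trigger_indices <- as.integer(trigger_indices)
  if (any(diff(trigger_indices) <= 0)) {
    stop("trigger indices must be strictly increasing")
  }
  if (max(trigger_indices) > length(samples) || min(trigger_indices) < 1) {
    stop("trigger indices outside the trace")
  }
  structure(list(samples = samples, rate_hz = rate_hz,
                 trigger_indices = trigger_indices),
            class = "physio_trace")
}

#' Read a physiological trace from delimited text
#'
#' Two-column text (sample index or time, amplitude); triggers as a
#' separate one-column index file.
#'
#' @param trace_path two-column delimited file.
#' @param trigger_path one-column file of 1-based sample indices.
#' @param rate_hz sampling rate of the trace in Hz.
#' @return A [physio_trace()].
#' @export
read_physio_trace <- function(trace_path, trigger_path, rate_hz) {
  tr <- read.table(trace_path)
  trig <- scan(trigger_path, quiet = TRUE)
  physio_trace(tr[[2]], rate_hz, trig)
}

#' Slice-timing correction of a 4D series
#'
#' Slices of an EPI volume are acquired at different times within one TR.
#' When enabled, each slice's voxel time series is linearly interpolated
#' to the acquisition phase of the reference slice (the first slice in
#' `slice_order`); when disabled the series is returned untouched.
#'
#' @param series 4D [mri_volume()].
#' @param slice_order permutation of `1:nz` giving temporal acquisition
#'   order.
#' @param enabled logical switch.
#' @return The corrected 4D `mri_volume`.
#' @export
slice_timing_correct <- function(series, slice_order, enabled = TRUE) {
  stopifnot(inherits(series, "mri_volume"))
  if (!is_4d(series)) stop("slice timing correction requires a 4D series")
  if (!enabled) return(series)
  d <- dim(series$data)
  nz <- d[3]
  if (length(slice_order) != nz || !setequal(slice_order, seq_len(nz))) {
    stop("'slice_order' must be a permutation of 1:", nz)
  }
  # slice z acquired at fraction (position in order - 1)/nz of the TR
  frac <- (match(seq_len(nz), slice_order) - 1) / nz
  tt <- seq_len(d[4])
  out <- series$data
  for (z in seq_len(nz)) {
    if (frac[z] == 0) next
    sl <- matrix(series$data[, , z, ], ncol = d[4])
    # sample v[t] reflects physical time t + frac; interpolate at t - frac
    # so every slice ends up on the reference slice's phase
    shifted <- t(apply(sl, 1, function(v)
      approx(tt, v, xout = tt - frac[z], rule = 2)$y))
    out[, , z, ] <- array(shifted, c(d[1], d[2], d[4]))
  }
  series$data <- out
  series
}

#' In-plane Gaussian smoothing of a 4D series
#'
#' Applies a 2D Gaussian filter (sigma = FWHM / 2.3548 per axis, converted
#' to voxels) within each axial slice of each frame. Because EPI voxels
#' are strongly anisotropic in z, no smoothing is applied across slices,
#' and none across time.
#'
#' @param series 4D [mri_volume()].
#' @param fwhm_mm full width at half maximum in mm (default 3.0).
#' @return The smoothed 4D `mri_volume`.
#' @export
smooth_inplane <- function(series, fwhm_mm = 3.0) {
  stopifnot(inherits(series, "mri_volume"))
  if (!is_4d(series)) stop("smooth_inplane() requires a 4D series")
  if (fwhm_mm <= 0) stop("'fwhm_mm' must be positive")
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  sig_vox <- sigma_mm / series$voxel_size[1:2]
  if (any(sigma_mm < series$voxel_size[1:2])) {
    warning("FWHM below one voxel; smoothing applied anyway")
  }
  series$data <- gauss_smooth(series$data, sig_vox, axes = 1:2)
  series
}

#' Temporal high-pass filter
#'
#' Removes slow drifts below `cutoff_hz` while preserving fluctuations
#' above it, and removes the mean. The default filter subtracts a
#' Gaussian-weighted running-line fit (local linear trend, sigma =
#' 1/(4 * cutoff) seconds), which attenuates a component at one fifth of
#' the cutoff by over 90% while passing components above twice the cutoff
#' within 10%. `method = "fft"` applies a hard spectral cut instead.
#'
#' @param x 4D [mri_volume()] or a [regional_timeseries()] (filtered per
#'   region), or a plain numeric vector/matrix (rows = series) with
#'   `t_step` supplied.
#' @param cutoff_hz high-pass cutoff frequency (default 0.01 Hz).
#' @param method `"gaussline"` (default) or `"fft"`.
#' @param t_step sampling interval in seconds (taken from `x` when it
#'   carries one).
#' @return Object of the same type, filtered and mean-removed.
#' @export
highpass_temporal <- function(x, cutoff_hz = 0.01,
                              method = c("gaussline", "fft"), t_step = NULL) {
  method <- match.arg(method)
  if (inherits(x, "mri_volume")) {
    if (!is_4d(x)) stop("high-pass filtering requires a 4D series")
    d <- dim(x$data)
    mat <- matrix(x$data, nrow = prod(d[1:3]))
    filt <- highpass_matrix(mat, cutoff_hz, x$t_step, method)
    x$data <- array(filt, d)
    return(x)
  }
  if (inherits(x, "regional_timeseries")) {
    x$series <- highpass_matrix(x$series, cutoff_hz, x$t_step, method)
    return(x)
  }
  if (is.null(t_step)) stop("'t_step' required for plain numeric input")
  if (is.vector(x)) {
    as.vector(highpass_matrix(matrix(x, nrow = 1), cutoff_hz, t_step, method))
  } else {
    highpass_matrix(as.matrix(x), cutoff_hz, t_step, method)
  }
}

# rows = series
highpass_matrix <- function(mat, cutoff_hz, t_step, method) {
  nt <- ncol(mat)
  if (nt < 16) stop("series too short (< 16 timepoints)")
  nyquist <- 1 / (2 * t_step)
  if (cutoff_hz >= nyquist) stop("cutoff at or above the Nyquist frequency")
  if (method == "fft") {
    fr <- (seq_len(nt) - 1) / (nt * t_step)
    fr <- pmin(fr, 1 / t_step - fr)       # two-sided frequency axis
    keep <- fr >= cutoff_hz
    keep[1] <- FALSE                       # remove mean
    ft <- t(apply(mat, 1, fft))
    ft[, !keep] <- 0
    out <- t(apply(ft, 1, function(v) Re(fft(v, inverse = TRUE)) / nt))
  } else {
    sigma_s <- 1 / (4 * cutoff_hz)
    sigma_vol <- sigma_s / t_step
    tt <- seq_len(nt)
    # precompute the local-linear smoother matrix once
    S <- matrix(0, nt, nt)
    for (i in tt) {
      w <- exp(-((tt - i)^2) / (2 * sigma_vol^2))
      dtc <- tt - i
      sw <- sum(w); swx <- sum(w * dtc); swx2 <- sum(w * dtc^2)
      den <- sw * swx2 - swx^2
      S[i, ] <- (swx2 * w - swx * w * dtc) / den
    }
    trend <- mat %*% t(S)
    out <- mat - trend
  }
  sweep(out, 1, rowMeans(out), `-`)
}

#' Respiration regressor from a breathing trace
#'
#' Baseline-corrects the trace by subtracting a running median, detects
#' inspiration peaks as local maxima exceeding an adaptive threshold
#' (0.3 times the inter-decile range of the corrected trace), converts
#' the peak train to an instantaneous respiratory rate (1 / inter-peak
#' interval), and samples that rate at the volume trigger times.
#'
#' @param trace a [physio_trace()].
#' @param n_volumes number of image volumes the regressor must cover.
#' @return Numeric vector of length `n_volumes` (breaths per second),
#'   with the detected peak sample indices as attribute `peaks`. A trace
#'   with no detectable peaks yields a flat zero regressor with a warning.
#' @export
respiration_regressor <- function(trace, n_volumes) {
  stopifnot(inherits(trace, "physio_trace"))
  x <- trace$samples
  fs <- trace$rate_hz
  win <- max(3L, as.integer(2 * fs) %/% 2L * 2L + 1L)   # ~2 s, odd
  base <- runmed(x, min(win, length(x) - (1 - length(x) %% 2)))
  xc <- x - base
  thr <- 0.3 * diff(quantile(xc, c(0.1, 0.9)))
  n <- length(xc)
  is_peak <- c(FALSE, xc[2:(n - 1)] > xc[1:(n - 2)] & xc[2:(n - 1)] >= xc[3:n],
               FALSE) & xc > thr
  peaks <- which(is_peak)
  if (length(peaks) < 2) {
    warning("no inspiration peaks detected; returning a flat regressor")
    return(structure(rep(0, n_volumes), peaks = integer(0)))
  }
  rate <- fs / diff(peaks)                 # breaths per second per interval
  mid <- (peaks[-1] + peaks[-length(peaks)]) / 2
  trig <- trace$trigger_indices
  if (length(trig) < n_volumes) {
    warning("fewer triggers than volumes; extrapolating with the median TR")
    tr_step <- if (length(trig) > 1) median(diff(trig)) else fs
    trig <- c(trig, trig[length(trig)] +
                tr_step * seq_len(n_volumes - length(trig)))
  }
  trig <- trig[seq_len(n_volumes)]
  reg <- approx(mid, rate, xout = trig, rule = 2)$y
  structure(reg, peaks = peaks)
}

# ---- regional series and connectivity ----------------------------------

#' Regional time-series container
#'
#' @param series matrix regions x timepoints.
#' @param label_ids region label ids (row legend).
#' @param t_step temporal spacing in seconds.
#' @return A `regional_timeseries`.
#' @export
regional_timeseries <- function(series, label_ids, t_step) {
  series <- as.matrix(series)
  stopifnot(nrow(series) == length(label_ids), all(is.finite(series)))
  structure(list(series = series, label_ids = as.integer(label_ids),
                 t_step = t_step),
            class = "regional_timeseries")
}

#' @export
print.regional_timeseries <- function(x, ...) {
  cat("<regional_timeseries> ", nrow(x$series), " regions x ",
      ncol(x$series), " timepoints (TR ", signif(x$t_step, 4), " s)\n", sep = "")
  invisible(x)
}

#' Extract regional mean time series
#'
#' Per region and frame, the arithmetic mean over in-region voxels. Empty
#' regions are dropped and reported. The per-region binary mask stack
#' (x, y, z, region) is returned alongside for export.
#'
#' @param series 4D [mri_volume()].
#' @param lab label `mri_volume` registered to the series' space.
#' @return A [regional_timeseries()] with attributes `dropped` (label ids
#'   absent from the field of view) and `mask_stack` (4D array of
#'   per-region binary masks).
#' @export
extract_regional_timeseries <- function(series, lab) {
  stopifnot(inherits(series, "mri_volume"), inherits(lab, "mri_volume"))
  if (!is_4d(series)) stop("need a 4D series")
  d <- dim(series$data)
  if (!identical(d[1:3], dim(lab$data))) stop("label volume shape mismatch")
  codes <- as.vector(lab$data)
  ids <- sort(unique(codes))
  ids <- ids[ids != 0]
  if (length(ids) == 0) stop("no region overlaps the field of view")
  mat <- matrix(series$data, nrow = prod(d[1:3]))
  sums <- rowsum(mat[codes != 0, , drop = FALSE], codes[codes != 0])
  counts <- as.vector(table(codes[codes != 0]))
  means <- sums / counts
  ord <- order(as.integer(rownames(sums)))   # numeric region order
  ids_out <- as.integer(rownames(sums))[ord]
  means <- unname(means[ord, , drop = FALSE])
  stack <- array(0, c(d[1:3], length(ids)))
  for (r in seq_along(ids)) stack[, , , r] <- (lab$data == ids[r]) * 1
  out <- regional_timeseries(means, ids_out, series$t_step)
  attr(out, "dropped") <- integer(0)
  attr(out, "mask_stack") <- stack
  out
}

#' Functional connectivity matrix
#'
#' Optionally residualizes each regional series against nuisance
#' regressors (ordinary least squares, with intercept), then computes
#' pairwise Pearson correlations. Zero-variance regions get zero entries
#' and are flagged.
#'
#' @param ts a [regional_timeseries()].
#' @param nuisance optional numeric vector or matrix (timepoints x
#'   regressors) of nuisance series, e.g. [respiration_regressor()].
#' @param fisher_z if `TRUE`, return Fisher z-transformed correlations
#'   (diagonal set to 0).
#' @return A `connectivity_matrix` (kind "functional"), symmetric with
#'   unit diagonal, entries in [-1, 1]; attribute `zero_variance` lists
#'   flagged label ids.
#' @export
functional_connectivity <- function(ts, nuisance = NULL, fisher_z = FALSE) {
  stopifnot(inherits(ts, "regional_timeseries"))
  X <- t(ts$series)                       # time x regions
  nt <- nrow(X)
  if (nt < 16) stop("need >= 16 timepoints")
  if (!is.null(nuisance)) {
    N <- as.matrix(nuisance)
    if (nrow(N) != nt) stop("nuisance length does not match timepoints")
    X <- qr.resid(qr(cbind(1, N)), X)
  }
  sds <- apply(X, 2, sd)
  flagged <- ts$label_ids[sds == 0]
  ok <- sds > 0
  M <- matrix(0, ncol(X), ncol(X), dimnames = list(ts$label_ids, ts$label_ids))
  if (any(ok)) M[ok, ok] <- cor(X[, ok, drop = FALSE])
  diag(M) <- 1
  if (fisher_z) {
    M <- atanh(pmin(pmax(M, -0.999999), 0.999999))
    diag(M) <- 0
  }
  structure(M, class = c("connectivity_matrix", "matrix"),
            kind = "functional", zero_variance = flagged)
}

#' Write regional time series as TSV
#' @param ts a [regional_timeseries()].
#' @param path output file (regions x time, label ids in first column).
#' @return `path`, invisibly.
#' @export
write_regional_tsv <- function(ts, path) {
  df <- data.frame(label_id = ts$label_ids, ts$series, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
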