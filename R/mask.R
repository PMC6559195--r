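# Brain masking: Otsu threshold + largest 6-connected component +
# morphological closing, constrained to a sphere around the intensity
# centre of mass. A built-in replacement for external skull-stripping
# tools so the pipeline runs with zero external binaries.

otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(pmax(findInterval(x, seq(rng[1], rng[2], length.out = n_bins + 1L),
                                       all.inside = TRUE), 1L), n_bins), n_bins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) * diff(rng) / n_bins
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

# 6-connected components of a 3D logical array by vectorized frontier BFS.
# Returns integer array of component labels (0 = background).
label_components_6 <- function(fg) {
  d <- dim(fg)
  lab <- array(0L, d)
  unvisited <- fg
  comp <- 0L
  shift_or <- function(a) {
    out <- array(FALSE, d)
    out[-1, , ] <- out[-1, , ] | a[-d[1], , ]
    out[-d[1], , ] <- out[-d[1], , ] | a[-1, , ]
    out[, -1, ] <- out[, -1, ] | a[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] | a[, -1, ]
    out[, , -1] <- out[, , -1] | a[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] | a[, , -1]
    out
  }
  while (any(unvisited)) {
    comp <- comp + 1L
    seed <- which(unvisited)[1]
    frontier <- array(FALSE, d)
    frontier[seed] <- TRUE
    member <- frontier
    unvisited[seed] <- FALSE
    repeat {
      nxt <- shift_or(frontier) & unvisited
      if (!any(nxt)) break
      member <- member | nxt
      unvisited[nxt] <- FALSE
      frontier <- nxt
    }
    lab[member] <- comp
  }
  lab
}

# Binary dilation/erosion with the 6-neighbour cross, `iter` times.
dilate6 <- function(a, iter = 1L) {
  d <- dim(a)
  for (it in seq_len(iter)) {
    out <- a
    out[-1, , ] <- out[-1, , ] | a[-d[1], , ]
    out[-d[1], , ] <- out[-d[1], , ] | a[-1, , ]
    out[, -1, ] <- out[, -1, ] | a[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] | a[, -1, ]
    out[, , -1] <- out[, , -1] | a[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] | a[, , -1]
    a <- out
  }
  a
}

erode6 <- function(a, iter = 1L) !dilate6(!a, iter)

close6 <- function(a, iter = 1L) erode6(dilate6(a, iter), iter)

#' Estimate a brain mask from an intensity volume
#'
#' Thresholds the volume (Otsu), keeps the largest 6-connected foreground
#' component, fills small gaps by morphological closing, and clips the
#' result to a sphere of `1.5 * radius_hint` around the intensity centre of
#' mass. Intended as a self-contained stand-in for external skull-stripping
#' tools on high-contrast rodent data.
#'
#' @param vol a 3D [mri_volume()].
#' @param radius_hint approximate brain radius in mm (mouse brain: ~5 mm).
#' @return A binary `mri_volume` with `modality = "mask"`.
#' @export
estimate_brain_mask <- function(vol, radius_hint = 5) {
  stopifnot(inherits(vol, "mri_volume"))
  if (is_4d(vol)) stop("estimate_brain_mask() requires a 3D volume")
  a <- vol$data
  if (all(a == 0)) stop("all-zero volume: cannot estimate a brain mask")
  thr <- otsu_threshold(a)
  fg <- a > thr
  if (!any(fg)) fg <- a > mean(range(a))
  comps <- label_components_6(fg)
  sizes <- tabulate(comps[comps > 0])
  mask <- comps == which.max(sizes)
  mask <- close6(mask, 1L)
  # sphere constraint around the intensity centre of mass (world mm)
  d <- dim(a)
  idx <- voxel_index_grid(d)
  w <- as.vector(a) - min(a)
  com <- colSums(idx * w) / sum(w) * vol$voxel_size
  pos <- sweep(idx, 2, vol$voxel_size, `*`)
  r2 <- rowSums(sweep(pos, 2, com, `-`)^2)
  sphere <- array(r2 <= (1.5 * radius_hint)^2, d)
  mask <- mask & sphere
  as_volume_like(array(as.numeric(mask), d), vol, modality = "mask")
}

#' Apply a binary mask to a volume
#'
#' Voxels outside the mask are set to zero. For 4D series the mask is
#' applied to every frame.
#'
#' @param vol an [mri_volume()].
#' @param mask a binary `mri_volume` of matching spatial shape.
#' @return The masked volume.
#' @export
apply_mask <- function(vol, mask) {
  stopifnot(inherits(vol, "mri_volume"), inherits(mask, "mri_volume"))
  dm <- dim(mask$data)
  dv <- dim(vol$data)
  if (!identical(dv[1:3], dm)) stop("mask shape does not match volume")
  m <- mask$data != 0
  out <- vol$data
  if (is_4d(vol)) {
    out <- out * array(rep(as.numeric(m), dv[4]), dv)
  } else {
    out[!m] <- 0
  }
  vol$data <- out
  vol
}
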