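# Deterministic whole-brain streamline tractography: bidirectional Euler
# integration along the principal diffusion direction, nearest-voxel
# direction lookup, with termination on mask exit, low FA or sharp turns.
# Streamlines are propagated in large vectorized batches so a
# million-fiber run stays tractable in pure R.

fa_from_eigenvalues <- function(ev) {
  d3 <- dim(ev)[1:3]
  l1 <- array(ev[, , , 1], d3)
  l2 <- array(ev[, , , 2], d3)
  l3 <- array(ev[, , , 3], d3)
  md <- (l1 + l2 + l3) / 3
  nrm <- sqrt(l1^2 + l2^2 + l3^2)
  dev <- sqrt((l1 - md)^2 + (l2 - md)^2 + (l3 - md)^2)
  ifelse(nrm > 0, sqrt(1.5) * dev / nrm, 0)
}

#' Deterministic streamline tractography
#'
#' Seeds are drawn uniformly from the masked voxels (with sub-voxel
#' jitter) and propagated in both directions along the principal
#' eigenvector field with Euler steps of `step_mm`, taking the direction
#' of the nearest voxel at each step (sign-aligned with the previous
#' direction). A streamline stops when it leaves the mask, enters a voxel
#' with FA below `fa_stop`, or would turn by more than `angle_deg`.
#' Fibers outside the `[min_len_mm, max_len_mm]` window are discarded;
#' generation stops exactly when `fiber_cap` fibers have been retained.
#' Identical seeds give bit-identical results.
#'
#' @param tf a `tensor_field` from [fit_tensor()].
#' @param mask binary `mri_volume` restricting tracking.
#' @param step_mm Euler step length (default 0.5 mm).
#' @param angle_deg maximum turning angle between consecutive steps
#'   (default 55 degrees), in (0, 90).
#' @param min_len_mm,max_len_mm retained length window (defaults 0.5 and
#'   12 mm).
#' @param fiber_cap retained-fiber count at which generation stops
#'   (default one million).
#' @param fa_stop FA termination threshold (default 0.2).
#' @param seed integer RNG seed; required for reproducibility.
#' @return A `streamline_set`: flat `points` matrix (mm), per-fiber
#'   `n_points`/`offsets`, `step_mm`, attempt counts and parameters.
#' @export
track_deterministic <- function(tf, mask, step_mm = 0.5, angle_deg = 55,
                                min_len_mm = 0.5, max_len_mm = 12,
                                fiber_cap = 1e6, fa_stop = 0.2, seed = 1L) {
  stopifnot(inherits(tf, "tensor_field"), inherits(mask, "mri_volume"))
  if (angle_deg <= 0 || angle_deg >= 90) stop("'angle_deg' must be in (0, 90)")
  if (step_mm <= 0 || min_len_mm <= 0 || max_len_mm <= min_len_mm ||
      fiber_cap < 1) stop("invalid tracking parameters")
  dims <- dim(tf$s0)
  vs <- tf$voxel_size
  m <- mask$data != 0
  if (!any(m)) stop("empty tracking mask")
  fa <- fa_from_eigenvalues(tf$eigenvalues)
  e1x <- tf$e1[, , , 1]; e1y <- tf$e1[, , , 2]; e1z <- tf$e1[, , , 3]
  track_ok <- as.vector(m & fa >= fa_stop)
  mask_idx <- which(as.vector(m))
  cos_thr <- cos(angle_deg * pi / 180)
  max_steps <- as.integer(ceiling(max_len_mm / step_mm)) + 1L
  nvox <- prod(dims)
  # linear voxel index (1-based) of world positions; 0 when outside grid
  vox_of <- function(P) {
    i <- round(P[, 1] / vs[1]); j <- round(P[, 2] / vs[2]); k <- round(P[, 3] / vs[3])
    inside <- i >= 0 & i <= dims[1] - 1 & j >= 0 & j <= dims[2] - 1 &
      k >= 0 & k <= dims[3] - 1
    lin <- integer(nrow(P))
    lin[inside] <- (i[inside] + 1) + dims[1] * j[inside] +
      dims[1] * dims[2] * k[inside]
    lin
  }
  propagate <- function(P0, D0, alive0) {
    B <- nrow(P0)
    traj <- array(NA_real_, c(B, 3, max_steps + 1L))
    traj[, , 1] <- P0
    n <- as.integer(alive0)
    pos <- P0
    dir <- D0
    alive <- alive0
    for (s in seq_len(max_steps)) {
      if (!any(alive)) break
      newpos <- pos + step_mm * dir
      lin <- vox_of(newpos)
      ok <- alive & lin > 0
      ok[ok] <- track_ok[lin[ok]]
      if (any(ok)) {
        li <- lin[ok]
        nd <- cbind(e1x[li], e1y[li], e1z[li])
        dp <- rowSums(nd * dir[ok, , drop = FALSE])
        flip <- dp < 0
        nd[flip, ] <- -nd[flip, ]
        dp <- abs(dp)
        turn_ok <- dp >= cos_thr
        ok[ok] <- turn_ok
        if (any(turn_ok)) {
          idx_ok <- which(ok)
          traj[cbind(rep(idx_ok, 3), rep(1:3, each = length(idx_ok)),
                     n[idx_ok] + 1L)] <- newpos[idx_ok, ]
          n[idx_ok] <- n[idx_ok] + 1L
          pos[idx_ok, ] <- newpos[idx_ok, ]
          dir[idx_ok, ] <- nd[turn_ok, , drop = FALSE]
        }
      }
      alive <- ok
    }
    list(traj = traj, n = n)
  }
  batch_size <- 65536L
  pieces <- list()
  counts <- list()
  retained <- 0
  attempted <- 0
  with_private_seed(as.integer(seed), {
    while (retained < fiber_cap && attempted < 10 * fiber_cap) {
      B <- batch_size
      vi <- mask_idx[sample.int(length(mask_idx), B, replace = TRUE)]
      jit <- matrix(runif(3 * B, -0.5, 0.5), B, 3)
      ai <- arrayInd(vi, dims)
      P0 <- sweep(ai - 1 + jit, 2, vs, `*`)
      D0 <- cbind(e1x[vi], e1y[vi], e1z[vi])
      valid <- track_ok[vi] & rowSums(D0^2) > 0.5
      fwd <- propagate(P0, D0, valid)
      bwd <- propagate(P0, -D0, valid)
      npts <- fwd$n + bwd$n - 1L
      len <- (npts - 1L) * step_mm
      keep <- valid & len >= min_len_mm & len <= max_len_mm
      attempted <- attempted + B
      if (any(keep)) {
        ki <- which(keep)
        nb <- bwd$n[ki] - 1L          # backward points excluding the seed
        nf <- fwd$n[ki]
        ct <- nb + nf
        off <- cumsum(ct) - ct
        out <- matrix(0, sum(ct), 3)
        if (any(nb > 0)) {
          src_f <- rep(ki, nb)
          src_s <- sequence(nb, from = nb + 1L, by = -1L)
          dst <- sequence(nb, from = off + 1L)
          for (comp in 1:3) {
            out[dst, comp] <- bwd$traj[cbind(src_f, comp, src_s)]
          }
        }
        src_f <- rep(ki, nf)
        src_s <- sequence(nf, from = 1L, by = 1L)
        dst <- sequence(nf, from = off + nb + 1L)
        for (comp in 1:3) {
          out[dst, comp] <- fwd$traj[cbind(src_f, comp, src_s)]
        }
        pieces[[length(pieces) + 1L]] <- out
        counts[[length(counts) + 1L]] <- ct
        retained <- retained + length(ki)
      }
    }
  })
  if (retained == 0) {
    stop("no streamlines retained after ", attempted,
         " seed attempts; check mask, FA threshold and length window")
  }
  n_points <- unlist(counts, use.names = FALSE)
  points <- do.call(rbind, pieces)
  if (retained > fiber_cap) {
    n_points <- n_points[seq_len(fiber_cap)]
    points <- points[seq_len(sum(n_points)), , drop = FALSE]
  }
  offsets <- cumsum(n_points) - n_points
  structure(
    list(points = points, n_points = n_points, offsets = offsets,
         step_mm = step_mm, seed = as.integer(seed), n_attempted = attempted,
         params = list(angle_deg = angle_deg, min_len_mm = min_len_mm,
                       max_len_mm = max_len_mm, fiber_cap = fiber_cap,
                       fa_stop = fa_stop),
         voxel_size = vs, dims = dims),
    class = "streamline_set"
  )
}

#' @export
print.streamline_set <- function(x, ...) {
  len <- (x$n_points - 1) * x$step_mm
  cat("<streamline_set> ", length(x$n_points), " fibers (",
      x$n_attempted, " seeds attempted)\n", sep = "")
  cat("  length: median ", signif(median(len), 4), " mm, range [",
      signif(min(len), 4), ", ", signif(max(len), 4), "] mm, step ",
      x$step_mm, " mm\n", sep = "")
  invisible(x)
}

#' Extract one streamline's points
#' @param x a `streamline_set`.
#' @param i fiber index.
#' @return n x 3 matrix of world coordinates (mm).
#' @export
get_streamline <- function(x, i) {
  stopifnot(inherits(x, "streamline_set"))
  x$points[x$offsets[i] + seq_len(x$n_points[i]), , drop = FALSE]
}

#' Streamline lengths in mm
#' @param x a `streamline_set`.
#' @return Numeric vector of fiber arc lengths.
#' @export
streamline_lengths <- function(x) (x$n_points - 1) * x$step_mm

#' Structural connectivity matrix from streamlines
#'
#' For every streamline, the set of distinct atlas regions its points
#' traverse is computed; each unordered pair of regions in that set
#' increments the corresponding (symmetric) matrix entries by one
#' (`count = "pass"`), and a fiber confined to a single region increments
#' that region's diagonal entry. `count = "end"` uses only the two
#' endpoints. Fibers touching no labelled voxel are counted toward
#' background and excluded.
#'
#' @param fibers a `streamline_set`.
#' @param lab label `mri_volume` in the same space.
#' @param count `"pass"` (default) or `"end"`.
#' @return A `connectivity_matrix` (entries: fiber counts; attribute
#'   `n_background` = fibers entirely outside the labelled field).
#' @export
structural_connectivity <- function(fibers, lab, count = c("pass", "end")) {
  count <- match.arg(count)
  stopifnot(inherits(fibers, "streamline_set"), inherits(lab, "mri_volume"))
  vs <- lab$voxel_size
  dims <- dim(lab$data)
  nf <- length(fibers$n_points)
  if (count == "end") {
    first <- fibers$offsets + 1L
    last <- fibers$offsets + fibers$n_points
    pts <- fibers$points[c(first, last), , drop = FALSE]
    fid <- rep(seq_len(nf), 2)
  } else {
    pts <- fibers$points
    fid <- rep(seq_len(nf), fibers$n_points)
  }
  i <- round(pts[, 1] / vs[1]); j <- round(pts[, 2] / vs[2]); k <- round(pts[, 3] / vs[3])
  inside <- i >= 0 & i <= dims[1] - 1 & j >= 0 & j <= dims[2] - 1 &
    k >= 0 & k <= dims[3] - 1
  lv <- integer(length(fid))
  lv[inside] <- lab$data[cbind(i[inside] + 1, j[inside] + 1, k[inside] + 1)]
  keep <- lv != 0
  fid <- fid[keep]
  lv <- lv[keep]
  ids <- sort(unique(as.vector(lab$data)))
  ids <- ids[ids != 0]
  nr <- length(ids)
  M <- matrix(0, nr, nr, dimnames = list(ids, ids))
  touched <- logical(nf)
  if (length(fid)) {
    key <- !duplicated(paste(fid, lv))
    fid <- fid[key]
    lv <- lv[key]
    touched[unique(fid)] <- TRUE
    per <- split(match(lv, ids), fid)
    for (labs in per) {
      if (length(labs) == 1L) {
        M[labs, labs] <- M[labs, labs] + 1
      } else {
        prs <- utils::combn(sort(labs), 2)
        for (c_ in seq_len(ncol(prs))) {
          a <- prs[1, c_]; b <- prs[2, c_]
          M[a, b] <- M[a, b] + 1
          M[b, a] <- M[b, a] + 1
        }
      }
    }
  }
  structure(M, class = c("connectivity_matrix", "matrix"),
            kind = "structural", n_background = sum(!touched))
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  kind <- attr(x, "kind")
  cat("<connectivity_matrix> ", kind, ", ", nrow(x), " regions\n", sep = "")
  print(unclass(x)[seq_len(min(8, nrow(x))), seq_len(min(8, ncol(x))), drop = FALSE])
  if (nrow(x) > 8) cat("  ... (", nrow(x), " x ", ncol(x), " total)\n", sep = "")
  invisible(x)
}

#' Write a connectivity matrix to CSV
#'
#' CSV with label ids as header row and first column.
#' @param x a `connectivity_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_connectivity_csv <- function(x, path) {
  df <- data.frame(label_id = rownames(x), unclass(x), check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---- TrackVis .trk output ----------------------------------------------

#' Write streamlines in TrackVis .trk format
#'
#' Minimal TrackVis writer (version 2 header, no scalars/properties,
#' coordinates in voxel-mm as produced by the tracker).
#'
#' @param x a `streamline_set`.
#' @param path output `.trk` file.
#' @return `path`, invisibly.
#' @export
write_trk <- function(x, path) {
  stopifnot(inherits(x, "streamline_set"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("TRACK", con, nchars = 5, eos = NULL)
  writeBin(raw(1), con)
  writeBin(as.integer(x$dims), con, size = 2)
  writeBin(as.numeric(x$voxel_size), con, size = 4)
  writeBin(numeric(3), con, size = 4)                  # origin
  writeBin(0L, con, size = 2)                          # n_scalars
  writeBin(raw(200), con)                              # scalar names
  writeBin(0L, con, size = 2)                          # n_properties
  writeBin(raw(200), con)                              # property names
  vox2ras <- diag(c(x$voxel_size, 1))
  writeBin(as.numeric(t(vox2ras)), con, size = 4)
  writeBin(raw(444), con)                              # reserved
  writeChar("RAS", con, nchars = 3, eos = NULL)
  writeBin(raw(5), con)                                # pad
  writeBin(c(1, 0, 0, 0, 1, 0), con, size = 4)         # orientation patient
  writeBin(raw(8), con)                                # pad1 + invert flags
  writeBin(length(x$n_points), con, size = 4)
  writeBin(2L, con, size = 4)
  writeBin(1000L, con, size = 4)
  for (i in seq_along(x$n_points)) {
    p <- get_streamline(x, i)
    writeBin(nrow(p), con, size = 4)
    writeBin(as.numeric(t(p)), con, size = 4)
  }
  invisible(path)
}

#' Read a TrackVis .trk file written by [write_trk()]
#' @param path `.trk` file.
#' @return A list with `points`, `n_points`, `offsets`, `dims`,
#'   `voxel_size`.
#' @export
read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, raw(), 6)
  dims <- readBin(con, integer(), 3, size = 2)
  vs <- readBin(con, numeric(), 3, size = 4)
  seek(con, 1000 - 12)
  n_count <- readBin(con, integer(), 1, size = 4)
  seek(con, 1000)
  pts <- list()
  np <- integer(n_count)
  for (i in seq_len(n_count)) {
    np[i] <- readBin(con, integer(), 1, size = 4)
    pts[[i]] <- matrix(readBin(con, numeric(), 3 * np[i], size = 4),
                       ncol = 3, byrow = TRUE)
  }
  list(points = do.call(rbind, pts), n_points = np,
       offsets = cumsum(np) - np, dims = dims, voxel_size = vs)
}
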