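#' MRI volume container
#'
#' Light-weight container for a 3D (or 3D+time) scalar image together with
#' the geometric metadata the pipeline needs: per-axis voxel spacing in mm,
#' a three-letter anatomical orientation code and, for 4D series, the
#' temporal spacing in seconds. World coordinates are defined as
#' `(0-based voxel index) * voxel_size` in RAS after re-orientation.
#'
#' @param data numeric array, 3D or 4D (4th axis = time).
#' @param voxel_size numeric vector of 3 strictly positive spacings (mm).
#' @param orientation three-letter axis code (one of R/L, A/P, S/I per
#'   axis, each anatomical axis used once), e.g. `"RAS"`, `"LAS"`.
#' @param t_step temporal spacing in seconds; required for 4D data,
#'   must be `NULL` for 3D data.
#' @param modality one of `"t2"`, `"t2map"`, `"dwi"`, `"bold"`, `"label"`,
#'   `"mask"`.
#' @return An object of class `mri_volume`.
#' @export
mri_volume <- function(data, voxel_size, orientation = "RAS", t_step = NULL,
                       modality = c("t2", "t2map", "dwi", "bold", "label", "mask")) {
  modality <- match.arg(modality)
  data <- as.array(data)
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L)) {
    stop("'data' must be a 3D or 4D array, got ", nd, " dimensions")
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    stop("'voxel_size' must be 3 strictly positive spacings in mm")
  }
  parse_orientation(orientation)  # validates
  if (nd == 4L) {
    if (is.null(t_step)) stop("4D data requires 't_step' (seconds)")
    t_step <- as.numeric(t_step)
    if (length(t_step) != 1L || !is.finite(t_step) || t_step <= 0) {
      stop("'t_step' must be one positive number (seconds)")
    }
  } else if (!is.null(t_step)) {
    stop("'t_step' given for 3D data")
  }
  structure(
    list(data = data, voxel_size = voxel_size, orientation = toupper(orientation),
         t_step = t_step, modality = modality),
    class = "mri_volume"
  )
}

#' @export
print.mri_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("<mri_volume> ", x$modality, "  ", paste(d, collapse = " x "), "\n", sep = "")
  cat("  voxel size : ", paste(signif(x$voxel_size, 4), collapse = " x "), " mm",
      if (!is.null(x$t_step)) paste0("   TR ", signif(x$t_step, 4), " s"), "\n", sep = "")
  cat("  orientation: ", x$orientation, "\n", sep = "")
  rng <- range(x$data)
  cat("  intensity  : [", signif(rng[1], 5), ", ", signif(rng[2], 5), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.mri_volume <- function(x) dim(x$data)

is_4d <- function(vol) length(dim(vol$data)) == 4L

as_volume_like <- function(data, template, modality = template$modality,
                           t_step = template$t_step) {
  if (length(dim(as.array(data))) == 3L) t_step <- NULL
  mri_volume(data, template$voxel_size, template$orientation,
             t_step = t_step, modality = modality)
}

# ---- orientation handling ----------------------------------------------

# Letter semantics: letter i gives the anatomical direction toward which the
# i-th storage axis *increases*. Target is RAS ("neurological"): +x right,
# +y anterior, +z superior.
.axis_pairs <- c(R = "L", L = "R", A = "P", P = "A", S = "I", I = "S")
.axis_group <- c(R = 1L, L = 1L, A = 2L, P = 2L, S = 3L, I = 3L)

parse_orientation <- function(code) {
  if (!is.character(code) || length(code) != 1L || nchar(code) != 3L) {
    stop("orientation code must be a single 3-letter string, got: ",
         deparse(code))
  }
  letters3 <- strsplit(toupper(code), "")[[1]]
  if (!all(letters3 %in% names(.axis_pairs))) {
    stop("invalid orientation code '", code, "': letters must be from R/L, A/P, S/I")
  }
  grp <- .axis_group[letters3]
  if (anyDuplicated(grp)) {
    stop("ambiguous orientation code '", code,
         "': each anatomical axis (R/L, A/P, S/I) must appear exactly once")
  }
  letters3
}

#' Re-orient a volume to the RAS convention
#'
#' Rearranges the storage axes of a volume so that the first axis increases
#' to the subject's right, the second to anterior and the third to superior
#' (the right-handed "neurological" RAS convention). The operation is a pure
#' index permutation/flip: no interpolation, the multiset of voxel values is
#' preserved exactly. For 4D series the time axis is untouched.
#'
#' @param vol an [mri_volume()].
#' @param source_code three-letter code describing the stored layout; letter
#'   i names the anatomical direction toward which storage axis i increases
#'   (e.g. `"LAS"`: axis 1 increases to the subject's left).
#' @return The re-oriented `mri_volume` with `orientation = "RAS"` and
#'   consistently permuted `voxel_size`.
#' @export
reorient_to_ras <- function(vol, source_code = vol$orientation) {
  stopifnot(inherits(vol, "mri_volume"))
  letters3 <- parse_orientation(source_code)
  target <- c("R", "A", "S")
  grp <- .axis_group[letters3]
  perm <- match(1:3, grp)             # source axis feeding target axis 1..3
  flip <- letters3[perm] != target    # source axis points the opposite way
  a <- vol$data
  nd <- length(dim(a))
  ax_perm <- if (nd == 4L) c(perm, 4L) else perm
  a <- aperm(a, ax_perm)
  for (i in which(flip)) {
    idx <- rep(list(quote(expr = )), nd)
    idx[[i]] <- dim(a)[i]:1
    a <- do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  }
  mri_volume(a, vol$voxel_size[perm], "RAS", t_step = vol$t_step,
             modality = vol$modality)
}

#' Scale the voxel-size header of a volume
#'
#' Multiplies the header voxel spacing by a constant while leaving the data
#' array bit-identical. Mouse voxels are roughly an order of magnitude
#' smaller than human ones; scaling the header by 10 makes mouse data
#' digestible by tools calibrated for human geometry, without interpolating
#' the image. The temporal spacing is untouched.
#'
#' @param vol an [mri_volume()].
#' @param factor strictly positive scalar.
#' @return The volume with `voxel_size * factor`.
#' @export
scale_voxel_header <- function(vol, factor) {
  stopifnot(inherits(vol, "mri_volume"))
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) || factor <= 0) {
    stop("'factor' must be one strictly positive number")
  }
  vol$voxel_size <- vol$voxel_size * factor
  vol
}

#' Collapse a 4D series to a registration-ready 3D volume
#'
#' Takes the per-voxel minimum over time, then smooths the resulting 3D
#' volume with a Gaussian kernel. The minimum over frames suppresses
#' spike artefacts and the smoothing suppresses noise while preserving the
#' structures needed for registration of diffusion/BOLD series to anatomy.
#'
#' @param vol4d a 4D [mri_volume()].
#' @param gauss_sigma Gaussian sigma in mm (converted to voxels per axis);
#'   default 0.45 mm, about half an EPI voxel. `0` disables smoothing.
#' @return A 3D `mri_volume`.
#' @export
collapse_4d <- function(vol4d, gauss_sigma = 0.45) {
  stopifnot(inherits(vol4d, "mri_volume"))
  if (!is_4d(vol4d)) stop("collapse_4d() requires a 4D volume")
  d <- dim(vol4d$data)
  m <- array(apply(vol4d$data, 1:3, min), dim = d[1:3])
  if (gauss_sigma > 0) {
    m <- gauss_smooth(m, gauss_sigma / vol4d$voxel_size)
  }
  mri_volume(m, vol4d$voxel_size, vol4d$orientation, modality = "t2")
}

# ---- NIfTI I/O ----------------------------------------------------------

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 file into an [mri_volume()]. Voxel sizes and the
#' temporal spacing are taken from the header; the stored orientation code
#' is derived from the header xform when available, otherwise assumed RAS.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param modality modality tag for the result, see [mri_volume()].
#' @return An `mri_volume`.
#' @export
read_nifti_volume <- function(path, modality = "t2") {
  img <- RNifti::readNifti(path)
  pix <- attr(img, "pixdim")
  units <- attr(img, "pixunits")
  d <- dim(img)
  orient <- tryCatch(RNifti::orientation(img), error = function(e) "RAS")
  # RNifti codes orientation by the closest anatomical axes of the xform.
  if (!is.character(orient) || nchar(orient) != 3L) orient <- "RAS"
  t_step <- NULL
  if (length(d) == 4L) {
    t_step <- if (length(pix) >= 4 && pix[4] > 0) pix[4] else 1
    if (!is.null(units) && any(units == "ms")) t_step <- t_step / 1000
  }
  dat <- array(as.numeric(img), dim = d)
  mri_volume(dat, pix[1:3], orient, t_step = t_step, modality = modality)
}

#' Write a volume to NIfTI
#'
#' Masks are stored as unsigned 8-bit, labels as unsigned 32-bit integers,
#' all other modalities as 32-bit float. Voxel sizes and TR go into the
#' header; the image is written with an RAS-aligned xform.
#'
#' @param vol an [mri_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(vol, path) {
  stopifnot(inherits(vol, "mri_volume"))
  datatype <- switch(vol$modality, mask = "uint8", label = "uint32", "float")
  a <- vol$data
  attr(a, "pixdim") <- c(vol$voxel_size, if (!is.null(vol$t_step)) vol$t_step)
  attr(a, "pixunits") <- c("mm", "s")
  img <- RNifti::asNifti(a, datatype = datatype)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
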