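# Spatial transforms under the resampling (pull-back) convention: every
# transform maps *target-grid* world coordinates (mm, RAS, world = 0-based
# index * voxel size) to *source* world coordinates, so applying a
# transform means sampling the source image at the mapped points. Chains
# are ordered lists of transforms applied first-to-last to the points.

#' Affine world-coordinate transform
#'
#' @param matrix 4x4 homogeneous matrix mapping target world coordinates
#'   (mm) to source world coordinates; last row must be (0,0,0,1).
#' @param dof degrees of freedom used to build it (6 rigid or 12 full).
#' @param session provenance tag (imaging session the transform belongs to).
#' @return An `affine_transform`.
#' @export
affine_transform <- function(matrix = diag(4), dof = 12L, session = "default") {
  matrix <- as.matrix(matrix)
  stopifnot(identical(dim(matrix), c(4L, 4L)))
  if (!isTRUE(all.equal(matrix[4, ], c(0, 0, 0, 1)))) {
    stop("last row of an affine matrix must be (0, 0, 0, 1)")
  }
  if (abs(det(matrix[1:3, 1:3])) <= 1e-12) stop("affine matrix is singular")
  structure(list(matrix = matrix, dof = as.integer(dof), session = session),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform> dof ", x$dof, ", session '", x$session, "'\n", sep = "")
  print(signif(x$matrix, 5))
  invisible(x)
}

# Build a 4x4 matrix from parameters about `center` (mm):
# p = (tx, ty, tz [mm], rx, ry, rz [deg] [, log-scales sx sy sz,
#      shears hxy hxz hyz]).
affine_params_to_matrix <- function(p, center = c(0, 0, 0)) {
  t3 <- p[1:3]
  ang <- p[4:6] * pi / 180
  cx <- cos(ang[1]); sx <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  A <- Rz %*% Ry %*% Rx
  if (length(p) >= 12) {
    S <- diag(exp(p[7:9]))
    H <- diag(3)
    H[1, 2] <- p[10]; H[1, 3] <- p[11]; H[2, 3] <- p[12]
    A <- A %*% S %*% H
  }
  M <- diag(4)
  M[1:3, 1:3] <- A
  M[1:3, 4] <- t3 + center - A %*% center
  M
}

#' Invert an affine transform
#' @param x an `affine_transform`.
#' @return The inverse `affine_transform`.
#' @export
invert_affine <- function(x) {
  stopifnot(inherits(x, "affine_transform"))
  affine_transform(solve(x$matrix), dof = x$dof, session = x$session)
}

#' Compose two affine transforms
#'
#' Returns the affine equivalent to applying `a` then `b` to a point
#' (i.e. matrix product `b$matrix %*% a$matrix`).
#' @param a,b `affine_transform`s.
#' @return An `affine_transform`.
#' @export
compose_affine <- function(a, b) {
  affine_transform(b$matrix %*% a$matrix, dof = max(a$dof, b$dof), session = a$session)
}

# ---- B-spline free-form deformation ------------------------------------

# Control point j (1-based) of axis a sits at world (j - 2) * spacing[a];
# a domain [0, L] therefore needs floor(L/spacing) + 4 control points
# (one-cell margin each side). The dense displacement at x is
#   u(x) = sum_j B(x/spacing - (j - 2)) * C[j]
# with B the cubic B-spline (support (-2, 2), partition of unity).

bspline_weights_1d <- function(g) {
  # g = x / spacing; returns list(j0 = floor(g), w = length(g) x 4 weights
  # for control indices j0 + 1 .. j0 + 4)
  j0 <- floor(g)
  u <- g - j0
  w <- cbind((1 - u)^3 / 6,
             (3 * u^3 - 6 * u^2 + 4) / 6,
             (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6,
             u^3 / 6)
  list(j0 = as.integer(j0), w = w)
}

#' B-spline displacement field
#'
#' Free-form deformation parameterized by a regular grid of control-point
#' displacements (mm). The transform maps a point x to `x + u(x)` where u
#' is the cubic B-spline interpolation of the control displacements.
#'
#' @param control numeric array `(nx, ny, nz, 3)` of control displacements
#'   in mm.
#' @param spacing control-grid spacing in mm (scalar or length 3).
#' @param session provenance tag.
#' @return A `bspline_field`.
#' @export
bspline_field <- function(control, spacing, session = "default") {
  stopifnot(length(dim(control)) == 4L, dim(control)[4] == 3L)
  spacing <- rep(as.numeric(spacing), length.out = 3)
  stopifnot(all(spacing > 0))
  structure(list(control = control, spacing = spacing, session = session),
            class = "bspline_field")
}

#' @export
print.bspline_field <- function(x, ...) {
  d <- dim(x$control)
  u <- sqrt(apply(x$control^2, 1:3, sum))
  cat("<bspline_field> control grid ", paste(d[1:3], collapse = " x "),
      ", spacing ", paste(signif(x$spacing, 4), collapse = "/"), " mm\n", sep = "")
  cat("  |u|: mean ", signif(mean(u), 4), " mm, max ", signif(max(u), 4), " mm\n", sep = "")
  invisible(x)
}

n_control_points <- function(extent_mm, spacing) as.integer(floor(extent_mm / spacing) + 4)

# Dense displacement over a full voxel grid; returns list(ux, uy, uz) arrays.
bspline_dense_field <- function(field, dims, voxel_size) {
  C <- field$control
  sp <- field$spacing
  wx <- bspline_weights_1d((seq_len(dims[1]) - 1) * voxel_size[1] / sp[1])
  wy <- bspline_weights_1d((seq_len(dims[2]) - 1) * voxel_size[2] / sp[2])
  wz <- bspline_weights_1d((seq_len(dims[3]) - 1) * voxel_size[3] / sp[3])
  out <- vector("list", 3)
  for (comp in 1:3) {
    acc <- array(0, dims)
    for (l1 in 1:4) for (l2 in 1:4) for (l3 in 1:4) {
      W <- outer(outer(wx$w[, l1], wy$w[, l2]), wz$w[, l3])
      acc <- acc + W * C[wx$j0 + l1, wy$j0 + l2, wz$j0 + l3, comp]
    }
    out[[comp]] <- acc
  }
  names(out) <- c("ux", "uy", "uz")
  out
}

# Displacement at arbitrary world points (n x 3, mm).
bspline_displacement_at <- function(field, pts) {
  C <- field$control
  dC <- dim(C)
  sp <- field$spacing
  wx <- bspline_weights_1d(pts[, 1] / sp[1])
  wy <- bspline_weights_1d(pts[, 2] / sp[2])
  wz <- bspline_weights_1d(pts[, 3] / sp[3])
  clamp <- function(j, n) pmin(pmax(j, 1L), n)
  u <- matrix(0, nrow(pts), 3)
  for (l1 in 1:4) for (l2 in 1:4) for (l3 in 1:4) {
    W <- wx$w[, l1] * wy$w[, l2] * wz$w[, l3]
    i1 <- clamp(wx$j0 + l1, dC[1])
    i2 <- clamp(wy$j0 + l2, dC[2])
    i3 <- clamp(wz$j0 + l3, dC[3])
    for (comp in 1:3) {
      u[, comp] <- u[, comp] + W * C[cbind(i1, i2, i3, comp)]
    }
  }
  u
}

# Voxelwise Jacobian determinant of x + u(x) from central differences of
# the dense field (interior voxels; edges replicated).
jacobian_determinant_dense <- function(dense, voxel_size) {
  grad <- function(a, axis) {
    d <- dim(a)
    g <- array(0, d)
    n <- d[axis]
    idx_hi <- idx_lo <- rep(list(quote(expr = )), 3)
    idx_hi[[axis]] <- c(2:n, n)
    idx_lo[[axis]] <- c(1, 1:(n - 1))
    hi <- do.call(`[`, c(list(a), idx_hi, list(drop = FALSE)))
    lo <- do.call(`[`, c(list(a), idx_lo, list(drop = FALSE)))
    den <- array(2 * voxel_size[axis], d)
    edge <- rep(list(quote(expr = )), 3)
    edge[[axis]] <- c(1, n)
    den <- do.call(`[<-`, c(list(den), edge, list(value = voxel_size[axis])))
    (hi - lo) / den
  }
  u11 <- grad(dense$ux, 1); u12 <- grad(dense$ux, 2); u13 <- grad(dense$ux, 3)
  u21 <- grad(dense$uy, 1); u22 <- grad(dense$uy, 2); u23 <- grad(dense$uy, 3)
  u31 <- grad(dense$uz, 1); u32 <- grad(dense$uz, 2); u33 <- grad(dense$uz, 3)
  a11 <- 1 + u11; a22 <- 1 + u22; a33 <- 1 + u33
  a11 * (a22 * a33 - u23 * u32) - u12 * (u21 * a33 - u23 * u31) +
    u13 * (u21 * u32 - a22 * u31)
}

# ---- chains -------------------------------------------------------------

#' Ordered transform chain
#'
#' A chain is an ordered list of transforms applied first-to-last to
#' target-grid points; applying a chain to a volume samples that volume at
#' the fully mapped points. All members must carry the same session tag.
#'
#' @param transforms list of `affine_transform` / `bspline_field` objects.
#' @return A `transform_chain`.
#' @export
transform_chain <- function(transforms) {
  stopifnot(length(transforms) >= 1)
  ok <- vapply(transforms, function(t)
    inherits(t, "affine_transform") || inherits(t, "bspline_field"), logical(1))
  if (!all(ok)) stop("chain members must be affine_transform or bspline_field")
  sessions <- unique(vapply(transforms, `[[`, character(1), "session"))
  if (length(sessions) > 1) {
    stop("provenance mismatch: chain mixes transforms from sessions ",
         paste(sessions, collapse = ", "))
  }
  structure(list(transforms = transforms, session = sessions),
            class = "transform_chain")
}

#' @export
print.transform_chain <- function(x, ...) {
  cat("<transform_chain> session '", x$session, "', ",
      length(x$transforms), " transform(s): ",
      paste(vapply(x$transforms, function(t) class(t)[1], character(1)),
            collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' Map points through a transform
#'
#' @param transform an `affine_transform`, `bspline_field` or
#'   `transform_chain`.
#' @param pts n x 3 matrix of world coordinates (mm).
#' @return The mapped n x 3 matrix.
#' @export
transform_points <- function(transform, pts) {
  if (inherits(transform, "affine_transform")) {
    M <- transform$matrix
    sweep(pts %*% t(M[1:3, 1:3]), 2, M[1:3, 4], `+`)
  } else if (inherits(transform, "bspline_field")) {
    pts + bspline_displacement_at(transform, pts)
  } else if (inherits(transform, "transform_chain")) {
    for (tf in transform$transforms) pts <- transform_points(tf, pts)
    pts
  } else {
    stop("unknown transform type")
  }
}

#' Build the per-session transform chain for a modality
#'
#' The non-linear deformation between template and anatomy is estimated
#' once per imaging session on the T2 scan; every other modality of the
#' session reuses it, linked with that modality's affine to the T2 space.
#' Under the resampling convention the chain maps a modality-grid point
#' first through `modality_affine` (modality -> T2 space), then through the
#' session's non-linear field and T2 affine (T2 -> template/atlas space).
#'
#' @param t2_affine affine of the T2 registration (T2 -> template).
#' @param t2_nonlinear `bspline_field` of the T2 registration.
#' @param modality_affine affine mapping the modality grid to T2 space;
#'   identity for the T2 chain itself.
#' @return A `transform_chain` mapping modality space to template space.
#' @export
build_session_chain <- function(t2_affine, t2_nonlinear,
                                modality_affine = affine_transform(session = t2_affine$session)) {
  transform_chain(list(modality_affine, t2_nonlinear, t2_affine))
}

#' Resample a volume through a transform chain
#'
#' Samples `vol` at the chain-mapped coordinates of every voxel of the
#' target grid. Label and mask volumes are always resampled with
#' nearest-neighbour interpolation (the label set can shrink but never
#' grow); requesting linear interpolation for them is an error.
#'
#' @param chain a `transform_chain` (or single transform).
#' @param vol the source [mri_volume()] to resample.
#' @param target an `mri_volume` defining the output grid (its data values
#'   are ignored).
#' @param interpolation `"linear"` or `"nearest"`.
#' @return The resampled `mri_volume` on the target grid.
#' @export
apply_chain <- function(chain, vol, target,
                        interpolation = c("linear", "nearest")) {
  user_specified <- !missing(interpolation)
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(vol, "mri_volume"), inherits(target, "mri_volume"))
  is_label <- vol$modality %in% c("label", "mask")
  if (is_label) {
    if (user_specified && interpolation == "linear") {
      stop("label/mask volumes must be resampled with nearest-neighbour ",
           "interpolation")
    }
    interpolation <- "nearest"
  }
  d <- dim(target$data)[1:3]
  pts <- sweep(voxel_index_grid(d), 2, target$voxel_size, `*`)
  pts <- transform_points(chain, pts)
  idx <- sweep(pts, 2, vol$voxel_size, `/`)
  v <- if (interpolation == "nearest") sample_nearest(vol$data, idx)
       else sample_trilinear(vol$data, idx)
  out <- mri_volume(array(v, d), target$voxel_size, target$orientation,
                    modality = vol$modality)
  attr(out, "hemisphere_offset") <- attr(vol, "hemisphere_offset")
  out
}

# ---- serialization ------------------------------------------------------

transform_to_list <- function(t) {
  if (inherits(t, "affine_transform")) {
    list(type = "affine", dof = t$dof, session = t$session,
         matrix = as.vector(t(t$matrix)))           # 16 floats, row-major
  } else {
    list(type = "bspline", session = t$session, spacing = t$spacing,
         grid = dim(t$control)[1:3], displacements = as.vector(t$control))
  }
}

transform_from_list <- function(l) {
  if (l$type == "affine") {
    affine_transform(matrix(unlist(l$matrix), 4, 4, byrow = TRUE),
                     dof = l$dof, session = l$session)
  } else {
    g <- unlist(l$grid)
    bspline_field(array(unlist(l$displacements), c(g, 3)),
                  spacing = unlist(l$spacing), session = l$session)
  }
}

#' Save / load transforms and chains as JSON
#'
#' Affine matrices are stored as 16 row-major floats; B-spline fields as
#' grid metadata plus the displacement array; chains as ordered manifests.
#'
#' @param x an `affine_transform`, `bspline_field` or `transform_chain`.
#' @param path JSON file path.
#' @return `path` (save) or the reconstructed object (load).
#' @export
save_transform <- function(x, path) {
  obj <- if (inherits(x, "transform_chain")) {
    list(type = "chain", session = x$session,
         transforms = lapply(x$transforms, transform_to_list))
  } else {
    transform_to_list(x)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_transform
#' @export
load_transform <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (identical(l$type, "chain")) {
    transform_chain(lapply(l$transforms, transform_from_list))
  } else {
    transform_from_list(l)
  }
}
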