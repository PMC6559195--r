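# Multiplicative intrinsic component optimization (MICO): joint fuzzy
# tissue classification and smooth multiplicative bias-field estimation by
# alternating closed-form minimization of
#   E = sum_x sum_k u_k(x) * (I(x) - b(x) * c_k)^2
# over memberships u, class centroids c and the polynomial coefficients of
# the bias field b. Each update is an exact minimizer given the others, so
# the energy is non-increasing across iterations.

# Polynomial basis of total order <= p over mask coordinates scaled to
# [-1, 1]; first column is the constant 1.
poly_basis <- function(idx_vox, voxel_size, order) {
  pos <- sweep(idx_vox, 2, voxel_size, `*`)
  rng <- apply(pos, 2, range)
  span <- pmax(rng[2, ] - rng[1, ], 1e-9)
  u <- sweep(sweep(pos, 2, rng[1, ], `-`), 2, span / 2, `/`) - 1
  cols <- list()
  for (a in 0:order) for (b in 0:(order - a)) for (c in 0:(order - a - b)) {
    cols[[length(cols) + 1L]] <- u[, 1]^a * u[, 2]^b * u[, 3]^c
  }
  do.call(cbind, cols)
}

#' Fit a MICO bias-field model
#'
#' Estimates a smooth multiplicative bias field and per-class centroids for
#' a masked intensity volume by alternating minimization of the MICO
#' energy. With the hard-membership variant (`fuzzifier = 1`, the default)
#' every update is closed form: memberships assign each voxel to the class
#' with the smallest residual, centroids are bias-weighted least-squares
#' means, and bias coefficients solve a weighted normal system over a
#' polynomial basis. The fitted field is gauge-fixed to mean 1 inside the
#' mask (the energy is invariant to rescaling bias by s and centroids by
#' 1/s).
#'
#' @param vol a 3D [mri_volume()].
#' @param mask binary `mri_volume` of the region to model (e.g. the brain).
#' @param n_classes number of tissue classes (>= 2); default 3 (GM/WM/CSF).
#' @param basis_order total polynomial order of the bias basis; default 3
#'   (20 basis functions).
#' @param max_iter maximum alternating iterations.
#' @param tol relative energy-change convergence threshold.
#' @param fuzzifier membership exponent; 1 (hard, closed form) or 2 (fuzzy).
#' @return A `bias_model`: list with `centroids`, `basis_coeffs`, the
#'   reconstructed `bias` volume (1 outside the mask), hard `classes`
#'   (integer volume), fuzzy `memberships` (voxels x classes, masked),
#'   `energy` trace and `converged` flag.
#' @export
mico_fit <- function(vol, mask, n_classes = 3L, basis_order = 3L,
                     max_iter = 100L, tol = 1e-6, fuzzifier = 1) {
  stopifnot(inherits(vol, "mri_volume"), inherits(mask, "mri_volume"))
  if (n_classes < 2) stop("'n_classes' must be >= 2")
  if (!fuzzifier %in% c(1, 2)) stop("'fuzzifier' must be 1 or 2")
  m <- mask$data != 0
  idx <- voxel_index_grid(dim(vol$data))[as.vector(m), , drop = FALSE]
  I <- vol$data[m]
  G <- poly_basis(idx, vol$voxel_size, basis_order)
  nb <- ncol(G)
  if (length(I) < 10 * nb) {
    stop("mask too small: need at least ", 10 * nb, " voxels for a basis of ",
         nb, " functions")
  }
  # centroid init: k-means on masked intensities (private fixed seed)
  cent <- with_private_seed(1L, {
    km <- kmeans(I, centers = n_classes, nstart = 5, iter.max = 50)
    sort(as.vector(km$centers))
  })
  w <- c(1, rep(0, nb - 1))           # constant-1 bias field
  b <- as.vector(G %*% w)
  energy <- numeric(0)
  U <- NULL
  q <- fuzzifier
  for (it in seq_len(max_iter)) {
    # residuals per class
    R2 <- vapply(seq_len(n_classes), function(k) (I - b * cent[k])^2,
                 numeric(length(I)))
    if (q == 1) {
      cls <- max.col(-R2, ties.method = "first")
      U <- matrix(0, length(I), n_classes)
      U[cbind(seq_along(I), cls)] <- 1
    } else {
      inv <- 1 / pmax(R2, 1e-300)
      U <- (inv / rowSums(inv))^1  # q = 2: u_k = (1/R2_k) / sum_j (1/R2_j)
    }
    Uq <- if (q == 1) U else U^2
    # centroids
    cent <- vapply(seq_len(n_classes), function(k) {
      num <- sum(Uq[, k] * b * I)
      den <- sum(Uq[, k] * b^2)
      if (den <= 0) cent[k] else num / den
    }, numeric(1))
    # bias coefficients: weighted least squares
    chat2 <- as.vector(Uq %*% cent^2)   # sum_k u_k c_k^2
    chat1 <- as.vector(Uq %*% cent)     # sum_k u_k c_k (hard: assigned c)
    A <- crossprod(G, G * chat2)
    rhs <- crossprod(G, I * chat1)
    w_new <- tryCatch(solve(A, rhs), error = function(e) {
      stop("singular bias-basis normal equations (conditioning error): ",
           conditionMessage(e))
    })
    w <- as.vector(w_new)
    b <- as.vector(G %*% w)
    e <- sum(Uq * vapply(seq_len(n_classes),
                         function(k) (I - b * cent[k])^2, numeric(length(I))))
    energy <- c(energy, e)
    if (it > 1 && abs(energy[it - 1] - e) <= tol * abs(energy[it - 1])) break
  }
  converged <- length(energy) < max_iter
  # gauge fix: mean bias = 1 inside mask
  s <- mean(b)
  b <- b / s
  w <- w / s
  cent <- cent * s
  ord <- order(cent)
  cent <- cent[ord]
  U <- U[, ord, drop = FALSE]
  bias_arr <- array(1, dim(vol$data))
  bias_arr[m] <- b
  cls_arr <- array(0L, dim(vol$data))
  cls_arr[m] <- max.col(U, ties.method = "first")
  structure(
    list(centroids = cent, basis_coeffs = w, basis_order = basis_order,
         bias = as_volume_like(bias_arr, vol, modality = "t2map"),
         classes = as_volume_like(cls_arr, vol, modality = "label"),
         memberships = U, mask = mask, energy = energy,
         converged = converged, fuzzifier = q),
    class = "bias_model"
  )
}

#' @export
print.bias_model <- function(x, ...) {
  cat("<bias_model> MICO fit, ", length(x$centroids), " classes, ",
      length(x$energy), " iterations",
      if (!x$converged) " (max_iter reached)", "\n", sep = "")
  cat("  centroids: ", paste(signif(x$centroids, 5), collapse = ", "), "\n", sep = "")
  cat("  bias range in mask: [",
      signif(min(x$bias$data[x$mask$data != 0]), 4), ", ",
      signif(max(x$bias$data[x$mask$data != 0]), 4), "]\n", sep = "")
  cat("  final energy: ", signif(tail(x$energy, 1), 6), "\n", sep = "")
  invisible(x)
}

#' Correct a volume with a fitted bias model
#'
#' Divides intensities by the reconstructed bias field inside the model's
#' mask and leaves voxels outside untouched.
#'
#' @param vol the 3D [mri_volume()] to correct (same shape the model was
#'   fitted on).
#' @param model a `bias_model` from [mico_fit()].
#' @return The corrected `mri_volume`.
#' @export
mico_correct <- function(vol, model) {
  stopifnot(inherits(vol, "mri_volume"), inherits(model, "bias_model"))
  if (!identical(dim(vol$data), dim(model$bias$data))) {
    stop("model was fitted on a volume of different shape")
  }
  m <- model$mask$data != 0
  b <- model$bias$data[m]
  if (any(b < 1e-6)) stop("bias field below positivity floor (1e-6) inside mask")
  out <- vol$data
  out[m] <- out[m] / b
  vol$data <- out
  vol
}
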