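#' Image grid
#'
#' A light container for a regular 3D sampling grid: integer dimensions and
#' a 4x4 affine mapping 0-based voxel indices to world (mm) coordinates.
#' If no affine is given an axis-aligned grid is built from the voxel size,
#' centred on the world origin.
#'
#' @param dim Integer vector of length 3.
#' @param affine Optional 4x4 voxel-to-mm matrix.
#' @param voxel_mm Voxel size in mm (used when \code{affine} is NULL).
#' @return An object of class \code{nf_grid}.
#' @export
nf_grid <- function(dim, affine = NULL, voxel_mm = c(3, 3, 3)) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 1L))
  if (is.null(affine)) {
    voxel_mm <- rep_len(voxel_mm, 3L)
    affine <- diag(4)
    diag(affine)[1:3] <- voxel_mm
    affine[1:3, 4] <- -(dim - 1) / 2 * voxel_mm
  }
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)))
  structure(list(dim = dim, affine = affine), class = "nf_grid")
}

#' @export
print.nf_grid <- function(x, ...) {
  cat(sprintf("<nf_grid> %s voxels, voxel size %s mm\n",
              paste(x$dim, collapse = "x"),
              paste(signif(grid_voxel_size(x), 3), collapse = "x")))
  invisible(x)
}

grid_voxel_size <- function(grid) {
  sqrt(colSums(grid$affine[1:3, 1:3]^2))
}

grid_n_voxels <- function(grid) prod(grid$dim)

# 0-based voxel index array (N x 3) for every voxel, column-major order
grid_voxel_indices <- function(grid) {
  as.matrix(expand.grid(i = 0:(grid$dim[1] - 1L),
                        j = 0:(grid$dim[2] - 1L),
                        k = 0:(grid$dim[3] - 1L)))
}

# voxel (N x 3, 0-based) -> world mm (N x 3)
voxel_to_world <- function(grid, vox) {
  vox <- rbind(t(vox), 1)
  t(grid$affine %*% vox)[, 1:3, drop = FALSE]
}

world_to_voxel <- function(grid, mm) {
  mm <- rbind(t(mm), 1)
  t(solve(grid$affine) %*% mm)[, 1:3, drop = FALSE]
}

#' A-priori spherical ROI specification
#'
#' The two regions used for connectivity feedback are defined as spheres
#' in MNI space: the right anterior superior temporal lobe (ATL, 4 mm
#' radius around MNI 58, 0, -12) and the subgenual cingulate cortex
#' (SCC, 6 mm radius around MNI -4, 23, -5), each smoothed with a 6 mm
#' FWHM Gaussian before warping to native space.
#'
#' @param name ROI name.
#' @param centre_mni Sphere centre in MNI mm.
#' @param radius_mm Sphere radius in mm.
#' @param smoothing_fwhm_mm FWHM of the smoothing kernel (default 6).
#' @return An object of class \code{roi_spec}.
#' @export
roi_spec <- function(name, centre_mni, radius_mm, smoothing_fwhm_mm = 6) {
  stopifnot(length(centre_mni) == 3L, radius_mm >= 0, smoothing_fwhm_mm >= 0)
  structure(list(name = name, centre_mni = as.numeric(centre_mni),
                 radius_mm = radius_mm,
                 smoothing_fwhm_mm = smoothing_fwhm_mm),
            class = "roi_spec")
}

#' @rdname roi_spec
#' @export
atl_spec <- function() roi_spec("ATL", c(58, 0, -12), 4)

#' @rdname roi_spec
#' @export
scc_spec <- function() roi_spec("SCC", c(-4, 23, -5), 6)

new_roi_mask <- function(space, grid, weights, provenance) {
  structure(list(space = space, grid = grid,
                 weights = array(weights, dim = grid$dim),
                 provenance = provenance),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> space %s, %d/%d voxels > 0, peak %.3g\n",
              x$space, sum(x$weights > 0), grid_n_voxels(x$grid),
              max(x$weights)))
  cat("  provenance:", paste(vapply(x$provenance, `[[`, "", "step"),
                             collapse = " -> "), "\n")
  invisible(x)
}

#' Rasterise a spherical ROI onto a grid
#'
#' A voxel is included iff its centre lies within \code{radius_mm}
#' (Euclidean distance in mm) of the sphere centre. A radius-0 sphere at a
#' voxel centre therefore selects exactly that voxel.
#'
#' @param spec An \code{roi_spec}.
#' @param grid An \code{nf_grid} (assumed to be in the same space as the
#'   centre coordinate, normally MNI).
#' @param space Space label recorded on the mask.
#' @return A binary \code{roi_mask}.
#' @export
make_sphere_roi <- function(spec, grid, space = "MNI") {
  stopifnot(inherits(spec, "roi_spec"), inherits(grid, "nf_grid"))
  centres <- voxel_to_world(grid, grid_voxel_indices(grid))
  d2 <- (centres[, 1] - spec$centre_mni[1])^2 +
        (centres[, 2] - spec$centre_mni[2])^2 +
        (centres[, 3] - spec$centre_mni[3])^2
  inside <- as.numeric(d2 <= spec$radius_mm^2 + 1e-9)
  if (!any(inside > 0))
    stop("sphere '", spec$name, "' lies entirely outside the grid")
  new_roi_mask(space, grid, inside,
               list(list(step = "sphere", name = spec$name,
                         centre_mni = spec$centre_mni,
                         radius_mm = spec$radius_mm)))
}

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  half <- max(1L, ceiling(4 * sigma_vox))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

convolve_axis <- function(arr, kernel, axis) {
  if (length(kernel) == 1L) return(arr)
  half <- (length(kernel) - 1L) / 2L
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  for (o in seq_along(kernel)) {
    off <- o - half - 1L            # source offset relative to target
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n      # zero padding beyond the boundary
    out[ok, ] <- out[ok, ] + kernel[o] * m[src[ok], , drop = FALSE]
  }
  aperm(array(out, dim(a)), order(perm))
}

#' Smooth an ROI mask with an isotropic Gaussian
#'
#' Separable convolution with a Gaussian of the given FWHM (in mm,
#' converted to voxels per axis from the grid affine). Mass is conserved
#' up to truncation at the grid boundary; \code{fwhm_mm = 0} is the
#' identity.
#'
#' @param mask An \code{roi_mask}.
#' @param fwhm_mm Full width at half maximum in mm.
#' @return A weighted \code{roi_mask}.
#' @export
smooth_mask <- function(mask, fwhm_mm = 6) {
  stopifnot(inherits(mask, "roi_mask"))
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  w <- mask$weights
  if (fwhm_mm > 0) {
    sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
    vox <- grid_voxel_size(mask$grid)
    for (ax in 1:3)
      w <- convolve_axis(w, gaussian_kernel_1d(sigma_mm / vox[ax]), ax)
  }
  new_roi_mask(mask$space, mask$grid, w,
               c(mask$provenance, list(list(step = "smooth",
                                            fwhm_mm = fwhm_mm))))
}

#' Warp a mask into native space through a 12-parameter affine
#'
#' \code{affine_native_to_mni} maps native-space mm coordinates to MNI mm
#' (the forward registration); the mask is resampled onto
#' \code{native_grid} through its inverse: each native voxel centre is
#' carried into MNI space and the mask is interpolated there.
#' Nearest-neighbour interpolation is used for binary masks and trilinear
#' for weighted ones unless overridden.
#'
#' @param mask An \code{roi_mask} in MNI space.
#' @param affine_native_to_mni 4x4 matrix (native mm to MNI mm).
#' @param native_grid Target \code{nf_grid}; defaults to the mask's grid.
#' @param interpolation \code{"auto"}, \code{"nearest"} or
#'   \code{"trilinear"}.
#' @return An \code{roi_mask} with \code{space = "NATIVE"}.
#' @export
warp_to_native <- function(mask, affine_native_to_mni,
                           native_grid = mask$grid,
                           interpolation = c("auto", "nearest", "trilinear")) {
  stopifnot(inherits(mask, "roi_mask"), inherits(native_grid, "nf_grid"))
  interpolation <- match.arg(interpolation)
  A <- as.matrix(affine_native_to_mni)
  stopifnot(all(dim(A) == c(4L, 4L)))
  if (abs(det(A)) < 1e-12) stop("affine_native_to_mni is singular")
  binary <- all(mask$weights %in% c(0, 1))
  if (interpolation == "auto")
    interpolation <- if (binary) "nearest" else "trilinear"

  native_mm <- voxel_to_world(native_grid, grid_voxel_indices(native_grid))
  mni_mm <- t(A %*% rbind(t(native_mm), 1))[, 1:3, drop = FALSE]
  src_vox <- world_to_voxel(mask$grid, mni_mm)   # fractional, 0-based
  w <- sample_volume(mask$weights, src_vox, interpolation)
  new_roi_mask("NATIVE", native_grid, w,
               c(mask$provenance,
                 list(list(step = "warp_to_native",
                           affine_native_to_mni = A,
                           interpolation = interpolation))))
}

# sample a 3D array at fractional 0-based voxel coordinates (N x 3)
sample_volume <- function(vol, vox, interpolation) {
  d <- dim(vol)
  n <- nrow(vox)
  if (interpolation == "nearest") {
    idx <- round(vox)
    ok <- idx[, 1] >= 0 & idx[, 1] < d[1] &
          idx[, 2] >= 0 & idx[, 2] < d[2] &
          idx[, 3] >= 0 & idx[, 3] < d[3]
    out <- numeric(n)
    lin <- idx[ok, 1] + d[1] * (idx[ok, 2] + d[2] * idx[ok, 3]) + 1
    out[ok] <- vol[lin]
    return(out)
  }
  out <- numeric(n)
  f <- floor(vox)
  frac <- vox - f
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- f[, 1] + dx; iy <- f[, 2] + dy; iz <- f[, 3] + dz
    wgt <- (dx * frac[, 1] + (1 - dx) * (1 - frac[, 1])) *
           (dy * frac[, 2] + (1 - dy) * (1 - frac[, 2])) *
           (dz * frac[, 3] + (1 - dz) * (1 - frac[, 3]))
    ok <- ix >= 0 & ix < d[1] & iy >= 0 & iy < d[2] & iz >= 0 & iz < d[3] &
          wgt > 0
    lin <- ix[ok] + d[1] * (iy[ok] + d[2] * iz[ok]) + 1
    out[ok] <- out[ok] + wgt[ok] * vol[lin]
  }
  out
}

canonical_hrf <- function(t) {
  # double-gamma impulse response (SPM-style shape parameters)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

condition_regressors <- function(timeline, hrf = FALSE) {
  conds <- nf_emotional_conditions()
  X <- sapply(conds, function(cn) as.numeric(timeline$conditions == cn))
  if (hrf) {
    tr <- timeline$tr_seconds
    h <- canonical_hrf(seq(0, 30, by = tr))
    X <- apply(X, 2, function(col) {
      full <- stats::convolve(col, rev(h), type = "open")
      full[seq_along(col)]
    })
  }
  colnames(X) <- conds
  cbind(intercept = 1, X)
}

#' Voxelwise GLM contrast map
#'
#' Fits, independently per voxel, an ordinary least-squares model with an
#' intercept and one box-car regressor per emotional condition
#' (subtraction is the implicit baseline), and returns the t statistic of
#' the requested condition contrast. Box-cars are unconvolved by default,
#' as in real-time use; set \code{hrf = TRUE} for a canonical
#' double-gamma convolution.
#'
#' @param series Either a 4D array (x, y, z, t) or a volumes-by-voxels
#'   matrix.
#' @param timeline The run's \code{nf_timeline}; its length must match
#'   the series.
#' @param contrast Character pair, e.g. \code{c("GUILT", "SUBTRACTION")}
#'   or \code{c("GUILT", "INDIGNATION")}.
#' @param grid \code{nf_grid} of the series (required for 4D arrays; used
#'   for the map metadata).
#' @param include_volumes Optional logical vector (length = total
#'   volumes): volumes flagged \code{FALSE} (e.g. motion-gated ones) are
#'   excluded from the fit.
#' @param hrf Convolve the box-cars with a canonical HRF.
#' @return An object of class \code{activation_map} with a per-voxel
#'   \code{statistic} array/vector.
#' @export
glm_activation_map <- function(series, timeline,
                               contrast = c("GUILT", "SUBTRACTION"),
                               grid = NULL, include_volumes = NULL,
                               hrf = FALSE) {
  stopifnot(inherits(timeline, "nf_timeline"))
  if (is.array(series) && length(dim(series)) == 4L) {
    d <- dim(series)
    if (is.null(grid)) grid <- nf_grid(d[1:3])
    Y <- matrix(series, nrow = prod(d[1:3]), ncol = d[4])
    Y <- t(Y)
  } else {
    Y <- as.matrix(series)
  }
  if (nrow(Y) != timeline$total_volumes)
    stop("series has ", nrow(Y), " volumes but the timeline has ",
         timeline$total_volumes)
  valid <- c("GUILT", "INDIGNATION", "SUBTRACTION")
  stopifnot(length(contrast) == 2L, all(contrast %in% valid))

  X <- condition_regressors(timeline, hrf = hrf)
  if (!is.null(include_volumes)) {
    stopifnot(length(include_volumes) == nrow(Y))
    X <- X[include_volumes, , drop = FALSE]
    Y <- Y[include_volumes, , drop = FALSE]
  }
  cvec <- c(intercept = 0, GUILT = 0, INDIGNATION = 0, SUBTRACTION = 0)
  cvec[contrast[1]] <- 1
  cvec[contrast[2]] <- cvec[contrast[2]] - 1
  cvec <- cvec[colnames(X)]   # SUBTRACTION is the baseline column-free level

  XtXinv <- solve(crossprod(X))
  beta <- XtXinv %*% crossprod(X, Y)
  resid <- Y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(sigma2 * drop(t(cvec) %*% XtXinv %*% cvec))
  tval <- drop(t(cvec) %*% beta) / se
  tval[se == 0] <- 0

  structure(list(statistic = if (!is.null(grid)) array(tval, grid$dim) else tval,
                 statistic_type = "t",
                 contrast = contrast, df = df, grid = grid,
                 hrf = hrf),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("<activation_map> %s vs %s, t statistic, df = %d\n",
              x$contrast[1], x$contrast[2], x$df))
  invisible(x)
}

#' Select the most activated fraction of an ROI
#'
#' Takes the mask support (weights above \code{support_eps} times the
#' peak weight), ranks supported voxels by the activation statistic, and
#' returns the top \code{ceiling(fraction * N)} voxels. Ties are broken
#' by ascending linear voxel index so the selection is deterministic.
#'
#' @param map An \code{activation_map} on the same grid as the mask.
#' @param mask An \code{roi_mask}.
#' @param fraction Selection fraction in (0, 1]; default 0.10.
#' @param support_eps Support threshold as a fraction of the peak weight
#'   (default 0.05); 0 keeps every voxel with positive weight.
#' @return An object of class \code{selected_roi} with 1-based linear
#'   \code{voxel_indices}, the support size and provenance.
#' @export
select_top_fraction <- function(map, mask, fraction = 0.10,
                                support_eps = 0.05) {
  stopifnot(inherits(map, "activation_map"), inherits(mask, "roi_mask"))
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  w <- as.vector(mask$weights)
  support <- which(w > support_eps * max(w))
  if (length(support) == 0L) stop("mask support is empty")
  stat <- as.vector(map$statistic)
  if (length(stat) != length(w))
    stop("activation map and mask are on different grids")
  k <- ceiling(fraction * length(support))
  ord <- support[order(-stat[support], support)]
  sel <- sort(ord[seq_len(k)])
  structure(list(voxel_indices = sel,
                 n_support = length(support),
                 fraction = fraction,
                 grid = mask$grid,
                 contrast = map$contrast,
                 provenance = c(mask$provenance,
                                list(list(step = "select_top_fraction",
                                          fraction = fraction,
                                          n_support = length(support),
                                          n_selected = k,
                                          contrast = map$contrast)))),
            class = "selected_roi")
}

#' @export
print.selected_roi <- function(x, ...) {
  cat(sprintf("<selected_roi> %d of %d support voxels (fraction %.2f), contrast %s vs %s\n",
              length(x$voxel_indices), x$n_support, x$fraction,
              x$contrast[1], x$contrast[2]))
  invisible(x)
}

#' Mean ROI signal per volume
#'
#' @param series 4D array (x, y, z, t) or volumes-by-voxels matrix laid
#'   out on the ROI's grid.
#' @param roi A \code{selected_roi}.
#' @return Numeric vector, one value per volume.
#' @export
extract_mean_signal <- function(series, roi) {
  stopifnot(inherits(roi, "selected_roi"))
  if (is.array(series) && length(dim(series)) == 4L) {
    d <- dim(series)
    Y <- t(matrix(series, nrow = prod(d[1:3]), ncol = d[4]))
  } else {
    Y <- as.matrix(series)
  }
  if (max(roi$voxel_indices) > ncol(Y))
    stop("ROI voxel index outside the series grid")
  rowMeans(Y[, roi$voxel_indices, drop = FALSE])
}

#' Read / write a FLIRT-style affine matrix
#'
#' Plain-text whitespace-delimited 4x4 matrix, one row per line.
#'
#' @param path File path.
#' @export
read_affine_mat <- function(path) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  stopifnot(all(dim(m) == c(4L, 4L)))
  m
}

#' @rdname read_affine_mat
#' @param affine 4x4 matrix.
#' @export
write_affine_mat <- function(affine, path) {
  utils::write.table(format(affine, digits = 10), path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' NIfTI helpers for masks and series
#'
#' Thin wrappers over \pkg{RNifti} keeping the package's grid convention
#' (0-based voxel-to-mm affine) in sync with the NIfTI sform.
#'
#' @param mask An \code{roi_mask}.
#' @param path Output/input path (\code{.nii} or \code{.nii.gz}).
#' @export
write_mask_nifti <- function(mask, path) {
  img <- RNifti::asNifti(mask$weights)
  RNifti::sform(img) <- structure(mask$grid$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_mask_nifti
#' @param space Space label to record on the mask read back.
#' @export
read_mask_nifti <- function(path, space = "NATIVE") {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), code = NULL)
  grid <- nf_grid(dim(img)[1:3], affine = matrix(as.numeric(aff), 4, 4))
  new_roi_mask(space, grid, as.numeric(img),
               list(list(step = "read_nifti", path = path)))
}
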