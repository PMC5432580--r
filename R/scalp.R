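#' MRI-like scalar volume
#'
#' @param voxels 3D numeric array.
#' @param affine 4x4 invertible voxel-to-world matrix (world in mm; voxel
#'   indices 0-based, so world = affine %*% c(i, j, k, 1)).
#' @return An object of class `head_volume`.
#' @export
head_volume <- function(voxels, affine) {
  if (length(dim(voxels)) != 3L) stop("voxels must be a rank-3 array")
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine)) < 1e-12) stop("affine must be invertible")
  structure(list(voxels = voxels, affine = affine), class = "head_volume")
}

#' @export
print.head_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<head_volume: %d x %d x %d voxels, %.2f mm det^(1/3)>\n",
              d[1], d[2], d[3], abs(det(x$affine[1:3, 1:3]))^(1 / 3)))
  invisible(x)
}

#' Read / write a NIfTI volume
#' @param path `.nii` / `.nii.gz` path.
#' @return `read_volume()`: a [head_volume()] with the NIfTI sform/qform
#'   world affine; `write_volume()`: `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  arr <- as.array(img)
  if (length(dim(arr)) > 3L) arr <- arr[, , , 1]
  # RNifti xforms map 1-based R voxel indices; convert to a 0-based affine
  A <- unclass(aff)
  A0 <- A
  A0[1:3, 4] <- A[1:3, 4] + A[1:3, 1:3] %*% c(1, 1, 1)
  head_volume(arr, A0)
}

#' @rdname read_volume
#' @param vol a [head_volume()].
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "head_volume"))
  img <- RNifti::asNifti(vol$voxels)
  A <- vol$affine
  A1 <- A
  A1[1:3, 4] <- A[1:3, 4] - A[1:3, 1:3] %*% c(1, 1, 1)
  img <- RNifti::`sform<-`(img, structure(A1, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Extract a scalp surface mesh from an MRI-like volume
#'
#' Binarizes at `threshold_frac` times the robust maximum (99th intensity
#' percentile), applies morphological closing with a spherical element,
#' keeps the largest connected component, fills internal holes, extracts
#' the 0.5 isosurface of the (lightly smoothed) mask by marching
#' tetrahedra, and maps voxel coordinates to world mm via the affine. The
#' result is a single watertight connected surface.
#'
#' @param vol a [head_volume()].
#' @param threshold_frac fraction of the robust maximum (default 0.10).
#' @param closing_radius structuring-element radius in voxels (default 2).
#' @param smooth_sigma Gaussian sigma (voxels) applied to the binary mask
#'   before isosurfacing; reduces voxel staircase (default 0.6).
#' @param frame_id frame tag of the output mesh (default `"mri"`).
#' @return A [textured_mesh()] (untextured) of the scalp surface.
#' @export
scalp_mesh_from_volume <- function(vol, threshold_frac = 0.10,
                                   closing_radius = 2, smooth_sigma = 0.6,
                                   frame_id = "mri") {
  stopifnot(inherits(vol, "head_volume"))
  robust_max <- stats::quantile(vol$voxels, 0.99, names = FALSE)
  thr <- threshold_frac * robust_max
  mask <- vol$voxels > thr
  if (!any(mask))
    stop("empty foreground after thresholding; try a lower threshold_frac")
  storage.mode(mask) <- "logical"
  if (closing_radius > 0) {
    mask <- .binary_morph3d(mask, as.integer(closing_radius), TRUE)
    mask <- .binary_morph3d(mask, as.integer(closing_radius), FALSE)
  }
  mask <- .largest_component_fill(mask)
  field <- array(as.numeric(mask), dim = dim(vol$voxels))
  if (smooth_sigma > 0) field <- .gauss_smooth3d(field, smooth_sigma)
  surf <- .marching_tetrahedra(field, 0.5)
  if (nrow(surf$vertices) == 0L)
    stop("no isosurface found; try a lower threshold_frac")
  world <- sweep(surf$vertices %*% t(vol$affine[1:3, 1:3]), 2L,
                 vol$affine[1:3, 4], "+")
  textured_mesh(world, surf$faces, frame_id = frame_id)
}
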