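#' Facial segment of a mesh
#'
#' A subset of mesh vertices covering the rigid facial region (forehead,
#' brow, nose ridge, cheekbones) used for scaling and surface matching.
#'
#' @param points n x 3 numeric matrix (mm) or a `textured_mesh` plus
#'   `indices`.
#' @param indices optional vertex indices into `points` when `points` is a
#'   mesh.
#' @param source_frame optional frame tag.
#' @return An object of class `facial_segment`.
#' @export
facial_segment <- function(points, indices = NULL, source_frame = NULL) {
  if (inherits(points, "textured_mesh")) {
    if (is.null(indices)) stop("indices required when points is a mesh")
    if (min(indices) < 1L || max(indices) > nrow(points$vertices))
      stop("segment indices out of range for mesh")
    source_frame <- source_frame %||% points$frame_id
    points <- points$vertices[indices, , drop = FALSE]
  }
  points <- as_points(points)
  if (nrow(points) < 1L) stop("segment must be non-empty")
  structure(list(points = points, source_frame = source_frame),
            class = "facial_segment")
}

seg_points <- function(x) {
  if (inherits(x, "facial_segment")) x$points
  else if (inherits(x, "electrode_set")) x$points
  else if (inherits(x, "textured_mesh")) x$vertices
  else as_points(x)
}

#' Centroid of a point set
#'
#' Arithmetic mean coordinate, computed across each dimension separately.
#' @param points n x 3 matrix, `facial_segment`, or `electrode_set`.
#' @return Length-3 numeric vector.
#' @export
centroid <- function(points) {
  pts <- seg_points(points)
  if (nrow(pts) < 1L) stop("centroid of an empty point set")
  colMeans(pts)
}

#' Centroid-ratio scaling factor between facial segments
#'
#' Computes the isotropic scale mapping the model frame into MRI units as
#' the ratio of mean centroid distances:
#' \deqn{s = \frac{\frac{1}{N_{MRI}}\sum_i \|v_i^{MRI} - C^{MRI}\|}
#'            {\frac{1}{N_{model}}\sum_i \|v_i^{model} - C^{model}\|}}
#' where each centroid \eqn{C} is the per-axis mean of its segment. All
#' model coordinates are then multiplied by `s` before surface matching.
#'
#' @param mri_seg,model_seg [facial_segment()]s (>= 2 points each).
#' @return Positive scalar scale factor.
#' @export
scaling_factor <- function(mri_seg, model_seg) {
  a <- seg_points(mri_seg)
  b <- seg_points(model_seg)
  if (nrow(a) < 2L || nrow(b) < 2L) stop("segments need at least 2 points")
  spread <- function(p) mean(sqrt(rowSums(sweep(p, 2L, colMeans(p))^2)))
  sa <- spread(a)
  sb <- spread(b)
  if (sb <= .Machine$double.eps)
    stop("model segment has zero spread (all points coincident)")
  if (sa <= .Machine$double.eps)
    stop("MRI segment has zero spread (all points coincident)")
  sa / sb
}

#' Least-squares rigid / similarity fit for known correspondences
#'
#' Kabsch-Umeyama solve: finds the rotation (det +1, reflections rejected),
#' translation and optionally isotropic scale minimizing
#' `sum ||T(source_i) - target_i||^2`.
#'
#' @param source,target n x 3 matrices with row-wise correspondence, n >= 3.
#' @param allow_scale estimate an isotropic scale (similarity) instead of a
#'   rigid transform.
#' @param weights optional non-negative per-correspondence weights.
#' @return A [head_transform()].
#' @export
best_fit_rigid <- function(source, target, allow_scale = FALSE, weights = NULL) {
  s <- as_points(source)
  t <- as_points(target)
  if (nrow(s) != nrow(t)) stop("source and target must have equal length")
  if (nrow(s) < 3L) stop("need at least 3 correspondences")
  w <- if (is.null(weights)) rep(1, nrow(s)) else as.numeric(weights)
  w <- w / sum(w)
  cs <- colSums(s * w)
  ct <- colSums(t * w)
  sc <- sweep(s, 2L, cs)
  tc <- sweep(t, 2L, ct)
  H <- t(sc * w) %*% tc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) stop("degenerate geometry (collinear or coincident points)")
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  var_s <- sum(w * rowSums(sc^2))
  if (var_s <= .Machine$double.eps^0.5 * max(1, sum(tc^2)))
    stop("degenerate geometry (source points coincident)")
  if (isTRUE(all.equal(sv$d[2], 0, tolerance = 1e-9 * max(sv$d[1], 1))))
    stop("degenerate geometry (collinear points)")
  scale <- if (allow_scale) sum(sv$d * diag(D)) / var_s else 1
  tr <- ct - scale * as.numeric(R %*% cs)
  head_transform(R, tr, scale,
                 kind = if (allow_scale) "similarity" else "rigid")
}

best_fit_affine <- function(source, target) {
  s <- as_points(source)
  t <- as_points(target)
  X <- cbind(s, 1)
  # least-squares solve of X B = t; B is 4 x 3
  B <- tryCatch(qr.solve(X, t), error = function(e)
    stop("degenerate geometry for affine fit"))
  A <- t(B[1:3, ])
  if (det(A) <= 0) stop("affine fit collapsed to non-positive determinant")
  head_transform(A, B[4, ], kind = "affine")
}

#' Nearest-neighbour indices from query to reference points
#' @param query,ref n x 3 matrices (or meshes / electrode sets).
#' @return List with 1-based `index` into `ref` and `distance` (mm).
#' @export
nearest_neighbors <- function(query, ref) {
  .nn_index(as_points(seg_points(query)), as_points(seg_points(ref)))
}

#' Iterative closest point registration
#'
#' Alternates nearest-neighbour correspondence with a least-squares
#' transform solve, minimizing the sum of squared distances from each
#' source point to its closest reference point. The RMS objective is
#' non-increasing across iterations (for untrimmed rigid/similarity mode).
#'
#' @param source n x 3 matrix (or segment/mesh/electrode set) to move.
#' @param target reference points (matrix, mesh, segment or electrode set).
#' @param mode `"rigid"`, `"similarity"` (rigid + isotropic scale) or
#'   `"affine"`.
#' @param init initial [head_transform()] applied to `source` (identity by
#'   default).
#' @param max_iter maximum iterations.
#' @param tol stop when the RMS change between iterations falls below this
#'   (mm).
#' @param trim_frac fraction (0-0.5) of the worst correspondences dropped in
#'   each solve, a robustness stand-in for manually removing mismatching
#'   mesh parts.
#' @return A `head_transform` with attributes `converged` (logical),
#'   `iterations` and `rms` (final trimmed RMS, mm).
#' @export
icp <- function(source, target, mode = c("rigid", "similarity", "affine"),
                init = head_transform(), max_iter = 100L, tol = 1e-6,
                trim_frac = 0) {
  mode <- match.arg(mode)
  src0 <- as_points(seg_points(source))
  tgt <- as_points(seg_points(target))
  if (nrow(src0) < 3L) stop("ICP needs at least 3 source points")
  if (trim_frac < 0 || trim_frac >= 0.5) stop("trim_frac must be in [0, 0.5)")
  current <- init
  prev_rms <- Inf
  converged <- FALSE
  iter <- 0L
  rms <- NA_real_
  n_keep <- max(3L, ceiling((1 - trim_frac) * nrow(src0)))
  while (iter < max_iter) {
    iter <- iter + 1L
    moved <- apply_transform_mat(current, src0)
    nn <- .nn_index(moved, tgt)
    keep <- seq_len(nrow(src0))
    if (n_keep < nrow(src0))
      keep <- order(nn$distance)[seq_len(n_keep)]
    corr_t <- tgt[nn$index[keep], , drop = FALSE]
    fit <- switch(mode,
      rigid = best_fit_rigid(src0[keep, , drop = FALSE], corr_t),
      similarity = best_fit_rigid(src0[keep, , drop = FALSE], corr_t,
                                  allow_scale = TRUE),
      affine = best_fit_affine(src0[keep, , drop = FALSE], corr_t))
    current <- fit
    moved <- apply_transform_mat(current, src0)
    nn <- .nn_index(moved, tgt)
    rms <- sqrt(mean(sort(nn$distance)[seq_len(n_keep)]^2))
    if (abs(prev_rms - rms) < tol) { converged <- TRUE; break }
    prev_rms <- rms
  }
  if (!converged)
    current$converged <- FALSE
  else
    current$converged <- TRUE
  current$iterations <- iter
  current$rms <- rms
  current
}

#' Coarse initialization by principal-axis alignment
#'
#' Aligns the principal axes of two point clouds (after centroid matching),
#' trying the four proper axis-sign combinations and keeping the one with
#' the lowest nearest-neighbour RMS. Used as the automatic replacement for
#' interactive pre-orientation.
#'
#' @param source,target point matrices (or segments).
#' @return A rigid `head_transform`.
#' @export
principal_axes_init <- function(source, target) {
  s <- as_points(seg_points(source))
  t <- as_points(seg_points(target))
  cs <- colMeans(s)
  ct <- colMeans(t)
  es <- eigen(stats::cov(s), symmetric = TRUE)$vectors
  et <- eigen(stats::cov(t), symmetric = TRUE)$vectors
  if (det(es) < 0) es[, 3] <- -es[, 3]
  if (det(et) < 0) et[, 3] <- -et[, 3]
  signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  best <- NULL
  best_rms <- Inf
  for (sg in signs) {
    R <- et %*% diag(sg) %*% t(es)
    tr <- head_transform(R, ct - as.numeric(R %*% cs), kind = "rigid")
    nn <- .nn_index(apply_transform_mat(tr, s), t)
    rms <- sqrt(mean(nn$distance^2))
    if (rms < best_rms) { best_rms <- rms; best <- tr }
  }
  best
}

#' Coregister a photogrammetric model into MRI space
#'
#' Implements the surface-matching workflow: compute the centroid-ratio
#' [scaling_factor()] between corresponding facial segments, scale the
#' whole model, then rigid-ICP the scaled model segment onto the MRI
#' segment (with an automatic principal-axes initialization). The returned
#' transform maps the full model, and anything in its frame (e.g. detected
#' electrodes), into the MRI frame.
#'
#' @param model the model [textured_mesh()] (used for frame bookkeeping;
#'   the fit itself uses the segments).
#' @param model_seg,mri_seg [facial_segment()]s covering corresponding
#'   facial regions.
#' @param icp_params list of [icp()] arguments (`max_iter`, `tol`,
#'   `trim_frac`).
#' @return A similarity `head_transform` (model frame to MRI frame) with
#'   `converged`, `iterations`, `rms` fields as in [icp()].
#' @export
coregister_model_to_mri <- function(model = NULL, model_seg, mri_seg,
                                    icp_params = list()) {
  s <- scaling_factor(mri_seg, model_seg)
  scale_tr <- head_transform(scale = s, kind = "similarity")
  src <- apply_transform_mat(scale_tr, seg_points(model_seg))
  init <- principal_axes_init(src, seg_points(mri_seg))
  args <- c(list(source = src, target = seg_points(mri_seg), mode = "rigid",
                 init = init), icp_params)
  fit <- do.call(icp, args)
  out <- compose_transforms(fit, scale_tr)
  out$converged <- fit$converged
  out$iterations <- fit$iterations
  out$rms <- fit$rms
  out$from_frame <- if (!is.null(model)) model$frame_id else
    (if (inherits(model_seg, "facial_segment")) model_seg$source_frame else NULL)
  out$to_frame <- if (inherits(mri_seg, "facial_segment")) mri_seg$source_frame else NULL
  out
}

fiducial_frame <- function(fids) {
  # fids: named list/matrix with nasion, LPA, RPA rows
  if (is.matrix(fids)) {
    nm <- rownames(fids)
    fids <- stats::setNames(lapply(seq_len(nrow(fids)), function(i) fids[i, ]), nm)
  }
  names(fids) <- tolower(names(fids))
  need <- c("nasion", "lpa", "rpa")
  if (!all(need %in% names(fids)))
    stop("fiducials must be named nasion, LPA, RPA")
  nas <- as.numeric(fids[["nasion"]])
  lpa <- as.numeric(fids[["lpa"]])
  rpa <- as.numeric(fids[["rpa"]])
  origin <- (lpa + rpa) / 2
  x <- rpa - origin
  nx <- sqrt(sum(x^2))
  if (nx < 1e-12) stop("preauricular points coincide")
  x <- x / nx
  y0 <- nas - origin
  y <- y0 - sum(y0 * x) * x
  ny <- sqrt(sum(y^2))
  if (ny < 1e-9 * max(1, sqrt(sum(y0^2))))
    stop("collinear fiducials: nasion lies on the LPA-RPA line")
  y <- y / ny
  z <- c(x[2] * y[3] - x[3] * y[2], x[3] * y[1] - x[1] * y[3],
         x[1] * y[2] - x[2] * y[1])
  list(origin = origin, R = cbind(x, y, z))
}

#' Fiducial-based rigid alignment
#'
#' Builds the canonical head frame on each side (origin at the midpoint of
#' the preauricular points, x toward RPA, y toward the nasion within the
#' fiducial plane, z = x cross y) and composes source-frame -> canonical ->
#' destination-frame. Exact on noiseless, rigidly-related fiducials.
#'
#' @param src_fids,dst_fids fiducials as a named list (`nasion`, `LPA`,
#'   `RPA`) of length-3 points, or a 3 x 3 matrix with those rownames.
#' @return A rigid `head_transform`.
#' @export
fiducial_transform <- function(src_fids, dst_fids) {
  fs <- fiducial_frame(src_fids)
  fd <- fiducial_frame(dst_fids)
  R <- fd$R %*% t(fs$R)
  head_transform(R, fd$origin - as.numeric(R %*% fs$origin), kind = "rigid")
}
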