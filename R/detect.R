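#' Binarize a texture to separate electrodes from cap
#'
#' Converts the texture to grayscale (Rec. 601 luminance) and applies a
#' global threshold; when no threshold is given it is chosen automatically
#' to maximize the between-class variance (Otsu's criterion).
#'
#' @param texture h x w matrix or h x w x 3 array with values in \[0, 1\].
#' @param threshold optional fixed threshold in (0, 1).
#' @param polarity `"bright"`: foreground = above threshold (electrode
#'   patches brighter than the cap); `"dark"`: foreground = below.
#' @return A binary (0/1) h x w matrix.
#' @export
binarize_texture <- function(texture, threshold = NULL,
                             polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  if (is.null(texture)) stop("no texture present")
  g <- if (length(dim(texture)) == 3L)
    0.299 * texture[, , 1] + 0.587 * texture[, , 2] + 0.114 * texture[, , 3]
  else texture
  if (diff(range(g)) < 1e-9)
    stop("constant-intensity texture: no contrast to threshold")
  if (is.null(threshold))
    threshold <- EBImage::otsu(EBImage::Image(t(g)), range = range(g))
  out <- if (polarity == "bright") (g > threshold) else (g < threshold)
  storage.mode(out) <- "double"
  out
}

#' Detect circles in a binary image via a circular Hough transform
#'
#' Gradient-based accumulation: Sobel edge pixels vote along the local
#' gradient direction across the radius search range; perimeter-normalized
#' accumulator maxima above `sensitivity` are returned strongest-first,
#' with non-maximum suppression of centers closer than `r_min` (or inside
#' an accepted stronger circle). Sub-pixel centers come from the local
#' accumulator centroid.
#'
#' @param img binary (0/1) matrix.
#' @param r_min,r_max radius search range in pixels, `r_min < r_max`.
#' @param sensitivity accumulator threshold as a fraction of a full
#'   circle's perimeter vote (0-1).
#' @return A data frame with columns `x`, `y` (continuous pixel
#'   coordinates, origin at the raster's top-left corner), `r` (px) and
#'   `strength`; zero rows when nothing is found.
#' @export
detect_circles <- function(img, r_min, r_max, sensitivity = 0.3) {
  if (r_min >= r_max) stop("r_min must be < r_max")
  if (length(img) == 0L) stop("empty image")
  det <- .hough_circles(as.matrix(img) * 1.0, r_min, r_max, sensitivity,
                        r_min)
  out <- as.data.frame(det)
  names(out) <- c("x", "y", "r", "strength")
  out
}

#' Back-project 2D circle detections to the mesh surface
#'
#' Maps each detected circle center through the render's reverse lookup
#' (face + barycentric coordinates of the pixel's visible surface point)
#' to a 3D point. Detections landing on background pixels are dropped with
#' a warning.
#'
#' @param dets data frame from [detect_circles()].
#' @param rendered_view a `binary_view` from [render_binary_views()] (the
#'   same mesh/view the detections came from).
#' @param mesh the rendered [textured_mesh()].
#' @return n x 3 matrix of surface points (mm).
#' @export
backproject <- function(dets, rendered_view, mesh) {
  if (nrow(dets) == 0L) return(matrix(numeric(0), 0L, 3L))
  fa <- rendered_view$face
  H <- nrow(fa); W <- ncol(fa)
  col <- pmin(W, pmax(1L, as.integer(round(dets$x + 0.5))))
  row <- pmin(H, pmax(1L, as.integer(round(dets$y + 0.5))))
  pix <- cbind(row, col)
  fid <- fa[pix]
  ok <- fid > 0L
  if (any(!ok))
    warning(sum(!ok), " detection(s) at background pixels dropped")
  if (!any(ok)) return(matrix(numeric(0), 0L, 3L))
  i0 <- (fid[ok] - 1L) * 3L
  cx <- mesh$vertices[t(mesh$faces), , drop = FALSE]
  b1 <- rendered_view$b1[pix][ok]
  b2 <- rendered_view$b2[pix][ok]
  b3 <- rendered_view$b3[pix][ok]
  out <- matrix(0, sum(ok), 3L)
  for (k in 1:3)
    out[, k] <- b1 * cx[i0 + 1L, k] + b2 * cx[i0 + 2L, k] + b3 * cx[i0 + 3L, k]
  out
}

#' Merge multi-view 3D detection candidates
#'
#' Single-linkage clustering at `merge_radius`; each cluster is reduced to
#' its centroid. Output order: descending cluster size, then ascending z.
#' The result is independent of input point order.
#'
#' @param points n x 3 matrix of candidate positions (mm).
#' @param merge_radius linkage distance (mm), > 0.
#' @param frame_id frame tag for the result.
#' @return An [electrode_set()] with attribute `support` (cluster sizes).
#' @export
merge_candidates <- function(points, merge_radius = 10, frame_id = NULL) {
  if (merge_radius <= 0) stop("merge_radius must be > 0")
  points <- as_points(points)
  if (nrow(points) == 0L)
    return(electrode_set(matrix(numeric(0), 0L, 3L), frame_id = frame_id))
  if (nrow(points) == 1L) {
    out <- electrode_set(points, frame_id = frame_id)
    attr(out, "support") <- 1L
    return(out)
  }
  hc <- stats::hclust(stats::dist(points), method = "single")
  cl <- stats::cutree(hc, h = merge_radius)
  groups <- split(seq_along(cl), cl)
  cent <- unname(t(vapply(groups, function(idx)
    colMeans(points[idx, , drop = FALSE]), numeric(3))))
  size <- unname(lengths(groups))
  ord <- order(-size, cent[, 3])
  out <- electrode_set(cent[ord, , drop = FALSE], frame_id = frame_id)
  attr(out, "support") <- as.integer(size[ord])
  out
}

#' Project electrodes orthogonally onto a scalp surface
#'
#' Replaces each electrode position by its closest point on the scalp
#' surface (true point-to-triangle distance, not nearest vertex).
#'
#' @param set an [electrode_set()] in the scalp's frame.
#' @param scalp the scalp [textured_mesh()].
#' @return The projected `electrode_set`.
#' @export
project_to_scalp <- function(set, scalp) {
  stopifnot(inherits(set, "electrode_set"), inherits(scalp, "textured_mesh"))
  cp <- .closest_on_mesh(set$points, scalp$vertices, scalp$faces)
  set$points <- cp$point
  set
}

#' Detect electrode positions on a textured head mesh
#'
#' The full detection pipeline: binarize the texture, render binary views
#' from (by default) 10 perspectives, run circular Hough detection in each
#' view, back-project circle centers to the surface, and merge multi-view
#' candidates. Candidate clusters supported by fewer than `min_views`
#' views are discarded as spurious. The result can be hand-edited (add /
#' remove / move rows) before labeling — the manual-correction hook.
#'
#' @param mesh textured [textured_mesh()] (already in its final frame).
#' @param views list of [view_projection()]s; [default_views()] when NULL.
#' @param r_min_mm,r_max_mm electrode radius search range (mm), converted
#'   per view through its pixel pitch.
#' @param sensitivity Hough accumulator threshold (see [detect_circles()]).
#' @param merge_radius candidate merge distance (mm).
#' @param min_views minimum number of supporting detections per electrode.
#' @param threshold,polarity passed to [binarize_texture()].
#' @return An [electrode_set()] of detected positions with attribute
#'   `support`.
#' @export
detect_electrodes <- function(mesh, views = NULL, r_min_mm = 2,
                              r_max_mm = 8, sensitivity = 0.3,
                              merge_radius = 10, min_views = 2,
                              threshold = NULL, polarity = "bright") {
  if (is.null(mesh$texture)) stop("mesh has no texture: cannot detect electrodes")
  if (is.null(views)) views <- default_views(mesh)
  btex <- binarize_texture(mesh$texture, threshold = threshold,
                           polarity = polarity)
  rendered <- render_binary_views(mesh, btex, views)
  pts <- matrix(numeric(0), 0L, 3L)
  for (i in seq_along(rendered)) {
    pitch <- rendered[[i]]$view$pixel_pitch
    dets <- detect_circles(rendered[[i]]$img, r_min_mm / pitch,
                           r_max_mm / pitch, sensitivity)
    if (nrow(dets))
      pts <- rbind(pts, backproject(dets, rendered[[i]], mesh))
  }
  if (nrow(pts) == 0L)
    stop("no electrodes detected; consider lowering the binarization ",
         "threshold or widening the Hough radius range")
  merged <- merge_candidates(pts, merge_radius, frame_id = mesh$frame_id)
  support <- attr(merged, "support")
  keep <- support >= min_views
  if (!any(keep))
    stop("no electrode candidate supported by >= ", min_views, " views")
  out <- electrode_set(merged$points[keep, , drop = FALSE],
                       frame_id = mesh$frame_id)
  attr(out, "support") <- support[keep]
  out
}
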