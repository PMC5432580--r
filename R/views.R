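#' Orthographic view projection
#'
#' Defines an orthographic camera linking the mesh surface to a 2D raster:
#' a unit viewing `direction` (from camera toward the scene), an `up` hint,
#' a `pixel_pitch` in mm/pixel, a raster size and a 3D `center` mapped to
#' the raster center.
#'
#' @param direction length-3 viewing direction (normalized internally).
#' @param up length-3 up hint, not parallel to `direction`.
#' @param pixel_pitch mm per pixel, > 0.
#' @param center 3D point mapped to the raster center (mm).
#' @param raster_size `c(height, width)` in pixels.
#' @return An object of class `view_projection` with orthonormalized
#'   `right`/`up` screen axes.
#' @export
view_projection <- function(direction, up, pixel_pitch, center,
                            raster_size) {
  if (pixel_pitch <= 0) stop("degenerate view: pixel_pitch must be > 0")
  d <- direction / sqrt(sum(direction^2))
  r <- c(d[2] * up[3] - d[3] * up[2],
         d[3] * up[1] - d[1] * up[3],
         d[1] * up[2] - d[2] * up[1])
  nr <- sqrt(sum(r^2))
  if (nr < 1e-9) stop("up vector parallel to viewing direction")
  r <- r / nr
  u <- c(r[2] * d[3] - r[3] * d[2],
         r[3] * d[1] - r[1] * d[3],
         r[1] * d[2] - r[2] * d[1])
  structure(list(direction = d, up = -u, right = r,
                 pixel_pitch = pixel_pitch, center = as.numeric(center),
                 raster_size = as.integer(raster_size)),
            class = "view_projection")
}

# screen coordinates (x right, y down, origin top-left of raster; pixel
# (r,c) centre at (c-0.5, r-0.5)) plus depth along the viewing direction
project_points <- function(view, pts) {
  rel <- sweep(as_points(pts), 2L, view$center)
  H <- view$raster_size[1]; W <- view$raster_size[2]
  cbind(x = rel %*% view$right / view$pixel_pitch + W / 2,
        y = rel %*% (-view$up) / view$pixel_pitch + H / 2,
        z = rel %*% view$direction)
}

#' Default multi-view set for electrode detection
#'
#' Ten orthographic views: azimuths `{0, 72, 144, 216, 288}` degrees around
#' the head's vertical axis at elevations `{20, 55}` degrees, covering the
#' cap area with overlap.
#'
#' @param mesh the textured head mesh (determines raster extent).
#' @param pixel_pitch mm per pixel.
#' @param up head vertical axis (default +z).
#' @param anterior head anterior axis (azimuth 0; default +y).
#' @param azimuths_deg,elevations_deg view angles (degrees).
#' @return List of [view_projection()]s.
#' @export
default_views <- function(mesh, pixel_pitch = 0.6, up = c(0, 0, 1),
                          anterior = c(0, 1, 0),
                          azimuths_deg = c(0, 72, 144, 216, 288),
                          elevations_deg = c(20, 55)) {
  ctr <- colMeans(mesh$vertices)
  rad <- max(sqrt(rowSums(sweep(mesh$vertices, 2L, ctr)^2))) + 6
  npix <- as.integer(ceiling(2 * rad / pixel_pitch))
  up <- up / sqrt(sum(up^2))
  ant <- anterior - sum(anterior * up) * up
  ant <- ant / sqrt(sum(ant^2))
  right <- c(up[2] * ant[3] - up[3] * ant[2],
             up[3] * ant[1] - up[1] * ant[3],
             up[1] * ant[2] - up[2] * ant[1])
  views <- list()
  for (el in elevations_deg) {
    for (az in azimuths_deg) {
      a <- az * pi / 180; e <- el * pi / 180
      outward <- cos(e) * (cos(a) * ant + sin(a) * right) + sin(e) * up
      views[[length(views) + 1L]] <-
        view_projection(direction = -outward, up = up,
                        pixel_pitch = pixel_pitch, center = ctr,
                        raster_size = c(npix, npix))
    }
  }
  views
}

# z-buffered rasterization of a mesh under a view; returns the raw raster
# record (face ids, barycentrics, depth) used for texture sampling and
# back-projection
render_mesh_view <- function(mesh, view) {
  corner_idx <- as.integer(t(mesh$faces))
  pxyz <- project_points(view, mesh$vertices)
  corner_xy <- pxyz[corner_idx, 1:2, drop = FALSE]
  corner_z <- pxyz[corner_idx, 3]
  ras <- .rasterize_corners(corner_xy, corner_z, nrow(mesh$faces),
                            view$raster_size[2], view$raster_size[1])
  ras$view <- view
  ras
}

#' Render binary texture views of a mesh
#'
#' Orthographic z-buffered rasterization from each view; every output pixel
#' carries the binary texture value of the visible surface point, and the
#' underlying face + barycentric record is kept for back-projection.
#'
#' @param mesh a textured mesh (UV coordinates required).
#' @param binary_tex h x w binary (0/1) matrix in texture layout (row 1 =
#'   image top).
#' @param views list of [view_projection()]s.
#' @return A list of `binary_view` objects, each with `img` (0/1 matrix),
#'   the rasterization record and its view.
#' @export
render_binary_views <- function(mesh, binary_tex, views) {
  if (is.null(mesh$uv)) stop("mesh has no UV coordinates")
  th <- nrow(binary_tex); tw <- ncol(binary_tex)
  corner_uv <- mesh$uv
  lapply(views, function(view) {
    ras <- render_mesh_view(mesh, view)
    hit <- which(ras$face > 0L)
    img <- matrix(0, nrow(ras$face), ncol(ras$face))
    if (length(hit)) {
      i0 <- (ras$face[hit] - 1L) * 3L
      u <- ras$b1[hit] * corner_uv[i0 + 1L, 1] +
           ras$b2[hit] * corner_uv[i0 + 2L, 1] +
           ras$b3[hit] * corner_uv[i0 + 3L, 1]
      v <- ras$b1[hit] * corner_uv[i0 + 1L, 2] +
           ras$b2[hit] * corner_uv[i0 + 2L, 2] +
           ras$b3[hit] * corner_uv[i0 + 3L, 2]
      u <- u %% 1
      col <- pmin(tw, pmax(1L, ceiling(u * tw)))
      row <- pmin(th, pmax(1L, ceiling((1 - v) * th)))
      img[hit] <- binary_tex[cbind(row, col)]
    }
    structure(c(list(img = img), ras), class = "binary_view")
  })
}
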