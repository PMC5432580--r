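#' @section Synthetic fixtures:
#' The synthetic module generates every input the pipeline consumes, with
#' machine-readable ground truth: a head-like closed surface with rigid
#' facial features, a UV-mapped texture with painted circular electrode
#' patches, an MRI-like volume voxelized from the same head, chroma-key
#' photographs, and noise/perturbation generators.
#' @name synthetic
NULL

icosphere <- function(n_subdiv = 3L) {
  p <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  p, 0), c(1,  p, 0), c(-1, -p, 0), c(1, -p, 0),
    c(0, -1,  p), c(0, 1,  p), c(0, -1, -p), c(0, 1, -p),
    c( p, 0, -1), c(p, 0, 1), c(-p, 0, -1), c(-p, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(n_subdiv)) {
    edge_mid <- new.env(hash = TRUE)
    nv <- nrow(v)
    verts <- vector("list", 0)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- edge_mid[[key]]
      if (!is.null(id)) return(id)
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts[[length(verts) + 1L]] <<- m
      id <- nv + length(verts)
      edge_mid[[key]] <- id
      id
    }
    newf <- matrix(0L, 4L * nrow(f), 3L)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newf[(k - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                           c(c, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, verts))
    f <- newf
  }
  list(vertices = v, faces = f)
}

ang_bump <- function(u, center, amp, sigma_az, sigma_el = sigma_az) {
  # anisotropic angular Gaussian on the sphere; az = horizontal tangent,
  # el = vertical tangent at the bump centre
  center <- center / sqrt(sum(center^2))
  up <- c(0, 0, 1)
  e_az <- c(center[2] * up[3] - center[3] * up[2],
            center[3] * up[1] - center[1] * up[3],
            center[1] * up[2] - center[2] * up[1])
  n_az <- sqrt(sum(e_az^2))
  if (n_az < 1e-9) e_az <- c(1, 0, 0) else e_az <- e_az / n_az
  e_el <- c(e_az[2] * center[3] - e_az[3] * center[2],
            e_az[3] * center[1] - e_az[1] * center[3],
            e_az[1] * center[2] - e_az[2] * center[1])
  d <- sweep(u, 2L, center)
  t_az <- d %*% e_az
  t_el <- d %*% e_el
  t_rad <- d %*% center
  # suppress the antipodal lobe
  amp * exp(-(t_az^2 / (2 * sigma_az^2) + t_el^2 / (2 * sigma_el^2))) *
    (t_rad > -1)
}

head_radius_field <- function(u, params) {
  # radial distance (mm) of the head surface along unit directions u
  u <- as_points(u)
  a <- params$axes
  r <- 1 / sqrt((u[, 1] / a[1])^2 + (u[, 2] / a[2])^2 + (u[, 3] / a[3])^2)
  for (b in params$bumps)
    r <- r + ang_bump(u, b$center, b$amp, b$sigma_az, b$sigma_el)
  as.numeric(r)
}

default_head_params <- function(seed = 1L) {
  jit <- with_seed(seed * 7757L + 11L, stats::runif(5, 0.92, 1.08))
  bumps <- list(
    list(center = c(0, 0.97, -0.26), amp = 24 * jit[1],
         sigma_az = 0.11, sigma_el = 0.26),                       # nose ridge
    list(center = c(0, 0.95, 0.30), amp = 7 * jit[2],
         sigma_az = 0.45, sigma_el = 0.12),                       # brow
    list(center = c(0.45, 0.85, -0.17), amp = 8 * jit[3],
         sigma_az = 0.20, sigma_el = 0.20),                       # cheekbone R
    list(center = c(-0.45, 0.85, -0.17), amp = 8 * jit[3],
         sigma_az = 0.20, sigma_el = 0.20),                       # cheekbone L
    list(center = c(0, 0.90, -0.55), amp = 9 * jit[4],
         sigma_az = 0.22, sigma_el = 0.20))                       # chin
  # smooth seeded lumps away from the face keep heads individual
  lumps <- with_seed(seed * 7757L + 29L, {
    n <- 10L
    dirs <- matrix(stats::rnorm(3 * n), n, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    amps <- stats::rnorm(n, 0, 1.3)
    list(dirs = dirs, amps = amps)
  })
  for (k in seq_along(lumps$amps)) {
    d <- lumps$dirs[k, ]
    if (d[2] > 0.45) next  # keep the facial region feature-stable
    bumps[[length(bumps) + 1L]] <- list(center = d, amp = lumps$amps[k],
                                        sigma_az = 0.45, sigma_el = 0.45)
  }
  list(axes = c(78, 96, 92) * with_seed(seed * 7757L + 3L,
                                        stats::runif(3, 0.96, 1.04)),
       bumps = bumps)
}

sphere_uv <- function(u) {
  # seam at azimuth 189 deg (posterior, rotated off the midline so no
  # electrode column of the canonical layout straddles it)
  ang <- atan2(u[, 1], u[, 2]) - pi / 20
  cbind((ang / (2 * pi) + 0.5) %% 1,
        1 - acos(pmin(1, pmax(-1, u[, 3]))) / pi)
}

#' Generate a synthetic textured head with known ground truth
#'
#' Builds a closed, watertight head-like surface by radially displacing a
#' subdivided icosahedron: an ellipsoidal base (roughly 78 x 96 x 92 mm
#' semi-axes, anterior = +y, vertex = +z) with a protruding nose ridge,
#' brow bulge, cheekbone bulges and chin — the rigid features surface
#' matching relies on — plus smooth seeded lumps outside the facial region
#' so heads differ between seeds. Deterministic per seed.
#'
#' @param seed integer seed controlling head individuality.
#' @param n_subdiv icosphere subdivision level (4 gives 2562 vertices).
#' @param frame_id frame tag for the mesh (default `"model"`).
#' @return A list of class `synthetic_head` with elements `mesh`
#'   (a [textured_mesh()] with UV coordinates but no texture yet),
#'   `fiducials` (3 x 3 matrix, rows nasion/LPA/RPA, mm), `facial_indices`
#'   (vertex indices of the rigid facial segment), `params` (the radial
#'   field parameters), and `up`/`anterior` unit axes.
#' @export
make_head <- function(seed = 1L, n_subdiv = 4L, frame_id = "model") {
  ico <- icosphere(n_subdiv)
  u <- ico$vertices
  params <- default_head_params(seed)
  r <- head_radius_field(u, params)
  verts <- u * r
  uv_vert <- sphere_uv(u)
  faces <- ico$faces
  # per-corner UV with seam unwrap (faces crossing u = 0/1 get u shifted +1)
  uv <- uv_vert[t(faces), , drop = FALSE]
  for (f in seq_len(nrow(faces))) {
    idx <- (f - 1L) * 3L + 1:3
    uu <- uv[idx, 1]
    if (max(uu) - min(uu) > 0.5)
      uv[idx, 1] <- ifelse(uu < 0.5, uu + 1, uu)
  }
  mesh <- textured_mesh(verts, faces, uv = uv, frame_id = frame_id)
  fid_dirs <- rbind(nasion = c(0, 0.995, 0.10),
                    LPA = c(-1, 0.02, -0.12),
                    RPA = c(1, 0.02, -0.12))
  fid_dirs <- fid_dirs / sqrt(rowSums(fid_dirs^2))
  fiducials <- fid_dirs * head_radius_field(fid_dirs, params)
  facial_indices <- which(u[, 2] > 0.60 & u[, 3] > -0.45 & u[, 3] < 0.55)
  structure(list(mesh = mesh, fiducials = fiducials,
                 facial_indices = facial_indices, params = params,
                 up = c(0, 0, 1), anterior = c(0, 1, 0), seed = seed),
            class = "synthetic_head")
}

#' @export
print.synthetic_head <- function(x, ...) {
  cat(sprintf("<synthetic_head: seed %d, %d vertices, %d facial-segment vertices>\n",
              x$seed, nrow(x$mesh$vertices), length(x$facial_indices)))
  invisible(x)
}

slerp <- function(a, b, f) {
  w <- acos(pmin(1, pmax(-1, sum(a * b))))
  if (w < 1e-12) return(a)
  (sin((1 - f) * w) * a + sin(f * w) * b) / sin(w)
}

dir_from_angles <- function(theta_deg, phi_deg) {
  th <- theta_deg * pi / 180
  ph <- phi_deg * pi / 180
  c(sin(th) * sin(ph), sin(th) * cos(ph), cos(th))
}

layout_68_directions <- function() {
  rows <- list(
    list(mid = "Fpz", midline = c(72, 0), end = c(72, 18),
         left = "Fp1", right = "Fp2", fr = 1),
    list(mid = NA, midline = c(54, 0), end = c(72, 36),
         left = c("AF3", "AF7"), right = c("AF4", "AF8"), fr = c(0.5, 1)),
    list(mid = "Fz", midline = c(36, 0), end = c(72, 54),
         left = c("F1", "F3", "F5", "F7"), right = c("F2", "F4", "F6", "F8"),
         fr = c(0.25, 0.5, 0.75, 1)),
    list(mid = "FCz", midline = c(18, 0), end = c(72, 72),
         left = c("FC1", "FC3", "FC5", "FT7"),
         right = c("FC2", "FC4", "FC6", "FT8"), fr = c(0.25, 0.5, 0.75, 1)),
    list(mid = "Cz", midline = c(0, 0), end = c(72, 90),
         left = c("C1", "C3", "C5", "T7"), right = c("C2", "C4", "C6", "T8"),
         fr = c(0.25, 0.5, 0.75, 1)),
    list(mid = "CPz", midline = c(18, 180), end = c(72, 108),
         left = c("CP1", "CP3", "CP5", "TP7"),
         right = c("CP2", "CP4", "CP6", "TP8"), fr = c(0.25, 0.5, 0.75, 1)),
    list(mid = "Pz", midline = c(36, 180), end = c(72, 126),
         left = c("P1", "P3", "P5", "P7"), right = c("P2", "P4", "P6", "P8"),
         fr = c(0.25, 0.5, 0.75, 1)),
    list(mid = "POz", midline = c(54, 180), end = c(72, 144),
         left = c("PO3", "PO7"), right = c("PO4", "PO8"), fr = c(0.5, 1)),
    list(mid = "Oz", midline = c(72, 180), end = c(72, 162),
         left = "O1", right = "O2", fr = 1))
  labels <- character(0)
  dirs <- NULL
  for (row in rows) {
    m <- dir_from_angles(row$midline[1], row$midline[2])
    eR <- dir_from_angles(row$end[1], row$end[2])
    eL <- dir_from_angles(row$end[1], -row$end[2])
    if (!is.na(row$mid)) {
      labels <- c(labels, row$mid)
      dirs <- rbind(dirs, m)
    }
    for (k in seq_along(row$fr)) {
      labels <- c(labels, row$left[k], row$right[k])
      dirs <- rbind(dirs, slerp(m, eL, row$fr[k]), slerp(m, eR, row$fr[k]))
    }
  }
  # inferior 9/10 row on the equator band
  extra <- rbind(F9 = c(90, -54), F10 = c(90, 54),
                 FT9 = c(90, -72), FT10 = c(90, 72),
                 TP9 = c(90, -108), TP10 = c(90, 108),
                 P9 = c(90, -126), P10 = c(90, 126))
  for (k in seq_len(nrow(extra))) {
    labels <- c(labels, rownames(extra)[k])
    dirs <- rbind(dirs, dir_from_angles(extra[k, 1], extra[k, 2]))
  }
  rownames(dirs) <- labels
  dirs
}

#' Canonical 68-electrode cap layout
#'
#' A 10-10-style layout of 68 uniquely labeled positions on the upper head
#' (rows Fp through O plus an inferior 9/10 row), with `Fpz` and `Oz` the
#' extreme anterior/posterior midsagittal electrodes. Positions are placed
#' on a synthetic head surface when one is supplied, otherwise on a 92 mm
#' sphere.
#'
#' @param head optional [make_head()] result; electrodes are placed on its
#'   surface.
#' @return A labeled [electrode_set()].
#' @export
standard_layout_68 <- function(head = NULL) {
  dirs <- layout_68_directions()
  if (is.null(head)) {
    pts <- dirs * 92
    frame <- "canonical"
  } else {
    pts <- dirs * head_radius_field(dirs, head$params)
    frame <- head$mesh$frame_id
  }
  electrode_set(pts, rownames(dirs), frame_id = frame)
}

#' Paint circular electrode patches into a head texture
#'
#' Renders the mesh into texture space to obtain a per-texel 3D position
#' map, then paints a filled disc of `radius_mm` (surface distance, so
#' discs stay circular on the surface) around each electrode's surface
#' projection. The rest of the texture gets the cap background color.
#'
#' @param head a [make_head()] result or a [textured_mesh()] with UV.
#' @param layout an [electrode_set()] of positions on/near the surface.
#' @param radius_mm electrode patch radius (mm).
#' @param fg_color,bg_color length-3 RGB in \[0,1\] for patches and cap.
#' @param texture_size `c(height, width)` of the generated texture.
#' @return A list with `mesh` (textured), `centers` (ground-truth 3D disc
#'   centers on the mesh surface, an `electrode_set`), and `layout`.
#' @export
paint_electrodes <- function(head, layout, radius_mm = 4,
                             fg_color = c(0.96, 0.96, 0.96),
                             bg_color = c(0.10, 0.10, 0.14),
                             texture_size = c(1024, 2048)) {
  mesh <- if (inherits(head, "synthetic_head")) head$mesh else head
  if (is.null(mesh$uv)) stop("mesh has no UV coordinates")
  H <- texture_size[1]; W <- texture_size[2]
  pos <- texture_position_map(mesh, W, H)
  tex <- array(rep(bg_color, each = H * W), dim = c(H, W, 3))
  centers <- matrix(numeric(0), 0L, 3L)
  if (length(layout) > 0) {
    cp <- .closest_on_mesh(layout$points, mesh$vertices, mesh$faces)
    centers <- cp$point
    valid <- !is.na(pos$x)
    px <- pos$x[valid]; py <- pos$y[valid]; pz <- pos$z[valid]
    lin <- which(valid)
    for (e in seq_len(nrow(centers))) {
      d2 <- (px - centers[e, 1])^2 + (py - centers[e, 2])^2 +
            (pz - centers[e, 3])^2
      hit <- lin[d2 <= radius_mm^2]
      for (ch in 1:3) tex[hit + (ch - 1L) * H * W] <- fg_color[ch]
    }
    dd <- as.matrix(stats::dist(centers))
    diag(dd) <- Inf
    if (any(dd < 2 * radius_mm))
      warning("electrode discs overlap (centers closer than 2 * radius_mm)")
  }
  mesh$texture <- tex
  list(mesh = mesh,
       centers = electrode_set(centers, layout$labels,
                               frame_id = mesh$frame_id),
       layout = layout)
}

# Rasterize mesh faces into texture space; returns per-texel interpolated
# 3D positions (NA on unmapped texels). Handles the seam by re-rasterizing
# wrap-around faces shifted one texture width left.
texture_position_map <- function(mesh, W, H) {
  uv <- mesh$uv
  xy <- cbind(uv[, 1] * W, (1 - uv[, 2]) * H)
  nf <- nrow(mesh$faces)
  corner_xyz <- mesh$vertices[t(mesh$faces), , drop = FALSE]
  wrap <- which(tapply(xy[, 1], rep(seq_len(nf), each = 3L), max) > W)
  if (length(wrap)) {
    extra_idx <- as.integer(t(outer(wrap - 1L, 1:3, function(a, b) a * 3L + b)))
    xy <- rbind(xy, cbind(xy[extra_idx, 1] - W, xy[extra_idx, 2]))
    corner_xyz <- rbind(corner_xyz, corner_xyz[extra_idx, , drop = FALSE])
    nf_all <- nf + length(wrap)
  } else nf_all <- nf
  ras <- .rasterize_corners(xy, rep(0, nrow(xy)), nf_all, W, H)
  fa <- ras$face
  mapped <- fa > 0L
  i0 <- (fa[mapped] - 1L) * 3L
  b1 <- ras$b1[mapped]; b2 <- ras$b2[mapped]; b3 <- ras$b3[mapped]
  out <- list(x = matrix(NA_real_, H, W), y = matrix(NA_real_, H, W),
              z = matrix(NA_real_, H, W))
  for (k in 1:3) {
    vals <- b1 * corner_xyz[i0 + 1L, k] + b2 * corner_xyz[i0 + 2L, k] +
            b3 * corner_xyz[i0 + 3L, k]
    out[[k]][mapped] <- vals
  }
  out
}

#' Voxelize a head mesh into an MRI-like volume
#'
#' Fills the closed head surface into a voxel grid (parity ray casting),
#' scales interior intensity to ~100, smooths by `smooth_mm`, and places
#' the volume in a world frame rigidly offset from the mesh frame by a
#' known transform (returned, so ground truth carries over exactly).
#'
#' @param head a [make_head()] result or closed `textured_mesh`.
#' @param smooth_mm Gaussian smoothing of the intensity volume (mm).
#' @param voxel_mm isotropic voxel size (mm).
#' @param offset optional rigid [head_transform()] from mesh frame to the
#'   volume's world frame; a small fixed rotation + translation by default.
#' @return A list with `volume` (a [head_volume()]), `transform` (mesh
#'   frame to volume world frame) and `fiducials_world` when the input
#'   carries fiducials.
#' @export
make_mri_like <- function(head, smooth_mm = 1, voxel_mm = 2, offset = NULL) {
  mesh <- if (inherits(head, "synthetic_head")) head$mesh else head
  if (is.null(offset))
    offset <- head_transform(rotation_xyz(0.04, -0.03, 0.05), c(4, -3, 7),
                             kind = "rigid", from_frame = mesh$frame_id,
                             to_frame = "mri")
  margin <- 4 * voxel_mm
  lo <- apply(mesh$vertices, 2L, min) - margin
  hi <- apply(mesh$vertices, 2L, max) + margin
  dims <- as.integer(ceiling((hi - lo) / voxel_mm)) + 1L
  vox_verts <- sweep(mesh$vertices, 2L, lo) / voxel_mm
  occ <- .voxelize_mesh(vox_verts, mesh$faces, dims[1], dims[2], dims[3])
  vol <- array(as.numeric(occ) * 100, dim = dims)
  if (smooth_mm > 0)
    vol <- .gauss_smooth3d(vol, smooth_mm / voxel_mm)
  # voxel (i,j,k) 0-based maps to world via the rigid offset of mesh coords
  A_mesh <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  A_mesh[1:3, 4] <- lo
  M_off <- transform_matrix(offset)
  affine <- M_off %*% A_mesh
  out <- list(volume = head_volume(vol, affine), transform = offset)
  if (inherits(head, "synthetic_head"))
    out$fiducials_world <- apply_transform_mat(offset, head$fiducials)
  out
}

#' Render a synthetic chroma-key photograph of a head
#'
#' Orthographic Lambertian render of the (untextured) head surface over a
#' uniform key-color background, plus the exact silhouette mask.
#'
#' @param head a [make_head()] result or `textured_mesh`.
#' @param view a [view_projection()]; a frontal default is derived from the
#'   mesh when omitted.
#' @param key_color RGB background color (default chroma green).
#' @return A list with `photo` (h x w x 3 array) and `silhouette`
#'   (logical h x w matrix, TRUE = object).
#' @export
make_chroma_photo <- function(head, view = NULL,
                              key_color = c(0.00, 0.72, 0.15)) {
  mesh <- if (inherits(head, "synthetic_head")) head$mesh else head
  if (is.null(view))
    view <- view_projection(direction = c(0, -1, 0), up = c(0, 0, 1),
                            pixel_pitch = 1,
                            center = colMeans(mesh$vertices),
                            raster_size = c(256, 256))
  ras <- render_mesh_view(mesh, view)
  H <- nrow(ras$face); W <- ncol(ras$face)
  sil <- ras$face > 0L
  # per-pixel face normals, headlamp shading
  fn <- face_normals(mesh)
  img <- array(rep(key_color, each = H * W), dim = c(H, W, 3))
  hit <- which(sil)
  if (length(hit)) {
    nrm <- fn[ras$face[hit], , drop = FALSE]
    lambert <- pmax(0, -(nrm %*% view$direction))
    shade <- 0.25 + 0.65 * lambert
    skin <- c(0.85, 0.72, 0.62)
    for (ch in 1:3) img[hit + (ch - 1L) * H * W] <- skin[ch] * shade
  }
  list(photo = img, silhouette = sil)
}

face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], ] - v[f[, 1], ]
  e2 <- v[f[, 3], ] - v[f[, 1], ]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  n <- n / pmax(len, 1e-12)
  # orient outward for star-shaped meshes
  ctr <- colMeans(v)
  mid <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  flip <- rowSums(n * sweep(mid, 2L, ctr)) < 0
  n[flip, ] <- -n[flip, ]
  n
}

#' Displace electrodes with isotropic Gaussian jitter
#'
#' @param set an [electrode_set()].
#' @param sigma_mm noise standard deviation per axis (mm).
#' @param seed integer seed (reproducible draw).
#' @return A jittered `electrode_set`.
#' @export
jitter_electrodes <- function(set, sigma_mm, seed = NULL) {
  stopifnot(inherits(set, "electrode_set"), sigma_mm >= 0)
  if (sigma_mm == 0) return(set)
  n <- nrow(set$points)
  noise <- if (is.null(seed)) stats::rnorm(3 * n, 0, sigma_mm) else
    with_seed(seed, stats::rnorm(3 * n, 0, sigma_mm))
  set$points <- set$points + matrix(noise, n, 3)
  set
}
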