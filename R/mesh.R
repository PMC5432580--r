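#' Textured triangular mesh
#'
#' Container for a closed triangular head surface with an optional UV-mapped
#' texture. Vertices are in millimetres. Faces index vertices 1-based. UV
#' coordinates are stored per face corner (row `(f - 1) * 3 + corner` of
#' `uv`) with the V axis measured from the *bottom* of the texture image,
#' the Wavefront OBJ convention; textures are stored as arrays in the
#' [png::readPNG()] layout (row 1 = top of the image).
#'
#' @param vertices n x 3 numeric matrix (mm), n >= 4.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param uv optional (3 m) x 2 matrix of per-face-corner UV coordinates.
#' @param texture optional texture raster: h x w matrix (grayscale) or
#'   h x w x 3 array (RGB), values in \[0, 1\].
#' @param frame_id optional free-text coordinate-frame tag.
#' @return An object of class `textured_mesh`.
#' @export
textured_mesh <- function(vertices, faces, uv = NULL, texture = NULL,
                          frame_id = NULL) {
  vertices <- as_points(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L) stop("faces must be m x 3 triangles")
  if (nrow(vertices) < 4L) stop("mesh needs at least 4 vertices")
  if (any(!is.finite(vertices))) stop("mesh vertices contain NaN/Inf")
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  if (!is.null(uv)) {
    uv <- as.matrix(uv)
    storage.mode(uv) <- "double"
    if (nrow(uv) != 3L * nrow(faces) || ncol(uv) != 2L)
      stop("uv must have one 2D row per face corner")
  }
  if (!is.null(texture) && is.null(uv))
    stop("textured mesh requires per-corner uv coordinates")
  structure(list(vertices = vertices, faces = faces, uv = uv,
                 texture = texture, frame_id = frame_id),
            class = "textured_mesh")
}

#' @export
print.textured_mesh <- function(x, ...) {
  cat(sprintf("<textured_mesh: %d vertices, %d faces%s%s>\n",
              nrow(x$vertices), nrow(x$faces),
              if (!is.null(x$texture)) sprintf(", texture %dx%d",
                                               dim(x$texture)[2], dim(x$texture)[1]) else "",
              if (!is.null(x$frame_id)) paste0(", frame ", x$frame_id) else ""))
  invisible(x)
}

#' Labeled or unlabeled electrode positions
#'
#' @param points n x 3 numeric matrix of positions (mm).
#' @param labels optional character vector of unique labels, one per point.
#' @param frame_id optional coordinate-frame tag.
#' @return An object of class `electrode_set`.
#' @export
electrode_set <- function(points, labels = NULL, frame_id = NULL) {
  points <- as_points(points)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(points))
      stop("labels must match the number of points")
    if (anyDuplicated(labels))
      stop("duplicate electrode labels: ",
           paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  structure(list(points = points, labels = labels, frame_id = frame_id),
            class = "electrode_set")
}

#' @export
print.electrode_set <- function(x, ...) {
  cat(sprintf("<electrode_set: %d points%s%s>\n", nrow(x$points),
              if (!is.null(x$labels)) ", labeled" else "",
              if (!is.null(x$frame_id)) paste0(", frame ", x$frame_id) else ""))
  invisible(x)
}

#' @export
length.electrode_set <- function(x) nrow(x$points)

#' Read a Wavefront OBJ mesh (with optional texture)
#'
#' Parses `v`, `vt` and `f` records. Quad and larger faces are fan
#' triangulated from the first corner. The texture is located through the
#' `mtllib`/`map_Kd` chain or, failing that, a sibling PNG named like the
#' OBJ; if faces reference `vt` records but no texture image can be read, a
#' warning is emitted and the mesh is returned untextured.
#'
#' @param path path to an `.obj` file.
#' @param frame_id optional frame tag for the result.
#' @return A [textured_mesh()].
#' @export
read_textured_mesh <- function(path, frame_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  toks <- strsplit(trimws(lines), "[ \t]+")
  key <- vapply(toks, function(t) if (length(t)) t[[1]] else "", "")

  parse_num <- function(idx, what, nmin) {
    out <- lapply(idx, function(i) {
      v <- suppressWarnings(as.numeric(toks[[i]][-1]))
      if (length(v) < nmin || anyNA(v[seq_len(nmin)]))
        stop(sprintf("malformed %s record at line %d: '%s'", what, i, lines[i]))
      v[seq_len(nmin)]
    })
    do.call(rbind, out)
  }
  vi <- which(key == "v")
  if (!length(vi)) stop("no vertex records in ", path)
  verts <- parse_num(vi, "vertex", 3L)
  ti <- which(key == "vt")
  vts <- if (length(ti)) parse_num(ti, "texture-coordinate", 2L) else NULL

  fi <- which(key == "f")
  faces <- list(); fuv <- list(); has_vt <- FALSE
  for (i in fi) {
    corners <- toks[[i]][-1]
    if (length(corners) < 3L)
      stop(sprintf("malformed face record at line %d: '%s'", i, lines[i]))
    parts <- strsplit(corners, "/", fixed = TRUE)
    v_idx <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    t_idx <- suppressWarnings(as.integer(vapply(parts, function(p)
      if (length(p) >= 2L && nzchar(p[2])) p[2] else NA_character_, "")))
    if (anyNA(v_idx))
      stop(sprintf("malformed face record at line %d: '%s'", i, lines[i]))
    v_idx <- ifelse(v_idx < 0L, nrow(verts) + v_idx + 1L, v_idx)
    if (any(v_idx < 1L | v_idx > nrow(verts)))
      stop(sprintf("face index out of range at line %d: '%s'", i, lines[i]))
    if (any(!is.na(t_idx))) has_vt <- TRUE
    # fan triangulation from the first corner
    for (k in seq_len(length(v_idx) - 2L)) {
      faces[[length(faces) + 1L]] <- v_idx[c(1L, k + 1L, k + 2L)]
      fuv[[length(fuv) + 1L]] <- t_idx[c(1L, k + 1L, k + 2L)]
    }
  }
  faces <- do.call(rbind, faces)

  texture <- NULL
  uv <- NULL
  if (has_vt && !is.null(vts)) {
    tidx <- do.call(rbind, fuv)
    if (anyNA(tidx)) {
      warning("mixed textured/untextured faces; dropping texture coordinates")
    } else {
      if (min(tidx) < 1L || max(tidx) > nrow(vts))
        stop("texture-coordinate index out of range")
      uv <- vts[t(tidx), , drop = FALSE]
      tex_path <- find_obj_texture(path, lines, key, toks)
      if (!is.null(tex_path)) {
        texture <- read_raster(tex_path)
      } else if (any(key == "mtllib")) {
        # a material library was declared but its image is unresolvable;
        # UV-only meshes without materials stay silent
        warning("faces carry texture coordinates but no texture image was ",
                "found; returning untextured mesh")
      }
    }
  }
  textured_mesh(verts, faces, uv = uv, texture = texture, frame_id = frame_id)
}

find_obj_texture <- function(path, lines, key, toks) {
  dir <- dirname(path)
  mtl <- which(key == "mtllib")
  if (length(mtl)) {
    mtl_path <- file.path(dir, paste(toks[[mtl[1]]][-1], collapse = " "))
    if (file.exists(mtl_path)) {
      ml <- readLines(mtl_path, warn = FALSE)
      map <- grep("^\\s*map_Kd\\s+", ml, value = TRUE)
      if (length(map)) {
        tex <- file.path(dir, sub("^\\s*map_Kd\\s+", "", map[1]))
        if (file.exists(tex)) return(tex)
      }
    }
  }
  sib <- file.path(dir, paste0(tools::file_path_sans_ext(basename(path)), ".png"))
  if (file.exists(sib)) sib else NULL
}

read_raster <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L && dim(img)[3] >= 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write a mesh as Wavefront OBJ (+ MTL + PNG texture)
#'
#' Emits one `vt` record per face corner; output bytes are deterministic for
#' a fixed mesh. A textured mesh additionally produces `<stem>.mtl` and
#' `<stem>_texture.png` next to the OBJ.
#'
#' @param mesh a [textured_mesh()].
#' @param path output `.obj` path.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "textured_mesh"))
  if (nrow(mesh$vertices) == 0L) stop("refusing to write an empty mesh")
  stem <- tools::file_path_sans_ext(basename(path))
  dir <- dirname(path)
  con <- file(path, open = "wb")
  on.exit(close(con))
  wl <- function(x) writeLines(x, con, sep = "\n")
  wl("# headgeo OBJ export")
  if (!is.null(mesh$texture)) {
    mtl <- file.path(dir, paste0(stem, ".mtl"))
    tex <- paste0(stem, "_texture.png")
    wl(paste("mtllib", basename(mtl)))
    writeLines(c("newmtl material_0", paste("map_Kd", tex)), mtl)
    img <- mesh$texture
    png::writePNG(img, file.path(dir, tex))
  }
  wl(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1], mesh$vertices[, 2],
             mesh$vertices[, 3]))
  if (!is.null(mesh$uv)) {
    wl(sprintf("vt %.9g %.9g", mesh$uv[, 1], mesh$uv[, 2]))
    n3 <- seq_len(nrow(mesh$faces))
    wl(sprintf("f %d/%d %d/%d %d/%d",
               mesh$faces[, 1], (n3 - 1L) * 3L + 1L,
               mesh$faces[, 2], (n3 - 1L) * 3L + 2L,
               mesh$faces[, 3], (n3 - 1L) * 3L + 3L))
  } else {
    wl(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]))
  }
  invisible(path)
}

#' Read / write electrode coordinate files
#'
#' Plain-text format: one electrode per line, either `label x y z` or
#' `x y z`, whitespace or comma separated; `#` starts a comment.
#' Coordinates are millimetres.
#'
#' @param path file path.
#' @param frame_id optional frame tag for the result.
#' @return `read_electrodes()`: an [electrode_set()]; `write_electrodes()`:
#'   `path` invisibly.
#' @export
read_electrodes <- function(path, frame_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) stop("no electrode records in ", path)
  toks <- strsplit(trimws(lines[keep]), "[ \t,]+")
  n_tok <- lengths(toks)
  labeled <- n_tok == 4L
  if (!all(n_tok %in% c(3L, 4L)) || (any(labeled) && !all(labeled)))
    stop("electrode lines must consistently be 'label x y z' or 'x y z'")
  pts <- matrix(NA_real_, length(keep), 3L)
  labels <- if (all(labeled)) character(length(keep)) else NULL
  for (i in seq_along(keep)) {
    t <- toks[[i]]
    xyz <- suppressWarnings(as.numeric(t[(n_tok[i] - 2L):n_tok[i]]))
    if (anyNA(xyz))
      stop(sprintf("non-numeric coordinate at line %d: '%s'",
                   keep[i], trimws(lines[keep[i]])))
    pts[i, ] <- xyz
    if (!is.null(labels)) labels[i] <- t[1]
  }
  electrode_set(pts, labels, frame_id = frame_id)
}

#' @rdname read_electrodes
#' @param set an [electrode_set()].
#' @export
write_electrodes <- function(set, path) {
  stopifnot(inherits(set, "electrode_set"))
  if (is.null(set$labels)) {
    lines <- sprintf("%.9g %.9g %.9g", set$points[, 1], set$points[, 2],
                     set$points[, 3])
  } else {
    lines <- sprintf("%s %.9g %.9g %.9g", set$labels, set$points[, 1],
                     set$points[, 2], set$points[, 3])
  }
  writeLines(lines, path)
  invisible(path)
}

#' Check whether a mesh is watertight
#'
#' A closed orientable triangle mesh has every undirected edge shared by
#' exactly two faces.
#' @param mesh a [textured_mesh()].
#' @return Logical scalar.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}
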