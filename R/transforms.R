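#' Similarity and affine spatial transforms
#'
#' A `head_transform` maps 3D points from one coordinate frame into another
#' as `y = s * A x + t`. For `kind = "rigid"` and `kind = "similarity"`,
#' `A` is a proper rotation (orthonormal, det +1); for `kind = "affine"`,
#' `A` is any invertible 3x3 matrix with positive determinant and `s` is
#' fixed at 1. All translations are in millimetres.
#'
#' @param rotation 3x3 matrix: rotation (rigid/similarity) or general linear
#'   part (affine).
#' @param translation numeric length-3 translation (mm).
#' @param scale positive isotropic scale factor (ignored for affine).
#' @param kind one of `"rigid"`, `"similarity"`, `"affine"`.
#' @param from_frame,to_frame optional free-text frame tags carried through
#'   [apply_transform()] to catch frame mixing.
#' @return An object of class `head_transform`.
#' @export
head_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                           scale = 1, kind = c("rigid", "similarity", "affine"),
                           from_frame = NULL, to_frame = NULL) {
  kind <- match.arg(kind)
  rotation <- unname(as.matrix(rotation))
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (any(!is.finite(rotation)) || any(!is.finite(translation)))
    stop("non-finite transform components")
  if (kind == "affine") {
    if (det(rotation) <= 0) stop("affine linear part must have positive determinant")
    scale <- 1
  } else {
    if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
      stop("rotation must be orthonormal")
    if (det(rotation) < 0) stop("rotation must be proper (det +1), reflections rejected")
    if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
      stop("scale must be a positive scalar")
  }
  structure(list(rotation = rotation, translation = unname(as.numeric(translation)),
                 scale = as.numeric(scale), kind = kind,
                 from_frame = from_frame, to_frame = to_frame),
            class = "head_transform")
}

#' @export
print.head_transform <- function(x, ...) {
  cat(sprintf("<head_transform: %s", x$kind))
  if (!is.null(x$from_frame) || !is.null(x$to_frame))
    cat(sprintf(", %s -> %s", x$from_frame %||% "?", x$to_frame %||% "?"))
  cat(sprintf(">\n  scale %.6g, translation [%s] mm\n", x$scale,
              paste(sprintf("%.3f", x$translation), collapse = ", ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a transform to points, electrodes or a mesh
#'
#' @param transform a [head_transform()].
#' @param x an n x 3 numeric matrix of points, an `electrode_set`, or a
#'   `textured_mesh`.
#' @return The transformed object (same class as `x`); `frame_id` of sets
#'   and meshes is updated to the transform's `to_frame` when set.
#' @export
apply_transform <- function(transform, x) {
  stopifnot(inherits(transform, "head_transform"))
  if (inherits(x, "electrode_set")) {
    check_frame(transform, x$frame_id)
    x$points <- apply_transform_mat(transform, x$points)
    if (!is.null(transform$to_frame)) x$frame_id <- transform$to_frame
    return(x)
  }
  if (inherits(x, "textured_mesh")) {
    check_frame(transform, x$frame_id)
    x$vertices <- apply_transform_mat(transform, x$vertices)
    if (!is.null(transform$to_frame)) x$frame_id <- transform$to_frame
    return(x)
  }
  apply_transform_mat(transform, x)
}

apply_transform_mat <- function(transform, pts) {
  pts <- as_points(pts)
  sweep(pts %*% t(transform$scale * transform$rotation), 2L,
        transform$translation, "+")
}

check_frame <- function(transform, frame_id) {
  if (!is.null(transform$from_frame) && !is.null(frame_id) &&
      !identical(transform$from_frame, frame_id))
    warning(sprintf("transform expects frame '%s' but object is in frame '%s'",
                    transform$from_frame, frame_id))
  invisible(NULL)
}

as_points <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3L, byrow = TRUE)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop("points must be n x 3")
  x
}

#' Compose two transforms
#'
#' `compose_transforms(second, first)` returns the transform equivalent to
#' applying `first` and then `second`.
#' @param second,first [head_transform()] objects.
#' @return A `head_transform`; affine if either input is affine.
#' @export
compose_transforms <- function(second, first) {
  stopifnot(inherits(second, "head_transform"), inherits(first, "head_transform"))
  if (second$kind == "affine" || first$kind == "affine") {
    A <- (second$scale * second$rotation) %*% (first$scale * first$rotation)
    t <- (second$scale * second$rotation) %*% first$translation + second$translation
    return(head_transform(A, t, kind = "affine",
                          from_frame = first$from_frame, to_frame = second$to_frame))
  }
  kind <- if (second$scale * first$scale == 1 &&
              second$kind == "rigid" && first$kind == "rigid") "rigid" else "similarity"
  head_transform(second$rotation %*% first$rotation,
                 as.numeric(second$scale * second$rotation %*% first$translation +
                            second$translation),
                 second$scale * first$scale, kind = kind,
                 from_frame = first$from_frame, to_frame = second$to_frame)
}

#' Invert a transform
#' @param transform a [head_transform()].
#' @return The inverse `head_transform`.
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "head_transform"))
  if (transform$kind == "affine") {
    Ai <- solve(transform$rotation)
    return(head_transform(Ai, as.numeric(-Ai %*% transform$translation),
                          kind = "affine",
                          from_frame = transform$to_frame,
                          to_frame = transform$from_frame))
  }
  Rt <- t(transform$rotation)
  head_transform(Rt, as.numeric(-(1 / transform$scale) * Rt %*% transform$translation),
                 1 / transform$scale, kind = transform$kind,
                 from_frame = transform$to_frame, to_frame = transform$from_frame)
}

#' Convert a transform to / from a 4x4 homogeneous matrix
#' @param transform a [head_transform()].
#' @return `transform_matrix()`: a 4x4 matrix; `transform_from_matrix()`: a
#'   `head_transform` (kind detected from the linear part).
#' @export
transform_matrix <- function(transform) {
  M <- diag(4)
  M[1:3, 1:3] <- transform$scale * transform$rotation
  M[1:3, 4] <- transform$translation
  M
}

#' @rdname transform_matrix
#' @param M a 4x4 homogeneous matrix with last row (0,0,0,1).
#' @export
transform_from_matrix <- function(M) {
  M <- as.matrix(M)
  stopifnot(all(dim(M) == c(4L, 4L)))
  if (!isTRUE(all.equal(M[4, ], c(0, 0, 0, 1), tolerance = 1e-9)))
    stop("last row must be (0,0,0,1)")
  A <- M[1:3, 1:3]
  s <- det(A)
  if (s <= 0) return(head_transform(A, M[1:3, 4], kind = "affine"))
  s <- s^(1 / 3)
  R <- A / s
  if (max(abs(crossprod(R) - diag(3))) <= 1e-6) {
    kind <- if (abs(s - 1) < 1e-12) "rigid" else "similarity"
    head_transform(R, M[1:3, 4], s, kind = kind)
  } else {
    head_transform(A, M[1:3, 4], kind = "affine")
  }
}

#' Read / write a transform as JSON
#'
#' Serializes the 4x4 homogeneous matrix, kind and frame tags.
#' @param transform a [head_transform()].
#' @param path file path.
#' @return `write_transform()` returns `path` invisibly; `read_transform()`
#'   a `head_transform`.
#' @export
write_transform <- function(transform, path) {
  obj <- list(matrix = transform_matrix(transform), kind = transform$kind,
              from_frame = transform$from_frame, to_frame = transform$to_frame)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- transform_from_matrix(obj$matrix)
  tr$from_frame <- obj$from_frame
  tr$to_frame <- obj$to_frame
  tr
}

rotation_xyz <- function(ax, ay, az) {
  # R = Rz %*% Ry %*% Rx, angles in radians
  cx <- cos(ax); sx <- sin(ax)
  cy <- cos(ay); sy <- sin(ay)
  cz <- cos(az); sz <- sin(az)
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Draw a random similarity transform
#'
#' Samples the perturbations used in the coregistration-error simulation:
#' per-axis rotation angles uniform on \[1, 360\] degrees (composed as
#' `Rz Ry Rx`), per-axis translations uniform on \[1, 100\] mm, and an
#' isotropic scale uniform on \[1, 5\].
#'
#' @param seed integer seed; the draw is reproducible for a fixed seed.
#' @param scale_range length-2 numeric; set to `c(1, 1)` for rigid-only
#'   perturbations (the fiducial workflow, where no arbitrary model scale
#'   exists).
#' @return A `head_transform` of kind `"similarity"` (or `"rigid"` when the
#'   scale range collapses to 1).
#' @export
random_similarity <- function(seed = NULL, scale_range = c(1, 5)) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(as.integer(seed))
  }
  ang <- stats::runif(3, 1, 360) * pi / 180
  tr <- stats::runif(3, 1, 100)
  s <- stats::runif(1, scale_range[1], scale_range[2])
  kind <- if (s == 1) "rigid" else "similarity"
  head_transform(rotation_xyz(ang[1], ang[2], ang[3]), tr, s, kind = kind)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Evaluate an expression under a temporary RNG seed
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`; the caller's RNG state is restored afterwards.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  expr
}
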