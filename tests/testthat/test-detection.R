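test_that("texture binarization separates discs from the cap background", {
  tex <- shared_painted()$mesh$texture
  b <- binarize_texture(tex)
  expect_true(all(b %in% c(0, 1)))
  comp <- EBImage::bwlabel(EBImage::Image(t(b)))
  expect_equal(max(comp), 68L)

  expect_error(binarize_texture(array(0, c(8, 8, 3))), "no contrast")
  # inverting the colors with the dark polarity recovers the same classes
  inv <- 1 - tex
  expect_equal(binarize_texture(inv, polarity = "dark"), b)
})

test_that("rendered binary views respect visibility and foreshortening", {
  ds <- disc_sphere(c(0, 0, 1))
  btex <- binarize_texture(ds$mesh$texture)
  mk_view <- function(dir) view_projection(dir, up = c(0, 1, 0),
                                           pixel_pitch = 0.5,
                                           center = c(0, 0, 0),
                                           raster_size = c(240, 240))
  front <- render_binary_views(ds$mesh, btex, list(mk_view(c(0, 0, -1))))[[1]]
  expect_gt(sum(front$img), 0)
  hit <- which(front$img > 0, arr.ind = TRUE)
  expect_lt(max(abs(colMeans(hit) - 120)), 2)  # blob centred in the raster

  behind <- render_binary_views(ds$mesh, btex, list(mk_view(c(0, 0, 1))))[[1]]
  expect_equal(sum(behind$img), 0)  # occluded by the sphere body
})

test_that("oblique viewing elongates a disc as the projection predicts", {
  ds <- disc_sphere(c(0, 0, 1))
  ang <- 60 * pi / 180
  dir <- -c(0, sin(ang), cos(ang))
  v <- view_projection(dir, up = c(0, 1, 0), pixel_pitch = 0.5,
                       center = c(0, 0, 0), raster_size = c(240, 240))
  btex <- binarize_texture(ds$mesh$texture)
  img <- render_binary_views(ds$mesh, btex, list(v))[[1]]$img
  hit <- which(img > 0, arr.ind = TRUE)
  spread <- apply(hit, 2, function(x) diff(range(x)))
  ecc <- max(spread) / min(spread)
  expect_gt(ecc, 1.3)  # cos(60 deg) = 0.5 foreshortening, minus curvature
})

test_that("degenerate views are rejected", {
  expect_error(view_projection(c(0, 0, 1), c(0, 1, 0), 0, c(0, 0, 0),
                               c(10, 10)), "pixel_pitch")
  expect_error(view_projection(c(0, 0, 1), c(0, 0, 2), 1, c(0, 0, 0),
                               c(10, 10)), "parallel")
})

test_that("Hough detection finds constructed discs to within a pixel", {
  expect_equal(nrow(detect_circles(matrix(0, 50, 50), 3, 10)), 0L)

  img <- raster_disc(120, 120, cx = 50, cy = 60, r = 10)
  d <- detect_circles(img, 5, 15)
  expect_equal(nrow(d), 1L)
  expect_lt(abs(d$x - 50), 1)
  expect_lt(abs(d$y - 60), 1)
  expect_lt(abs(d$r - 10), 1)

  img2 <- raster_disc(120, 120, 30, 40, 8) + raster_disc(120, 120, 70, 40, 8)
  d2 <- detect_circles(img2, 4, 12)
  expect_equal(nrow(d2), 2L)
  got <- d2[order(d2$x), ]
  expect_lt(max(abs(got$x - c(30, 70))), 1)
  expect_lt(max(abs(got$y - 40)), 1)
})

test_that("Hough detection is equivariant to image translation", {
  img <- raster_disc(100, 100, 40, 45, 9)
  base <- detect_circles(img, 4, 14)
  shifted <- raster_disc(100, 100, 52, 57, 9)
  d <- detect_circles(shifted, 4, 14)
  expect_equal(nrow(d), 1L)
  expect_equal(d$x - base$x, 12, tolerance = 0.5)
  expect_equal(d$y - base$y, 12, tolerance = 0.5)
  expect_equal(d$r, base$r, tolerance = 0.3)
})

test_that("back-projection inverts rendering on painted disc centers", {
  ds <- disc_sphere(c(0, 0, 1))
  v <- view_projection(c(0, 0, -1), up = c(0, 1, 0), pixel_pitch = 0.5,
                       center = c(0, 0, 0), raster_size = c(240, 240))
  btex <- binarize_texture(ds$mesh$texture)
  rv <- render_binary_views(ds$mesh, btex, list(v))[[1]]
  d <- detect_circles(rv$img, 6, 20)
  expect_gte(nrow(d), 1L)
  p3 <- backproject(d[1, ], rv, ds$mesh)
  expect_lt(sqrt(sum((p3 - ds$center)^2)), 2 * v$pixel_pitch)

  # a detection over background is dropped with a warning
  bg <- data.frame(x = 2, y = 2, r = 5, strength = 1)
  expect_warning(out <- backproject(bg, rv, ds$mesh), "dropped")
  expect_equal(nrow(out), 0L)
})

test_that("multi-view detection hits every painted electrode", {
  pe <- shared_painted()
  det <- shared_detected()
  nn <- nearest_neighbors(pe$centers$points, det$points)
  expect_gte(mean(nn$distance <= 2), 0.95)
})

test_that("candidate merging follows single-linkage semantics", {
  two <- rbind(c(0, 0, 0), c(1, 0, 0))
  m1 <- merge_candidates(two, merge_radius = 5)
  expect_equal(nrow(m1$points), 1L)
  expect_equal(m1$points[1, ], c(0.5, 0, 0))

  far <- rbind(c(0, 0, 0), c(20, 0, 0))
  expect_equal(nrow(merge_candidates(far, merge_radius = 5)$points), 2L)

  chain <- cbind(seq(0, 20, by = 4), 0, 0)
  expect_equal(nrow(merge_candidates(chain, merge_radius = 5)$points), 1L)
  expect_error(merge_candidates(two, merge_radius = 0), "merge_radius")
})

test_that("merge output is independent of input point order", {
  pts <- matrix(with_seed(12, rnorm(60, sd = 30)), 20, 3)
  a <- merge_candidates(pts, 10)
  b <- merge_candidates(pts[sample.int(20), ], 10)
  expect_equal(a$points, b$points, tolerance = 1e-12)
  expect_identical(attr(a, "support"), attr(b, "support"))
})

test_that("scalp projection equals brute-force closest-triangle search", {
  h <- shared_head()
  pts <- sweep(matrix(with_seed(13, rnorm(30, sd = 20)), 10, 3), 2,
               c(0, 0, 120), "+")
  got <- project_to_scalp(electrode_set(pts), h$mesh)$points
  # exhaustive oracle on a face subset containing the true minima
  closest_tri <- function(p, a, b, c) {
    # dense sampling of the triangle, independent of the C++ routine
    w <- expand.grid(u = seq(0, 1, length.out = 60),
                     v = seq(0, 1, length.out = 60))
    w <- w[w$u + w$v <= 1, ]
    q <- cbind(a[1] + w$u * (b[1] - a[1]) + w$v * (c[1] - a[1]),
               a[2] + w$u * (b[2] - a[2]) + w$v * (c[2] - a[2]),
               a[3] + w$u * (b[3] - a[3]) + w$v * (c[3] - a[3]))
    min(sqrt(rowSums(sweep(q, 2, p)^2)))
  }
  f <- h$mesh$faces
  v <- h$mesh$vertices
  for (i in 1:3) {
    d_pkg <- sqrt(sum((got[i, ] - pts[i, ])^2))
    d_oracle <- min(vapply(seq_len(nrow(f)), function(k)
      closest_tri(pts[i, ], v[f[k, 1], ], v[f[k, 2], ], v[f[k, 3], ]),
      numeric(1)))
    expect_lt(abs(d_pkg - d_oracle), 0.05)  # oracle grid resolution
  }
})

test_that("projection onto a sphere scalp moves points radially", {
  ico <- headgeo:::icosphere(4)
  sph <- textured_mesh(ico$vertices * 50, ico$faces)
  p_out <- matrix(c(0, 0, 53), 1, 3)
  proj <- project_to_scalp(electrode_set(p_out), sph)
  expect_lt(abs(sqrt(sum(proj$points^2)) - 50), 0.05)
  # a point already on a face stays put
  face1 <- sph$faces[1, ]
  on_face <- colMeans(sph$vertices[face1, ])
  same <- project_to_scalp(electrode_set(matrix(on_face, 1, 3)), sph)
  expect_lt(sqrt(sum((same$points - on_face)^2)), 1e-9)
})

test_that("detector precondition errors are informative", {
  expect_error(detect_electrodes(shared_head()$mesh), "no texture")
  ds <- disc_sphere(c(0, 0, 1))
  det <- detect_electrodes(ds$mesh, r_min_mm = 3, r_max_mm = 10)
  expect_equal(nrow(det$points), 1L)
  expect_lt(sqrt(sum((det$points[1, ] - ds$center)^2)), 1.5)
})
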