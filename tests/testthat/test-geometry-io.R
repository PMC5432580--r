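test_that("minimal OBJ parses and malformed records raise named errors", {
  obj <- tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "v 0 0 1",
               "f 1 2 3", "f 1 3 4"), obj)
  m <- read_textured_mesh(obj)
  expect_equal(nrow(m$vertices), 4L)
  expect_equal(nrow(m$faces), 2L)
  expect_null(m$texture)

  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "v 0 0 1", "f 1 2 5"), obj)
  expect_error(read_textured_mesh(obj), "out of range.*line 5")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "v 0 0 1", "f 1 2 x"), obj)
  expect_error(read_textured_mesh(obj), "malformed face record")
})

test_that("textured OBJ round trip preserves geometry, UV and texture", {
  pe <- shared_painted()
  dir <- tempfile(); dir.create(dir)
  path <- file.path(dir, "head.obj")
  write_mesh(pe$mesh, path)
  back <- read_textured_mesh(path)
  expect_lt(max(abs(back$vertices - pe$mesh$vertices)), 1e-6)
  expect_identical(back$faces, pe$mesh$faces)
  expect_lt(max(abs(back$uv - pe$mesh$uv)), 1e-6)
  expect_false(is.null(back$texture))
  # PNG stores 8/16-bit: binarized content must survive exactly
  expect_equal(binarize_texture(back$texture),
               binarize_texture(pe$mesh$texture))
  # deterministic byte output (same stem in a second directory)
  dir2 <- tempfile(); dir.create(dir2)
  path2 <- file.path(dir2, "head.obj")
  write_mesh(pe$mesh, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("missing texture image degrades to an untextured mesh with warning", {
  dir <- tempfile(); dir.create(dir)
  path <- file.path(dir, "head.obj")
  write_mesh(shared_painted()$mesh, path)
  file.remove(file.path(dir, "head_texture.png"))
  file.remove(file.path(dir, "head.mtl"))
  expect_warning(m <- read_textured_mesh(path), "no texture image")
  expect_null(m$texture)
  expect_equal(nrow(m$vertices), nrow(shared_painted()$mesh$vertices))
})

test_that("quad faces are fan-triangulated deterministically", {
  obj <- tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0",
               "f 1 2 3 4"), obj)
  m <- read_textured_mesh(obj)
  expect_identical(m$faces, rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
})

test_that("electrode text files round-trip and reject bad input", {
  set <- electrode_set(matrix(rnorm(68 * 3) * 50, 68, 3),
                       labels = paste0("E", 1:68))
  path <- tempfile(fileext = ".txt")
  write_electrodes(set, path)
  back <- read_electrodes(path)
  expect_lt(max(abs(back$points - set$points)), 1e-6)
  expect_identical(back$labels, set$labels)

  writeLines("Fpz 0 100 60", path)
  one <- read_electrodes(path)
  expect_equal(nrow(one$points), 1L)
  expect_identical(one$labels, "Fpz")

  writeLines(c("Cz 0 0 90", "Cz 1 1 80"), path)
  expect_error(read_electrodes(path), "duplicate")
  writeLines(c("Cz 0 zero 90"), path)
  expect_error(read_electrodes(path), "line 1")
  writeLines(c("# only a comment"), path)
  expect_error(read_electrodes(path), "no electrode records")
})

test_that("unlabeled electrode files and comments are handled", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("# coords in mm", "1 2 3", "4,5,6"), path)
  set <- read_electrodes(path)
  expect_null(set$labels)
  expect_equal(set$points, rbind(c(1, 2, 3), c(4, 5, 6)))
})

test_that("mesh constructor enforces its invariants", {
  v <- diag(3)
  expect_error(textured_mesh(v, rbind(c(1, 2, 3))), "at least 4")
  v <- rbind(v, c(1, 1, 1))
  expect_error(textured_mesh(v, rbind(c(1, 2, 9))), "out of range")
  v[1, 1] <- NaN
  expect_error(textured_mesh(v, rbind(c(1, 2, 3))), "NaN")
  expect_error(write_mesh(structure(list(vertices = matrix(0, 0, 3)),
                                    class = "textured_mesh"), tempfile()),
               "empty")
})

test_that("scalp extraction matches the analytic sphere and scales with the affine", {
  g <- seq_len(121) - 61
  vol <- array(0, c(121, 121, 121))
  for (k in seq_len(121))
    vol[, , k] <- (outer(g^2, g^2, "+") + g[k]^2 < 50^2) * 100
  m1 <- scalp_mesh_from_volume(head_volume(vol, diag(4)))
  r1 <- sqrt(rowSums(sweep(m1$vertices, 2L, c(60, 60, 60))^2))
  expect_true(all(abs(r1 - 50) <= 1))
  expect_true(is_watertight(m1))

  aff2 <- diag(c(2, 2, 2, 1))
  m2 <- scalp_mesh_from_volume(head_volume(vol, aff2))
  r2 <- sqrt(rowSums(sweep(m2$vertices, 2L, c(120, 120, 120))^2))
  expect_true(all(abs(r2 - 100) <= 2))
  # affine commutation: world coordinates scale exactly with the affine
  expect_equal(m2$vertices, 2 * m1$vertices, tolerance = 1e-9)
})

test_that("all-zero volumes raise an empty-foreground error", {
  vol <- head_volume(array(0, c(10, 10, 10)), diag(4))
  expect_error(scalp_mesh_from_volume(vol), "lower threshold")
})

test_that("NIfTI volumes round-trip voxels and affine", {
  h <- shared_head()
  mri <- make_mri_like(h, voxel_mm = 4)
  path <- tempfile(fileext = ".nii.gz")
  write_volume(mri$volume, path)
  back <- read_volume(path)
  expect_equal(dim(back$voxels), dim(mri$volume$voxels))
  expect_equal(max(abs(back$voxels - mri$volume$voxels)), 0, tolerance = 1e-3)
  expect_lt(max(abs(back$affine - mri$volume$affine)), 1e-4)
})
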