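test_that("centroid equals the per-axis mean from independent summation", {
  expect_equal(centroid(rbind(c(0, 0, 0), c(2, 0, 0))), c(1, 0, 0))
  p <- c(3.2, -1, 7)
  expect_equal(centroid(matrix(p, 1, 3)), p)
  pts <- matrix(with_seed(5, rnorm(300)), 100, 3)
  oracle <- c(sum(pts[, 1]), sum(pts[, 2]), sum(pts[, 3])) / 100
  expect_lt(max(abs(centroid(pts) - oracle)), 1e-12)
  expect_error(centroid(matrix(numeric(0), 0, 3)), "empty")
})

test_that("scaling factor follows the centroid-ratio formula", {
  a <- matrix(with_seed(2, rnorm(15, sd = 10)), 5, 3)
  expect_equal(scaling_factor(facial_segment(a), facial_segment(a)), 1.0)
  expect_equal(scaling_factor(facial_segment(a), facial_segment(a * 4)), 0.25)
  b <- matrix(with_seed(3, rnorm(15, sd = 10)), 5, 3)
  # direct evaluation of the formula, written independently
  norm_spread <- function(p) {
    ctr <- colMeans(p)
    s <- 0
    for (i in seq_len(nrow(p)))
      s <- s + sqrt(sum((p[i, ] - ctr)^2))
    s / nrow(p)
  }
  expect_lt(abs(scaling_factor(facial_segment(a), facial_segment(b)) -
                norm_spread(a) / norm_spread(b)), 1e-12)
})

test_that("scaling factor is reciprocal and rigid-motion invariant", {
  a <- matrix(with_seed(4, rnorm(30, sd = 20)), 10, 3)
  b <- matrix(with_seed(5, rnorm(30, sd = 20)), 10, 3)
  sa <- facial_segment(a); sb <- facial_segment(b)
  expect_equal(scaling_factor(sa, sb) * scaling_factor(sb, sa), 1,
               tolerance = 1e-12)
  tr <- random_similarity(9, scale_range = c(1, 1))
  b2 <- facial_segment(apply_transform(tr, b))
  expect_equal(scaling_factor(sa, b2), scaling_factor(sa, sb),
               tolerance = 1e-9)
  expect_error(scaling_factor(sa, facial_segment(matrix(1, 4, 3))),
               "zero spread")
})

test_that("best-fit rigid recovers constructed and random transforms", {
  src <- matrix(with_seed(6, rnorm(60, sd = 30)), 20, 3)
  id <- best_fit_rigid(src, src)
  expect_lt(max(abs(transform_matrix(id) - diag(4))), 1e-9)

  R90 <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  fit <- best_fit_rigid(src, src %*% t(R90))
  expect_lt(max(abs(fit$rotation - R90)), 1e-9)

  tr <- random_similarity(17)
  tgt <- apply_transform(tr, src)
  fit2 <- best_fit_rigid(src, tgt, allow_scale = TRUE)
  expect_lt(max(abs(transform_matrix(fit2) - transform_matrix(tr))), 1e-9)
})

test_that("best-fit residual beats a 1000-candidate random-search oracle", {
  src <- matrix(with_seed(8, rnorm(30, sd = 20)), 10, 3)
  tgt <- apply_transform(random_similarity(21, scale_range = c(1, 1)), src) +
    matrix(with_seed(9, rnorm(30, sd = 0.5)), 10, 3)
  fit <- best_fit_rigid(src, tgt)
  rss <- function(tr) sum((apply_transform(tr, src) - tgt)^2)
  best_oracle <- with_seed(10, min(vapply(1:1000, function(k) {
    ang <- runif(3, 0, 2 * pi)
    R <- headgeo:::rotation_xyz(ang[1], ang[2], ang[3])
    tcand <- colMeans(tgt) - as.numeric(R %*% colMeans(src)) + rnorm(3, 0, 1)
    rss(head_transform(R, tcand))
  }, numeric(1))))
  expect_lte(rss(fit), best_oracle)
})

test_that("degenerate geometry is rejected in best-fit solves", {
  line <- cbind(1:5, 0, 0)
  expect_error(best_fit_rigid(line, line + 1), "degenerate|collinear")
  expect_error(best_fit_rigid(matrix(1, 5, 3), matrix(2, 5, 3)),
               "degenerate")
})

test_that("ICP recovers a known facial-segment transform", {
  seg <- shared_head()$mesh$vertices[shared_head()$facial_indices, ]
  fit0 <- icp(seg, seg)
  expect_lt(max(abs(transform_matrix(fit0) - diag(4))), 1e-9)
  expect_true(fit0$converged)

  tr <- head_transform(rot_z(10), c(5, 2, -3))
  moved <- apply_transform(tr, seg)
  # surface patches need the automatic coarse init; identity init can stall
  # in a sliding local minimum on smooth regions
  fit <- icp(moved, seg, init = principal_axes_init(moved, seg))
  expect_lt(fit$rms, 1e-3)
  recovered <- apply_transform(fit, moved)
  expect_lt(mean(sqrt(rowSums((recovered - seg)^2))), 1e-3)
})

test_that("trimmed ICP shrugs off outlier points", {
  # volumetric cloud: identity init converges, outliers must not bias it
  tgt <- matrix(with_seed(11, rnorm(600, sd = 40)), 200, 3)
  n_out <- 50L  # 20% of the source
  outliers <- matrix(with_seed(12, rnorm(3 * n_out, sd = 200)), n_out, 3)
  tr <- head_transform(rot_z(3), c(2, -1, 1))
  src <- rbind(apply_transform(tr, tgt), outliers)
  fit <- icp(src, tgt, trim_frac = 0.25)
  inlier <- apply_transform(fit, src[seq_len(nrow(tgt)), , drop = FALSE])
  expect_lt(sqrt(mean(rowSums((inlier - tgt)^2))), 0.1)
})

test_that("ICP objective is monotone non-increasing across iterations", {
  seg <- shared_head()$mesh$vertices[shared_head()$facial_indices, ]
  tr <- head_transform(rot_z(25), c(15, -10, 5))
  src <- apply_transform(tr, seg)
  rms_at <- vapply(1:8, function(k)
    icp(src, seg, max_iter = k, tol = 0)$rms, numeric(1))
  expect_true(all(diff(rms_at) <= 1e-9))
})

test_that("ICP agrees with the direct solve when correspondences are nearest", {
  seg <- shared_head()$mesh$vertices[shared_head()$facial_indices, ]
  src <- apply_transform(head_transform(rot_z(2), c(0.5, 0.2, -0.1)), seg)
  direct <- best_fit_rigid(src, seg)
  via_icp <- icp(src, seg, max_iter = 1L, tol = 0)
  expect_lt(max(abs(transform_matrix(direct) - transform_matrix(via_icp))),
            1e-9)
})

test_that("full coregistration recovers electrodes from a shifted frame copy", {
  h <- shared_head()
  seg <- h$mesh$vertices[h$facial_indices, ]
  el <- shared_layout()
  shift <- head_transform(translation = c(30, -20, 12))
  fit <- coregister_model_to_mri(
    model_seg = facial_segment(apply_transform(shift, seg)),
    mri_seg = facial_segment(seg))
  rec <- apply_transform(fit, apply_transform(shift, el$points))
  expect_lt(mean(sqrt(rowSums((rec - el$points)^2))), 1e-3)
})

test_that("coregistration recovers electrodes under random similarity shifts", {
  h <- shared_head()
  seg <- h$mesh$vertices[h$facial_indices, ]
  el <- shared_layout()
  for (s in c(31, 32, 33)) {
    tr <- random_similarity(s)
    fit <- coregister_model_to_mri(
      model_seg = facial_segment(apply_transform(tr, seg)),
      mri_seg = facial_segment(seg))
    rec <- apply_transform(fit, apply_transform(tr, el$points))
    expect_lt(mean(sqrt(rowSums((rec - el$points)^2))), 0.01)
  }
})

test_that("disjoint facial regions yield a large residual but still report", {
  h <- shared_head()
  u <- h$mesh$vertices / sqrt(rowSums(h$mesh$vertices^2))
  back <- which(u[, 2] < -0.6)
  fit <- coregister_model_to_mri(
    model_seg = facial_segment(h$mesh$vertices[back, ]),
    mri_seg = facial_segment(h$mesh$vertices[h$facial_indices, ]))
  expect_true(is.logical(fit$converged))
  expect_gt(fit$rms, 1)
})

test_that("fiducial alignment is exact on rigid fiducials, errors when collinear", {
  fids <- rbind(nasion = c(0, 100, 10), LPA = c(-70, 0, 0), RPA = c(70, 0, 0))
  id <- fiducial_transform(fids, fids)
  expect_lt(max(abs(transform_matrix(id) - diag(4))), 1e-9)

  tr <- random_similarity(77, scale_range = c(1, 1))
  moved <- apply_transform(tr, fids)
  rownames(moved) <- rownames(fids)
  rec <- fiducial_transform(fids, moved)
  expect_lt(max(abs(transform_matrix(rec) - transform_matrix(tr))), 1e-9)

  bad <- rbind(nasion = c(0, 0, 0), LPA = c(-70, 0, 0), RPA = c(70, 0, 0))
  expect_error(fiducial_transform(bad, bad), "collinear")
})
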