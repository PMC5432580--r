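test_that("deviation report summaries are recomputable from per-item rows", {
  deltas <- matrix(with_seed(16, rnorm(90)), 30, 3)
  rep <- deviation_report(deltas)
  eu <- rep$per_item$euclidean
  expect_equal(eu, sqrt(rep$per_item$dx^2 + rep$per_item$dy^2 +
                        rep$per_item$dz^2), tolerance = 1e-9)
  expect_equal(rep$summary$mean, mean(eu), tolerance = 1e-9)
  expect_equal(rep$summary$median, median(eu), tolerance = 1e-9)
  expect_equal(rep$summary$sd, sd(eu), tolerance = 1e-9)
  expect_equal(rep$summary$percentile95, quantile(eu, 0.95, names = FALSE),
               tolerance = 1e-9)
})

test_that("mesh deviation measures nearest-vertex offsets", {
  m <- shared_head()$mesh
  expect_equal(mesh_deviation(m, m)$summary$mean, 0)
  shift <- head_transform(translation = c(1, 0, 0))
  moved <- apply_transform(shift, m)
  rep <- mesh_deviation(moved, m)
  # every vertex's nearest original is itself: per-axis offsets all (1,0,0)
  expect_true(all(abs(rep$per_item$dx - 1) < 1e-9))
  expect_true(all(rep$per_item$dy < 1e-9 & rep$per_item$dz < 1e-9))
})

test_that("mesh deviation equals exhaustive nearest-vertex search", {
  ico <- headgeo:::icosphere(2)
  a <- textured_mesh(ico$vertices * 40, ico$faces)
  b <- textured_mesh(ico$vertices[sample.int(nrow(ico$vertices)), ] * 41 + 0.5,
                     ico$faces)
  rep <- mesh_deviation(a, b)
  brute <- vapply(seq_len(nrow(a$vertices)), function(i)
    min(sqrt(colSums((t(b$vertices) - a$vertices[i, ])^2))), numeric(1))
  expect_equal(rep$per_item$euclidean, brute, tolerance = 1e-9)
})

test_that("aligned mesh deviation removes a similarity disturbance", {
  m <- shared_head()$mesh
  tr <- random_similarity(61)
  moved <- apply_transform(tr, m)
  rep <- mesh_deviation(moved, m, align = TRUE)
  expect_lt(rep$summary$mean, 0.01)
})

test_that("electrode deviation matches by label with exclusions", {
  lay <- shared_layout()
  expect_equal(electrode_deviation(lay, lay)$summary$mean, 0)
  shifted <- electrode_set(lay$points + rep(c(2, 0, 0), each = 68),
                           lay$labels)
  rep <- electrode_deviation(shifted, lay)
  expect_true(all(abs(rep$per_item$euclidean - 2) < 1e-9))
  rep2 <- electrode_deviation(shifted, lay, exclude = "TP10")
  expect_equal(rep2$summary$n, 67L)
  expect_false("TP10" %in% rep2$per_item$label)
  expect_error(electrode_deviation(
    electrode_set(lay$points, paste0("X", 1:68)), lay), "no common labels")
})

test_that("mean Gaussian displacement matches the chi(3) closed form", {
  sigma <- 1.5
  n <- 2e4
  noise <- matrix(with_seed(17, rnorm(3 * n, 0, sigma)), n, 3)
  rep <- electrode_deviation(
    electrode_set(noise), electrode_set(matrix(0, n, 3)), match_by = "order")
  expected <- sigma * 2 * sqrt(2 / pi)  # E||N(0, sigma^2 I_3)||
  expect_equal(rep$summary$mean, expected, tolerance = 0.02)
})

test_that("pure-position deviation removes rigid motion before residuals", {
  lay <- shared_layout()
  tr <- random_similarity(62, scale_range = c(1, 1))
  moved <- electrode_set(apply_transform(tr, lay$points), lay$labels)
  rep <- pure_position_deviation(moved, lay)
  expect_lt(rep$summary$mean, 1e-6)

  noisy <- jitter_electrodes(moved, 1, seed = 3)
  aligned <- pure_position_deviation(noisy, lay)
  unaligned <- electrode_deviation(noisy, lay)
  expect_lte(aligned$summary$mean, unaligned$summary$mean)
})

test_that("pure-position residuals match a random-restart alignment oracle", {
  a <- matrix(with_seed(18, rnorm(15, sd = 30)), 5, 3)
  b <- apply_transform(random_similarity(63, scale_range = c(1, 1)), a) +
    matrix(with_seed(19, rnorm(15, sd = 0.3)), 5, 3)
  rep <- pure_position_deviation(electrode_set(b), electrode_set(a),
                                 match_by = "order")
  rss_pkg <- sum(rep$per_item$euclidean^2)
  oracle <- with_seed(20, min(vapply(1:2000, function(k) {
    ang <- runif(3, 0, 2 * pi)
    R <- headgeo:::rotation_xyz(ang[1], ang[2], ang[3])
    tt <- colMeans(a) - as.numeric(R %*% colMeans(b)) + rnorm(3, 0, 0.2)
    sum((sweep(b %*% t(R), 2, tt, "+") - a)^2)
  }, numeric(1))))
  expect_lte(rss_pkg, oracle + 1e-9)
})

test_that("coregistration simulation is deterministic and near-exact when clean", {
  h <- shared_head()
  lay <- shared_layout()
  r1 <- coreg_error_simulation(h, lay, method = "surface", n_reps = 3,
                               seed = 5)
  r2 <- coreg_error_simulation(h, lay, method = "surface", n_reps = 3,
                               seed = 5)
  expect_identical(r1$per_item, r2$per_item)
  expect_lt(r1$summary$mean, 1e-6)
})

test_that("surface matching beats the noisy fiducial baseline", {
  h <- shared_head()
  lay <- shared_layout()
  surf <- coreg_error_simulation(h, lay, method = "surface", n_reps = 10,
                                 seed = 6)
  fid <- coreg_error_simulation(h, lay, fiducials = h$fiducials,
                                method = "fiducial", n_reps = 10, seed = 6,
                                fiducial_sigma = 1)
  expect_lt(surf$summary$mean, fid$summary$mean)
  w <- wilcoxon_signed_rank(attr(fid, "per_rep_mean"),
                            attr(surf, "per_rep_mean"))
  expect_lt(w$p_value, 0.01)
})

test_that("Wilcoxon p-values agree with exact enumeration at n = 6", {
  a <- c(3.1, 2.0, 4.5, 1.2, 5.0, 2.2)
  b <- c(2.5, 2.65, 3.0, 1.0, 4.1, 1.4)
  got <- wilcoxon_signed_rank(a, b)
  # independent enumeration written from scratch
  d <- a - b
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  mu <- 6 * 7 / 4
  vs <- numeric(0)
  for (mask in 0:63) {
    bits <- as.integer(intToBits(mask))[1:6]
    vs <- c(vs, sum(r[bits == 1]))
  }
  p_oracle <- mean(abs(vs - mu) >= abs(v_obs - mu))
  expect_equal(got$p_value, p_oracle, tolerance = 1e-12)
  expect_identical(got$method, "exact enumeration")
  # tie-free case agrees with the reference implementation
  ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE)
  expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-12)
})

test_that("Wilcoxon handles extremes, symmetry and degenerate input", {
  expect_error(wilcoxon_signed_rank(1:6, 1:6), "zero")
  a <- seq(10, 29) + with_seed(21, runif(20, 0.5, 1.5))
  b <- seq(10, 29) * 1.0
  w <- wilcoxon_signed_rank(a, b)
  expect_lt(w$p_value, 1e-4)
  w2 <- wilcoxon_signed_rank(b, a)
  expect_equal(w$p_value, w2$p_value, tolerance = 1e-12)
  expect_gt(w$p_value, 0)
  # large-n approximation tracks the reference implementation
  set.seed(22)
  x <- rnorm(40); y <- x + rnorm(40, 0.3)
  got <- wilcoxon_signed_rank(y, x)
  ref <- wilcox.test(y, x, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-9)
})
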