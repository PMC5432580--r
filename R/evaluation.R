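#' Per-item spatial deviation report
#'
#' Collects per-electrode (or per-vertex) deviations: absolute per-axis
#' offsets (L1 components) and the Euclidean (L2) distance, with summary
#' statistics (mean, median, SD and the 95th percentile of the Euclidean
#' distances).
#'
#' @param deltas n x 3 matrix of signed offsets (test minus reference, mm).
#' @param labels optional per-item labels.
#' @return An object of class `deviation_report` with `per_item`
#'   (data frame: `dx`, `dy`, `dz`, `euclidean`) and `summary`.
#' @export
deviation_report <- function(deltas, labels = NULL) {
  deltas <- as_points(deltas)
  eu <- sqrt(rowSums(deltas^2))
  per_item <- data.frame(dx = abs(deltas[, 1]), dy = abs(deltas[, 2]),
                         dz = abs(deltas[, 3]), euclidean = eu)
  if (!is.null(labels)) per_item <- cbind(label = labels, per_item)
  structure(list(
    per_item = per_item,
    summary = list(mean = mean(eu), median = stats::median(eu),
                   sd = stats::sd(eu),
                   percentile95 = stats::quantile(eu, 0.95, names = FALSE),
                   n = length(eu))),
    class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<deviation_report: n = %d>\n  mean %.3f mm, median %.3f mm,",
                     " SD %.3f mm, 95th pct %.3f mm\n"),
              s$n, s$mean, s$median, s$sd, s$percentile95))
  invisible(x)
}

#' Write a deviation report as JSON + CSV
#' @param report a [deviation_report()].
#' @param stem output path stem; writes `<stem>.json` and `<stem>.csv`.
#' @return The stem, invisibly.
#' @export
write_deviation_report <- function(report, stem) {
  jsonlite::write_json(report$summary, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$per_item, paste0(stem, ".csv"), row.names = FALSE)
  invisible(stem)
}

#' Nearest-vertex deviation between two meshes
#'
#' For each test vertex, the closest vertex of the ground-truth mesh is
#' located and the offsets in each orthogonal direction (L1 components)
#' plus the Euclidean distance are recorded. With `align = TRUE`, the test
#' mesh is first scaled by the centroid-ratio factor between the full
#' vertex clouds and rigid-ICP aligned onto the truth.
#'
#' @param test,truth [textured_mesh()]es in comparable frames (unless
#'   `align = TRUE`).
#' @param align run scaling + ICP before measuring.
#' @param icp_params arguments for the alignment [icp()].
#' @param mode `"vertex"` measures to the nearest truth vertex (the
#'   default); `"surface"` measures true point-to-triangle distance.
#' @return A [deviation_report()].
#' @export
mesh_deviation <- function(test, truth, align = FALSE, icp_params = list(),
                           mode = c("vertex", "surface")) {
  mode <- match.arg(mode)
  stopifnot(inherits(test, "textured_mesh"), inherits(truth, "textured_mesh"))
  if (nrow(test$vertices) == 0L || nrow(truth$vertices) == 0L)
    stop("empty mesh")
  tv <- test$vertices
  if (align) {
    s <- scaling_factor(facial_segment(truth$vertices),
                        facial_segment(tv))
    tv <- tv * s
    init <- principal_axes_init(tv, truth$vertices)
    fit <- do.call(icp, c(list(source = tv, target = truth$vertices,
                               mode = "rigid", init = init), icp_params))
    tv <- apply_transform_mat(fit, tv)
  }
  if (mode == "vertex") {
    nn <- .nn_index(tv, truth$vertices)
    ref <- truth$vertices[nn$index, , drop = FALSE]
  } else {
    ref <- .closest_on_mesh(tv, truth$vertices, truth$faces)$point
  }
  deviation_report(tv - ref)
}

#' Euclidean deviation between matched electrode sets
#'
#' @param test,truth [electrode_set()]s.
#' @param match_by `"labels"` matches by common labels; `"order"` by row
#'   order (requires equal cardinality).
#' @param exclude labels dropped before comparison (e.g. electrodes known
#'   to be poorly reproduced on the reference).
#' @return A [deviation_report()].
#' @export
electrode_deviation <- function(test, truth,
                                match_by = c("labels", "order"),
                                exclude = NULL) {
  match_by <- match.arg(match_by)
  stopifnot(inherits(test, "electrode_set"), inherits(truth, "electrode_set"))
  if (match_by == "labels") {
    if (is.null(test$labels) || is.null(truth$labels))
      stop("label matching requires labeled sets")
    common <- setdiff(intersect(test$labels, truth$labels), exclude)
    if (!length(common)) stop("no common labels between the sets")
    a <- test$points[match(common, test$labels), , drop = FALSE]
    b <- truth$points[match(common, truth$labels), , drop = FALSE]
    deviation_report(a - b, labels = common)
  } else {
    if (nrow(test$points) != nrow(truth$points))
      stop("order matching requires equal cardinality")
    keep <- if (!is.null(exclude) && !is.null(truth$labels))
      !(truth$labels %in% exclude) else rep(TRUE, nrow(truth$points))
    deviation_report(test$points[keep, , drop = FALSE] -
                     truth$points[keep, , drop = FALSE],
                     labels = truth$labels[keep])
  }
}

#' Method-intrinsic electrode deviation after best rigid alignment
#'
#' Rigidly aligns the test set onto the ground truth (least-squares fit on
#' the matched correspondences, the fixed point of correspondence-based
#' ICP) before tabulating residuals, separating the method's intrinsic
#' localization error from any residual coregistration error.
#'
#' @inheritParams electrode_deviation
#' @return A [deviation_report()].
#' @export
pure_position_deviation <- function(test, truth,
                                    match_by = c("labels", "order"),
                                    exclude = NULL) {
  match_by <- match.arg(match_by)
  if (match_by == "labels") {
    common <- setdiff(intersect(test$labels, truth$labels), exclude)
    if (!length(common)) stop("no common labels between the sets")
    a <- test$points[match(common, test$labels), , drop = FALSE]
    b <- truth$points[match(common, truth$labels), , drop = FALSE]
    labs <- common
  } else {
    if (nrow(test$points) != nrow(truth$points))
      stop("order matching requires equal cardinality")
    a <- test$points; b <- truth$points; labs <- truth$labels
  }
  fit <- best_fit_rigid(a, b)
  deviation_report(apply_transform_mat(fit, a) - b, labels = labs)
}

#' Simulate the coregistration error of either workflow
#'
#' Repeats coregistration on randomly transformed copies of the model and
#' its electrodes (and fiducials): per repetition a [random_similarity()]
#' perturbation (rotations 1-360 degrees and translations 1-100 mm per
#' axis; the arbitrary 1-5 model scale only for the surface method, since
#' digitized fiducial sets carry no such scale) is applied, the
#' coregistration recovered by the chosen method, and the Euclidean
#' distances between the original electrode positions and the recovered
#' ones pooled over repetitions.
#'
#' @param model a [make_head()] result (provides the facial segment), or a
#'   list with `mesh` and `facial_indices`.
#' @param electrodes reference [electrode_set()] in the model frame.
#' @param fiducials 3 x 3 matrix (rows nasion/LPA/RPA) for the fiducial
#'   method.
#' @param method `"surface"` (scaling + facial-segment ICP) or
#'   `"fiducial"` (landmark-frame alignment).
#' @param n_reps number of random perturbations.
#' @param seed master seed; each repetition derives its own sub-seed.
#' @param fiducial_sigma per-fiducial isotropic placement noise SD (mm)
#'   injected in the fiducial method; noiseless fiducials would recover
#'   exactly and carry no information about digitization error.
#' @param icp_params arguments for the surface-matching [icp()].
#' @return A [deviation_report()] pooled over repetitions, with attribute
#'   `per_rep_mean` (mean deviation per repetition).
#' @export
coreg_error_simulation <- function(model, electrodes, fiducials = NULL,
                                   method = c("surface", "fiducial"),
                                   n_reps = 100L, seed = 1L,
                                   fiducial_sigma = 2,
                                   icp_params = list()) {
  method <- match.arg(method)
  mesh <- model$mesh
  seg_pts <- mesh$vertices[model$facial_indices, , drop = FALSE]
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_reps))
  deltas <- vector("list", n_reps)
  per_rep <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    if (method == "surface") {
      tr <- random_similarity(sub_seeds[r])
      moved_seg <- apply_transform_mat(tr, seg_pts)
      moved_el <- apply_transform_mat(tr, electrodes$points)
      fit <- coregister_model_to_mri(
        model_seg = facial_segment(moved_seg),
        mri_seg = facial_segment(seg_pts), icp_params = icp_params)
      rec <- apply_transform_mat(fit, moved_el)
    } else {
      if (is.null(fiducials)) stop("fiducial method requires fiducials")
      tr <- random_similarity(sub_seeds[r], scale_range = c(1, 1))
      moved_el <- apply_transform_mat(tr, electrodes$points)
      moved_fid <- apply_transform_mat(tr, fiducials)
      noisy_fid <- moved_fid + matrix(
        with_seed(sub_seeds[r] + 1L, stats::rnorm(9, 0, fiducial_sigma)), 3L, 3L)
      rownames(noisy_fid) <- rownames(fiducials)
      fit <- fiducial_transform(noisy_fid, fiducials)
      rec <- apply_transform_mat(fit, moved_el)
    }
    deltas[[r]] <- rec - electrodes$points
    per_rep[r] <- mean(sqrt(rowSums(deltas[[r]]^2)))
  }
  rep_labels <- if (!is.null(electrodes$labels))
    rep(electrodes$labels, n_reps) else NULL
  out <- deviation_report(do.call(rbind, deltas), labels = rep_labels)
  attr(out, "per_rep_mean") <- per_rep
  out
}

#' Wilcoxon signed-rank test for paired deviations
#'
#' Two-sided signed-rank test. Zero differences are dropped and tied
#' absolute differences mid-ranked. For n <= 12 retained pairs the p-value
#' is exact, from full enumeration of all 2^n sign assignments of the
#' observed ranks; above that, the normal approximation with continuity
#' and tie corrections is used.
#'
#' @param a,b equal-length paired samples (n >= 5).
#' @return List with `statistic` (V, the positive-rank sum), `p_value`,
#'   `n_effective` and `method`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  if (length(a) < 5L) stop("need at least 5 pairs")
  d <- a - b
  d <- d[d != 0]
  if (!length(d)) stop("all paired differences are zero")
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= 12L) {
    # exact null: every sign assignment of the observed (tied) ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Vs <- as.numeric(signs %*% r)
    p <- mean(abs(Vs - mu) >= abs(V - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (V - mu - 0.5 * sign(V - mu)) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = V, p_value = min(1, p), n_effective = n, method = method)
}
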