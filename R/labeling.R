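#' Template collection for electrode labeling
#'
#' A list of fully labeled electrode sets sharing an identical label
#' inventory; electrode counts must match the montage to be labeled.
#'
#' @param templates list of labeled [electrode_set()]s.
#' @return An object of class `template_set`.
#' @export
template_set <- function(templates) {
  if (!length(templates)) stop("empty template list")
  labs <- lapply(templates, function(t) {
    if (!inherits(t, "electrode_set") || is.null(t$labels))
      stop("every template must be a fully labeled electrode_set")
    sort(t$labels)
  })
  for (k in seq_along(labs))
    if (!identical(labs[[k]], labs[[1]]))
      stop("template ", k, " has a different label inventory")
  structure(list(templates = templates), class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set: %d templates, %d electrodes each>\n",
              length(x$templates), length(x$templates[[1]])))
  invisible(x)
}

#' @export
length.template_set <- function(x) length(x$templates)

#' Normalize a labeled set into a template entry
#'
#' Centers the set at its centroid and rescales it to unit RMS radius, so
#' templates from different heads are comparable; the label inventory
#' checksum is attached for compatibility checks.
#'
#' @param labeled_set a fully labeled [electrode_set()].
#' @return A normalized labeled `electrode_set` with attribute
#'   `label_checksum`.
#' @export
build_template <- function(labeled_set) {
  stopifnot(inherits(labeled_set, "electrode_set"))
  if (is.null(labeled_set$labels))
    stop("template source set must be fully labeled")
  p <- sweep(labeled_set$points, 2L, colMeans(labeled_set$points))
  rms <- sqrt(mean(rowSums(p^2)))
  if (rms <= 0) stop("degenerate template (all points coincident)")
  out <- electrode_set(p / rms, labeled_set$labels, frame_id = "template")
  attr(out, "label_checksum") <- paste(sort(labeled_set$labels),
                                       collapse = "|")
  out
}

#' Default seven-template collection
#'
#' Seven templates generated from the canonical 68-electrode layout by
#' fixed-seed 3 mm isotropic jitter (one independent draw per template),
#' then normalized with [build_template()]. Real-world template curation is
#' expected to replace these with user-supplied digitized sets.
#'
#' @param n number of templates (default 7).
#' @param sigma_mm jitter amplitude (mm).
#' @return A [template_set()].
#' @export
default_templates <- function(n = 7L, sigma_mm = 3) {
  canon <- standard_layout_68()
  template_set(lapply(seq_len(n), function(k)
    build_template(jitter_electrodes(canon, sigma_mm, seed = 100L + k))))
}

fit_sphere_center <- function(p) {
  A <- cbind(2 * p, 1)
  b <- rowSums(p^2)
  x <- qr.solve(A, b)
  x[1:3]
}

cloud_up_axis <- function(p) {
  ctr <- fit_sphere_center(p)
  u <- colMeans(p) - ctr
  list(center = ctr, up = u / sqrt(sum(u^2)))
}

#' Detect the Fpz and Oz landmark electrodes
#'
#' Orientation-free landmark detection on an unlabeled electrode cloud:
#' the cap's vertical axis is estimated from a least-squares sphere fit
#' (centroid of a hemispheric cap lies above the sphere center), the
#' midsagittal plane is found as the best reflection-symmetry plane
#' containing that axis, and the two midsagittal electrodes at extreme
#' anterior/posterior positions within the lower cap band are taken as the
#' landmark pair. Anterior (Fpz) vs posterior (Oz) is disambiguated by
#' trial landmark-anchored alignment against the templates both ways,
#' keeping the assignment preferred by the majority.
#'
#' @param set an unlabeled [electrode_set()] with >= 10 electrodes
#'   covering the scalp.
#' @param templates a [template_set()] used for the anterior/posterior
#'   decision (defaults to [default_templates()]).
#' @param band_frac electrodes whose height above the lowest electrode is
#'   below this fraction of the cap height form the lower band (default 0.5,
#'   keeping the outer ring and inferior row but excluding the next
#'   midline row even on strongly anisotropic heads).
#' @return A list with `Fpz` and `Oz` (length-3 points) and their row
#'   indices `Fpz_index` / `Oz_index` in `set`.
#' @export
detect_landmark_electrodes <- function(set, templates = default_templates(),
                                       band_frac = 0.5) {
  p <- set$points
  if (nrow(p) < 10L) stop("landmark detection needs >= 10 electrodes")
  ax <- cloud_up_axis(p)
  rel <- sweep(p, 2L, ax$center)
  h <- as.numeric(rel %*% ax$up)
  hn <- (h - min(h)) / (max(h) - min(h))
  scale <- mean(sqrt(rowSums(rel^2)))
  # orthobasis perpendicular to up
  e1 <- c(ax$up[2], -ax$up[1], 0)
  if (sum(e1^2) < 1e-9) e1 <- c(1, 0, 0)
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(ax$up[2] * e1[3] - ax$up[3] * e1[2],
          ax$up[3] * e1[1] - ax$up[1] * e1[3],
          ax$up[1] * e1[2] - ax$up[2] * e1[1])
  sym_cost <- function(psi) {
    n <- cos(psi) * e1 + sin(psi) * e2
    refl <- rel - 2 * as.numeric(rel %*% n) %o% n
    mean(.nn_index(refl + rep(ax$center, each = nrow(p)), p)$distance)
  }
  psis <- seq(0, pi, length.out = 61L)[-61L]
  costs <- vapply(psis, sym_cost, numeric(1))
  psi1 <- psis[which.min(costs)]
  # a cap grid is close to reflection-symmetric about the coronal plane
  # too; keep both orthogonal minima as plane hypotheses and let the
  # template trial alignment arbitrate
  circ_dist <- abs(((psis - psi1) + pi / 2) %% pi - pi / 2)
  far <- circ_dist > pi / 4
  psi2 <- psis[far][which.min(costs[far])]
  refine <- function(psi0) {
    fine <- seq(psi0 - 0.06, psi0 + 0.06, length.out = 13L)
    fine[which.min(vapply(fine, sym_cost, numeric(1)))]
  }
  pairs <- list()
  for (psi in c(refine(psi1), refine(psi2))) {
    n <- cos(psi) * e1 + sin(psi) * e2
    m <- c(n[2] * ax$up[3] - n[3] * ax$up[2],
           n[3] * ax$up[1] - n[1] * ax$up[3],
           n[1] * ax$up[2] - n[2] * ax$up[1])
    sag <- abs(as.numeric(rel %*% n)) < 0.12 * scale
    cand <- which(sag & hn < band_frac)
    if (length(cand) < 2L) next
    t_m <- as.numeric(rel[cand, , drop = FALSE] %*% m)
    a <- cand[which.max(t_m)]
    b <- cand[which.min(t_m)]
    pairs[[length(pairs) + 1L]] <- c(a, b)
    pairs[[length(pairs) + 1L]] <- c(b, a)
  }
  if (!length(pairs))
    stop("could not find two midsagittal lower-band electrodes")
  # trial alignment of every orientation hypothesis against the templates
  total <- numeric(length(pairs))
  wins <- integer(length(pairs))
  for (tpl in templates$templates) {
    cc <- vapply(pairs, function(pr)
      landmark_alignment_cost(set, pr[1], pr[2], ax, tpl), numeric(1))
    total <- total + cc
    wins[which.min(cc)] <- wins[which.min(cc)] + 1L
  }
  ord <- order(total)
  if (length(pairs) > 1L &&
      (total[ord[2]] - total[ord[1]]) < 1e-9 * max(1, total[ord[1]]))
    stop("ambiguous anterior/posterior landmarks; candidates at rows ",
         pairs[[ord[1]]][1], " and ", pairs[[ord[2]]][1])
  best <- pairs[[ord[1]]]
  a_idx <- best[1]
  b_idx <- best[2]
  list(Fpz = p[a_idx, ], Oz = p[b_idx, ], Fpz_index = a_idx, Oz_index = b_idx)
}

landmark_frame <- function(fpz, oz, up) {
  origin <- (fpz + oz) / 2
  ex <- fpz - oz
  d <- sqrt(sum(ex^2))
  ex <- ex / d
  ez <- up - sum(up * ex) * ex
  ez <- ez / sqrt(sum(ez^2))
  ey <- c(ez[2] * ex[3] - ez[3] * ex[2],
          ez[3] * ex[1] - ez[1] * ex[3],
          ez[1] * ex[2] - ez[2] * ex[1])
  list(origin = origin, R = cbind(ex, ey, ez), span = d)
}

template_init_transform <- function(set, fpz_idx, oz_idx, ax, tpl) {
  tpl_ax <- cloud_up_axis(tpl$points)
  ft <- landmark_frame(tpl$points[match("Fpz", tpl$labels), ],
                       tpl$points[match("Oz", tpl$labels), ], tpl_ax$up)
  fs <- landmark_frame(set$points[fpz_idx, ], set$points[oz_idx, ], ax$up)
  s <- fs$span / ft$span
  R <- fs$R %*% t(ft$R)
  head_transform(R, fs$origin - s * as.numeric(R %*% ft$origin), s,
                 kind = "similarity")
}

landmark_alignment_cost <- function(set, fpz_idx, oz_idx, ax, tpl) {
  # refine the landmark-anchored init with a short similarity ICP so the
  # cost reflects the residual structure mismatch, not the init quality
  tr <- template_init_transform(set, fpz_idx, oz_idx, ax, tpl)
  fit <- icp(tpl$points, set$points, mode = "similarity", init = tr,
             max_iter = 30L)
  moved <- apply_transform_mat(fit, tpl$points)
  # one-to-one greedy matching cost: unlike plain nearest-neighbour cost it
  # penalizes the pile-ups a front/back flip produces on asymmetric rows
  n1 <- nrow(moved)
  d <- matrix(0, n1, nrow(set$points))
  for (k in 1:3)
    d <- d + outer(moved[, k], set$points[, k], "-")^2
  tot <- 0
  for (k in seq_len(min(dim(d)))) {
    ij <- arrayInd(which.min(d), dim(d))
    tot <- tot + sqrt(d[ij])
    d[ij[1], ] <- Inf
    d[, ij[2]] <- Inf
  }
  tot / min(n1, nrow(set$points))
}

#' Label electrodes by seven-template majority vote
#'
#' For each template: a landmark-anchored similarity initialization
#' followed by affine ICP aligns the template onto the unlabeled set, and
#' each electrode receives the label of its nearest template electrode.
#' The final label per electrode is the mode of the (up to 7) proposals,
#' ties broken by the lowest template index. Duplicate final labels are
#' resolved by a globally optimal one-to-one nearest assignment among the
#' conflicting electrodes and the freed labels.
#'
#' @param set unlabeled [electrode_set()]; its electrode count must equal
#'   the template count.
#' @param templates a [template_set()] (default [default_templates()]).
#' @param icp_params list of [icp()] arguments for the affine stage.
#' @param landmarks optional precomputed [detect_landmark_electrodes()]
#'   result (the manual-correction hook for landmark overrides).
#' @return A labeled `electrode_set` (same point order) with attribute
#'   `votes` (n x n_templates character matrix of per-template proposals).
#' @export
label_majority_vote <- function(set, templates = default_templates(),
                                icp_params = list(max_iter = 50L),
                                landmarks = NULL) {
  stopifnot(inherits(set, "electrode_set"), inherits(templates, "template_set"))
  n <- nrow(set$points)
  if (n != length(templates$templates[[1]]))
    stop("electrode count (", n, ") does not match template count (",
         length(templates$templates[[1]]), ")")
  if (is.null(landmarks))
    landmarks <- detect_landmark_electrodes(set, templates)
  ax <- cloud_up_axis(set$points)
  ntpl <- length(templates)
  votes <- matrix(NA_character_, n, ntpl)
  all_labels <- sort(templates$templates[[1]]$labels)
  # mean aligned template position per label, for duplicate resolution
  label_pos <- array(0, c(length(all_labels), 3L))
  for (k in seq_len(ntpl)) {
    tpl <- templates$templates[[k]]
    init <- template_init_transform(set, landmarks$Fpz_index,
                                    landmarks$Oz_index, ax, tpl)
    fit <- do.call(icp, c(list(source = tpl$points, target = set$points,
                               mode = "affine", init = init), icp_params))
    moved <- apply_transform_mat(fit, tpl$points)
    nn <- .nn_index(set$points, moved)
    votes[, k] <- tpl$labels[nn$index]
    label_pos <- label_pos + moved[match(all_labels, tpl$labels), ] / ntpl
  }
  winner <- character(n)
  for (i in seq_len(n)) {
    tab <- table(votes[i, ])
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) winner[i] <- top
    else winner[i] <- votes[i, which(votes[i, ] %in% top)[1]]
  }
  # resolve duplicate winners by optimal assignment over freed labels
  dup_labels <- unique(winner[duplicated(winner)])
  if (length(dup_labels)) {
    conflict <- which(winner %in% dup_labels)
    free_labels <- c(dup_labels, setdiff(all_labels, winner))
    cost <- matrix(0, length(conflict), length(free_labels))
    for (j in seq_along(free_labels)) {
      lp <- label_pos[match(free_labels[j], all_labels), ]
      cost[, j] <- sqrt(rowSums(sweep(set$points[conflict, , drop = FALSE],
                                      2L, lp)^2))
    }
    assign <- min_cost_assignment(cost)
    if (anyNA(assign))
      stop("could not resolve duplicate labels: ",
           paste(dup_labels, collapse = ", "))
    winner[conflict] <- free_labels[assign]
  }
  out <- electrode_set(set$points, winner, frame_id = set$frame_id)
  attr(out, "votes") <- votes
  out
}

# minimum-total-cost one-to-one assignment of rows to columns (square
# matrix); exhaustive for small conflicts, greedy beyond
min_cost_assignment <- function(cost) {
  k <- nrow(cost)
  if (k != ncol(cost)) stop("assignment matrix must be square")
  if (k <= 7L) {
    perms <- permutations_of(k)
    tot <- apply(perms, 1L, function(p) sum(cost[cbind(seq_len(k), p)]))
    return(unname(perms[which.min(tot), ]))
  }
  assign <- rep(NA_integer_, k)
  used_r <- used_c <- logical(k)
  for (step in seq_len(k)) {
    sub <- cost
    sub[used_r, ] <- Inf
    sub[, used_c] <- Inf
    ij <- arrayInd(which.min(sub), dim(sub))
    assign[ij[1]] <- ij[2]
    used_r[ij[1]] <- TRUE
    used_c[ij[2]] <- TRUE
  }
  assign
}

permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(k - 1L)
  out <- matrix(0L, 0L, k)
  for (i in seq_len(k)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}

#' Read / write a template directory
#'
#' A template directory holds one electrode text file per template plus a
#' `manifest.json` listing them in order.
#'
#' @param dir directory path.
#' @return `read_templates()`: a [template_set()]; `write_templates()`:
#'   `dir` invisibly.
#' @export
read_templates <- function(dir) {
  man <- file.path(dir, "manifest.json")
  files <- if (file.exists(man))
    jsonlite::read_json(man, simplifyVector = TRUE)$templates
  else sort(list.files(dir, pattern = "\\.txt$"))
  template_set(lapply(file.path(dir, files), read_electrodes))
}

#' @rdname read_templates
#' @param templates a [template_set()].
#' @export
write_templates <- function(templates, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("template_%02d.txt", seq_along(templates$templates))
  for (k in seq_along(files))
    write_electrodes(templates$templates[[k]], file.path(dir, files[k]))
  jsonlite::write_json(list(templates = files), file.path(dir, "manifest.json"),
                       auto_unbox = FALSE)
  invisible(dir)
}
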