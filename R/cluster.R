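# Stage 2: robust standardization, 4D descriptors, OPTICS clustering with
# merge rules, and the nearest-neighbour retain step.

#' Robust standardization Z(s | S)
#'
#' Centres a feature by its median and rescales by its median absolute
#' deviation (MAD, unscaled): \eqn{Z(s) = (s - \mathrm{median})/\mathrm{MAD}}.
#' A zero MAD (constant feature) yields all-zero output with attribute
#' `degenerate = TRUE`.
#'
#' @param values numeric vector.
#' @return standardized vector (median 0, MAD 1 unless degenerate).
#' @export
robust_z <- function(values) {
  if (any(!is.finite(values))) stop("non-finite values in robust_z input")
  med <- stats::median(values)
  mad <- stats::median(abs(values - med))
  if (mad == 0) {
    out <- rep(0, length(values))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (values - med) / mad
}

#' 4D clustering descriptors for the foreground set
#'
#' For each foreground Gaussian, the descriptor
#' \eqn{\phi_g = [x', y', z', d']} concatenates the robustly standardized
#' world coordinates with the standardized view-agnostic depth cue
#' \eqn{\bar r_g}: the mean distance from the Gaussian centre to the centres
#' of the cameras whose frustum contains it. A Gaussian visible in no view
#' falls back to averaging over all views (logged) so the depth cue stays
#' well defined.
#'
#' @param foreground 0-based splat ids from [foreground_select()].
#' @param splats the full-scene [splat_set()].
#' @param views list of all [camera_view()]s.
#' @return object of class `cluster_features`: `ids`, `phi` (n x 4),
#'   `mean_cam_dist`, `visible_cams` (list of view-index vectors).
#' @export
build_descriptors <- function(foreground, splats, views) {
  stopifnot(length(foreground) > 0, length(views) > 0)
  idx <- match(as.integer(foreground), splats$ids)
  if (anyNA(idx)) stop("foreground contains unknown ids")
  pos <- splats$positions[idx, , drop = FALSE]
  centers <- t(vapply(views, camera_center, numeric(3)))
  vis <- lapply(views, function(v) in_frustum(v, pos))
  vis <- do.call(cbind, vis)  # n x n_views
  none <- rowSums(vis) == 0
  if (any(none)) {
    message(sum(none), " foreground splat(s) visible in no view; using all views")
    vis[none, ] <- TRUE
  }
  # mean distance to visible camera centres
  dmat <- matrix(0, nrow(pos), length(views))
  for (j in seq_along(views))
    dmat[, j] <- sqrt(colSums((t(pos) - centers[j, ])^2))
  rbar <- rowSums(dmat * vis) / rowSums(vis)
  phi <- cbind(robust_z(pos[, 1]), robust_z(pos[, 2]), robust_z(pos[, 3]),
               robust_z(rbar))
  vindex <- vapply(views, function(v) v$view_index, integer(1))
  structure(list(ids = splats$ids[idx], phi = unname(phi),
                 mean_cam_dist = rbar,
                 visible_cams = apply(vis, 1, function(r) vindex[r],
                                      simplify = FALSE)),
            class = "cluster_features")
}

#' OPTICS clustering, cluster selection and merging
#'
#' Runs OPTICS (xi extraction, default xi = 0.1) on the 4D descriptors,
#' selects the cluster with the largest lift-score mass as the target
#' plant (summed scores centred on their foreground mean, which makes the
#' criterion scale-consistent across the nested xi ranges; when no range
#' carries a score mass distinguishable from exchangeable-support noise the
#' largest range is selected instead), and merges every other cluster into the kept set iff (i) its
#' centroid lies within the 90th percentile of the selected cluster's
#' point-to-centroid distances (descriptor space) and (ii) its median depth
#' cue differs from the selected cluster's by less than 15 percent. Noise
#' points are never merged. When xi extraction yields no cluster, the
#' contiguous reachability valley around the global reachability minimum is
#' used as a fallback (logged).
#'
#' @param features a `cluster_features` from [build_descriptors()].
#' @param support lift scores aligned with `features$ids` (vector of
#'   per-foreground-splat S(g)).
#' @param xi OPTICS steepness (default 0.1).
#' @param min_samples OPTICS density floor; default
#'   `max(5, round(0.005 * n))`.
#' @return object of class `cluster_outcome`: `labels` (per foreground
#'   splat, -1 noise), `selected` (cluster id), `kept` (0-based splat ids),
#'   `merge_log` (data.frame of cluster/reason events).
#' @export
optics_cluster_merge <- function(features, support, xi = 0.1,
                                 min_samples = NULL) {
  phi <- features$phi
  n <- nrow(phi)
  stopifnot(length(support) == n)
  if (is.null(min_samples)) min_samples <- max(5, round(0.005 * n))
  if (n < min_samples) stop("fewer foreground splats than min_samples")
  opt <- optics_order(phi, min_samples)
  fine <- extract_xi(opt, xi = xi, min_samples = min_samples)
  # The selection and merge rules operate at plant scale, but the xi
  # hierarchy has no canonical flat level: innermost ranges are organ-scale
  # valleys, outermost ranges are near-root. Selection therefore runs over
  # all extracted ranges using the background-corrected support mass
  # sum(S(g) - mean(S)): the plain sum is monotone under nesting (a parent
  # always outscores its children) whereas the corrected mass is maximized
  # by the range holding the high-support mass and penalized for every
  # below-average point it absorbs. The remaining clusters, which only feed
  # the merge rules, are the maximal extracted ranges disjoint from the
  # selected one.
  labels <- xi_mass_flatten(fine, support)
  if (all(labels == -1L)) {
    message("xi extraction found no cluster; falling back to the densest reachability valley")
    r <- opt$reachability[opt$order]
    finite <- is.finite(r)
    thr <- stats::quantile(r[finite], 0.25, names = FALSE)
    inval <- r <= thr
    inval[!finite] <- FALSE
    # contiguous run containing the global minimum
    jmin <- which.min(ifelse(finite, r, Inf))
    lo <- jmin; while (lo > 1 && inval[lo - 1]) lo <- lo - 1
    hi <- jmin; while (hi < n && inval[hi + 1]) hi <- hi + 1
    labels[opt$order[lo:hi]] <- 0L
  }
  cl_ids <- sort(unique(labels[labels >= 0]))
  # cluster 0 is the score-mass selection made during flattening (or the
  # fallback valley); the remaining clusters only feed the merge rules
  sel <- 0L
  sel_idx <- labels == sel
  cen_sel <- colMeans(phi[sel_idx, , drop = FALSE])
  p90 <- stats::quantile(sqrt(colSums((t(phi[sel_idx, , drop = FALSE]) - cen_sel)^2)),
                         0.90, names = FALSE)
  dep_sel <- stats::median(features$mean_cam_dist[sel_idx])
  kept_mask <- sel_idx
  log_rows <- list()
  for (cl in setdiff(cl_ids, sel)) {
    ci <- labels == cl
    cen <- colMeans(phi[ci, , drop = FALSE])
    dcen <- sqrt(sum((cen - cen_sel)^2))
    dep <- stats::median(features$mean_cam_dist[ci])
    near <- dcen <= p90
    depth_ok <- abs(dep - dep_sel) / dep_sel < 0.15
    if (near && depth_ok) {
      kept_mask <- kept_mask | ci
      log_rows[[length(log_rows) + 1]] <-
        data.frame(cluster = cl, action = "merged",
                   reason = sprintf("centroid %.3f <= P90 %.3f; depth ratio %.3f",
                                    dcen, p90, abs(dep - dep_sel) / dep_sel))
    } else {
      log_rows[[length(log_rows) + 1]] <-
        data.frame(cluster = cl, action = "rejected",
                   reason = if (!near) "centroid beyond P90" else "depth differs >= 15%")
    }
  }
  structure(list(labels = labels, selected = sel,
                 kept = features$ids[kept_mask],
                 merge_log = if (length(log_rows)) do.call(rbind, log_rows)
                 else data.frame(cluster = integer(0), action = character(0),
                                 reason = character(0)),
                 reachability = opt$reachability, order = opt$order),
            class = "cluster_outcome")
}

#' Nearest-neighbour retain
#'
#' Restores rejected Gaussians lying within the global radius
#' \eqn{r_{nr} = \beta \tilde d_{1NN}}, where \eqn{\tilde d_{1NN}} is the
#' median nearest-neighbour distance among the kept Gaussians (world
#' coordinates). A single pass: points restored in this step do not extend
#' the neighbour pool. Candidates are all scene splats not currently kept,
#' including those rejected by the lift threshold.
#'
#' @param kept 0-based ids of currently kept splats.
#' @param splats the full-scene [splat_set()].
#' @param beta radius scale (default 2).
#' @return augmented 0-based id vector (kept plus restored, sorted).
#' @export
nn_retain <- function(kept, splats, beta = 2) {
  stopifnot(length(kept) > 0)
  if (length(kept) < 2) {
    warning("fewer than 2 kept splats; NN-retain skipped")
    return(sort(as.integer(kept)))
  }
  kidx <- match(as.integer(kept), splats$ids)
  if (anyNA(kidx)) stop("kept contains unknown ids")
  kp <- splats$positions[kidx, , drop = FALSE]
  d1 <- FNN::get.knn(kp, k = 1)$nn.dist[, 1]
  r_nr <- beta * stats::median(d1)
  cand <- setdiff(seq_len(n_splats(splats)), kidx)
  if (length(cand) == 0) return(sort(as.integer(kept)))
  dnn <- FNN::get.knnx(kp, splats$positions[cand, , drop = FALSE], k = 1)$nn.dist[, 1]
  restored <- cand[dnn <= r_nr]
  sort(c(as.integer(kept), splats$ids[restored]))
}
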