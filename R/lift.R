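# Stage 1: lifting sparse 2D cue masks into per-Gaussian multi-view
# support scores.

#' Masked footprint fraction of a projected Gaussian
#'
#' Given a projected ellipse with normalized footprint kernel kappa and a
#' binary mask M for the same raster, computes the masked footprint fraction
#' \eqn{\tilde s = \sum_{u \in \Omega} \kappa(u) M(u)} and its
#' opacity-weighted score \eqn{s = \alpha\,\tilde s}.
#'
#' @param ellipse an `ellipse2d` from [project_gaussian()].
#' @param mask logical matrix indexed `[x + 1, y + 1]` (0-based pixels).
#' @param alpha the Gaussian's opacity in [0, 1].
#' @return list with `s_tilde`, `s` and `clipped` (TRUE when the footprint
#'   was empty after clipping, in which case both scores are 0).
#' @export
masked_fraction <- function(ellipse, mask, alpha = 1) {
  if (is.null(ellipse) || nrow(ellipse$footprint) == 0)
    return(list(s_tilde = 0, s = 0, clipped = TRUE))
  m <- mask[cbind(ellipse$footprint[, 1] + 1L, ellipse$footprint[, 2] + 1L)]
  s_tilde <- sum(ellipse$kernel * m)
  list(s_tilde = s_tilde, s = alpha * s_tilde, clipped = FALSE)
}

# Unit eigenvector of the smallest eigenvalue of Sigma (the disc normal for
# flattened foliage Gaussians). Returns NULL when the minimal eigenvalue is
# degenerate (repeated within tol), in which case orientation carries no
# information.
min_axis <- function(Sigma, tol = 1e-9) {
  e <- eigen(Sigma, symmetric = TRUE)
  vals <- e$values
  if (abs(vals[3] - vals[2]) <= tol) return(NULL)
  e$vectors[, 3]
}

#' Geometry- and quality-dependent view weight
#'
#' Computes \eqn{w_v = \bar\alpha_{g,v}\,\max(\cos\theta_{g,v}, 0)\,\rho_v}
#' where \eqn{\bar\alpha} is a visibility proxy (by default the splat's own
#' opacity; optionally the mean of a per-view accumulated-opacity map over
#' the footprint), \eqn{\theta} is the angle between the viewing ray to the
#' Gaussian centre and the Gaussian's minimal-eigenvalue axis (the surface
#' normal of a flattened splat; the absolute cosine is used because the
#' eigenvector sign is arbitrary), and \eqn{\rho_v \in [0,1]} the normalized
#' sharpness of the view.
#'
#' @param splats a [splat_set()].
#' @param index 0-based splat id.
#' @param view a [camera_view()].
#' @param rho normalized sharpness of this view in [0, 1].
#' @param alpha_bar visibility proxy; default `NULL` uses the splat's own
#'   opacity.
#' @return scalar weight in [0, 1].
#' @export
view_weight <- function(splats, index, view, rho, alpha_bar = NULL) {
  i <- match(as.integer(index), splats$ids)
  if (is.na(i)) stop("unknown splat id: ", index)
  if (is.null(alpha_bar))
    alpha_bar <- 1 / (1 + exp(-splats$opacity_logits[i]))
  ray <- splats$positions[i, ] - camera_center(view)
  nr <- sqrt(sum(ray^2))
  if (nr == 0) return(0)
  axis <- min_axis(splat_cov(splats, i))
  ct <- if (is.null(axis)) 1 else abs(sum(ray / nr * axis))
  alpha_bar * max(ct, 0) * rho
}

# Per-view accumulated-opacity map at reduced resolution: front-to-back
# compositing of all splats, A <- A + (1 - A) * alpha * g(u). A coarse
# visibility field; optional (see support_scores mode "rendered").
accumulated_opacity_map <- function(splats, view, k_sigma = 3, scale = 4L) {
  w <- as.integer(ceiling(view$image_size[1] / scale))
  h <- as.integer(ceiling(view$image_size[2] / scale))
  Kd <- view$intrinsics
  Kd[1, ] <- Kd[1, ] / scale
  Kd[2, ] <- Kd[2, ] / scale
  vd <- camera_view(Kd, view$rotation, view$translation, c(w, h),
                    view$sharpness, view$view_index)
  pr <- project_points(view, splats$positions)
  ord <- order(pr$depth)
  ord <- ord[pr$depth[ord] > 0]
  alpha <- 1 / (1 + exp(-splats$opacity_logits))
  A <- matrix(0, w, h)
  for (i in ord) {
    el <- project_gaussian(splats, splats$ids[i], vd, k_sigma)
    if (is.null(el) || nrow(el$footprint) == 0) next
    idx <- cbind(el$footprint[, 1] + 1L, el$footprint[, 2] + 1L)
    g <- el$kernel / max(el$kernel)
    A[idx] <- A[idx] + (1 - A[idx]) * alpha[i] * g
  }
  A
}

#' Multi-view support scores for all Gaussians
#'
#' Aggregates the per-view opacity-weighted masked fractions into the
#' support score \eqn{S(g) = \sum_v w_v s_{g,v} / \sum_v w_v}, summing only
#' over seeded views where the Gaussian projects in front of the camera with
#' a nonempty footprint. Gaussians supported by no view get S = 0.
#'
#' @param splats a [splat_set()].
#' @param views list of all calibrated [camera_view()]s (used for sharpness
#'   normalization across the scene).
#' @param cues a [cue_set()]; masks sharing a view are OR-combined.
#' @param k_sigma footprint truncation (default 3).
#' @param visibility `"opacity"` (default; the splat's own alpha as
#'   visibility proxy) or `"rendered"` (mean of a per-view
#'   accumulated-opacity map over the footprint).
#' @param per_view keep the per-(splat, view) table of s_tilde, s and w.
#' @return object of class `lift_result` with fields `support`, `per_view`
#'   (optional data.frame), `quantile_q`, `threshold` and `foreground`
#'   (the latter filled by [foreground_select()]).
#' @export
support_scores <- function(splats, views, cues, k_sigma = 3,
                           visibility = c("opacity", "rendered"),
                           per_view = FALSE) {
  visibility <- match.arg(visibility)
  if (length(views) == 0) stop("no calibrated views provided")
  masks <- cue_masks_by_view(cues)
  vidx <- vapply(views, function(v) v$view_index, integer(1))
  seeded <- views[vidx %in% as.integer(names(masks))]
  if (length(seeded) == 0) stop("no seeded views: cues reference unknown views")
  for (v in seeded) {
    m <- masks[[as.character(v$view_index)]]
    if (!all(dim(m) == v$image_size))
      stop("cue/view dimension mismatch for view ", v$view_index)
  }
  rho_all <- if (length(views) >= 2)
    normalize_sharpness(vapply(views, function(v) v$sharpness, numeric(1)))
  else rep(1, length(views))
  names(rho_all) <- as.character(vidx)
  alpha <- 1 / (1 + exp(-splats$opacity_logits))
  amaps <- if (visibility == "rendered")
    lapply(seeded, function(v) accumulated_opacity_map(splats, v, k_sigma))
  n <- n_splats(splats)
  num <- numeric(n); den <- numeric(n)
  tab <- if (per_view) vector("list", length(seeded))
  for (k in seq_along(seeded)) {
    v <- seeded[[k]]
    m <- masks[[as.character(v$view_index)]]
    rho <- rho_all[[as.character(v$view_index)]]
    rows <- if (per_view) data.frame(id = integer(0), view = integer(0),
                                     s_tilde = numeric(0), s = numeric(0),
                                     w = numeric(0))
    for (i in seq_len(n)) {
      el <- project_gaussian(splats, splats$ids[i], v, k_sigma)
      if (is.null(el) || nrow(el$footprint) == 0) next
      mf <- masked_fraction(el, m, alpha[i])
      ab <- if (visibility == "rendered") {
        am <- amaps[[k]]
        idx <- cbind(pmin(el$footprint[, 1] %/% 4L + 1L, nrow(am)),
                     pmin(el$footprint[, 2] %/% 4L + 1L, ncol(am)))
        mean(am[idx])
      } else NULL
      w <- view_weight(splats, splats$ids[i], v, rho, alpha_bar = ab)
      num[i] <- num[i] + w * mf$s
      den[i] <- den[i] + w
      if (per_view)
        rows <- rbind(rows, data.frame(id = splats$ids[i], view = v$view_index,
                                       s_tilde = mf$s_tilde, s = mf$s, w = w))
    }
    if (per_view) tab[[k]] <- rows
  }
  S <- ifelse(den > 0, num / den, 0)
  structure(list(support = S, ids = splats$ids,
                 per_view = if (per_view) do.call(rbind, tab),
                 quantile_q = NA_real_, threshold = NA_real_,
                 foreground = NULL,
                 seeded_views = vapply(seeded, function(v) v$view_index, integer(1))),
            class = "lift_result")
}

#' Scene-adaptive foreground selection
#'
#' Thresholds the support scores at the scene quantile
#' \eqn{\tau = \mathrm{quantile}(S, q)} and returns the foreground set
#' \eqn{F = \{g : S(g) \ge \tau\}} (ties kept). The default q = 0.88 keeps
#' the top 12 percent of scores.
#'
#' @param result a `lift_result` from [support_scores()].
#' @param q percentile in (0, 1).
#' @return the updated `lift_result` with `threshold`, `quantile_q` and
#'   `foreground` (0-based splat ids) filled in.
#' @export
foreground_select <- function(result, q = 0.88) {
  stopifnot(inherits(result, "lift_result"), q > 0, q < 1)
  S <- result$support
  tau <- stats::quantile(S, q, names = FALSE)
  if (max(S) == min(S))
    warning("all support scores identical; foreground = all splats")
  result$threshold <- tau
  result$quantile_q <- q
  keep <- S >= tau
  if (tau == 0 && max(S) > 0) {
    # the quantile landed inside the zero-support mass: zero-support splats
    # carry no cue evidence and are not foreground
    message("threshold fell on zero support; restricting foreground to S > 0")
    keep <- S > 0
  }
  result$foreground <- result$ids[keep]
  result
}
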