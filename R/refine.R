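# Stage 3: chromatic refinement in CIELAB and dual export.

#' sRGB to CIELAB conversion
#'
#' Converts sRGB values in [0, 1] (standard 2.4-exponent transfer, D65
#' white) to CIE L*a*b*. Out-of-range inputs are clipped with a warning.
#'
#' @param rgb N x 3 matrix of sRGB values in [0, 1].
#' @return N x 3 matrix of Lab triples (L in [0, 100]).
#' @export
rgb_to_lab <- function(rgb) {
  rgb <- matrix(as.numeric(rgb), ncol = 3)
  if (any(rgb < 0 | rgb > 1)) {
    warning("RGB values outside [0, 1] clipped")
    rgb <- pmin(pmax(rgb, 0), 1)
  }
  grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
}

#' @rdname rgb_to_lab
#' @param lab N x 3 matrix of Lab triples.
#' @return for `lab_to_rgb`: N x 3 sRGB matrix, clipped to [0, 1].
#' @export
lab_to_rgb <- function(lab) {
  lab <- matrix(as.numeric(lab), ncol = 3)
  pmin(pmax(grDevices::convertColor(lab, from = "Lab", to = "sRGB"), 0), 1)
}

# Stratified quantile-cell subsample: partition each Lab channel into
# `bins` quantile bins, then sample proportionally per occupied cell.
quantile_cell_subsample <- function(lab, cap, bins = 8L) {
  n <- nrow(lab)
  if (n <= cap) return(seq_len(n))
  cellcode <- rep(0L, n)
  for (j in 1:3) {
    br <- unique(stats::quantile(lab[, j], probs = seq(0, 1, length.out = bins + 1)))
    b <- cut(lab[, j], breaks = br, include.lowest = TRUE, labels = FALSE)
    cellcode <- cellcode * bins + (b - 1L)
  }
  cells <- split(seq_len(n), cellcode)
  quota <- vapply(cells, length, integer(1)) / n * cap
  take <- floor(quota)
  # distribute the remainder to the cells with the largest fractional parts
  rem <- cap - sum(take)
  if (rem > 0) {
    fr <- order(quota - take, decreasing = TRUE)
    take[fr[seq_len(rem)]] <- take[fr[seq_len(rem)]] + 1L
  }
  idx <- unlist(lapply(seq_along(cells), function(i) {
    ids <- cells[[i]]
    k <- min(length(ids), take[i])
    if (k == 0) return(integer(0))
    if (k == length(ids)) ids else sample(ids, k)
  }))
  sort(idx[seq_len(min(length(idx), cap))])
}

#' Fit a full-covariance Gaussian mixture to Lab colours
#'
#' Fits mixtures with 1 to `max_components` full-covariance components and
#' keeps the one minimizing the Bayesian Information Criterion. Sets larger
#' than `cap` points are reduced by stratified quantile-cell subsampling
#' (8 quantile bins per Lab channel, proportional allocation per occupied
#' cell) so the colour distribution is preserved.
#'
#' @param lab N x 3 Lab matrix (N >= 10).
#' @param max_components maximum number of mixture components (default 4).
#' @param cap subsampling threshold (default 50000).
#' @param rng_seed seed for the stratified subsample (fitting itself uses a
#'   deterministic hierarchical initialization).
#' @return object of class `color_model`: `n_components`, `weights`,
#'   `means` (k x 3), `covariances` (list of 3x3), `dominant` (index of the
#'   maximal-weight component), `bic_trace`.
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_color_gmm <- function(lab, max_components = 4, cap = 50000, rng_seed = 0) {
  lab <- as.matrix(lab)
  stopifnot(nrow(lab) >= 10, ncol(lab) == 3)
  sub <- with_seed(rng_seed, quantile_cell_subsample(lab, cap))
  labs <- lab[sub, , drop = FALSE]
  fit <- with_seed(rng_seed,
    mclust::Mclust(labs, G = 1:max_components, modelNames = "VVV",
                   verbose = FALSE))
  if (is.null(fit)) stop("GMM fit failed")
  k <- fit$G
  covs <- lapply(seq_len(k), function(j) {
    S <- fit$parameters$variance$sigma[, , j]
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < 1e-8) {
      message("singular colour covariance regularized (component ", j, ")")
      S <- S + diag(1e-6, 3)
    }
    S
  })
  w <- fit$parameters$pro
  structure(list(n_components = k, weights = w,
                 means = t(fit$parameters$mean),
                 covariances = covs,
                 dominant = which.max(w),
                 bic_trace = -as.numeric(fit$BIC[, "VVV"]),  # minimized scale
                 n_fit = nrow(labs)),
            class = "color_model")
}

# Squared Mahalanobis distances of Lab rows to a mixture component.
component_mahalanobis2 <- function(lab, model, component) {
  stats::mahalanobis(as.matrix(lab), model$means[component, ],
                     model$covariances[[component]])
}

# Most-probable component per point (weighted Gaussian densities).
assign_component <- function(lab, model) {
  lab <- as.matrix(lab)
  k <- model$n_components
  logd <- vapply(seq_len(k), function(j) {
    S <- model$covariances[[j]]
    d2 <- component_mahalanobis2(lab, model, j)
    log(model$weights[j]) - 0.5 * (d2 + determinant(S)$modulus)
  }, numeric(nrow(lab)))
  if (is.null(dim(logd))) logd <- matrix(logd, nrow = 1)
  max.col(logd, ties.method = "first")
}

#' Chromatic Mahalanobis filter
#'
#' Retains the kept Gaussians whose squared Mahalanobis distance to the
#' dominant mixture component (by weight) lies inside the ellipsoidal
#' chromaticity window \eqn{D_M^2(x) \le \tau(\zeta)}, parameterized by a
#' single coverage value \eqn{\zeta}. \eqn{\tau(\zeta)} is the
#' \eqn{\zeta}-quantile of the in-component Mahalanobis distance — the
#' distance measured against the dominant component — over the candidate
#' set, so exactly the \eqn{1-\zeta} chromatically most distant candidates
#' are attenuated. On a chromatically pure candidate set this retains a
#' \eqn{\zeta} fraction of the dominant component; on a contaminated set
#' the removed tail is occupied by the contaminants, so plant tissue is
#' spared (see the vignette for why the alternative readings of the window
#' behave worse). The default \eqn{\zeta = 0.80}; a relaxed 0.90 is used
#' when preparing training data for organ segmentation.
#'
#' @param kept 0-based splat ids to filter.
#' @param lab Lab colours aligned with `kept` (n x 3).
#' @param model a `color_model` from [fit_color_gmm()].
#' @param zeta coverage in (0, 1), default 0.80.
#' @param tau_method how the window is set: `"candidate"` (default; the
#'   zeta-quantile of the squared distances over all candidates),
#'   `"incomponent"` (quantile over dominant-assigned candidates only) or
#'   `"coverage"` (the theoretical chi-squared quantile).
#' @return list with `refined` (0-based ids), `tau` and `d2`.
#' @export
chroma_filter <- function(kept, lab, model, zeta = 0.80,
                          tau_method = c("candidate", "incomponent", "coverage")) {
  tau_method <- match.arg(tau_method)
  stopifnot(length(kept) == nrow(as.matrix(lab)), zeta > 0, zeta < 1)
  lab <- as.matrix(lab)
  comp <- assign_component(lab, model)
  incomp <- comp == model$dominant
  if (sum(incomp) < 5) {
    warning("dominant component has fewer than 5 members; filter skipped")
    return(list(refined = as.integer(kept), tau = Inf,
                d2 = component_mahalanobis2(lab, model, model$dominant)))
  }
  d2 <- component_mahalanobis2(lab, model, model$dominant)
  tau <- switch(tau_method,
    candidate = stats::quantile(d2, zeta, names = FALSE),
    incomponent = stats::quantile(d2[incomp], zeta, names = FALSE),
    coverage = stats::qchisq(zeta, df = 3))
  list(refined = as.integer(kept)[d2 <= tau], tau = tau, d2 = d2)
}

#' Refine a kept splat subset chromatically
#'
#' Convenience wrapper: derives DC colours of the kept subset, converts to
#' Lab, fits the mixture and applies [chroma_filter()].
#'
#' @param splats full-scene [splat_set()].
#' @param kept 0-based ids to refine.
#' @param zeta coverage (default 0.80).
#' @param rng_seed passed to [fit_color_gmm()].
#' @return list with `refined` ids, `model`, `tau`.
#' @export
refine_subset <- function(splats, kept, zeta = 0.80, rng_seed = 0) {
  sub <- subset_splats(splats, kept)
  lab <- rgb_to_lab(derived_params(sub, "rgb")$rgb)
  model <- fit_color_gmm(lab, rng_seed = rng_seed)
  res <- chroma_filter(kept, lab, model, zeta)
  list(refined = res$refined, model = model, tau = res$tau)
}

#' Sample a coloured point cloud from a Gaussian subset
#'
#' Draws `max(1, round(density * alpha_i))` samples per Gaussian from
#' \eqn{N(\mu_i, \Sigma_i)} truncated at `trunc` Mahalanobis units
#' (rejection sampling in the principal-axis frame), coloured by the
#' splat's DC RGB.
#'
#' @param splats a [splat_set()].
#' @param subset 0-based ids to sample (default all).
#' @param density samples per unit opacity (default 20).
#' @param trunc truncation radius in sigma (default 2).
#' @param rng_seed integer seed.
#' @return list with `points` (M x 3), `rgb` (M x 3), `source_id`
#'   (0-based splat id per sample).
#' @export
export_point_cloud <- function(splats, subset = NULL, density = 20,
                               trunc = 2, rng_seed = 0) {
  stopifnot(density >= 1)
  subset <- if (is.null(subset)) splats$ids else as.integer(subset)
  if (length(subset) == 0) stop("empty subset")
  sub <- subset_splats(splats, subset)
  dp <- derived_params(sub, c("alpha", "rgb"))
  nper <- pmax(1L, as.integer(round(density * dp$alpha)))
  with_seed(rng_seed, {
    pts <- vector("list", n_splats(sub))
    for (i in seq_len(n_splats(sub))) {
      R <- quat_to_rotmat(sub$rotations[i, ])
      s <- exp(sub$log_scales[i, ])
      m <- nper[i]
      acc <- matrix(numeric(0), ncol = 3)
      while (nrow(acc) < m) {
        z <- matrix(stats::rnorm(3 * max(m, 8L)), ncol = 3)
        ok <- rowSums(z^2) <= trunc^2
        acc <- rbind(acc, z[ok, , drop = FALSE])
      }
      z <- acc[seq_len(m), , drop = FALSE]
      pts[[i]] <- t(R %*% (t(z) * s) + sub$positions[i, ])
    }
    points <- do.call(rbind, pts)
    list(points = points,
         rgb = dp$rgb[rep(seq_len(n_splats(sub)), nper), , drop = FALSE],
         source_id = subset[rep(seq_along(subset), nper)])
  })
}

#' Write a coloured point cloud as binary PLY
#'
#' @param cloud result of [export_point_cloud()].
#' @param path output `.ply` path.
#' @return `path`, invisibly.
#' @export
write_point_cloud_ply <- function(cloud, path) {
  n <- nrow(cloud$points)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("ply", "format binary_little_endian 1.0",
               sprintf("element vertex %d", n),
               sprintf("property float %s", c("x", "y", "z")),
               sprintf("property uchar %s", c("red", "green", "blue")),
               "end_header"), con)
  cols <- round(pmin(pmax(cloud$rgb, 0), 1) * 255)
  for (i in seq_len(n)) {
    writeBin(as.numeric(cloud$points[i, ]), con, size = 4L, endian = "little")
    writeBin(as.raw(cols[i, ]), con)
  }
  invisible(path)
}
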