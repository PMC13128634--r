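#' 3D Gaussian Splatting scene container
#'
#' A `splat_set` holds the per-Gaussian parameters of a 3DGS scene: centre
#' positions, per-axis log-scales, orientation quaternions (w, x, y, z),
#' opacity logits and the degree-0 spherical-harmonic (DC) colour
#' coefficients. Quaternions are renormalized on construction when they
#' deviate from unit norm by more than 1e-6.
#'
#' @param positions N x 3 matrix of world-space Gaussian centres.
#' @param log_scales N x 3 matrix of per-axis log standard deviations.
#' @param rotations N x 4 matrix of quaternions in (w, x, y, z) order.
#' @param opacity_logits length-N vector of opacity logits.
#' @param dc_color N x 3 matrix of SH DC coefficients.
#' @param extra optional named list of additional per-splat columns carried
#'   through PLY round trips verbatim (e.g. normals, higher-order SH).
#' @return object of class `splat_set` with stable integer `ids` 0..N-1.
#' @export
splat_set <- function(positions, log_scales, rotations, opacity_logits,
                      dc_color, extra = NULL) {
  positions <- as.matrix(positions)
  log_scales <- as.matrix(log_scales)
  rotations <- as.matrix(rotations)
  dc_color <- as.matrix(dc_color)
  n <- nrow(positions)
  stopifnot(ncol(positions) == 3, ncol(log_scales) == 3,
            ncol(rotations) == 4, ncol(dc_color) == 3,
            nrow(log_scales) == n, nrow(rotations) == n,
            length(opacity_logits) == n, nrow(dc_color) == n)
  if (n == 0) stop("empty scene: a splat_set needs at least one Gaussian")
  bad <- !stats::complete.cases(cbind(positions, log_scales, rotations,
                                      opacity_logits, dc_color))
  if (any(bad))
    stop("non-finite splat parameters at ids: ",
         paste(utils::head(which(bad) - 1L, 5), collapse = ", "))
  nrm <- sqrt(rowSums(rotations^2))
  if (any(nrm == 0)) stop("zero-norm quaternion")
  fix <- abs(nrm - 1) > 1e-6
  if (any(fix)) rotations[fix, ] <- rotations[fix, , drop = FALSE] / nrm[fix]
  structure(list(
    positions = positions, log_scales = log_scales, rotations = rotations,
    opacity_logits = as.numeric(opacity_logits), dc_color = dc_color,
    ids = seq_len(n) - 1L, extra = extra
  ), class = "splat_set")
}

#' @export
print.splat_set <- function(x, ...) {
  cat(sprintf("splat_set: %d Gaussians\n", length(x$ids)))
  invisible(x)
}

#' Number of Gaussians in a splat set
#' @param splats a `splat_set`.
#' @return integer count.
#' @export
n_splats <- function(splats) length(splats$ids)

#' Subset a splat set by 0-based ids
#'
#' @param splats a `splat_set`.
#' @param ids 0-based splat ids to keep (order preserved).
#' @return a new `splat_set`; `ids` are reindexed 0..n-1, the original ids
#'   are kept in attribute `source_ids`.
#' @export
subset_splats <- function(splats, ids) {
  idx <- match(as.integer(ids), splats$ids)
  if (anyNA(idx)) stop("unknown splat ids")
  out <- splat_set(splats$positions[idx, , drop = FALSE],
                   splats$log_scales[idx, , drop = FALSE],
                   splats$rotations[idx, , drop = FALSE],
                   splats$opacity_logits[idx],
                   splats$dc_color[idx, , drop = FALSE],
                   extra = if (!is.null(splats$extra))
                     lapply(splats$extra, function(col) col[idx]))
  attr(out, "source_ids") <- splats$ids[idx]
  out
}

#' Derived per-Gaussian parameters
#'
#' Computes the quantities used throughout the pipeline from the stored
#' optimization parameters: the 3x3 world-space covariance
#' \eqn{\Sigma = R\,\mathrm{diag}(e^{2s})\,R^\top}, the opacity
#' \eqn{\alpha = \sigma(\omega) = 1/(1+e^{-\omega})}, and the DC RGB colour
#' \eqn{\mathrm{clip}(0.5 + C_0\,c_{dc}, 0, 1)} with the degree-0 SH constant
#' \eqn{C_0 = 0.28209479177387814}.
#'
#' @param splats a `splat_set`.
#' @param which subset of `c("cov", "alpha", "rgb")` to compute.
#' @return list with elements `cov` (list of 3x3 matrices), `alpha`
#'   (numeric vector in (0,1)) and `rgb` (N x 3 matrix in [0,1]).
#' @export
derived_params <- function(splats, which = c("cov", "alpha", "rgb")) {
  out <- list()
  if ("cov" %in% which) {
    out$cov <- lapply(seq_len(n_splats(splats)), function(i) {
      R <- quat_to_rotmat(splats$rotations[i, ])
      s2 <- exp(splats$log_scales[i, ])^2
      S <- R %*% diag(s2, 3) %*% t(R)
      (S + t(S)) / 2
    })
  }
  if ("alpha" %in% which) out$alpha <- 1 / (1 + exp(-splats$opacity_logits))
  if ("rgb" %in% which) {
    C0 <- 0.28209479177387814
    out$rgb <- pmin(pmax(0.5 + C0 * splats$dc_color, 0), 1)
  }
  out
}

# Single-splat covariance (3x3), avoiding the full list when only a few are
# needed.
splat_cov <- function(splats, i) {
  R <- quat_to_rotmat(splats$rotations[i, ])
  s2 <- exp(splats$log_scales[i, ])^2
  S <- R %*% diag(s2, 3) %*% t(R)
  (S + t(S)) / 2
}
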