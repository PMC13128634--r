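# Video-frame subsampling policies used before structure-from-motion.

#' Variance-of-Laplacian sharpness score
#'
#' Applies the 3x3 discrete Laplacian (4-neighbour stencil) to a grayscale
#' image and returns the variance of the response over all valid (interior)
#' pixels. Higher values indicate sharper frames; a constant image scores 0.
#'
#' @param image numeric matrix (grayscale image), at least 3x3.
#' @return nonnegative scalar.
#' @export
laplacian_variance <- function(image) {
  image <- as.matrix(image)
  nr <- nrow(image); nc <- ncol(image)
  if (nr < 3 || nc < 3) stop("image must be at least 3x3")
  ci <- 2:(nr - 1); cj <- 2:(nc - 1)
  resp <- image[ci - 1, cj] + image[ci + 1, cj] +
    image[ci, cj - 1] + image[ci, cj + 1] - 4 * image[ci, cj]
  v <- stats::var(as.vector(resp))
  if (is.na(v)) 0 else v
}

#' Robust per-scene sharpness normalization
#'
#' Clips raw scores to their 5th-95th percentile range and rescales
#' affinely so that P5 maps to 0 and P95 to 1. When the two percentiles
#' coincide (degenerate spread) all frames receive rho = 1.
#'
#' @param scores numeric vector of raw variance-of-Laplacian scores
#'   (>= 2 frames).
#' @return vector of rho values in [0, 1].
#' @export
normalize_sharpness <- function(scores) {
  stopifnot(length(scores) >= 2, all(is.finite(scores)))
  p <- stats::quantile(scores, c(0.05, 0.95), names = FALSE)
  if (p[2] <= p[1]) {
    message("degenerate sharpness spread: all frames given rho = 1")
    return(rep(1, length(scores)))
  }
  pmin(pmax((scores - p[1]) / (p[2] - p[1]), 0), 1)
}

#' Frame score table
#'
#' @param frame_index strictly increasing integer frame positions.
#' @param sharpness per-frame variance-of-Laplacian scores (>= 0).
#' @param motion per-frame inter-frame displacement proxy in pixels
#'   (displacement relative to the previous frame; first frame 0).
#' @return data.frame of class `frame_scores`.
#' @export
frame_scores <- function(frame_index, sharpness, motion = NULL) {
  stopifnot(all(diff(frame_index) > 0), all(sharpness >= 0))
  if (is.null(motion)) motion <- rep(0, length(frame_index))
  structure(data.frame(frame_index = as.integer(frame_index),
                       sharpness = sharpness, motion = motion),
            class = c("frame_scores", "data.frame"))
}

#' Translation proxy between two frames
#'
#' Cheap inter-frame motion estimate: the image is divided into a grid of
#' 16x16-pixel patches and each patch of the first frame is matched against
#' the second by integer-shift SSD search; the median displacement magnitude
#' (pixels) is returned.
#'
#' @param a,b grayscale image matrices of equal size.
#' @param patch patch side in pixels (default 16).
#' @param search maximum absolute shift searched per axis (default 8).
#' @return nonnegative scalar displacement in pixels.
#' @export
estimate_motion <- function(a, b, patch = 16L, search = 8L) {
  stopifnot(all(dim(a) == dim(b)))
  nr <- nrow(a); nc <- ncol(a)
  xs <- seq(1 + search, nr - patch - search, by = patch)
  ys <- seq(1 + search, nc - patch - search, by = patch)
  if (length(xs) == 0 || length(ys) == 0) return(0)
  disp <- c()
  for (x in xs) for (y in ys) {
    pa <- a[x:(x + patch - 1), y:(y + patch - 1)]
    best <- c(0, 0); bestssd <- Inf
    for (dx in -search:search) for (dy in -search:search) {
      pb <- b[(x + dx):(x + dx + patch - 1), (y + dy):(y + dy + patch - 1)]
      ssd <- sum((pa - pb)^2)
      if (ssd < bestssd) { bestssd <- ssd; best <- c(dx, dy) }
    }
    disp <- c(disp, sqrt(sum(best^2)))
  }
  stats::median(disp)
}

#' Select a subset of video frames for reconstruction
#'
#' Three policies:
#' \describe{
#'   \item{uniform}{evenly spaced frames, start-anchored at index 0.}
#'   \item{sharpness}{top-k frames by sharpness, re-sorted temporally.}
#'   \item{coverage_sharpness}{the sequence is split into k contiguous
#'     equal windows; within each window the sharpest frame is retained,
#'     skipping candidates whose accumulated motion relative to the
#'     previously retained frame is below `min_motion` (falling back to the
#'     window's sharpest when no candidate qualifies).}
#' }
#'
#' @param table a [frame_scores()] table.
#' @param keep_fraction fraction of frames to keep in (0, 1].
#' @param policy one of `"uniform"`, `"sharpness"`, `"coverage_sharpness"`.
#' @param min_motion minimum parallax proxy in pixels (default 2).
#' @return strictly increasing vector of retained `frame_index` values.
#' @export
select_frames <- function(table, keep_fraction,
                          policy = c("coverage_sharpness", "uniform", "sharpness"),
                          min_motion = 2) {
  policy <- match.arg(policy)
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  n <- nrow(table)
  k <- round(keep_fraction * n)
  if (k < 2) stop("too few frames retained: keep_fraction * N < 2")
  idx <- switch(policy,
    uniform = floor((0:(k - 1)) * n / k) + 1L,
    sharpness = sort(order(table$sharpness, decreasing = TRUE)[1:k]),
    coverage_sharpness = {
      bounds <- floor((0:k) * n / k)
      cummot <- cumsum(table$motion)
      kept <- integer(0)
      for (w in seq_len(k)) {
        win <- (bounds[w] + 1):bounds[w + 1]
        cand <- win[order(table$sharpness[win], decreasing = TRUE)]
        pick <- NA_integer_
        for (cc in cand) {
          if (length(kept) == 0 ||
              abs(cummot[cc] - cummot[kept[length(kept)]]) >= min_motion) {
            pick <- cc; break
          }
        }
        if (is.na(pick)) {
          message(sprintf("window %d: no candidate met min_motion; keeping sharpest", w))
          pick <- cand[1]
        }
        kept <- c(kept, pick)
      }
      kept
    })
  sort(unique(table$frame_index[idx]))
}
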