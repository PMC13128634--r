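#' Calibrated pinhole camera view
#'
#' Stores the intrinsics, world-to-camera pose, image size, raw sharpness
#' score and list position of one calibrated view. The camera convention is
#' `x_cam = R %*% x_world + t` with the optical axis along +z in camera
#' coordinates; pixels are 0-based with the origin at the top-left corner and
#' pixel centres at integer coordinates.
#'
#' @param intrinsics 3x3 upper-triangular pinhole matrix (zero skew).
#' @param rotation 3x3 world-to-camera rotation (orthonormal, det +1).
#' @param translation length-3 world-to-camera translation.
#' @param image_size integer (width, height) in pixels.
#' @param sharpness raw variance-of-Laplacian score (>= 0).
#' @param view_index integer position in the calibrated camera list.
#' @return object of class `camera_view`.
#' @export
camera_view <- function(intrinsics, rotation, translation, image_size,
                        sharpness = 0, view_index = 0L) {
  intrinsics <- as.matrix(intrinsics); rotation <- as.matrix(rotation)
  stopifnot(all(dim(intrinsics) == c(3, 3)), all(dim(rotation) == c(3, 3)),
            length(translation) == 3, length(image_size) == 2,
            sharpness >= 0)
  if (intrinsics[1, 1] <= 0 || intrinsics[2, 2] <= 0 ||
      any(abs(intrinsics[lower.tri(intrinsics)]) > 1e-9) ||
      abs(intrinsics[3, 3] - 1) > 1e-9)
    stop("intrinsics must be upper triangular with positive focal lengths")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 || det(rotation) < 0)
    stop("rotation must be orthonormal with det +1")
  structure(list(intrinsics = intrinsics, rotation = rotation,
                 translation = as.numeric(translation),
                 image_size = as.integer(image_size),
                 sharpness = as.numeric(sharpness),
                 view_index = as.integer(view_index)),
            class = "camera_view")
}

#' Camera centre in world coordinates
#' @param view a [camera_view()].
#' @return length-3 numeric vector \eqn{-R^\top t}.
#' @export
camera_center <- function(view) as.numeric(-crossprod(view$rotation, view$translation))

#' Project world points through a pinhole camera
#'
#' @param view a [camera_view()].
#' @param points N x 3 matrix of world coordinates.
#' @return list with `px` (N x 2 pixel coordinates) and `depth`
#'   (camera-frame z; points with `depth <= 0` are behind the camera and
#'   their pixel coordinates are `NA`).
#' @export
project_points <- function(view, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  cam <- t(view$rotation %*% t(points) + view$translation)
  z <- cam[, 3]
  K <- view$intrinsics
  px <- cbind(K[1, 1] * cam[, 1] / z + K[1, 3],
              K[2, 2] * cam[, 2] / z + K[2, 3])
  px[z <= 0, ] <- NA_real_
  list(px = px, depth = z)
}

# Is each world point inside the camera frustum (in front and inside image
# bounds, tested at pixel centres)?
in_frustum <- function(view, points) {
  pr <- project_points(view, points)
  w <- view$image_size[1]; h <- view$image_size[2]
  ok <- pr$depth > 0 & !is.na(pr$px[, 1]) &
    pr$px[, 1] >= 0 & pr$px[, 1] <= w - 1 &
    pr$px[, 2] >= 0 & pr$px[, 2] <= h - 1
  ok & !is.na(ok)
}

#' Project one Gaussian to an image-space ellipse with footprint kernel
#'
#' Projects the Gaussian's centre through the pinhole model and linearizes
#' the projection at the centre (perspective Jacobian J), giving the 2D
#' image-space covariance \eqn{J W \Sigma W^\top J^\top} where W is the
#' world-to-camera rotation. The footprint is the set of pixels whose centres
#' lie inside the `k_sigma` Mahalanobis ellipse, clipped to image bounds; the
#' kernel holds the 2D Gaussian density evaluated at pixel centres,
#' renormalized to sum to one over the footprint.
#'
#' @param splats a [splat_set()].
#' @param index 0-based splat id.
#' @param view a [camera_view()].
#' @param k_sigma footprint truncation radius in Mahalanobis units
#'   (default 3).
#' @return an object of class `ellipse2d` with fields `center`, `cov2d`,
#'   `footprint` (M x 2 integer 0-based pixel coordinates), `kernel`
#'   (length-M weights summing to 1 when nonempty) and `clipped`;
#'   or `NULL` when the Gaussian centre is behind the camera.
#' @export
project_gaussian <- function(splats, index, view, k_sigma = 3) {
  i <- match(as.integer(index), splats$ids)
  if (is.na(i)) stop("unknown splat id: ", index)
  mu <- splats$positions[i, ]
  cam <- as.numeric(view$rotation %*% mu + view$translation)
  if (cam[3] <= 0) return(NULL)
  K <- view$intrinsics
  fx <- K[1, 1]; fy <- K[2, 2]
  z <- cam[3]
  center <- c(fx * cam[1] / z + K[1, 3], fy * cam[2] / z + K[2, 3])
  J <- matrix(c(fx / z, 0, -fx * cam[1] / z^2,
                0, fy / z, -fy * cam[2] / z^2), nrow = 2, byrow = TRUE)
  Sigma <- splat_cov(splats, i)
  JW <- J %*% view$rotation
  cov2d <- JW %*% Sigma %*% t(JW)
  cov2d <- (cov2d + t(cov2d)) / 2
  ev <- eigen(cov2d, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {  # near-singular projection: standard 3DGS dilation
    cov2d <- cov2d + diag(0.3, 2)
  }
  ellipse_footprint(center, cov2d, k_sigma, view$image_size)
}

# Footprint + normalized kernel for a 2D Gaussian on a raster. Exposed via
# project_gaussian; separated for testability and reuse by the mask renderer.
ellipse_footprint <- function(center, cov2d, k_sigma, image_size) {
  w <- image_size[1]; h <- image_size[2]
  Pm <- solve(cov2d)
  half <- k_sigma * sqrt(pmax(diag(cov2d), 0))
  x0 <- max(0L, as.integer(floor(center[1] - half[1])))
  x1 <- min(w - 1L, as.integer(ceiling(center[1] + half[1])))
  y0 <- max(0L, as.integer(floor(center[2] - half[2])))
  y1 <- min(h - 1L, as.integer(ceiling(center[2] + half[2])))
  clipped <- center[1] - half[1] < 0 || center[1] + half[1] > w - 1 ||
    center[2] - half[2] < 0 || center[2] + half[2] > h - 1
  out <- structure(list(center = center, cov2d = cov2d,
                        footprint = matrix(integer(0), ncol = 2),
                        kernel = numeric(0), clipped = clipped),
                   class = "ellipse2d")
  if (x1 < x0 || y1 < y0) return(out)
  gx <- x0:x1; gy <- y0:y1
  dx <- rep(gx, times = length(gy)) - center[1]
  dy <- rep(gy, each = length(gx)) - center[2]
  d2 <- Pm[1, 1] * dx^2 + 2 * Pm[1, 2] * dx * dy + Pm[2, 2] * dy^2
  keep <- d2 <= k_sigma^2
  if (!any(keep)) return(out)
  fx <- rep(gx, times = length(gy))[keep]
  fy <- rep(gy, each = length(gx))[keep]
  k <- exp(-0.5 * d2[keep])
  out$footprint <- cbind(fx, fy)
  out$kernel <- k / sum(k)
  out
}
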