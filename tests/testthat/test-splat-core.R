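# Splat containers, PLY round-trips, derived parameters, and projection
# geometry.

test_that("PLY round-trip is bit-identical and validation rejects bad input", {
  b <- fx_bundle(0)
  p1 <- withr::local_tempfile(fileext = ".ply")
  p2 <- withr::local_tempfile(fileext = ".ply")
  write_splat_ply(b$scene, p1)
  s2 <- read_splat_ply(p1)
  write_splat_ply(s2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  expect_equal(n_splats(s2), n_splats(b$scene))
  expect_identical(s2$ids, b$scene$ids)
  expect_identical(s2$positions, b$scene$positions)

  # quaternion renormalization: (2,0,0,0) stored as (1,0,0,0)
  s <- splat_set(matrix(0, 1, 3), matrix(0, 1, 3),
                 matrix(c(2, 0, 0, 0), 1, 4), 0, matrix(0, 1, 3))
  expect_equal(s$rotations[1, ], c(1, 0, 0, 0))

  # validation errors
  expect_error(splat_set(matrix(numeric(0), 0, 3), matrix(numeric(0), 0, 3),
                         matrix(numeric(0), 0, 4), numeric(0),
                         matrix(numeric(0), 0, 3)),
               "empty scene")
  expect_error(splat_set(matrix(c(NA, 0, 0), 1, 3), matrix(0, 1, 3),
                         matrix(c(1, 0, 0, 0), 1, 4), 0, matrix(0, 1, 3)),
               "ids")
  expect_error(splat_set(matrix(0, 1, 3), matrix(0, 1, 3),
                         matrix(0, 1, 4), 0, matrix(0, 1, 3)),
               "zero-norm")
  bad <- withr::local_tempfile(fileext = ".ply")
  writeLines("not a ply", bad)
  expect_error(read_splat_ply(bad), "not a PLY")
})

test_that("derived parameters follow the activation definitions", {
  # omega = 0 -> alpha = 0.5
  s <- splat_set(matrix(0, 1, 3), matrix(0, 1, 3),
                 matrix(c(1, 0, 0, 0), 1, 4), 0, matrix(0, 1, 3))
  d <- derived_params(s)
  expect_equal(d$alpha[1], 0.5)
  # zero log-scales + identity rotation -> identity covariance
  expect_equal(d$cov[[1]], diag(3), tolerance = 1e-12)
  # dc = 0 -> mid-gray
  expect_equal(d$rgb[1, ], c(0.5, 0.5, 0.5))
  # adding ln 2 to every log-scale scales covariance eigenvalues by 4
  s2 <- splat_set(matrix(0, 1, 3), matrix(log(2), 1, 3),
                  matrix(c(0.5, 0.5, 0.5, 0.5), 1, 4), 0, matrix(0, 1, 3))
  e1 <- eigen(derived_params(s2)$cov[[1]])$values
  s3 <- splat_set(matrix(0, 1, 3), matrix(log(2) + log(2), 1, 3),
                  matrix(c(0.5, 0.5, 0.5, 0.5), 1, 4), 0, matrix(0, 1, 3))
  e2 <- eigen(derived_params(s3)$cov[[1]])$values
  expect_equal(e2, 4 * e1, tolerance = 1e-12)
})

test_that("subset_splats reindexes ids and preserves provenance", {
  b <- fx_bundle(0)
  pick <- b$scene$ids[c(5, 10, 20)]
  sub <- subset_splats(b$scene, pick)
  expect_equal(sub$ids, 0:2)
  expect_equal(attr(sub, "source_ids"), pick)
  expect_equal(sub$positions, b$scene$positions[pick + 1L, , drop = FALSE])
})

test_that("generator scenes carry contiguous zero-based ids", {
  b <- fx_bundle(0)
  expect_equal(b$scene$ids, seq_len(n_splats(b$scene)) - 1L)
  expect_equal(length(b$gt$plant_label), n_splats(b$scene))
})

test_that("projection matches the pinhole and linearized-covariance oracles", {
  # isotropic splat on the optical axis: f = 100, depth 1, scale 0.01
  # -> 2D covariance (f * scale)^2 = 1 px^2 per axis
  K <- matrix(c(100, 0, 32, 0, 100, 32, 0, 0, 1), 3, 3, byrow = TRUE)
  v <- camera_view(K, diag(3), c(0, 0, 0), c(64, 64))
  s <- fx_iso_splats(matrix(c(0, 0, 1), 1, 3), scale = 0.01)
  e <- project_gaussian(s, 0, v)
  expect_equal(e$center, c(32, 32), tolerance = 1e-9)
  expect_equal(e$cov2d, diag(2), tolerance = 1e-6)

  # splats behind the camera project to NULL / NA
  sb <- fx_iso_splats(matrix(c(0, 0, -1), 1, 3))
  expect_null(project_gaussian(sb, 0, v))
  expect_true(all(is.na(project_points(v, matrix(c(0, 0, -1), 1, 3))$px)))

  # homogeneous pinhole oracle on 100 random point/camera pairs
  set.seed(11)
  for (i in 1:100) {
    eye <- stats::rnorm(3, sd = 2)
    pt <- matrix(stats::rnorm(3, sd = 0.2), 1, 3)
    if (sqrt(sum((pt - eye)^2)) < 0.5) next
    cam <- fx_lookat_camera(eye, at = c(0, 0, 0))
    pr <- project_points(cam, pt)
    Kx <- cam$intrinsics %*% (cam$rotation %*% t(pt) + cam$translation)
    if (Kx[3] <= 0) {
      expect_true(all(is.na(pr$px)))
    } else {
      expect_equal(as.numeric(pr$px), as.numeric(Kx[1:2] / Kx[3]),
                   tolerance = 1e-8)
      expect_equal(pr$depth, Kx[3], tolerance = 1e-8)
    }
  }
})

test_that("ellipse footprint kernels are normalized over their pixels", {
  set.seed(13)
  v <- fx_lookat_camera(c(0, -1.2, 0.4), at = c(0, 0, 0.3))
  total <- 0L
  for (i in 1:1000) {
    s <- fx_iso_splats(matrix(c(stats::rnorm(2, sd = 0.15),
                                stats::runif(1, 0.1, 0.5)), 1, 3),
                       scale = stats::runif(1, 0.003, 0.02))
    e <- project_gaussian(s, 0, v)
    if (is.null(e) || length(e$kernel) == 0) next
    expect_equal(sum(e$kernel), 1, tolerance = 1e-9)
    total <- total + 1L
  }
  expect_gt(total, 900)
})

test_that("camera validation and center computation behave", {
  K <- matrix(c(100, 0, 32, 0, 100, 32, 0, 0, 1), 3, 3, byrow = TRUE)
  badK <- K
  badK[2, 1] <- 5
  expect_error(camera_view(badK, diag(3), c(0, 0, 0), c(64, 64)), "triangular")
  expect_error(camera_view(K, diag(3) * 2, c(0, 0, 0), c(64, 64)), "orthonormal")
  eye <- c(0.3, -1.1, 0.7)
  cam <- fx_lookat_camera(eye)
  expect_equal(camera_center(cam), eye, tolerance = 1e-12)
})
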