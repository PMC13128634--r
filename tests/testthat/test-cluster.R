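# Descriptors, OPTICS ordering/extraction, cluster selection + merging, and
# neighborhood retention.

fx_blob <- function(center, n, sd = 0.02, seed = 1) {
  set.seed(seed)
  sweep(matrix(stats::rnorm(n * 3, sd = sd), n, 3), 2, center, "+")
}

fx_ring_cams <- function(r = 1.5, z = 0.8, k = 4) {
  lapply(seq_len(k), function(i) {
    a <- 2 * pi * (i - 1) / k
    fx_lookat_camera(c(r * cos(a), r * sin(a), z), at = c(0, 0, 0),
                     view_index = i - 1L)
  })
}

test_that("robust_z standardizes by median and MAD", {
  expect_equal(robust_z(c(1, 2, 3)), c(-1, 0, 1))
  zc <- robust_z(rep(5, 7))
  expect_equal(as.numeric(zc), rep(0, 7))
  expect_true(isTRUE(attr(zc, "degenerate")))
  # affine invariance for a > 0
  set.seed(2)
  x <- stats::rnorm(50)
  expect_equal(as.numeric(robust_z(3.7 * x + 11)), as.numeric(robust_z(x)),
               tolerance = 1e-12)
  expect_error(robust_z(c(1, NA)), "finite")
})

test_that("mean camera distance averages over visible views only", {
  K <- matrix(c(100, 0, 32, 0, 100, 32, 0, 0, 1), 3, 3, byrow = TRUE)
  origin_cam <- camera_view(K, diag(3), c(0, 0, 0), c(64, 64), view_index = 0L)
  s <- fx_iso_splats(matrix(c(0, 0, 2), 1, 3))
  f <- build_descriptors(0L, s, list(origin_cam))
  expect_equal(f$mean_cam_dist, 2, tolerance = 1e-9)

  cams <- list(fx_lookat_camera(c(1, 0, 0), up = c(0, 1, 0), view_index = 0L),
               fx_lookat_camera(c(-1, 0, 0), up = c(0, 1, 0), view_index = 1L))
  s0 <- fx_iso_splats(matrix(c(0, 0, 0), 1, 3))
  f0 <- build_descriptors(0L, s0, cams)
  expect_equal(f0$mean_cam_dist, 1, tolerance = 1e-9)
})

test_that("descriptors are robust z-scores of position and depth", {
  cams <- fx_ring_cams()
  pos <- cbind(c(-0.1, 0, 0.1), 0, 0.2)
  s <- fx_iso_splats(pos)
  f <- suppressMessages(build_descriptors(0:2, s, cams))
  expect_equal(f$phi[, 1], c(-1, 0, 1), tolerance = 1e-9)
  expect_equal(f$phi[, 2], rep(0, 3))  # constant coordinate -> degenerate 0
  expect_equal(dim(f$phi), c(3, 4))
})

test_that("optics ordering and xi clusters match sklearn", {
  skip_if(Sys.which("python3") == "", "python3 not on PATH")
  set.seed(7)
  x <- rbind(matrix(stats::rnorm(120 * 2, sd = 0.08), 120, 2),
             sweep(matrix(stats::rnorm(80 * 2, sd = 0.06), 80, 2), 2,
                   c(2, 0), "+"),
             sweep(matrix(stats::rnorm(60 * 2, sd = 0.05), 60, 2), 2,
                   c(0, 2), "+"))
  opt <- optics_order(x, min_samples = 5)

  csv <- withr::local_tempfile(fileext = ".csv")
  out <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(x, csv, row.names = FALSE, col.names = FALSE, sep = ",")
  py <- sprintf("
import numpy as np
from sklearn.cluster import OPTICS
x = np.loadtxt(%s, delimiter=',')
m = OPTICS(min_samples=5, xi=0.1).fit(x)
np.savetxt(%s, np.c_[m.ordering_, m.reachability_[m.ordering_], m.labels_],
           delimiter=',')
", shQuote(csv), shQuote(out))
  st <- system2("python3", c("-c", shQuote(py)), stdout = TRUE, stderr = TRUE)
  skip_if(!file.exists(out) || file.size(out) == 0,
          paste("sklearn unavailable:", paste(st, collapse = " ")))
  ref <- utils::read.csv(out, header = FALSE)

  expect_equal(opt$order, as.integer(ref$V1) + 1L)
  rr <- opt$reachability[opt$order]
  fin <- is.finite(rr) & is.finite(ref$V2)
  expect_equal(rr[fin], ref$V2[fin], tolerance = 1e-8)
  expect_equal(sum(!is.finite(rr)), sum(!is.finite(ref$V2)))

  lab <- extract_xi(opt, xi = 0.1, min_samples = 5)
  skl <- as.integer(ref$V3)
  expect_identical(as.integer(lab), skl)
})

test_that("support mass picks the cued blob and merging respects the rules", {
  # mimics a cue-lifted foreground: mostly the target blob plus a smaller
  # far contaminant, so descriptor scales are set by the target's spread
  cams <- fx_ring_cams()
  a <- fx_blob(c(0, 0, 0.2), 300, seed = 10)
  b <- fx_blob(c(0.5, 0, 0.2), 60, seed = 11)
  s <- fx_iso_splats(rbind(a, b))
  feats <- build_descriptors(s$ids, s, cams)
  support <- c(stats::runif(300, 0.6, 1), stats::runif(60, 0, 0.05))
  out <- optics_cluster_merge(feats, support)
  in_a <- out$kept < 300
  expect_gt(mean(in_a), 0.95)           # selected cluster is the cued blob
  expect_lt(sum(out$kept >= 300), 4)    # distant blob not merged in

  # a blob split by a thin gap is merged back (centroid within P90)
  a1 <- fx_blob(c(-0.03, 0, 0.2), 200, sd = 0.012, seed = 12)
  a2 <- fx_blob(c(0.03, 0, 0.2), 200, sd = 0.012, seed = 13)
  far <- fx_blob(c(0.6, 0, 0.2), 150, sd = 0.015, seed = 14)
  s2 <- fx_iso_splats(rbind(a1, a2, far))
  feats2 <- build_descriptors(s2$ids, s2, cams)
  support2 <- c(stats::runif(200, 0.6, 1), stats::runif(200, 0.25, 0.65),
                stats::runif(150, 0, 0.05))
  out2 <- optics_cluster_merge(feats2, support2)
  expect_gt(mean(0:399 %in% out2$kept), 0.9)
  expect_lt(sum(out2$kept >= 400), 8)
})

test_that("a depth clone with 1.5x camera distance is not merged", {
  # two clusters overlapping in x-y but at different heights: the ring
  # cameras see them at mean distances differing well beyond the 15% gate
  cams <- lapply(1:4, function(i) {
    a <- 2 * pi * (i - 1) / 4
    fx_lookat_camera(c(1.2 * cos(a), 1.2 * sin(a), 1.6), at = c(0, 0, 0.6),
                     view_index = i - 1L)
  })
  near <- fx_blob(c(0, 0, 1.2), 200, sd = 0.02, seed = 20)
  clone <- fx_blob(c(0, 0, 0.0), 200, sd = 0.02, seed = 21)
  s <- fx_iso_splats(rbind(near, clone))
  feats <- build_descriptors(s$ids, s, cams)
  ratio <- mean(feats$mean_cam_dist[1:200]) /
    mean(feats$mean_cam_dist[201:400])
  expect_true(ratio < 0.8 || ratio > 1.2)
  support <- c(stats::runif(200, 0.6, 1), stats::runif(200, 0, 0.05))
  out <- optics_cluster_merge(feats, support)
  expect_gt(mean(out$kept < 200), 0.95)
  expect_lt(sum(out$kept >= 200), 11)
})

test_that("clustering is invariant to rigid motion plus uniform scale", {
  cams <- fx_ring_cams()
  pts <- rbind(fx_blob(c(0, 0, 0.2), 180, seed = 30),
               fx_blob(c(0.45, 0, 0.25), 150, seed = 31))
  support <- c(stats::runif(180, 0.5, 1), stats::runif(150, 0, 0.1))
  s1 <- fx_iso_splats(pts)
  f1 <- build_descriptors(s1$ids, s1, cams)
  o1 <- optics_cluster_merge(f1, support)

  th <- 0.6
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  sc <- 2.5
  tr <- c(3, -1, 0.5)
  tf <- function(p) sweep(sc * p %*% t(R), 2, tr, "+")
  cams2 <- lapply(cams, function(v) {
    eye <- tf(matrix(camera_center(v), 1, 3))
    fx_lookat_camera(as.numeric(eye), at = as.numeric(tf(matrix(0, 1, 3))),
                     view_index = v$view_index)
  })
  s2 <- fx_iso_splats(tf(pts), scale = 0.01 * sc)
  f2 <- build_descriptors(s2$ids, s2, cams2)
  o2 <- optics_cluster_merge(f2, support)
  expect_setequal_int(o1$kept, o2$kept)
})

test_that("nn_retain keeps within 2x the median spacing, single pass", {
  g <- as.matrix(expand.grid(x = seq(0, 0.4, by = 0.05),
                             y = seq(0, 0.4, by = 0.05), z = 0))
  h <- 0.05
  extra <- rbind(c(0.2, 0.2, 1.9 * h),
                 c(0.2, 0.2, 2.1 * h),
                 c(0.4 + 1.9 * h, 0.2, 0))
  s <- fx_iso_splats(rbind(g, extra))
  kept <- s$ids[seq_len(nrow(g))]
  r <- nn_retain(kept, s, beta = 2)
  n <- nrow(g)
  expect_true((n + 0L) %in% r)               # 1.9h above the grid: kept
  expect_false((n + 1L) %in% r)              # 2.1h above the grid: dropped
  expect_true((n + 2L) %in% r)               # 1.9h beyond the grid edge: kept
  # chained point beyond reach of kept is NOT pulled in by a retained one
  s2 <- fx_iso_splats(rbind(g, c(0.2, 0.2, 1.9 * h), c(0.2, 0.2, 3.8 * h)))
  r2 <- nn_retain(s2$ids[seq_len(n)], s2, beta = 2)
  expect_true(n %in% r2)
  expect_false((n + 1L) %in% r2)
  # brute-force oracle on a randomized instance
  set.seed(40)
  cand <- matrix(stats::runif(3 * 60, -0.1, 0.5), 60, 3)
  s3 <- fx_iso_splats(rbind(g, cand))
  r3 <- nn_retain(s3$ids[seq_len(n)], s3, beta = 2)
  dmed <- stats::median(FNN::get.knn(g, k = 1)$nn.dist[, 1])
  dmin <- apply(cand, 1, function(p)
    min(sqrt(rowSums(sweep(g, 2, p)^2))))
  oracle <- s3$ids[n + which(dmin <= 2 * dmed)]
  expect_setequal_int(setdiff(r3, kept), oracle)
  # warning path: fewer than two kept splats
  expect_warning(nn_retain(s$ids[1], s), "few|skip")
})
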