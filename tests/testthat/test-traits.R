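# Metric alignment and the six phenotypic traits.

fx_ground_scene <- function(seed = 1, n_ground = 400, n_plant = 200) {
  set.seed(seed)
  ground <- cbind(stats::runif(n_ground, -0.5, 0.5),
                  stats::runif(n_ground, -0.5, 0.5),
                  stats::rnorm(n_ground, 0, 5e-4))
  plant <- cbind(stats::rnorm(n_plant, 0, 0.05),
                 stats::rnorm(n_plant, 0, 0.05),
                 stats::runif(n_plant, 0.02, 0.35))
  rbind(ground, plant)
}

rot_angle_deg <- function(R) {
  acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1)) * 180 / pi
}

test_that("reference pair fixes the metric scale and levels the frame", {
  pts <- fx_ground_scene()
  ref <- rbind(c(-0.25, 0.4, 0.05), c(0.25, 0.4, 0.05))  # 0.5 units apart
  al <- metric_scale_align(pts, ref, ref_length_m = 0.42)
  expect_equal(al$frame$scale_s, 0.84, tolerance = 1e-9)
  expect_lt(rot_angle_deg(al$frame$rotation_R), 1)
  # re-estimating on the aligned output is the identity transform
  ref2 <- apply_metric_frame(al$frame, ref)
  al2 <- metric_scale_align(al$points, ref2, ref_length_m = 0.42)
  expect_equal(al2$frame$scale_s, 1, tolerance = 1e-6)
  expect_lt(max(abs(al2$frame$rotation_R - diag(3))), 5e-4)
  expect_lt(max(abs(al2$points - al$points)), 5e-4)
  # identity mode leaves coordinates untouched apart from the scale
  ali <- metric_scale_align(pts, ref, 0.42, alignment = "identity")
  expect_equal(ali$frame$rotation_R, diag(3))
})

test_that("transform_splat_set carries the frame onto full Gaussians", {
  b <- fx_bundle(0)
  ref <- b$scene$positions[b$gt$ref_ids + 1L, ]
  al <- metric_scale_align(b$scene$positions, ref, b$gt$ref_length_m)
  ts <- transform_splat_set(al$frame, b$scene)
  expect_equal(ts$positions, apply_metric_frame(al$frame, b$scene$positions),
               tolerance = 1e-9)
  i <- 10L
  S_raw <- derived_params(subset_splats(b$scene, i), "cov")$cov[[1]]
  S_new <- derived_params(subset_splats(ts, i), "cov")$cov[[1]]
  R <- al$frame$rotation_R
  s <- al$frame$scale_s
  expect_equal(S_new, s^2 * R %*% S_raw %*% t(R), tolerance = 1e-9)
})

test_that("rasterized height resists spurious ceiling splats", {
  set.seed(13)
  pts <- cbind(stats::runif(2000, 0, 0.2), stats::runif(2000, 0, 0.2),
               stats::runif(2000, 0, 0.40))
  cell <- stats::median(FNN::get.knn(pts, k = 1)$nn.dist[, 1])
  h <- plant_height(pts)
  expect_lt(abs(h - 0.40), 0.5 * cell)
  # five floaters hovering above a plateau canopy: opening removes them
  g <- as.matrix(expand.grid(seq(0, 0.2, by = 0.004), seq(0, 0.2, by = 0.004)))
  canopy <- cbind(g, 0.40)
  junk <- cbind(stats::runif(5, 0.02, 0.18), stats::runif(5, 0.02, 0.18), 0.50)
  h_with <- plant_height(rbind(canopy, junk), operator = "opening")
  expect_lt(abs(h_with - 0.40), 0.004)
  # with closing (fill-holes semantics) the same floaters survive
  h_close <- plant_height(rbind(canopy, junk), operator = "closing")
  expect_gt(h_close, 0.45)
  # single point: height is its z
  expect_equal(plant_height(matrix(c(0, 0, 0.31), 1, 3)), 0.31)
  expect_warning(plant_height(matrix(c(0, 0, -0.1), 1, 3)), "ground")
})

test_that("plot area and alpha-shape area match their analytic values", {
  expect_equal(plot_area_from_diameter(0.214), pi * 0.107^2)
  expect_equal(plot_area_from_diameter(0.214), 0.036, tolerance = 1e-3)
  set.seed(14)
  n <- 5000
  rr <- sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  xy <- cbind(rr * cos(th), rr * sin(th))
  a <- alpha_shape_area(xy, alpha = 0.25)
  expect_equal(a, pi, tolerance = 0.03 * pi)
  # collinear points carry no area
  flat <- cbind(seq(0, 1, length.out = 50), 0)
  expect_message(a0 <- leaf_area_lai(list(), a_plot_m2 = 0.036), NA)
})

test_that("disc-splat leaves recover their area within tolerance", {
  area_cm2 <- 74.9
  r <- sqrt(area_cm2 * 1e-4 / pi)
  sg <- r / 5
  set.seed(15)
  n <- 100
  rad <- (r - 2 * sg) * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  pos <- cbind(rad * cos(th), rad * sin(th), 0.2)
  leaf <- splat_set(pos, matrix(log(c(sg, sg, sg / 10)), n, 3, byrow = TRUE),
                    cbind(rep(1, n), 0, 0, 0), rep(3, n),
                    matrix(0, n, 3))
  la <- leaf_area_lai(list(leaf))
  expect_lt(abs(la$per_leaf_m2[1] - area_cm2 * 1e-4) / (area_cm2 * 1e-4),
            0.15)
  expect_equal(la$lsa_m2, sum(la$per_leaf_m2))
  expect_equal(la$lai, la$lsa_m2 / 0.036, tolerance = 1e-12)
})

test_that("leaf counting merges fragments and drops specks", {
  d_med <- 0.01
  # one leaf split into two fragments closer than d_med
  frag <- rbind(c(0, 0, 0.1), c(0.5 * d_med, 0, 0.1))
  lc <- leaf_count(frag, c(20e-4, 15e-4), d_med)
  expect_equal(lc$count, 1L)
  expect_equal(lc$areas_m2, 35e-4)
  # sub-centimetre speck is removed
  lc2 <- leaf_count(rbind(frag, c(0.3, 0, 0.1)), c(20e-4, 15e-4, 0.5e-4),
                    d_med)
  expect_equal(lc2$count, 1L)
  # seven leaves, two of them fragmented, count seven
  set.seed(16)
  cents <- cbind(seq(0, 0.6, length.out = 7), 0, 0.1)
  areas <- rep(30e-4, 7)
  cents <- rbind(cents, cents[2, ] + c(0.4 * d_med, 0, 0),
                 cents[5, ] + c(0, 0.4 * d_med, 0))
  areas <- c(areas, 8e-4, 8e-4)
  lc7 <- leaf_count(cents, areas, d_med)
  expect_equal(lc7$count, 7L)
})

test_that("contraction collapses a cylinder onto its axis", {
  set.seed(17)
  n <- 800
  R_cyl <- 0.003
  th <- stats::runif(n, 0, 2 * pi)
  rad <- R_cyl * sqrt(stats::runif(n))
  pts <- cbind(rad * cos(th), rad * sin(th), stats::runif(n, 0, 0.2))
  nodes <- stem_skeleton(pts, k = 40)
  # the tube collapses well inside its own radius and onto the right axis
  r_axis <- sqrt(nodes[, 1]^2 + nodes[, 2]^2)
  expect_lt(max(r_axis), 0.25 * R_cyl)
  expect_lt(stats::median(r_axis), 0.10 * R_cyl)
  dirv <- prcomp(nodes)$rotation[, 1]
  expect_gt(abs(dirv[3]), cos(1 * pi / 180))

  # per-iteration contraction shrinks radial variance monotonically
  v_prev <- Inf
  for (it in 1:4) {
    nd <- stem_skeleton(pts, iterations = it, node_spacing = 1e-9)
    v <- sum(apply(nd[, 1:2], 2, stats::var))
    expect_lt(v, v_prev)
    v_prev <- v
  }
  # lambda = 0 is a pure farthest-point subsample of the raw points
  raw <- stem_skeleton(pts, lambda = 0, node_spacing = 0.02)
  d <- FNN::get.knnx(pts, raw, k = 1)$nn.dist[, 1]
  expect_equal(max(d), 0)
  expect_error(stem_skeleton(pts[1:5, ]), "too few")
})

test_that("internode statistics recover junction spacing on known skeletons", {
  d <- 0.04
  stem <- cbind(0, 0, seq(0, 0.24, by = 0.008))
  branches <- do.call(rbind, lapply(1:5, function(i)
    cbind(seq(0.008, 0.04, by = 0.008), 0.002, i * d)))
  ist <- internode_stats(rbind(stem, branches))
  expect_equal(ist$node_count, 5L)
  expect_equal(length(ist$internode_lengths_m), 4)
  expect_true(all(abs(ist$internode_lengths_m - d) <= 0.1 * d))

  # curved stem: geodesic between junctions follows the arc, not the chord
  Rarc <- 0.1
  ang <- seq(0, pi / 2, length.out = 61)  # junction angles lie on the grid
  arc <- cbind(Rarc * cos(ang), 0, Rarc * sin(ang))
  twig <- function(a0, dy) {
    base <- c(Rarc * cos(a0), 0, Rarc * sin(a0))
    cbind(base[1], seq(0.005, 0.025, by = 0.005) * sign(dy), base[3])
  }
  nodes <- rbind(arc, twig(pi / 6, 1), twig(pi / 3, -1))
  ist2 <- internode_stats(nodes)
  expect_equal(ist2$node_count, 2L)
  geo <- ist2$internode_lengths_m[1]
  ell <- Rarc * pi / 6
  chord <- 2 * Rarc * sin(pi / 12)
  expect_lt(abs(geo - ell) / ell, 0.05)
  expect_gt(geo, chord)

  # an unbranched stem has no junctions and no internodes
  ist0 <- internode_stats(stem)
  expect_equal(ist0$node_count, 0L)
  expect_equal(length(ist0$internode_lengths_m), 0)
})
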