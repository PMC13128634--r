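# Density normalization, instance grouping, and splat remapping.

fx_pts <- function(n, center, sd = 0.004, seed = 1) {
  set.seed(seed)
  sweep(matrix(stats::rnorm(n * 3, sd = sd), n, 3), 2, center, "+")
}

test_that("normalize_cloud rescales spacing and is translation-equivariant", {
  # unit grid with k = 1: median neighbour spacing 1, delta 0.5 halves it
  g <- as.matrix(expand.grid(0:4, 0:4, 0:4))
  nc <- normalize_cloud(g, k = 1, delta = 0.5)
  d_raw <- FNN::get.knn(g, k = 1)$nn.dist[, 1]
  d_new <- FNN::get.knn(nc$points, k = 1)$nn.dist[, 1]
  expect_equal(d_new, d_raw / 2, tolerance = 1e-12)
  expect_equal(nc$spacing_s, 1)

  # normalizing an already-normalized cloud is the identity
  set.seed(4)
  x <- matrix(stats::rnorm(300), 100, 3)
  n1 <- normalize_cloud(x)
  n2 <- normalize_cloud(n1$points)
  expect_equal(n2$points, n1$points, tolerance = 1e-9)

  # translation equivariance
  tr <- c(5, -3, 2)
  nt <- normalize_cloud(sweep(x, 2, tr, "+"))
  expect_equal(nt$points, sweep(n1$points, 2, tr, "+"), tolerance = 1e-9)

  expect_error(normalize_cloud(matrix(0, 20, 3)), "degenerate")
})

test_that("grouping separates distant blobs and bridges sub-radius gaps", {
  blob_r <- 0.02
  two <- rbind(fx_pts(60, c(0, 0, 0), sd = blob_r / 3, seed = 5),
               fx_pts(60, c(10 * blob_r * 8, 0, 0), sd = blob_r / 3, seed = 6))
  cl <- normalize_cloud(two)
  inst <- group_instances(cl, rep("leaf", 120), rep(3, 120), min_points = 10)
  expect_equal(length(inst), 2)
  expect_setequal_int(sort(unlist(lapply(inst, `[[`, "member_ids"))), 1:120)
  expect_equal(unique(vapply(inst, `[[`, character(1), "semantic_class")),
               "leaf")
  expect_equal(vapply(inst, `[[`, numeric(1), "confidence"), c(3, 3))

  # the same two blobs almost touching collapse into one instance
  near <- rbind(fx_pts(60, c(0, 0, 0), sd = blob_r / 3, seed = 5),
                fx_pts(60, c(blob_r, 0, 0), sd = blob_r / 3, seed = 6))
  cln <- normalize_cloud(near)
  instn <- group_instances(cln, rep("leaf", 120), rep(3, 120), min_points = 10)
  expect_equal(length(instn), 1)

  # huge gamma: one instance per present class
  mix <- rbind(two, fx_pts(40, c(0.5, 0.5, 0), sd = blob_r / 3, seed = 7))
  clm <- normalize_cloud(mix)
  classes <- c(rep("leaf", 120), rep("stem", 40))
  insth <- group_instances(clm, classes, rep(2, 160), gamma = 1e6,
                           min_points = 10)
  expect_equal(sort(vapply(insth, `[[`, character(1), "semantic_class")),
               c("leaf", "stem"))

  expect_error(group_instances(cl, rep("root", 120), rep(1, 120)),
               "unknown semantic class")
  expect_message(group_instances(cl, rep("leaf", 120), rep(1, 120),
                                 min_points = 100),
                 "dropped")
})

test_that("components match a brute-force union-find oracle", {
  set.seed(3)
  x <- matrix(stats::runif(500 * 3), 500, 3)
  cl <- normalize_cloud(x)
  inst <- group_instances(cl, rep("leaf", 500), rep(1, 500), min_points = 1)
  # brute-force all-pairs connected components at r = gamma * delta
  p <- cl$points
  r <- 2.5 * cl$delta
  parent <- seq_len(500)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  d <- as.matrix(stats::dist(p))
  for (i in 1:499) for (j in (i + 1):500) if (d[i, j] <= r) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(1:500, find, integer(1))
  oracle <- split(seq_len(500), roots)
  got <- lapply(inst, `[[`, "member_ids")
  expect_equal(length(got), length(oracle))
  key <- function(sets) sort(vapply(sets, function(s)
    paste(sort(s), collapse = ","), character(1)))
  expect_equal(key(got), key(unname(oracle)))
})

test_that("grouping is invariant to point order", {
  set.seed(8)
  x <- rbind(fx_pts(50, c(0, 0, 0), seed = 9),
             fx_pts(50, c(0.5, 0, 0), seed = 10))
  classes <- rep(c("leaf", "stem"), each = 50)
  logits <- stats::runif(100, 1, 4)
  cl <- normalize_cloud(x)
  base <- group_instances(cl, classes, logits, min_points = 5)
  perm <- sample(100)
  clp <- normalize_cloud(x[perm, ])
  permuted <- group_instances(clp, classes[perm], logits[perm], min_points = 5)
  key <- function(inst, map) sort(vapply(inst, function(o)
    paste(o$semantic_class, paste(sort(map[o$member_ids]), collapse = ","),
          sep = ":"), character(1)))
  expect_equal(key(base, seq_len(100)), key(permuted, perm))
})

test_that("noiseless remap recovers the ground-truth organ classes", {
  b <- fx_bundle(4)
  tgt <- b$gt$plant_label == "target"
  plant <- subset_splats(b$scene, b$scene$ids[tgt])
  gt_class <- ifelse(b$gt$organ_label[tgt] == "stem", "stem", "leaf")
  cl <- export_point_cloud(plant, density = 20, rng_seed = 4)
  cloud <- normalize_cloud(cl$points)
  pt_class <- gt_class[cl$source_id + 1L]
  inst <- suppressMessages(
    group_instances(cloud, pt_class, rep(4, nrow(cl$points)), min_points = 30))
  rm_ <- remap_to_splats(inst, cloud, plant, zeta_strict = NA)
  expect_true(all(rm_$assigned))
  # agreement up to stem/leaf junction splats (all observed mismatches sit
  # within ~1 cm of the opposite organ, i.e. within sampling spread)
  expect_gt(mean(rm_$class == gt_class[rm_$id + 1L]), 0.95)
  # leaf instances are recovered 1:1 (same count as ground-truth leaves)
  n_leaves <- length(unique(grep("^leaf",
                                 b$gt$organ_label[tgt], value = TRUE)))
  expect_equal(sum(vapply(inst, `[[`, character(1),
                          "semantic_class") == "leaf"), n_leaves)
})

test_that("remap respects opacity visibility and the assignment radius", {
  set.seed(12)
  pos <- matrix(stats::rnorm(60 * 3, sd = 0.03), 60, 3)
  logits <- rep(3, 60)
  logits[1] <- stats::qlogis(0.05)
  s <- splat_set(pos, matrix(log(0.004), 60, 3),
                 cbind(rep(1, 60), 0, 0, 0), logits,
                 matrix(rep(c(-0.5, 0.6, -0.4), each = 60), 60, 3))
  cl <- export_point_cloud(s, density = 10, rng_seed = 1)
  cloud <- normalize_cloud(cl$points)
  inst <- group_instances(cloud, rep("leaf", nrow(cl$points)),
                          rep(2, nrow(cl$points)), min_points = 5)
  # tau_op computed through the same sigmoid so alpha == tau_op bit-exactly:
  # the strict inequality must exclude the splat
  tau <- 1 / (1 + exp(-logits[1]))
  rm_ <- remap_to_splats(inst, cloud, s, tau_op = tau, zeta_strict = NA)
  expect_false(0 %in% rm_$id)
  expect_true(all(rm_$assigned))
  # a vanishing assignment radius leaves every splat unassigned
  rm0 <- remap_to_splats(inst, cloud, s, alpha_r = 1e-12, zeta_strict = NA)
  expect_false(any(rm0$assigned))
  expect_true(all(is.na(rm0$class)))
  # no visible splats at all is a degenerate-data error
  dark <- splat_set(pos, matrix(log(0.004), 60, 3),
                    cbind(rep(1, 60), 0, 0, 0), rep(-10, 60),
                    matrix(0, 60, 3))
  expect_error(remap_to_splats(inst, cloud, dark), "no visible splats")
})
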