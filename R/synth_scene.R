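# Synthetic multi-plant greenhouse scene generator with full ground truth.
#
# The generator emulates the acquisition setting the pipeline targets: a row
# of young cucurbit plants at 0.72 m within-row spacing in front of a gray
# trellis, a soil ground plane and pots, recorded by two horizontal camera
# passes at roughly 0.5 m and 1.5 m height. Plants are built from elongated
# stem Gaussians and flattened leaf-disc Gaussians whose short axis is the
# disc normal; trait distributions follow the early-vegetative cohort
# statistics (leaf count 6.9 +/- 2.1, internode 3.7 +/- 0.9 cm, leaf area
# 74.9 +/- 22.8 cm^2). A "floater" population of low-opacity splats with
# colours blended between plant and background emulates the boundary
# artifacts real 3DGS reconstructions produce at plant-background contacts.
# Everything is generated in metres and then multiplied by a fake
# reconstruction scale so that metric calibration is exercised nontrivially.

# quaternion (w,x,y,z) from a rotation matrix (Shepperd's method)
rotmat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

# orthonormal basis with first column along `d`
basis_from_dir <- function(d) {
  d <- d / sqrt(sum(d^2))
  a <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- a - sum(a * d) * d
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2], d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  cbind(d, u, v)
}

# DC coefficients from Lab colours (inverse of the refinement's transform so
# chromatic separation is controlled where filtering happens)
lab_to_dc <- function(lab) {
  C0 <- 0.28209479177387814
  (lab_to_rgb(lab) - 0.5) / C0
}

rnorm_clip <- function(n, mean, sd, lo, hi) pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)

logit <- function(p) log(p / (1 - p))

#' Default synthetic scene recipe
#'
#' @return named list of generator parameters (see the vignette for the
#'   rationale behind each default).
#' @export
default_scene_recipe <- function() {
  list(
    n_plants = 3L, row_spacing = 0.72, target_plant = 2L,
    leaf_count_mean = 6.9, leaf_count_sd = 2.1, leaf_count_range = c(4, 11),
    internode_mean_cm = 3.7, internode_sd_cm = 0.9,
    internode_range_cm = c(1.9, 6.1),
    leaf_area_mean_cm2 = 74.9, leaf_area_sd_cm2 = 22.8,
    leaf_area_range_cm2 = c(39, 122),
    splats_per_leaf = 40L, stem_splats_per_cm = 1.4, petiole_splats = 4L,
    n_ground = 1500L, n_pole = 120L, n_bar = 120L, n_pot = 60L,
    n_floaters_per_plant = NA,  # NA: 22% of each plant's splat count
    recon_scale = 1.19, ref_length_m = 0.42,
    image_size = c(512L, 384L), focal_px = 460,
    cams_per_pass = 12L, pass_heights = c(0.5, 1.5), cam_y = -1.1,
    a_plot_m2 = 0.036,
    # Lab colour bases (L, a, b) and per-splat jitter SDs
    leaf_lab = c(50, -32, 32), leaf_jitter = c(4.5, 3.5, 3.5),
    stem_lab = c(49, -29, 30), ground_lab = c(45, 8, 18),
    pot_lab = c(35, 3, 6), trellis_lab = c(65, 2, 5),
    bg_jitter = c(3, 2, 2)
  )
}

#' Generate a synthetic greenhouse 3DGS scene with ground truth
#'
#' Deterministic given `seed`. Builds the target plant and its neighbours
#' (curved stem chain of elongated Gaussians with one petiole + leaf disc
#' per junction), background structures, two-pass cameras, and records full
#' ground truth: per-splat plant and organ labels, per-plant traits, the
#' metric reference pair and the applied reconstruction scale.
#'
#' @param params recipe list as from [default_scene_recipe()] (entries can
#'   be overridden).
#' @param seed integer RNG seed.
#' @return object of class `scene_bundle`: `scene` ([splat_set()], scene
#'   units), `cameras`, `gt` (labels + traits in metres), `params`, `seed`,
#'   `default_cue_views`.
#' @export
make_scene <- function(params = default_scene_recipe(), seed = 0) {
  p <- utils::modifyList(default_scene_recipe(), params)
  if (p$n_plants < 1 || p$n_ground < 0 || p$splats_per_leaf < 1)
    stop("infeasible scene recipe")
  with_seed(seed, .make_scene_impl(p, seed))
}

.make_scene_impl <- function(p, seed) {
  pos <- list(); logs <- list(); quat <- list(); alpha <- list(); lab <- list()
  plant_id <- list(); organ <- list()
  add <- function(position, scale3, R, a, lab3, pid, org) {
    pos[[length(pos) + 1]] <<- position
    logs[[length(logs) + 1]] <<- log(scale3)
    quat[[length(quat) + 1]] <<- rotmat_to_quat(R)
    alpha[[length(alpha) + 1]] <<- a
    lab[[length(lab) + 1]] <<- lab3
    plant_id[[length(plant_id) + 1]] <<- pid
    organ[[length(organ) + 1]] <<- org
  }

  xs <- (seq_len(p$n_plants) - (p$n_plants + 1) / 2) * p$row_spacing
  traits <- vector("list", p$n_plants)

  for (pl in seq_len(p$n_plants)) {
    x0 <- xs[pl]
    leaf_base <- p$leaf_lab + stats::rnorm(3, 0, c(2, 2, 2))
    n_leaves <- as.integer(rnorm_clip(1, p$leaf_count_mean, p$leaf_count_sd,
                                      p$leaf_count_range[1], p$leaf_count_range[2]))
    spacings <- rnorm_clip(n_leaves, p$internode_mean_cm, p$internode_sd_cm,
                           p$internode_range_cm[1], p$internode_range_cm[2]) / 100
    areas <- rnorm_clip(n_leaves, p$leaf_area_mean_cm2, p$leaf_area_sd_cm2,
                        p$leaf_area_range_cm2[1], p$leaf_area_range_cm2[2]) / 1e4
    base <- c(x0 + stats::rnorm(1, 0, 0.01), stats::rnorm(1, 0, 0.01), 0.06)
    dirv <- c(0, 0, 1)
    node <- base
    junctions <- matrix(0, n_leaves, 3)
    stem_pts_prev <- node
    segment <- function(a, b, radius, pid, org, n_s) {
      d <- b - a; L <- sqrt(sum(d^2))
      if (L == 0) return()
      ts <- seq(0, 1, length.out = max(2L, n_s))
      R <- basis_from_dir(d)
      for (t in ts)
        add(a + t * d, c(max(L / (2 * max(2L, n_s)), radius), radius, radius), R,
            stats::runif(1, 0.8, 0.98),
            p$stem_lab + stats::rnorm(3, 0, p$leaf_jitter * 0.9), pid, org)
    }
    for (j in seq_len(n_leaves)) {
      tilt <- stats::rnorm(2, 0, 0.06)
      dirv <- dirv + c(tilt, 0)
      dirv <- dirv / sqrt(sum(dirv^2))
      nxt <- node + dirv * spacings[j]
      segment(node, nxt, 0.003, pl, "stem",
              max(2L, round(spacings[j] * 100 * p$stem_splats_per_cm)))
      node <- nxt
      junctions[j, ] <- node
      # petiole + leaf disc
      az <- stats::runif(1, 0, 2 * pi)
      pet_dir <- c(cos(az) * 0.95, sin(az) * 0.95, 0.35)
      pet_dir <- pet_dir / sqrt(sum(pet_dir^2))
      pet_len <- stats::runif(1, 0.045, 0.075)
      leaf_cen <- node + pet_dir * pet_len
      segment(node, leaf_cen, 0.002, pl, "stem", p$petiole_splats)
      r_l <- sqrt(areas[j] / pi)
      nrm <- c(stats::rnorm(2, 0, 0.25), 1)
      nrm <- nrm / sqrt(sum(nrm^2))
      Bl <- basis_from_dir(nrm)  # col1 = normal; cols 2:3 in-plane
      sig_in <- r_l / 5
      inset <- r_l - 2 * sig_in
      Rleaf <- cbind(Bl[, 2], Bl[, 3], Bl[, 1])  # axes: in-plane, in-plane, normal
      for (s in seq_len(p$splats_per_leaf)) {
        rr <- inset * sqrt(stats::runif(1)); th <- stats::runif(1, 0, 2 * pi)
        cpt <- leaf_cen + rr * cos(th) * Bl[, 2] + rr * sin(th) * Bl[, 3]
        add(cpt, c(sig_in, sig_in, sig_in / 10), Rleaf,
            stats::runif(1, 0.8, 0.98),
            leaf_base + stats::rnorm(3, 0, p$leaf_jitter),
            pl, paste0("leaf_", j))
      }
    }
    # short apical tip above the last junction (a leafless recipe still
    # gets a stem of one internode so the plant is never empty)
    apex_len <- if (n_leaves > 0) spacings[n_leaves] * 0.4
                else p$internode_mean_cm / 100
    apex <- node + dirv * apex_len
    segment(node, apex, 0.0025, pl, "stem", if (n_leaves > 0) 3L else 8L)
    traits[[pl]] <- list(leaf_count = n_leaves, leaf_areas_m2 = areas,
                         lsa_m2 = sum(areas), lai = sum(areas) / p$a_plot_m2,
                         node_count = n_leaves,
                         internode_lengths_m = spacings[-1],
                         junctions = junctions, apex = apex)
  }

  n_plant_splats <- length(pos)

  # ground plane (soil)
  for (i in seq_len(p$n_ground)) {
    add(c(stats::runif(1, min(xs) - 0.6, max(xs) + 0.6),
          stats::runif(1, -0.5, 0.45), abs(stats::rnorm(1, 0, 0.004))),
        c(0.02, 0.02, 0.004), diag(3), stats::runif(1, 0.7, 0.95),
        p$ground_lab + stats::rnorm(3, 0, p$bg_jitter), 0L, "background")
  }
  # pots
  for (pl in seq_len(p$n_plants)) for (i in seq_len(p$n_pot)) {
    th <- stats::runif(1, 0, 2 * pi)
    add(c(xs[pl] + 0.075 * cos(th), 0.075 * sin(th), stats::runif(1, 0, 0.10)),
        c(0.012, 0.012, 0.02), diag(3), stats::runif(1, 0.7, 0.95),
        p$pot_lab + stats::rnorm(3, 0, p$bg_jitter), 0L, "background")
  }
  # trellis: one vertical pole behind each plant + one horizontal bar
  Rz <- basis_from_dir(c(0, 0, 1))
  for (pl in seq_len(p$n_plants)) for (i in seq_len(p$n_pole)) {
    add(c(xs[pl] + stats::rnorm(1, 0, 0.002), 0.10 + stats::rnorm(1, 0, 0.002),
          stats::runif(1, 0, 1.2)),
        c(0.02, 0.005, 0.005), Rz, stats::runif(1, 0.7, 0.95),
        p$trellis_lab + stats::rnorm(3, 0, p$bg_jitter), 0L, "background")
  }
  Rx <- basis_from_dir(c(1, 0, 0))
  for (i in seq_len(p$n_bar)) {
    add(c(stats::runif(1, min(xs) - 0.4, max(xs) + 0.4),
          0.10 + stats::rnorm(1, 0, 0.002), 1.15 + stats::rnorm(1, 0, 0.002)),
        c(0.02, 0.005, 0.005), Rx, stats::runif(1, 0.7, 0.95),
        p$trellis_lab + stats::rnorm(3, 0, p$bg_jitter), 0L, "background")
  }
  # metric reference pair: two bright markers on the bar, ref_length_m apart
  ref_ids <- c(length(pos), length(pos) + 1L)  # 0-based ids
  for (sgn in c(-1, 1))
    add(c(sgn * p$ref_length_m / 2, 0.10, 1.15), c(0.008, 0.008, 0.008),
        diag(3), 0.95, c(75, 0, 0), 0L, "background")
  # floaters: boundary-blend artifacts around each plant's canopy
  plant_pos <- do.call(rbind, pos[seq_len(n_plant_splats)])
  plant_pid <- unlist(plant_id[seq_len(n_plant_splats)])
  plant_lab_m <- do.call(rbind, lab[seq_len(n_plant_splats)])
  for (pl in seq_len(p$n_plants)) {
    own <- which(plant_pid == pl)
    n_fl <- if (is.na(p$n_floaters_per_plant))
      round(0.22 * length(own)) else p$n_floaters_per_plant
    for (i in seq_len(n_fl)) {
      a0 <- own[sample.int(length(own), 1)]
      t <- stats::runif(1, 0.15, 0.7)
      bg <- switch(sample.int(3, 1), p$ground_lab, p$trellis_lab, p$pot_lab)
      add(plant_pos[a0, ] + stats::rnorm(3, 0, 0.012),
          c(0.006, 0.006, 0.003), diag(3), stats::runif(1, 0.55, 0.9),
          t * plant_lab_m[a0, ] + (1 - t) * bg + stats::rnorm(3, 0, 1.5),
          0L, "background")
    }
  }

  positions <- do.call(rbind, pos)
  log_scales <- do.call(rbind, logs)
  rotations <- do.call(rbind, quat)
  alphav <- unlist(alpha)
  labm <- do.call(rbind, lab)
  pid <- unlist(plant_id)
  org <- unlist(organ)

  # cameras: two passes; look-at with z up, image y pointing downward
  cams <- list()
  vi <- 0L
  for (h in p$pass_heights) for (xc in seq(min(xs) - 0.4, max(xs) + 0.4,
                                           length.out = p$cams_per_pass)) {
    cpos <- c(xc, p$cam_y, h)
    look <- c(xc * 0.3, 0, if (h < 1) 0.45 else 0.30)
    f <- look - cpos; f <- f / sqrt(sum(f^2))
    xc_ <- c(f[2], -f[1], 0); xc_ <- xc_ / sqrt(sum(xc_^2))
    # right-handed: x right, y down, z forward
    yc_ <- c(f[2] * xc_[3] - f[3] * xc_[2], f[3] * xc_[1] - f[1] * xc_[3],
             f[1] * xc_[2] - f[2] * xc_[1])
    R <- rbind(xc_, yc_, f)
    if (det(R) < 0) R[2, ] <- -R[2, ]
    if (R[2, 3] > 0) { R[1, ] <- -R[1, ]; R[2, ] <- -R[2, ] }  # y down in world
    cpos_s <- cpos * p$recon_scale
    K <- matrix(c(p$focal_px, 0, (p$image_size[1] - 1) / 2,
                  0, p$focal_px, (p$image_size[2] - 1) / 2,
                  0, 0, 1), 3, 3, byrow = TRUE)
    cams[[length(cams) + 1]] <- camera_view(
      K, R, -as.numeric(R %*% cpos_s), p$image_size,
      sharpness = stats::runif(1, 100, 600), view_index = vi)
    vi <- vi + 1L
  }

  # apply the fake reconstruction scale; snap all fields through float32 so
  # that PLY round trips are bit-stable
  sf <- function(m) matrix(snap_float32(m), nrow = nrow(m))
  scene <- splat_set(sf(positions * p$recon_scale),
                     sf(log_scales + log(p$recon_scale)),
                     sf(rotations), snap_float32(logit(alphav)),
                     sf(lab_to_dc(labm)))

  # default seeded cue views: two low-pass views flanking the target plant
  # and the closest high-pass view
  x_t <- xs[p$target_plant]
  low <- seq_len(p$cams_per_pass)
  high <- p$cams_per_pass + low
  cam_x <- vapply(cams, function(v) camera_center(v)[1], numeric(1)) / p$recon_scale
  lo_ord <- low[order(abs(cam_x[low] - x_t))]
  left <- lo_ord[cam_x[lo_ord] <= x_t][1]
  right <- lo_ord[cam_x[lo_ord] > x_t][1]
  hi_pick <- high[order(abs(cam_x[high] - x_t))][1]
  cue_views <- vapply(cams[c(left, right, hi_pick)], function(v) v$view_index,
                      integer(1))

  gt_label <- ifelse(pid == 0L, "background",
                     ifelse(pid == p$target_plant, "target", "neighbor"))
  structure(list(
    scene = scene, cameras = cams,
    gt = list(plant_id = pid, plant_label = gt_label, organ_label = org,
              traits = traits, ref_ids = ref_ids,
              ref_length_m = p$ref_length_m, recon_scale = p$recon_scale,
              target_plant = p$target_plant,
              gt_height_m = vapply(seq_len(p$n_plants), function(pl)
                max(positions[pid == pl, 3]), numeric(1))),
    params = p, seed = seed, default_cue_views = cue_views),
    class = "scene_bundle")
}

#' Render synthetic cue masks for seeded views
#'
#' The clean mask of a view is the union of the filled 2-sigma projected
#' ellipses of the target plant's splats. The noise model emulates loose
#' detection masks: binary dilation by `dilate_px`, `clutter_boxes` random
#' rectangles switched on, and random dropout of a fraction of the plant
#' ellipses (missed thin structures).
#'
#' @param bundle a `scene_bundle`.
#' @param view_indices views to seed (default the bundle's
#'   `default_cue_views`).
#' @param noise list with `dilate_px`, `clutter_boxes`, `dropout`.
#' @param seed RNG seed for the noise model.
#' @return a [cue_set()].
#' @export
render_cue_masks <- function(bundle, view_indices = bundle$default_cue_views,
                             noise = list(dilate_px = 0, clutter_boxes = 0,
                                          dropout = 0), seed = 0) {
  noise <- utils::modifyList(list(dilate_px = 0, clutter_boxes = 0, dropout = 0),
                             noise)
  target_ids <- bundle$scene$ids[bundle$gt$plant_label == "target"]
  vidx <- vapply(bundle$cameras, function(v) v$view_index, integer(1))
  entries <- list()
  with_seed(seed, {
    for (v in view_indices) {
      cam <- bundle$cameras[[match(v, vidx)]]
      ids <- target_ids
      if (noise$dropout > 0) {
        keep <- stats::runif(length(ids)) >= noise$dropout
        ids <- ids[keep]
      }
      m <- matrix(FALSE, cam$image_size[1], cam$image_size[2])
      for (id in ids) {
        el <- project_gaussian(bundle$scene, id, cam, k_sigma = 2)
        if (is.null(el) || nrow(el$footprint) == 0) next
        m[el$footprint + 1L] <- TRUE
      }
      if (!any(m)) {
        warning("target plant not visible in view ", v, "; view skipped")
        next
      }
      if (noise$dilate_px > 0)
        m <- disc_dilate(m * 1, noise$dilate_px) > 0.5
      if (noise$clutter_boxes > 0) for (b in seq_len(noise$clutter_boxes)) {
        bw <- sample(10:40, 1); bh <- sample(10:40, 1)
        bx <- sample.int(cam$image_size[1] - bw, 1)
        by <- sample.int(cam$image_size[2] - bh, 1)
        m[bx:(bx + bw - 1), by:(by + bh - 1)] <- TRUE
      }
      on <- which(m, arr.ind = TRUE)
      bbox <- c(min(on[, 1]) - 1L, min(on[, 2]) - 1L,
                max(on[, 1]) - 1L, max(on[, 2]) - 1L)
      entries[[length(entries) + 1]] <- list(
        image_id = sprintf("frame_%04d", v), view_index = as.integer(v),
        mask_id = 1L, bbox = bbox, mask = m)
    }
  })
  cue_set(entries, bundle$cameras)
}
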