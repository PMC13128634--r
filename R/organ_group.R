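# Density normalization, radius-BFS instance grouping of semantic labels,
# and remapping of instance labels back onto the Gaussian splats.

#' Normalize a point cloud to a target spacing
#'
#' Applies \eqn{x' = c + (x - c)\,\Delta/s} where c is the per-axis median
#' centroid and s the median over points of the mean distance to their k
#' nearest neighbours. The transform parameters are stored so it can be
#' inverted exactly.
#'
#' @param points N x 3 matrix.
#' @param k neighbour count for the spacing estimate (default 8).
#' @param delta target spacing (default 0.02 normalized units).
#' @return object of class `normalized_cloud`: `points`, `centroid_c`,
#'   `spacing_s`, `delta`.
#' @export
normalize_cloud <- function(points, k = 8, delta = 0.02) {
  points <- as.matrix(points)
  stopifnot(nrow(points) >= k + 1)
  cen <- apply(points, 2, stats::median)
  kn <- FNN::get.knn(points, k = k)
  s <- stats::median(rowMeans(kn$nn.dist))
  if (s == 0) stop("degenerate cloud: zero median neighbour spacing")
  out <- t((t(points) - cen) * (delta / s) + cen)
  structure(list(points = out, centroid_c = cen, spacing_s = s, delta = delta),
            class = "normalized_cloud")
}

#' Invert the spacing normalization
#' @param cloud a `normalized_cloud`.
#' @param points points in normalized coordinates (default the cloud's own).
#' @return points mapped back to the raw frame.
#' @export
denormalize_points <- function(cloud, points = cloud$points) {
  points <- as.matrix(points)
  t((t(points) - cloud$centroid_c) * (cloud$spacing_s / cloud$delta) +
      cloud$centroid_c)
}

#' Group labelled points into organ instances
#'
#' PointGroup-style bottom-up grouping: for each semantic class, the points
#' of that class are partitioned into connected components of the graph
#' linking pairs within the density-relative radius \eqn{r = \gamma\Delta}
#' (breadth-first aggregation). Components smaller than `min_points` are
#' dropped (logged). Instance confidence is the mean semantic logit of the
#' winning class over members.
#'
#' @param cloud a `normalized_cloud`.
#' @param classes character/factor vector per point (`"stem"`/`"leaf"`).
#' @param logits numeric vector per point: the winning-class logit.
#' @param gamma radius scale (default 2.5).
#' @param min_points minimum instance size (default 30).
#' @return list of `organ_instance` objects (fields `semantic_class`,
#'   `member_ids` (1-based point indices), `confidence`, `instance_id`).
#' @export
group_instances <- function(cloud, classes, logits, gamma = 2.5,
                            min_points = 30) {
  pts <- cloud$points
  stopifnot(length(classes) == nrow(pts), length(logits) == nrow(pts))
  classes <- as.character(classes)
  bad <- !classes %in% c("stem", "leaf")
  if (any(bad)) stop("unknown semantic class: ", unique(classes[bad])[1])
  r <- gamma * cloud$delta
  instances <- list()
  iid <- 0L
  for (cls in c("stem", "leaf")) {
    sel <- which(classes == cls)
    if (length(sel) == 0) next
    memb <- radius_components(pts[sel, , drop = FALSE], r)
    for (comp in sort(unique(memb))) {
      ids <- sel[memb == comp]
      if (length(ids) < min_points) {
        message(sprintf("dropped %s component of %d point(s) (< min_points)",
                        cls, length(ids)))
        next
      }
      instances[[length(instances) + 1]] <- structure(
        list(semantic_class = cls, member_ids = ids,
             confidence = mean(logits[ids]), instance_id = iid),
        class = "organ_instance")
      iid <- iid + 1L
    }
  }
  instances
}

#' Remap organ instance labels back onto the Gaussian splats
#'
#' Considers only visible splats (opacity strictly above `tau_op`),
#' computes the density-aware assignment radius
#' \eqn{r_{assign} = \alpha_r d_{med}} from the median nearest-neighbour
#' spacing of the visible splats (world frame), and assigns each visible
#' splat the class/instance/confidence of its nearest labelled cloud point
#' within that radius (labels carried through the inverse normalization).
#' Splats with no labelled point in range stay unassigned (retained and
#' flagged). The strict chromatic filter at `zeta_strict` is then reapplied
#' per semantic class to drop chromatic outliers from the labelled sets.
#'
#' @param instances list of `organ_instance`s from [group_instances()].
#' @param cloud the `normalized_cloud` the instances were grouped in.
#' @param splats the plant-subset [splat_set()] the cloud was exported from.
#' @param tau_op opacity threshold (default 0.05, strict inequality).
#' @param alpha_r assignment radius scale (default 3).
#' @param zeta_strict coverage for the strict chromatic re-filter
#'   (default 0.80; `NA` disables it).
#' @param rng_seed seed for the colour-model fit.
#' @return data.frame with one row per visible splat: `id` (0-based),
#'   `class`, `instance`, `confidence`, `assigned`.
#' @export
remap_to_splats <- function(instances, cloud, splats, tau_op = 0.05,
                            alpha_r = 3, zeta_strict = 0.80, rng_seed = 0) {
  alpha <- 1 / (1 + exp(-splats$opacity_logits))
  vis <- which(alpha > tau_op)
  if (length(vis) == 0) stop("no visible splats above the opacity threshold")
  vp <- splats$positions[vis, , drop = FALSE]
  dmed <- stats::median(FNN::get.knn(vp, k = 1)$nn.dist[, 1])
  r_assign <- alpha_r * dmed
  labelled <- unlist(lapply(instances, `[[`, "member_ids"))
  out <- data.frame(id = splats$ids[vis], class = NA_character_,
                    instance = NA_integer_, confidence = NA_real_,
                    assigned = FALSE)
  if (length(labelled) > 0 && r_assign > 0) {
    lab_world <- denormalize_points(cloud)[labelled, , drop = FALSE]
    point_class <- rep(vapply(instances, `[[`, character(1), "semantic_class"),
                       vapply(instances, function(o) length(o$member_ids), integer(1)))
    point_inst <- rep(vapply(instances, `[[`, integer(1), "instance_id"),
                      vapply(instances, function(o) length(o$member_ids), integer(1)))
    point_conf <- rep(vapply(instances, `[[`, numeric(1), "confidence"),
                      vapply(instances, function(o) length(o$member_ids), integer(1)))
    nn <- FNN::get.knnx(lab_world, vp, k = 1)
    hit <- nn$nn.dist[, 1] <= r_assign
    j <- nn$nn.index[hit, 1]
    out$class[hit] <- point_class[j]
    out$instance[hit] <- point_inst[j]
    out$confidence[hit] <- point_conf[j]
    out$assigned[hit] <- TRUE
  }
  if (!is.na(zeta_strict) && any(out$assigned)) {
    asg <- which(out$assigned)
    lab <- rgb_to_lab(derived_params(subset_splats(splats, out$id[asg]),
                                     "rgb")$rgb)
    if (length(asg) >= 10) {
      model <- fit_color_gmm(lab, rng_seed = rng_seed)
      res <- chroma_filter(out$id[asg], lab, model, zeta_strict)
      dropped <- setdiff(out$id[asg], res$refined)
      di <- match(dropped, out$id)
      out$class[di] <- NA_character_
      out$instance[di] <- NA_integer_
      out$confidence[di] <- NA_real_
      out$assigned[di] <- FALSE
    }
  }
  out
}

#' Export each organ instance as an individual 3DGS PLY
#'
#' @param remap data.frame from [remap_to_splats()].
#' @param splats the plant-subset [splat_set()].
#' @param dir output directory.
#' @param plant label used in file names (`{plant}_{class}{instance}.ply`).
#' @return data.frame of written files with confidences and counts.
#' @export
export_organ_plys <- function(remap, splats, dir, plant = "plant") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  asg <- remap[remap$assigned, ]
  summary <- list()
  for (key in unique(paste(asg$class, asg$instance))) {
    rows <- asg[paste(asg$class, asg$instance) == key, ]
    path <- file.path(dir, sprintf("%s_%s%d.ply", plant, rows$class[1],
                                   rows$instance[1]))
    write_splat_ply(subset_splats(splats, rows$id), path)
    summary[[length(summary) + 1]] <- data.frame(
      file = basename(path), class = rows$class[1],
      instance = rows$instance[1], n_splats = nrow(rows),
      confidence = rows$confidence[1])
  }
  info <- do.call(rbind, summary)
  jsonlite::write_json(list(instances = info,
                            unassigned = sum(!remap$assigned)),
                       file.path(dir, sprintf("%s_summary.json", plant)))
  info
}
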