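# Extraction and instance-segmentation evaluation metrics.

#' Splat-level extraction metrics
#'
#' Confusion counts of a predicted target-plant id set against ground-truth
#' labels (neighbour plants count as background), with precision, recall and
#' the mean IoU over the plant and background classes.
#'
#' @param predicted 0-based splat ids predicted as the target plant.
#' @param gt_labels character vector per splat
#'   (`"target"`/`"neighbor"`/`"background"`), index = id + 1.
#' @return list with `tp`, `fp`, `fn`, `tn`, `precision`, `recall`,
#'   `iou_plant`, `iou_background`, `miou` and `empty_prediction` flag.
#' @export
extraction_metrics <- function(predicted, gt_labels) {
  n <- length(gt_labels)
  pred <- logical(n)
  pred[as.integer(predicted) + 1L] <- TRUE
  pos <- gt_labels == "target"
  tp <- sum(pred & pos); fp <- sum(pred & !pos)
  fn <- sum(!pred & pos); tn <- sum(!pred & !pos)
  empty <- (tp + fp) == 0
  if (empty) warning("empty prediction: precision reported as 0")
  precision <- if (empty) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  iou_p <- if (tp + fp + fn == 0) 0 else tp / (tp + fp + fn)
  iou_b <- if (tn + fp + fn == 0) 0 else tn / (tn + fp + fn)
  list(tp = tp, fp = fp, fn = fn, tn = tn, precision = precision,
       recall = recall, iou_plant = iou_p, iou_background = iou_b,
       miou = (iou_p + iou_b) / 2, empty_prediction = empty)
}

#' Staged precision-recall sweep over lift percentiles
#'
#' Re-runs the stage chain at each retention percentile (top 2 to 20
#' percent by default) and records precision/recall for each enabled
#' configuration: lift only, + clustering, + NN-retain, + chromatic
#' refinement.
#'
#' @param lift a `lift_result` with computed support scores.
#' @param bundle the `scene_bundle` the scores were computed on.
#' @param percentiles quantiles q of the lift threshold (default
#'   `seq(0.80, 0.98, by = 0.02)`).
#' @param stages character subset of
#'   `c("lift", "cluster", "retain", "refine")`.
#' @param xi,beta,zeta stage parameters.
#' @param rng_seed seed for the colour-model fit.
#' @return data.frame with columns `stage`, `q`, `precision`, `recall`,
#'   `miou`, `n_kept`.
#' @export
pr_sweep <- function(lift, bundle, percentiles = seq(0.80, 0.98, by = 0.02),
                     stages = c("lift", "cluster", "retain", "refine"),
                     xi = 0.1, beta = 2, zeta = 0.80, rng_seed = 0) {
  gt <- bundle$gt$plant_label
  rows <- list()
  for (q in percentiles) {
    fg <- foreground_select(lift, q)$foreground
    sets <- list(lift = fg)
    if (any(c("cluster", "retain", "refine") %in% stages)) {
      feats <- build_descriptors(fg, bundle$scene, bundle$cameras)
      supp <- lift$support[match(fg, lift$ids)]
      kept <- tryCatch(
        optics_cluster_merge(feats, supp, xi = xi)$kept,
        error = function(e) fg)
      sets$cluster <- kept
      if (any(c("retain", "refine") %in% stages)) {
        ret <- nn_retain(kept, bundle$scene, beta = beta)
        sets$retain <- ret
        if ("refine" %in% stages)
          sets$refine <- refine_subset(bundle$scene, ret, zeta = zeta,
                                       rng_seed = rng_seed)$refined
      }
    }
    for (st in intersect(stages, names(sets))) {
      m <- extraction_metrics(sets[[st]], gt)
      rows[[length(rows) + 1]] <- data.frame(
        stage = st, q = q, precision = m$precision, recall = m$recall,
        miou = m$miou, n_kept = length(sets[[st]]))
    }
  }
  do.call(rbind, rows)
}

# Point-set IoU between two index sets.
set_iou <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Instance-level AP50 / AR50
#'
#' Greedy one-to-one matching of predicted instances (sorted by confidence)
#' to ground-truth instances of the same class at point-set IoU >= `iou_thr`;
#' AP is the area under the all-point interpolated precision-recall curve,
#' AR the matched fraction of ground-truth instances.
#'
#' @param pred list of `organ_instance`s (fields `semantic_class`,
#'   `member_ids`, `confidence`).
#' @param gt list of ground-truth instances (same fields; confidence
#'   ignored).
#' @param iou_thr matching threshold (default 0.5).
#' @return list with per-class `ap`, `ar` and the class means `mean_ap`,
#'   `mean_ar`.
#' @export
instance_ap <- function(pred, gt, iou_thr = 0.5) {
  classes <- unique(vapply(gt, `[[`, character(1), "semantic_class"))
  ap <- ar <- stats::setNames(numeric(0), character(0))
  for (cls in classes) {
    g <- Filter(function(o) o$semantic_class == cls, gt)
    p <- Filter(function(o) o$semantic_class == cls, pred)
    if (length(g) == 0) { message("no ground-truth instances of class ", cls); next }
    if (length(p) == 0) { ap[cls] <- 0; ar[cls] <- 0; next }
    conf <- vapply(p, `[[`, numeric(1), "confidence")
    p <- p[order(conf, decreasing = TRUE)]
    matched_gt <- rep(FALSE, length(g))
    tp <- numeric(length(p))
    for (i in seq_along(p)) {
      ious <- vapply(seq_along(g), function(j) {
        if (matched_gt[j]) return(-1)
        set_iou(p[[i]]$member_ids, g[[j]]$member_ids)
      }, numeric(1))
      j <- which.max(ious)
      if (ious[j] >= iou_thr) { matched_gt[j] <- TRUE; tp[i] <- 1 }
    }
    cum_tp <- cumsum(tp)
    prec <- cum_tp / seq_along(tp)
    rec <- cum_tp / length(g)
    # all-point interpolation
    a <- 0; prev_r <- 0
    for (i in seq_along(tp)) {
      if (i == length(tp) || TRUE) {
        pmax_right <- max(prec[i:length(prec)])
        a <- a + (rec[i] - prev_r) * pmax_right
        prev_r <- rec[i]
      }
    }
    ap[cls] <- a
    ar[cls] <- mean(matched_gt)
  }
  list(ap = ap, ar = ar, mean_ap = mean(ap), mean_ar = mean(ar))
}
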