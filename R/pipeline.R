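#' Full plant extraction pipeline (lift, cluster, retain, refine)
#'
#' Runs the three extraction stages end to end on a 3DGS scene: multi-view
#' cue lifting with scene-adaptive foreground selection, OPTICS clustering
#' with merge rules and nearest-neighbour retain, and CIELAB chromatic
#' refinement.
#'
#' @param splats full-scene [splat_set()].
#' @param views list of all [camera_view()]s.
#' @param cues a [cue_set()].
#' @param q lift retention percentile (default 0.88, the top 12 percent).
#' @param xi OPTICS steepness (default 0.1).
#' @param beta NN-retain radius scale (default 2).
#' @param zeta chromatic coverage (default 0.80).
#' @param k_sigma footprint truncation (default 3).
#' @param rng_seed seed for the colour-model fit.
#' @param lift_result optionally reuse precomputed [support_scores()].
#' @return list with `lift` (lift_result), `foreground`, `cluster`
#'   (cluster_outcome), `kept`, `retained`, `refined` (all 0-based id
#'   vectors) and `color_model`.
#' @export
extract_plant <- function(splats, views, cues, q = 0.88, xi = 0.1, beta = 2,
                          zeta = 0.80, k_sigma = 3, rng_seed = 0,
                          lift_result = NULL) {
  lr <- lift_result %||% support_scores(splats, views, cues, k_sigma = k_sigma)
  lr <- foreground_select(lr, q)
  feats <- build_descriptors(lr$foreground, splats, views)
  supp <- lr$support[match(lr$foreground, lr$ids)]
  cl <- optics_cluster_merge(feats, supp, xi = xi)
  retained <- nn_retain(cl$kept, splats, beta = beta)
  ref <- refine_subset(splats, retained, zeta = zeta, rng_seed = rng_seed)
  list(lift = lr, foreground = lr$foreground, cluster = cl, kept = cl$kept,
       retained = retained, refined = ref$refined, color_model = ref$model)
}
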