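# Shared fixtures. Scene bundles are expensive, so they are memoized per
# (seed, options) in a session-level cache.

.fx_cache <- new.env(parent = emptyenv())

fx_memo <- function(key, fn) {
  if (!exists(key, envir = .fx_cache)) assign(key, fn(), envir = .fx_cache)
  get(key, envir = .fx_cache)
}

fx_bundle <- function(seed = 0) {
  fx_memo(paste0("bundle_", seed), function() make_scene(seed = seed))
}

fx_cues <- function(seed = 0, noisy = FALSE) {
  fx_memo(paste0("cues_", seed, "_", noisy), function() {
    b <- fx_bundle(seed)
    noise <- if (noisy) list(dilate_px = 3, clutter_boxes = 2, dropout = 0)
             else list(dilate_px = 0, clutter_boxes = 0, dropout = 0)
    suppressWarnings(render_cue_masks(b, noise = noise, seed = seed))
  })
}

fx_extraction <- function(seed = 0) {
  fx_memo(paste0("extract_", seed), function() {
    b <- fx_bundle(seed)
    suppressMessages(extract_plant(b$scene, b$cameras, fx_cues(seed),
                                   rng_seed = seed))
  })
}

# A pinhole camera looking from `eye` toward `at`, y-down image convention.
fx_lookat_camera <- function(eye, at = c(0, 0, 0), f = 460,
                             image_size = c(512, 384), up = c(0, 0, 1),
                             view_index = 0L, sharpness = 0) {
  fwd <- at - eye
  fwd <- fwd / sqrt(sum(fwd^2))
  right <- c(fwd[2] * up[3] - fwd[3] * up[2],
             fwd[3] * up[1] - fwd[1] * up[3],
             fwd[1] * up[2] - fwd[2] * up[1])
  right <- right / sqrt(sum(right^2))
  down <- c(fwd[2] * right[3] - fwd[3] * right[2],
            fwd[3] * right[1] - fwd[1] * right[3],
            fwd[1] * right[2] - fwd[2] * right[1])
  R <- rbind(right, down, fwd)
  rownames(R) <- NULL
  K <- matrix(c(f, 0, image_size[1] / 2,
                0, f, image_size[2] / 2,
                0, 0, 1), 3, 3, byrow = TRUE)
  camera_view(K, R, as.numeric(-R %*% eye), image_size,
              sharpness = sharpness, view_index = view_index)
}

# Minimal splat set: isotropic Gaussians at given positions.
fx_iso_splats <- function(positions, scale = 0.01, opacity_logit = 3,
                          dc = matrix(0, nrow(positions), 3)) {
  n <- nrow(positions)
  splat_set(positions,
            matrix(log(scale), n, 3),
            cbind(rep(1, n), 0, 0, 0),
            rep(opacity_logit, n),
            dc)
}

fx_full_mask <- function(view) matrix(TRUE, view$image_size[1], view$image_size[2])

fx_cue_entry <- function(view_index, mask) {
  idx <- which(mask, arr.ind = TRUE)
  bbox <- if (nrow(idx) > 0)
    c(min(idx[, 1]) - 1L, min(idx[, 2]) - 1L,
      max(idx[, 1]) - 1L, max(idx[, 2]) - 1L)
  else c(0L, 0L, 0L, 0L)
  list(view_index = as.integer(view_index), mask = mask, bbox = bbox)
}

expect_setequal_int <- function(a, b) {
  expect_setequal(as.integer(a), as.integer(b))
}
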