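# JSON/PNG interchange for cameras and cue masks.

#' Read and write calibrated camera lists
#'
#' Cameras are exchanged as a JSON array with per-view fields
#' `view_index, width, height, fx, fy, cx, cy, rotation` (3x3 row-major),
#' `translation` and `sharpness`.
#'
#' @param path JSON file path.
#' @return list of [camera_view()] objects.
#' @export
read_cameras_json <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(js, function(v) {
    K <- matrix(c(v$fx, 0, v$cx, 0, v$fy, v$cy, 0, 0, 1), 3, 3, byrow = TRUE)
    camera_view(K, matrix(unlist(v$rotation), 3, 3, byrow = TRUE),
                unlist(v$translation), c(v$width, v$height),
                v$sharpness %||% 0, v$view_index)
  })
}

#' @rdname read_cameras_json
#' @param cameras list of [camera_view()] objects.
#' @export
write_cameras_json <- function(cameras, path) {
  js <- lapply(cameras, function(v) list(
    view_index = v$view_index, width = v$image_size[1],
    height = v$image_size[2],
    fx = v$intrinsics[1, 1], fy = v$intrinsics[2, 2],
    cx = v$intrinsics[1, 3], cy = v$intrinsics[2, 3],
    rotation = as.numeric(t(v$rotation)), translation = v$translation,
    sharpness = v$sharpness))
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Seeded 2D cue set
#'
#' Binary cue masks for a handful of seeded views, each carrying the
#' metadata `{image_id, view_index, mask_id, bbox}`. Masks are stored as
#' logical matrices indexed `[x + 1, y + 1]` with 0-based pixel coordinates,
#' matching the projection raster.
#'
#' @param entries list of entries, each a list with fields `image_id`
#'   (character), `view_index` (integer), `mask_id` (integer), `bbox`
#'   (x0, y0, x1, y1 in pixels) and `mask` (logical width x height matrix).
#' @param cameras optional camera list used to validate mask dimensions.
#' @return object of class `cue_set`.
#' @export
cue_set <- function(entries, cameras = NULL) {
  if (length(entries) == 0) stop("cue_set needs at least one entry")
  for (e in entries) {
    stopifnot(is.matrix(e$mask), length(e$bbox) == 4)
    w <- nrow(e$mask); h <- ncol(e$mask)
    if (any(e$bbox[c(1, 3)] < 0) || any(e$bbox[c(1, 3)] > w - 1) ||
        any(e$bbox[c(2, 4)] < 0) || any(e$bbox[c(2, 4)] > h - 1))
      stop("cue bbox outside image bounds")
    if (!is.null(cameras)) {
      v <- Find(function(cv) cv$view_index == e$view_index, cameras)
      if (is.null(v)) stop("cue references unknown view_index ", e$view_index)
      if (!all(c(w, h) == v$image_size))
        stop("cue mask dimensions do not match view ", e$view_index)
    }
  }
  structure(list(entries = entries), class = "cue_set")
}

#' Combined mask per seeded view
#'
#' Multiple masks for the same view (mask fragments of one target) are
#' OR-combined before lifting.
#'
#' @param cues a [cue_set()].
#' @return named list of logical matrices, names = view_index.
#' @export
cue_masks_by_view <- function(cues) {
  views <- unique(vapply(cues$entries, function(e) e$view_index, integer(1)))
  out <- lapply(views, function(v) {
    ms <- Filter(function(e) e$view_index == v, cues$entries)
    m <- ms[[1]]$mask
    for (e in ms[-1]) m <- m | e$mask
    m
  })
  names(out) <- as.character(views)
  out
}

#' Write / read cue masks as 8-bit PNGs with JSON sidecars
#'
#' Each entry `i` is written as `cue_<i>.png` (0/255) plus
#' `cue_<i>.json` holding the metadata.
#'
#' @param cues a [cue_set()].
#' @param dir directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cues <- function(cues, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cues$entries)) {
    e <- cues$entries[[i]]
    # png arrays are [row = y, col = x]
    img <- t(e$mask) * 1
    png::writePNG(img, file.path(dir, sprintf("cue_%03d.png", i)))
    jsonlite::write_json(
      list(image_id = e$image_id, view_index = e$view_index,
           mask_id = e$mask_id, bbox = e$bbox),
      file.path(dir, sprintf("cue_%03d.json", i)), auto_unbox = TRUE)
  }
  invisible(dir)
}

#' @rdname write_cues
#' @export
read_cues <- function(dir) {
  pngs <- sort(list.files(dir, pattern = "^cue_.*\\.png$", full.names = TRUE))
  if (length(pngs) == 0) stop("no cue PNGs found in ", dir)
  entries <- lapply(pngs, function(p) {
    meta <- jsonlite::read_json(sub("\\.png$", ".json", p), simplifyVector = TRUE)
    img <- png::readPNG(p)
    if (length(dim(img)) == 3) img <- img[, , 1]
    list(image_id = meta$image_id, view_index = as.integer(meta$view_index),
         mask_id = as.integer(meta$mask_id), bbox = as.numeric(meta$bbox),
         mask = t(img > 0.5))
  })
  cue_set(entries)
}
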