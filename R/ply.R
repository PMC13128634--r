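# Binary 3DGS PLY input/output.
#
# Dialect: binary_little_endian 1.0, one `vertex` element whose float
# properties follow the convention of reference 3DGS implementations:
# x, y, z, [nx, ny, nz], f_dc_0..2, [f_rest_*], opacity, scale_0..2 (logs),
# rot_0..3 (w, x, y, z). Properties outside the required set are preserved
# verbatim on write; higher-order SH coefficients are stored but never used
# for colour.

.ply_required <- c("x", "y", "z", paste0("f_dc_", 0:2), "opacity",
                   paste0("scale_", 0:2), paste0("rot_", 0:3))

.ply_type_size <- c(float = 4L, float32 = 4L, double = 8L, float64 = 8L,
                    uchar = 1L, uint8 = 1L, char = 1L, int8 = 1L,
                    ushort = 2L, uint16 = 2L, short = 2L, int16 = 2L,
                    uint = 4L, uint32 = 4L, int = 4L, int32 = 4L)

#' Read a 3DGS scene from a binary PLY file
#'
#' Parses the binary-little-endian PLY dialect written by standard 3DGS
#' implementations. All float properties are loaded; quaternions are
#' renormalized; record order is preserved as ids 0..N-1. Properties beyond
#' the required 3DGS set are kept in `$extra` and written back verbatim by
#' [write_splat_ply()].
#'
#' @param path path to a `.ply` file.
#' @return a [splat_set()].
#' @export
read_splat_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(magic, "ply")) stop("not a PLY file: ", path)
  fmt <- NULL; nvert <- NULL
  props <- character(0); types <- character(0)
  in_vertex <- FALSE
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("truncated PLY header")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      in_vertex <- tok[2] == "vertex"
      if (in_vertex) nvert <- as.integer(tok[3])
    } else if (tok[1] == "property" && in_vertex) {
      if (tok[2] == "list") stop("list properties unsupported in vertex element")
      types <- c(types, tok[2]); props <- c(props, tok[3])
    } else if (tok[1] == "end_header") break
  }
  if (!identical(fmt, "binary_little_endian"))
    stop("unsupported PLY format: ", fmt %||% "<missing>")
  if (is.null(nvert)) stop("PLY has no vertex element")
  if (nvert == 0) stop("empty scene: PLY contains zero vertex records")
  missing <- setdiff(.ply_required, props)
  if (length(missing) > 0)
    stop("missing required 3DGS PLY property: ", paste(missing, collapse = ", "))
  sizes <- .ply_type_size[types]
  if (anyNA(sizes)) stop("unknown PLY property type: ",
                         paste(types[is.na(sizes)], collapse = ", "))
  stride <- sum(sizes)
  raw <- readBin(con, what = "raw", n = nvert * stride)
  if (length(raw) < nvert * stride) stop("truncated PLY payload")
  cols <- vector("list", length(props))
  names(cols) <- props
  if (all(types %in% c("float", "float32"))) {
    vals <- readBin(raw, what = "numeric", n = nvert * length(props),
                    size = 4L, endian = "little")
    m <- matrix(vals, nrow = nvert, byrow = TRUE)
    for (j in seq_along(props)) cols[[j]] <- m[, j]
  } else {
    offs <- cumsum(c(0L, sizes[-length(sizes)]))
    dim(raw) <- c(stride, nvert)
    for (j in seq_along(props)) {
      bytes <- raw[offs[j] + seq_len(sizes[j]), , drop = FALSE]
      what <- if (types[j] %in% c("float", "float32", "double", "float64"))
        "numeric" else "integer"
      signed <- !grepl("^u", types[j])
      cols[[j]] <- readBin(as.vector(bytes), what = what, n = nvert,
                           size = sizes[j], signed = signed || sizes[j] == 4,
                           endian = "little")
    }
  }
  extra_names <- setdiff(props, .ply_required)
  extra <- if (length(extra_names) > 0) cols[extra_names] else NULL
  if (!is.null(extra)) attr(extra, "ply_types") <- types[match(extra_names, props)]
  splat_set(
    positions = cbind(cols$x, cols$y, cols$z),
    log_scales = cbind(cols$scale_0, cols$scale_1, cols$scale_2),
    rotations = cbind(cols$rot_0, cols$rot_1, cols$rot_2, cols$rot_3),
    opacity_logits = cols$opacity,
    dc_color = cbind(cols$f_dc_0, cols$f_dc_1, cols$f_dc_2),
    extra = extra
  )
}

#' Write a 3DGS scene to a binary PLY file
#'
#' @param splats a [splat_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_splat_ply <- function(splats, path) {
  n <- n_splats(splats)
  extra <- splats$extra
  extra_names <- names(extra) %||% character(0)
  extra_types <- attr(extra, "ply_types") %||% rep("float", length(extra_names))
  props <- c("x", "y", "z", extra_names[extra_names %in% c("nx", "ny", "nz")],
             paste0("f_dc_", 0:2),
             extra_names[grepl("^f_rest_", extra_names)],
             "opacity", paste0("scale_", 0:2), paste0("rot_", 0:3),
             setdiff(extra_names,
                     c("nx", "ny", "nz",
                       extra_names[grepl("^f_rest_", extra_names)])))
  types <- ifelse(props %in% extra_names,
                  extra_types[match(props, extra_names)], "float")
  types[is.na(types)] <- "float"
  header <- c("ply", "format binary_little_endian 1.0",
              sprintf("element vertex %d", n),
              sprintf("property %s %s", types, props),
              "end_header")
  get_col <- function(p) {
    switch(p,
      x = splats$positions[, 1], y = splats$positions[, 2],
      z = splats$positions[, 3],
      f_dc_0 = splats$dc_color[, 1], f_dc_1 = splats$dc_color[, 2],
      f_dc_2 = splats$dc_color[, 3],
      opacity = splats$opacity_logits,
      scale_0 = splats$log_scales[, 1], scale_1 = splats$log_scales[, 2],
      scale_2 = splats$log_scales[, 3],
      rot_0 = splats$rotations[, 1], rot_1 = splats$rotations[, 2],
      rot_2 = splats$rotations[, 3], rot_3 = splats$rotations[, 4],
      extra[[p]])
  }
  all_float <- all(types %in% c("float", "float32"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con)
  if (all_float) {
    m <- do.call(cbind, lapply(props, get_col))
    writeBin(as.numeric(t(m)), con, size = 4L, endian = "little")
  } else {
    cols <- lapply(props, get_col)
    for (i in seq_len(n)) {
      for (j in seq_along(props)) {
        sz <- .ply_type_size[[types[j]]]
        if (types[j] %in% c("float", "float32", "double", "float64"))
          writeBin(as.numeric(cols[[j]][i]), con, size = sz, endian = "little")
        else writeBin(as.integer(cols[[j]][i]), con, size = sz, endian = "little")
      }
    }
  }
  invisible(path)
}
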