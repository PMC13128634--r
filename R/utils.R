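# Internal numeric and raster utilities shared across the pipeline.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rotation matrix from a unit quaternion
#'
#' Converts a quaternion in (w, x, y, z) convention into the corresponding
#' 3x3 rotation matrix. The quaternion is normalized first.
#'
#' @param q numeric length-4 vector (w, x, y, z).
#' @return 3x3 orthonormal rotation matrix.
#' @export
quat_to_rotmat <- function(q) {
  stopifnot(length(q) == 4, all(is.finite(q)))
  n <- sqrt(sum(q^2))
  if (n == 0) stop("zero quaternion")
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Snap doubles through IEEE float32 representation; used by the generator so
# that PLY round trips are bit-stable.
snap_float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
          what = "numeric", n = length(x), size = 4L, endian = "little")
}

# Evaluate a function with a temporarily seeded RNG, restoring global state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Integer offsets of a disc-shaped structuring element of the given radius
# (in cells), including the centre.
disc_offsets <- function(radius) {
  r <- as.integer(ceiling(radius))
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g <- g[g$dx^2 + g$dy^2 <= radius^2 + 1e-9, , drop = FALSE]
  as.matrix(g)
}

# Shift a matrix by (dx, dy) cells, padding with `fill`.
shift_mat <- function(m, dx, dy, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  sr <- max(1, 1 - dx):min(nr, nr - dx)
  sc <- max(1, 1 - dy):min(nc, nc - dy)
  if (length(sr) > 0 && length(sc) > 0)
    out[sr + dx, sc + dy] <- m[sr, sc, drop = FALSE]
  out
}

#' Grayscale morphological operations with a disc structuring element
#'
#' Moving maximum (`dilate`) / minimum (`erode`) filters and their closing /
#' opening compositions, applied to a numeric matrix. Used for cue-mask noise
#' models and for the height-map filter in trait computation. Outside-image
#' values behave as -Inf for dilation and +Inf for erosion so that borders do
#' not create artificial extrema.
#'
#' @param m numeric matrix.
#' @param radius disc radius in cells.
#' @return filtered matrix of the same dimensions.
#' @export
disc_dilate <- function(m, radius) {
  off <- disc_offsets(radius)
  out <- matrix(-Inf, nrow(m), ncol(m))
  for (i in seq_len(nrow(off)))
    out <- pmax(out, shift_mat(m, off[i, 1], off[i, 2], -Inf))
  out
}

#' @rdname disc_dilate
#' @export
disc_erode <- function(m, radius) {
  off <- disc_offsets(radius)
  out <- matrix(Inf, nrow(m), ncol(m))
  for (i in seq_len(nrow(off)))
    out <- pmin(out, shift_mat(m, off[i, 1], off[i, 2], Inf))
  out
}

#' @rdname disc_dilate
#' @export
disc_closing <- function(m, radius) disc_erode(disc_dilate(m, radius), radius)

#' @rdname disc_dilate
#' @export
disc_opening <- function(m, radius) disc_dilate(disc_erode(m, radius), radius)

# Exact fixed-radius neighbour graph via spatial grid binning. Returns a
# two-column matrix of index pairs (i < j) with euclidean distance <= r.
radius_pairs <- function(x, r) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  d <- ncol(x)
  cell <- pmax(r, 1e-12)
  key <- floor(sweep(x, 2, apply(x, 2, min)) / cell)
  kid <- apply(key, 1, paste, collapse = "_")
  buckets <- split(seq_len(n), kid)
  keymat <- key[match(names(buckets), kid), , drop = FALSE]
  # neighbour cell offsets (full 3^d block; pairs deduplicated by i<j)
  offs <- as.matrix(do.call(expand.grid, rep(list(-1:1), d)))
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  for (b in seq_along(buckets)) assign(names(buckets)[b], b, envir = lookup)
  out <- vector("list", length(buckets))
  r2 <- r^2
  for (b in seq_along(buckets)) {
    ids_b <- buckets[[b]]
    cand <- ids_b
    for (o in seq_len(nrow(offs))) {
      if (all(offs[o, ] == 0)) next
      nb <- paste(keymat[b, ] + offs[o, ], collapse = "_")
      j <- mget(nb, envir = lookup, ifnotfound = list(NULL))[[1]]
      if (!is.null(j)) cand <- c(cand, buckets[[j]])
    }
    cand <- cand[cand > min(ids_b) - 1L]  # keep all, dedupe below by i<j
    if (length(cand) < 2) { out[[b]] <- NULL; next }
    pr <- vector("list", length(ids_b))
    for (k in seq_along(ids_b)) {
      i <- ids_b[k]
      js <- cand[cand > i]
      if (length(js) == 0) next
      dd <- colSums((t(x[js, , drop = FALSE]) - x[i, ])^2)
      hit <- js[dd <= r2]
      if (length(hit) > 0) pr[[k]] <- cbind(i, hit)
    }
    out[[b]] <- do.call(rbind, pr)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) matrix(integer(0), ncol = 2) else res
}

# Connected components of n points under a fixed linking radius.
radius_components <- function(x, r) {
  n <- nrow(as.matrix(x))
  pr <- radius_pairs(x, r)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(pr) > 0) g <- igraph::add_edges(g, t(pr))
  igraph::components(g)$membership
}
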