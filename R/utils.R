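#' Wrap phases into (-pi, pi]
#'
#' @param x numeric vector of phases (radians).
#' @return phases wrapped to the half-open interval (-pi, pi].
#' @examples
#' wrap_phase(c(0, pi, -pi, 3 * pi))
#' @export
wrap_phase <- function(x) {
  x - 2 * pi * ceiling((x - pi) / (2 * pi))
}

#' Circular difference a - b wrapped to (-pi, pi]
#' @param a,b phases in radians.
#' @return wrapped differences.
#' @export
phase_diff <- function(a, b) wrap_phase(a - b)

# Deterministic per-stream seed derivation; keeps results below 2^31.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 65011 + 1) * 7919 + stream) %% 2147483647L
}

#' Bresenham line rasterization
#'
#' Integer line rasterization between two pixel coordinates, as used to
#' sample intensities along normal sections of a curved organ centerline.
#'
#' @param r0,c0 start pixel (row, column), integers.
#' @param r1,c1 end pixel (row, column), integers.
#' @return two-column integer matrix (row, col), one row per rasterized
#'   pixel, ordered from start to end.
#' @examples
#' bresenham(1, 1, 5, 5)  # 45 degree staircase
#' @export
bresenham <- function(r0, c0, r1, c1) {
  r0 <- as.integer(round(r0)); c0 <- as.integer(round(c0))
  r1 <- as.integer(round(r1)); c1 <- as.integer(round(c1))
  dr <- abs(r1 - r0); sr <- if (r0 < r1) 1L else -1L
  dc <- -abs(c1 - c0); sc <- if (c0 < c1) 1L else -1L
  err <- dr + dc
  n <- max(abs(r1 - r0), abs(c1 - c0)) + 1L
  rs <- integer(n); cs <- integer(n)
  for (k in seq_len(n)) {
    rs[k] <- r0; cs[k] <- c0
    if (r0 == r1 && c0 == c1) { rs <- rs[1:k]; cs <- cs[1:k]; break }
    e2 <- 2L * err
    if (e2 >= dc) { err <- err + dc; r0 <- r0 + sr }
    if (e2 <= dr) { err <- err + dr; c0 <- c0 + sc }
  }
  cbind(row = rs, col = cs)
}

#' Exact 3x3 median filter
#'
#' Vectorized median-of-9 (sorting network), replicate padding at the
#' borders. Unlike rescaling/quantizing implementations, output values are
#' exact medians of the input values, so single-pixel spikes are removed
#' without altering flat regions.
#'
#' @param x numeric matrix.
#' @return matrix of the same dimension.
#' @export
median_filter3 <- function(x) {
  stopifnot(is.matrix(x))
  nr <- nrow(x); nc <- ncol(x)
  if (nr < 2 || nc < 2) return(x)
  xp <- rbind(x[1, , drop = FALSE], x, x[nr, , drop = FALSE])
  xp <- cbind(xp[, 1, drop = FALSE], xp, xp[, nc, drop = FALSE])
  p <- vector("list", 9)
  k <- 0
  for (dr in 0:2) for (dc in 0:2) {
    k <- k + 1
    p[[k]] <- xp[dr + seq_len(nr), dc + seq_len(nc)]
  }
  op <- function(a, b) {
    lo <- pmin(p[[a]], p[[b]])
    p[[b]] <<- pmax(p[[a]], p[[b]])
    p[[a]] <<- lo
  }
  # Paeth's 19-exchange median-of-9 network (1-indexed); median ends in p[[5]]
  op(2, 3); op(5, 6); op(8, 9); op(1, 2); op(4, 5); op(7, 8)
  op(2, 3); op(5, 6); op(8, 9); op(1, 4); op(6, 9); op(5, 8)
  op(4, 7); op(2, 5); op(3, 6); op(5, 8); op(5, 3); op(7, 5); op(5, 3)
  p[[5]]
}

# Undirected neighbor pairs among occupied pixel coordinates.
# coords: matrix/data.frame with columns row, col. connectivity: 8 or 4.
# Returns a 2-column integer matrix of indices into coords (i < j not
# guaranteed; each unordered pair appears once).
neighbor_pairs <- function(coords, connectivity = 8) {
  row <- as.integer(coords[, "row"]); col <- as.integer(coords[, "col"])
  stride <- max(col) + 2L
  key <- row * stride + col
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  if (connectivity == 4) offs <- offs[1:2]
  out <- vector("list", length(offs))
  for (k in seq_along(offs)) {
    o <- offs[[k]]
    j <- match(key + o[1] * stride + o[2], key)
    i <- which(!is.na(j))
    out[[k]] <- cbind(i, j[i])
  }
  do.call(rbind, out)
}

# Label 8-connected components of a logical mask via igraph.
# Returns an integer matrix: 0 = background, k = component id.
label_components <- function(mask, connectivity = 8) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (!length(idx)) return(lab)
  coords <- cbind(row = (idx - 1L) %% nrow(mask) + 1L,
                  col = (idx - 1L) %/% nrow(mask) + 1L)
  pr <- neighbor_pairs(coords, connectivity)
  g <- igraph::graph_from_edgelist(matrix(as.integer(pr), ncol = 2),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

# Linear interpolation of interior NA runs of length <= max_gap in a vector;
# longer runs and edge NAs are left missing.
fill_gaps <- function(x, max_gap = 2L) {
  na <- is.na(x)
  if (!any(na) || all(na)) return(x)
  r <- rle(na)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  xi <- x
  ok <- which(!na)
  for (k in which(r$values)) {
    if (r$lengths[k] > max_gap) next
    s <- starts[k]; e <- ends[k]
    if (s == 1L || e == length(x)) next
    xi[s:e] <- stats::approx(ok, x[ok], xout = s:e)$y
  }
  xi
}

`%||%` <- function(a, b) if (is.null(a)) b else a
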