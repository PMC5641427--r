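#' Validate and canonicalize a contour
#'
#' A contour is an ordered closed polygon stored as a two-column numeric
#' matrix (columns \code{x}, \code{y}) of vertex coordinates in pixel units,
#' in a y-up Cartesian frame. The closing vertex is not duplicated: the edge
#' from the last row back to the first row is implied.
#'
#' @param xy A two-column numeric matrix or data frame of vertices.
#' @return A numeric matrix with columns \code{x} and \code{y}.
#' @export
as_contour <- function(xy) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L) stop("a contour needs exactly two columns (x, y)")
  storage.mode(xy) <- "double"
  if (any(!is.finite(xy))) stop("contour contains non-finite coordinates")
  # drop a duplicated closing vertex if present
  n <- nrow(xy)
  if (n > 1L && all(xy[1L, ] == xy[n, ])) xy <- xy[-n, , drop = FALSE]
  if (nrow(xy) < 3L) stop("a contour needs at least 3 vertices")
  colnames(xy) <- c("x", "y")
  xy
}

#' Signed polygon area (shoelace formula)
#'
#' Positive for counter-clockwise vertex order in the y-up frame.
#'
#' @param xy Contour matrix (see [as_contour()]).
#' @return Signed area in squared pixel units.
#' @export
polygon_area <- function(xy) {
  xy <- as_contour(xy)
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Polygon perimeter
#' @param xy Contour matrix.
#' @return Total boundary length in pixels.
#' @export
polygon_perimeter <- function(xy) {
  xy <- as_contour(xy)
  dx <- diff(c(xy[, 1L], xy[1L, 1L]))
  dy <- diff(c(xy[, 2L], xy[1L, 2L]))
  sum(sqrt(dx^2 + dy^2))
}

#' Test whether a closed polygon is simple (non-self-intersecting)
#'
#' Exhaustive segment-pair sweep: every pair of non-adjacent edges is tested
#' for proper or improper intersection. Quadratic in the vertex count, which
#' is fine at the contour sizes used here (a few hundred vertices).
#'
#' @param xy Contour matrix.
#' @param tol Relative tolerance for the orientation tests (scaled by the
#'   squared contour extent, so the verdict does not change under similarity
#'   transforms).
#' @return Logical scalar.
#' @export
is_simple_polygon <- function(xy, tol = 1e-12) {
  xy <- as_contour(xy)
  n <- nrow(xy)
  # normalize to unit scale so the verdict is similarity-invariant
  L <- max(diff(range(xy[, 1L])), diff(range(xy[, 2L])))
  if (L <= 0) return(FALSE)
  xy[, 1L] <- (xy[, 1L] - mean(range(xy[, 1L]))) / L
  xy[, 2L] <- (xy[, 2L] - mean(range(xy[, 2L]))) / L
  p <- xy
  q <- xy[c(2:n, 1L), , drop = FALSE]
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in 1:(n - 1L)) {
    # skip adjacent edges (share a vertex), including the wrap-around pair
    if (i + 2L > n) next
    j <- setdiff((i + 2L):n, if (i == 1L) n else integer(0))
    if (!length(j)) next
    d1 <- cross(p[i, 1L], p[i, 2L], q[i, 1L], q[i, 2L], p[j, 1L], p[j, 2L])
    d2 <- cross(p[i, 1L], p[i, 2L], q[i, 1L], q[i, 2L], q[j, 1L], q[j, 2L])
    d3 <- cross(p[j, 1L], p[j, 2L], q[j, 1L], q[j, 2L], p[i, 1L], p[i, 2L])
    d4 <- cross(p[j, 1L], p[j, 2L], q[j, 1L], q[j, 2L], q[i, 1L], q[i, 2L])
    hit <- (d1 * d2 < -tol) & (d3 * d4 < -tol)
    if (any(hit)) return(FALSE)
  }
  TRUE
}

#' Enforce counter-clockwise vertex order
#'
#' Reverses the vertex order (keeping the first vertex first) when the signed
#' area is negative, so that downstream first-harmonic aspect ratios are
#' positive.
#'
#' @param xy Contour matrix.
#' @return Contour matrix with positive signed area.
#' @export
ensure_ccw <- function(xy) {
  xy <- as_contour(xy)
  if (polygon_area(xy) < 0) {
    n <- nrow(xy)
    xy <- xy[c(1L, n:2L), , drop = FALSE]
  }
  xy
}

# Rigid/similarity transform helper used by the generator and tests.
transform_contour <- function(xy, rotation = 0, scale = 1, shift = c(0, 0)) {
  xy <- as_contour(xy)
  R <- matrix(c(cos(rotation), sin(rotation), -sin(rotation), cos(rotation)), 2L)
  out <- scale * (xy %*% t(R))
  out[, 1L] <- out[, 1L] + shift[1L]
  out[, 2L] <- out[, 2L] + shift[2L]
  colnames(out) <- c("x", "y")
  out
}
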