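#' Signed orientation (cross-product) test
#'
#' Computes `(b.x - a.x) * (c.y - a.y) - (b.y - a.y) * (c.x - a.x)`, the z
#' component of the cross product of `b - a` and `c - a`. The sign
#' classifies `c` against the directed line `a -> b`: positive means `c`
#' lies strictly to the left (a counterclockwise turn), negative strictly
#' to the right, zero collinear. Plain double precision; the sign is exact
#' whenever the products are (no epsilon is applied).
#'
#' @param a,b,c Points: length-2 numeric vectors `c(x, y)`, or matrices
#'   with columns x,y (vectorized over rows, recycled to a common length).
#' @return Numeric vector of signed orientation values.
#' @examples
#' orient(c(0, 0), c(1, 0), c(0, 1)) # +1, counterclockwise
#' orient(c(0, 0), c(1, 0), c(2, 0)) # 0, collinear
#' @export
orient <- function(a, b, c) {
  a <- .pt_mat(a); b <- .pt_mat(b); c <- .pt_mat(c)
  .orient(a[, 1L], a[, 2L], b[, 1L], b[, 2L], c[, 1L], c[, 2L])
}

# coordinate-vector form, fully vectorized; hot path of the keep test
.orient <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

.pt_mat <- function(p) {
  if (is.matrix(p)) p else matrix(as.numeric(p), ncol = 2L)
}

#' Is a point strictly outside a fence segment?
#'
#' A point is strictly outside the lower fence when it lies strictly below
#' the directed segment `p1 -> p2` (orientation < 0), and strictly outside
#' the upper fence when strictly above it (orientation > 0). Segments are
#' stored left to right for both sides; the upper-side test flips the sign
#' rather than reversing the segment. Collinear points (orientation 0) are
#' not outside: a point on a fence segment is a convex combination of two
#' retained points and can never be a strict hull vertex.
#'
#' @param p1,p2 Segment endpoints with `p1` left of `p2` (`p1[1] < p2[1]`).
#' @param p Query point(s); vectorized as in [orient()].
#' @param side `"lower"` or `"upper"`.
#' @return Logical vector.
#' @examples
#' is_strictly_outside(c(2, 1), c(8, 0), c(5, 0.2), "lower") # TRUE
#' is_strictly_outside(c(2, 1), c(8, 0), c(5, 2),   "lower") # FALSE
#' @export
is_strictly_outside <- function(p1, p2, p, side = c("lower", "upper")) {
  side <- match.arg(side)
  o <- orient(p1, p2, p)
  if (side == "lower") o < 0 else o > 0
}

#' Remove non-convex points from an x-monotone polyline
#'
#' One stack-based left-to-right pass over an x-sorted polyline, the
#' x-monotone specialization of convex-chain computation. For a lower
#' fence the surviving chain turns strictly counterclockwise (every
#' consecutive triple has orientation > 0); for an upper fence strictly
#' clockwise (orientation < 0). Collinear interior points are removed:
#' a point interior to a segment between two other points can never be a
#' strict hull vertex. The first and last points are never removed.
#'
#' @param poly k x 2 matrix of polyline coordinates, non-decreasing in x.
#' @param side `"lower"` or `"upper"`.
#' @return A list with `kept` (logical flags parallel to the input rows)
#'   and `polyline` (the surviving coordinates).
#' @examples
#' convexify_polyline(rbind(c(0, 0), c(1, 2), c(2, 0)), "lower")$kept
#' @export
convexify_polyline <- function(poly, side = c("lower", "upper")) {
  side <- match.arg(side)
  poly <- .pt_mat(poly)
  k <- nrow(poly)
  if (k < 2L) stop("polyline must have at least 2 points")
  if (is.unsorted(poly[, 1L])) stop("polyline must be sorted by x")
  sgn <- if (side == "lower") 1 else -1
  x <- poly[, 1L]; y <- poly[, 2L]
  stack <- integer(k); stack[1:2] <- 1:2; top <- 2L
  if (k > 2L) for (i in 3:k) {
    while (top >= 2L &&
           sgn * .orient(x[stack[top - 1L]], y[stack[top - 1L]],
                         x[stack[top]], y[stack[top]], x[i], y[i]) <= 0) {
      top <- top - 1L
    }
    top <- top + 1L
    stack[top] <- i
  }
  kept <- logical(k)
  kept[stack[seq_len(top)]] <- TRUE
  list(kept = kept, polyline = poly[kept, , drop = FALSE])
}
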