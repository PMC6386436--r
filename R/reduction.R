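#' Keep the points strictly outside one convex fence
#'
#' The one-step accept test: each point is compared against the single
#' fence segment selected by its rebinned label (label `j` picks the
#' segment from fence vertex `j` to `j + 1`) with one cross product.
#' Points strictly outside (below the lower fence / above the upper
#' fence) are kept. Collinear points (orientation exactly 0) are not kept
#' here: a point on a fence segment is a convex combination of two fence
#' vertices, which are themselves input points, so it can never be a
#' strict hull vertex — and the fence vertices are added to the output
#' separately by [reduce_points()], so nothing is lost.
#'
#' @param points A point set.
#' @param labels Rebinned labels from [rebin()] against this fence.
#' @param fence Convexified fence coordinates, a k x 2 matrix sorted by x.
#' @param side `"lower"` or `"upper"`.
#' @return Integer vector of row indices of the points kept.
#' @export
keep_points <- function(points, labels, fence, side = c("lower", "upper")) {
  side <- match.arg(side)
  p <- .xy(points)
  fence <- .pt_mat(fence)
  labels <- as.integer(labels)
  if (length(labels) != p$n) stop("`labels` must be parallel to `points`")
  if (any(labels < 1L) || any(labels > nrow(fence) - 1L))
    stop("internal consistency: label outside fence segment range")
  o <- .orient(fence[labels, 1L], fence[labels, 2L],
               fence[labels + 1L, 1L], fence[labels + 1L, 2L],
               p$x, p$y)
  which(if (side == "lower") o < 0 else o > 0)
}

#' Reduce a point set without changing its convex hull
#'
#' The end-to-end linear-time preprocessor. The x-range is split into `m`
#' uniform bins; each bin's y-extreme points are joined into a lower and
#' an upper fence anchored at the x-extreme points; the fences are made
#' convex; every point is re-labeled against the moved bin boundaries in
#' constant time (prefix-sum rebinning) and tested with one cross product
#' per side. The output is the union of the surviving fence vertices of
#' both sides and all points strictly outside either convex fence. Its
#' guarantee: the strict convex hull vertex set of the kept subset equals
#' that of the full input, so any hull algorithm may be run on the (much
#' smaller) kept subset instead.
#'
#' Degenerate inputs: with n <= 3 all points are returned; when every
#' point shares one x value (vertical line) the minimum-y and maximum-y
#' points are returned; `m` is clamped to at most n.
#'
#' @param points A point set (see [as_points()]); coordinates must be
#'   finite.
#' @param m Number of bins, a positive integer, or `"auto"` to use
#'   [choose_m()].
#' @return An object of class `reduction_result`: list with `indices`
#'   (sorted row indices of the kept points), `s` (kept count), `n`,
#'   `m_used`, `reduction_factor` (`1 - s/n`) and `counters` (kept fence
#'   vertices, points outside each fence, discarded count).
#' @examples
#' sq <- make_fixture("square_plus_center")
#' r <- reduce_points(sq, m = 2)
#' r$indices            # the four corners; the center is discarded
#' r$reduction_factor   # 0.2
#' @export
reduce_points <- function(points, m = "auto") {
  p <- .xy(points)
  n <- p$n
  mk <- function(indices, m_used, counters = NULL) {
    indices <- sort(unique(as.integer(indices)))
    structure(list(indices = indices, s = length(indices), n = n,
                   m_used = m_used,
                   reduction_factor = 1 - length(indices) / n,
                   counters = counters),
              class = "reduction_result")
  }
  if (n <= 3L) return(mk(seq_len(n), m_used = NA_integer_))
  if (identical(m, "auto")) m <- choose_m(n)
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("`m` must be a positive integer or \"auto\"")
  m <- min(m, n)
  if (max(p$x) == min(p$x))        # vertical line: hull is the y-extreme pair
    return(mk(c(which.min(p$y), which.max(p$y)), m_used = m))
  bins <- quantize_uniform(points, m)
  extremes <- per_bin_extremes(points, bins)
  fences <- convexify_fences(build_fences(points, bins, extremes), points)
  out_side <- function(f) {
    new_lab <- rebin(p$x, bins$labels, f$tables)
    keep_points(points, new_lab, f$coords, side = f$side)
  }
  out_lo <- out_side(fences$lower)
  out_hi <- out_side(fences$upper)
  fence_idx <- c(fences$lower$polyline, fences$upper$polyline)
  idx <- sort(unique(c(fence_idx, out_lo, out_hi)))
  mk(idx, m_used = m,
     counters = list(fence_kept = length(unique(fence_idx)),
                     outside_lower = length(out_lo),
                     outside_upper = length(out_hi),
                     discarded = n - length(idx)))
}

#' @export
print.reduction_result <- function(x, ...) {
  cat(sprintf("Point-set reduction: n = %d -> s = %d (%.2f%% removed, m = %s)\n",
              x$n, x$s, 100 * x$reduction_factor,
              ifelse(is.na(x$m_used), "-", x$m_used)))
  invisible(x)
}

#' Choose the number of bins
#'
#' Heuristic for the bin count `m`. The speedup-maximising region lies
#' between 10 and lg n, so the default mode returns 10 once `lg n >= 10`
#' (10 is also the default bin count of several numerical environments)
#' and `max(2, floor(lg n))` for smaller inputs; mode `"lg"` returns
#' `ceiling(lg n)`. The result never exceeds `n`.
#'
#' @param n Number of points (>= 1).
#' @param mode `"default"` (constant 10) or `"lg"` (`ceiling(lg n)`).
#' @return A positive integer.
#' @examples
#' choose_m(1e6)          # 10
#' choose_m(1e6, "lg")    # 20
#' choose_m(64)           # 6
#' @export
choose_m <- function(n, mode = c("default", "lg")) {
  mode <- match.arg(mode)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be a positive integer")
  lgn <- log2(n)
  m <- if (mode == "lg") as.integer(ceiling(lgn))
       else if (lgn >= 10) 10L
       else max(2L, as.integer(floor(lgn)))
  max(1L, min(m, n))
}
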