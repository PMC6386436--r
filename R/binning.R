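#' Find the points with extreme x-coordinates
#'
#' Locates the points with the smallest and greatest x-coordinate. When
#' several points tie on an extreme x value, the tie is broken per fence
#' side: the lower fence uses the tied point with the smallest y at both
#' ends, the upper fence the largest y. (Keeping an arbitrary tied point
#' could place another tied extreme strictly inside one fence; the
#' per-side rule guarantees the hull-preservation contract under ties.)
#'
#' @param points A point set (see [as_points()]).
#' @param side Tie-break variant, `"lower"` or `"upper"`.
#' @return List with `ixmin`, `ixmax` (row indices) and `xmin`, `xmax`
#'   (the extreme x values).
#' @examples
#' find_x_extremes(rbind(c(2.3, 0), c(9.1, 5), c(5, 1)))
#' @export
find_x_extremes <- function(points, side = c("lower", "upper")) {
  side <- match.arg(side)
  p <- .xy(points)
  xmin <- min(p$x); xmax <- max(p$x)
  pick <- function(cand) {
    if (side == "lower") cand[which.min(p$y[cand])]
    else cand[which.max(p$y[cand])]
  }
  list(ixmin = pick(which(p$x == xmin)), ixmax = pick(which(p$x == xmax)),
       xmin = xmin, xmax = xmax)
}

#' Quantize points into m equal-width x-intervals
#'
#' Divides the range `[xmin, xmax]` of the x-coordinates into `m`
#' equal-width bins and labels each point with its bin, 1..m, in constant
#' time per point: `floor((x - xmin) / width) + 1`, clamped to `[1, m]`.
#' Bin j covers the half-open interval
#' `[xmin + (j-1) * width, xmin + j * width)`; the last bin is closed on
#' the right so that `x = xmax` gets label `m`.
#'
#' @param points A point set.
#' @param m Number of bins (>= 1).
#' @return An object of class `bin_assignment`: list with `labels`
#'   (integer vector, 1..m), `m`, `xmin`, `xmax` and `width`.
#' @examples
#' b <- quantize_uniform(rbind(c(2.3, 0), c(9.1, 5), c(5, 1)), m = 4)
#' b$width          # 1.7
#' b$labels         # bins of the three points
#' @export
quantize_uniform <- function(points, m) {
  p <- .xy(points)
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("`m` must be a positive integer")
  xmin <- min(p$x); xmax <- max(p$x)
  if (xmax == xmin)
    stop(errorCondition(
      "all points share one x value (degenerate vertical line)",
      class = "hullprep_degenerate_x"))
  width <- (xmax - xmin) / m
  labels <- pmin.int(pmax.int(floor((p$x - xmin) / width) + 1, 1L), m)
  structure(list(labels = as.integer(labels), m = m,
                 xmin = xmin, xmax = xmax, width = width),
            class = "bin_assignment")
}

#' Per-bin y-extreme points
#'
#' Finds, for every bin, the point with the minimum and the point with the
#' maximum y-coordinate (both located in one sweep). Ties on y within a
#' bin keep the first-seen point (smallest row index). Bins containing no
#' point are flagged empty.
#'
#' @param points A point set.
#' @param bins A `bin_assignment` from [quantize_uniform()] for the same
#'   points.
#' @return List with integer vectors `min_y_index`, `max_y_index` (row
#'   index per bin, `NA` where empty) and logical `empty`, each of length
#'   `bins$m`.
#' @export
per_bin_extremes <- function(points, bins) {
  p <- .xy(points)
  stopifnot(inherits(bins, "bin_assignment"))
  q <- bins$labels
  if (length(q) != p$n) stop("bin assignment does not match point set")
  m <- bins$m
  min_y <- max_y <- rep(NA_integer_, m)
  o <- order(q, p$y)                       # stable radix sort
  fst <- !duplicated(q[o])
  min_y[q[o][fst]] <- o[fst]
  o2 <- order(q, -p$y)
  fst2 <- !duplicated(q[o2])
  max_y[q[o2][fst2]] <- o2[fst2]
  list(min_y_index = min_y, max_y_index = max_y, empty = is.na(min_y))
}

#' Build rebinning tables for one fence
#'
#' Projects the pre-convexification fence points onto the x-axis (vector
#' `C` of boundary values, first entry `xmin`, last `xmax`) and annotates
#' which positions were removed — either because the bin was empty, the
#' projected point duplicated its predecessor, or fence convexification
#' dropped it. `S` is the inclusive prefix sum of the removed flags, so
#' `S[j]` counts removals at positions `<= j`. The boundaries that survive
#' define the new, non-uniform bins used by [rebin()]; `j`-th new bin lies
#' between surviving boundaries `j` and `j + 1`.
#'
#' @param boundaries Numeric vector of projected fence x-values, sorted
#'   non-decreasing, strictly increasing on the surviving positions.
#' @param removed Logical vector parallel to `boundaries`; the first and
#'   last position must be `FALSE` (endpoints always survive).
#' @return An object of class `rebin_tables`: list with `C`, `removed`,
#'   `S`, the surviving boundaries `C_surv` and the new bin count
#'   `n_new_bins`.
#' @examples
#' tb <- build_rebin_tables(1:7, c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
#' tb$S   # 0 1 1 1 2 2 2
#' @export
build_rebin_tables <- function(boundaries, removed) {
  boundaries <- as.numeric(boundaries)
  removed <- as.logical(removed)
  k <- length(boundaries)
  if (length(removed) != k) stop("`removed` must be parallel to `boundaries`")
  if (k < 2L) stop("need at least two boundaries")
  if (removed[1L] || removed[k])
    stop("internal consistency: an endpoint boundary is flagged removed")
  if (is.unsorted(boundaries)) stop("boundaries must be sorted")
  surv <- boundaries[!removed]
  if (any(diff(surv) <= 0))
    stop("surviving boundaries must be strictly increasing")
  structure(list(C = boundaries, removed = removed,
                 S = cumsum(as.integer(removed)),
                 C_surv = surv, n_new_bins = length(surv) - 1L),
            class = "rebin_tables")
}

#' Re-label points against fence-induced bins in constant time
#'
#' After fence convexification the bin boundaries move to the projections
#' of the surviving fence points and become non-uniform. Rather than a
#' binary search per point (O(lg m) each), each new label is computed in
#' O(1) from the point's original uniform label `q` and the prefix-sum
#' table: if `x >= C[q + 1]` the new label is `q + 1 - S[q + 1]`,
#' otherwise `q - S[q]`. New label `j` means the point is tested against
#' the `j`-th segment of the convexified fence.
#'
#' @param x Numeric vector of point x-coordinates.
#' @param labels Integer vector of original uniform bin labels (1-based),
#'   parallel to `x`.
#' @param tables A `rebin_tables` object built from the same fence.
#' @return Integer vector of new labels in `1..tables$n_new_bins`.
#' @seealso [rebin_binary_search()] for the reference O(lg m) method.
#' @export
rebin <- function(x, labels, tables) {
  stopifnot(inherits(tables, "rebin_tables"))
  x <- as.numeric(x); q <- as.integer(labels)
  k <- length(tables$C)
  if (length(q) != length(x)) stop("`labels` must be parallel to `x`")
  if (any(q < 1L) || any(q > k - 1L))
    stop("internal consistency: bin label out of range")
  hi <- x >= tables$C[q + 1L]
  new_q <- q - tables$S[q]
  new_q[hi] <- q[hi] + 1L - tables$S[q[hi] + 1L]
  if (any(new_q < 1L) || any(new_q > tables$n_new_bins))
    stop("internal consistency: rebinned label out of segment range")
  as.integer(new_q)
}

#' Reference rebinning by binary search
#'
#' Labels each point against the surviving (non-uniform) boundaries by
#' binary search, O(lg m) per point. This is the conventional method that
#' the constant-time [rebin()] replaces; it is retained as an independent
#' reference implementation and oracle.
#'
#' @inheritParams rebin
#' @return Integer vector of labels in `1..tables$n_new_bins`.
#' @export
rebin_binary_search <- function(x, tables) {
  stopifnot(inherits(tables, "rebin_tables"))
  lab <- findInterval(as.numeric(x), tables$C_surv)
  pmin.int(pmax.int(lab, 1L), tables$n_new_bins)
}
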