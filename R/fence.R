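#' Assemble the lower and upper fences from per-bin extremes
#'
#' The lower fence is the x-sorted polyline joining the minimum-x endpoint,
#' each non-empty bin's minimum-y point in bin order, and the maximum-x
#' endpoint; the upper fence joins the maximum-y points analogously. With
#' all m bins non-empty each fence has m + 2 points. Internally each fence
#' keeps a slot array of length m + 2 (one slot per endpoint and bin):
#' empty-bin slots carry a placeholder boundary (the bin's left uniform
#' edge) and are pre-flagged removed, as is any slot whose point coincides
#' exactly with the previous surviving slot's point (an endpoint that is
#' also its bin's extreme is stored once). This keeps the rebin-table
#' machinery uniform whether or not every bin has points.
#'
#' @param points A point set.
#' @param bins A `bin_assignment` from [quantize_uniform()].
#' @param extremes Per-bin extremes from [per_bin_extremes()].
#' @return An object of class `fence_pair`: list with components `lower`
#'   and `upper`, each a list with `slots` (point row index per slot, `NA`
#'   where empty), `boundaries` (projected x per slot), `slot_removed`
#'   (logical), `side`, and — after [convexify_fences()] — `polyline`
#'   (surviving point indices), `coords` and `tables` (a `rebin_tables`).
#' @export
build_fences <- function(points, bins, extremes) {
  p <- .xy(points)
  stopifnot(inherits(bins, "bin_assignment"))
  m <- bins$m
  one_side <- function(side) {
    ends <- find_x_extremes(points, side = side)
    ext <- if (side == "lower") extremes$min_y_index else extremes$max_y_index
    slots <- c(ends$ixmin, ext, ends$ixmax)
    empty <- is.na(slots)
    bnd <- numeric(m + 2L)
    bnd[1L] <- bins$xmin
    bnd[m + 2L] <- bins$xmax
    inner <- 2:(m + 1L)
    bnd[inner] <- ifelse(empty[inner], bins$xmin + (inner - 2L) * bins$width,
                         p$x[slots[inner]])
    # placeholder boundaries of empty slots must not fall below their
    # predecessor when floating-point label rounding lets a bin's extreme
    # sit marginally past its nominal edge; removed slots never label any
    # point, so raising them is free
    for (j in inner) if (empty[j] && bnd[j] < bnd[j - 1L]) bnd[j] <- bnd[j - 1L]
    removed <- empty
    # dedup: drop a slot whose point coincides with the last surviving one
    last_x <- p$x[slots[1L]]; last_y <- p$y[slots[1L]]
    for (j in inner) {
      if (removed[j]) next
      if (p$x[slots[j]] == last_x && p$y[slots[j]] == last_y) {
        removed[j] <- TRUE
      } else {
        last_x <- p$x[slots[j]]; last_y <- p$y[slots[j]]
      }
    }
    j <- m + 2L
    if (p$x[slots[j]] == last_x && p$y[slots[j]] == last_y) {
      # final endpoint equals the last surviving interior slot: drop the
      # interior copy, endpoints themselves are never flagged
      dupj <- max(which(!removed[-j]))
      removed[dupj] <- TRUE
    }
    list(slots = slots, boundaries = bnd, slot_removed = removed, side = side)
  }
  structure(list(lower = one_side("lower"), upper = one_side("upper")),
            class = "fence_pair")
}

#' Convexify both fences and build their rebin tables
#'
#' Applies [convexify_polyline()] to each fence's surviving slots, merges
#' the convexification removals into the slot flags, and builds the
#' prefix-sum rebin tables ([build_rebin_tables()]). All surviving fence
#' points belong to the reduced output set. The two sides are independent;
#' processing order between them never changes the result.
#'
#' @param pair A `fence_pair` from [build_fences()].
#' @param points The same point set the pair was built from.
#' @return The `fence_pair` with `polyline` (surviving point row indices),
#'   `coords` (their coordinates) and `tables` filled in per side.
#' @export
convexify_fences <- function(pair, points) {
  stopifnot(inherits(pair, "fence_pair"))
  p <- .xy(points)
  do_side <- function(f) {
    alive <- which(!f$slot_removed)
    idx <- f$slots[alive]
    xy <- cbind(x = p$x[idx], y = p$y[idx])
    cv <- convexify_polyline(xy, side = f$side)
    f$slot_removed[alive[!cv$kept]] <- TRUE
    f$polyline <- idx[cv$kept]
    f$coords <- cv$polyline
    f$tables <- build_rebin_tables(f$boundaries, f$slot_removed)
    f
  }
  pair$lower <- do_side(pair$lower)
  pair$upper <- do_side(pair$upper)
  pair
}
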