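#' @name hull-algorithms
#' @title 2D convex hull algorithms
#'
#' @description
#' Three self-contained planar convex hull algorithms sharing one canonical
#' output convention:
#'
#' * `monotone_chain_hull()` — Andrew's monotone chain, O(n lg n); the
#'   production algorithm.
#' * `chan_hull()` — Chan's output-sensitive algorithm, O(n lg h): points
#'   are partitioned into groups of size g, each group's hull is computed
#'   by monotone chain, and the global hull is gift-wrapped using tangent
#'   queries against the group hulls, restarting with the squaring
#'   schedule g = min(n, 2^(2^t)) until the wrap closes within g steps.
#' * `jarvis_hull()` — gift wrapping, O(n h); an independent implementation
#'   sharing no code with the other two, intended as a test oracle.
#'
#' The returned polygon is the *strict* hull: collinear boundary midpoints
#' are excluded and duplicate input points collapse (the hull of collinear
#' input is the 2-vertex extreme segment, of identical points a single
#' vertex). Vertices are listed counterclockwise starting at the
#' lexicographically smallest (x, then y) vertex, so two hulls are equal
#' iff their vertex sequences are identical. Vertex indices refer to input
#' rows; when several input rows share a vertex coordinate the first
#' occurrence is reported.
#'
#' @param points A point set (see [as_points()]); at least one point.
#' @return An object of class `hull_polygon`: a list with `indices`
#'   (input row numbers of the vertices, canonical order), `x`, `y`
#'   (vertex coordinates) and `h` (vertex count).
#' @examples
#' sq <- make_fixture("square_plus_center")
#' monotone_chain_hull(sq)$indices  # the four corners
#' chan_hull(sq)$h                  # 4
NULL

.hull_polygon <- function(idx, x, y) {
  structure(list(indices = idx, x = x, y = y, h = length(idx)),
            class = "hull_polygon")
}

#' @export
print.hull_polygon <- function(x, ...) {
  cat("Convex hull polygon:", x$h, "vertices (counterclockwise)\n")
  print(utils::head(data.frame(index = x$indices, x = x$x, y = x$y), 10L))
  if (x$h > 10L) cat("...", x$h - 10L, "more vertices\n")
  invisible(x)
}

# lexicographically sorted unique coordinates with first-occurrence input
# indices; shared canonicalization for monotone chain and Chan
.unique_sorted <- function(points) {
  p <- .xy(points)
  o <- order(p$x, p$y)              # stable: first occurrence wins ties
  x <- p$x[o]; y <- p$y[o]
  keep <- c(TRUE, x[-1L] != x[-length(x)] | y[-1L] != y[-length(y)])
  list(x = x[keep], y = y[keep], idx = o[keep])
}

# monotone chain scan over lexicographically sorted unique coordinates;
# returns positions into the sorted arrays, counterclockwise from the
# lexicographic minimum
.chain_scan <- function(x, y) {
  k <- length(x)
  if (k <= 2L) return(seq_len(k))
  half <- function(ord) {
    st <- integer(k); st[1:2] <- ord[1:2]; top <- 2L
    for (i in ord[3:k]) {
      while (top >= 2L &&
             .orient(x[st[top - 1L]], y[st[top - 1L]],
                     x[st[top]], y[st[top]], x[i], y[i]) <= 0) {
        top <- top - 1L
      }
      top <- top + 1L
      st[top] <- i
    }
    st[seq_len(top)]
  }
  lower <- half(seq_len(k))
  upper <- half(rev(seq_len(k)))
  c(lower[-length(lower)], upper[-length(upper)])
}

#' @rdname hull-algorithms
#' @export
monotone_chain_hull <- function(points) {
  u <- .unique_sorted(points)
  pos <- .chain_scan(u$x, u$y)
  .hull_polygon(u$idx[pos], u$x[pos], u$y[pos])
}

#' @rdname hull-algorithms
#' @export
jarvis_hull <- function(points) {
  # gift wrapping; deliberately shares no code path with the chain scan
  p <- .xy(points)
  dup <- duplicated(cbind(p$x, p$y))
  ux <- p$x[!dup]; uy <- p$y[!dup]; uidx <- which(!dup)
  k <- length(ux)
  if (k == 1L) return(.hull_polygon(uidx, ux, uy))
  cand <- which(ux == min(ux))
  start <- cand[which.min(uy[cand])]
  hull <- integer(0L)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    best <- if (cur == 1L) 2L else 1L
    for (j in seq_len(k)) {
      if (j == cur || j == best) next
      cr <- (ux[best] - ux[cur]) * (uy[j] - uy[cur]) -
            (uy[best] - uy[cur]) * (ux[j] - ux[cur])
      if (cr < 0) {
        best <- j
      } else if (cr == 0) {
        dj <- (ux[j] - ux[cur])^2 + (uy[j] - uy[cur])^2
        db <- (ux[best] - ux[cur])^2 + (uy[best] - uy[cur])^2
        if (dj > db) best <- j
      }
    }
    if (best == start || length(hull) > k) break
    cur <- best
  }
  .hull_polygon(uidx[hull], ux[hull], uy[hull])
}

# index of the vertex of a strictly convex CCW polygon that is the right
# tangent point seen from an external point (px, py): every polygon vertex
# lies on or to the left of the ray p -> V[t]. Binary search (chain
# bisection on edge directions) for large polygons, linear scan for small
# ones; either way the result is verified and, if needed, corrected by a
# local climb under the gift-wrap ordering (more clockwise wins, farther
# wins on collinear ties), which at a true tangent stops immediately.
.rtangent <- function(vx, vy, px, py) {
  n <- length(vx)
  il <- function(i, j) (vx[i] - px) * (vy[j] - py) - (vy[i] - py) * (vx[j] - px)
  better <- function(i, j) { # is vertex j strictly better than i?
    cr <- il(i, j)
    cr < 0 || (cr == 0 &&
      (vx[j] - px)^2 + (vy[j] - py)^2 > (vx[i] - px)^2 + (vy[i] - py)^2)
  }
  if (n <= 32L) {
    t <- 1L
    for (j in 2:max(2L, n)) if (j <= n && better(t, j)) t <- j
    return(t)
  }
  ix <- function(i0) (i0 %% n) + 1L                 # 0-based chain -> 1-based
  A <- function(i0, j0) il(ix(i0), ix(j0)) > 0
  B <- function(i0, j0) il(ix(i0), ix(j0)) < 0
  if (B(1L, 0L) && !A(n - 1L, 0L)) {
    t <- 1L
  } else {
    a <- 0L; b <- n
    repeat {
      if (b - a == 1L) { t <- ix(if (A(a, b)) a else b); break }
      cc <- (a + b) %/% 2L
      dnC <- B(cc + 1L, cc)
      if (dnC && !A(cc - 1L, cc)) { t <- ix(cc); break }
      if (A(a + 1L, a)) {
        if (dnC) b <- cc else if (A(a, cc)) b <- cc else a <- cc
      } else {
        if (!dnC) a <- cc else if (B(a, cc)) b <- cc else a <- cc
      }
    }
  }
  guard <- 0L
  repeat {
    nxt <- (t %% n) + 1L
    prv <- ((t - 2L) %% n) + 1L
    if (better(t, nxt)) t <- nxt
    else if (better(t, prv)) t <- prv
    else break
    guard <- guard + 1L
    if (guard > n) break
  }
  t
}

#' @rdname hull-algorithms
#' @export
chan_hull <- function(points) {
  u <- .unique_sorted(points)
  k <- length(u$x)
  if (k <= 2L) return(.hull_polygon(u$idx, u$x, u$y))
  t <- 0L
  repeat {
    t <- t + 1L
    g <- if (2^t >= 31) k else min(k, as.integer(2^(2^t)))
    ngroups <- ceiling(k / g)
    offs <- (seq_len(ngroups) - 1L) * g
    subs <- vector("list", ngroups)
    for (i in seq_len(ngroups)) {
      sel <- (offs[i] + 1L):min(offs[i] + g, k)
      pos <- .chain_scan(u$x[sel], u$y[sel])
      subs[[i]] <- list(x = u$x[sel][pos], y = u$y[sel][pos],
                        gpos = sel[pos])   # positions into sorted arrays
    }
    # global lexicographic minimum = sorted position 1 = vertex 1 of group 1
    hull <- integer(0L)
    cur_g <- 1L; cur_v <- 1L
    cur_gpos <- subs[[1L]]$gpos[1L]
    start_gpos <- cur_gpos
    wrapped <- FALSE
    for (step in seq_len(g)) {
      hull <- c(hull, cur_gpos)
      px <- u$x[cur_gpos]; py <- u$y[cur_gpos]
      bx <- by <- NA_real_; best_g <- best_v <- NA_integer_
      for (i in seq_len(ngroups)) {
        S <- subs[[i]]
        h_i <- length(S$x)
        if (i == cur_g) {
          if (h_i == 1L) next                 # group is just the current point
          v <- (cur_v %% h_i) + 1L            # successor along own sub-hull
        } else {
          v <- .rtangent(S$x, S$y, px, py)
        }
        cx <- S$x[v]; cy <- S$y[v]
        if (is.na(best_g)) {
          best_g <- i; best_v <- v; bx <- cx; by <- cy
        } else {
          cr <- (bx - px) * (cy - py) - (by - py) * (cx - px)
          if (cr < 0 || (cr == 0 &&
              (cx - px)^2 + (cy - py)^2 > (bx - px)^2 + (by - py)^2)) {
            best_g <- i; best_v <- v; bx <- cx; by <- cy
          }
        }
      }
      cur_g <- best_g; cur_v <- best_v
      cur_gpos <- subs[[best_g]]$gpos[best_v]
      if (cur_gpos == start_gpos) { wrapped <- TRUE; break }
    }
    if (wrapped)
      return(.hull_polygon(u$idx[hull], u$x[hull], u$y[hull]))
  }
}
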