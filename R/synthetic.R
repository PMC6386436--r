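#' Sample points uniformly inside a convex superellipse
#'
#' Draws `n` i.i.d. points uniform on the region
#' `|x/a|^t + |y/b|^t <= 1` by rejection sampling from the bounding box
#' `[-a, a] x [-b, b]`. The region is convex for every shape exponent
#' `t >= 1`, interpolating from a rhombus (t = 1) to a rectangle with
#' rounded corners (t -> Inf); `t < 1` is rejected because the reduction
#' method's premise requires a convex support. The worst-case acceptance
#' rate is 1/2 (at t = 1), so rejection stays cheap at any size.
#'
#' @param n Number of points.
#' @param a,b Semi-axes (> 0).
#' @param t Shape exponent (>= 1); `t = 2` is an ellipse.
#' @param seed Optional integer; when given, the sample is a pure
#'   function of the arguments and the caller's RNG state is left intact.
#' @return An n x 2 matrix of points with columns `x`, `y`.
#' @examples
#' p <- sample_superellipse(1000, a = 2, b = 1, t = 4, seed = 1)
#' max(abs(p[, 1] / 2)^4 + abs(p[, 2])^4) <= 1
#' @export
sample_superellipse <- function(n, a = 1, b = 1, t = 2, seed = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be a positive integer")
  if (!is.finite(a) || a <= 0 || !is.finite(b) || b <= 0)
    stop("semi-axes `a` and `b` must be positive")
  if (!is.finite(t) || t < 1)
    stop("shape exponent `t` must be >= 1 (convex superellipse)")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  # acceptance rate = area ratio; batch draws sized by its estimate
  rate <- gamma(1 + 1 / t)^2 / gamma(1 + 2 / t)
  x <- numeric(0L); y <- numeric(0L)
  while (length(x) < n) {
    todo <- n - length(x)
    k <- ceiling(todo / rate * 1.1) + 100
    cx <- stats::runif(k, -a, a)
    cy <- stats::runif(k, -b, b)
    ok <- abs(cx / a)^t + abs(cy / b)^t <= 1
    x <- c(x, cx[ok]); y <- c(y, cy[ok])
  }
  cbind(x = x[seq_len(n)], y = y[seq_len(n)])
}

#' Sample points in a randomly shaped convex superellipse
#'
#' Draws the superellipse shape at random — shape exponent
#' `t ~ Uniform[1.5, 8]` and aspect ratio `a/b ~ Uniform[0.5, 2]` (b fixed
#' at 1; the reduction is scale-free) — then samples `n` uniform points
#' inside it. This is the randomized-shape generator used for the
#' synthetic reduction experiments.
#'
#' @param n Number of points.
#' @param seed Optional integer seed, as in [sample_superellipse()].
#' @return An n x 2 point matrix with attribute `spec` (list of `a`, `b`,
#'   `t` actually drawn).
#' @export
sample_random_superellipse <- function(n, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  t <- stats::runif(1, 1.5, 8)
  a <- stats::runif(1, 0.5, 2)
  p <- sample_superellipse(n, a = a, b = 1, t = t)
  attr(p, "spec") <- list(a = a, b = 1, t = t)
  p
}

#' Deterministic point-set fixtures
#'
#' Small named point sets exercising the degenerate and edge-case paths of
#' the reduction and hull code: the 5-point square-plus-center worked
#' example, collinear and vertical-line sets, exact duplicates, an integer
#' grid (the method is agnostic to integer vs real coordinates), a set
#' with ties on the extreme x values, and a small scattered cloud.
#'
#' @param name One of `"square_plus_center"`, `"collinear_horizontal"`,
#'   `"vertical_line"`, `"duplicates"`, `"integer_grid"`,
#'   `"xtie_extremes"`, `"fig1_like"`.
#' @return A point matrix with columns `x`, `y`.
#' @examples
#' make_fixture("square_plus_center")
#' @export
make_fixture <- function(name) {
  fixtures <- list(
    square_plus_center = cbind(x = c(0, 4, 4, 0, 2), y = c(0, 0, 4, 4, 2)),
    collinear_horizontal = cbind(x = c(0, 1, 2), y = c(0, 0, 0)),
    vertical_line = cbind(x = rep(1, 5), y = c(3, -1, 0, 2, 7)),
    duplicates = cbind(x = c(0, 3, 3, 0, 1, 1, 3), y = c(0, 0, 2, 2, 1, 1, 0)),
    integer_grid = {
      g <- expand.grid(x = 0:4, y = 0:3)
      cbind(x = as.numeric(g$x), y = as.numeric(g$y))
    },
    xtie_extremes = cbind(x = c(0, 0, 0, 5, 5, 2, 3),
                          y = c(1, -2, 4, 0, 3, -1, 5)),
    fig1_like = cbind(
      x = c(1.2, 2.1, 2.8, 3.5, 4.2, 4.9, 5.6, 6.3, 7.4, 8.1, 8.8, 9.3,
            3.1, 5.2, 6.8, 4.4),
      y = c(2.5, 4.8, 0.7, 5.6, 1.1, 6.2, 0.4, 5.9, 1.8, 4.6, 2.2, 3.4,
            3.0, 3.3, 3.1, 2.2))
  )
  if (!name %in% names(fixtures))
    stop("unknown fixture `", name, "`; valid names: ",
         paste(names(fixtures), collapse = ", "))
  fixtures[[name]]
}
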