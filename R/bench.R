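#' Reduction factor
#'
#' The fraction of points removed by preprocessing: `p_r = 1 - s/n`. It
#' depends only on the ratio `s/n`.
#'
#' @param n Input point count.
#' @param s Kept point count, `1 <= s <= n`.
#' @return `1 - s/n`.
#' @examples
#' reduction_factor(100, 8)  # 0.92
#' @export
reduction_factor <- function(n, s) {
  if (any(s < 1) || any(s > n)) stop("`s` must satisfy 1 <= s <= n")
  1 - s / n
}

#' Measure the speedup from preprocessing
#'
#' Times (i) the convex hull on the full set (`t_n`), (ii) the point
#' reduction (`t_r`), and (iii) the hull on the reduced set (`t_s`), each
#' as the best of `repeats` wall-clock runs, and reports the speedup
#' `t_n / (t_r + t_s)` together with the Amdahl decomposition of
#' [amdahl_decompose()]. Before any timing is reported the hull computed
#' with and without preprocessing must be identical (same canonical vertex
#' coordinate sequence); a mismatch raises an error, since correctness
#' precedes timing. Wall-clock values are machine-dependent and are
#' reported, never asserted.
#'
#' @param points A point set.
#' @param m Bin count or `"auto"`.
#' @param algorithm Hull algorithm: `"monotone"`, `"chan"` or `"jarvis"`.
#' @param repeats Timing repetitions (>= 1); the minimum is kept.
#' @return A one-row data frame of class `bench_record` with columns
#'   `algorithm, n, m, s, p_r, t_r, t_s, t_n, speedup, k,
#'   predicted_speedup`.
#' @export
measure_speedup <- function(points, m = "auto",
                            algorithm = c("monotone", "chan", "jarvis"),
                            repeats = 3L) {
  algorithm <- match.arg(algorithm)
  repeats <- as.integer(repeats)
  if (is.na(repeats) || repeats < 1L) stop("`repeats` must be >= 1")
  points <- as_points(points)
  hull_fun <- switch(algorithm, monotone = monotone_chain_hull,
                     chan = chan_hull, jarvis = jarvis_hull)
  clock <- function(expr) {
    best <- Inf; val <- NULL
    for (i in seq_len(repeats)) {
      t0 <- proc.time()[["elapsed"]]
      val <- expr()
      dt <- proc.time()[["elapsed"]] - t0
      if (dt < best) best <- dt
    }
    list(t = best, value = val)
  }
  full <- clock(function() hull_fun(points))
  red <- clock(function() reduce_points(points, m = m))
  sub <- points[red$value$indices, , drop = FALSE]
  part <- clock(function() hull_fun(sub))
  same <- identical(full$value$x, part$value$x) &&
          identical(full$value$y, part$value$y)
  if (!same)
    stop("hull of the reduced set differs from the hull of the full set")
  n <- nrow(points); s <- red$value$s
  rec <- data.frame(algorithm = algorithm, n = n,
                    m = red$value$m_used, s = s,
                    p_r = reduction_factor(n, s),
                    t_r = red$t, t_s = part$t, t_n = full$t,
                    speedup = full$t / (red$t + part$t),
                    stringsAsFactors = FALSE)
  am <- tryCatch(amdahl_decompose(rec),
                 hullprep_undefined_decomposition = function(e)
                   list(k = NA_real_, predicted_speedup = NA_real_))
  rec$k <- am$k
  rec$predicted_speedup <- am$predicted_speedup
  class(rec) <- c("bench_record", "data.frame")
  rec
}

#' Amdahl's-law decomposition of a preprocessing speedup
#'
#' Treats the reduction as accelerating the fraction `p_r = 1 - s/n` of
#' the hull workload by an enhanced-speedup factor `k`, estimated from the
#' measured times as `k = t_n (n - s) / (n (t_r + t_s) - s t_n)`, and
#' predicts the overall speedup `1 / ((1 - p_r) + p_r / k)`. Substituting
#' the estimator into the prediction returns exactly `t_n / (t_r + t_s)`,
#' so the prediction agrees with the measured speedup by construction; the
#' value of `k` itself is the informative quantity (how much faster the
#' "enhanced" fraction effectively ran).
#'
#' @param record A `bench_record` (or any list/data frame with fields
#'   `n`, `s`, `t_r`, `t_s`, `t_n`).
#' @return List with `k` and `predicted_speedup`.
#' @examples
#' amdahl_decompose(list(n = 1e6, s = 1e4, t_r = 0.1, t_s = 0.05, t_n = 1))
#' @export
amdahl_decompose <- function(record) {
  n <- record$n[[1L]]; s <- record$s[[1L]]
  t_r <- record$t_r[[1L]]; t_s <- record$t_s[[1L]]; t_n <- record$t_n[[1L]]
  denom <- n * (t_r + t_s) - s * t_n
  if (denom == 0)
    stop(errorCondition("Amdahl decomposition undefined: n (t_r + t_s) = s t_n",
                        class = "hullprep_undefined_decomposition"))
  k <- t_n * (n - s) / denom
  p_r <- 1 - s / n
  # Amdahl limit: with nothing reduced the prediction is 1 whatever k is
  pred <- if (p_r == 0) 1 else 1 / ((1 - p_r) + p_r / k)
  list(k = k, predicted_speedup = pred)
}

#' Run a grid of speedup benchmarks
#'
#' Calls [measure_speedup()] for every combination of bin count and
#' algorithm and binds the records into one data frame (the bench CSV
#' schema).
#'
#' @param points A point set.
#' @param m_list Vector of bin counts (integers or `"auto"`).
#' @param algorithms Character vector of hull algorithm names.
#' @param repeats Timing repetitions per leg.
#' @return A data frame with one `bench_record` row per combination.
#' @export
run_bench <- function(points, m_list = "auto",
                      algorithms = c("monotone", "chan"), repeats = 3L) {
  points <- as_points(points)
  rows <- list()
  for (m in m_list) for (alg in algorithms) {
    mm <- if (identical(m, "auto")) m else as.integer(m)
    rows[[length(rows) + 1L]] <-
      measure_speedup(points, m = mm, algorithm = alg, repeats = repeats)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
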