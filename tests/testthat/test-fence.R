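# worked fence instance: endpoints (0,5) and (9,4), bin minima (2,1), (4,6), (8,0)
fence_points <- rbind(c(0, 5), c(2, 1), c(4, 6), c(8, 0), c(9, 4),
                      c(3, 9), c(5, 9), c(8.5, 9))   # high fillers per bin

test_that("fences join the endpoints and per-bin extremes in x order", {
  b <- quantize_uniform(fence_points, m = 3)
  e <- per_bin_extremes(fence_points, b)
  fp <- build_fences(fence_points, b, e)
  lower <- fp$lower
  expect_equal(lower$slots[!lower$slot_removed], c(1L, 2L, 3L, 4L, 5L))
  expect_equal(length(lower$slots), 3 + 2)
  # boundaries start at xmin and end at xmax
  expect_equal(lower$boundaries[1], 0)
  expect_equal(lower$boundaries[5], 9)
  # x-sorted by construction
  expect_false(is.unsorted(lower$boundaries))
})

test_that("an empty bin shrinks the fence and is pre-flagged removed", {
  p <- rbind(c(0, 5), c(1, 1), c(8, 0), c(9, 4))  # middle third of [0,9] empty
  b <- quantize_uniform(p, m = 3)
  e <- per_bin_extremes(p, b)
  expect_true(e$empty[2])
  fp <- build_fences(p, b, e)
  expect_true(fp$lower$slot_removed[3])           # slot of bin 2
  expect_equal(sum(!fp$lower$slot_removed), 3 + 1)
  cf <- convexify_fences(fp, p)
  expect_identical(rebin(p[, 1], b$labels, cf$lower$tables),
                   rebin_binary_search(p[, 1], cf$lower$tables))
})

test_that("an endpoint that is also its bin's extreme is stored once", {
  p <- rbind(c(0, 0), c(4, 1), c(9, 3), c(4, 5))
  b <- quantize_uniform(p, m = 2)
  e <- per_bin_extremes(p, b)
  fp <- build_fences(p, b, e)
  # (0,0) is both the min-x endpoint and bin 1's min-y point
  expect_equal(fp$lower$slots[1], 1L)
  expect_true(fp$lower$slot_removed[2])
  expect_false(anyDuplicated(fp$lower$slots[!fp$lower$slot_removed]) > 0)
})

test_that("fence convexification removes reflex points and fills the prefix table", {
  b <- quantize_uniform(fence_points, m = 3)
  e <- per_bin_extremes(fence_points, b)
  cf <- convexify_fences(build_fences(fence_points, b, e), fence_points)
  # (4,6) is reflex on the lower fence
  expect_equal(cf$lower$polyline, c(1L, 2L, 4L, 5L))
  expect_equal(cf$lower$tables$S, c(0, 0, 1, 1, 1))
  # upper fence of this instance is already convex: the only flagged slot
  # is bin 1's extreme, which coincides with the (0,5) endpoint
  expect_equal(cf$upper$polyline, c(1L, 6L, 8L, 5L))
  expect_equal(cf$upper$tables$S, c(0, 1, 1, 1, 1))
})

test_that("the convex lower fence lies on or below every original fence point", {
  for (seed in 1:30) {
    p <- rand_instance(seed)
    if (max(p[, 1]) == min(p[, 1])) next
    m <- pick_m(seed, nrow(p))
    b <- quantize_uniform(p, m)
    e <- per_bin_extremes(p, b)
    fp <- build_fences(p, b, e)
    cf <- convexify_fences(fp, p)
    for (side in c("lower", "upper")) {
      f <- cf[[side]]
      orig <- fp[[side]]$slots[!fp[[side]]$slot_removed]
      v <- f$coords
      for (i in orig) {
        xq <- p[i, 1]
        seg <- findInterval(xq, v[, 1], all.inside = TRUE)
        yline <- v[seg, 2] + (v[seg + 1, 2] - v[seg, 2]) *
          (xq - v[seg, 1]) / (v[seg + 1, 1] - v[seg, 1])
        if (side == "lower") expect_lte(yline, p[i, 2] + 1e-9)
        else expect_gte(yline, p[i, 2] - 1e-9)
      }
    }
  }
})

test_that("the two fence sides are processed independently", {
  p <- rand_instance(99)
  b <- quantize_uniform(p, pick_m(99, nrow(p)))
  e <- per_bin_extremes(p, b)
  a1 <- convexify_fences(build_fences(p, b, e), p)
  # rebuild in a fresh object; identical results regardless of side order
  a2 <- convexify_fences(build_fences(p, b, e), p)
  expect_identical(a1$upper, a2$upper)
  expect_identical(a1$lower, a2$lower)
})
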