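test_that("x-extreme search matches the worked range and breaks ties per side", {
  p <- rbind(c(2.3, 0), c(9.1, 5), c(5, 1))
  e <- find_x_extremes(p)
  expect_equal(e$xmin, 2.3)
  expect_equal(e$xmax, 9.1)
  expect_equal(e$ixmin, 1L)
  expect_equal(e$ixmax, 2L)

  single <- find_x_extremes(rbind(c(1, 1)))
  expect_identical(single$ixmin, single$ixmax)

  tie <- rbind(c(0, 3), c(0, -1), c(7, 2))
  expect_equal(find_x_extremes(tie, "lower")$ixmin, 2L) # smaller y
  expect_equal(find_x_extremes(tie, "upper")$ixmin, 1L) # larger y
})

test_that("uniform quantization reproduces the worked boundaries and clamps xmax", {
  p <- rbind(c(2.3, 0), c(9.1, 5), c(5, 1))
  b <- quantize_uniform(p, m = 4)
  expect_equal(b$width, 1.7)
  expect_equal(b$xmin + 0:4 * b$width, c(2.3, 4.0, 5.7, 7.4, 9.1))
  expect_equal(b$labels[3], 2L)      # 5.0 lies in [4.0, 5.7)
  expect_equal(b$labels[2], 4L)      # x = xmax goes to bin m, not m + 1
  expect_error(quantize_uniform(rbind(c(1, 0), c(1, 5)), 3),
               class = "hullprep_degenerate_x")
})

test_that("quantization is exhaustive and per-bin extremes bound their bins", {
  for (seed in 1:25) {
    p <- rand_instance(seed)
    if (max(p[, 1]) == min(p[, 1])) next
    m <- pick_m(seed, nrow(p))
    b <- quantize_uniform(p, m)
    expect_true(all(b$labels >= 1L & b$labels <= m))
    expect_length(b$labels, nrow(p))
    e <- per_bin_extremes(p, b)
    for (j in seq_len(m)) {
      members <- which(b$labels == j)
      expect_identical(e$empty[j], length(members) == 0L)
      if (length(members)) {
        expect_equal(unname(p[e$min_y_index[j], 2]), min(p[members, 2]))
        expect_equal(unname(p[e$max_y_index[j], 2]), max(p[members, 2]))
      }
    }
  }
})

test_that("per-bin extremes keep the first-seen point on y ties", {
  p <- rbind(c(4, 6), c(5, 1), c(5.5, 3), c(4.5, 1))  # two minima at y = 1
  b <- quantize_uniform(rbind(p, c(0, 0), c(10, 0)), m = 1)
  e <- per_bin_extremes(rbind(p, c(0, 0), c(10, 0)), b)
  expect_equal(e$max_y_index[1], 1L)
  b2 <- quantize_uniform(p, m = 1)
  e2 <- per_bin_extremes(p, b2)
  expect_equal(e2$min_y_index[1], 2L)   # row 2 precedes row 4
})

test_that("rebin tables carry the inclusive prefix sum of removals", {
  tb <- build_rebin_tables(1:7, c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(tb$S, c(0, 1, 1, 1, 2, 2, 2))
  expect_equal(build_rebin_tables(1:5, rep(FALSE, 5))$S, rep(0L, 5))
  tb2 <- build_rebin_tables(c(0, 2, 4, 8, 9), c(F, F, T, F, F))
  expect_equal(tb2$S, c(0, 0, 1, 1, 1))
  expect_equal(tb2$n_new_bins, 3L)
  expect_error(build_rebin_tables(1:3, c(TRUE, FALSE, FALSE)), "endpoint")
})

test_that("constant-time rebinning matches the worked six-bin configuration", {
  # six original bins -> eight projected boundaries; fence points at
  # positions 2 and 5 were removed during convexification
  C <- c(0, 1, 2, 3, 4, 5, 6, 7)
  tb <- build_rebin_tables(C, c(F, T, F, F, T, F, F, F))
  # old bin 4, x at or beyond the fifth boundary: 5 - S_5 = 3
  expect_identical(rebin(4.5, 4L, tb), 3L)
  # old bin 4, x between the fourth and fifth boundaries: 4 - S_4 = 3
  expect_identical(rebin(3.5, 4L, tb), 3L)

  tb2 <- build_rebin_tables(c(0, 2, 4, 8, 9), c(F, F, T, F, F))
  expect_identical(rebin(c(5, 3.5, 8.5), c(2L, 2L, 3L), tb2), c(2L, 2L, 3L))
})

test_that("rebin labels equal binary search over surviving boundaries", {
  for (seed in 1:40) {
    p <- rand_instance(seed)
    if (max(p[, 1]) == min(p[, 1])) next
    m <- pick_m(seed, nrow(p))
    b <- quantize_uniform(p, m)
    e <- per_bin_extremes(p, b)
    fp <- convexify_fences(build_fences(p, b, e), p)
    for (side in c("lower", "upper")) {
      tb <- fp[[side]]$tables
      fast <- rebin(p[, 1], b$labels, tb)
      slow <- rebin_binary_search(p[, 1], tb)
      expect_identical(fast, slow)
    }
  }
})
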