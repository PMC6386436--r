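test_that("all three algorithms agree on the canonical fixtures", {
  sq <- make_fixture("square_plus_center")
  for (fun in list(monotone_chain_hull, chan_hull, jarvis_hull)) {
    h <- fun(sq)
    expect_equal(h$h, 4L)
    expect_equal(h$indices, c(1L, 2L, 3L, 4L))     # CCW from (0,0)
    expect_equal(h$x, c(0, 4, 4, 0))
    expect_equal(h$y, c(0, 0, 4, 4))
  }
  # collinear input degenerates to the 2-vertex extreme segment
  col <- make_fixture("collinear_horizontal")
  for (fun in list(monotone_chain_hull, chan_hull, jarvis_hull)) {
    h <- fun(col)
    expect_equal(h$h, 2L)
    expect_equal(h$x, c(0, 2))
  }
  # identical points collapse to a single vertex
  one <- rbind(c(1, 2), c(1, 2), c(1, 2))
  for (fun in list(monotone_chain_hull, chan_hull, jarvis_hull)) {
    expect_equal(fun(one)$h, 1L)
    expect_equal(fun(rbind(c(0, 0)))$h, 1L)
  }
  expect_error(monotone_chain_hull(matrix(numeric(0), ncol = 2)), "empty")
})

test_that("hull vertices are strictly convex and contain every input point", {
  for (seed in 1:40) {
    p <- rand_instance(seed)
    h <- monotone_chain_hull(p)
    v <- cbind(h$x, h$y)
    if (h$h >= 3) {
      k <- h$h
      nxt <- c(2:k, 1L); nn <- c(3:k, 1L, 2L)
      o <- orient(v, v[nxt, , drop = FALSE], v[nn, , drop = FALSE])
      expect_true(all(o > 0))               # strictly convex, CCW
      # every point on or left of every directed edge
      for (i in seq_len(k)) {
        oo <- orient(v[i, , drop = FALSE], v[nxt[i], , drop = FALSE], p)
        expect_true(all(oo > -1e-9))
      }
    }
  }
})

test_that("monotone chain, Chan and Jarvis return identical vertex sequences", {
  for (seed in 1:120) {
    n <- if (seed %% 10 == 0) sample(1000:2000, 1) else sample(1:400, 1)
    p <- rand_instance(seed + 5000, n = max(n, 1L))
    hm <- monotone_chain_hull(p)
    hc <- chan_hull(p)
    hj <- jarvis_hull(p)
    info <- paste("seed", seed, attr(p, "family"), "n", nrow(p))
    expect_same_hull(hm, hc, info = info)
    expect_same_hull(hm, hj, info = info)
    expect_identical(hm$indices, hc$indices)
    expect_identical(hm$indices, hj$indices)
  }
})

test_that("Chan's algorithm exercises the binary tangent search on larger inputs", {
  for (seed in 1:4) {
    set.seed(seed)
    p <- cbind(x = runif(3000), y = runif(3000))
    expect_same_hull(monotone_chain_hull(p), chan_hull(p))
    # near-cocircular cloud: sub-hulls keep hundreds of vertices, so the
    # wrapping must rely on the binary tangent search
    th <- runif(2000, 0, 2 * pi); rr <- runif(2000, 0.99, 1)
    pc <- cbind(x = rr * cos(th), y = 0.7 * rr * sin(th))
    expect_same_hull(monotone_chain_hull(pc), chan_hull(pc))
  }
})

test_that("binary tangent search agrees with the linear scan on convex polygons", {
  rt <- hullprep:::.rtangent
  for (seed in 1:60) {
    set.seed(seed)
    # random strictly convex CCW polygon: sorted angles on an ellipse,
    # rotated so the sequence starts at the lexicographic minimum
    k <- sample(35:400, 1)
    th <- sort(runif(k, 0, 2 * pi))
    ex <- 0.5 + 1.3 * cos(th); ey <- 0.5 + 0.8 * sin(th)
    s <- order(ex, ey)[1]
    vx0 <- c(ex[s:k], ex[seq_len(s - 1)]); vy0 <- c(ey[s:k], ey[seq_len(s - 1)])
    h <- list(h = k, x = vx0, y = vy0)
    vx <- h$x; vy <- h$y
    for (q in 1:8) {
      # external query points, including far away and just outside
      ang <- runif(1, 0, 2 * pi); r <- runif(1, 1.35, 50)
      px <- 0.5 + r * cos(ang); py <- 0.5 + r * sin(ang)
      lin <- {
        best <- 1L
        for (j in 2:length(vx)) {
          cr <- (vx[best] - px) * (vy[j] - py) - (vy[best] - py) * (vx[j] - px)
          if (cr < 0) best <- j
        }
        best
      }
      expect_identical(rt(vx, vy, px, py), lin,
                       info = paste("seed", seed, "q", q))
    }
  }
})
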