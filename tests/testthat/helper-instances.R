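# randomized point-set families used by the property tests; every family
# stresses a different degeneracy of the reduction / hull code

instance_families <- c("uniform", "gaussian", "superellipse", "clustered",
                       "collinear_heavy", "duplicate_heavy", "integer_grid")

rand_instance <- function(seed, n = NULL, family = NULL, nmax = 400L) {
  set.seed(seed)
  if (is.null(family)) family <- sample(instance_families, 1L)
  if (is.null(n)) n <- sample(4:nmax, 1L)
  p <- switch(family,
    uniform = cbind(x = runif(n), y = runif(n)),
    gaussian = cbind(x = rnorm(n), y = rnorm(n)),
    superellipse = sample_superellipse(n, a = runif(1, 0.5, 2), b = 1,
                                       t = runif(1, 1, 8)),
    clustered = {
      kc <- sample(2:5, 1L)
      cx <- runif(kc, -5, 5); cy <- runif(kc, -5, 5)
      g <- sample.int(kc, n, replace = TRUE)
      cbind(x = cx[g] + rnorm(n, sd = 0.3), y = cy[g] + rnorm(n, sd = 0.3))
    },
    collinear_heavy = {
      xs <- runif(n)
      on_line <- runif(n) < 0.7
      cbind(x = xs, y = ifelse(on_line, 2 * xs + 1, runif(n, 0, 4)))
    },
    duplicate_heavy = {
      base <- cbind(x = round(runif(max(2L, n %/% 3)), 2),
                    y = round(runif(max(2L, n %/% 3)), 2))
      base[sample.int(nrow(base), n, replace = TRUE), , drop = FALSE]
    },
    integer_grid = cbind(x = as.numeric(sample.int(12L, n, replace = TRUE)),
                         y = as.numeric(sample.int(12L, n, replace = TRUE)))
  )
  colnames(p) <- c("x", "y")
  attr(p, "family") <- family
  p
}

# canonical hull equality: identical vertex coordinate sequences
expect_same_hull <- function(h1, h2, info = NULL) {
  expect_identical(h1$x, h2$x, info = info)
  expect_identical(h1$y, h2$y, info = info)
}

# a bin count to exercise per instance
pick_m <- function(seed, n) {
  switch((seed %% 4L) + 1L, 2L, 3L, 10L, max(2L, as.integer(ceiling(log2(n)))))
}
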