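Package: hullprep
Title: Linear-Time Point-Set Reduction for Fast 2D Convex Hulls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reduces a set of n planar points to a much smaller subset with
    an identical convex hull, in O(n) time, so that any convex hull
    algorithm runs faster on the reduced set. Points are binned along x,
    per-bin y-extremes are joined into lower and upper fences, the fences
    are convexified, and every point strictly outside a fence is kept via a
    constant-time prefix-sum rebinning and a single cross-product test.
    Also provides self-contained hull algorithms (monotone chain, Chan's
    output-sensitive algorithm, gift wrapping), a uniform-superellipse
    point generator, and a benchmark harness with an Amdahl's-law speedup
    decomposition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
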