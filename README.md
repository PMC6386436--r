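# hullprep

Linear-time point-set reduction for fast 2D convex hulls.

Convex hulls sit at the core of minimum convex polygon (MCP) home-range
estimation in ecology, shape analysis of segmented biological images, and
general computational geometry pipelines. Inputs often have millions of
points while the hull has only tens to hundreds of vertices. `hullprep`
reduces a set of n points to a small subset of s points **with an identical
strict convex hull**, in O(n) time and without sorting, so any hull
algorithm then runs on s points instead of n.

The method: bin points into m equal-width x-intervals; join each bin's
y-extreme points into a lower and an upper *fence* anchored at the
x-extreme points; make each fence convex with one stack scan; then keep
exactly the points strictly outside a fence. The segment each point must
be tested against is found in O(1) by reusing its original bin label `q`
together with a prefix sum `S` of removed fence positions over the
projected boundaries `C`:

    new label = q + 1 - S[q+1]   if x >= C[q+1]
              = q - S[q]         otherwise

followed by a single cross-product sign test. This replaces the O(n lg m)
binary search that non-uniform binning normally requires and is what keeps
the whole preprocessing linear. With p_r = 1 - s/n the observed hull
speedup is t_n / (t_r + t_s), which the package also decomposes in
Amdahl's-law terms with the enhanced-speedup estimate
k = t_n (n - s) / (n (t_r + t_s) - s t_n).

The package also bundles three self-contained hull algorithms sharing one
canonical output (strict vertices, counterclockwise from the lexicographic
minimum): Andrew's monotone chain, Chan's O(n lg h) output-sensitive
algorithm, and an independent Jarvis march used as a test oracle; a
uniform-superellipse point generator for synthetic experiments; a
benchmark harness; and a command-line interface (`inst/cli/hullprep`) with
`reduce`, `hull`, `simulate` and `bench` subcommands.

## Worked example

```r
library(hullprep)

set.seed(1)
p <- sample_superellipse(1e6, a = 1.3, b = 1, t = 3, seed = 42)
r <- reduce_points(p, m = 10)
r
#> Point-set reduction: n = 1000000 -> s = 52902 (94.71% removed, m = 10)

h_full <- monotone_chain_hull(p)
h_red  <- monotone_chain_hull(p[r$indices, ])
identical(h_full$x, h_red$x) && identical(h_full$y, h_red$y)
#> [1] TRUE
h_full$h
#> [1] 327
```

A million points shrink to ~53k (94.7% removed) in about a second, and the
hull of the kept subset is vertex-for-vertex identical to the hull of the
full input — here a 327-vertex polygon. `choose_m(n)` picks the bin count
(10, or lg n via `mode = "lg"`); `measure_speedup()` times hull
computation with and without the preprocessing and refuses to report
timings unless both hulls agree.

From a shell:

```sh
Rscript inst/cli/hullprep simulate --n 100000 --t 3 --a 1.5 --seed 4 --output pts.csv
Rscript inst/cli/hullprep reduce --input pts.csv --m 10 --output kept.txt --stats stats.json
Rscript inst/cli/hullprep hull --input pts.csv --algorithm chan --output hull.csv --geojson hull.geojson
```

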