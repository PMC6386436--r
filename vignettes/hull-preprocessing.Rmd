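---
title: "Linear-time point reduction for 2D convex hulls: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear-time point reduction for 2D convex hulls: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hullprep)
```

## The problem

The convex hull of a planar point set is the workhorse behind the minimum
convex polygon (MCP) home-range estimator in ecology, shape envelopes in
biological image analysis, and countless other geometric computations. Real
workloads routinely have n in the millions while the hull itself has only
tens to hundreds of vertices, so almost all the input is irrelevant to the
answer. `hullprep` implements a preprocessing step that discards most of
those irrelevant points in O(n) time, with a hard guarantee: **the strict
convex hull vertex set of the kept subset equals that of the full input.**
Any hull algorithm can then run on the kept subset instead.

## The method

`reduce_points()` runs six passes, none of which sorts the points:

1. **Extremes.** Find the points with smallest and greatest x-coordinate
   (`find_x_extremes()`). When several points tie on an extreme x value the
   fence sides use different representatives: the lower fence takes the
   tied point with smallest y, the upper fence the largest y. An arbitrary
   choice would be cheaper but can strand another tied extreme strictly
   inside one fence, which would break the guarantee.
2. **Binning.** Split `[xmin, xmax]` into m equal-width intervals and label
   each point with its bin in O(1) (`quantize_uniform()`). Bins are
   half-open with the last bin right-closed, the standard histogram
   convention, so every x (including `x = xmax`) has exactly one label.
3. **Per-bin extremes.** Find each bin's minimum-y and maximum-y point in
   one sweep (`per_bin_extremes()`); y-ties keep the first-seen row.
4. **Fences.** Join the minimum-y points, anchored at the x-extreme
   points, into the x-sorted *lower fence* polyline; maximum-y points give
   the upper fence (`build_fences()`). With every bin occupied a fence has
   m + 2 points. Empty bins simply shrink the fence: their slot keeps a
   placeholder boundary and is pre-flagged as removed so the bookkeeping
   below stays uniform.
5. **Convexification.** Drop reflex points from each fence with one
   stack-based scan (`convexify_polyline()`); because the polyline is
   x-monotone this replaces a general convex-chain routine. Collinear
   interior fence points are also dropped: a point interior to a segment
   between two other input points can never be a strict hull vertex, and
   strictness makes hull equality a plain vertex-sequence comparison.
   All surviving fence points enter the output.
6. **Keep test.** A point can now only matter if it lies strictly below
   the convex lower fence or strictly above the convex upper fence. The
   segment a point must be tested against is found in O(1) by *rebinning*:
   project the original fence points onto the x-axis (vector `C`), mark
   the removed positions, take the inclusive prefix sum `S`, and map an old
   label q to `q + 1 - S[q+1]` if `x >= C[q+1]`, else to `q - S[q]`
   (`rebin()`). The label picks one fence segment and a single
   cross-product sign (`keep_points()`) decides keep or discard.

The rebinning is the step that keeps the whole pipeline linear: labeling n
points against m non-uniform intervals normally costs O(n lg m) by binary
search. `rebin_binary_search()` implements that conventional route and is
used throughout the tests as an oracle; the constant-time rule must agree
with it on every point.

Every pass is vectorized R (the per-bin extremes use a stable radix
`order()`, C-level code touching each point a constant number of times);
a million points reduce in about a second on commodity hardware.

## Parameters

* **`m` — number of bins** (default `"auto"`). More bins hug the boundary
  more tightly (higher reduction) but grow the fixed per-bin overhead; the
  speedup-maximising region is `m` between 10 and lg n. `choose_m()`
  returns 10 for n >= 1024 (the default bin count of several numerical
  environments) and `max(2, floor(lg n))` below, with a `"lg"` mode giving
  `ceiling(lg n)`. `m` is clamped to n; `m` larger than the number of
  distinct x values is legal and simply yields empty bins.
* **Superellipse generator** (`sample_superellipse()`): semi-axes `a`, `b`
  (same units as the coordinates), shape exponent `t >= 1`. The region
  `|x/a|^t + |y/b|^t <= 1` is convex for `t >= 1`, sweeping from a rhombus
  (t = 1) to a rectangle with rounded corners (large t). Sampling is by
  rejection from the bounding box — exact uniformity with worst-case
  acceptance 1/2 at t = 1 — rather than an approximate inverse transform.
  `sample_random_superellipse()` additionally draws `t ~ U[1.5, 8]` and
  aspect `a/b ~ U[0.5, 2]` (b = 1; the reduction is invariant to per-axis
  affine scaling, so only the shape matters).

## Numerical and degenerate-input choices

* **Predicates.** Orientation tests use plain double-precision cross
  products with exact sign and no epsilon. Exact/robust arithmetic is out
  of scope; inputs whose correctness hinges on sub-ulp sign decisions are
  not supported, which is the usual contract for floating-point hull code.
* **Degenerate inputs.** n <= 3 passes through unchanged; a vertical-line
  input (all x equal) returns the min-y and max-y points; the hull of
  collinear input is its 2-vertex extreme segment and of identical points
  a single vertex, keeping the strict-vertex convention total.
* **Coincident fence slots.** An endpoint that is also its bin's extreme
  is stored once; the duplicate slot is flagged removed. Two interior
  bins can never contribute the same projected abscissa (labels are
  monotone in x), so surviving boundaries are strictly increasing.
* **Empty-bin placeholders** use the bin's left uniform edge, nudged up to
  the previous boundary if floating-point label rounding would make the
  sequence non-monotone; removed slots never label any point, so the value
  only has to keep `C` sorted.
* **Keep-test strictness.** Points exactly on a fence segment are *not*
  kept by the scan (they are convex combinations of two fence vertices);
  fence vertices themselves are added by the orchestrator. A literal
  non-strict test would also be correct but would re-keep every on-fence
  point and double-count fence vertices scanned against their own
  segments.
* **Indices are 1-based** input row numbers everywhere, including output
  files, following R convention.

## The hull algorithms

`monotone_chain_hull()` (Andrew's monotone chain, O(n lg n)) is the
production algorithm. `chan_hull()` implements Chan's O(n lg h)
output-sensitive construction — group partition, monotone-chain sub-hulls,
gift-wrapping over per-group tangents with the squaring schedule
`g = min(n, 2^(2^t))`. Tangents to sub-hulls with more than 32 vertices are
found by binary search on the convex chain; the result is then verified
(and on collinear ties corrected toward the farther point) by a local
climb, so a tangent query is never silently wrong. `jarvis_hull()` is a
deliberately independent gift-wrapping implementation kept as the test
oracle. All three share one canonical output convention — strict vertices,
counterclockwise, starting at the lexicographic minimum — so equality is
`identical()` on the vertex sequences.

## What the tests show, and what they do not

The property suite checks, over a thousand randomized instances spanning
uniform, Gaussian, superellipse, clustered, collinear-heavy,
duplicate-heavy and integer-grid families (n from 4 to 5000, m in
{2, 3, 10, lg n}): hull preservation against the gift-wrapping oracle,
agreement of constant-time rebinning with binary search on every point,
cross-algorithm hull equality, containment of all discarded points in the
hull of the kept subset, and determinism. The synthetic experiments use
n = 10^6 points per run. These sizes were chosen to exercise every code
path (including the binary tangent search and the empty-bin machinery)
while keeping the default suite quick; the method itself has no size
limit.

Synthetic superellipse data is a well-behaved scenario: a convex support
and a uniform distribution mean every bin is occupied and both fences hug
the boundary. Real point clouds — GPS relocation fixes, segmented image
foregrounds, scanned surfaces — are clumpy, anisotropic and hole-ridden;
the guarantee (identical hull) is unconditional, but the *amount* of
reduction observed on synthetic shapes should be read as favourable
territory, not a promise.

One shape effect is worth knowing: at fixed m = 10 the reduction
percentage falls as the superellipse approaches a rectangle (large t),
because the two end bins then span the rounded corners and the fence
chords cut off large corner regions; rhombus-like shapes reduce best.
Raising m to lg n restores the reduction on rectangle-like shapes — one
more reason the recommended m region is 10 to lg n rather than a single
constant.

## Benchmarking and the Amdahl decomposition

`measure_speedup()` times the hull on the full set (t_n), the reduction
(t_r) and the hull on the kept subset (t_s), best-of-repeats on the
elapsed-time clock, and only reports timings after verifying both routes
give the identical hull. The speedup is t_n / (t_r + t_s). Viewing the
reduction through Amdahl's law — a fraction p_r = 1 - s/n of the workload
accelerated by a factor k — `amdahl_decompose()` estimates
k = t_n (n - s) / (n (t_r + t_s) - s t_n) and predicts
1 / ((1 - p_r) + p_r / k). Substituting the estimator makes the prediction
collapse algebraically to the measured speedup, which the tests assert to
1e-9 relative tolerance; the informative output is k itself. Wall-clock
numbers are hardware-dependent and are reported, never asserted.

## Known limitations

* 2D only; no exact-arithmetic predicates; no parallel execution of the
  two fence sides (they are independent, so the extension is mechanical).
* The reduction guarantee concerns *strict* hull vertices; callers who
  need collinear boundary points preserved must keep the full input.
* `chan_hull()` in pure R is slower in wall-clock terms than the monotone
  chain despite the better asymptotic bound; it is included for
  completeness and cross-validation rather than speed.
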