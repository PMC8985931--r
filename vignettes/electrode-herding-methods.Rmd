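---
title: "Geometry, synthetic cultures and herding quantification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry, synthetic cultures and herding quantification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fractalherd)
```

`fractalherd` models and quantifies the "herding" of dissociated retinal
cells on patterned micro-electrodes: neurons are steered onto textured
carbon-nanotube (VACNT) branches while glial cells settle in the smooth
SiO~2~ gaps between them. This vignette records the models, the numerical
choices, and the design decisions behind the package, and what the
synthetic-data tests do and do not demonstrate.

## Electrode geometry

An H-tree electrode is described by its fractal dimension $D$
($1 < D \le 2$), the number of repeating H levels $m$, the branch width
$w$ and the overall pattern width $W$. Branch orders $n = 0..N$ with
$N = 2m - 1$ alternate between horizontal (even $n$) and vertical (odd
$n$), and segment lengths shrink as

$$L_n = L_0 \, 2^{-n/D}.$$

The base length $L_0$ is solved exactly from the width constraint
$W = 2\sum_{\text{even } n \le N-1} L_n + w$: the two outermost vertical
branch columns contribute one half-width each. Every segment is an
axis-aligned rectangle of width $w$ running exactly $L_n$ from its parent
junction centreline; free branch ends carry **no** half-width cap. That
reading is not arbitrary — it is the only one that reproduces the
fabricated minimum gap width $W_{Si\text{-}min} = L_{N-2} - L_N - w/2$
(25.0 µm for the $D = 2$, $m = 6$ design at $W = 6262$ µm) together with
the published branch areas.

Derived descriptors (all closed-form):

* total centreline branch length $L_b = \sum_n 2^{n+1} L_n$;
* branch area $A_{CNT} = w L_b - \sum_{n\ge 1} 2^n w^2/2$, the junction
  double-count correction being half a $w \times w$ square per child pair;
* total edge length $E = 2A_{CNT}/w + w\,2^{N+1} - \sum_{n \ge 1} w\,2^n$,
  which reduces to perimeter $= 2 \times$ area/width $+ 2w$ and is exact
  for this axis-aligned geometry (verified against a face-adjacency raster
  count within 1% on every design);
* normalized edge length $E_n = E/W$ and mean tortuosity $T$, the
  (identical) centre-to-tip path length divided by the straight-line
  displacement, averaged over all $2^{N+1}$ finest-branch endpoints;
* the branch-bounded gap rectangles $A_{min}$ (framed by the two finest
  orders), $A_{max}$, their ratio $A_r$, and the connected gap area $A_c$.

Euclidean row designs pack the largest number of rows
$n_{rows} w_{CNT} + (n_{rows}-1) w_{Si} \le W$; this packing rule is
inferred from exact agreement with all published row areas. They have
$T = 1$ and $A_r = 1$ by construction.

**Bounding-rectangle convention.** The tabulated bounding height is read
as $2\sum_{\text{odd } n} L_n + w$ — one branch width beyond the finest
tips, mirroring the width convention. The raster grid covers this nominal
rectangle, so a $w/2$ gap strip runs along its top and bottom edges.

**A note on $A_c$ and $A_r$.** The analytic $A_c$ agrees with the
raster's largest 4-connected gap component (margin-free) for low-$D$
designs but falls below it for space-filling designs, where the raster
component stays connected through the finest corridors; the operational
`connected_gap_area()` is therefore the raster measure, and the closed
form is reported as the analytic family value. Both decrease with $m$ at
$D = 2$. The ratio $A_r = A_{max}/A_{min}$ *falls* steeply with $D$ but
*rises* with $m$ (the smallest gap closes faster than the largest); the
package follows the defining equations, which the independent
maximal-empty-rectangle search confirms within 1% on every design.

## Raster representation and proximity

`rasterize()` samples pixel centres against the union of branch
rectangles (half-open on the right/top, so rows of integer width are
pixel-exact). The default metric resolution is 1 µm/px — branches at least
20 µm wide are well resolved — and coarser rasters (2–2.5 µm/px) are used
for trend maps where only monotone comparisons matter. Proximity is the
exact Euclidean distance transform (via `EBImage::distmap`, whose image
border is *not* treated as background) of the gap to the nearest branch
pixel, reciprocals averaged over gap pixels; units are 1/µm at the mask
resolution, which is recorded because the source material leaves the
units of proximity unstated. Gap connectivity is 4-connected: diagonally
touching gap pixels are not a path a spreading cell can use. The
maximal-empty-rectangle search uses the histogram-of-heights stack
algorithm with first-occurrence tie-breaking in row-major order.

## The synthetic culture generator

The raw fluorescence images behind the study are not public, so the
package generates synthetic cultures with exact ground truth. The
generator is a coarse rule-based model — the pipeline, not the biology,
is the test target — but each qualitative phenomenon reported for the
real cultures is represented and independently toggleable:

* **Seeding**: homogeneous spatial Poisson at 9.3×10³ cells/mm² (the
  measured plating density); a configurable neuron fraction of 0.7 (the
  real neuron:glia ratio is not reported; only the spatial contrast is
  under test).
* **Migration**: neurons random-walk at 10–20 µm/h in 1 h steps and
  attach permanently with probability 0.9 when they step onto a branch.
  Each neuron's active migration lasts an exponentially distributed time
  (mean 24 h, capped at 96 h): aggregation forces take over after the
  first day. Without this settling term every gap neuron of a 25–100 µm
  gap reaches a branch within hours and the gap cluster networks that the
  study describes cannot form.
* **Clustering**: surviving gap neurons aggregate on a 200 µm scale into
  soma clusters (centres snapped to the nearest member soma so they stay
  in the gap); attached neurons aggregate into small clusters strung
  along their branch. Cluster blob radii adapt to the local gap
  clearance.
* **Processes**: attached neurons grow polylines that follow branch edges
  on discrete inset lines 2–8 µm inside the edge (more lines on wider
  branches), turning at junctions onto the child on the same side so the
  corner stays on the branch. Clusters send straight, lightly jittered
  bundles to visible neighbouring clusters — one polyline per bundle,
  because both the reference tracing algorithm and a skeleton count a
  bundle once — and boundary connections to the nearest branch edge;
  bundles that must cross a branch do so perpendicular to its edge
  (processes climb the sidewalls; they do not graze them). Unclustered
  gap neurons within 150 µm of a branch grow a single process to the
  nearest edge (the boundary-region individuals). Process count and
  length rise to a maximum-complexity peak at 7 DIV and are partly
  pruned/bundled away by 17 DIV.
* **Glia**: coverage grows as disks whose growth probability decays with
  distance to the nearest branch (scale 120 µm), producing covered
  boundary and cluster regions near branches and sparse "deserts" far
  from them; non-growing individuals keep a single-cell footprint
  (radius 8 µm). Glia are confined by the branches — gap disks clip at
  the branch boundary — and only a small fraction (2%) of the glia that
  land on a branch remain there.

All stochasticity flows from one seed; regeneration is bit-identical.
Ground truth splits every polyline exactly at the pixel boundaries of the
mask and rasterizes the glial disk union on the mask grid, then applies
the same normalization as the measurement pipeline.

**What the generator does not emulate**: point-spread functions, focus
drift and channel bleed-through; curved or branching neurites (processes
are straight between anchor points); biologically calibrated effect
sizes. Passing the recovery tests therefore shows that the measurement
pipeline is faithful to known geometry under realistic densities, noise
and soma clutter — not that the model reproduces real biological effect
sizes, which the study's unavailable raw data would be needed for.

## Rendering and measurement

Channels are rendered at a configurable pixel size (0.32 µm/px emulates
the study's camera; the suite uses the mask resolution). Curves are drawn
with a distance-kernel of half-width 1.5 px, max-composited so that
coincident curves do not stack intensity and the thin-line core is
continuous at every angle; somas render as filled blobs clipped to their
surface, glia as filled textured disks; Poisson shot noise on a
photon-count scale plus Gaussian read noise is added. Tiles of
2048×2048 px with 10% overlap reproduce the study's stitched acquisition;
stitching places tiles on the fixed stride grid and averages overlap
strips.

Measurement binarizes with a global Otsu threshold (a manual value can be
supplied — the "semi-automated" step), removes speckle below 6 px,
removes isolated soma blobs (components above 80 µm² whose convex
solidity exceeds 0.8 *and* whose footprint is compact; an elongation
guard keeps straight short processes, and components where processes
attach to or cross a soma are kept whole so the skeleton passes through
the blob), thins to a 1 px skeleton (Zhang–Suen), and measures length by
chord summation over traced skeleton paths. Chords span 4 px, are
anchored at sharp corners so right-angle turns are not cut, skip
redundant diagonal edges of staircase skeletons, and add a 1.2 px
end-correction per open line end — together this keeps straight-line
length errors near 1% at any angle. Each chord's length is assigned to
the surface label under its midpoint. Glial area is the thresholded,
opened (3 px disc) coverage summed per label.

The herding indices follow the study's definitions:
$N_{CNT}$, $N_{Si}$ are total process length per available surface area,
$G_{CNT}$, $G_{Si}$ are glial area fractions, and
$N = N_{CNT}/(N_{CNT}+N_{Si})$, $G = G_{Si}/(G_{CNT}+G_{Si})$,
$GN = G\cdot N$; values above 0.5 indicate successful herding. The glial
regime threshold $G_T = 0.95$ splits electrodes into low ($G \le G_T$,
boundary inclusive) and high regimes; the threshold is configurable
because the empirical boundary case is only implied by the regime
definition.

## Problem sizes used by the test-suite

The suite simulates cultures on central 1024 µm windows of each design at
1.5 µm/px with the default density (≈10⁴ cells per window), 10 seeds per
design for recovery and 20 seeds for the 7-DIV peak; recovery is judged
on per-design totals over the seeded scenes, mirroring the per-electrode
summation over fields of view that defines the normalized quantities.
Full-scale rasters (1 µm/px, up to 28 Mpx) are used where printed areas
and edge lengths are checked. One caveat of window-scale simulation: the
central windows of the $m = 4$ designs contain only the order-0 crossbar,
so different $D$ values produce nearly identical local scenes there;
design-resolving comparisons should use larger fields.

## Statistics

Group comparisons use the Kruskal–Wallis rank test (tie-corrected, χ²
reference) with Dunn's pairwise z post-hoc from the pooled ranks. Raw
two-sided p-values are the default report — the common convention after
a significant omnibus test — with Holm or Bonferroni adjustment
available, since the source analysis does not state its adjustment.
Median confidence intervals use a seeded percentile bootstrap (10⁴
resamples by default), chosen for distribution-freeness; its ~95%
coverage at n = 20 is verified by simulation in the suite. Significance
stars follow the usual convention (\*, \*\*, \*\*\*, \*\*\*\* at 0.05,
0.01, 0.001, 0.0001).

## Known limitations

* The generator's processes are straight between anchors; curvature-based
  morphology (and hence Sholl-type analyses) is out of scope.
* Skeleton-based length is overlap-insensitive by design: deliberately
  bundled or coincident processes count once. The generator keeps
  *distinct* default processes resolvable so recovery can be checked;
  real cultures violate this and would be undercounted exactly as the
  reference algorithm is.
* The analytic $A_c$/$A_r$ expressions describe the central gap family;
  corridor connectivity of space-filling designs makes the raster
  component larger (see above).
* No electrical, capacitance or network-topology modelling; those are
  downstream questions the geometry here is meant to feed.
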