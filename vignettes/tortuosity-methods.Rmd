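---
title: "Measuring arterial tortuosity with DFM curves along minimal-cost-path centerlines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring arterial tortuosity with DFM curves along minimal-cost-path centerlines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesseltort)
```

## The measurement problem

Arterial tortuosity — how much a vessel twists relative to a straight course
— is most often quantified with the distance factor metric,
$\mathrm{DFM} = L/d$, where $L$ is the centerline arc length between two
points and $d$ their Euclidean separation. A two-point DFM hides local
structure: tortuosity rises and falls along an artery, and many arteries
have only one well-defined anatomical endpoint in a given volume. This
package therefore computes the DFM at *every* point along a centerline from
a fixed start, producing a tortuosity curve
$\mathrm{DFM}_i = L_i / d_i$, and summarizes it either at the end of the
path or at its maximum (the peak), whichever suits the artery being
measured. The curve can be indexed by $d$ or by $L$; both exports are
supported.

At the path's first point $d = 0$, so $\mathrm{DFM}_0$ is defined as 1, and
the peak search excludes points with $d$ below two voxel diagonals
($2\sqrt{s_x^2+s_y^2+s_z^2}$): near the origin, $L/d$ is near-singular and a
one-voxel sideways step would otherwise dominate the whole curve. The peak
is taken over the discrete curve with no smoothing.

## Centerline extraction

Centerlines are lowest-cost paths through the segmented vessel volume,
computed by Dijkstra's algorithm on the 26-connected graph of object
voxels. Each voxel carries a nonnegative cost that is small in the vessel
core; the weight of the edge between voxels $u$ and $v$ is
$\tfrac{1}{2}(c_u + c_v)\,\lVert \Delta x \rVert$ with $\lVert \Delta x
\rVert$ the physical step length in mm. This node-to-edge mapping is
symmetric and spacing-aware; the priority queue breaks cost ties by
insertion order so results are bit-reproducible.

Four cost functions are provided:

- **DFE** (distance from edge): the exact Euclidean distance from each
  object voxel centre to the nearest background voxel centre, computed with
  a separable lower-envelope distance transform under anisotropic spacing,
  in mm. The DFE alone is degenerate — adjacent voxels deep inside a vessel
  often share the same value.
- **MDFE**: inverted DFE, $\max(\mathrm{DFE}) - \mathrm{DFE}$, refined with
  a tie-breaking term proportional to the neighbourhood (26-neighbour +
  self) mean DFE and scaled to stay strictly below the smallest gap between
  distinct base costs. Equal-DFE neighbours thus get distinct costs, the
  more central neighbourhood winning. This preserves the published purpose
  of the modification — deterministic tie-breaking from local spatial
  information — without reproducing any particular legacy implementation.
- **COM**: every object voxel carries a continuous position initialized at
  its centre; each iteration moves every position to the mean of the
  previous iteration's positions over its in-mask 26-neighbourhood
  (synchronous, Jacobi-style updates; the voxel's own position is included
  for stability). The object collapses inward; edge voxels travel far,
  central voxels barely move. After 30 iterations (sufficient for vessels
  of the calibers considered here) the cumulative travelled distance is
  divided by the minimum positive cumulative distance in the segmentation
  and cubed. The cube sharpens the centre-to-edge contrast; the normalizer
  makes the field scale-free. A single-voxel object never moves, leaving
  the minimum undefined; the field then degrades to uniform zero cost with
  a warning.
- **DFE-COM** (default): the COM collapse with each neighbour weighted by
  its DFE, giving interior voxels more pull. This combines the global
  geometry sensitivity of the collapse with the centrality information of
  the distance map, and is the cost used for all tortuosity measurements.

Distances in the collapse and the distance map are physical (mm), so
anisotropic clinical voxels are handled without resampling.

### Goal selection and tree extraction

All paths are rooted at a goal voxel. The automatic strategy takes the
minimum-cost voxel, restricted to the largest 26-connected component of the
mask (isolated speckle that survives segmentation has near-zero collapse
cost and must not become the root), with ties broken by proximity to the
component centroid and then lexicographically. A user-supplied goal is
validated against the mask.

The centerline tree consists of the longest lowest-cost paths from the
distal ends back to the goal. Branches are emitted greedily: the unclaimed
voxel with the greatest physical path length to the goal is the next distal
tip; its parent chain is traced until it meets the goal or an
already-claimed voxel and emitted as a branch; a tube of radius equal to
the local DFE around the emitted path is claimed, so each artery produces
one branch rather than a bundle of near-parallel ones.

Candidate branches shorter than a pruning threshold are discarded. The
threshold is `prune_factor` (default 3) times the *local vessel caliber*,
estimated as the largest DFE along the candidate branch and up to eight
parent steps beyond its attachment point. Using the caliber of the parent
vessel, rather than the DFE at the tip voxel, matters: tips sit on cap or
noise surfaces where the DFE is about 1 voxel for vessels of any width, and
noisy segmentation boundaries sprout whiskers several voxels long that a
tip-scaled threshold keeps. Scaled by the parent caliber, a branch must be
at least about three radii long to count — surface whiskers vanish while
anatomical side branches (which are long relative to their parent's
caliber) survive. With this single default the extraction recovers exactly
one branch per distal tip on every validation phantom: six on the comb
(spine plus five teeth), three on the Y phantom at either noise level, two
on a helix, with no per-phantom adjustment.

## Numeric phantoms: the validation conditions

Phantoms are generated from continuous parametric centerlines; all voxels
whose centre lies within the tube radius of any centerline sample become
object voxels, and the nearest-voxel discretization of the samples
(deduplicated, order preserved) is stored as ground truth.

- **Helix series**: $h(t) = [r\cos t,\, r\sin t,\, p\,t/(2\pi)]$ with
  $r = 100$ voxels, tube radius 6, pitches $5(2\pi)$, $10(2\pi)$,
  $20(2\pi)$, $40(2\pi)$ and 8/4/2/1 coils respectively, so all four span
  the same z-extent. The pitch is stored in the same units the formula
  uses: the helix climbs $p$ voxels per full turn. Peak DFM at full coils
  is $\sqrt{r^2 + (p/2\pi)^2}\,/\,(p/2\pi)$ for the continuous curve —
  2.69 for the loosest helix — and the measured voxel-path values sit a few
  percent above it (see *Numerical behaviour*). Tube boundaries are binary;
  no anti-aliasing is applied.
- **Comb**: a 100-voxel spine with five 40-voxel perpendicular teeth at
  spacing 20 and tube radius 3. The teeth attach starting at one spine end,
  leaving a 20-voxel handle at the other — a geometry chosen so the
  structure has six distal tips, matching the branch count the validation
  table reports; published comb dimensions are not available, so absolute
  accuracy/stability numbers for the comb are treated as ordering anchors
  (DFE-COM at least as accurate as COM, RMSE below one voxel), not exact
  targets.
- **Y-branch**: a 60-voxel trunk splitting into two 50-voxel arms at
  ±40° in a plane, tube radius 4, with additive i.i.d. Gaussian noise of
  SD 10 or 20 (intensity units, against foreground 200 / background 0,
  clipped at zero) for the noise series. This is a parameterized stand-in
  for the published branching phantom whose exact mesh is not available.
  Foreground/background defaults (200/0) are arbitrary and recorded in the
  phantom's provenance.

Noise is drawn from R's RNG, so a fixed seed makes phantoms reproducible.
What the phantoms do *not* emulate: MR acquisition physics (flow artifacts,
coil shading, partial-volume intensity profiles), vessel caliber variation
along a branch, and kissing vessels. Passing phantom tests shows the
geometric machinery is correct at known ground truth; it does not by itself
establish performance on clinical volumes.

## Segmentation (ZBS)

The Z-buffer segmentation assumes arteries are the brightest, sparse,
spatially coherent structures:

1. **Seed detection**: cast a ray along z through every (x, y) column and
   record the position of its brightest voxel. Columns whose maximum equals
   the global intensity floor are uninformative (their argmax is an
   arbitrary tie) and are dropped. The remaining 3-D points are clustered
   by single linkage at radius $\sqrt{3}$ (26-neighbour proximity);
   clusters with at least 5 members become seeds. Vessels produce large
   coherent clusters; noise maxima scatter in z and mostly fail the size
   filter.
2. **Region growing**: the growth threshold is the 20th percentile (linear
   interpolation between order statistics) of the seed intensities; the
   mask is the union of 26-connected regions reachable from seeds through
   voxels at or above the threshold.
3. **Bubble filling**: background components (6-connectivity) not touching
   the volume boundary — cavities from slow or recirculating blood — become
   object.
4. **Edge-hole filling**: three synchronous sweeps; a background voxel is
   filled when rays along at least 24 of the 26 discrete neighbour
   directions meet an object voxel within 8 steps (the first offset counts
   as step 1).
5. Bubble filling is repeated.

The original method does not state the connectivity of growing or
clustering; 26-connectivity is used throughout for consistency with the
26-direction hole filling, and all choices are recorded in the mask's
provenance. One behaviour is worth understanding when applying the pipeline
to synthetic flat-intensity tubes: the seed intensities are column *maxima*,
so on a flat foreground with additive Gaussian noise their 20th percentile
sits about half a noise SD above the foreground mean, and the thresholded
recall of the tube interior is limited by construction; in volumes with a
shallow z-extent, chance clusters of background maxima enter the seed set,
pull the percentile down, and the tube is recovered almost completely (Dice
above 0.95 on the noisy Y phantom) at the price of a little background
speckle — which is why automatic goal selection confines itself to the
dominant component. Real MRA intensities vary smoothly across vessels,
which is the regime the percentile rule was designed for.

## Preprocessing

**Median subtraction** removes smooth background (for example the noise
floor of ultra-high-field acquisitions): the volume minus its per-slice
2-D $k \times k$ median-filtered copy, clipped at zero. The kernel is 2-D
per transverse slice — the standard kernel notation ("5×5", "11×11") is
2-D and slab acquisitions are filtered slice-wise — with 5 and 11 the two
standard widths. The median is exact (order statistics, not a quantized
histogram); windows truncate at image borders. Clipping at zero matches
the bright-vessel positivity the segmentation assumes.

**Sinc interpolation** upsamples volumes to a common resolution before
comparison, as the discrete equivalent of convolution with a sinc kernel:
the DFT is zero-padded symmetrically about the centred spectrum and
inverted. For even input lengths the Nyquist bin is split half-and-half
between $+N/2$ and $-N/2$ so the output stays real; no window is applied,
so edge ringing is left as-is (an explicit simplicity choice, recorded
here). The achieved spacing is $s \cdot n_{\mathrm{old}}/n_{\mathrm{new}}$
with $n_{\mathrm{new}} = \mathrm{round}(n_{\mathrm{old}}\, s /
s_{\mathrm{target}})$ and is recorded on the output, since non-integer
zooms cannot hit the requested spacing exactly. Downsampling is refused.
Band-limited inputs are reproduced at new grid points to near machine
precision, the mean is conserved, and decimating a 2× upsampled volume
returns the original samples.

## Numerical behaviour and choices

- **Coordinates**: user-facing voxel indices are 1-based (R array
  convention, as in the NIfTI readers this package uses); physical
  coordinates are $(\mathrm{index}-1)\cdot\mathrm{spacing} +
  \mathrm{origin}$ in mm. All lengths are reported in mm.
- **Digital path length bias**: a 26-connected voxel chain that follows a
  smooth curve is systematically *longer* than the curve — summing
  unit/diagonal steps overestimates arc length by up to roughly 10–12%
  depending on orientation. Measured helix peaks therefore sit a few
  percent above the continuous-curve values (e.g. 3.00 vs 2.69 for the
  one-coil helix at full scale), in the same direction as published
  voxel-path measurements. Ratios between phantoms cancel most of this
  bias. No path smoothing is applied, by design.
- **Determinism**: cost fields are pure functions of the mask; Dijkstra tie
  order is fixed; phantom noise derives from the caller's seed. Repeated
  runs are bit-identical, and identical-goal stability is exactly 1.
- **Percentiles** use R's default type-7 interpolation; recorded so that
  thresholds are reproducible.
- **Wilcoxon variants**: exact distribution when the combined sample size
  is at most 25 with no ties, otherwise the normal approximation with tie
  correction; the variant used is reported alongside the p-values, and the
  Bonferroni threshold is $\beta = \alpha/n$ for $n$ comparisons.
- **Stability metric**: the mean over run pairs of the symmetric fraction
  of centerline voxels of one run within 1 voxel of the other. The
  published validation tables report stability values without defining the
  formula, so this tolerance-overlap definition is a package choice and
  published stability values serve as qualitative anchors only.
- **RMSE direction**: computed-to-truth, since the truth polyline is
  densely sampled while the computed tree is deliberately pruned.

## Problem sizes

The full-scale helix series runs at grids of roughly $230 \times 230
\times 280$ voxels with up to $5.7 \times 10^5$ tube voxels; a half-scale
series (`scale = 0.5`) exercises the identical geometry at one eighth the
voxel count and is used for fast checks, since the DFM is scale-invariant.
The comb and Y phantoms are small ($\sim 10^4$ object voxels) and run in
seconds.

## Known limitations

- The DFE-COM collapse assumes a filled, roughly tubular mask; it is not a
  vesselness filter and will not rescue a failed segmentation.
- Kissing or self-touching vessels (the carotid siphon case) are handled
  only as well as the cost contrast allows; no explicit loop-closure logic
  exists.
- The claimed-tube radius during tree extraction is measured in voxels of
  the smallest spacing axis; under strong anisotropy claims are
  conservative.
- ZBS seed detection assumes the vessel axis is not parallel to z
  everywhere at background intensity contrast; volumes where vessels run
  mostly in-plane work best.
- The MDFE refinement preserves the documented intent (strict ordering,
  locality) of the published modification but is not a re-implementation of
  any specific legacy code.
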