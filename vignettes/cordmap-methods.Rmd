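---
title: "Quantification methods in cordmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods in cordmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cordmap)
```

`cordmap` quantifies corticospinal sprouting, microglial activation,
densitometric scores, behavioral performance and time-course differential
expression in a stroke-denervated spinal hemicord. This vignette is the
package's account of each procedure, its assumptions, the tunable
parameters, and the design decisions taken where the underlying protocol
left room.

## Coordinate conventions

One convention is used everywhere: images are numeric matrices whose rows
run dorsal to ventral (y downwards) and whose columns run medial to lateral
(x rightwards); physical coordinates are micrometers with the midline at
the template's medial edge; the center of pixel `(row, col)` sits at
`origin + (col - 0.5, row - 0.5) * pixel_size_um`; landmark CSV tables are
0-based row/col pixel positions. The packaged `hemicord_template()` is a
convex simplification of a cervical hemicord GM (1.2 x 1.6 mm) rasterized
at 5 um/px; convexity guarantees each grid line meets the GM in a single
segment, which keeps profile clipping unambiguous.

## Landmark registration (affine moving least squares)

Sections are fitted into the GM template from five corresponding landmarks.
For an evaluation point $p$, landmark pair $(s_i, d_i)$ receives weight
$w_i = 1/|p - s_i|^{2\alpha}$ and the best weighted affine map of sources
onto destinations is applied to $p$. The map interpolates the landmarks
exactly (the weight diverges there; we return $d_i$ analytically at
$s_i$), is smooth elsewhere, and reproduces any global affine transform of
the landmark set — the property the test suite asserts to $10^{-6}$ px.

The underlying protocol names only a landmark-MLS deformation, not the
variant or weight exponent; we default to the affine variant with
$\alpha = 1$ (the common default family of landmark-correspondence tools)
and expose `alpha` as a parameter. Warping uses inverse-mapping resampling:
each template pixel is pulled through the MLS field fitted with the
landmark roles swapped, which is the exact inverse for affine
configurations and the standard landmark-consistent approximation
otherwise. Gray images are resampled bilinearly (which cannot leave the
input intensity range); masks and label images use nearest-neighbor so
categories stay categorical. Collinear source landmarks are rejected as
degenerate.

## Fiber counting by extended minima

A 20 x 20 sampling grid is anchored to the GM geometry: 20 equispaced
vertical lines from the midline to the lateral GM extreme and 20 equispaced
horizontal lines from the ventral GM--WM border to the dorsal extreme. The
anchoring sides are protocol-defined; the opposite extent is the GM
bounding box, and panels whose centers fall outside the GM polygon are
reported in an explicit `extra-GM` bucket rather than silently dropped.

Gray values are read along each line at the pixel pitch with bilinear
interpolation, averaged over a 3-px line width (three parallel sample lines
1 px apart) — the usual line-width setting of profile densitometry. The
averaging matters quantitatively: a single-pixel profile carries the full
sensor noise, whose range over a ~250-sample line approaches $5\sigma$ and
would occasionally exceed the event depth on fiber-free lines; averaging
three lines brings the noise range well below any sensible `h` while
leaving crossing dips (which are wider than 1 px) at full depth.

A fiber crossing is one *extended minimum* of the profile: a connected
component lying more than `h` gray levels below the lowest barrier
separating it from any deeper region — the regional minima of the
morphological h-minima transform (reconstruction by erosion of $f + h$
over $f$). Two conventions are fixed by degenerate cases: a dip of depth
exactly `h` merges into its barrier plateau and is not an event (the
strict inequality of the morphological definition), and a "component"
spanning the whole profile is no event, so constant or noise-only profiles
with range below `h` count zero. The implementation floods the profile in
order of increasing value with union-find basin merging (the elder rule
decides survival at merges; ties break by activation order); the test
suite checks it against a naive fixpoint reconstruction plus exhaustive
plateau scan on thousands of random integer profiles, where ties are
plentiful.

`h` is not fixed by the protocol. The default is relative,
`h = 0.10 x (profile max - min)`, which makes counts invariant under
affine intensity rescaling (asserted in the tests); an absolute `h` in
gray levels can be supplied instead, and the polarity flag handles
bright-on-dark stains by inverting the profile. The manual fiber-redrawing
step of the original workflow is deliberately not reproduced; the
line-width averaging above is the only denoising applied.

Each crossing is booked to exactly one panel — the panel owning the grid
edge it sits on, with the panel chosen on the crossing's medial (for
horizontal positions) or ventral (for vertical positions) side, and
positions beyond the outer line clamped into the outermost panel. Panel
totals therefore equal line totals identically, and laminar sums (each
panel added to the Rexed group containing its center) reproduce the map
total exactly. Midline crossings are located once on the whole midline
profile, assigned to 100-um windows by position, and summed pairwise into
200-um bins; locating events once avoids splitting a dip across window
edges. The protocol's "approximately" 100/200 um is fixed to exactly
100/200 um for testability. A detected event position is the deepest
sample of its component, within a pixel or two of the true crossing, so an
event hugging a panel or bin boundary can be booked to the neighbor — the
counts are conserved, and the validation tracks this as a small flip rate
rather than hiding it.

Counts are normalized by the animal-specific factor
`mean(animal CST gray) / mean(cohort CST gray)` (applied as
`raw / factor`), group maps are elementwise means of normalized maps, and
difference maps are stroke minus sham.

## Synthetic sections and what they do (not) show

`gen_section()` renders dark fibers (DAB polarity) as smooth correlated
random walks of ~300 um, stroke width 2–3 px, on a bright background with
additive Gaussian noise, and records the analytic intersections of the
fiber center-lines with every grid line. The generator only accepts fiber
placements whose crossings are unambiguous profile events: crossings on a
line at least 8 px apart (the ground-truth contract requires 3 px; the
stricter spacing keeps the barrier between neighboring dips at background
level), crossing angles at least 30 degrees from the line, no tangential
grazes or near-line hovering, and clearance from the clipped span ends.
Widths below 2 px are not drawn because a 1-px stroke sampled with
bilinear interpolation can produce a dip of roughly half the nominal
contrast, breaking the one-minimum-per-crossing contract the fixtures
exist to provide.

These constraints define what passing tests mean: they validate the
counting machinery on resolvable crossings, exactly. They do not show
robustness to fasciculating fibers, tangential approaches, staining
gradients, vascular artifacts or registration error on real tissue — real
sections violate the resolvability conditions at some rate, and counts
there inherit that ambiguity.

The validation suite uses 20 sections of 40 fibers (contrast 40 gray
levels, noise SD 5, `h = 20`), 1000 random profiles for the oracle
comparison, and 100 seeded runs for the sampling properties; these sizes
were chosen as the package's standard validation load.

## Microglia activation

The activation index is `longest process / soma diameter` (smaller = more
activated). Soma diameter and process length are annotation inputs (or
synthetic ground truth) — the package deliberately does not segment
processes. The semi-random sampler lays a square grid of random spacing
drawn from 50–100 um at a random offset, selects the nearest unselected
marked cell to each in-GM intersection (ties to the lowest cell index),
and shrinks the spacing by 10% (restarting selection) until 20 distinct
cells are selected. When more than 20 result, the 20 kept are a greedy
farthest-point subset of the selecting intersections. This keep-rule is a
deliberate design choice: keeping the smallest intersection-to-cell
distances retains a spatially random subset (which fails an
all-quadrants-covered contract roughly one run in ten), and keeping every
k-th intersection in scan order aliases with the grid row length;
farthest-point thinning is deterministic and preserves the even coverage
that motivates the grid in the first place. On the packaged hemicord
template, quadrant balance is additionally limited by anatomy — the
dorsolateral GM quadrant is small — so the coverage property is asserted
on a rectangular GM.

The CST projection area is read literally as an intensity level set: the
tracing-density image is Gaussian-smoothed (default sigma 20 um), and the
connected component containing the maximum at 80% of the smoothed maximum
is returned. The alternative reading — the smallest region holding 80% of
total signal mass — is implemented behind `method = "mass"`. Region
priority for cell classification is CST > CPA > VH > DH > GM-other; cells
outside everything are excluded with a warning. Fold-change maps against
sham emit missing values (not infinities) for panels with no sham cells.

## Densitometric scores

In situ signal fractions use gene-specific thresholds derived by applying
a per-image rule (default Otsu, which the protocol leaves unspecified) to
five randomly selected images and averaging; the fraction is the
percentage of strictly suprathreshold pixels in the region mask, making it
invariant under any strictly monotone intensity transform applied jointly
to image and threshold, and percentages are computed per section and then
averaged per animal. Lesion completeness is `100 x lesioned / healthy` CST
signal. Neurite outgrowth counts each maximal run of neurite pixels along
a grid line as one intersection, divided by the cell-body count and
normalized to the vehicle control when given.

## Behavioral scores

Ladder steps score 1 (full placement), 0.5 (partial: digit or palm
misplacement) or 0 (miss); the success score is the point percentage of
the maximum and the foot-fault rate is misplacements over steps. The
protocol's "misplacements" is ambiguous against its own 0.5-point
category; the default counts any non-full step as a misplacement (so 100%
success and zero faults coincide), with `misplacement = "miss_only"` as
the alternative. A step with multiple scoring faults deducts at most the
partial category. Cylinder paw-drag percentages are drags over touches,
undefined (missing) for trials without touches.

## Expression time courses

Counts are CPM-normalized (library size = column sum unless supplied);
genes with mean CPM at or below 5 are excluded (boundary drops, per the
filtering rule; `aggregate = "max"` is available since the rule's
aggregation is unstated). Fold change per post-stroke group is group mean
CPM over sham mean CPM with a 0.5-CPM pseudocount on both means, so 0/0 is
1 and zeros stay defined. SDEG calling tests each gene per time point on
`log2(CPM + 0.5)` with a pluggable two-group test, adjusts per time point
with Benjamini–Hochberg, and flags `fdr < 0.05` and `|log2 FC| >= 1.5`
(two-sided, reading the threshold as a minimum absolute log2 fold change).
FDR is controlled per time point; pooling across time points is the
stricter unstated alternative and is not the default.

The default test is limma's empirical-Bayes moderated t rather than a
plain Welch t-test. At five samples per group, per-gene Welch variances
carry eight degrees of freedom; their instability gives the p-value
distribution of true effects a heavy tail that BH punishes, and measured
gene-level sensitivity on planted effects (|log2FC| = 2, dispersion 0.1)
is about 0.82 — below the 0.85 the pipeline is validated against.
Variance moderation is the standard remedy at this scale and lifts
sensitivity to ~0.99 at zero observed false-discovery proportion. Welch
(with an exact-permutation fallback for degenerate variances) and the
exact permutation test itself remain available as `test = "welch"` /
`"permutation"`, or any function returning per-row p-values.

SDEG group-mean profiles are z-scored per gene and clustered with
agglomerative hierarchical clustering (Euclidean distance, complete
linkage — configurable), cut to `k = 4`. Each cluster is labeled from its
centroid with `s` the sham value, `e` the 4/7-dpi mean minus `s`, `l` the
28/42-dpi mean minus `s`, and threshold `tau = 0.5` z-units:
persistent-down (`e, l < -tau`), late-up (`l > tau`, `e <= tau`),
late-down (`l < -tau`, `e >= -tau`), early-up (`e > tau`, `l <= tau`),
otherwise "other". Constant profiles cannot be z-scored and fewer than
`k` distinct profiles cannot be cut into `k` clusters; both raise errors
rather than degrade silently.

`gen_counts()` draws negative-binomial counts (`Var = mu + phi mu^2`)
with a constant baseline mean per gene and multiplicative group shifts for
the planted pattern sets (late patterns shift 28/42 dpi, early-up shifts
4/7 dpi, persistent-down shifts every post-stroke point). A constant
baseline keeps the moment invariant exactly checkable; real data's
baseline spread, outlier samples and library-size variation are not
emulated, so planted-recovery results bound the pipeline's behavior under
the stated noise model only.

## Known limitations

- Registration quality is bounded by landmark placement; no intensity-based
  refinement is attempted, and the MLS inverse is approximate for strongly
  non-affine deformations.
- Event positions are sample-quantized, so panel and midline-bin
  assignment can flip across a boundary by up to ~2 px; totals are always
  conserved.
- The microglia module carries annotated morphometry; it neither segments
  cells nor distinguishes microglia from macrophages.
- The expression module ships simple two-group tests behind a pluggable
  interface; it does not reimplement TMM normalization or NB dispersion
  machinery, and group-level inferential statistics (ANOVA/LMM) are out of
  scope throughout.
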