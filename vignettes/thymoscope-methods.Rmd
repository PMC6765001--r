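---
title: "Models and methods behind thymoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind thymoscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thymoscope)
```

## The scientific problem

The thymus atrophies faster than any other tissue, yet it can be regrown by
stimuli such as androgen ablation. Whether atrophy and regeneration reflect
death and proliferation of thymic epithelial cells (TEC), or merely changes
in the size and shape of the cells that are already there, is hard to answer
because (i) stromal cells cannot be cleanly isolated — any microdissected
tissue sample is dominated by lymphocytes — and (ii) cortical TEC (cTEC)
form an interdigitated network in which conventional staining cannot tell
where one cell ends and the next begins.

`thymoscope` implements the two complementary analysis stacks this question
requires, together with synthetic-data generators that carry full ground
truth so that every estimator can be validated by calibration recovery:

1. **Stromal deconvolution of expression time courses.** Paired
   tissue/lymphoid microarray signals over a regeneration time axis are
   smoothed, the lymphoid proportion of each tissue sample is estimated from
   lymphoid-specific marker genes, and stroma-only expression is obtained by
   inverting the two-component mixture. Downstream, time-resolved gene-set
   over-representation describes which biology moves during regrowth.
2. **3D morphometry of reporter-labelled TEC.** Multi-channel confocal-like
   volumes are segmented (global thresholding for sparse single cells,
   seeded watershed for the packed medulla), and each object is summarised
   by volume, surface area, feret diameter, compactness (surface area over
   volume) and the volume:ellipsoid ratio; nuclei are counted for density
   and EdU labeling-index estimation.

## The mixture model

For each gene and day the measured tissue signal is modelled as

$$T = p\,L + (1 - p)\,S,$$

where $L$ is the lymphoid signal, $S$ the stromal signal, and
$p \in (0,1)$ the lymphoid proportion of the tissue sample. Inverting gives
the deconvolution formula applied elementwise per day:

$$S = \frac{T - p\,L}{1 - p}.$$

For a lymphoid-specific gene $S = 0$, so $T/L = p$: the lymphoid proportion
is estimated as the mean tissue:lymphoid ratio over a curated marker list.
This also fixes the direction of the ratio — with $p$ strictly inside
$(0,1)$ only tissue/lymphoid can estimate it, so the package uses that
orientation throughout. The estimate is computed per day on spline-fitted
values, clamped to $(0, 1 - 10^{-6}]$; days at $p \ge 1$ are a domain error.
Negative deconvolved values (possible under noise) are floored at zero and
counted in the run report. Per-day quantile renormalization maps the ranked
stromal values onto the sorted tissue spline fits, so each day's stromal
distribution matches the measured distribution; ties are broken by stable
gene order.

The formula presumes linear additivity of signal, so the generator emits
linear-scale intensities and the deconvolution applies the formula to
whatever scale it receives. Whether the original arrays were deconvolved on
the linear or the log2 scale is not recoverable from the text we build on;
linear is the default and the only mode the generator's exactness guarantees
apply to.

## Robust spline smoothing

Each gene's regeneration time course (integer days; the separate "young"
condition never enters the spline) is fitted with a natural cubic spline
with interior knots at days 6 and 17 and boundary knots at the observed day
range — four coefficients in the default design. Fitting is iteratively
reweighted least squares with Hampel weights on MAD-scaled residuals,
cutpoints $(a, b, c) = (2, 4, 8)$ MAD units: residuals below $2$ keep weight
1, so on clean data the fit *is* ordinary least squares; gross outliers
(beyond $8$) get weight 0. Convergence is declared when no coefficient moves
by more than $10^{-8}$, with a 50-iteration cap. Fewer distinct days than
basis dimensions is a rank-deficiency error rather than a silent fit.

## The expression generator

`simulate_expression()` emulates the sampling design of the study it
supports: a "young" condition plus days 0–23 post-castration with extra
replicates at the inflection points (young ×5, day 0 ×4, day 6 ×3, day 7
×2, day 12 ×3, day 16 ×2, day 17 ×3, day 20 ×3, one array otherwise), two
paired fractions (tissue, lymphoid), multiplicative Gaussian noise
(`noise_sd`, default 5% of signal), and Affymetrix-style P/M/A detection
calls (Present above 1.2× the chip median, Absent below 0.8×, Marginal
between — the analysis consumes calls, so their generating rule is a
package choice).

Three choices matter for interpretation:

* **Flat lymphoid proportion (default 0.85 every day).** No printed value
  of $p$ exists to copy; 0.85 reflects a lymphocyte-dominated cortical
  tissue sample. A *flat* default keeps the tissue mixture inside the
  spline's function space, which is what makes the end-to-end exactness
  contract (noise-free recovery to $<10^{-6}$ relative error) well-posed. A
  day-varying trajectory is accepted via `p_trajectory`, at the cost of that
  exactness.
* **Dynamic trajectories live in the basis span.** Dip-and-recover and
  rise-and-fall prototypes are projected onto the spline basis and scaled to
  fold changes drawn log-uniformly in $[2, 6]$ — 2-fold being the study's
  criterion for "dynamically regulated". Noise-free data are therefore
  exactly representable by the smoother, separating "does the pipeline
  invert the mixture correctly" from "how much does smoothing distort
  out-of-span biology", which the noisy tests cover.
* **Markers are exactly stromal-silent.** Marker genes have $S \equiv 0$,
  so the marker-ratio estimator of $p$ is exactly calibrated, and any bias
  observed in tests is attributable to noise and smoothing alone.

What the generator does *not* emulate: probe-level effects, batch effects,
array saturation, compositional drift of the lymphoid pool over the time
course, and between-marker heterogeneity of lymphoid specificity. Passing
tests therefore certify the estimators under the stated mixture model, not
the full messiness of microarray data.

## Stromal gene lists and dynamics

The high-confidence stromal list thresholds each gene's tissue:lymphoid
ratio at the marker mean plus $k$ standard deviations ($k = 2.5$ minimises
false positives, $k = 2.0$ false negatives; the $k=2.5$ list is nested in
the $k=2.0$ list by construction). The default statistic compared against
the threshold is the gene's **mean ratio across the evaluated days**. The
alternative — admit a gene if its ratio exceeds the threshold on *any*
day — makes the expected marker false-positive rate scale with the number
of days (any mean + 2 s.d. threshold is exceeded by ~2% of marker-days by
construction, hence by some day of most markers over a 19-day course),
which contradicts the minimum-false-positive purpose of the stringent
list. Both modes and explicit day subsets are available via `days=`.
Dynamic genes are flagged when max/min over days reaches the fold threshold
(default 2), with the minimum floored at $10^{-8}$.

## Enrichment dynamics

Over-representation is the exact hypergeometric upper tail (the one-sided
Fisher exact test), BH-corrected across sets within each day.
`enrichment_timecourse()` reports each set's trajectory as
$\mathrm{sign} \times (-\log_{10} p_d + \log_{10} p_{d0})$ — the change in
statistical significance relative to day 0, positive for
over-representation. Set collections are flat GMT files; GO graph
conditioning (parent/child propagation) is deliberately not modelled, so
deeply nested ontologies will show correlated rows rather than conditioned
ones. Temporal trajectories are classified by the sign of the mean
normalized value in an early (days 1–11) versus late (days 12–23) window —
the windows bracket the spline knots; no formal rule exists in the source
material, and the windows are configurable.

## The volume generator

`simulate_volume()` renders four channels (reporter, H2b-style nuclei, EdU,
autofluorescence) at anisotropic spacing (default 1 × 0.5 × 0.5 µm in
z, y, x) on the 8-bit intensity scale:

* **Young cortical TEC** are slightly flattened ovoids, long axis drawn
  from N(75, 10²) µm and radially aligned, with semi-axis ratios
  (0.24, 0.5, 0.30) of the long axis. The intracellular labyrinth is
  modelled as 20–30 disjoint spherical lymphocyte voids carved strictly
  inside the ovoid (≥ 2 µm wall, ≥ 1 µm inter-void gap, clearance around
  the nucleus), each holding 2–10 recorded lymphocyte centres — about 150
  per cell in expectation. Exact loop topology is not modelled; the
  complement of the voids plays that role, and the void count and enclosed
  lymphocyte count are exactly recoverable ground truth.
* **Aged cortex** contracts the long axis (45 ± 8 µm), thins walls, and
  adds autofluorescent age-pigment bodies whose broad-spectrum emission is
  rendered as equal intensity in the reporter *and* the dedicated
  autofluorescence channel, so `subtract_autofluorescence()` can remove it.
* **Medulla** packs ~250 filled ovoid mTEC (semi-axes ~5–7 µm, random
  orientation) on a jittered 15-µm grid with support-function overlap
  checks, one nucleus per cell. Real mTEC shape diversity is broader than
  these ovoids; the generator's job is countable, measurable ground truth,
  not shape realism, which is why the shape-distribution KDE tests use
  constructed populations instead.
* **Nuclei** are 11 × 8 × 8 µm ellipsoids rendered with a centre-bright
  chromatin profile (peak 185, falling 45% toward the rim). The gradient
  matters: flat-intensity ellipsoids produce two local maxima at the ends
  of a tilted nucleus and double-count in maxima-based detection; a single
  central peak reflects how chromatin reporters actually image through a
  point-spread function.
* **EdU** marks each TEC nucleus with probability `edu_rate` (defaults:
  young cortex 1/1024, medulla 4.5%). The EdU and autofluorescence channels
  carry signal only where biology puts it — a zero rate or zero pigment
  density yields an identically zero channel. EdU-bright cortical
  lymphoblasts are *not* rendered; the labeling index samples the EdU
  channel only at detected TEC nuclei, so this omission is immaterial to
  the estimator under test.

Not modelled, by design: the optical point-spread function, photon shot
noise, spectral bleed-through beyond the pigment model, and depth-dependent
attenuation.

## Image processing and morphometry

Filter recipes follow the standard ImageJ-style chain: percentile contrast
stretch, rolling-ball (or sliding-paraboloid) background subtraction as a
per-slice grayscale opening, box-window 3D median/minimum filters, and
median-based outlier removal. One parameter deserves its own paragraph: the
**rolling-ball radius must exceed the largest foreground object**, because
a ball smaller than a cell classifies the cell interior as background and
deletes it. Printed radii travel with the pixel size of the images they
were tuned on; at this package's default 0.5 µm xy spacing an mTEC is
~25 px wide, so `segment_mtec_field()` defaults to radius 40 px while the
recipe presets keep the conventional 10/25 px values for data at coarser
pixel sizes. For radii above 15 px the background is estimated on a
2×-downsampled slice and bilinearly upsampled — the same large-radius
strategy the reference plugin uses.

Segmentation stand-ins are declared rather than cloned: automatic global
thresholding is Otsu's method; "purify" is retention of the largest
26-connected component; mTEC seeding is Gaussian-smoothed local maxima
(radii in physical µm) feeding an intensity-ordered region-growing
watershed with the conventional seed (50) and image (20) thresholds on the
8-bit scale. Parity with any particular GUI plugin is a non-goal; recovery
of generator ground truth is the contract.

Shape descriptors use foreground connectivity 26 and background (void)
connectivity 6 — the complementary pair that avoids topological paradoxes.
A void is a background component not connected to the volume border.
Geometry is computed in physical µm: volume as voxel count × voxel volume;
surface area by exposed voxel-face counting (exact for axis-aligned shapes;
overestimates smooth curved surfaces by up to ~1.5×, a known property of
face counting — compactness comparisons between objects measured the same
way are unaffected); feret diameter as the maximum pairwise distance over
convex-hull candidates of surface-voxel **centres** (the per-slice 2D hull
union, which contains every 3D hull vertex); and the volume:ellipsoid ratio
against the minimum-volume enclosing ellipsoid of the same candidates
(Khachiyan's algorithm, tolerance $10^{-3}$, ≤ 1000 iterations). Using
voxel centres rather than voxel corners makes a digitized sphere of radius
$r$ measure feret $2r$ exactly and keeps its volume:ellipsoid ratio within
0.05 of 1; the corresponding closed forms for a 10-voxel cube are a feret
of $9\sqrt{3}$ µm and a ratio of $1000 / \frac{4}{3}\pi(4.5\sqrt{3})^3$.
Degenerate (coplanar) point sets make the enclosing ellipsoid singular; the
ratio is then reported as `NA` rather than a fabricated number.

The mTEC field pipeline finishes with the two filters that make "object"
mean "single cell": a lower volume cutoff (532 µm³ by default — the mean
mTEC nucleus volume + 3σ, recomputed from the nuclei channel when one is
supplied, since nothing smaller than a nucleus can be a whole cell) and an
upper trim excluding objects in the top 5% of feret, compactness **or**
volume:ellipsoid ratio (union semantics), which removes fusions of several
cells at a predictable cost of roughly 10–15% of true objects. Tests that
compare recovered counts to ground truth therefore switch the trim off via
`top_fraction = 0`.

## Density and proliferation

Nuclei counting follows the maxima recipe (median → rolling ball 25 →
outlier removal → intensity-band mask → outlier removal → 3D maxima with
xy/z exclusion radii 10/3 voxels and noise floor 10). Two nuclei closer
than the exclusion radius merge into one detection — documented behaviour,
tested explicitly. A capsule-proximal margin (low-y side) can be excluded
from counting and from the counted volume, since the sub-capsular sheet
approximates a 2D density. Group comparisons use the Welch two-sample
t-test; the degenerate equal-constant case returns $p = 1$ by convention.

The EdU labeling index samples each detected nucleus's mean EdU intensity
in a 3-µm ball and thresholds adaptively (Otsu over the per-nucleus means)
with an absolute floor of 25 on the 8-bit scale: the floor keeps Otsu from
splitting the noise band in volumes that contain no labelled nucleus at
all. A fixed-threshold mode exists for data where the adaptive split is
not trusted. The headline statistic is pooled labeled over pooled total
nuclei, with per-volume percentages retained for dispersion.

## Kernel density estimates of shape space

`kde_shape_distribution()` uses a Gaussian product kernel with Silverman
bandwidths $h_k = \hat\sigma_k (4/((d+2)n))^{1/(d+4)}$ over the three
discriminatory descriptors. Probability limits are highest-density
regions: the 10% region is $\{f \ge q_{0.90}(f(X))\}$ and the 90% region
$\{f \ge q_{0.10}(f(X))\}$, so the dark region is nested in the light one
by construction and the stated mass coverage is exact up to $1/n$. Mode
counting inspects grid local maxima above 5% of the peak.

## Problem sizes and seeds

The test suite and the acceptance script run at desk scale: 200–2000 genes
per expression simulation, 50 seeds for the proportion-recovery study, 20
single-cTEC volumes (~1.8 M voxels each) for the morphology calibrations,
one to ten default medulla volumes (~3.9 M voxels, ~250 cells each) for
segmentation, counting and labeling-index calibrations, and 1000 null
draws against a 100-set collection for false-discovery-rate control. All
randomness flows from explicit integer seeds; the same seed reproduces
byte-identical simulations.

## Known limitations

* Deconvolution exactness holds on the linear scale with a flat lymphoid
  proportion; day-varying proportions and log-scale inputs are supported
  but carry smoothing bias by construction.
* Surface area inherits the face-counting bias on curved surfaces; do not
  compare it against mesh-based measurements of the same object without a
  calibration factor.
* The mTEC generator produces mid-sized ovoids, not the full branched
  spectrum of real medullary epithelium; segmentation performance on real
  tissue will be bounded by factors the generator does not model.
* GO/Reactome graph structure is not conditioned on; enrichment rows for
  nested sets are correlated.
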