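# thymoscope

Tools for quantifying how the thymic stroma changes during age atrophy and
castration-induced regeneration, for researchers analysing paired
tissue/lymphoid expression time courses or 3D reporter imaging of thymic
epithelial cells (TEC).

The package implements three connected analysis stacks plus synthetic-data
generators with full ground truth:

1. **Stromal deconvolution.** Microdissected thymic tissue is dominated by
   lymphocytes, so stroma-only expression is recovered by inverting the
   two-component mixture `tissue = p · lymphoid + (1 − p) · stromal`, where
   the lymphoid proportion `p` is the mean tissue:lymphoid signal ratio
   over lymphoid-specific marker genes (for which the stromal term is
   zero). Time courses are smoothed with robust natural cubic splines
   (interior knots at days 6 and 17, Hampel-weighted IRLS) before
   deconvolution, then quantile-renormalized per day. High-confidence
   stromal gene lists threshold the tissue:lymphoid ratio at the marker
   mean + *k*·s.d. (*k* = 2.5 or 2.0), and genes with ≥ 2-fold trajectories
   are flagged as dynamic.
2. **Enrichment dynamics.** One-sided Fisher exact (hypergeometric)
   over-representation of per-day stromal lists against GMT gene-set
   collections, BH-corrected, expressed as the signed change in
   −log10 p relative to day 0, with size/keyword filters and
   early-vs-late temporal pattern classification.
3. **3D morphometry, density and proliferation.** Segmentation of
   single reporter-labelled cells (Otsu + largest component) and of packed
   medullary fields (seeded 3D watershed with volume and top-5% shape
   trims); per-object volume, surface area, feret diameter, compactness
   (SA/V) and volume:ellipsoid ratio (against the minimum-volume enclosing
   ellipsoid, Khachiyan's algorithm); enclosed-void counting; maxima-based
   nuclei counting for density; and EdU labeling-index estimation.

The generators (`simulate_expression()`, `simulate_volume()`) emulate the
corresponding experiments — the replicate design of the regeneration
time-course arrays, and confocal-like volumes of cortical TEC (75 ± 10 µm
ovoids with 20–30 lymphocyte-filled voids), aged cortex with broad-spectrum
age pigment, and medullary fields with one H2b-reporter nucleus per cell —
and return the ground truth every estimator is validated against.

## Worked example

Simulate a noisy expression time course, recover the lymphoid proportion
and the stromal matrix, and flag dynamic genes:

```r
library(thymoscope)

sim <- simulate_expression(expr_sim_config(n_genes = 500, noise_sd = 0.05,
                                           seed = 1))
expressed <- detection_filter(sim$tissue, sim$calls)
p <- estimate_lymphoid_proportion(sim$tissue, sim$lymphoid,
                                  sim$truth$markers)
head(p, 3)
#> # A tibble: 3 × 2
#>   day       p
#>   <chr> <dbl>
#> 1 young 0.858
#> 2 0     0.852
#> 3 1     0.851
```

The estimates sit within 0.01 of the generator's true proportion (0.85)
at 5% signal noise. Deconvolve and flag dynamics:

```r
tf  <- fit_robust_spline(sim$tissue)
lf  <- fit_robust_spline(sim$lymphoid)
est <- quantile_renormalize(deconvolve_stromal(tf, lf, p), tf)
dyn <- flag_dynamic_genes(est)
table(dyn$dynamic)
#> FALSE  TRUE
#>   229   271
```

271 of 500 genes show a ≥ 2-fold change over the time course — the
generator's designed dynamic genes plus borderline calls on low-expressed
genes whose deconvolved trajectories are noise-dominated (the
high-confidence stromal list and the detection filter exist to strip the
latter). On the imaging side, segment one synthetic young cortical TEC and measure
it:

```r
vs  <- simulate_volume(volume_sim_config("young_cortex", seed = 3))
pre <- preprocess_volume(vs$volume, "ctec_confetti", channel = "reporter")
obj <- segment_single_cell(pre, spacing_um = vs$volume$spacing)
measure_shape(obj)[, c("volume_um3", "feret_um", "compactness")]
#> # A tibble: 1 × 3
#>   volume_um3 feret_um compactness
#>        <dbl>    <dbl>       <dbl>
#> 1      39212     64.7       0.343
count_voids(obj)
#> [1] 26
```

The feret diameter (64.7 µm) matches this cell's generated long axis
(65.4 µm) and the 26 recovered voids equal the ground-truth void count
exactly.

## Command line

A thin CLI over the same functions ships in `inst/cli/thymoscope`
(subcommands `simulate-expr`, `simulate-volume`, `deconvolve`, `enrich`,
`density`, `edu-index`, `run`); `run_pipeline()` orchestrates the tabular
stages with per-stage seeds and a manifest of parameter hashes and output
checksums.
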