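---
title: "Regional quantification of aortic valve leaflet histology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional quantification of aortic valve leaflet histology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafletquant)
```

## The problem

Aortic valve (AV) leaflets owe their biomechanics to a precisely patterned
extracellular matrix: collagen concentrated toward the annulus attachment
(the *base*), glycosaminoglycans (GAGs) spread through the body of the
leaflet, and elastic fibers enriched toward the free edge (the *tip*).
Histomorphometric studies quantify this patterning by (i) outlining each
leaflet section as a region of interest, (ii) splitting the outline into
three portions of equal tissue area from base to tip, (iii) classifying
pixels into stain classes by color thresholds, and (iv) reporting, for each
stain, what percent of its total signal falls into each portion — the
*fractional distribution*, which sums to 100 per stain per leaflet.

`leafletquant` implements this pipeline, together with two companion
analyses that typically accompany it: relative gene expression by the Livak
2^-ddCt method, and verification of targeted-proteomics (PRM) precursor
m/z lists. Because archived slide scans of this kind of study are rarely
available, the package also ships a synthetic-data module that generates
leaflet-shaped images and Ct tables with *exact* ground truth, so the whole
pipeline is testable end to end.

## Equal-area tripartition

The ROI is a binary mask (loaded from a 0/255 PNG, a 0/1 matrix, or a
polygon rasterized by a half-open pixel-centre rule; pixel centres sit at
integer 0-based coordinates). The base-to-tip axis is not part of the input,
so it must be estimated:

* **Direction** — the principal eigenvector of the second-moment matrix of
  the foreground pixel coordinates. Masks with equal principal moments
  (perfect isotropy) have no defined axis and raise an error asking for a
  manual `axis_spec()`.
* **Orientation (which end is the base)** — the end with the larger mean
  cross-sectional width, because the leaflet base attaches to the annulus
  and is anatomically wider than the free edge. The heuristic can be
  overridden with `base_hint`, mirroring the manual ROI step such analyses
  start from.

Pixels are then sorted by signed projection onto the axis, ties broken by
row-major pixel order, and cut at cumulative areas `ceiling(A/3)` and
`ceiling(2A/3)`. This makes the partition fully deterministic — the three
areas depend on the total area alone — and lets a brute-force
sort-and-scan oracle verify it exactly:

```{r}
mask <- load_roi(matrix(1L, 30, 90))
part <- partition_equal_area(mask, axis_spec(c(1, 0)))
region_areas(part)
```

An equal-cumulative-area rule was chosen over distance binning because the
sectioning is defined *by area of the tissue*; with distance bins a tapered
leaflet would get unequal areas.

## Stain classification in HSI space

Pixels are classified by thresholds on hue, saturation and intensity. The
package implements the classic HSI model — intensity is the channel mean,
`S = 1 - min/mean`, hue from the standard angular formula — rather than HSV
or HSL; the variant name travels in the output metadata so reports are
auditable. Hue is undefined for achromatic pixels (`S = 0`) and is returned
as `NA`; a class whose hue interval spans the full circle (the dark classes)
accepts such pixels, any other class rejects them. Hue intervals may wrap
around 0° (useful for red chromogens).

Per-protocol presets ship with the package (`stain_presets()`):
yellow → collagen and blue → GAGs for Movat's pentachrome, near-black
low-intensity pixels → elastic fibers for van Gieson, red → chromogen for
AEC immunohistochemistry. Elastin and melanin are both near-black; they are
disambiguated by which staining protocol (i.e. which adjacent section) is
being analysed, not by color. The presets are calibrated against this
package's synthetic palettes: the numeric thresholds used in the original
microscope software are unpublished, so the presets are configuration
defaults, not reference values, and per-cohort configs can be supplied as
YAML/JSON (applied globally per cohort by default; per-section configs are
possible by running cohorts of one).

Classification is exclusive by default: a pixel takes the first matching
class in configuration order, so overlapping specs resolve
deterministically and per-class counts can never exceed the leaflet area.

## Fractional distributions and statistics

For each class, `percent(region) = 100 * count(class ∧ region) /
count(class)`; the denominator is the class total over the whole leaflet,
which is what makes the three percentages sum to 100 (a class with zero
pixels is reported as undefined, never 0/0). Cohort summaries are
arithmetic means with sample (n−1) standard deviations, rendered
`"m ± s%"` to one decimal.

Region differences are tested per class with a one-way ANOVA across the
three regions plus Tukey HSD pairwise contrasts; significance tiers are
`*` p < 0.05, `**` p < 0.01, `***` p < 0.001. Because the original test
behind such figures is typically unnamed, the method name is always carried
in the output, and a permutation alternative is provided that re-labels the
three region values *within* each leaflet (respecting the sum-to-100
constraint), enumerating all `6^n` relabellings exhaustively when feasible
(up to `6^6` by default) and Monte-Carlo sampling with the +1 correction
otherwise.

```{r}
mk <- function(b, m, t) distribution_from_counts(
  c(base = b, middle = m, tip = t), "elastin")
cohort <- list(mk(264, 207, 529), mk(310, 180, 510), mk(240, 260, 500))
summarize_cohort(cohort)
compare_regions(cohort, method = "permutation")$overall
```

## The synthetic-data module

The generator exists so that every downstream stage can be verified against
exact bookkeeping:

* **Shape** — a tapered super-ellipse (exponent 2.5) with optional seeded
  low-frequency sinusoidal boundary noise, floored so the outline cannot
  pinch into two components. Published leaflet outlines motivate but never
  parameterize a shape; any single-component elongated, tapered footprint
  serves the purpose. Defaults (elongation 2.5, taper 0.45) give outlines
  with a visibly wider base, matching leaflet anatomy. The realized area is
  iteratively rescaled to within 5% (normally ≪1%) of the target.
* **Stain placement** — each class's pixel budget is split across regions by
  largest-remainder rounding of the target distribution (realized counts
  match the design to the nearest pixel; e.g. a 1000-pixel budget at
  26.4/20.7/52.9 gives exactly 264/207/529), then placed uniformly at
  random within each region. Spatial clustering of fibers is deliberately
  not modelled: the quantification counts pixels, not objects, so clustering
  cannot change any statistic the pipeline computes.
* **Colors** — palette mean plus independent per-channel Gaussian noise,
  clamped and rounded; zero noise reproduces the palette exactly, which is
  what makes the zero-noise round trip an *exact* test of the
  classification thresholds.
* **Ct tables** — group means offset by `-log2(fold)` from the control,
  plus additive Gaussian replicate noise in Ct units (the standard qPCR
  error model; replicate noise of real instruments is also approximately
  Gaussian on the cycle scale). Zero-noise tables are recovered exactly by
  the 2^-ddCt stage.

All generators take an explicit seed, restore the caller's RNG state, and
are bit-reproducible. What passing these tests does *not* show: robustness
to real-slide artifacts — uneven illumination, stain batch variation,
out-of-focus regions, folds and debris — none of which the generator
emulates. Section resolution is likewise unspecified in typical reports, so
`micron_per_pixel` is carried as free metadata only.

## The qPCR and PRM strands

`delta_delta_ct()` follows the common Livak formulation: replicates are
averaged per sample (an optional policy drops replicates > 0.5 Ct from the
median), dCt is formed per sample, then averaged per group — rather than
differencing group means of raw Cts — and `2^-ddCt` is reported with the
control pinned at exactly 1. No amplification-efficiency correction is
applied (plain 2^-ddCt). Because the error treatment on n = 3 folds is
ambiguous in most reports, both the SD and the SEM of per-sample folds are
emitted.

`monoisotopic_mass()` sums an embedded 5-decimal monoisotopic residue
table plus water (18.010565 Da) and modification deltas;
`precursor_mz()` is `(M + z·1.007276)/z`. Reported precision is three
decimals, but comparisons always use full precision. The shipped
`prm_target_list()` carries a peptide whose printed precursor m/z matches
its *unmodified* form even though a Met-oxidation annotation accompanies
it (the oxidized form would sit ~8 m/z higher at 2+); `verify_targets()`
evaluates it unmodified and flags the discrepancy in the report's `note`
column instead of silently matching either way — whether the annotation or
the printed value is the transcription artifact cannot be decided from the
text alone.

```{r}
verify_targets(prm_target_list(), tolerance_mz = 0.005)[
  , c("protein", "peptide", "z", "expected_mz", "computed_mz", "pass")]
```

## Orchestration and reproducibility

`run_quantify()` drives the image pipeline over a cohort from an in-memory
or YAML/JSON config, isolating per-leaflet failures (the run fails only if
every leaflet fails) and writing tidy CSVs plus a provenance manifest
(seed, config hash, package version). `run_all_demo()` generates a
three-leaflet zero-noise cohort painted at wild-type-like regional
distributions (collagen 76.9/21.7/1.3, GAGs 38.8/19.3/41.8, elastin
26.4/20.7/52.9 — renormalized to sum to exactly 100, since one-decimal
rounding makes some printed triplets sum to 99.9), quantifies it, runs the
two qPCR scenarios (designed relative expressions 0.58 and 2.6), verifies
the PRM list, and writes one JSON report; two runs with the same seed
produce bit-identical files. This package is a library with a scripted
entry point (`scripts/acceptance.R`) rather than a multi-command shell
tool: the exported functions *are* the interface, and the demo doubles as
the end-to-end executable example.

Problem sizes were chosen so the whole test suite runs in seconds on a
laptop: demo leaflets of 11–14k pixels, property checks over ~100 random
blobs of 300–1100 pixels, 200-seed Monte-Carlo for the noisy qPCR recovery.

## Known limitations

* The axis width-heuristic can misorient nearly symmetric masks; use
  `base_hint` when the anatomy is known.
* Thresholds are global per cohort; no illumination correction or stain
  deconvolution is attempted, so heavily counterstained or faded sections
  need recalibrated configs.
* The partition's equal areas are exact by construction, but the *shape* of
  the cut boundary is projection-based (straight cuts perpendicular to the
  axis); strongly curved leaflets may prefer a curvilinear axis, which is
  out of scope.
* Fractional distributions from adjacent sections are compared without any
  image registration across sections.
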