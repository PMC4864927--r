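---
title: "Quantitative mapping of perfusion and hypoxia in whole tumor sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative mapping of perfusion and hypoxia in whole tumor sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumormapr)
```

## The measurement problem

Solid tumors are microregionally heterogeneous: functional (perfused)
vessels, transiently shut-down vessels, hypoxic tissue and necrosis can
all occur within a few hundred micrometers of each other. A standard way
to quantify this is multiplexed immunofluorescence on frozen tumor
sections: CD31 marks all endothelium (every vessel cross-section), an
intravenously injected carbocyanine dye (DiOC7(3)) marks only vessels
that carried blood in the minutes before tissue harvest, pimonidazole
adducts report tissue hypoxia as a graded intensity, HIF1-α marks the
transcriptional hypoxia response, BrdUrd marks proliferating cells, and
Hoechst 33342 counterstains all nuclei. Entire sections (square
centimeters) are imaged by tiling microscope fields at 0.75 µm/pixel.

`tumormapr` turns such registered multi-channel section images into
per-section summary statistics and spatial profiles:

* the **perfused vessel fraction** — the share of CD31 objects whose
  area is at least 50% covered by DiOC7 signal;
* **positive tissue fractions** (HIF1-α, BrdUrd) and **mean marker
  intensities** (pimonidazole, HIF1-α) over viable tissue;
* **unperfused and necrotic area fractions** of whole tissue;
* **distance profiles**: mean pimonidazole intensity of all pixels at
  each distance to the nearest CD31 object;
* arm-level comparisons by one-way ANOVA with Bonferroni post-tests.

Because the slide scans such studies are based on are not generally
available, the package ships a synthetic section generator with full
ground truth, so the entire pipeline is verifiable end to end.

## Pipeline model and fixed rules

Each section is a `section_stack`: named intensity channels on a common
pixel grid plus the physical pixel size (default 0.75 µm/pixel) and
cohort metadata. Staining group 1 carries DiOC7/CD31/pimonidazole/
BrdUrd/Hoechst; group 2 carries DiOC7/CD31/HIF1a/Hoechst. Metrics that
need an absent channel return an `NA` sentinel rather than a guess.

Segmentation follows a fixed, recorded stage order:

1. **Exclusions.** Manual removal of necrosis and staining artifacts is
   rendered as user-supplied ROI masks (`exclusion_roi`); excluded
   pixels are set to background everywhere downstream. This is the only
   faithful desk-scale rendering of an interactive step.
2. **Fixed thresholds.** A pixel is positive iff intensity ≥ threshold.
   The inclusive boundary makes integer-valued images behave
   predictably. Threshold values are deliberately explicit
   configuration (there is no principled universal value for antibody
   staining); the defaults were calibrated once against the synthetic
   generator as background mean + 5·noise SD, and every run logs the
   values used.
3. **Connected components.** CD31 objects are 8-connected by default
   (vessel cross-sections are blobby); 4-connectivity is available.
   Labels are assigned in raster-scan order of each object's first
   pixel, so output is reproducible across runs.
4. **Artifact filter.** CD31 objects with area strictly below 9 µm²
   (pixel count × pixel size²) are removed. At 0.75 µm/pixel a 15-pixel
   object (8.4375 µm²) is removed and a 16-pixel object (9.0 µm²) is
   retained — the "less than" is read literally.

Perfusion classification computes, per CD31 object, the fraction of its
pixels that are DiOC7-positive; the object is perfused iff coverage
≥ 0.5 (the boundary is inclusive at exactly 50%). A section with zero
vessels yields an `NA` fraction with a warning — never 0 — so cohort
means are not silently biased.

The tissue denominator is delineated from the Hoechst channel:
threshold, morphological closing with a 6 µm disk, hole filling, and
retention of the largest component. Viable tissue is tissue minus
necrosis and artifact exclusions; necrotic, artifact-excluded and
viable areas always partition tissue exactly (integer pixel counts).

### Distance profiles

`distance_to_nearest_vessel` computes an exact Euclidean distance
transform: for every pixel, the distance between pixel centers to the
nearest pixel of a reference object (0 inside objects). The reference
set is either all CD31 objects or a subset such as the perfused ones.
`intensity_distance_profile` then averages a channel over left-closed
distance bins `[k·w, (k+1)·w)`. The default bin width of one pixel
(0.75 µm) is the finest resolution the imaging supports; the default
300 µm maximum keeps sparse far-field bins out of the summary. Empty
bins carry `NA`, not 0, and the per-bin pixel counts plus out-of-range
and non-viable counts always add up to the full pixel count. Necrotic
pixels are excluded from profiles, consistent with computing intensity
statistics after removal of necrosis; this choice is recorded here
because the alternative (profiling all tissue) is also defensible.

### Interpretation ambiguities resolved in configuration

Two quantities in this family of analyses are commonly underspecified,
and `tumormapr` makes the resolution explicit rather than silent:

* **Mean marker intensity** can be averaged over all viable tissue or
  over marker-positive tissue only. Both modes are implemented
  (`intensity_mode` of `"all_viable"` or `"positive_only"`); the
  default is all viable tissue and the mode is recorded in the
  run metadata.
* **Unperfused ("gross vascular shutdown") area** has no standard
  operational definition. The package uses a distance rule: viable
  tissue farther than `supply_radius_um` (default 150 µm, roughly the
  oxygen diffusion distance with margin) from any perfused vessel,
  expressed as a percent of whole tissue. The criterion name is
  attached to the result so a rule-based number is never mistaken for
  a manual delineation.

### Statistics

`summarize_groups` reports per-arm n, mean and sample SD (n−1), the
bar-plus-SD convention. `anova_bonferroni` runs classical one-way ANOVA
and pairwise comparisons using the pooled within-group error, so the
two-group case collapses to the squared pooled t statistic. Raw p
values are adjusted as `min(1, m·p_raw)`; by default all `k(k−1)/2`
pairs are compared, with a vs-control mode (`m = k−1`) available
because post-test conventions differ between analysts. Both raw and
adjusted p values are always reported. Sentinel-valued metrics are
dropped per metric, never imputed. Degenerate inputs (zero within-group
variance with unequal means) return `NA` rather than an arbitrary
number; identical data across arms return F = 0, p = 1.

## Image I/O and registration

Stacks are written as multi-page 16-bit TIFFs (lossless for integer
intensities in [0, 65535]; storage is 16-bit unsigned, analysis is
floating point). Channel names, pixel size and section metadata travel
in a JSON sidecar `<path>.json`; on read, a `key=value` TIFF
description tag is also honored so stacks written by other toolchains
can carry their metadata inline. If both the file metadata and the
cohort manifest state a pixel size they must agree — a conflict is an
error, not a silent preference.

Whole-section images are mosaics of adjacent fields of view.
`tile_mosaic` places a complete rectangular grid of fields with a
configurable overlap; within overlap bands the later-placed field wins.
Last-placed-wins is deterministic and introduces no interpolation
artifacts into masks, which matters more here than seam cosmetics. The
acquisition overlap is exposed as configuration, not inferred from the
data.

When one physical slide is imaged in two rounds (e.g. native DiOC7
fluorescence before antibody staining, markers after), the rounds must
be overlaid pixel-to-pixel. `register_rounds` estimates an integer
translation by exhaustive normalized cross-correlation within
±`max_shift_px` (default 50), computed exactly on each candidate
overlap via FFT cross-sums and integral images. Re-imaged slides shift
by at most a few pixels and do not rotate or scale measurably, which is
why sub-pixel and deformable models are deliberately out of scope.
Zero-variance images make correlation undefined; the function warns and
returns shift (0, 0) with `NA` confidence. Ties are broken toward the
smallest shift.

## The synthetic section generator

`section_model`/`simulate_section` emulate the statistical structure
the analysis assumes, with complete ground truth:

* **Vessels**: `n_vessels` non-overlapping disks (rejection sampling,
  ≤ 1000 retries per vessel, error on failure) with radii uniform in
  `vessel_radius_um` (default 3–8 µm), placed in viable tissue. Each is
  independently perfused with probability `p_perfused`; DiOC7 paints
  exactly the perfused disks. The perfusion draws are the first
  consumption of the seeded RNG stream, so they can be replayed
  independently of everything else.
* **Hypoxia**: pimonidazole intensity follows a four-parameter sigmoid
  of distance `d` to the nearest perfused vessel,
  `I(d) = I0 + (Imax − I0) / (1 + exp(−(d − d0)/s))`, defaults
  I0 = 200, Imax = 3000, d0 = 100 µm, s = 25 µm. The half-rise distance
  sits at the commonly cited oxygen diffusion distance and the form
  captures the diffusion-limited plateau; it is a modeling choice and
  plain configuration, not doctrine. Necrotic tissue is set to the low
  constant I0. An `"all_vessels"` reference mode ties hypoxia to every
  vessel instead, mimicking intermittent perfusion where dye-negative
  vessels still oxygenate tissue part-time; it must be selected
  explicitly.
* **HIF1-α**: tissue beyond `hif_distance_cutoff_um` (default 100 µm)
  is positive with expected fraction `p_hif`, drawn as smoothed random
  patches rather than per-pixel salt-and-pepper.
* **Necrosis**: a smoothed random field thresholded inside tissue at
  the quantile that hits `necrosis_fraction` to within one pixel
  quantile step (±0.01 comfortably).
* **Artifacts**: `n_specks` connected blobs of 1–15 pixels (all
  strictly below 9 µm² at 0.75 µm/pixel) injected into the CD31
  channel, placed clear of vessels so they never merge with real
  objects.
* **Noise**: additive Gaussian with SD `noise_sd` (default 50 on the
  16-bit scale), clipped at zero. Poisson noise is deliberately
  omitted; tests use relative tolerances. Every channel is rounded to
  integers so stacks round-trip losslessly through TIFF; the
  quantization is part of the generator's contract and the test
  oracles account for it.

All randomness derives from `seed` with pinned RNG kinds, so identical
models give pixel-identical output across platforms. `simulate_cohort`
derives distinct per-section seeds deterministically from a master
seed and emits a manifest in the same CSV schema the reader uses.

Default geometry is 768×768 pixels (576 µm square) with 300 vessels —
about one in five perfused at the control setting of
`p_perfused = 0.21`, against 0.28 for the treated arm — and six
sections per arm, matching the group size such studies use. These
defaults are the regime the statistics are exercised in; tests and the
acceptance script use them directly, with smaller 192-pixel sections
for unit-level checks.

**What passing tests do and do not show.** The generator produces
circular vessels, radially smooth hypoxia, stationary Gaussian noise
and perfectly registered channels. Real sections have elongated and
branching vessel profiles, illumination gradients, staining batch
effects, folds and debris, and imperfect registration. Tests against
the generator therefore validate the *bookkeeping* — segmentation
boundaries, area accounting, distance geometry, estimator bias,
determinism — not the biological fidelity of any particular threshold
choice on real slides. Threshold selection on real data remains the
analyst's responsibility, which is why thresholds are mandatory,
logged configuration.

## Numerical choices

* Pixel-count geometry throughout: areas are counts × pixel size²; no
  sub-pixel boundary estimation.
* All boundary rules are inclusive-≥ (thresholds, coverage) except the
  artifact filter, which removes strictly-< 9 µm² objects.
* Distances are between pixel centers; inside-object distance is 0.
  The distance transform is exact (verified against a brute-force scan
  to 1e-9 µm).
* Undefined quantities are `NA` sentinels with warnings (zero-vessel
  perfusion fraction, single-value SDs, degenerate ANOVA), never 0.
* The registration score at shifts with degenerate overlap variance is
  `NA` and excluded from the argmax.
* CSV outputs are written with fixed column order and no row names;
  identical configuration plus master seed reproduces byte-identical
  CSVs.

## Known limitations

* Registration is integer-translation only — adequate for re-imaged
  slides, not for serial sections.
* Distances are 2-D within a section; no geodesic (tissue-constrained)
  or 3-D modeling.
* The unperfused-area rule is a stand-in for an unstated manual
  criterion and is labelled as such in the output.
* The generator's intermittent-perfusion mode changes only the hypoxia
  reference set; it does not model time-varying flow.
* BrdUrd is summarized as a positive-tissue fraction only; no
  cell-cycle modeling.
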