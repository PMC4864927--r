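# tumormapr

Quantitative immunohistology of the tumor microenvironment from
whole-section multi-channel fluorescence images.

Studies of tumor blood-flow modification image entire tumor
cryosections (at 0.75 µm/pixel, tiled from adjacent microscope fields)
stained for CD31 (all vessels), DiOC7(3) (vessels perfused at harvest),
pimonidazole (tissue hypoxia), HIF1-α, BrdUrd and Hoechst, and reduce
them to per-section microregional statistics that are then compared
across treatment arms. `tumormapr` implements that analysis as a
tested, reusable pipeline for image analysts and tumor-microenvironment
researchers, together with a seeded synthetic section generator (with
complete ground truth) so every stage is verifiable without access to
original slide scans.

## What it computes

For each section, after manual-style exclusion of necrosis/artifact
ROIs, fixed-threshold segmentation, connected-component labeling and
removal of CD31 objects smaller than 9 µm²:

* **Perfused vessel fraction** — with CD31 objects $V_1..V_K$ and
  DiOC7-positive mask $D$,

  $$\hat p = \frac{1}{K}\sum_{k=1}^K \mathbf 1\!\left[\frac{|V_k \cap D|}{|V_k|} \ge 0.5\right]$$

* **Positive tissue fractions and mean intensities** over viable
  tissue (tissue minus necrosis and artifacts), e.g. percent HIF1-α
  positive tissue and mean pimonidazole intensity.
* **Unperfused and necrotic area** as percent of whole tissue area
  (unperfused = viable tissue farther than a supply radius, default
  150 µm, from any perfused vessel).
* **Distance profiles** — exact Euclidean distance from every tissue
  pixel to the nearest CD31 object, and the mean pimonidazole
  intensity of all pixels at each distance (0.75 µm bins).
* **Arm comparisons** — per-arm n/mean/SD, one-way ANOVA, and
  Bonferroni-adjusted pairwise post-tests
  ($p_\text{adj} = \min(1, m\,p_\text{raw})$).
* Caliper tumor volume $V = \frac{\pi}{6}abc$ from three orthogonal
  diameters.

## Worked example

Simulate a two-arm cohort (six sections per arm, ~300 vessel
cross-sections per section, per-vessel perfusion probability 0.21 in
controls vs 0.28 at 12 h post-treatment), quantify every section, and
compare the arms:

```r
library(tumormapr)

models <- list(control = section_model(p_perfused = 0.21),
               `12h`   = section_model(p_perfused = 0.28))
co <- simulate_cohort(models, n_per_arm = 6, master_seed = 42)

est <- arm <- c()
for (i in seq_along(co$stacks)) {
  gt <- co$ground_truths[[i]]
  sm <- compute_section_metrics(
    co$stacks[[i]], default_config(),
    list(exclusion_roi(gt$necrosis_mask, "necrosis")))
  est[i] <- sm$perfused_vessel_fraction
  arm[i] <- co$manifest$arm[i]
}

summarize_groups(data.frame(arm = arm, pf = est), "pf")
#>      arm n      mean         sd
#>  control 6 0.2022222 0.01833838
#>      12h 6 0.2694444 0.01373020

anova_bonferroni(split(est, arm), metric = "perfused_vessel_fraction")
#> One-way ANOVA on perfused_vessel_fraction:
#>   F(1, 10) = 51.66, p = 2.969e-05
#>   Bonferroni post-tests (m = 1):
#>  arm_i   arm_j   mean_diff        p_raw p_bonferroni significant
#>    12h control -0.06722222 2.969294e-05 2.969294e-05        TRUE
```

The per-section estimates recover the configured regime — about 20% of
vessels perfused in controls rising to about 27% in the treated arm —
and the contrast is detected at n = 6 per group. Against the stored
ground truth the estimates equal the realized per-section fractions
exactly, because at the default 5σ thresholds segmentation reconstructs
the simulated masks pixel-for-pixel.

The same analysis runs from a YAML config over a directory of real
section TIFFs plus a cohort manifest (see `?run_pipeline` and the
`inst/cli/tumormapr` wrapper with `simulate`, `quantify`, `stats` and
`run` subcommands); outputs are per-section, per-vessel, profile,
group-summary and ANOVA CSVs, plots, and a log recording every
threshold, boundary rule, seed and stage order.

## Documentation

The methods vignette (`vignettes/tumor-section-mapping.Rmd`) documents
the model assumptions, every fixed boundary rule (inclusive thresholds,
the strict 9 µm² filter, the 50% coverage cutoff), the synthetic
generator's design and its limits, and the configuration surface.
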