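# organoidquant

Image quantitation for fluorescence microscopy of epithelial (lung
tip-progenitor) organoids, aimed at groups doing live kinase-reporter
imaging and immunofluorescence morphometry who want the measurement chain
— not the microscope — to be the reproducible part.

The package implements:

* **KTR ratio time series.** A kinase translocation reporter (KTR) moves
  between nucleus and cytoplasm as its kinase phosphorylates it, so the
  per-cell cytoplasm/nucleus mean-intensity ratio *C/N* reads out kinase
  activity live. The pipeline segments nuclei on the nuclear-dye channel,
  builds a 5-px ring around each nucleus as the cytoplasmic proxy,
  computes *C/N = mean(I_cyt) / mean(I_nuc)* per cell, normalises to the
  cohort mean at T0 (= 100%), and reports per-organoid traces with
  t-based 95% confidence bands plus a replicate-means one-way ANOVA
  between T0 and a later frame.
* **Epithelial morphometrics.** Lateral/apical/basal cell lengths and
  length/width ratios from line-segment annotations (columnar vs cuboidal
  vs squamous shape regimes); nucleus circularity *4πA/P²* from traced
  polygons (exact vertex chain) or masks (Crofton 4-direction perimeter).
* **Per-cell marker intensity** (mean nuclear + mean ring, pERK/pAKT
  style), **proliferation fractions** (EdU/KI67-positive nuclei, 2D and
  3D), and **organoid area and budding classification** (solidity cut,
  manual labels override).
* **A seeded synthetic generator** for every input: reporter movies with
  first-order relaxation kinetics driven by a latent activity, trapezoidal
  epithelia on circular contours, positivity scenes with exact positive
  counts, and spherical/lobed silhouettes — each with lossless ground
  truth, so every stage is validated against known truth.

## Worked example

Simulate a 12-cell organoid movie (13 frames, 10-min spacing, saturating
stimulation at T0), run the full analysis, and test T0 against T12:

```r
library(organoidquant)

scene <- ktr_scene(n_cells = 12, image_shape = c(224, 224), seed = 7)
movie <- render_movie(scene)            # two channels, 5% multiplicative noise
res   <- ktr_pipeline(movie)

head(res$trace[, c("time_min", "mean", "sd", "n", "ci_lo", "ci_hi")], 5)
#>   time_min  mean    sd  n  ci_lo ci_hi
#> 1        0 100.0 2.275 12  98.55 101.4
#> 2       10 171.7 3.829 12 169.28 174.1
#> 3       20 216.4 4.834 12 213.29 219.4
#> 4       30 242.4 5.097 12 239.16 245.6
#> 5       40 258.9 5.571 12 255.34 262.4

a <- anova_t0_vs_t(res$records$ratio_pct[res$records$time_min == 0],
                   res$records$ratio_pct[res$records$time_min == 120])
sprintf("T0 vs T12: F = %.1f, p = %.3g", a$F, a$p)
#> "T0 vs T12: F = 8162.8, p = 8.91e-30"
```

The trace starts at exactly 100% (the T0 normalisation anchor) and rises
as the reporter translocates to the cytoplasm; `n` is the number of
scored cells per frame and `ci_lo`/`ci_hi` the 95% confidence band.
Morphology works the same way:

```r
sil <- generate_silhouette("budding", n_lobes = 3, radius = 60, seed = 4)
classify_budding(sil$mask)[c("class", "solidity")]
#> $class: "budding"     $solidity: 0.846
```

A thin command-line front end (`inst/cli/organoidquant`) exposes the same
pipeline as subcommands (`simulate`, `segment`, `ktr`, `shape`,
`proliferation`, `area`, `stats`) driven by a strict YAML config; see
`?oq_cli`. The vignette in `vignettes/organoidquant-methods.Rmd` documents
the models, defaults and validation design.

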