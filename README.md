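# exoquant

Quantitative image analysis of **macrophage exophagy** — the process by which
macrophages digest dead adipocytes that are far too large to phagocytose.
Macrophages in white adipose tissue ring dead adipocytes in crown-like
structures (CLS), seal an extracellular compartment against the adipocyte
surface, acidify it, and deliver lysosomal enzymes into it by lysosome
exocytosis; uptake of the liberated fragments turns the macrophage into a
foam cell. exoquant implements the measurements that establish each step of
this biology, for researchers analysing multi-channel fluorescence microscopy
and FIB-SEM volumes of macrophage–adipocyte interactions:

- **Surface / lysosomal LAMP-1 per cell** (tissue immunofluorescence, the
  lysosome-exocytosis readout): 5×5 Gaussian smoothing, an F4/80 (FITC)
  binary mask times the inverted calnexin (Cy5) mask to keep intact
  macrophages, applied to the LAMP-1 (Cy3) channel and normalized by the
  DAPI nucleus count:
  `LAMP1_per_cell = sum(Cy3 · [FITC > t₁] · ¬[Cy5 > t₂]) / N_nuclei`.
- **Ratiometric extracellular pH maps**: CypHer 5E (pH-sensitive) over
  Alexa488 (pH-insensitive) after 7×7 smoothing and background masking,
  inverted through a monotone calibration curve fit to buffer standards,
  with nuclear exclusion and clamp reporting.
- **Per-macrophage uptake and foam cells**: CtB-based cell labelling,
  adipocyte-contact gating, fluorescence *power* (the raw sum of pixel
  intensities within the cell boundary), and adaptive positivity calls
  (median + 3·MAD of control).
- **Sealed compartments in 3D EM**: intensity-band phase classification,
  26-connected lumen components, sealedness by flood-fill topology (no path
  to a volume face or to background), dual adjacency to macrophage and
  adipocyte phases, and physical volumes `voxels × dz·dy·dx` for anisotropic
  voxels (e.g. 20×10×10 nm).
- **Statistics**: per-day normalization to the control median, Wilcoxon
  rank-sum with an exact enumerated null for small samples (midranks under
  ties), pooled t-test, SEM summaries, and tidy comparison reports.
- **Seeded synthetic scenes with complete ground truth** for every assay —
  crown vs. dispersed geometry, permeable subpopulations, pH fields imaged
  through a known ratio response, per-cell uptake truths, and sealed/open
  EM cavities — so the whole pipeline is validated by parameter recovery.

Tabular results are tibbles throughout, with `tidy()`/`glance()` methods and
`autoplot()` for stacks, calibration curves, pH maps and compartment tables.

## Worked example

A self-contained in-silico version of the core tissue experiment — crown
macrophages generated with 2.2× the membrane LAMP-1 of dispersed (resident)
macrophages, 40 cells per arm at SNR 10, quantified blind to the truth:

```r
library(exoquant)

exp <- simulate_lamp1_experiment(n_cells = 40, fold_change = 2.2,
                                 snr = 10, seed = 7)
exp$fold_field    # field-level fold change (signal per cell, treated/control)
#> [1] 2.10433
exp$fold_per_cell # ratio of per-macrophage medians
#> [1] 2.395923
exp$p_value       # Wilcoxon rank-sum, treated vs control per-cell signals
#> [1] 1.843566e-09
```

The generated 2.2-fold surface-LAMP-1 difference comes back at the field and
the per-cell level, and the rank-sum test detects it decisively. The same
run as a reproducible pipeline with provenance-stamped CSV outputs:

```r
res <- run_pipeline(run_config(n_cells = 40, fold_change = 2.2, snr = 10,
                               seed = 7, out_dir = "lamp1_demo"))
res$report
#> # A tibble: 1 x 9
#>   metric          n_a   n_b statistic  p_value fold_change test_used normalized
#>   <chr>         <int> <int>     <dbl>    <dbl>       <dbl> <chr>     <lgl>
#> 1 surface_lamp1    34    32      1608  1.84e-9        2.40 rank_sum  TRUE
```

(34 and 32 cells remain after excluding calnexin-positive permeable
macrophages, drawn at the 22% tissue rate; a `config_hash` column ties every
row to the resolved run configuration.) Other assays follow the same
pattern, e.g. a pH map:

```r
field <- ph_pocket_field(c(192, 192), ph_ambient = 7.4, ph_pocket = 4.8)
scene <- generate_ph_scene(ph_scene_spec(field, alexa_level = 800,
                                         noise_sd = 40, seed = 1))
curve <- fit_calibration(calibration_standards(seq(4, 8, by = 0.5)))
pm    <- ph_map(ratio_image(scene$stack), curve)
glance(pm)
autoplot(pm)
```

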