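# enteromotion

Quantitative phenotyping pipelines for ex vivo gastrointestinal studies in
R. The package targets labs measuring how genetic models (e.g. *Shank3B*
mutant mice) alter gut structure and motility, and implements the full
computational side of that workflow:

- **Colonic moving contraction (CMC) analysis** — the core of the package.
  A spatiotemporal map (STMap) `D[r, t]` records colon diameter by position
  (rows, proximal at the top) and time (columns). The pipeline normalizes
  each row by its mean (removing banding, i.e. static baseline-diameter
  differences), smooths with an 8×8 Gaussian kernel (σ = 3 px, replicate
  borders), extracts band-averaged deviation profiles (proximal 5%
  initiation band + ten 10% tracking bands), detects peaks by MAD-scaled
  topographic prominence, and tracks each initiated contraction
  proximal→distal by nearest-time association. Per contraction it reports
  onset/end coordinates, span (% of colon length), velocity (mm/s),
  duration, and completion under the **>80% propagation rule**; per
  recording it reports counts, means, percent completed, and
  inter-contraction intervals. Contractions still propagating at the end
  of the recording are discarded.
- **Myenteric plexus density** — REAVER-style segmentation (background
  subtraction by large averaging filter, light blur, Otsu threshold,
  border cleaning, closing + size-limited hole fill) with component
  filters (area ≥ 1,200 px, mean skeleton thickness ≥ 8 px);
  density = plexus pixels / image pixels.
- **Ganglion quantification** — neuron counts (HuC/D) by smooth → threshold
  → distance-transform watershed inside polygon ROIs, and SHANK3 expression
  normalized to PGP 9.5 as a mask-mean intensity ratio.
- **FITC-Dextran permeability** — linear standard curve (OLS), triplicate
  sample inversion, dilution correction (1:7 plasma dilution → factor 8).
- **Group statistics** — per-animal aggregation, mean ± SEM, one-way and
  type-II two-way ANOVA with Tukey HSD (α = 0.05), via `aov`/`car`.
- **Synthetic generators** for every input type with exact planted ground
  truth (`simulate_stmap()`, `simulate_plexus_image()`,
  `simulate_ganglia_image()`, `simulate_plate_run()`,
  `simulate_group_data()`), so each stage is verifiable end to end without
  any archived recordings.

See `vignettes/methods.Rmd` for the models, parameter meanings, defaults
and their rationale, and known limitations.

## Worked example

Plant three CMCs (velocity 1.3 mm/s, span 90% of a 30 mm colon) into a
15-minute synthetic recording with realistic noise, then recover them:

```r
library(enteromotion)
tc  <- lapply(c(100, 300, 500), function(o)
  true_contraction(o, origin_frac = 0.02, span_frac = 0.9,
                   velocity_mm_s = 1.3, amplitude_frac = 0.5))
m   <- simulate_stmap(contractions = tc, noise_sd = 0.125, seed = 42)
fit <- cmc_analysis(m)
fit
#> CMC analysis: 3 contraction(s) in a 900 s recording (0 discarded as possibly unfinished)
#>   id onset_time_s onset_pos_mm end_time_s end_pos_mm span_pct velocity_mm_s
#> 1  1        100.5         0.75      118.9       25.5     82.5         1.301
#> 2  2        300.4         0.75      319.0       25.5     82.5         1.293
#> 3  3        500.1         0.75      518.9       25.5     82.5         1.298
#>   duration_s n_band_peaks completed
#> 1      18.39            9      TRUE
#> 2      18.57            9      TRUE
#> 3      18.77            9      TRUE
summary(fit)
#> Colonic motility summary
#>   recording 900 s, colon 30.0 mm
#>   contractions initiated : 3
#>   mean span              : 82.5 %
#>   completed propagation  : 100 %
#>   mean velocity          : 1.3 mm/s
#>   mean duration          : 18.6 s
#>   mean onset interval    : 200 s
```

All three planted contractions are found at their onsets (100, 300,
500 s); the recovered velocities are within 0.5% of the planted
1.3 mm/s. Spans read 82.5% rather than 90% because positions are
quantized to tracking-band centers (10% of colon length) — still above
the 80% completion threshold, so all three count as completed. `plot(fit)`
overlays the tracked trajectories on the map.

The other assays follow the same pattern, e.g.:

```r
seg <- segment_plexus(simulate_plexus_image(seed = 1)$image)   # density
cv  <- fit_standard_curve(c(0, 1, 2), c(0, 1000, 2000))
quantify_sample(cv, c(900, 1000, 1100), dilution_factor = 8)   # 8.0 ug/mL
run_demo(seed = 1)       # every assay on genotype-like presets, checked
```

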