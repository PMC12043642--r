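---
title: "Methods: quantitative GI phenotyping with enteromotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative GI phenotyping with enteromotion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enteromotion)
```

# Scope

`enteromotion` implements the computational readouts of an ex vivo
gastrointestinal phenotyping workflow: colonic moving contraction (CMC)
analysis on spatiotemporal diameter maps, myenteric plexus segmentation and
density, per-ganglion neuron counting and SHANK3/PGP 9.5 expression ratios,
FITC-Dextran permeability quantification, and grouped per-animal statistics.
Because raw videos, micrographs and plate readings of such studies are
rarely deposited, every input type has a synthetic generator that plants
exact ground truth; all validation in this package is against planted
truth, not against archived recordings.

# Spatiotemporal map model

An STMap is a matrix of colon diameters: rows are positions along the colon
(row 1 most proximal), columns are video frames, with calibration
`mm_per_row` and `s_per_frame`. A CMC appears as a stripe of reduced
diameter sweeping distally. The generator renders each planted contraction
as a Gaussian-in-time diameter reduction propagating at constant velocity:

$$D(r, t) = g_r \, D_0 \Big(1 - \sum_k a_k
  \exp\big(-\tfrac{(t - \tau_k(r))^2}{2 w_k^2}\big)\Big) + \varepsilon,$$

where $\tau_k(r)$ is the arrival time of contraction $k$ at position $r$
(linear in position at velocity $v_k$), $a_k$ is the fractional amplitude,
$w_k$ the temporal width at a fixed site, $g_r$ a static per-row
multiplicative banding gain, and $\varepsilon$ i.i.d. Gaussian noise. The
constant-velocity Gaussian stripe is the minimal parameterization that
reproduces the oblique bands seen in real maps while keeping every derived
metric (onset, span, velocity, duration) analytically known.

Default study conditions, used throughout the tests and the acceptance
script: a 30 mm colon sampled at 0.25 mm/row (120 rows), a 15-minute
recording at 1 frame/s (900 columns), baseline diameter 2.5 mm, contraction
amplitude 50% of baseline, temporal width 4 s, and contractions initiating
within the proximal 2% of the colon. These are typical of adult mouse colon
preparations; the noisy condition adds pixel noise with SD equal to 10% of
the contraction amplitude in diameter units.

# CMC detection pipeline

1. **Row normalization** divides each row by its mean. A static per-row
   gain (banding, from baseline diameter differences along the colon)
   cancels exactly: this is an algebraic identity, and the package tests it
   as an invariance (same counts, identical times) rather than a tolerance.
2. **Gaussian smoothing** correlates the map with an 8 × 8 kernel,
   $\sigma = 3$ pixels, borders replicate-padded. The even-sized kernel is
   centered at index `floor((h+1)/2)`, the square-kernel convention of the
   common numerical environments; the implementation is separable but is
   pinned by test to the direct 2-D convolution to 1e-12.
3. **Band profiles.** The initiation band is the proximal 5% of rows;
   ten contiguous 10% blocks tile the map. Each band's trace is the mean
   normalized intensity per frame; its deviation is `|trace − reference|`.
   The reference defaults to the trace median rather than the constant 1:
   when contractions occupy part of the recording, the row mean includes
   the dips, so quiescent segments sit at a small positive offset whose
   plateaus would otherwise acquire spurious prominence on clean maps. The
   constant-1 reference remains available
   (`detection_config(deviation_reference = "baseline")`).
4. **Peak detection.** Local maxima of the deviation trace with topographic
   prominence at least `prominence_k` × robust SD (1.4826 × MAD) of the
   band trace, thinned to a minimum separation of 5 s, with sub-frame
   parabolic refinement of peak times. `prominence_k` defaults to 6: at the
   default noise condition, band-trace noise extrema reach about 4.3 robust
   SDs over a 900-frame recording while genuine contraction peaks sit near
   30, so 6 separates the two populations with margin on both sides.
5. **Tracking.** Each initiation-band peak seeds a contraction; bands are
   scanned proximal→distal, associating the nearest-in-time peak within
   `[t_prev − 1 frame, t_prev + Δmax]`, `Δmax` = band length / `v_min`
   (default 0.1 mm/s, i.e. 30 s under the defaults). Each band peak can be
   claimed once. A *coverage gate* then drops trailing associated peaks
   whose height is below half the median associated-peak height: a band
   only grazed by the end of a contraction (or reached only by smoothing
   smear) produces a strongly attenuated peak whose band-center position
   would bias span and velocity by 5–20%.
6. **Metrics.** Onset is the initiation peak (time, initiation-band
   center); end is the last retained peak (time, its band center). Span is
   the onset→end distance as a percent of colon length — quantized to band
   centers, so it is reported at 10%-of-length resolution. Velocity is the
   endpoint formula applied over the propagation phase: from the *second*
   associated tracking band to the last when three or more bands were
   tracked. The initiation and first band overlap the birth site, where the
   band average mixes rows the contraction has not yet reached; measured
   from the second band onward the noise-free velocity error stays below 2%
   across velocities 0.3–2.0 mm/s. Duration is onset→end time. A
   contraction whose end lies within `end_margin_s` (default `Δmax`) of the
   end of the recording may not have finished propagating and is discarded
   before any summary, and a contraction *completes* if its span exceeds
   80% of colon length. Because measured spans are band-quantized
   (±7.5 points under the defaults at most), completion classification is
   exact whenever planted spans are at least one band away from the 80%
   threshold, which is how the completion tests are constructed.

The per-recording summary reports the contraction count, mean span, percent
completed, mean velocity, mean duration, and mean inter-onset interval;
with no contractions the means are reported as undefined (`NA`), never 0.

# Plexus segmentation

The segmentation follows the standard curvilinear-network recipe: a large
averaging filter (default 101 px) estimates background illumination, which
is subtracted; a light 3 px blur suppresses pixel noise; Otsu thresholding
produces the initial mask; a 3 px averaging filter re-binarized at 0.5
cleans ragged borders; morphological closing (disc radius 2) and hole
filling consolidate strands; finally components with area < 1,200 px or
mean thickness < 8 px are removed. Thickness is twice the mean Euclidean
distance-transform value sampled along the component's skeleton
(Zhang–Suen thinning) — the vessel-diameter convention — because a
bounding-box minimum side would misclassify long thin ribbons. Components
are 8-connected, since strands meet diagonally at junctions. Hole filling
is size-limited (default 64 px): large background regions enclosed by
crossing strands are genuine background, and filling them distorts density
by several percentage points. Density is the mask pixel count divided by
the image pixel count.

The filter boundaries are sharp by construction (area < 1,200 removed at
1,199, retained at 1,201; thickness 6 px removed, 12 px retained), and on
synthetic strand images with a ±30% illumination gradient and 5% noise the
recovered density stays within 2 percentage points of the planted truth
(typically within 0.7).

# Ganglion quantification

ROIs are polygons in pixel coordinates, rasterized by an even-odd
point-in-polygon test on pixel centers; no pixel outside the polygon
contributes to any statistic (the neuron channel is zeroed outside the ROI
before smoothing so no intensity can leak in through the blur). The
ganglion mask thresholds the PGP 9.5 channel inside the ROI; the expression
ratio is mean SHANK3 intensity over the mask divided by mean PGP 9.5
intensity, computed on raw intensities (no background subtraction), so it
is exactly invariant to joint rescaling and exactly linear in a
SHANK3-only rescaling. Neuron counting smooths the HuC/D channel
(Gaussian, σ = 2 px), thresholds inside the ROI, splits touching somata by
a distance-transform watershed, and drops regions under 50 px. This
deterministic detector replaces interactive, trained pixel classification,
which cannot be reproduced from a publication; it is parameter-light and
exact on disk-like somata, and the substitution is part of this package's
design, documented here rather than hidden. Animals are summarized by the
arithmetic mean over their unflagged ganglia.

# Permeability assay

The standard curve is an ordinary least-squares line of reading against
concentration over the standard wells, blank included, intercept free.
Samples are read in triplicate, averaged, inverted through the curve, and
multiplied by the dilution factor. Plasma "diluted 1:7" is read as 1 volume
plasma + 7 volumes PBS, hence a default factor of 8 (override to 7 via the
`dilution_factor` argument if the 1-in-7 reading is intended); both the
diluted and corrected concentrations are carried in the result. Readings
that invert below zero are clipped to 0 and flagged rather than reported
negative.

# Group statistics

Repeated measurements are first aggregated to one value per animal
(arithmetic mean), making animals the replication unit; summaries are mean
± SEM (sample SD / √n, n ≥ 2 required). One-way comparisons use standard
ANOVA with Tukey HSD for all pairwise groups at α = 0.05. Two-way designs
(genotype × region) use type-II sums of squares, the standard choice under
mild imbalance when the interaction is not the primary target, and apply
Tukey comparisons between genotypes within each region, mirroring
within-region brackets on grouped plots; a single-level region degenerates
exactly to the one-way analysis. These are deliberately thin wrappers over
`stats::aov`, `stats::TukeyHSD` and `car::Anova` — the statistics are
standard, and the package's tests pin them to hand-computed sums of squares
(the fixed worked example gives F = 27 on 2 and 6 df) and to a calibrated
type-I error rate (0.03–0.07 at α = 0.05 over 2,000 null simulations).

# What the synthetic data does and does not emulate

The generators reproduce the *geometry* the pipeline must recover:
propagating diameter reductions with banding and pixel noise; curvilinear
strands under uneven illumination with exact-area distractors;
non-overlapping disk somata with proportional channels; linear plate
responses with replicate noise; normal group-structured scalars. They do
not emulate peristaltic fluid dynamics, curved or moving preparations,
3-D confocal stacks, anisotropic point-spread functions, autofluorescence,
or non-normal biological variation. Passing the recovery tests therefore
demonstrates correctness of the computations under known ground truth, not
robustness to every artifact of real recordings; the config surface
(thresholds, windows, prominence, gates) exists precisely because real
data will need those dials.

# Numerical choices and degenerate inputs

Maps must be at least 20 × 50 with positive calibration; all-zero rows
refuse normalization by name; kernels larger than the map are refused; an
empty contraction list yields an `NA`-flagged summary, not zeros. Peak ties
are resolved strongest-first under the separation constraint; watershed
tolerance defaults to 1 intensity unit. The simulation sizes used by the
tests and acceptance script (120 × 900 maps; 600 × 600 plexus images;
400 × 400 ganglion fields; 20-seed replications; 2,000 null ANOVA
simulations) were chosen to exercise every code path at full fidelity while
keeping a complete validation run in the low minutes on a single core.

# Known limitations

Span resolution is one tracking band (10% of colon length); sub-band
refinement is deliberately omitted from the defaults. Velocity assumes
near-constant propagation speed; strongly accelerating contractions are
summarized by an average. Retrograde contractions, ripples and
segmentation-type motor patterns are out of scope, as are vessel-topology
metrics beyond density and any emulation of trained pixel classifiers.
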