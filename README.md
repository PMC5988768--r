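# psoct

Simulation and quantification of cartilage birefringence for
polarisation-sensitive optical coherence tomography (PS-OCT).

Early cartilage degeneration is fibrillar-scale destructuring of the collagen
network in tissue that still looks normal. PS-OCT sees collagen organisation
through birefringence, but bovine cartilage imaged normal to its surface is
nearly isotropic — unless it is mechanically indented, which reorients the
fibres and makes healthy tissue strongly birefringent while degenerate tissue
stays dull. The discriminating quantity is the **birefringence coefficient
(BRC)**: the retardation gradient of the depth-resolved phase profile,

```
R(z) ∝ A_V(z)² + A_H(z)²          (reflectivity)
δ(z) = arctan(A_V / A_H) ∈ [0, π/2]   (retardation, π/2 phase wrap)
BRC  = Σ |δ[i+1] − δ[i]| / depth   (rad/mm, smoothed profile)
```

This package contains, for R:

* a **Jones-calculus simulator** of a 1310 nm two-channel PS-OCT system
  (QWP circular incidence, orthogonal channel split, Rayleigh speckle,
  π/2 wrap) imaging channel-indented cartilage blocks with grade presets
  (G0 intact / G1 mild / G2 moderate degeneration) calibrated to published
  group statistics;
* the **BRC pipeline**: surface detection, maximum-depth thresholding,
  10-A-scan window averaging, running-average smoothing, cumulative
  |Δphase|/depth with n = 1.36 depth calibration, aggregated over 5 adjacent
  B-scans;
* the **group statistics**: one-way ANOVA and Tukey HSD across grades per
  imaging plane, with a formatted summary table;
* a virtual **Berek-compensator experiment** validating the phase
  measurement against theory.

Everything is tidyverse-flavoured: per-sample results are tibbles,
fitted/derived objects have `tidy()`/`glance()` methods, result types have
`autoplot()`.

## Worked example

```r
library(psoct)

preset <- grade_presets(config = "XZ_indented", grade = "G0")
tissue <- make_tissue(preset, seed = 3)            # draws this specimen's true BRC
volume <- simulate_volume(tissue, acquisition_params(), n_bscans = 5, seed = 3)
res <- compute_sample_brc(volume, default_center_ascan(tissue))
res
#> <brc_result> BRC 3.080 rad/mm over 5 B-scans (per-B-scan: 2.983, 3.050, 3.217, 3.003, 3.149)
#>   simulation truth: 3.165 rad/mm
```

The specimen's ground-truth gradient was drawn as 3.165 rad/mm from the G0
indented preset (mean 3.0, SD 0.5 rad/mm); the pipeline recovers
3.080 rad/mm through speckle, folding and thresholding — within a few
percent, which is the scale of the smoothing/noise bias the methods vignette
quantifies. `tidy(res)` shows the five per-B-scan values with the detected
surface (pixel 91) and maximum depth (image bottom, pixel 256).

A full study — 10 G0, 8 G1, 8 G2 specimens in three imaging planes, plus
ANOVA and post-hoc tables laid out like the published summary table — is one
call:

```r
study <- replicate_study(study_config(seed = 1))
study$summary      # grade × plane means ± SD, ANOVA p, Tukey stars
autoplot(study)    # boxplots by grade, one panel per plane
```

A thin CLI over the same functions (subcommands `simulate`, `reconstruct`,
`brc`, `stats`, `replicate-study`) ships at `inst/cli/psoct.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the headline replication quantities from scratch: it simulates
the 26-specimen indented-configuration study 20 times with the default
presets, runs the full pipeline on every volume, and writes the majority
(median) one-way ANOVA p-value across grades and the mean recovered G0
retardation gradient. Runtime is a few minutes on one CPU.
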