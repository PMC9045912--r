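# jmoct

Polarization-sensitive optical coherence tomography (OCT) resolves not
only how strongly tissue scatters light but how it transforms the light's
polarization state. `jmoct` implements the analysis chain used to
characterize tissue with a Jones-matrix OCT (JM-OCT) system — for example
to contrast tumor against healthy tissue in small-animal imaging — plus
the reconstruction and mosaicking steps of an accompanying
spectral-domain OCT (SD-OCT) system. Because raw JM-OCT measurements are
rarely shareable, the package also ships a full synthetic-phantom forward
model with known ground truth, so every stage is testable end to end
without any external data.

It is aimed at researchers building or validating PS-OCT processing
pipelines, and at anyone who needs a reference implementation of these
estimators with documented conventions.

## What it computes

From a volume of per-voxel 2×2 complex Jones matrices `J(z, x, y)`:

- **Scatter intensity** — the mean absolute-squared value of the four
  matrix entries (the four polarization channels),
  `I = (|J₁₁|² + |J₁₂|² + |J₂₁|² + |J₂₂|²)/4`, linear or dB.
- **Depth-resolved attenuation coefficient** — per-pixel tail
  normalization, `µ(i) = I(i) / (2Δ Σ_{j>i} I(j))` with Δ the pixel pitch
  in mm, assuming full attenuation within the recorded depth.
- **Local birefringence** — from the local matrix
  `L(z) = J(z+d) J(z)⁻¹`, the round-trip retardation
  `δ = |arg λ₁ − arg λ₂|` of its eigenvalues (wrapped to [0, π]),
  converted to `Δn = δ λ₀ / (4π d Δz)`. A maximum a posteriori variant
  corrects the positive noise bias near δ = 0 using a Monte-Carlo
  tabulated likelihood at the measured local SNR, and every pixel carries
  a reliability in [0, 1].
- **DOPU** — degree of polarization uniformity: the length of the
  kernel-averaged normalized Stokes vector, averaged over the two
  incident channels; 1 = polarization preserving, → 0 = scrambling.

Around these sit: an SD-OCT reconstructor (k-linearization → Gaussian
spectral shaping → polynomial dispersion compensation → average-spectrum
subtraction → FFT), phase-correlation tile registration and
feather-blended stitching for translation-stage mosaics, region
statistics (per-B-scan means under binary masks, box-whisker summaries,
hand-rolled Mann–Whitney U with exact small-sample enumeration, Levene's
test), and reliability-gated pseudo-color renderings.

## Worked example

Simulate a tumor/control dataset (muscle-like control region; tumor with
lowered birefringence, lowered scrambling, raised attenuation), compute
the contrasts, and test the regions:

```r
library(jmoct)

ds <- generate_tumor_control_dataset(n_bscans = 16, seed = 7)
contrasts <- compute_contrasts(ds$volume, noise_floor = ds$noise_floor)
report <- quantify_regions(
  contrasts[c("attenuation", "birefringence", "dopu")], ds$masks)
tidy(report)[, c("contrast", "u", "p_mann_whitney", "p_levene", "direction")]
#> # A tibble: 3 × 5
#>   contrast          u p_mann_whitney p_levene direction
#>   <chr>         <dbl>          <dbl>    <dbl> <chr>
#> 1 attenuation     256     0.00000154    0.811 tumor > control
#> 2 birefringence     0     0.00000154    0.448 tumor < control
#> 3 dopu            256     0.00000154    0.306 tumor > control

glance(report)
#> # A tibble: 1 × 5
#>   n_bscans n_contrasts n_significant_mw n_significant_levene alpha
#>      <int>       <int>            <int>                <int> <dbl>
#> 1       16           3                3                    0  0.05
```

Each row compares the per-B-scan region means of one contrast between the
two labels (16 B-scans per group). `u` is the Mann–Whitney statistic of
the first (tumor) sample — 0 and `n1·n2 = 256` are the extremes, meaning
complete separation; with the default effect the tumor region shows lower
birefringence, higher DOPU and higher attenuation than control, each with
p ≈ 1.5e−6. `autoplot(report)` draws the corresponding box-whisker
panels with the individual B-scan means overlaid.

## Layout

- `R/` — phantom simulator, contrasts, SD-OCT, mosaicking, statistics,
  rendering, TIFF/JSON/YAML I/O
- `tests/testthat/` — unit, property and end-to-end tests with
  independent oracles
- `vignettes/jmoct-methods.Rmd` — models, conventions, parameter
  defaults and limitations
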