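---
title: "Models and methods behind jmoct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind jmoct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jmoct)
```

This vignette documents the measurement model, the estimators, the
synthetic-data forward model, and the numerical and design choices the
package makes — in particular where several defensible conventions exist
and one had to be fixed.

## The measurement model

A Jones-matrix OCT system measures, per voxel, a complex 2×2 matrix
describing the round-trip polarization response of the sample at that
depth. For a reciprocal medium the round-trip matrix has the transpose
symmetry $J_{meas}(z) \propto J_{cum}(z)^T J_{cum}(z)$, where
$J_{cum}(z)$ is the one-way cumulative Jones matrix from the surface down
to $z$. Two consequences the package relies on:

- the round-trip retardation accrued over a depth interval is **twice**
  the single-pass value, which is why the birefringence conversion
  divides by $4\pi$ rather than $2\pi$;
- the measured matrix is symmetric, so the simulator only needs to
  synthesize $J_{11}, J_{12} = J_{21}, J_{22}$.

The measured matrix is additionally scaled by an unknown complex speckle
amplitude per voxel and embedded between unknown system matrices
(fibers, optics). All estimators in the package are built exclusively
from quantities invariant to those nuisances: entry power sums
(intensity), eigenvalue phase differences of matrix ratios
(birefringence), and per-voxel-normalized Stokes vectors (DOPU).
Eigenvectors of the local matrix are never used, since the unknown
system birefringence turns the local matrix into a similarity transform
of the true one; optic-axis estimation is therefore out of scope.

## The four contrasts

**Scatter intensity.** The mean of the four channel powers,
$I = (|J_{11}|^2+|J_{12}|^2+|J_{21}|^2+|J_{22}|^2)/4$. The dB variant is
referenced to the volume maximum unless a reference is supplied; display
code uses a default range of [−30, 0] dB.

**Attenuation.** The depth-resolved tail-normalization estimator
$\mu(i) = I(i) / (2 \Delta \sum_{j>i} I(j))$ with $\Delta$ the axial
pitch in mm. Its core assumption is that the beam is fully attenuated
within the recorded depth; no tail extrapolation is attempted, the
deepest pixel (empty tail) is masked `NA` rather than returned infinite.
On a discrete noiseless exponential the estimator converges to
$(e^{2\mu\Delta}-1)/(2\Delta)$, not exactly $\mu$ — a discretization bias
of $+\mu\Delta$ to first order (≈0.7% per mm⁻¹ at 7.24 µm pitch), which
the tests treat as the documented reference value. The estimator is
scale-invariant, so uncalibrated intensities are fine.

**Local birefringence.** The local matrix $L(z) = J(z+d)\,J(z)^{-1}$
cancels everything above $z$; the round-trip local retardation is the
wrapped eigenvalue phase difference $\delta \in [0, \pi]$, and
$\Delta n = \delta \lambda_0 / (4\pi d \Delta z)$. To express the result
as retardation per length: $\Delta n = 1\times10^{-3}$ at
$\lambda_0 = 1.31\,\mu m$ corresponds to
$360\,\Delta n/\lambda_0 \approx 0.27$ deg/µm single-pass. The default
depth separation is $d = 2$ pixels (14.5 µm at the 7.24 µm pitch) — small
enough to stay local, large enough that the per-interval retardation of
muscle-like tissue rises above the noise floor; it is exposed as an
argument.

The naive eigen-phase estimator is positively biased at low retardation:
noise always pushes $|\arg\lambda_1 - \arg\lambda_2|$ away from zero. The
**MAP estimator** addresses this with an explicitly simulation-based
noise model: for a grid of 256 true retardations on $[0, \pi]$ and a set
of SNR bins (5–40 dB), the distribution of the observed eigen-phase
difference under additive complex Gaussian noise on the Jones entries is
tabulated by Monte Carlo (2000 draws per grid point, fixed tabulation
seed, cached). With a flat prior, the posterior over true retardation
given the observed bin is a normalized likelihood column; the estimator
returns the posterior mode, and **reliability** is the posterior mass
within ±0.1 rad of that mode. This construction is validated by its
bias-reduction property (the package tests assert the MAP mean is below
the naive mean on zero-birefringence phantoms at 20 dB), not by identity
with any particular published closed form. Pixels whose local SNR falls
below the tabulated range, or whose $J(z)$ is numerically singular, are
returned `NA` with reliability 0.

**DOPU.** Per incident channel (column of $J$) the normalized Stokes
vector $(q, u, v)$ is averaged over a centered kernel and its length
taken; the output is the mean of the two channels. The default kernel is
3 (axial) × 5 (lateral) pixels — 15 voxels spanning several speckle
grains at the stated pitches while limiting axial blur; both sizes are
arguments and must be odd. Zero-intensity voxels are excluded from the
kernel mean, and kernels are truncated at volume borders rather than
padded. For fully random per-speckle states the kernel mean follows the
resultant-length law of isotropic unit vectors
($E[R] \approx \sqrt{8/(3\pi n)}$, ≈ 0.24 for $n = 15$) — the package
tests check this against a Monte-Carlo oracle rather than a closed form.

## The phantom forward model

`generate_phantom()` builds layered media in which every downstream
estimate has a known target:

- each depth pixel is a linear retarder with single-pass retardation
  $2\pi\,\Delta n\,\Delta z/\lambda_0$ at the layer axis; the cumulative
  product and the transpose-symmetric round trip give the deterministic
  per-depth matrix;
- fully developed speckle: a circular complex Gaussian amplitude per
  voxel with mean power equal to the layer reflectivity attenuated by
  $\exp(-2\int\mu\,dz)$ (the surface pixel unattenuated, so the mean log
  power slope is exactly $-2\mu$ per physical depth);
- polarization scrambling with index $s$: each voxel independently, with
  probability $s$, replaces the deterministic round trip by a random
  symmetric unitary whose output state is uniform on the Poincaré
  sphere (a unit spinor with i.i.d. complex-normal components completed
  to a symmetric unitary). $s=0$ preserves the state exactly; $s=1$
  reproduces the isotropic resultant-length law; the expected DOPU
  recorded in the ground truth is $1-s$ (exact in the large-kernel
  limit);
- additive complex white Gaussian noise on each entry, with power set by
  `snr_db` relative to the first layer's mean power under the intensity
  convention above ($I_{signal} = P/2$ for a unitary round trip of mean
  power $P$). Sensitivity roll-off is not simulated.

Default acquisition constants are a 1310-nm swept-source system with a
7.24 µm depth pixel separation; the SD-OCT fringe generator defaults to
an 840-nm spectrometer system with a 2.5 µm reconstructed pitch. The
same seed always produces bit-identical volumes.

What the phantoms deliberately do **not** emulate: galvo/stage motion
artifacts, sensitivity roll-off (a linear dB/mm option would be a
straightforward extension), multiple scattering (scrambling is drawn
per speckle, not propagated), refraction at tissue interfaces, axis
variation within a layer, and sample-arm optics. Tests passing on these
phantoms therefore demonstrate estimator correctness under the stated
model, not robustness to every artifact of in-vivo data.

The `generate_tumor_control_dataset()` defaults encode a muscle-like
control region ($\Delta n = 1.5\times10^{-3}$, scrambling 0.25,
$\mu = 2$ mm⁻¹) and a tumor region shifted by
$(-1\times10^{-3}, -0.15, +1\;\mathrm{mm^{-1}})$ at 25 dB SNR — the
direction of the reported tumor effects (lower birefringence, higher
DOPU, higher attenuation). The magnitudes are free parameters of the
synthetic study: the in-vivo effect sizes exist only as figure-level box
plots and were not calibrated against; the package claims direction-of-
effect reproduction, not effect-size reproduction.

## SD-OCT reconstruction

The chain is applied in a fixed order: cubic-spline resampling onto a
uniform wavenumber grid, Gaussian spectral shaping, multiplication by
$\exp(-i(a_2(k-k_0)^2 + a_3(k-k_0)^3))$, subtraction of the across-A-line
mean spectrum, FFT, squared modulus of the positive-frequency half.
Choices the data did not dictate: interpolation kind (cubic spline;
linear grids reconstruct identically with resampling on or off), window
center (spectrum center) and width (half the sampled band, as a standard
deviation), and treating the dispersion coefficients as known inputs —
no automatic dispersion search. Because the mean-spectrum subtraction is
linear and sits after all per-A-line multiplications, any static
component common to all A-lines cancels exactly; consequently a single
static reflector common to all A-lines cancels too, which is why
single-A-line fixtures disable the subtraction.

## Mosaicking

Registration is phase correlation of en-face projections with the argmax
restricted to a window around the nominal stage offset, integer-pixel
only: at 5% overlap the information for subpixel refinement is marginal
and stage repeatability dominates. Confidence is the ratio of the chosen
peak to the strongest peak elsewhere on the correlation surface; flat
overlaps return confidence 0 and the nominal offset. Global layout
chains consecutive pairwise offsets in acquisition order (adequate for
short strips; a least-squares adjustment over all pairs is the natural
extension for large grids and is not implemented). Feathering weights
each tile by its distance to its own border and normalizes per canvas
pixel, so weights sum to exactly 1 wherever any tile contributes; on
exact offsets the overlap content is identical in both tiles and the
mosaic equals the source scene to rounding. One practical sizing note:
with ~5% overlap, reliable registration needs the overlap strip to
contain a reasonable number of independent texture grains — the tests
use 512-pixel tiles (26-pixel overlaps) for this reason.

## Region statistics

The quantification follows the B-scan-wise protocol: binary masks select
a region per B-scan, the per-B-scan mean of each contrast (excluding
`NA` voxels) is one data point, and the two labels are compared with a
Mann–Whitney U test and a Levene test at α = 0.05, without
multiple-testing correction across contrasts.

Conventions fixed here, since several exist:

- **Mann–Whitney**: U from midrank sums; exact two-sided p by full
  enumeration of rank assignments when $n_1+n_2 \le 16$ and the pooled
  data are tie-free; otherwise normal approximation with tie-corrected
  variance and continuity correction. Degenerate pooled samples give
  p = 1.
- **Levene**: classic mean-centered form (ANOVA F on absolute deviations
  from the group mean), with the median-centered Brown–Forsythe variant
  as an option.
- **Box-whisker**: quartiles by linear interpolation (R quantile type
  7); whiskers at the most extreme points within 1.5 IQR of the box,
  points beyond flagged as outliers. A caption reading "maximum and
  minimum values" alongside drawn outlier crosses is self-contradictory;
  the 1.5 IQR rule is the convention consistent with showing outliers,
  and the multiplier is an argument.
- Whether B-scans should be pooled across animals is a study-design
  question; `quantify_regions(animal_id = ...)` reports both the pooled
  and the per-animal tests, labelled by scope.

## Rendering

The pseudo-color birefringence tomogram gates on reliability: hue from
$\Delta n$ over a value range (default [0, 2×10⁻³]), brightness from
clipped dB intensity, gray where unreliable (threshold default 0.7). The
DOPU composite colors only pixels above an intensity floor (default
−25 dB), leaving background gray. The hue palettes of the original
figures are not published; the defaults (blue→red HSV ramps) are
recorded, together with ranges and thresholds, in each image's legend
metadata, and re-running with the legend parameters reproduces the image
bit-exactly — faithfulness is in the gating logic, not the palette.

## Numerical choices and degenerate inputs

- Eigenvalues of 2×2 matrices are computed from the closed form
  $(\mathrm{tr} \pm \sqrt{\mathrm{tr}^2 - 4\det})/2$, vectorized over
  the volume; the eigen-phase difference is wrapped into $[0, \pi]$.
- Local matrices with $|\det J(z)|$ below $10^{-12}$ of the entry scale
  are treated as singular (below noise floor) → `NA`, reliability 0.
- Attenuation with a non-positive tail sum is `NA`, never `Inf`.
- The likelihood tables add a small smoothing constant ($10^{-3}$ per
  histogram bin) so empty bins cannot produce degenerate posteriors.
- Volume I/O stores 32-bit TIFF samples with an affine offset/scale in a
  JSON sidecar (the installed TIFF backend has no float sample format);
  round-trip relative error is ~1e−9, and sample value 0 is reserved to
  encode `NA`.

## Problem sizes

The test-suite and acceptance-script simulations are sized to give each
statistical check comfortable resolution while staying quick on one
core: attenuation phantoms of 400×64 A-scans (2.9 mm depth, so the
full-attenuation assumption holds even at µ = 1 mm⁻¹), a 36×1440
fully-scrambled volume (≈ 49 000 full DOPU kernels against a
20 000-replicate oracle), 1024-sample spectra, 256×1484 stitching
scenes, 2000 Mann–Whitney null replicates, and 32 B-scans per group for
the tumor/control analysis. The whole suite runs in well under a minute.

## Known limitations

- Attenuation estimates carry the documented discretization bias and,
  with speckle, a per-pixel relative error of roughly
  $1/\sqrt{N_{avg}}$; the 64-A-scan averaging used in the recovery
  checks leaves a ~8–10% median error, dominated by speckle, not by the
  estimator.
- The MAP noise model conditions on a binned point estimate of local
  SNR and ignores speckle amplitude variation between the two depths of
  the local pair; it is an approximation designed to remove the zero-
  retardation bias, not a full posterior over the imaging chain.
- Cumulative (non-local) phase retardation, optic-axis orientation,
  refraction correction, vignetting correction and nonrigid registration
  are out of scope.
- The tumor/control generator produces spatially homogeneous regions;
  real tumors are heterogeneous, which the per-B-scan variance of real
  data reflects and these phantoms do not.
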