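---
title: "opticyto: methods and modeling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{opticyto: methods and modeling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opticyto)
```

## The problem

Flow cytometry is the reference technique for per-cell fluorescence
readouts, but it destroys spatial context and requires detaching the cells.
A fluorescence microscope observing the same dye-loaded cultures produces
images from which per-cell intensities can be extracted computationally —
if segmentation, quantification and histogram analysis are done carefully,
the microscope delivers flow-cytometry-like distributions and the same
group-level conclusions. `opticyto` implements that computational pathway
and, because no public imaging/flow dataset accompanies it, ships a
synthetic-data generator with full ground truth so that every stage is
validated by parameter recovery rather than by eye.

## Segmentation model

An acquired frame is a matrix of normalized intensities in $[0,1]$ with a
physical pixel pitch (default $1/2.7 \approx 0.37$ µm/px, the resolution
regime of a 20× benchtop fluorescence imager). Integer images are
normalized by the *dtype full scale* (255 or 65535), never by the per-image
maximum: acquisition at fixed gain, contrast and illumination makes
intensities comparable across frames, and per-image normalization would
destroy exactly that comparability.

**Thresholding.** Foreground is separated by global minimum cross-entropy
(Li) thresholding. Intensities are quantized to `n_bins` bin centers $g$
with histogram $h(g)$; for a candidate boundary $t$ the cost of replacing
each side by its intensity-weighted mean is
$$\mathrm{cost}(t) = -\sum_{g<t} g\,h(g)\ln\mu_{low}(t)
                     -\sum_{g\ge t} g\,h(g)\ln\mu_{high}(t),$$
and the minimizing boundary is the threshold. Candidates with an empty side
are skipped; ties break toward the smaller boundary; a constant image is a
degenerate-histogram error. The default `n_bins = 256` matches the 8-bit
quantization of typical exports; the implementation is an $O(n)$
cumulative-sum scan, and the test suite verifies it against a brute-force
evaluation of the cost at every boundary — the definition itself — on
dozens of random images at 64 and 256 bins.

**Labeling and declumping.** Connected components are labeled at 8- or
4-connectivity (default 8). At realistic plating densities neighboring
cells touch, so declumping is on by default: seeds are local maxima of the
Gaussian-smoothed distance transform (smoothing `declump_smooth_sigma`,
default 2 px), thinned so no two seeds are closer than
`declump_min_sep_um` (default 9 µm — half the smallest gateable cell; two
genuine cell centers cannot be closer), then labels grow from the seeds by
seeded watershed on the negated distance transform within the mask.
Components that end up without a seed keep their own label rather than
vanishing.

**Gating.** Objects are kept iff their equivalent diameter
$2\sqrt{A/\pi}\cdot\mathrm{pitch}$ lies in $[d_{min}, d_{max}]$ µm, bounds
inclusive, defaults 18 and 38 µm. The physical gate is canonical; at the
default pitch it corresponds to roughly 50–100 px. Workflows that would
hand objects outside the gate to a human reviewer are replaced by exclusion
plus a reported removed-count — a pipeline cannot reproduce a
human-in-the-loop step, but it can account for it. The gate is idempotent
and conserves objects (kept + removed = total), both tested.

**Measurement.** One record per cell: pixel area, equivalent diameter,
centroid, and the arithmetic mean intensity over the whole cell region — no
nuclear/cytoplasmic compartmentalization and no background subtraction.
The 8-bit value is exactly $255\times$ the normalized mean; no integer
rounding is applied anywhere, because quantizing before density estimation
would bias the histogram metrics.

## Histogram characteristics

Within each group × modality cell, intensities are pooled (cells from all
frames of a group, matching the convention that mean/median describe "all
cell populations"; per-frame averaging is the statistical layer's job, not
the histogram's) and summarized by:

- **peak**: argmax of a Gaussian-kernel density estimate with
  normal-reference bandwidth $h = 1.06\,s\,n^{-1/5}$ on a 512-point grid
  spanning $[\min - 3h, \max + 3h]$; ties break to the smallest grid value.
- **FWHM**: distance between the leftmost upward and rightmost downward
  crossings of half the peak density, bracketing the global peak, each
  located by linear interpolation between grid points. Multimodal curves
  therefore get a single FWHM tied to the global mode — a documented
  limitation, and the reason a far, light outlier cannot widen it.
- **mean**, **median**: computed from the raw sample, not the KDE.

A zero-variance or $n<2$ sample is an explicit error instructing the caller
to report raw values. The estimator's closed-form behavior — a Gaussian KDE
of Gaussian data is $N(\mu, \sigma^2 + h^2)$, so FWHM
$= 2.3548\sqrt{\sigma^2+h^2}$ — anchors the accuracy tests, and
scale/shift equivariance of all four metrics is tested as a property.

Group effects are expressed as relative changes,
$100\,(v_{group}-v_{control})/v_{control}$, flagged undefined when the
control value is 0, and the two modalities are joined metric-by-metric into
a concordance table with a sign-agreement flag (an exact zero agrees with
anything) and the magnitude ratio $|flow|/|imaging|$.

## Statistical layer

Two groups are compared by the classical equal-variance Student's
$t$-test, three or more by fixed-effects one-way ANOVA
($F = t^2$ with identical $p$ in the two-group case, tested to $10^{-12}$),
two-sided at $\alpha = 0.05$. The statistical unit is the per-frame mean
for imaging and the per-tube mean for flow — the number of independent
replicates is the number of frames (10–20 per group) or tubes (3–6), and
testing pooled per-cell values would inflate significance by an order of
magnitude. No multiple-testing correction is applied by default (a
Bonferroni option exists), mirroring the single-comparison-per-readout
design. Degenerate inputs follow fixed conventions: zero pooled variance
with equal means is a vacuous comparison ($p = 1$); with unequal means it
is an error rather than a silent infinity.

## The synthetic generator

The generator emulates the acquisition regime the pipeline targets, with
every default chosen once from that regime:

| parameter | default | rationale |
|---|---|---|
| frame | 1000 × 750 px | the random analysis-window size |
| pitch | 1/2.7 µm/px | ~1 µm optical resolution over ~2.7 px |
| frames per group | 15 | middle of the 10–20 used per group |
| cells per frame | 45 | ~28% area coverage; ~675 cells/group, the 10³ order of magnitude of imaging populations |
| cell diameters | U(18, 38) µm | spans the gate exactly |
| per-cell intensity | lognormal, median 0.35, sdlog 0.2 | right-skewed unimodal, comfortably inside (0, 1] |
| fold changes | control 1, treated 1.3 | a clearly detectable but not trivial shift |
| PSF sigma | 1 px | sub-resolution blur of a well-focused system |
| shot noise | 5000 photons at full scale | Gaussian approximation to Poisson |
| read noise | 0.002 (normalized) | 16-bit scientific-camera scale |
| microscopy SBR | 20 (glucose-like) / 80 (MMP-like) | the two channels' contrast regimes |
| flow events | 20,000 per group, 4 tubes | flow-scale populations, 3–6 samples/group |
| flow noise | lognormal, sdlog 0.15 | narrower than the biological spread |
| flow SBR | 10 (glucose-like) / 1000 (MMP-like) | baseline = control mean / SBR |

Cells are non-overlapping disks placed by seeded dart-throwing (largest
first, minimum edge gap 2 px, feasibility pre-check at ≤40% coverage of the
frame) — shape realism is irrelevant to intensity analytics, while
ground-truth masks must be unambiguous. Frames are rendered as plateau
disks on a uniform background, blurred, and corrupted by signal-dependent
Gaussian noise plus read noise, clipped to $[0,1]$.

**SBR calibration.** The background level starts at
$\bar I_{cell}/\mathrm{SBR}$, but the *measured* in-cell/background ratio
of a rendered frame is lower than that construction implies: the PSF
spills cell signal into the background, and zero-clipping biases dim
backgrounds upward. The generator therefore calibrates the background with
two fixed-point steps on a rendered calibration frame, so the measured
ratio matches the configured SBR (within ~±7% across seeds, dominated by
per-frame sampling of cell intensities). The flow baseline
$b = \bar I_{control}/\mathrm{SBR}_{flow}$ is added to every event; note
that it compresses flow relative changes by a factor
$1/(1+1/\mathrm{SBR}_{flow})$ — a +30% true shift reads out as ≈ +27% at
SBR 10, which is modeled instrument behavior, not an artifact.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: irregular cell morphology and
intensity gradients within cells, spatially varying illumination and
vignetting, focus drift, debris and dead-cell fluorescence, density-driven
biological effects, spectral cross-talk, and any gating subtlety beyond a
single size gate. Recovery results on synthetic data bound the pipeline's
*algorithmic* error, not its robustness to optical artifacts.

## Numerical and design details

- All RNG flows from one master seed; pipeline stages derive child seeds by
  a fixed affine map, so each stage is independently reproducible and two
  runs are byte-identical (tested on the emitted CSV bytes).
- CSV dialect is frozen (comma, `.` decimal, `\n`); images are written as
  32-bit TIFF (round trip exact to ~2·10⁻¹⁰) and label masks as 16-bit
  TIFF.
- FCS support is a deliberate minimal subset: list-mode, single data
  segment, `$DATATYPE` F/I, both byte orders; compensation and analysis
  segments are ignored.
- 8-connectivity is built from 4-connected components by merging diagonal
  neighbors via union-find.
- Threshold ties break toward the smaller boundary; KDE peak ties toward
  the smaller grid value; the crop corner is drawn uniformly over the valid
  grid (verified by a χ² test on the corner marginals).
- The test suite and calibration checks run at deliberately chosen desk
  scales: recovery tests use 10 frames of 500 × 375 px with 12 cells each
  (counts within ±5% of truth; recovered-vs-true intensity regression slope
  0.93), and the SBR calibration checks render one full-size default frame
  per channel.

## Known limitations

- FWHM is tied to the global mode; strongly bimodal distributions get the
  width of their dominant mode only.
- Declumping uses a pure distance-transform (shape) criterion; intensity-
  guided splitting is not implemented, so dumbbell-shaped debris may split
  where a human would not.
- The equal-variance $t$-test is used by design; with strongly unequal
  per-group spreads a Welch correction would be more appropriate than the
  classical test implemented here.
- Imaging relative changes are computed from segmented means, which blur
  slightly toward the background; at the default PSF this attenuates
  recovered per-cell intensities by ~5–8% (slope ≈ 0.93) but cancels almost
  entirely in *relative* changes between groups.
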