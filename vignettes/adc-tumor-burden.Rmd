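---
title: "Quantifying skeletal tumour burden on whole-body DWI: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying skeletal tumour burden on whole-body DWI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wbdwi)
```

## The problem

Bone metastases from breast and prostate cancer are often widespread, and
their response to systemic therapy is poorly captured by measuring a few
index lesions. Whole-body diffusion-weighted MRI (WB-DWI) makes the visible
tumour burden quantifiable: active marrow lesions restrict water diffusion
less than normal fat-rich marrow but more than necrotic tissue, so the
apparent diffusion coefficient (ADC) separates the three. A semi-automated
workflow — segment the skeleton on a high-b-value image, then isolate
lesions by an ADC window, then summarise the lesion ADC distribution —
yields per-examination statistics whose *changes* carry clinical meaning
(a rise of 25% or more in mean lesion ADC is the conventional signal of
response). Whether those statistics are trustworthy depends on how much
they vary when different observers, or the same observer on different days,
perform the segmentation. `wbdwi` implements both the quantification
pipeline and the agreement analysis, with a synthetic phantom supplying the
ground truth that clinical archives cannot.

## Signal model and ADC fitting

Each voxel is modelled as a mono-exponential decay
$S(b) = S_0 e^{-b \cdot \mathrm{ADC}}$. The assumptions are the usual ones
at moderate b-values: Gaussian diffusion (no kurtosis term), no perfusion
compartment (the lowest b of 50 s/mm² already suppresses most of the IVIM
pseudo-diffusion signal), and magnitude images whose noise is Rician.

`fit_adc()` uses the closed form
$\mathrm{ADC} = \ln(S_{b_1}/S_{b_2})/(b_2 - b_1)$ for two b-values and
ordinary least squares on $\log S$ versus $b$ for more. The fitted
coefficient (mm²/s) is converted to µm²/s exactly once, at the fit boundary
(factor $10^6$), because every downstream threshold is quoted in µm²/s.

Two rules handle non-physical voxels, and both flag rather than guess:

* any non-positive signal → `valid = FALSE`, value 0 (no logarithm exists);
* a negative fitted slope (signal rising with b, possible under noise) →
  clamped to 0 and `valid = FALSE`. A perfectly flat decay is a legitimate
  ADC of 0 and stays valid.

Vendor tools do not document their treatment of these voxels; the rule above
is this package's own, chosen so that every excluded voxel is auditable via
the validity volume. Invalid voxels are excluded from the lesion class and
from all statistics.

`synthesize_computed_b()` extrapolates the fitted decay from the lowest
acquired b-value. With a two-point fit this reproduces an acquired volume
when `b_target` equals its b-value — an identity the test suite asserts at
double precision (the fit is an exp/log round trip, so the last bit can
differ). The default `b_target` of 1000 s/mm² reflects where operators tend
to place the computed image for bone/soft-tissue contrast; it is a free
parameter of the pipeline.

## Bone segmentation as data, not gestures

Interactive cleanup of a threshold mask is inherently irreproducible, so the
package represents it as an **edit script**: an ordered list of subtractive
ellipsoid cuts, each either *full-depth* (an ellipse drawn on an axial,
coronal or sagittal projection, removing everything along the perpendicular
axis — which is what cutting on a maximum-intensity projection necessarily
does) or *single-slice*. Scripts serialize to JSON, replay deterministically,
and are idempotent; permuting disjoint edits cannot change the result. The
intensity threshold comparison is inclusive (`>=`): the choice is arbitrary
but must be fixed and documented, since the underlying workflow leaves it
unspecified.

## Lesion isolation

`classify_adc()` partitions bone-mask voxels by the ADC window, default
650–1400 µm²/s. The band edges are quoted in the field as "below 650" for
normal marrow and "above 1400" for necrosis, which leaves the boundary
values ambiguous; this package assigns the **closed interval [650, 1400] to
the lesion class**. At 64-bit resolution the choice is invisible on real
data but it makes the boundary rule testable. The three classes always
partition the bone mask exactly — a conservation property the tests check on
randomized inputs — and invalid-ADC voxels fall to the normal class, never
to lesion.

Residual soft tissue with ADC inside the window that survives thresholding
and editing stays in the lesion class. That mirrors the real workflow (such
tissue is acknowledged to contaminate clinical evaluations) and is why the
phantom places confounders with lesion-like ADC in the field of view.

## Histogram features

`compute_features()` reports, per segmentation: voxel count; Volume in ml
(count × voxel volume — with the 1.6 × 1.6 × 5.0 mm default grid one voxel
is 12.8 mm³); mean; **sample** (n−1) standard deviation; median and the 5th
and 95th percentiles with linear interpolation between order statistics;
Fisher–Pearson skewness $g_1 = m_3/m_2^{3/2}$ and excess kurtosis
$m_4/m_2^2 - 3$, both from population moments, the common radiomics
convention; and Shannon entropy in bits of the normalized histogram.

Entropy needs a binning convention that the workflow literature does not
state. The default here is 64 uniform bins over the lesion window
650–1400 µm²/s with out-of-range values clipped into the edge bins, base-2
logarithm. Both the bin count and range are explicit configuration, and the
practical consequence is stated plainly: entropy (and kurtosis) values are
comparable **within** a fixed configuration, not across papers that binned
differently.

Degenerate inputs are flagged results, not errors: an empty segmentation
returns Volume 0 with `NA` statistics, and a constant-valued region returns
SD 0, entropy 0 and `NA` skewness/kurtosis.

## Agreement statistics

* **Dice** `2|A∩B|/(|A|+|B|)` on voxel sets; two empty masks have no defined
  overlap and return `NA`.
* **Bland–Altman**, default on percentage differences
  $d_i = 100(x_{1i}-x_{2i})/\bar{x}_i$ because mean-ADC reproducibility is
  conventionally reported in percent; limits of agreement are bias ±
  1.96·SD(d) with the sample SD. Published limits are occasionally
  asymmetric around the printed bias, which cannot arise from this formula;
  such values reflect other computations (per-pair pooling, rounding) and
  are not replicated — the parametric 1.96 rule is used throughout.
  Proportional bias is probed with Kendall τ_b between |d| and the pair
  means. Inter-observer analyses pool all C(k,2) pairs (sign convention:
  lower observer index minus higher) within a session; intra-observer
  analyses pair session 1 against session 2 per observer.
* **ICC(A,1)** — two-way model, absolute agreement, single measurement —
  computed from the row/column/error mean squares, with the McGraw–Wong
  F-based 95% interval (Satterthwaite denominator degrees of freedom). The
  mean squares are exposed in the result for audit, and the estimate is
  invariant to affine rescaling of the table. A zero-variance table is
  degenerate and returns an `NA`-flagged result.
* The qualitative scale for both DSC and ICC: poor < 0.50 ≤ modest < 0.75 ≤
  good < 0.90 ≤ excellent, left-closed bands.

## The phantom: what it emulates and what it does not

`generate_phantom()` builds a three-station, 64 × 64 × 150-voxel torso at
1.6 × 1.6 × 5.0 mm (the in-plane matrix is scaled down from clinical size
for desk-scale speed; station structure, spacing and b-values 50/900 s/mm²
follow the clinical protocol). The default tissue list:

| tissue | geometry | S0 | ADC (µm²/s) |
|---|---|---|---|
| marrow column | 11 × 11 voxel box, full z | 450 | 350 ± 60, truncated < 650 |
| 3 lesions | ellipsoids r = (4,4,5) in the column | 550 | 1000 ± 120, truncated to [650, 1400] |
| necrotic focus | ellipsoid r = (2.5,2.5,3) | 500 | 1700 ± 150, truncated > 1400 |
| cord-like column | 4 × 4 box, full z, posterior | 600 | 900 ± 80 |
| spleen-like / node-like | ellipsoids | 650 / 620 | 850 ± 90 / 950 ± 70 |
| body block | 52 × 48 box, full z | 470 | 3000 ± 250, truncated > 2600 |

Lesion ADC near 1000 µm²/s matches the range reported for active bone
metastases in treated cohorts (roughly 940–1030 µm²/s). Per-tissue ADC is
drawn from a normal truncated to the tissue's classification band; the
truncation (an extension of truncating at zero) is what makes the noiseless
phantom classify *exactly*, so end-to-end tests can demand bit-level truth
recovery for lesion volume and mean ADC. Noise is Rician,
$\sqrt{(S+\epsilon_1)^2 + \epsilon_2^2}$ with
$\epsilon \sim N(0, \sigma)$; σ = 11 gives SNR ≈ 20 for lesion signal at
b = 900.

The body block deserves a note, because its parameters are load-bearing. It
plays two roles: its computed-b intensity tail (up to ≈ 35, just below the
nominal threshold of 41) is what makes the bone mask *sensitive to the
threshold*, so simulated observers with different thresholds produce
different masks — the dose-response that the observer-variability tests
measure. At the same time its true ADC is kept far above the lesion window
(> 2600 µm²/s) so that, even with noise-level uncertainty of several hundred
µm²/s in its fitted ADC (its b = 900 signal is weak), essentially no body
voxel is misclassified as lesion. An earlier design with body ADC just above
1400 µm²/s failed exactly there: under noise its fitted ADC spilled into the
window and contaminated the lesion mean by hundreds of µm²/s. High-ADC,
fluid-like soft tissue decouples the two roles.

`simulate_observer()` parameterizes an observer by threshold bias, threshold
jitter (SD, intensity units), a per-session threshold drift, the probability
of missing each designated confounder cut, and a Poisson rate of spurious
single-slice edits. Everything is seeded; identical specifications and seeds
reproduce masks bit for bit. Overlapping tissue primitives are an error by
default (`overlap = "error"`); the default phantom passes `overlap = "nest"`
explicitly, letting later tissues in the list (lesions, necrosis) claim
voxels inside earlier ones (marrow, body).

What the phantom does **not** emulate: anatomy beyond a schematic spine
(no ribs, pelvis, limbs), inter-station intensity discontinuities from coil
differences (the workflow sidesteps these by excluding the head/neck station,
and no normalization is implemented), partial-volume effects at tissue
boundaries, susceptibility/EPI distortion, or shim-technique differences
beyond the global noise level. Passing tests therefore demonstrate that the
*algorithms* are correct and that the *statistics* behave as designed under
a controlled observer model — not that clinical DSC or ICC values will match
any particular cohort.

## Validation conditions used by the test suite

Problem sizes were chosen so the whole suite runs in a few minutes on one
CPU: the default phantom (614,400 voxels) for round-trip and end-to-end
checks; 100 randomized 20 × 20 × 10 phantoms for partition conservation;
10⁵ uniform samples for feature recovery (mean within 3 standard errors,
entropy within 0.02 bits of log₂64); 1000 random 8 × 8 × 4 mask pairs
against a brute-force Dice oracle; 10⁴ simulated pairs for Bland–Altman
recovery of an injected 2% bias and 3% spread; 500 replicates of 200 × 4
tables for ICC recovery at truth 0.9 and empirical CI coverage; and a
5-level threshold-jitter sweep (SD 0, 4, 8, 16, 32 intensity units, 20 seed
replicates, 3 observers) for the dose-response of inter-observer DSC, tested
with a Kendall ordered-trend statistic. The noisy end-to-end tolerance for
lesion mean ADC was fixed in advance at 30 µm²/s from the per-voxel error
budget (ADC noise ≈ 63 µm²/s per voxel at SNR 20, ≈ 1000 lesion voxels,
plus allowances for window truncation and Rician bias).

## Pipeline and configuration

`run_pipeline()` chains phantom-or-read → station assembly → ADC fit →
computed-b synthesis → threshold + edit script → ADC-window isolation →
features, writing every stage's output and a JSON manifest in which all
defaults are materialized (b_target 1000, threshold 41, window 650–1400,
64 bins) together with input hashes, seed, package version and timestamps.
Configuration files are YAML — a widely readable, pre-installed format in
the R toolchain. In phantom mode with no user edit script, the pipeline
applies the phantom's own confounder cut list (and writes it next to the
other outputs), which is the scriptable stand-in for the manual cleanup an
operator would perform.

## Known limitations

* Two b-values give no way to detect departures from mono-exponential decay;
  IVIM and kurtosis models are out of scope.
* No noise-floor correction: at very low SNR the Rician floor biases ADC
  downward; the package flags non-positive and inverted signals but does not
  correct the bias.
* No inter-station intensity normalization or registration.
* Entropy and kurtosis values are convention-dependent (binning, moment
  definitions) and should only be compared within one configuration.
* The observer simulator models threshold and editing variability, not
  perceptual factors (lesion conspicuity, fatigue) — its dose-response
  curves are qualitative tools, not predictions of human DSC values.
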