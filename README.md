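# wbdwi — skeletal tumour burden from whole-body diffusion-weighted MRI

`wbdwi` is an R package for the semi-automated quantification of bone
metastases on whole-body diffusion-weighted MRI (WB-DWI), and for the
method-agreement statistics used to establish how reproducible such
quantification is across observers and reading sessions.

It is aimed at imaging scientists and medical physicists who work with
multi-station DWI of patients with metastatic breast or prostate cancer and
want a scriptable, auditable version of the workflow that is usually carried
out interactively on a vendor workstation.

## The method

**Signal model.** Each voxel's diffusion signal follows the mono-exponential
decay

```
S(b) = S0 · exp(−b · ADC)
```

with `b` the diffusion weighting (s/mm²) and ADC the apparent diffusion
coefficient, reported throughout in µm²/s (1 × 10⁻³ mm²/s = 1000 µm²/s).
With the two acquired b-values (50 and 900 s/mm²) the fit has the closed
form `ADC = ln(S_b1/S_b2)/(b2 − b1)`; with more b-values a log-linear least
squares fit is used. From the fitted map a *computed* high-b-value image

```
S(b_target) = S(b_low) · exp(−(b_target − b_low) · ADC)
```

is synthesized (default `b_target` = 1000 s/mm²), on which bone marrow is
bright and soft tissue suppressed.

**Segmentation.** Bone marrow is segmented by an intensity threshold on the
computed image (default 41, in native intensity units) followed by a
replayable script of subtractive ellipsoid edits — the scriptable equivalent
of cutting ellipses on a maximum-intensity projection to remove brain,
kidneys, spleen and other tissues that survive the threshold. Active lesions
are then isolated inside the bone mask by the fixed ADC window

```
normal marrow:      ADC < 650 µm²/s
lesion:             650 ≤ ADC ≤ 1400 µm²/s
necrosis or cyst:   ADC > 1400 µm²/s
```

**Quantification.** Each lesion segmentation is summarised by nine
first-order statistics: Volume (ml), Mean, SD, Median, 5th and 95th
percentile of ADC, skewness, excess kurtosis, and Shannon entropy of the
binned ADC histogram (64 bins over 650–1400 µm²/s, in bits).

**Agreement statistics.** The reproducibility toolbox implements the Dice
similarity coefficient `DSC = 2|A∩B|/(|A|+|B|)`; Bland–Altman analysis of
percentage differences `d_i = 100(x1−x2)/((x1+x2)/2)` with bias ± 1.96·SD
limits of agreement and a Kendall τ_b check for proportional bias; the
two-way mixed-effects, absolute-agreement, single-measure intraclass
correlation

```
ICC(A,1) = (MSR − MSE) / (MSR + (k−1)·MSE + (k/n)·(MSC − MSE))
```

with its F-based 95% confidence interval; Spearman correlation; and the
qualitative scale poor (< 0.50), modest (0.50–0.75), good (0.75–0.90),
excellent (≥ 0.90) applied to both DSC and ICC.

Because clinical WB-DWI data cannot be redistributed, the package ships a
synthetic whole-body phantom (`generate_phantom()`) with known per-tissue
truth — a spine-like marrow column with embedded lesions and a necrotic
focus, soft-tissue confounders, Rician noise — plus simulated observers, so
every stage is testable against ground truth.

## Worked example

```r
library(wbdwi)

ph    <- generate_phantom(noise_sigma = 11, seed = 7)  # SNR ~ 20 at b = 900
fused <- assemble_body_volume(ph$study)
adc   <- fit_adc(fused)
#> <adc_map> 64 x 64 x 150 voxels, 81.7% valid, b = {50, 900} s/mm^2

computed <- synthesize_computed_b(fused, adc, b_target = 1000)
obs <- simulate_observer(ph$truth, computed,
                         observer_spec(threshold_jitter = 4, seed = 1))
cls <- classify_adc(obs$mask, adc, adc_window(650, 1400))
#> <classified_mask> window [650, 1400] um^2/s: normal 17028 | lesion 1040 | necrotic_or_cyst 47243

compute_features(adc, lesion_mask(cls), bin_scheme(c(650, 1400), 64))
#>   n_voxels volume_ml mean_adc std_adc median_adc  p5_adc  p95_adc ...
#> 1     1040    13.312 1001.535 133.042    994.044 792.714 1235.571
```

The lesion class recovers 1040 of the 1041 true lesion voxels (13.3 ml) and
a mean ADC of 1002 µm²/s against a configured truth near 1000 µm²/s — the
kind of active-metastasis ADC seen in treated bone disease. Comparing two
simulated observers and a measurement table:

```r
o2 <- simulate_observer(ph$truth, computed,
                        observer_spec(threshold_jitter = 4, seed = 2))
dice(obs$mask, o2$mask)
#> 0.544  -> classify_agreement(): "modest"

m <- generate_measurement_matrix(20, 4, sigma_subject = 40,
                                 sigma_rater = 5, sigma_error = 10,
                                 mu = 970, seed = 7)
icc_a1(m)
#> <icc_result> ICC(A,1) = 0.950, 95% CI (0.878, 0.980), n = 20, k = 4 [excellent]
```

Note the deliberate contrast: threshold jitter degrades the *overlap* of the
bone masks (modest DSC) long before it degrades the *ADC statistics*, which
is exactly the dissociation the agreement toolbox is designed to expose.
`autoplot()` on a `ba_result` draws the Bland–Altman plot;
`plot_adc_histogram()` shows the in-mask ADC histogram with the three
classification bands; `tidy()`/`glance()` return tibbles for downstream use.

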