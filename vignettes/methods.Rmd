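---
title: "Methods: ASL quantification and vascular-risk moderation in vascbf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ASL quantification and vascular-risk moderation in vascbf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vascbf)
```

`vascbf` implements a complete pulsed-ASL perfusion study: quantification of
tag/control series into absolute, partial-volume-corrected cerebral blood
flow (CBF); extraction over six a-priori regions of interest (ROIs); scoring
and dichotomization of Framingham-derived vascular risk burden; and a
moderation analysis asking whether age-related CBF decline is confined to
participants with elevated burden. Because raw participant data of this kind
are rarely shareable, the package carries its own synthetic-cohort module:
a forward signal model with known ground truth that exercises every stage.
This vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic tests do and do not establish.

## 1. The quantification chain

The processing order is fixed: surround subtraction → calibration →
kinetic inversion → coil correction → partial-volume correction →
smoothing → negative clamping → physiological filtering. A regression test
pins this order, because permuting it changes results (a voxel with
uncorrected CBF 8 and tissue denominator 0.5 is retained at corrected
CBF 16 under this order, but would be discarded if the range filter ran
before the correction).

### Surround subtraction

With frames alternating tag/control (tag first), each interior frame is
compared against the mean of its two temporal neighbors, which carry the
opposite label; the signed differences are averaged over time. This
three-point estimator removes any linear temporal drift *exactly*, which
simple pairwise subtraction does not. The two series endpoints have only one
opposite-label neighbor. Including their two-point differences would
re-introduce a drift bias of `2b/N` for drift slope `b` over `N` frames, so
the default drops the endpoints and averages the `N − 2` exact differences;
`endpoints = "single"` provides the single-neighbor variant, and its bias is
itself pinned by a test. With 20 pairs the information loss from dropping
two of 40 frames is negligible against the guarantee of exact drift
immunity.

### Calibration and kinetic inversion

The CSF reference scan (inversion pulses off) estimates the equilibrium CSF
signal; its **median** over the CSF mask — robust to vessel or partial-volume
outliers — times a combined proton-density/relaxation factor
(`csf_to_blood_scale`, default 1.06) gives the blood equilibrium
magnetization M0b. The difference signal is then inverted under the QUIPSS
II single-compartment model:

$$ f \;=\; \frac{u\,\Delta M}{2\,\alpha\,M_{0b}\,TI_1\,
   e^{-TI_{2,slice}/T_{1b}}} $$

with slice-specific inversion time \(TI_{2,slice} = TI_2 + k\,\Delta t\)
for slice index \(k\). Defaults: \(TI_1 = 600\) ms, \(TI_2 = 1600\) ms
(first slice), \(\Delta t = 45\) ms, \(T_{1b} = 1664\) ms (3 T),
\(\alpha = 0.95\) (pulsed labeling), and \(u = 6000\lambda = 5400\)
(\(\lambda = 0.9\) mL/g) converting \(s^{-1}\) to mL/100 g/min. Blood T1,
labeling efficiency and the CSF-to-blood factor are not uniquely determined
by the study design; what the package guarantees instead is that the
forward generator and the inverse quantifier share *one* constant set
(a single `kinetic_scale()` function), making the forward–inverse round
trip exact. Users fitting real data should set these constants to their
scanner's calibration.

### Coil correction

The minimum-contrast scan estimates receive-coil sensitivity. The gain
field is normalized to unit mean over the analyzed (tissue) voxels and then
divided out, so a flat gain of any constant is a no-op and calibration
units survive. Two details matter for self-consistency: (i) because the
inversion is linear in ΔM, correcting the quantified map is identical to
correcting ΔM; (ii) the **CSF scan is corrected with the same normalized
gain before M0 estimation**. Estimating M0b from the raw, gain-modulated CSF
scan while correcting only the CBF map would leave a residual bias factor
mean(gain)/gain(CSF region) in every voxel; correcting both signals during
quantification removes it exactly. Voxels with non-positive gain are marked
invalid rather than divided.

### Partial-volume correction

$$ CBF_{corr} = \frac{CBF_{uncorr}}{GM + 0.4\,WM} $$

assumes CSF carries no perfusion and gray matter perfuses at 2.5× white
matter (0.4 = 1/2.5). The denominator is floored at 0.1: a voxel with less
than 10% gray-matter-equivalent tissue is effectively non-brain, and is
invalidated instead of amplified. The correction is monotone non-increasing
in GM fraction at fixed uncorrected CBF — more tissue, less flow per unit
tissue — which is property-tested.

### Smoothing, clamping, filtering

Smoothing uses a Gaussian kernel with \(\sigma = FWHM/(2\sqrt{2\ln 2})\)
per axis (default FWHM 4 mm), truncated at \(\lceil 3\sigma \rceil\)
voxels, applied with **mask-weighted normalization**: the output is the
kernel-weighted mean over *valid* neighbors only, so constants over valid
regions are preserved exactly and intensity never bleeds in from invalid
voxels (whether the original study masked before smoothing is unstated;
masked smoothing is the conservative choice and is documented as such).
Negative voxels are then set to zero, and values outside the physiological
range are invalidated. The range bounds 10 and 150 mL/100 g/min are
**inclusive** — "below 10 or greater than 150" excludes only strictly
outside values — and the boundary behavior (9.99 invalid, 10 valid, 150
valid, 150.01 invalid) plus filter idempotence are pinned by tests.

### ROI means

ROI means average corrected CBF over valid voxels only, with the valid
voxel count reported for quality control; an ROI with no valid voxels
yields a missing value, never zero. Whether the original analysis excluded
filtered voxels from its means is unstated; valid-only averaging is the
choice here, and it makes ROI means invariant to adding invalid voxels
(property-tested).

## 2. Vascular risk and the statistical battery

Hypertension is systolic ≥ 140 mmHg, diastolic ≥ 90 mmHg, or
antihypertensive use, with inclusive boundaries as stated; it is always
recomputed from those fields, never read from a precomputed flag.
Self-reported diagnosis without elevated pressure or medication does not
count. The six binary factors sum to a 0–6 count; burden is high at ≥ 2.
Missing indicators are errors, not imputed absences.

Group comparisons use the pooled-variance (Student) t-test and Pearson χ²
without continuity correction — these reproduce published demographic
tables computed by mainstream statistical software from the same summaries,
which Welch's t or Yates' correction would not. Both are cross-checked in
tests against independent oracles (raw-data `t.test(var.equal = TRUE)`;
exhaustive Σ(O−E)²/E over all 2×2 tables with margins ≤ 20).

The moderation model is a three-block hierarchical OLS per ROI: block 1
sex + APOE ε4, block 2 age + risk group, block 3 age×risk. ΔR² is the
increment in R² per block (non-negative, summing to the full-model R² to
1e-10, property-tested on 1000 random designs); coefficients are reported
from the block where each term first enters, mirroring the conventional
table layout, with full-model coefficients retained. Age enters uncentered
by default — centering changes main-effect coefficients but provably not
the interaction coefficient or its test (pinned by a test); a
`center_age` switch is provided. Missing outcomes are dropped listwise and
counted. Stratified CBF–cognition correlations are Pearson, pairwise
complete, per risk subgroup, skipping subgroups with fewer than three pairs
and reporting zero-variance cases as undefined with an explanatory note.
α = 0.05 throughout with no multiple-testing correction, matching the
analysis convention the package reproduces. One published summary-level
check is knowingly irreproducible: the CVLT group-comparison t printed in
the source table (0.43) cannot be obtained from its own printed means and
SDs (which give ≈ 0.09); it is documented rather than matched.

## 3. The synthetic cohort: what it emulates

The generator draws, per participant: age from a normal distribution
(mean 75, SD 7.8 years) truncated at 65 (the study design excludes younger
adults); sex (57.7% female) and APOE ε4 (36%); six independent risk factors
with prevalences 0.59, 0.07, 0.10, 0.085, 0.07, 0.028 (hypertension,
diabetes, cardiovascular disease, atrial fibrillation, TIA/stroke, current
smoking) — independence is a simplification; the marginal frequencies put
roughly 20% of participants at two or more factors. Blood pressures and
medication flags are drawn *consistently* with the hypertension indicator
(untreated hypertensives show elevated pressure; normotensives never cross
a threshold).

True regional CBF follows

$$ CBF_{i,roi} = \mu_{roi} + \beta_{sex} I(male_i)
   + \beta_{age,low}(age_i - 75)
   + I(high_i)\,\beta_{int,roi}\,(age_i - 75) + \varepsilon_{i,roi} $$

with baselines (55, 65, 70, 60, 65, 60 mL/100 g/min for medial temporal,
inferior parietal, posteromedial, frontal, thalamus, caudate),
\(\beta_{sex} = -8\) (women higher), \(\beta_{age,low} = 0\) (no age
effect in the low-risk group), and per-ROI interaction slopes defaulting to
(−0.86, −1.05, −0.63, −0.66, 0, 0) mL/100 g/min/year — the reported
moderation structure: negative cortical slopes confined to the high-risk
group, null subcortically. A scalar `beta_interaction` is applied to the
four cortical ROIs only. Residual SD defaults to 6 mL/100 g/min: within-ROI
variances are not published, so the noise default is chosen for test power,
calibrated so that the simulated interaction standard errors at n = 71
(≈ 0.2–0.45) fall inside the published SE range rather than above it.
Values are clamped to (0, 200), a physiological invariant with negligible
clipping probability under defaults.

Cognition is linked to CBF **only within the high-risk group**: Trails B
(seconds; higher is worse) declines with the mean of frontal and
inferior-parietal CBF (slope −1.5 s per mL/100 g/min, residual SD 25 s) and
CVLT-II rises with medial temporal CBF (slope 0.6, residual SD 10);
low-risk cognition is independent noise. White-matter-lesion volume is
log-normal with a positive age slope and no risk interaction. The phantom
is a 32×32×20 grid at 4 mm isotropic — the working resolution of the
analysis this package models — with one 3³-voxel box per ROI subregion
(GM-dominant cortically, pure gray matter for thalamus/caudate), a
WM-dominant core at nominal perfusion, and a CSF-filled ventricle used as
the calibration region. Boxes are separated by background gaps wider than
the default smoothing kernel, so masked smoothing never mixes regions of
different true CBF; that is what lets the noise-free round trip hold to
machine precision rather than merely 1e-3.

The forward acquisition multiplies baseline tissue signal and the kinetic
difference signal by a smooth coil gain field, adds linear per-frame drift
(default 0.02 signal units/frame, exercising surround subtraction's drift
immunity) and white Gaussian noise (default SD 1 against a CSF equilibrium
signal of 1000, i.e. a realistic ~1% perfusion signal on a ~700-unit
baseline at roughly 0.1% noise per frame).

**What passing tests show, and what they do not.** The round-trip and
recovery tests establish internal consistency: the quantifier exactly
inverts the generative model, the ROI pipeline preserves ground truth, and
the statistical battery recovers injected effects with calibrated error
rates (type-I ≈ 5% under a null interaction). They do not validate the
kinetic constants against physiology, anatomical realism (boxes are not
brains; there is no motion, no transit-delay dispersion, no reconstruction
artifact), nor the independence and log-normality assumptions of the
covariate generator. Real-data use inherits the usual ASL caveats: low SNR
and quantification assumptions, especially transit delay.

## 4. Reproducibility and problem sizes

All randomness flows through seeds derived deterministically from one
master seed per stage (`derive_seed(master, "cohort")`,
`derive_seed(master, "asl/p001")`, …), so stages re-run in isolation and an
identical config + seed reproduces cohort tables byte-identically and
stage outputs checksum-identically; `run_simulate()` writes a manifest with
MD5 checksums that `validate_manifest()` re-verifies. Test problem sizes
were chosen to make each check sharp at interactive runtimes: n = 4
participants for the noise-free imaging round trip, n = 71 (the study's
size) × 100 replicates for interaction-detection power, × 1000 replicates
at table level for type-I calibration, n = 500 for prevalence calibration
and parameter recovery (±0.1 on the injected slope at low noise), and 1000
random 30-row designs for ΔR² additivity.

## 5. Known limitations

- The kinetic constants are conventional values, not a scanner calibration;
  absolute CBF on real data depends on supplying site-specific constants.
- Motion correction, transit-delay modeling and multi-TI fitting are out of
  scope; the forward model is motion-free by construction.
- The tissue phantom's geometry is deliberately schematic; registration and
  atlas normalization are replaced by generation in a common grid (the
  resampling step is a no-op at the native 4 mm grid).
- Risk factors are simulated independently; comorbidity correlation
  structure is a configuration extension, off by default.
- The WML regression is summary-level (volumes in mm³ as numbers); no
  lesion imaging is synthesized.
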