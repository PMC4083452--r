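# vascbf

Cerebral blood flow (CBF) declines with age, and vascular risk factors —
hypertension, diabetes, cardiovascular disease, atrial fibrillation,
TIA/minor stroke, smoking — compound that decline. A recurring question in
preclinical Alzheimer's research is whether **vascular risk burden moderates
the age–CBF relationship**: does advancing age cost more perfusion in people
who carry multiple risk factors? `vascbf` implements the full computational
chain needed to ask that question with pulsed arterial spin labeling (ASL)
MRI, for neuroimaging researchers and methods developers who want a tested,
reproducible reference pipeline:

1. **ASL quantification** — converts QUIPSS II pulsed-ASL tag/control series
   into absolute CBF (mL/100 g/min): drift-immune surround subtraction,
   CSF-based calibration of blood magnetization, slice-specific inversion
   times, coil-inhomogeneity adjustment, partial-volume correction, masked
   Gaussian smoothing, negative clamping and physiological range filtering.
2. **ROI extraction** — mean corrected CBF over six a-priori regions:
   medial temporal, inferior parietal, posteromedial, frontal cortices;
   thalamus; caudate.
3. **Vascular risk scoring** — six Framingham-derived binary factors,
   burden dichotomized at two or more.
4. **Statistics** — demographic group comparisons (pooled-variance t,
   Pearson χ² without continuity correction), a three-block hierarchical
   regression per ROI testing the age×risk interaction via ΔR², white-matter
   lesion regressions, and risk-stratified CBF–cognition correlations.
5. **Synthetic cohort** — a forward model that generates participant tables,
   tissue/atlas phantoms and ASL acquisitions with known ground truth, so
   every stage is testable end to end without any imaging data.

## The models

**Kinetic inversion.** The perfusion difference signal ΔM of a pulsed,
QUIPSS II-constrained acquisition is inverted per voxel as

    f = u · ΔM / (2 α M0b TI1 exp(−TI2,slice / T1b))

with bolus duration TI1, slice-specific inversion time
TI2,slice = TI2 + k·Δt_slice, blood T1 `T1b`, labeling efficiency α, blood
equilibrium magnetization M0b estimated from a CSF reference scan, and
u = 6000·λ converting to mL/100 g/min (λ = 0.9 mL/g).

**Partial-volume correction.** Assuming CSF carries no perfusion and gray
matter perfuses at 2.5× white matter,

    CBF_corr = CBF_uncorr / (GM + 0.4·WM)

**Moderation analysis.** Per ROI, three nested OLS blocks — (1) sex, APOE ε4;
(2) age, risk group; (3) age×risk — with ΔR² per block and the interaction
coefficient B tested at α = 0.05.

## Worked example

Simulate a 71-participant study, forward-model the ASL scans, quantify,
extract ROI means and run the statistical battery:

```r
library(vascbf)
cfg <- cohort_config(n_participants = 71, seed = 7, n_pairs = 4,
                     asl_noise_sd = 0.5)
res <- run_full(cfg)
res$results
#> <study_results> n = 71, alpha = 0.05
#> age x risk interactions:
#> # A tibble: 6 × 5
#>   roi               estimate std_error     p_value delta_r2
#>   <chr>                <dbl>     <dbl>       <dbl>    <dbl>
#> 1 medial_temporal    -0.796      0.221 0.000616    0.103
#> 2 inferior_parietal  -1.39       0.241 0.000000234 0.234
#> 3 posteromedial      -0.935      0.208 0.0000302   0.156
#> 4 frontal            -0.447      0.203 0.0315      0.0432
#> 5 thalamus            0.134      0.250 0.594       0.00336
#> 6 caudate             0.0507     0.267 0.850       0.000385
```

The interaction estimates are the extra CBF change per year of age carried
by the high-risk group (mL/100 g/min/year): negative and significant in the
cortical ROIs, where the generator injected slopes of −0.86, −1.05, −0.63
and −0.66, and null in thalamus/caudate where it injected zero. The
recovery report makes the comparison explicit:

```r
res$recovery
#> # A tibble: 6 × 6
#>   roi               beta_true beta_est    se           p sign_match
#> 1 medial_temporal       -0.86  -0.796  0.221 0.000616    TRUE
#> 2 inferior_parietal     -1.05  -1.39   0.241 0.000000234 TRUE
#> 3 posteromedial         -0.63  -0.935  0.208 0.0000302   TRUE
#> 4 frontal               -0.66  -0.447  0.203 0.0315      TRUE
#> 5 thalamus               0      0.134  0.250 0.594       TRUE
#> 6 caudate                0      0.0507 0.267 0.850       TRUE
```

`plot_age_cbf_interaction(res$results)` draws the per-ROI age–CBF scatter
with separate fits per risk group; `plot_cbf_cognition()` the stratified
CBF–cognition panels. Published demographic tables can be checked directly
from their printed summaries:

```r
two_sample_t_summary(74.73, 7.92, 55, 75.94, 7.35, 16)   # age rows
#> # A tibble: 1 × 4
#>       t abs_t    df     p
#> 1 -0.546 0.546    69 0.587
chi_square_2x2(matrix(c(33, 22, 8, 8), 2))               # sex counts
#> # A tibble: 1 × 3
#>   chisq    df     p
#> 1 0.508     1 0.476
```

A thin command-line wrapper is installed at `inst/cli/vascbf`
(`simulate`, `quantify`, `analyze`, `run-full`, `make-fixtures`).

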