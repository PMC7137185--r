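# ivimtools

Quantitative intravoxel incoherent motion (IVIM) analysis of
diffusion-weighted MRI (DWI) of primary cervical tumours, aimed at the
question radiologists struggle with most: does this patient have
pelvic lymph-node (PLN) involvement, including *sub-centimetre*
metastatic nodes that size-based criteria miss? The package is for
imaging scientists who have 4D DWI volumes (NIfTI-1 + FSL-style bval
files) and tumour masks, and want parameter maps, tumour-level
features, cohort statistics and a compact nodal classifier from one
consistent toolchain — plus synthetic phantoms and cohorts so the whole
pipeline can be exercised and tested without clinical data.

## The models

Monoexponential decay gives the apparent diffusion coefficient from a
two-point closed form,

    S_b / S_0 = exp(-b * ADC),

and the biexponential IVIM model splits tissue diffusion (D) from
microvascular pseudo-diffusion (D*, signal fraction f):

    S_b / S_0 = f * exp(-b (D + D*)) + (1 - f) * exp(-b D).

Fitting is segmented ("two-step"): D by log-linear regression over
b ≥ 200 s/mm², then f and D* by bound-constrained Levenberg–Marquardt
with D and S0 fixed, iterated to a fixed point so noiseless curves are
recovered essentially exactly. A 3×3 Gaussian filter precedes fitting;
quality control excludes voxels with ADC or D > 3×10⁻³ mm²/s, f
outside [0, 1], or non-finite fits. Tumour features are the diffusion
tumour volume (DTV, b1000 area × slice thickness) and VOI
mean/percentile summaries of ADC, D and f. Cohort inference uses
Kruskal–Wallis + Nemenyi across nodal strata, Fisher's exact test,
and ICC(2,1) for interobserver agreement; classification uses
stepwise-forward logistic regression (≤ 2 features, AIC), ROC
analysis, and pooled two-proportion Z comparisons of accuracies.

## Worked example

```r
library(ivimtools)

# a synthetic patient: ellipsoidal tumour, 13 b-values, Rician noise
sim  <- simulate_phantom(phantom_spec(snr = 50), seed = 7)
maps <- fit_ivim(sim$study)
maps
#> IVIM parametric maps on a 12 x 12 x 3 grid
#>   valid voxels: 429 / 432 (99.3%)
#>   exclusions: d_out_of_range=3

summarize_voi(maps, sim$voi)
#> Tumour summary: DTV 1.968 cm^3, 84/84 voxels after QC
#>          mean      p10       p25       p50      p75      p90 skewness kurtosis
#> adc 0.0011860 0.001092 0.0011070 0.0011990 0.001248 0.001301   0.2285    1.679
#> d   0.0009738 0.000859 0.0008828 0.0009736 0.001057 0.001103   0.2302    1.826
#> f   0.1907000 0.170000 0.1790000 0.1898000 0.201000 0.213700  -0.4050    3.677

# a synthetic 50-patient cohort (29 none / 10 sub-centimetre / 11 size-significant)
co  <- simulate_cohort(seed = 1)
clf <- pln_classifier(co)
clf
#> Stepwise-forward logistic classifier of nodal involvement
#>   selected (aic): dtv + adc
#> (Intercept)         dtv         adc
#>     3.88800     0.05199    -6.42000
score_classifier(clf)
#> Classifier performance [resubstitution] (cutoff 0.50):
#>   accuracy     0.840 (95% CI 0.715-0.917, n = 50)
#>   sensitivity  0.667 (95% CI 0.454-0.828, n = 21)
#>   specificity  0.966 (95% CI 0.828-0.994, n = 29)
#>   AUC          0.864
```

The tumour summary's D and f means sit at the phantom's generating
values (0.9×10⁻³ mm²/s and 0.19; the ADC is higher because the
two-point estimate deliberately absorbs the perfusion compartment).
On this particular cohort the greedy search pairs tumour volume with
mean ADC and classifies 42 of 50 patients correctly at the 0.5
cutoff; across many simulated cohorts the modal selected pair is
{DTV, f} — tumour bulk plus hypoperfusion — with ADC its closest
competitor, as `scripts/acceptance.R` quantifies.

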