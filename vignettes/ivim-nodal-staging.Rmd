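---
title: "Quantitative IVIM analysis of cervical tumour DWI for nodal staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative IVIM analysis of cervical tumour DWI for nodal staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(ivimtools)
```

## The problem

Conventional MRI stages pelvic lymph-node (PLN) involvement in cervical
cancer by size and morphology criteria, which miss many sub-centimetre
metastatic nodes. An alternative is to quantify the *primary tumour's*
diffusion and perfusion characteristics, since tumours that seed nodal
metastases tend to be larger, more cellular (lower diffusivity) and more
hypoxic (lower perfusion). `ivimtools` implements that quantitative
chain end to end: voxel-wise parameter mapping from diffusion-weighted
imaging (DWI), tumour volumetry and histogram summaries over a manually
drawn volume of interest (VOI), rank-based group comparisons across
nodal strata, and a compact logistic classifier of nodal involvement.

## Signal models

The monoexponential model relates the diffusion-weighted signal at
weighting $b$ (s/mm$^2$) to the apparent diffusion coefficient:

$$ S_b / S_0 = \exp(-b \cdot \mathrm{ADC}). $$

The ADC map is computed in closed form from the $b = 0$ and
$b = 1000$ s/mm$^2$ images (`adc_two_point()`). The intravoxel
incoherent motion (IVIM) model splits the decay into a tissue
compartment with diffusion coefficient $D$ and a perfusion compartment
with pseudo-diffusion coefficient $D^* \gg D$ occupying signal
fraction $f$:

$$ S_b / S_0 = f e^{-b (D + D^*)} + (1 - f) e^{-b D}. $$

The default acquisition axis is the 13-value scheme
`r paste(as.numeric(bvalue_scheme()), collapse = ", ")` s/mm$^2$, with
the directional images combined by geometric averaging
(`geometric_average()`) before any fitting.

## The segmented inverse problem

Voxel-wise fitting (`fit_ivim()`) proceeds in the standard two-step
("segmented") fashion:

1. **Pre-smoothing.** A normalised 3×3 Gaussian kernel — the separable
   binomial kernel $(1,2,1)\otimes(1,2,1)/16$ with reflecting borders —
   is applied once, in-plane, to every b-value image. No kernel width
   beyond the 3×3 support is assumed; the binomial kernel is the
   discrete Gaussian of that support.
2. **Step 1 (D).** Above a perfusion cut (default 200 s/mm$^2$, the
   conventional regime where the pseudo-diffusion term has decayed
   away; configurable in `fit_config()`) the decay is treated as
   monoexponential and $D$ estimated by unweighted log-linear least
   squares.
3. **Step 2 (f, D\*).** With $D$ held fixed and $S_0$ pinned to the
   measured (smoothed) $b=0$ signal, $f$ and $D^*$ are estimated by
   bound-constrained Levenberg–Marquardt least squares over the full
   curve (`minpack.lm::nls.lm`), from a fixed three-point grid of
   $D^*$ starts so that fitting is fully deterministic.
4. **Refinement.** The step-1 estimate of $D$ is contaminated by the
   residual perfusion signal at the lowest retained b-values (for
   $D^* = 20\times10^{-3}$ mm$^2$/s the residual at $b=300$ biases
   $D$ by $\sim\!10^{-3}$ relative). We therefore iterate the two
   steps as a fixed point: the fitted perfusion component is
   subtracted from the high-b signals, $D$ re-estimated, and $f, D^*$
   refitted, until $D$ changes by less than 1 part in $10^9$ (at most
   25 iterations; typically 3–5). On noiseless curves this recovers
   all three parameters to $\sim\!10^{-8}$ relative error; on noisy
   curves it converges in a few iterations and leaves the estimator's
   variance unchanged. Setting `refine_iter = 0` restores the plain
   single-pass segmented fit.

Two bound choices deserve a note. The perfusion fraction's upper bound
is deliberately **2, not 1**: quality control must be able to observe
and exclude physically impossible fits with $f > 1$, which a bound at
1 would silently clip into the valid range. And $S_0$ is fixed rather
than refit, the most common segmented-fit convention, which removes a
near-degeneracy between $S_0$ and $f$.

### Quality control

`qc_filter()` excludes any voxel with ADC or $D$ above
$3\times10^{-3}$ mm$^2$/s (free-water diffusivity; values above it are
fit failures), negative ADC or $D$, $f$ outside $[0,1]$, or any
non-finite value — any single violation excludes the voxel
("incorrectly fitted" means incorrect for any reason). Boundary values
are retained (the rule is a strict inequality). Voxels whose signal is
non-positive at $b=0$ or at the step-1 b-values are flagged at fit
time and never imputed. $D^*$ is deliberately *not* carried into any
downstream analysis: at clinical SNR its estimate is too noisy to be
useful, so it is mapped but never summarised.

## Volumetry and VOI summaries

The diffusion tumour volume (`compute_dtv()`) is the mask voxel count
times the in-plane voxel area times (slice thickness + intersection
gap), in cm$^3$. QC exclusions do **not** shrink the DTV — the volume
is defined by b1000 hyperintensity, not by fit success — but they are
excluded from all intensity summaries (`summarize_voi()`): mean,
percentiles 10/25/50/75/90 (linear interpolation between order
statistics, `quantile` type 7), skewness and kurtosis of ADC, $D$ and
$f$ over the VOI.

## Cohort statistics

Patients are stratified as *none* / *sub-centimetre* /
*size-significant* by their worst PLN. Feature differences across the
three strata use the Kruskal–Wallis rank test with tie correction and
the Nemenyi all-pairs post-hoc (studentized-range reference, valid for
unequal group sizes; exact small-sample tables are out of scope).
P-values across the four features are reported unadjusted, and the
degenerate all-tied case is returned as $H=0, p=1$ rather than 0/0.
Categorical associations (histology, FIGO stage) use Fisher's exact
test; $r\times c$ tables are enumerated exactly up to a grand total of
40 and Monte-Carlo sampled (fixed seed, reported replicate count)
beyond. Two-sided 2×2 p-values follow the "sum of tables no more
probable than observed" convention, stated here because two-sided
Fisher conventions differ.

Interobserver reproducibility uses the single-rater, absolute-agreement
two-way random-effects ICC(2,1) (`icc_agreement()`). The guideline
bands are poor $<0.50$, moderate $0.50$–$0.75$, good $0.75$–$0.90$,
excellent $>0.90$, with boundaries assigned to the lower band. The
form is pinned to absolute agreement because each radiologist's VOI is
used alone downstream, so systematic offsets between readers matter.

## The nodal classifier

`pln_classifier()` fits a logistic regression of the binary label
(any involvement vs none) by greedy forward selection from the
candidate features (default: DTV and the VOI means of ADC, $D$, $f$;
histogram percentiles can be offered by naming their columns). The
entry criterion is AIC (a likelihood-ratio entry test at
$\alpha=0.05$ is available), at most two features enter by default,
and ties break by candidate order, making selection deterministic and
invariant to row permutations. Perfect separation is handled by a
small ridge refit ($\lambda = 10^{-3}$ on standardised slopes,
intercept unpenalised) so coefficients stay finite; the report flags
it. Class labels use a 0.5 probability cutoff; performance
(`score_classifier()`) reports accuracy, sensitivity and specificity
with 95% Wilson intervals, and the trapezoidal ROC AUC (equal to the
concordant-pair fraction with ties at one half). Reported accuracies
are resubstitution values and labelled as such — they are optimistic
relative to held-out data. Accuracies of two classifiers are compared
with the pooled two-proportion Z test (`compare_accuracy()`), with
Wilson CIs printed alongside since CI overlap is the other common
summary of such comparisons.

## What the synthetic generators emulate

`simulate_phantom()` builds a desk-scale digital phantom — an
ellipsoidal tumour in background tissue, default $12\times12\times3$
voxels of $2.42\times2.42\times4$ mm — whose every voxel decays
biexponentially over the 13-value scheme, corrupted by **Rician**
noise (magnitude of a complex Gaussian perturbation), the correct
noise family for magnitude MR: at high b the signal approaches the
noise floor from above, which is exactly what stresses a real fitter.
Default SNR is 50.

`simulate_cohort()` draws a 50-patient cohort with group sizes
29/10/11 (none / sub-centimetre / size-significant) whose per-group
feature distributions follow the means and SDs this analysis targets:

```{r}
default_cohort_moments()
```

DTV in cm$^3$; ADC and D in the display unit $10^{-3}$ mm$^2$/s; f
dimensionless. Features are sampled from positively-truncated
Gaussians ($f$ truncated to $[0,1]$); DTV can alternatively be drawn
log-normal, since volumes are visibly right-skewed in practice, but
the truncated Gaussian stays the default to match the declared
marginal moments. Between-feature correlation defaults to zero because
only marginal moments are declared; this is a known simplification.
A second reader's measurements add Gaussian noise calibrated so the
expected ICC(2,1) equals 0.95 (the observed interobserver agreement
regime); the first reader reports the latent values.

What the generators do *not* emulate: anatomy and partial-volume
structure, spatially correlated noise, coil profiles, motion, reader
bias in VOI placement, or any between-feature correlation. Passing
tests on these phantoms therefore demonstrate correctness of the
estimators and the statistical chain under the declared model, not
clinical performance on real data.

## Worked example

A noiseless phantom fits back to its generating parameters:

```{r}
sim <- simulate_phantom(phantom_spec(snr = Inf))
maps <- fit_ivim(sim$study, fit_config(smooth = FALSE))
maps
summarize_voi(maps, sim$voi)
```

A synthetic cohort, its group statistics and the selected model:

```{r}
co <- simulate_cohort(seed = 1)
cohort_association_stats(co)[, c("feature", "statistic", "p.value")]
clf <- pln_classifier(co)
clf
score_classifier(clf)
```

## Numerical choices and limitations

* Problem sizes used in the shipped tests — phantoms of a few hundred
  voxels, 200-replicate cohort simulations, 500-replicate noise
  studies — were chosen as the smallest sizes at which the Monte-Carlo
  error is comfortably below the tolerances being asserted.
* The voxel grid is indexed `[row, col, slice, b]`; masks must match
  the grid exactly, and nothing is ever resampled or rescaled
  silently. The only silent-looking transformation is the declared
  reordering of a shuffled b-value table (logged).
* Coefficients are held in SI units (mm$^2$/s) internally; the
  display unit $10^{-3}$ mm$^2$/s appears only at serialisation
  (`write_maps(units = "display")`) and in the cohort table, mirroring
  how such values are printed in the field.
* Under repeated simulation at reader ICC 0.95 the refit-on-reader-2
  accuracy typically shifts by 0–3 patients of 50; interobserver
  robustness to within 2 patients holds in roughly 70% of replicates,
  not more — a single favourable observed comparison on one cohort
  should not be over-read as a distributional guarantee.
* The classifier's reported accuracies are resubstitution estimates on
  50 patients; no cross-validated benchmarking is attempted beyond the
  pure-noise sanity test.
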