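---
title: "Building an epigenetic age clock for adolescents and young adults"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building an epigenetic age clock for adolescents and young adults}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(youthclock)
```

## The problem and the model

DNA methylation at CpG dinucleotides drifts with age, and linear models
over a few hundred CpG sites ("epigenetic clocks") predict chronological
age from blood surprisingly well. Clocks trained over wide adult spans,
however, are least precise for adolescents — the population for which
forensic age assessment matters most. This package builds clocks on a
deliberately narrow training span (default 12–25 years).

The response of the regression is the piecewise log-linear age transform
`transform_age()`: logarithmic below the adult-age knot, linear above it.
It is continuous and strictly increasing but only C0 at the knot; the
inverse `inverse_transform_age()` is exact on the full range. We take the
canonical knot of 20 years; the transform is optional
(`use_transform = FALSE`) because on a 12–25 span the fit is only mildly
affected by it, but it is kept on by default since it never hurts and is
required for sensible extrapolation beyond the span.

The fit itself is the elastic net: `(1/2n)·RSS + λ(α·L1 + (1−α)/2·L2)`
over standardized predictors, with α = 0.5 and λ chosen by 10-fold
cross-validated mean squared error on the transformed-age scale. MAD —
the *median of the absolute prediction errors*, in years, after inverse
transformation — is the reported accuracy measure throughout. It is
robust to the occasional grossly mispredicted sample, which is the
failure mode that array artefacts actually produce.

### A numerical note on the solver

Fitting goes through glmnet. For a gaussian response glmnet internally
standardizes `y`, which silently rescales the *ridge* part of the penalty
by `sd(y)` relative to the objective written above. `youthclock`
therefore reparameterizes every fit: it solves on `y/sd(y)` with an
adjusted mixing `α′ = (α/s)/(α/s + 1 − α)` and penalty
`λ′ = λ(α/s + 1 − α)` (where `s = sd(y)`), then rescales the
coefficients. This mapping is exact, so the returned coefficients
minimize the stated objective; the test suite pins the fits against an
independent FISTA (accelerated proximal gradient) solver to 1e−6.

### Choosing λ: min versus 1se

`select_lambda()` implements both rules. `lambda.min` minimizes CV error
and keeps several hundred sites; `lambda.1se` — the largest λ whose CV
error is within one standard error of that minimum — keeps a fraction of
them. The package defaults to `1se`: on held-out single-age cohorts the
sparser model is as accurate or slightly better, and a smaller site panel
is cheaper to port to targeted assays. The CV fold assignment shuffles
samples once with the configured seed and cuts contiguous blocks, without
stratification; the λ path is glmnet's geometric grid of 100 points
spanning four orders of magnitude below the all-zeroing λ.

## Filtering multimodal sites

Some CpG probes produce 2–3 discrete beta clusters — usually a SNP under
the probe splitting samples by genotype — rather than a continuous age
trend. They attract spurious weight in a linear clock. The detector
(`modality_scan()`) runs a Gaussian KDE on [0, 1] per site and counts
peaks, keeping a local maximum as a mode only if its topographic
prominence reaches 10% of the density maximum, and merging modes closer
than 0.2 beta (the higher peak wins). The defaults were chosen for the
geometry of the problem, not tuned on outcomes: genotype clusters sit
≥ 0.4 beta apart with within-cluster sd well under 0.1, while an
age-trend site spans at most ~0.3 beta as a *gradient*, which a KDE
renders as one wide peak. The bandwidth is Silverman's rule clipped below
at 0.02 so very large samples do not fragment a cluster into spikes.
Sites with fewer than 10 non-missing values are reported unimodal with a
`low_n` note rather than guessed at. We chose peak counting over
Hartigan's dip test because it reports *where* the modes are — useful in
QC reports — and has a directly interpretable specificity margin against
age gradients.

## Batch correction

Study-of-origin effects dominate raw methylation PCA. `fit_batch_model()`
implements the standard parametric empirical-Bayes location/scale
adjustment: per site, a mean model with batch indicators plus protected
covariates; standardization by the pooled residual variance; per-batch
location/scale estimates shrunk by a normal/inverse-gamma prior with
moment-matched hyperparameters. Only the parametric priors are
implemented — the non-parametric variant was never needed in practice for
this pipeline. Correction operates on the beta scale by default (a logit
option exists) and output is clipped to [0, 1] with the clip count
logged.

Two features matter for the forensic workflow:

* **Reference mode** (`reference = "study"`): the standardization targets
  come from the reference batch alone, whose samples pass through
  *bit-identical*; all other batches are mapped onto it. This is what
  keeps separately-corrected training and test cohorts comparable.
* **Protected covariates**: age (or any covariate) enters the
  standardization mean, so its signal survives. When true age is unknown
  — the forensic case — `protect_with_predicted_age()` substitutes the
  age predicted by an existing clock. Correcting *without* any protected
  variable removes age signal along with the batch signal and degrades
  predictions badly; the test suite reproduces this as a property, and it
  is not a recommended mode.

`batch_pca()` quantifies batch structure as per-component one-way ANOVA F
statistics of PC scores against batch, before and after correction.

## The synthetic world

`simulate_dataset()` generates the structure the pipeline assumes — it is
a stated world, not a fit to any dataset. Defaults: 900 samples uniform
on 12–25 years, 2000 sites of which 2% are age-associated and 5%
multimodal, within-site Gaussian noise of sd 0.03 on the beta scale, and
three equal studies with logit-scale shifts 0/+0.2/−0.2. Age-associated
sites follow a logistic link in *transformed* age — so the age transform
is exactly the right inverse link during recovery tests — with the
configured slope interpreted as the beta-scale slope per transformed-age
unit at the baseline (the logit slope is divided by the local logistic
derivative; baselines are drawn in 0.3–0.7). Slopes are drawn from
±[0.2, 0.5]: with 13 years of span this moves a site by 0.1–0.35 beta,
the magnitude of strong clock CpGs. Multimodal sites draw 2–3 cluster
means ≥ 0.4 apart with Hardy-Weinberg-style weights, independent of age.
Batch shifts are additive on the logit scale, which keeps betas in range
naturally before the final clip (< 1% of values clip at default noise).
Six whole-blood cell-type fractions are drawn from a Dirichlet with
realistic concentrations and, by default, have *no* methylation effect —
the null against which "cell fractions do not help" is tested. A
`linear` and a `piecewise` age link (independent slope above a
breakpoint) are available as deliberately misspecified modes; the
piecewise mode is what makes narrow-span training demonstrably better
than broad-span training on 18-year-olds.

`make_external_cohort()` replays the *same realized site parameters* at a
single target age (default 18.5 ± 0.5 y, n = 200, carrying the first,
unshifted, batch label), emulating an independent single-age validation
cohort. All generation is bit-reproducible from the seed via a fixed RNG
(Mersenne-Twister / inversion / rejection sampling).

What a green test on this world does establish: the estimators recover
planted structure at realistic effect sizes and noise. What it does not:
robustness to probe chemistry, cell-composition confounding, population
structure, or any of the messiness of real arrays — the synthetic noise
is homoscedastic Gaussian and the signal sites are exactly linear in the
link. External MADs near 0.2 years on this world are an upper bound on
what the method could achieve, not a claim about real cohorts, where
published narrow-span clocks reach roughly 0.7 years against independent
test data.

## Evaluation procedure

`evaluate_repeated()` mirrors the standard protocol: repeatedly (default
10×) split the training data 2/3–1/3, train with CV on the 2/3, record
MAD on the internal 1/3 and on the untouched external cohort. Per-repeat
seeds derive deterministically from the configured seed, so an identical
configuration reproduces identical records. Down-sampling
(`subsample_n`) and cell-fraction inclusion are switches of the same
procedure, which is how sample-size and cell-composition effects are
assessed.

## Degenerate inputs and numerical choices

* Betas outside [0, 1], duplicate site/sample ids, non-positive ages and
  unknown batch labels are hard errors at the boundary, with offending
  ids named.
* Missing betas are carried through IO and QC but are a hard error in
  training and batch fitting; imputation is a deliberate user step. At
  prediction time, absent model sites are an error by default
  (`impute_half` substitutes beta 0.5 and reports per-sample counts —
  silent imputation is dangerous when the output is an age assessment).
* Overlap percentages round half-away-from-zero to one decimal, the
  convention of published comparison tables; the denominator is the
  *first* clock's site count, so the measure is deliberately asymmetric.
* EB shrinkage iterates to a relative tolerance of 1e−5 (cap 200
  iterations); pooled variances are floored at 1e−12; a constant
  predicted age in the predicted-age-protected mode falls back, with a
  warning, to unprotected correction rather than a singular design.
* QC thresholds (max 5% missing, median beta in [0.2, 0.8]) are a stated
  stand-in for a full array-QC pipeline; QC only ever *flags* samples,
  it never deletes them.

## Known limitations

Probe-level chemistry (Infinium I/II, dye bias), background correction
and reference-based cell deconvolution are out of scope: the pipeline
starts from normalized betas and externally supplied cell fractions.
Site-count agreement with any published clock is not a target — the
multimodal detector is a reconstruction of the idea, not of an exact
threshold set. The generator's independence assumptions (sites
conditionally independent given age, batch and cluster) understate the
correlation structure of real arrays, which mainly makes variable
selection easier than in reality.
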