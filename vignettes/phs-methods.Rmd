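---
title: "Polygenic hazard scores for prostate cancer: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygenic hazard scores for prostate cancer: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Prostate cancer screening with PSA suffers from poor specificity: most
PSA-positive men do not have clinically significant disease. A polygenic
hazard score (PHS) addresses this by modelling *age at diagnosis* as a
time-to-event outcome driven by common germline variants, so that a man's
genotype shifts his entire age-specific risk curve. `polyhaz` implements
the development and evaluation pipeline for such a score: candidate-SNP
pruning, an L1-penalized Cox fit, percentile-based risk stratification,
comparison against family history, screening positive predictive values
(PPV), and genetic-risk-adjusted cumulative incidence curves.

Real consortium genotype data of the scale used to train such scores are
access-restricted, so the package ships a synthetic cohort generator that
reproduces the *statistical structure* the pipeline assumes. All tests and
the acceptance script run end-to-end on generated cohorts.

## The model

The PHS is the Cox log-relative-hazard
$\mathrm{PHS}_s = \sum_i \beta_i x_{si}$, where $x_{si}$ is subject $s$'s
effect-allele count at SNP $i$ and $\beta_i$ the per-allele log hazard
ratio. Model development proceeds in three stages.

**Pruning.** Among candidate SNPs, every pair with genotypic
$r^2 > 0.95$ is flagged; each flagged pair loses the member with the
larger univariable Cox p-value for association with age at diagnosis.
Pairs are processed in ascending order of the smaller member p-value, and
a SNP that has already been removed cannot trigger further removals. This
greedy rule makes the outcome deterministic and order-invariant when
p-values are distinct; exact ties keep the lexicographically smaller id.
$r^2$ is computed on the training cohort (pruning is part of model
development) from allele counts over pairwise-complete subjects —
genotypic, not haplotypic, correlation.

**Penalized fit.** Coefficients maximize the weighted Breslow partial
log-likelihood minus $\lambda \sum_{j \in \text{SNPs}} |\beta_j|$, with
the first four ancestry principal components included unpenalized:
shrinking confounder adjustments to zero would defeat their purpose.
Predictors are standardized internally and coefficients reported on the
allele-count scale. The solution path (100 log-spaced values from
$\lambda_{\max}$ down to $10^{-4}\lambda_{\max}$) is computed with
`glmnet`'s coordinate descent — the standard solver for this model — and
each retained solution is then refined by damped Newton steps on its
active set, which sharpens the solver output to near-machine-precision
stationarity. The package's own weighted Breslow likelihood, analytic
score gradient and Karush–Kuhn–Tucker verifier (`kkt_check()`) act as
independent checks on the solver: at every path point the fitted
coefficients must satisfy $|g_j| \le \lambda W v_j$ for penalized zeros
and $g_j = \lambda W v_j \,\mathrm{sign}(\beta_j)$ for active
coefficients, with zero gradient on the unpenalized columns.

**Lambda selection.** Ten-fold cross-validation, seeded, with folds
redrawn until every fold contains an event (or, in boundary
configurations such as leave-one-out, until every training complement
does). The per-fold error is the Verweij–Van Houwelingen out-of-fold
deviance $-2\{\ell(\hat\beta_{-k}; \text{all}) - \ell(\hat\beta_{-k};
\text{train}_{-k})\}$, which avoids the instability of small-fold partial
likelihoods; the chosen $\lambda$ minimizes the mean cross-validated
deviance (no one-standard-error rule). The exported weight table contains
exactly the SNPs with non-zero coefficients at that $\lambda$.

Breslow tie handling is used throughout (penalized fit, `coxph` fits,
likelihood and gradient): ages carry heavy ties in real data and Breslow
is the convention penalized Cox solvers share. Missing genotypes are
mean-imputed as twice the effect-allele frequency, computed on training
data; at scoring time a weight whose effect allele matches the genotype
file's *other* allele is applied to the flipped count $2 - x$, and any
other allele mismatch is an error rather than a silent default.

## Percentile reference and hazard ratios

All risk bands are defined once, on the training-set controls younger
than 70 years (older controls are depleted of high-risk genotypes, which
would compress the reference distribution). Thresholds are
inverse-empirical-CDF (type 1) quantiles — no interpolation — so band
counts are exact for distinct scores; the top band is closed above, and a
score at the 95th-percentile threshold belongs to both the top 20% and
the top 5%. The "middle 40%" band is the 30th–70th percentile interval,
the natural centered band around the median; the bounds are configurable
(`mid_band`) since a 40th–60th reading is also defensible.

Hazard ratios between bands are derived from the *continuous*-score Cox
coefficient and the reference band means:
$\mathrm{HR}_{A/B} = \exp\{\hat\beta\,(m_A - m_B)\}$ with $m$ the mean
PHS inside the band among young controls. Computing the means on the
reference rather than the testing set keeps HRs comparable across testing
datasets and makes
$\mathrm{HR}_{80/20} = \mathrm{HR}_{80/50} / \mathrm{HR}_{20/50}$ an
exact identity — categorical band-indicator regression would not have
that multiplicative structure.

Because evaluation cohorts oversample cases, Cox fits are
sample-weight-corrected: controls get weight 1 and cases
$w = \frac{\pi}{1-\pi}\cdot\frac{N_{\text{controls}}}{N_{\text{cases}}}$,
so the weighted case fraction equals the population lifetime risk $\pi$
(default 0.12). This inverse-probability scheme is the standard
correction for case-enriched survival data; the exact formula used in the
original consortium analyses is not public, so ours is documented as the
package's choice. Confidence intervals come from a bootstrap stratified
by case status (preserving the design ratio), 1000 replicates by default,
with 2.5–97.5 percentile intervals and the replicate mean as the reported
value.

Endpoints: *any* disease (cases are events at diagnosis age), *clinically
significant* disease (Gleason $\ge 7$, PSA $\ge 10$ ng/mL, stage T3–T4,
nodal or distant metastases; non-significant cases censored at diagnosis
age, with dropping them available as an alternative since the original
convention is not stated), and *fatal* disease (prostate cancer deaths
are events at death age; everyone else censored at last contact).

## Family history and screening PPV

Family history (any first-degree relative diagnosed) is the clinical
comparator. Restricted to subjects with known family history, the package
fits Cox models with family history alone and with family history plus
PHS, compares them by a likelihood-ratio test ($\chi^2_1$,
$\alpha = 0.01$), and reports the PHS effect as
$\exp\{\beta_{\mathrm{PHS}}(m_{80}-m_{20})\}$ (top vs bottom quintile)
and the family-history effect as $\exp(\beta_{\mathrm{FH}})$. P-values
are two-sided and truncated at $10^{-16}$ ("<1e-16") — below that,
floating-point p-values are numerically meaningless.

PPV of PSA testing is the fraction of PSA-positive subjects whose biopsy
shows clinically significant cancer. Estimates and intervals come from
1000 bootstrap replicates drawn from PSA-positive cases and controls
separately while holding the 1:2 case:control screening ratio fixed;
PPV$_{80}$ and PPV$_{95}$ restrict each replicate to the top 20% / top 5%
of PHS using the training reference thresholds (one percentile definition
across the whole package). Both the bootstrap mean and the full-sample
plug-in estimate are reported, since which one a published figure shows
is often ambiguous.

## Incidence curves

A user-supplied population table of cumulative incidence by age (40–70)
is validated for monotonicity, linearly interpolated onto integer ages,
and split into clinically significant and non-significant components by
an age-specific fraction schedule. Risk-adjusted curves for the top 20%
and top 5% of genetic risk multiply the component curves by the mean
HR$_{80/50}$ and HR$_{95/50}$. The direct product is a rare-disease
approximation and is followed deliberately, with values clipped at 1.0
(with a warning); `risk_adjust_exact()` additionally provides the exact
proportional-hazards transform $1-(1-F)^{\mathrm{HR}}$ for comparison.
The bundled `synthetic_uk_incidence.csv` and
`synthetic_significant_fraction.csv` are synthetic tables with plausible
shape (incidence reaching ~5% by age 70, significant fraction rising from
0.30 to 0.62); they stand in for national statistics, which the package
does not redistribute.

## The synthetic cohort generator

`sim_config()` fixes the study conditions; the generator is seeded and
byte-reproducible. Defaults, chosen once as a realistic desk-scale
emulation:

* **Genotypes** — Hardy–Weinberg Binomial(2, f) counts, effect-allele
  frequencies on an even grid over [0.1, 0.9]; one duplicate pair per
  twenty SNPs (capped at 5) copies its partner per allele with fidelity
  0.99, giving population $r^2 = 0.98$ — above the 0.95 pruning
  threshold, as intended.
* **Onset** — Weibull proportional hazards, shape 4.5 and scale 140
  years: a steeply age-increasing hazard with lifetime risk near 0.12 by
  the late 80s. The linear predictor over causal SNPs (default one in
  five, per-allele effects on an even grid over [0.1, 0.5] with an
  occasional negative sign) is centered at its expectation so the
  baseline governs marginal risk. Controls censor uniformly on
  [55, 85] years.
* **Sub-phenotypes** — 55% of cases are clinically significant, realized
  by drawing a full clinical record (Gleason, PSA, stage, nodes,
  metastases) and classifying it with the same rule the pipeline uses;
  15% of significant cases are fatal, with death age = diagnosis age plus
  an exponential survival time of mean 5 years (the simplest model
  consistent with deaths being a case subset). Family history is
  Bernoulli with logit linear in the *standardized true* linear predictor
  (baseline rate 10%, slope 0.8) — family history proxies inherited risk,
  so it is tied to the truth, not to the fitted score — and is missing
  completely at random for 20% of subjects. Principal components are the
  first four left singular vectors of the column-centered genotype
  matrix, scaled to unit variance.
* **Design layers** — case-control sampling keeps all cases where
  possible and subsamples controls to the requested ratio (2:1 cases to
  controls for training-like enrichment), retaining the population
  prevalence as an attribute so weights remain computable. The screening
  layer marks all cases and enough random controls PSA-positive to hit a
  1:2 case:control ratio among screen-positives; biopsy outcome equals
  clinical significance for cases and is negative for screened controls.

What the generator does *not* emulate: realistic chromosome-scale LD
beyond the constructed duplicate pairs, ancestry admixture (the PCs of an
unstructured panel carry no signal — they are exercised as covariates,
not as confounder corrections), genotyping-array batch effects, and
informative censoring. Passing tests therefore demonstrate the
correctness of the machinery under the generator's assumptions, not the
predictive performance of any particular published score on real data.

## Numerical choices and degenerate inputs

* Seeds: every stochastic routine takes one; sub-seeds are derived by a
  seeded draw so nested steps stay independent and reproducible.
* Quantiles: type 1 everywhere a band is defined; bootstrap CIs use R's
  default continuous quantile.
* A degenerate (all-equal) reference yields equal thresholds and means
  with a warning, and `band_hr()` then returns 1 with a warning rather
  than NaN.
* `pairwise_r2` requires at least three pairwise-complete subjects and
  errors on zero variance; univariable Cox screens convert
  convergence/infinite-coefficient warnings into errors so degenerate
  fits cannot pass silently.
* Bootstrap replicates without events are redrawn up to a retry cap
  (default 100), then error.
* Problem sizes in the test suite (population cohorts of 3–40 thousand,
  250–1000 bootstrap replicates, 20–50 simulation replicates per
  property) were chosen to give stable Monte-Carlo margins for each
  assertion.

## Known limitations

* The sample-weighting formula and the exact CV loss of the original
  consortium analyses are not public; the documented IPW scheme and
  partial-likelihood deviance are this package's choices.
* Whether published interval estimates are bootstrap means or plug-in
  values is unstated; both are reported.
* The incidence adjustment inherits the rare-disease approximation; for
  common outcomes or large HRs the clipped product overstates risk, which
  is why the exact transform is emitted alongside.
* No per-ancestry score renormalization, no competing-risks modelling,
  and no haplotype-based LD estimation.
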