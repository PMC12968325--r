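---
title: "Calibrating PP3/BP4 score thresholds for a single gene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating PP3/BP4 score thresholds for a single gene}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(misscalib)
```

## The problem

ACMG/AMP variant interpretation admits computational (in silico) evidence
through the PP3 (pathogenic) and BP4 (benign) criteria, and modern practice
grades that evidence from *supporting* to *very strong* according to the
likelihood ratio the predictor achieves. Genome-wide calibrations of tools
such as CADD, REVEL, BayesDel and AlphaMissense exist, but tools are not
equally reliable in every gene, and a gene-specific calibration needs a
gene-specific truth set. For a rare single-gene disorder — the reference
case in this package is *PHOX2B*-associated congenital central
hypoventilation syndrome (CCHS) — only a few dozen variants have confident
pathogenic/benign assignments, while several hundred are variants of
uncertain significance (VUS). A purely empirical (nonparametric, local)
calibration of the kind used genome-wide would be hopelessly conservative
at this sample size. `misscalib` instead implements a parametric
calibration that borrows strength from the VUS pool through multiple
imputation.

## The model

For one tool with score $s$, pathogenicity is modelled by a logistic
regression

$$\Pr(\text{pathogenic}\mid s) = \operatorname{logit}^{-1}(\beta_0 + \beta_1 s),$$

so that $e^{\hat\beta_0+\hat\beta_1 s}$ is the posterior odds of
pathogenicity at score $s$. Dividing by the prior odds gives the positive
likelihood ratio

$$\mathrm{lr}^+(s) = e^{\hat\beta_0+\hat\beta_1 s}\,
  \frac{1-P_\mathrm{Path}}{P_\mathrm{Path}},$$

the quantity the evidence-strength system is anchored on. The calibration
([`calibrate_tool()`]) proceeds in four steps:

1. **Prior-matched initial fit.** A weighted logistic regression on the
   known pathogenic/benign variants only, with weights
   $P_\mathrm{Path}/P_{\mathrm{Path,samp}}$ for pathogenic and
   $(1-P_\mathrm{Path})/(1-P_{\mathrm{Path,samp}})$ for benign records
   ([`prior_matching_weights()`]), correcting for the over-sampling of
   pathogenic variants in curated datasets.
2. **Imputation.** $m = 25$ datasets are generated by drawing a
   pathogenic/benign label for each VUS from its step-1 model probability
   ([`impute_vus_labels()`]).
3. **Per-imputation fit.** Each imputed dataset is refitted over *all*
   variants, with weight 1 for known-class variants and
   $2\,|0.5 - p_{i}|$ for the $i$-th VUS ([`vus_weight()`]): a VUS the
   model is sure about counts almost fully, a coin-flip VUS not at all.
4. **Pooling.** Coefficients and their covariance are pooled across
   imputations by Rubin's rules ([`pool_rubin()`]): pooled covariance =
   mean within-imputation covariance + $(1+1/m)\times$ between-imputation
   covariance, applied elementwise to the full $2\times 2$ matrix.

### Confidence-bounded thresholds

Rather than the point estimate, the threshold search uses the one-sided
95% bound of the log-odds,

$$\mathrm{lr}^+_{LB}(s) = e^{\hat\beta_0+\hat\beta_1 s
  - z\sqrt{\hat\sigma^2_{\beta_0} + s^2\hat\sigma^2_{\beta_1}
  + 2s\,\mathrm{cov}(\hat\beta_0,\hat\beta_1)}}\,
  \frac{1-P_\mathrm{Path}}{P_\mathrm{Path}}, \qquad z = 1.64,$$

for the pathogenic direction; for the benign direction the odds are
inverted and the sign in front of $z$ flips (the *upper* bound of the
odds, hence the conservative side in both directions). The published
display of this formula shows $+1.64$ with text stating it is the lower
bound for the pathogenic direction and that the benign case changes the
sign; we implement the self-consistent reading ($-z$ pathogenic, $+z$ then
inversion for benign), which is the conservative one in both directions.
$z = 1.64$ is kept exactly as printed (not 1.645) and is configurable.

For each strength level, [`find_strength_thresholds()`] solves
$\mathrm{lr}^+_{LB}(s) = \mathrm{LR}_\text{target}$ by bracketed
one-dimensional root finding (`stats::uniroot` on a 4096-point grid
bracketing) over the tool's score domain. Levels whose target is never
attained inside the domain are reported unreachable (rendered "—"). If the
bounded LR crosses a target more than once — possible because the variance
term is quadratic in $s$ — the most conservative root is taken (largest
for pathogenic, smallest for benign) with a warning.

### Targets and priors

The likelihood-ratio targets default to the exponential strength scale
implied by the posterior-probability anchors 0.10 (supporting), 0.21
(moderate), 0.61 (strong), 0.98 (very strong) at the prior:
$\mathrm{LR} = \text{posterior odds}/\text{prior odds}$. At the default
prior this gives approximately 2.41, 5.76, 33.9 and 1062. Both the anchors
and the LRs can be overridden (e.g. to enter the genome-wide published LR
values verbatim). The prior defaults to
$P_\mathrm{Path} = 0.0441\,(1 + a)$ with adjustment $a = 0$: the published
account multiplies the genome-wide missense prior estimate 0.044 by
$(1 + P_\mathrm{missense})$ without defining $P_\mathrm{missense}$, so the
adjustment is exposed as configuration and defaults to zero. If the
supporting-level target does not exceed 1 under a user-supplied prior the
configuration is rejected, since both directions' intervals would overlap.

### Interval semantics

Thresholds partition the score domain into benign strength intervals, an
indeterminate middle, and pathogenic strength intervals. Pathogenic
intervals are closed at their lower bound (a score exactly at a pathogenic
boundary earns that strength), benign intervals are closed at their upper
bound. [`assign_strength()`] is total over the domain: every score falls
in exactly one bin; out-of-domain scores are clamped.

## The frequency-based benign rule

[`max_tolerated_af()`] implements the maximum credible population allele
frequency: genotype frequency
$\text{prevalence}\times\text{genetic het.}\times\text{allelic het.}/
\text{penetrance}$, halved for monoallelic (heterozygous) inheritance
(square root for biallelic). With the reference CCHS parameters
(prevalence $10^{-5}$, penetrance 0.40, genetic heterogeneity 0.75,
allelic heterogeneity 0.10) the unrounded value is $9.375\times10^{-7}$.
The final rounding is *upward* to one significant figure, giving
$10^{-6}$ (0.0001%): nearest-rounding would give $9\times10^{-7}$, and
rounding up is the choice consistent with the framework's stated aim of
minimizing wrongful benign classification (a higher threshold reclassifies
fewer variants). Records whose GroupMax filtering allele frequency (FAF)
*strictly* exceeds the threshold are reassigned benign; an FAF of exactly
the threshold, an FAF of 0 (present in gnomAD with FAF bound zero) or a
missing FAF never reclassifies, and an expert pathogenic label is never
silently overridden (a conflict warning is emitted instead).

## Evaluation

[`repeated_holdout_auc()`] estimates discrimination by 200 stratified
80/20 splits: each training set preserves the pathogenic/benign/VUS
proportions, the calibration is rerun on it with a single imputation, and
the held-out known-class variants are scored by model probability; the
rank-based (midrank Mann–Whitney) AUC ([`auc()`]) is averaged over
replicates. Sampling is keyed by sorted variant id, so results are
independent of row order. If a training draw is perfectly separable — the
weighted fit has no finite optimum and raises a separation error — the
replicate falls back to ranking test variants by the raw score oriented by
the class means, which is monotone-equivalent to any logistic model and
therefore gives the same AUC as any converged fit would.
[`class_score_difference()`] reports class means with a two-sided Welch
t-test by default (the published account does not name its test;
Mann–Whitney is selectable).

## Domain analysis

The reference critical domain is the PHOX2B homeodomain, codons 98–157
inclusive ([`domain_definition()`]); the narrower span sometimes quoted
(Arg99–Arg154) describes observed variants, not the domain, so the full
encoded span is used. [`domain_class_fraction()`] reports per-class domain
occupancy; [`domain_score_enrichment()`] compares mean prediction scores
of exhaustive theoretical variants inside vs outside the domain with a
Welch test. Whether theoretical variants are counted at nucleotide or
amino-acid level is ambiguous in the source material for per-SNV tools, so
both are supported (`collapse = "amino_acid"` keeps the per-substitution
maximum).

## Synthetic data and the reference stand-in

[`generate_variant_table()`] draws class-conditional truncated-normal
scores per tool, VUS labels from a latent mixture, residue positions from
a domain-enrichment model, and a benign-only common allele-frequency tail.
Defaults emulate the reference study conditions: 33/81/392
pathogenic/benign/VUS, protein length 314, homeodomain 98–157 holding 82%
of pathogenic variants, per-tool class means equal to the reference class
summaries, and class spread solved from the reference AUC by the binormal
relation $\sigma = (\mu_p-\mu_b)/(\sqrt2\,\Phi^{-1}(\mathrm{AUC}))$. The
latent VUS pathogenic fraction defaults to 0.12, near the fraction of
VUSs the best-performing tools predict pathogenic. Equal class variances
are the default so that an exact logistic oracle exists
([`theoretical_logistic_params()`]); truncation is applied after the
oracle is computed, which biases the oracle at extreme truncation — the
parameter-recovery tests therefore place means well inside the domain.
The in-domain mean shift of the exhaustive score generator defaults to 2
standard deviations, matching the magnitude of the reference in/out
domain score differences.

[`phox2b_synthetic_dataset()`] is a deterministic synthetic stand-in for
the 506-variant reference table, built entirely from published summary
statistics: known-class scores are truncated-normal quantile samples whose
location is solved so class sample means equal the published means
exactly; VUS scores are placed inside the published threshold intervals
with the published per-bin counts; homeodomain occupancy is 27/33 and
4/81 by construction. It reproduces the published class means, counts and
strength tallies exactly, and is useful for exercising the full pipeline —
but it is *not* the original data: its deterministic quantile scores carry
less sampling noise than real variants, so a full recalibration on the
stand-in yields a steeper pooled slope (and correspondingly lower
pathogenic thresholds) than the published fit. What passes on synthetic
data therefore demonstrates the correctness of the machinery, not the
published per-variant dataset.

## Numerical choices

* IRLS (hand-rolled, two parameters) converges at a coefficient change
  below $10^{-8}$, cap 100 iterations; covariance is the inverse weighted
  Fisher information at the optimum with dispersion fixed at 1, so
  fractional case weights are handled exactly.
* Separation is declared when the slope magnitude exceeds 100 per score
  unit during iteration (configurable); an optional ridge stabiliser can
  be enabled. Imputation fits that fail are dropped with a warning; the
  run errors if fewer than half survive.
* Imputation draws use a deterministic substream per imputation index,
  over VUSs in sorted-id order, so results are independent of row order
  and of imputation parallelism; seeded runs are bit-reproducible.
* AUC uses midranks, so ties count one half; the ROC polyline renders tie
  blocks as diagonal segments and integrates back to the AUC exactly.
* Degenerate inputs: equal constant samples give p = 1 in the class
  difference test; single-class inputs are errors, not NaNs; curation
  requires either a reference codon or an explicit SNV-achievability flag
  and never guesses.

## Problem sizes

The test-suite simulations use 5 000-variant tables for
parameter-recovery checks, 60–200 hold-out replicates, and 40-seed
uniformity checks for the null enrichment; these sizes give Monte-Carlo
errors comfortably below the asserted tolerances while keeping the whole
suite under a minute.

## Limitations

* Single-score models only: no multi-covariate or tool-ensemble fits.
* The VUS imputation probabilities are fixed from the step-1 fit (as the
  published method describes) rather than refreshed between imputations;
  a fully iterative EM-like variant would be a different estimator.
* Scores are treated as given; no annotation, liftover or HGVS validation
  against a reference sequence is performed.
* The synthetic generator draws tools independently; real inter-tool
  score correlation is not emulated.
* The reference-domain enrichment means for real genome-wide score tables
  can only be reproduced when the user supplies those tables; they are
  not shipped.
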