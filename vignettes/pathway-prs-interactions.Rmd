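---
title: "Pathway polygenic scores for gene-environment interaction: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway polygenic scores for gene-environment interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the statistics it implements:
the models, the simulation design and its calibration, the numerical
choices, and the places where the design was genuinely open and a choice
had to be made.

## 1. Models

### Interaction testing

For a binary disease indicator $D$, a risk score $G$, an exposure $E$
and covariates $Z$, the working model is

$$\mathrm{logit}\,P(D=1\mid G,E,Z) =
  \beta_0 + \beta_g G + \beta_e E + \beta_{ge}\,G\times E + \beta_z Z,$$

and the hypothesis of interest is $H_0:\beta_{ge}=0$, tested by the
likelihood-ratio statistic against the nested no-interaction fit
(`fit_interaction()`). The Wald test is reported alongside and backs the
confidence intervals; at the sample sizes this package targets
($n\approx 10^4$) the two agree closely, and the test suite asserts that
agreement. By default the score and exposure are mean-centered before
the product is formed; this is a pure reparameterisation — the
interaction estimate, its SE and both p-values are unchanged (asserted
numerically to $10^{-8}$) — but it makes the main-effect coefficients
read approximately as marginal effects, which is how applied reports
quote them.

`fit_joint_pprs()` fits one model carrying a main effect and an
interaction for *every* pathway score (conventionally including the
non-pathway complement), with per-score Wald tests and a global
$K{+}1$-df LRT. Correlated pathway scores (shared SNPs) are legal but the
fit refuses exact collinearity, naming the offending columns.

### Scores

PRS weights come from a *single joint* logistic model of disease on all
$M$ selected SNPs (`estimate_weights()`): each weight is the SNP's
log-odds ratio adjusted for the other members of the panel. Pathway
scores reuse those weights unchanged over SNP subsets
(`compute_scores()`); nothing is refit per subset. Two consequences are
load-bearing and tested: scores are linear in the weights, and for any
partition of the panel the subset scores sum exactly to the overall PRS.

Estimating weights on the same sample that is later used for interaction
testing biases PRS *main-effect* inference but not the interaction test:
marginal SNP-disease associations and interaction estimates are
asymptotically independent. The package's type-I-error study
(`run_type1_study()`) verifies this "double use" empirically under five
different weight-SNP selection rules, including deliberately
significance-contaminated ones (every SNP with scan $p<0.05$) and a
random mix of causal and null SNPs.

### Exposure-OR profiling

Under the fitted model the exposure odds ratio at score value $s$ is
$\mathrm{OR}_E(s)=\exp(\beta_e+\beta_{ge}s)$. `exposure_or_profile()`
evaluates this at score percentiles — empirical quantiles when scores
are supplied, standard-normal quantiles otherwise (appropriate for a
standardized score) — with delta-method intervals using
$\mathrm{Var}(\beta_e)+s^2\mathrm{Var}(\beta_{ge})+2s\,\mathrm{Cov}$.
Both percentile conventions are available because published figures
rarely say which was used; for a score standardized to unit SD the two
agree closely except in the extreme tails.

## 2. The simulation design

`scenario_spec()` encodes the reference design: 1,000 independent binary
SNPs with population frequency 0.35; a binary exposure of prevalence
0.50; 20 causal SNPs of which 5 also interact with the exposure; 5
pathway SNPs whose overlap with the interaction / main-effect-only /
null classes varies over nine scenarios (`make_scenario()`); disease
generated as Bernoulli with

$$P(D=1) = \mathrm{expit}\big(\delta_0 + \delta_E E +
  \textstyle\sum_k \delta_{G_k} G_k + \sum_k \delta_{G\times E_k} G_k E\big),$$

and quota sampling until exactly 5,000 cases and 5,000 controls are
retained. Null SNPs do not enter the disease model, so the simulator
draws them only for retained subjects; the joint law of the output is
identical to generating everything up front, at a fraction of the cost.

Two generative constants are not identified by the design and had to be
fixed:

* **Intercept / prevalence.** $\delta_0$ is solved exactly (by
  convolution of the causal-SNP contributions) so that population
  disease prevalence is 0.10 — a typical common-disease figure; under
  case-control logistic analysis the intercept is absorbed, and
  operating characteristics are insensitive to it.
* **Exposure main effect.** $\mathrm{OR}_E=1.5$, a moderate, realistic
  exposure effect. Interaction power depends on it only weakly.

What the generator does *not* emulate: linkage disequilibrium between
SNPs, dosage uncertainty, continuous exposures, covariate confounding or
ancestry structure. Passing tests therefore demonstrate the statistical
machinery under an idealised architecture, not robustness to the
correlation structure of real genotype panels (real-data mode accepts
dosages and covariates, but the simulator never generates them).

## 3. Effect-size calibration

The generative effect sizes are not free dials; they are solved from
power targets, re-implementing the role of an external power calculator:

* **Main effects**: $\delta_G$ such that the two-sided per-SNP marginal
  test at $\alpha=0.05/1000$ has 90% power at 5,000/5,000 and SNP
  frequency 0.35. The solver (`calibrate_main_effect()`) enumerates the
  genotype-by-disease cells of the single-SNP population model, converts
  them to case-control frequencies, and uses the expected-information
  Wald noncentrality; the solution is found by root-finding and is
  monotone in the power target. This yields $\delta_G = 0.2214$
  (OR 1.248).
* **Interaction effects**: $\delta_{G\times E}$ such that the single-SNP
  interaction test at $\alpha=0.05/20$ has 10% power
  (`calibrate_gxe_effect()`), via the analogous eight-cell calculation.

Two conventions needed deciding:

* **Sidedness of the interaction calibration.** For a detection target
  as low as 10%, the solved effect depends heavily on whether the 10% is
  directional or two-sided: the implied noncentralities are 2.33 versus
  3.03, a 14% difference in $\delta_{G\times E}$ that propagates into
  every aggregate power. The package defaults to *directional*
  (one-sided) power — the alternative hypothesis in the design is
  directional, and this convention reproduces the reference design's
  operating characteristics — with `sided = "two"` available. The
  default gives $\delta_{G\times E}=0.1277$ (OR 1.136).
* **Main effects of interaction SNPs.** An interaction contributes to a
  SNP's exposure-collapsed marginal effect, so interaction SNPs that
  share the main-effect coefficient of the other causal SNPs are
  somewhat easier to discover than the nominal 90% target. The default
  (`gxe_main_effect = "shared"`) accepts this; the alternative
  `"marginal"` shrinks their main effect until every causal SNP's
  *detectable* (marginal) effect meets the same target, iterating the
  two solvers to a joint fixed point. `"shared"` tracks the reference
  design's aggregate behaviour more closely and is the default.

Every calibration is verifiable by simulation: `verify_power()` runs the
single-SNP Monte-Carlo oracle and the test suite requires the empirical
rejection rate to sit within three binomial SEs of the target (at 600
replicates the defaults verify at 0.887 for the main effect and 0.103
for the interaction).

## 4. The scan and the replicate engine

The per-SNP scan (`marginal_scan()`) is the efficient score test against
the covariate-only null: one null fit serves all SNPs and the statistics
reduce to column sums, which is what makes $10^5$–$10^6$ per-replicate
tests feasible on a desktop core. At $n=10{,}000$ the score test agrees
with the per-SNP maximum-likelihood LRT to well within 10% on the
p-value (tested against a `glm()` oracle); `snp_assoc_refit()` provides
the exact refit where an individual SNP matters. Monomorphic SNPs get
$p=1$ and a flag rather than an error. Discovery applies the Bonferroni
threshold $0.05/1000 = 5\times10^{-5}$ with the *declared* panel size as
denominator.

`run_power_study()` chains, per replicate: simulate → scan → discover →
joint weights (on the discovered SNPs, same data) → PRS/pPRS/npPRS →
three interaction LRTs at $\alpha=0.05$. Two structural observations
keep the study cheap:

* The nine scenarios share an identical generative law and differ only
  in which SNPs are *labelled* as the pathway, so one set of replicates
  is scored against all scenarios at marginal cost. Estimates across
  scenarios are therefore correlated (which, if anything, stabilises
  cross-scenario orderings); each is individually unbiased.
* With shared weights, the non-pathway score equals PRS minus pPRS
  exactly, so it is formed by subtraction.

Each replicate runs on an indexed substream of the master seed, so
results are bit-reproducible and independent of execution order.
Replicates with zero discovered SNPs (or an empty pathway intersection)
contribute non-rejections and are tallied. Interaction fits use the
unstandardized scores — interaction power is invariant to score scale —
while real-data mode standardizes so that reported ORs are per SD.

Problem sizes: the packaged studies use 300 replicates for power
(binomial SE ≤ 2.9 points) and 500 for type-I error (SE ≈ 1 point at the
5% level), with the full 1,000-replicate setting available through
`n_reps`.

## 5. Pathway overrepresentation

`overrepresentation_test()` cross-tabulates reference genes by pathway
membership and query membership and applies Fisher's exact test. The
defaults condition on the *mapped* query size (genes actually linked
from the SNP panel), not the panel size, and test one-sided
overrepresentation — enrichment is the scientific question, and
reported directions in applications are uniformly "+" — with
`alternative = "two.sided"` available since annotation services do not
always document their convention. Expected counts are
$\mathrm{ref}\times n_{query}/N_{ref}$ and fold enrichment is
observed/expected; the identity fold × expected = observed is asserted
to floating tolerance, and the Fisher p-value is checked against
brute-force hypergeometric enumeration for every table with a universe
of at most 100 genes. FDR is Benjamini–Hochberg, validated against the
step-up definition $\min_{j\ge i} p_{(j)} m/j$.

Annotation input is deliberately file-based (SNP→gene, gene→pathway,
reference sizes as TSVs): live annotation services change under a
pinned analysis, and file ingestion keeps the mapping reproducible. The
reference file must state the release's total annotated gene count,
since published tables print expected counts but not the universe size.

## 6. Numerical choices and degenerate inputs

* Logistic fits in the replicate loop use a lean Newton IRLS with step
  halving (deviance-monitored, 60-iteration cap), equivalent to
  `glm.fit` to ~12 digits on the same designs but about twice as fast,
  which matters at ~50 fits per replicate. Rank deficiency is detected
  up front via QR and reported with the collinear column names.
* Separation in the joint weight model triggers one retry with a small
  ridge penalty ($\lambda = 10^{-3}$ per observation, intercept
  unpenalised) and a flag; weights from a ridged fit remain valid for
  score construction.
* Quota sampling caps total draws at 100× the expected requirement and
  errors with the implied-prevalence diagnosis rather than spinning.
* Score standardization refuses to divide by a zero SD (constant score)
  and warns instead; the replicate engine treats constant scores as
  automatic non-rejections.
* Genotype dosages outside $[0,2]$ are an error naming the row and
  column; missing dosages are mean-imputed with a per-column report, the
  convention of standard PRS tooling. Strand-ambiguous (A/T, C/G)
  scoring-file SNPs are rejected rather than silently flipped.

## 7. Known limitations

* The simulator's independence assumptions (no LD, no covariates) mean
  simulated power is an upper bound on what correlated real panels give.
* The non-pathway interaction test can run slightly anticonservative in
  scenarios where strong pathway interactions are omitted from its
  model: omitting an interacting score makes the remaining genetic
  effect exposure-dependent through logistic non-collapsibility. This
  is a property of the single-score working model, visible in the
  scenario studies, and is one reason the joint all-scores model
  (`fit_joint_pprs()`) is provided.
* Weight estimation assumes the joint logistic model is fittable at the
  discovered panel size ($M \ll n$); shrinkage-based genome-wide scores
  are out of scope.
* Real-data mode trusts the supplied annotation tables; no attempt is
  made to resolve gene-identifier synonymy or enhancer-to-gene linking.
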