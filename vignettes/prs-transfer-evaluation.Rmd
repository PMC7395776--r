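---
title: "Evaluating a polygenic risk score across populations: models and methods"
author: "prstransfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating a polygenic risk score across populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prstransfer)
```

## The problem

A polygenic risk score (PRS) is a weighted sum of risk-allele dosages,
$\mathrm{PRS}_i = \sum_k \beta_k x_{ik}$, with per-allele log odds ratios
$\beta_k$ estimated in a development population. When the score is carried
into a different population, three things change at once: some variants that
are common in the development population are rare in the target population
(so the score's variance shrinks), the per-SD effect size depends on whose
standard deviation defines the "SD", and absolute risks depend on the target
population's incidence and competing mortality. This package implements the
full evaluation chain for that transfer problem — scoring, recalibration,
association and discrimination statistics, closed-form polygenic-model
predictions, absolute-risk projection, and cross-population concordance of
per-SNP effects — together with a synthetic-cohort generator that emulates
the statistical structure of a large breast-cancer case-control evaluation,
so that every estimator can be exercised and checked against known ground
truth without access to consortium individual-level data.

## Scoring and standardisation

`compute_prs()` resolves each panel variant in the dosage source by
identifier, flips dosages ($x \to 2 - x$) where the file's counted allele is
the panel's other allele, and errors on allele pairs matching neither
orientation. Palindromic (A/T, C/G) variants are matched by identifier first;
a `strict` mode rejects them on any allele mismatch. Missing dosages for a
resolvable variant are a hard error: the intended inputs are fully imputed
dosage sets, and silent mean-imputation would bias scores towards the panel
frequency.

Variants with imputation INFO below a cutoff (default 0.9) are removed by
`filter_by_info()` before scoring; `restrict_to_available()` additionally
drops panel variants absent or monomorphic in a particular dosage source.
When the SNP set shrinks this way the remaining weights are *not*
renormalised — scores from nested SNP sets are compared as-is, which is the
convention the summary tables this package emulates follow (their reduced-set
score means exceed the full-set means, consistent with no rescaling).

`standardize_prs()` divides raw scores by a reference-control SD without
mean-centering, so "OR per SD" always refers to an explicit, recorded SD.
`rescale_or()` converts an OR between SD conventions
($\exp(\ln \mathrm{OR} \cdot \sigma_{to}/\sigma_{from})$); with the bundled
defaults, an OR of 1.52 per European-control SD (0.597) becomes 1.48 per
Asian-control SD (0.556). Group summaries use the unbiased ($n-1$) SD — at
the precision such tables are printed, $n$ vs $n-1$ is indistinguishable, and
$n-1$ is the epidemiological convention.

## Association statistics

Per-SD odds ratios come from maximum-likelihood logistic regression
(`fit_logistic_per_sd()`), by default adjusted for ten principal-component
covariates and study/array/batch stratum indicators; confidence intervals are
Wald. Percentile-bin odds ratios (`percentile_bin_or()`) define bins by
control-distribution quantiles (type-7 convention; a value exactly at a
boundary goes to the upper bin — the convention is arbitrary but fixed and
documented) applied to cases and controls alike, with the 40–60% bin as
reference. Prospective hazard ratios use a Cox model on the age time scale
with delayed entry and Efron tie handling (`fit_cox_per_sd()`).

The study-adjusted AUC (`study_adjusted_auc()`) is the concordance over
within-stratum case-control pairs only, ties counting one half, pooled with
pair-count weights. This is one defensible reading of "AUC adjusted by
study"; it is invariant to monotone within-stratum transforms and reduces to
the ordinary Mann–Whitney AUC with a single stratum.

`fixed_effect_meta()` pools log-scale estimates by inverse variance and
reports Cochran's $Q$, $I^2 = \max(0, (Q - df)/Q)$ and a chi-square
heterogeneity p value. This is the fixed-effect-weight moment form; the
generalised-Q random-effects variant some forest plots use is deliberately
not reimplemented, a simplification flagged here. Interaction tests add a
product term to the logistic model and use the Wald z statistic — the
asymptotic equivalent of a t test on the coefficient.

Family-history attenuation (`fh_attenuation()`) fits the first-degree
family-history OR with and without conditioning on the PRS and reports
$100(\ln \mathrm{OR}_{unadj} - \ln \mathrm{OR}_{adj})/\ln \mathrm{OR}_{unadj}$;
the percentage is undefined (flagged NA) when the unadjusted OR is at or
below 1, which genuinely happens in small cohorts.

## The multiplicative polygenic model

With control PRS standard normal (per control SD) and log odds linear in the
PRS with slope $\gamma$, the case distribution is — in the rare-disease
limit — the control distribution shifted by $\gamma$. Three closed forms
follow:

* familial relative risk due to the score,
  $\lambda_P = \exp(\gamma^2/2)$, and the log-scale share of an assumed
  familial relative risk $\lambda$ explained,
  $\gamma^2 / (2 \ln \lambda)$ (`lambda_p()`, `frr_explained()`);
* predicted percentile-bin ORs,
  $\{[\Phi(b-\gamma)-\Phi(a-\gamma)]/[\Phi(b)-\Phi(a)]\}$ for bin $[a,b]$
  against the same ratio in the reference bin (`predicted_bin_or()`);
* theoretical AUC $\Phi(\gamma/\sqrt{2})$ (`theoretical_auc()`).

A modelling point worth stating prominently: $\gamma$ enters these formulas
as the **log** odds ratio per control SD. Quoted "OR per SD" values of, say,
1.48 must be logged first — only $\gamma = \ln 1.48$ reproduces the ~11%
familial-risk share that pairs with that OR; using 1.48 itself would give
nonsense. `polygenic_model(or_per_sd = , control_sd = , reference_sd = )`
does the conversion, including the SD-ratio rescaling when the quoted OR is
per a *reference* population's SD: $\gamma = \ln(\mathrm{OR}) \cdot
\sigma_{control}/\sigma_{reference}$.

`predicted_bin_or()` defaults to the rare-disease normal-shift form; an
`"exact"` mode integrates case and control densities under the model's
stated finite prevalence. At prevalence 0.01 the two differ by under 1% on
the log scale even in the extreme 1% bins; both modes are provided because
which one a given published prediction curve used is generally not
recoverable from the publication. Tests verify the predictions against a
Monte-Carlo simulation of the logistic model ($10^7$ draws in the acceptance
suite, $2\times10^6$ in the unit test) and verify the probability-conservation
identity (control-mass-weighted case enrichment sums to 1).

## Absolute risk with competing mortality

`calibrate_group_hazards()` converts percentile-group relative risks $r_g$
(ORs treated as RRs, adequate at the low annual risks involved) and a
population rates table into group-specific hazards constrained so that the
survivor-weighted mean of the group hazards equals the population incidence
at every age:
$$\lambda^*(u) = \lambda_{pop}(u)\,\frac{\sum_g f_g S_g(u)}{\sum_g f_g S_g(u) r_g},
\qquad \lambda_g(u) = r_g \lambda^*(u),\qquad S_g(u+1) = S_g(u)(1-\lambda_g(u)).$$
On a discrete one-year grid this forward recursion satisfies the constraint
*exactly* (to $10^{-12}$ in the property tests), so no fixed-point iteration
is needed; the recursion is the natural discrete implementation of an
"iterative" average-incidence calibration. Survivor weighting is chosen over
static weighting because it is the exact-conservation choice: the
whole-population cumulative risk assembled from calibrated groups then equals
the direct single-population computation to $10^{-10}$.

Cumulative risk is the discrete sum
$AR_g = \sum_u \lambda_g(u) S_g(u) S_m(u)$, with $S_m$ built from competing
(non-disease) mortality only — the input table must already exclude
disease-specific deaths — and both survival functions renormalised to the
starting age for conditional (e.g. 10-year) risks. Lifetime risk is reported
to age 80 by default; hazards with $\lambda_g(u) \ge 1$ (relative risk too
extreme for the grid) are an error rather than silently truncated.

`screening_eligibility()` builds fine centile groups (default 0.1%-wide)
whose relative risks are truncated-normal means of $e^{\gamma z}$,
normalised so the fraction-weighted mean is exactly 1, declares a centile
eligible if its maximum 10-year risk over ages 20–70 reaches the threshold
(default 2.3%, the 10-year risk of a 50-year-old woman of European
ancestry, i.e. the risk level at which conventional age-based screening
starts), and reports the eligible population fraction and the share of
calibrated lifetime cases they account for. A life-history microsimulation
($1.5\times10^5$ women in tests) confirms the case-capture arithmetic.

## Cross-population concordance of per-SNP effects

`fit_per_snp_effects()` fits one logistic regression per SNP per population
(log-additive dosage effect, adjusted for age, stratum and principal
components) and records estimate and Wald SE. `em_icc()` fits the
hierarchical measurement-error model $y_{ij} = \beta_{ij} + \delta_{ij}$,
$\delta_{ij} \sim N(0, \sigma_{ij}^2)$ with known $\sigma_{ij}$, by EM: the
E-step shrinks each estimate toward its SNP mean with precision weights
(equation in `?em_icc`), and the M-step treats the shrunken values as
complete data — $\alpha_i$ is their per-SNP mean and $\sigma_R^2$ their
pooled squared deviation. Iteration stops when the ICC changes by less than
$10^{-8}$. The ICC is defined as
$\mathrm{Var}(\hat\alpha_i)/(\mathrm{Var}(\hat\alpha_i)+\sigma_R^2)$ with
the unbiased sample variance — the natural estimand for this model, made
explicit here because variance-ratio "ICC" admits several conventions.

Two properties of the plug-in (complete-data) M-step deserve note. First,
because $\alpha_i$ is estimated per SNP, it absorbs $1/m$ of the residual
variance when $m$ populations contribute; the ICC$\to$0 limit (no
between-SNP spread, genuine within-SNP variation) is therefore approached
only as $m$ grows, and the limit test uses $m = 10$. Second, under pure
sampling noise the plug-in $\sigma_R^2$ can collapse towards zero (a known
hard-EM behaviour); the package reports `converged` and `n_iterations`, and
the test suite compares the EM fit against an independent
marginal-likelihood oracle (profiled over $\alpha_i$, maximised numerically
over $\sigma_R^2$), which shares the profile-likelihood degrees-of-freedom
bias and therefore isolates genuine disagreements. Agreement is within
±0.05 across simulated panels, and shared-architecture panels at realistic
GWAS standard-error scales (0.02–0.08) give ICC well above 0.7.

## The synthetic-cohort generator

The generator produces every input the real evaluation consumed, with
recorded ground truth. Its defaults are the study conditions this package
emulates:

| parameter | default | rationale |
|---|---|---|
| `n_snps` / `n_low_info` | 313 / 26 | panel size and low-INFO count; the INFO filter then retains 287 |
| `frac_rare_pop2` | 0.15 | 43 of 287 European-common SNPs rare in the target population |
| `per_sd_log_or` | log(1.52) | per-reference-SD effect for overall disease |
| `control_sd_pop1` / `control_sd_pop2` | 0.597 / 0.556 | reference / target control PRS SDs |
| `n_cases` / `n_controls` | 15,755 / 16,483 | case-control sample sizes |
| `prevalence` | 0.05 | baseline prevalence for case sampling; not stated by the emulated design, exposed as a parameter |
| `er_pos_frac` / `er_neg_frac` | 0.66 / 0.30 | ER-positive / ER-negative shares among cases |
| `fh_relative_correlation` | 0.5 | PRS correlation with one first-degree relative |
| `fh_prevalence` | 0.07 | marginal family-history prevalence, a realistic Asian lifetime figure |
| `n_women`, `followup_years`, `event_rate` | 10,255, 19.05, 413/195,317.2 | prospective cohort size, mean follow-up and marginal event rate |

Dosages are independent binomial(2, freq) draws — no linkage disequilibrium.
The polygenic theory being tested treats SNPs as exchangeable independent
contributions, and LD matters only for weight *derivation*, which is out of
scope; independence keeps the normal-approximation oracles exact in the
limit. Case status is sampled by rejection from a finite population under a
logistic model whose intercept is solved numerically for the configured
prevalence; by default individual PRSs are drawn from the normal
approximation (the limit the dosage model converges to), with a dosage mode
for tests that need genotypes. One seeded generator drives each dataset and
the seed is recorded, so identical configurations are byte-identical.

Because one shared weight vector cannot hit two population SDs exactly,
weights are scaled to match the reference-population SD and the target
population's SD is *emergent* (recorded in the ground truth); with the
default rare fraction it lands close to, but not exactly at, 0.556 — the
distributional-fidelity tests compare generated SDs against the recorded
panel-implied values. Family history simulates exactly one first-degree
relative (correlation 0.5, same log-linear risk model, marginal prevalence
calibrated numerically); pedigrees beyond that, LD, and genotype-error
models are non-goals. ER subtype is assigned independently of the PRS by
default, mirroring how subtype shares enter the emulated tables.

What passing tests on these data do **not** show: robustness to LD between
scored variants, to ancestry-confounded PCs (the simulated PCs are pure
noise covariates), to genotyping or imputation error beyond the INFO-filter
bookkeeping, or to non-normal PRS distributions. They demonstrate that the
estimators recover the parameters of the stated data-generating process at
the stated sample sizes.

## Numerical choices and degenerate inputs

* Logistic fits: IRLS with convergence tolerance $10^{-8}$, 100-iteration
  cap; non-convergence (separation) is an error with the deviance reported.
* Bin boundaries: type-7 quantiles; boundary values go to the upper bin;
  empty bins are an error.
* Meta-analysis: SEs recovered from CI endpoints as
  $(\ln u - \ln l)/(2 z_{0.975})$; zero-width CIs are an error.
* EM: ICC-change tolerance $10^{-8}$, 1000 iterations, $\sigma_R^2$ floored
  at $10^{-12}$; non-convergence warns and returns `converged = FALSE`.
* Rates: annual probabilities in [0, 1); a per-100,000 flag on the reader;
  negative or non-contiguous grids are errors.
* Intercept calibration integrates the logistic-normal marginal on
  $[-8, 8]$ SDs with `uniroot` at $10^{-10}$ tolerance.

## Problem sizes used by the test and acceptance suites

Parameter-recovery runs use the full study-scale cohort (32,238 women) per
seed, 100 seeds in the acceptance suite; distributional checks use 10,000+
individuals; the Monte-Carlo bin-OR oracle uses $10^7$ draws in the
acceptance test and $2\times10^6$ in the unit test; the screening
microsimulation uses $1.5\times10^5$ life histories; EM-vs-oracle
comparisons use 120–150 SNPs across three seeds. These sizes were chosen so
Monte-Carlo error is comfortably inside each assertion's tolerance.

## Known limitations

* ORs are treated as RRs in the absolute-risk calibration; fine at the
  annual hazards involved here, increasingly wrong above a few percent per
  year.
* The study-adjusted AUC is one reading of stratum adjustment; other
  published adjustments (e.g. model-based covariate-adjusted ROC) will
  differ in the third decimal.
* The fixed-effect heterogeneity statistics use moment Q on fixed-effect
  weights, not the generalised-Q random-effects estimator.
* The EM ICC is the plug-in variant described above; a full EM with
  posterior-variance augmentation would report slightly larger
  $\sigma_R^2$.
* Subtype-specific weights in the generator are proportional rescalings of
  the overall weights; a subtype-differential architecture is limited to
  scaling, not re-ranking, of SNP effects.
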