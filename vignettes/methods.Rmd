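---
title: "Models and methods behind triptanscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind triptanscore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triptanscore)
```

# The scientific setting

Cluster headache (CH) patients differ widely in whether they regularly use
triptans, the first-line abortive medication. Because direct response data
are rarely collected systematically, regular usage of the fast-acting forms
(subcutaneous injection, nasal spray) serves as a proxy for response, with
three groups: **users** (any fast-acting form), **tablet-only users**
(excluded from analysis — tablets are slow-acting and rarely appropriate for
CH attacks), and **non-users** (no triptans in any form; patients who
reported trying triptans without effect, and ergotamine users, count as
non-users). `triptanscore` analyses five candidate variants against this
grouping and compares clinical features between users and non-users.

The non-user group is the *case* group throughout: the scientific question
is what keeps patients off an effective drug, so every odds ratio is
oriented as odds(non-user) per unit of exposure.

# The association model

For a variant with effect allele $a$, let $d_i \in \{0,1,2\}$ be the number
of copies individual $i$ carries. The additive model is the logistic
regression

$$\operatorname{logit} P(\text{non-user}_i) = \beta_0 + \beta_1 d_i +
\beta_2\,\text{male}_i,$$

fitted by maximum likelihood; $e^{\beta_1}$ is the per-allele odds ratio
with a Wald 95% interval. Sex is the default covariate because usage
differs strongly by sex. The genotypic model replaces $d_i$ with indicator
contrasts against the reference homozygote and reports a 2-df
likelihood-ratio test (fewer df when a genotype class is absent). Both
Wald and likelihood-ratio p-values are exposed, since published analyses
rarely state which their software reported.

The effect allele defaults to the minor allele of the pooled called sample,
which reproduces the direction convention of the reference allele tables.
Multiple testing uses Bonferroni with $m = 5$ — the number of *variants*,
not models: the bi-allelic and tri-allelic 5-HTTLPR analyses share one slot.
The display convention prints `> 1.0` when $mp > 1$.

## The IRLS engine

The logistic fits use an in-package iteratively reweighted least squares
engine rather than `glm()`, so the estimator is exactly the documented one
and is itself testable against independent oracles (the test suite checks
it against both `glm` and a gradient-free likelihood grid search).
Numerical choices: start at $\beta = 0$; at most 50 iterations; convergence
when the log-likelihood improves by less than $10^{-10}$; weights floored
at $10^{-12}$; no penalisation. Complete or quasi-complete separation is
detected by a diverging coefficient norm (any $|\beta_j| > 30$ during
iteration, $>10$ at exhaustion) or by every fitted probability pinned to
0/1 at a likelihood plateau; separated fits are flagged and report no
numeric OR, matching how a careful analyst treats such tables.

## Hardy–Weinberg testing

Biallelic variants use the exact conditional test: given the allele counts,
heterozygote counts share the parity of the rare-allele count, their
conditional distribution is computed in log space, and the p-value is the
total probability of all configurations no more probable than the observed
one (tie tolerance $1+10^{-12}$, relative). The tri-allelic 5-HTTLPR system
uses a seeded Monte-Carlo permutation test: alleles are pooled, re-paired
uniformly, and the conditional probability of each permuted genotype table
is compared with the observed one, with the add-one estimator
$p = (1 + \#\{\text{perm} \le \text{obs}\})/(1 + n_{\text{perm}})$.
HWE is assessed on the full genotyped sample including tablet-only users —
the most inclusive choice; the grouping is an outcome, not a sampling frame.

# The 5-HTTLPR/rs25531 system and RFLP calling

The 43-bp promoter indel has long (L) and short (S) alleles; rs25531 splits
L into L~A~ and L~G~, and L~G~ expresses like S. Three analysis codings are
supported: raw tri-allelic, **bi-allelic** (L = L~A~ or L~G~ vs S; only
insertion presence matters), and **collapsed** (L~A~ vs S\* where S\* pools
L~G~ with S on expression grounds).

BcnI digestion yields constant 126 bp and 62 bp fragments for every allele
plus diagnostics: 341 bp (L~A~), 174 + 167 bp (L~G~), 298 bp (S). Expected
gel patterns for the six diploid genotypes are the deduplicated unions of
the per-allele sets (shared fragments co-migrate as one band); the six
patterns are pairwise distinct, which the package asserts. Calling matches
observed lengths at a relative tolerance of ±4% (default): 7 bp separates
the L~G~ doublet, below 3% agarose resolution, so a single observed band
within tolerance of both 174 and 167 satisfies both. The constant 126/62
bands are required for any call because they confirm digestion worked. A
pattern that is a clean L~G~/S *plus* an extra 341 bp band is called L~G~/S
but flagged `sequencing_required` — the extra band suggests a hidden L~A~
and such samples should be Sanger-confirmed before analysis; the pipeline
treats unconfirmed flagged calls as missing.

# The genetic effector score

A variant's **effector allele** is the allele more common in non-users than
users (frequency difference between groups, not the within-group majority).
Exact ties raise an error demanding an explicit override; overrides always
beat the data-driven choice and are tagged, which is how a cohort-based
assignment can be kept against conflicting literature (the panel's
rs6724624 C assignment is the standing example). The score is the
unweighted sum of effector-allele copies over the five variants, range
0–10, with 5-HTTLPR scored on its bi-allelic recoding (S copies; L~A~ and
L~G~ both non-effector). Individuals missing any scored genotype are
excluded — no imputation, matching the analysis the score reproduces.

The score regression is

$$\operatorname{logit} P(\text{non-user}) = \beta_0 + \beta_s\,s +
\beta_m\,\text{male} + \beta_a\,\text{age}$$

with age in years, uncentered, so coefficients are on the scale usually
reported (about 0.03 per year of age). Identifying effector alleles in the
analysis cohort itself is circular in-sample — the fitted score coefficient
is biased away from zero under the null. The package therefore accepts an
external effector specification for honest evaluation, and its own
recovery experiments (below) always score with the *generating*
specification.

# The synthetic cohort generator

The generator is first-class, tested code; it emulates the study design the
analysis assumes:

- **Genotypes**: two i.i.d. alleles per variant (Hardy–Weinberg), at pooled
  allele frequencies computed from the reference allele-count tables
  (`default_allele_freqs()`; e.g. rs1024905 G ≈ 0.510). The tri-allelic
  L~G~ frequency is the bi-allelic L count minus the L~A~ count over the
  total — the only decomposition the published tables admit. Variants are
  independent (no linkage disequilibrium).
- **Usage**: tablet-only status is drawn independently at rate 27/545;
  everyone else is non-user with probability
  $\operatorname{logit}^{-1}(\beta_0 + 0.204\,s + (-0.483)\,\text{male} +
  0.031\,(\text{age}-\bar{\text{age}}))$, the reported coefficient values
  as ground truth. The intercept is calibrated by solving for the marginal
  non-user fraction 109/518 over the exact score distribution (a 5-fold
  binomial convolution), the sex mix, and a 201-point quadrature grid on
  the truncated age distribution. Age enters the *generator* centered so
  the intercept controls the marginal rate directly; the *analysis* uses
  uncentered age — the slope is unaffected, only the intercept scale
  differs.
- **Demographics**: 65.6% male; age from a normal with mean 50.3, sd 14.3
  years truncated to [18, 90], rounded to whole years (survey resolution;
  also makes file round trips exact).
- **Clinical answers**: drawn per question from group-conditional category
  probabilities scaled from the published per-group percentages; numeric
  features (disease duration, age at onset) from group-conditional
  truncated normals. Tablet-only users reuse the user profile for the
  questions never tabulated for them. 5% of answers to the multi-tick
  severity-ordered questions receive a second ticked category, exercising
  the most-severe rule (the true multiplicity rate was never reported; 5%
  is a realistic questionnaire figure chosen once).
- **Missingness**: MCAR per variant at rates implied by the published call
  rates (qPCR SNPs 4–9 failures per 518; 5-HTTLPR 13 per 545 = 97.6%), and
  MCAR per question at rates matching the published response denominators.
  Non-response in real surveys is unlikely to be MCAR; no informative
  mechanism is modelled because none was characterised.

One root seed spawns eight component substreams in a fixed, documented
order (demographics, genotypes, tablet assignment, usage, delivery forms,
clinical answers, genotype missingness, clinical missingness), so
regeneration is byte-identical and changing one component's inputs does not
scramble the others.

What passing tests on these cohorts shows — and does not: the pipeline
recovers known parameters under the model's own assumptions (HWE,
independence, MCAR, correct link). Real cohorts violate several
(stratification, LD, informative missingness), so the tests certify the
machinery, not robustness to those violations.

# Clinical comparison

2×2 tables use Pearson chi-square **with** Yates continuity correction;
larger tables are uncorrected, on $(r-1)(c-1)$ df. This asymmetric
convention is deliberate: it is the one that reproduces the reference sex
comparison (p = 0.037; uncorrected gives ≈ 0.030). A zero row/column total
is a structural zero and an error; expected cells below 5 set a flag rather
than silently switching tests. Numeric features — including age and age at
onset, for which no test was ever named in the source analyses — use the
two-sample Wilcoxon rank-sum test, exact when the combined sample is ≤ 50
without ties, otherwise the continuity-corrected normal approximation.
Severity orders for the most-severe rule ship as package defaults matching
the questionnaire's category layouts. Computed p-values are reported as-is
and capped at 1 for display.

# Detectable odds ratios

For a control effect-allele frequency $p_0$ and odds ratio
$\theta$, the case frequency is $p_1 = \theta p_0 / (1 + p_0(\theta - 1))$.
`power_at_or()` computes the power of the *uncorrected* two-proportion
chi-square test at level $\alpha$ by default through **exact enumeration**:
the rejection probability is summed over the full binomial outcome grid
$(x_1, x_0)$, which is exact for the stated test and agrees with simulation
to Monte-Carlo error by construction. The closed-form normal approximation
(pooled-variance critical value, unpooled alternative variance) is kept as
`method = "approx"` and agrees to ~0.01 at these sample sizes.
`detectable_or()` bisects each side of $\theta = 1$ until the power is
within $10^{-6}$ of the target.

Two design choices deserve explanation. First, the default counting unit is
the **individual** (109 cases vs 409 controls, frequency treated as an
exposure proportion), the convention of the classical two-group power
programs; allele-level counting (218 vs 818) is available via
`unit = "allele"` and gives intervals roughly 30% narrower. The
individual-level convention is the default because it is the one under
which the published detectable-OR intervals for this design are
reproducible. Second, the reference control frequencies
(`reference_control_freqs()`: 0.47, 0.15, 0.29, 0.42, 0.42) are
European reference-panel scale values; the exact panel figures behind the
published intervals were never printed, so the package's reproduction of
those intervals is a consistency check at ±10%, not an exact target.

# Problem sizes and runtime choices

The test suite and acceptance script size their simulations for a desk run:
estimator-recovery uses 200 cohorts of n = 489 (matching the complete-case
count of the motivating analysis); coverage checks use 300 replicates of
n = 2000; HWE recovery uses one cohort of n = 10 000; the power solver is
validated against 20 000–100 000-replicate simulation oracles. These sizes
keep Monte-Carlo error well below the tolerances being checked while
completing in minutes.

# Known limitations

- Usage is a proxy for response; contraindications and side-effects also
  produce non-usage, and the generator inherits that interpretive limit.
- The effector score is unweighted and in-sample; no independent-cohort
  validation is modelled.
- No LD, population structure, or informative missingness in the
  generator.
- The VCF export covers only the four biallelic SNPs (the tri-allelic
  indel system has no faithful biallelic VCF encoding) and uses
  placeholder coordinates; the pipeline itself is position-agnostic.
- The tri-allelic HWE test is Monte-Carlo, not exact; its resolution is
  bounded by $1/(1+n_{\text{perm}})$.
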