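---
title: "Methods: building and validating weighted risk checklists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and validating weighted risk checklists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(checkrisk)
```

## The instrument and its scoring model

checkrisk works with the simplest family of clinical prediction
instruments: a checklist of dichotomous risk factors with small positive
integer weights. For a participant with item indicators
$x_j \in \{0, 1\}$ and weights $w_j \ge 1$,

$$S = \sum_j w_j\,x_j, \qquad 0 \le S \le \textstyle\sum_j w_j,$$

and the score maps to one of a handful of contiguous, named risk bands.
The packaged default instrument has 23 items, four of them double-weighted
(lifetime suicide attempt, lifetime psychiatric hospitalization, lifetime
nonsuicidal self-injury, lifetime borderline personality disorder), so the
maximum attainable score is 27; its six bands run 0–2 (lowest risk), 3–5,
6–8, 9–11, 12–14, and ≥15 (highest risk). Printed versions of the source
instrument label the top band "15–30"; since 27 is the attainable maximum
under the documented weights, we honour the printed label by making the
top band unbounded above rather than by inventing weights that reach 30.
A definition file can override any weight if a different configuration is
wanted.

**Missing data are scored as absent.** This is a deliberate property of
the instrument, not an imputation shortcut: a clinician who cannot
establish a risk factor leaves it unticked, and scores must remain
computable in exactly that situation. The package additionally reports a
per-participant count of missing items, and `score_cohort()` exposes an
optional completeness filter (`max_missing_frac`, default off) for study
designs that cap allowable missingness (e.g. at 35%).

## Discrimination: rank AUC and DeLong inference

All discrimination statistics are rank-based. The AUC is the
tie-corrected Mann–Whitney probability

$$\widehat{AUC} = \frac{1}{n_1 n_0} \sum_{i \in \text{cases}}
  \sum_{j \in \text{controls}}
  \left( \mathbf{1}[S_i > S_j] + \tfrac12 \mathbf{1}[S_i = S_j] \right),$$

computed via midranks. The ½-tie convention is load-bearing here: integer
checklist scores on tens of thousands of participants are almost all
tied, and any other convention changes the AUC materially. A binary
(yes/no) rater has a one-point ROC curve and the closed form
$AUC = (Se + Sp)/2$.

Standard errors and the paired two-score test use DeLong's
placement-value (structural component) estimator, provided by the pROC
package behind this package's interface. Confidence intervals are Wald on
the AUC scale, truncated to $[0,1]$ — published tables for this family of
instruments print symmetric intervals, which is what the untransformed
Wald interval produces; a logit-scale interval is available via
`auc_delong(..., logit = TRUE)` for AUCs near the boundary. A degenerate
AUC of exactly 0 or 1 has zero DeLong variance; the interval then
collapses to a point and a warning is raised. For the paired test, two
scores with rank-identical orderings have a zero-variance difference and
are reported as an exact tie ($z = 0$, $p = 1$) rather than `NaN`.

The test suite checks the estimator against independent routes: exhaustive
case–control pair enumeration for the point estimate (all $n \le 50$), a
2,000-replicate stratified bootstrap for the standard error, and a
1,000-replicate null simulation for the size of the paired test (5% ± 2%).

## Cut-point analysis and the quality indices

A positive screen is `score >= cutoff` throughout. For each cutoff the
package reports the confusion counts, prevalence $P$, positivity $Q$,
sensitivity, specificity, Youden's $J = Se + Sp - 1$, PPV, NPV, efficiency
(raw accuracy, $(tp+tn)/N$), and the chance-corrected quality indices

$$k(1) = \frac{NPV - (1-P)}{P}, \qquad
  k(0) = \frac{PPV - P}{1-P}, \qquad
  k(0.5) = \frac{2\,k(1)\,k(0)}{k(1) + k(0)},$$

with $k(0.5) = 0$ when $k(1) + k(0) = 0$. These are kappa-like rescalings
of the predictive values: a perfect test scores 1 on all three and a test
independent of the outcome scores 0, which makes them readable at the very
low prevalences (<1%) where raw PPV is inevitably tiny. The source
literature cites these indices without printing their formulas; the forms
above were fixed because they reproduce every checkable printed value at
cut scores 6 and 9 to the printed precision, and they should be read as
reverse-engineered in that sense. `optimal_cut()` maximizes $J$, breaking
ties toward the lower (more sensitive) cutoff.

Concentration-of-risk capture curves answer "what fraction of all future
events occurs in the top $q$ of scores?" Integer scores make exact
fractions unattainable, so thresholds flag whole score levels — never
splitting a tied score — using the smallest threshold whose flagged
fraction does not exceed $q$ when one exists, and the realized flagged
fraction is always reported alongside the captured fraction.

## Association statistics

Logistic calibration of outcome on score is fitted by IRLS
(`stats::glm`, binomial; convergence at $10^{-8}$ log-likelihood change or
100 iterations), with Wald per-point odds ratios and Nagelkerke's

$$R^2_N = \frac{1 - \exp\{2(LL_0 - LL_1)/n\}}{1 - \exp\{2 LL_0/n\}}.$$

Complete separation is detected and flagged (`converged = FALSE`) rather
than silently reported. Contingency analysis uses Wald intervals on the
log scale with $z = 1.96$ for both OR and RR — validated against the
printed interval 433.6–7,855.3 for the highest-versus-lowest band
comparison, which matches the Wald form to within rounding and rules out
exact or profile intervals — and Pearson's chi-squared without continuity
correction. Zero cells yield infinite estimates by default; the
Haldane–Anscombe +0.5 correction is available behind a flag. Risk-group
tables always take the lowest band as the reference category.
Report-level rounding follows the conventions of the published tables
(`round_report`: rates and percentages 1 dp, OR/RR 1 dp, AUC and kappa
indices 2 dp); full precision is retained internally.

## Measure development

Development is a two-stage, fully deterministic procedure.

1. **Evidence ranking.** Each candidate variable carries a 0–40 evidence
   score summing four meta-analytic components: the 0–10 rank of its broad
   risk category for death and for attempts, and its 0-or-6–10 rank among
   the top five specific predictors of each. Candidates enter strictly in
   descending evidence order (ties: attempt-category rank, then id), so
   strongly supported predictors are given the first claim on shared
   signal. This mirrors how the source instrument was built and is *not*
   greedy best-first selection; with correlated candidates the two can
   diverge.

2. **Forward selection on incremental AUC.** Starting from the empty
   score, each candidate is tentatively added with weight 1 and retained
   iff (a) its bivariate AUC exceeds 0.5 in at least one development
   cohort, (b) the cumulative AUC improves by at least $\varepsilon_{gain}$
   in at least one cohort, and (c) it drops by no more than
   $\varepsilon_{loss}$ in every other cohort. The published account states
   the retention logic but not numeric thresholds. We set
   $\varepsilon_{loss} = 0.01$ because the printed development trajectory
   shows retained steps with per-cohort dips of about 0.01 (e.g.
   0.92→0.91), and $\varepsilon_{gain} = 0.001$ — one order below the 2-dp
   resolution of the printed trajectory — so genuine sub-rounding gains
   count while pure noise does not. Both are `selection_params()`
   arguments. A final pass doubles the weight of nominated top predictors
   under the same gain/loss rule. Doubling the sole item of a score can
   never help (AUC is rank-invariant); doubling matters only once the item
   competes against sums of others.

The selection trace records per-cohort cumulative AUC after every
decision, and the suite verifies it is exactly reproducible by rescoring
the retained prefix from scratch. The procedure's operating
characteristics are pinned by a recovery experiment (also the acceptance
property): three cohorts of $n = 4{,}000$ with 23 independent
Bernoulli(0.2) items, ten of which raise the outcome log-odds by 0.9 each
(intercept −4.3, event rate ≈ 11%), must yield ≥ 8/10 informative and
≤ 3/13 null retentions. At these settings the observed result is 10/10
and 0/13. The human-in-the-loop exploration reported for the source
instrument (re-orderings, alternative operationalizations) is
deliberately not emulated; the algorithmic procedure is the package's
contract.

## The synthetic cohort generator

The generator exists to provide cohorts with the statistical structure the
analysis assumes — not to impersonate any real study population. Items
follow a single-factor Gaussian threshold (copula) model: participant
severity $L \sim N(0,1)$, and item $j$ is present iff

$$\lambda L + \sqrt{1-\lambda^2}\,e_j > \Phi^{-1}(1 - p_j),$$

which preserves each marginal prevalence $p_j$ exactly for any loading
$\lambda \in [0, 1)$ while inducing positive inter-item correlation —
enough to produce the heavy right tail a risk score needs. The outcome
depends on the items only through the score:
$Y \sim \text{Bernoulli}(\text{logit}^{-1}(\alpha + \beta S))$ with
defaults $\alpha = -7.15$, $\beta = 0.41$, the published calibration for
the combined validation cohort.

The published record gives score moments but no per-item prevalences, so
the package ships a documented default prevalence vector (plausible adult
general-population rates, weighted sum ≈ 3.3) and calibrates $\lambda$ by
bisection (`calibrate_loading`, 50,000 simulated participants per
evaluation, fixed internal seed, monotonicity of SD in $\lambda$) so the
score SD hits the target 2.5. The calibrated default is
$\lambda = 0.40$, giving, at $n = 18{,}024$: mean ≈ 3.3, SD ≈ 2.5, mode 2,
skewness ≈ +1.1, and outcome prevalence ≈ 0.6–0.7% (the study cohorts
printed 0.7–0.9%). All randomness derives from one seed through a
Lehmer-step splitting rule, so item and outcome streams are independently
reproducible.

**What the generator does not emulate — and what passing tests therefore
do not show.** Observed score skewness (≈1.8) is steeper than the copula
default (≈1.1); a zero-inflated or mixture structure might match it better
but is untestable without raw data, so the single-factor form is a
declared approximation. Item-level outcome effects are absent by
construction (outcome is conditionally independent of items given the
score), which is why simulated AUCs plateau near 0.80 while the real
cohorts reached 0.91–0.92: the published full-data AUCs are **not**
reproducible from any information in the published record, and no test
here claims otherwise. Survey design, attrition, subgroup-specific
generating processes, and instrument wording are all out of scope.

## Numerical and degenerate-input conventions

- All-tied score vectors have AUC exactly 0.5 (every pair ties), which is
  also the selection algorithm's starting cumulative AUC for the empty
  score.
- Empty confusion margins raise errors naming the undefined statistic;
  PPV with zero positives is reported as missing, not 0.
- `k(0.5)` is defined as 0 at $k(1)+k(0)=0$ to extend the harmonic mean
  continuously through the chance point.
- Band definitions must be contiguous from 0 with an unbounded top band,
  so band assignment is total and needs no error path.
- Cut-point ties in `optimal_cut` resolve toward the lower cutoff (higher
  sensitivity), the clinically conservative choice for a screen.
- Fixture count tables are checksummed against their published totals
  (17,630 / 18,024 / 35,654 participants; 288 events) at load time.

## Problem sizes used by the test suite

The suite favours the smallest sizes at which each property is decisive:
pair-enumeration oracles at $n \le 50$; bootstrap SE comparison at
$n = 200$ with 2,000 replicates; paired-test size at 1,000 replicates of
50 cases + 50 controls; selection recovery at 3 × 4,000 participants;
parameter recovery and the acceptance script at the validation-cohort size
$n = 18{,}024$ (20 replicates in the script, median reported); calibration
closure at 50,000. These choices are the package's own balance of
Monte-Carlo resolution against runtime.

## Known limitations

- The quality-index formulas are reverse-engineered from printed values
  (exactly reproduced at every checkable row), not transcribed from a
  stated formula.
- The evidence-ordered, single-pass selection is a deterministic
  approximation of a partly manual published procedure; its thresholds
  are declared defaults, not inferred constants.
- The generator's copula dependence is single-factor with a common
  loading; per-item loadings and item-level outcome effects are documented
  extension points.
- Checklist weights are positive integers by design (bedside
  computability); fractional-weight instruments are out of scope.
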