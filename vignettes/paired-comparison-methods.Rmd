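---
title: "Comparing two binary diagnostic tests under a paired design: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing two binary diagnostic tests under a paired design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compbdt)
```

## The data model

Two binary diagnostic tests and a gold standard are applied to every subject
of one random sample of size $n$. Cross-classifying disease status by the two
test results gives eight cells: $s_{ij}$ diseased and $r_{ij}$ non-diseased
subjects with result $i$ on Test 1 and result $j$ on Test 2 ($1$ positive,
$0$ negative), with group totals $s$ and $r$. Because both tests are applied
to the same subjects, results are correlated within a disease group; all
comparison statistics below account for that pairing through the joint cells.
The object returned by `paired_counts()` carries the cells and every derived
margin, and the package validates the table before any analysis: cells must
be non-negative integers, both disease groups non-empty, and each test must
have a positive estimated Youden index $\hat Y = \hat{Se} + \hat{Sp} - 1$ (a
test no better than chance cannot be meaningfully compared).

Three parameter families describe performance:

* *accuracies*: sensitivity $Se = P(T = 1 \mid D)$ and specificity
  $Sp = P(T = 0 \mid \bar D)$;
* *likelihood ratios*: $PLR = Se / (1 - Sp)$ and $NLR = (1 - Se)/Sp$,
  prevalence-free summaries equivalent to relative risks;
* *predictive values*: $PPV = P(D \mid T = 1)$ and $NPV = P(\bar D \mid T = 0)$,
  the clinically facing quantities, which depend on the prevalence
  $p = P(D)$.

## Estimation and confidence intervals

Sensitivities, specificities, predictive values and the prevalence are
binomial proportions; each is estimated by its observed proportion with the
usual binomial standard error (for the predictive values,
$\sqrt{ab/(a+b)^3}$ with $a$ and $b$ the diseased and non-diseased counts in
the relevant test-result margin). Interval estimation uses a modified Wilson
interval with centre shrunk towards $1/2$ by
$(m + z^4/53)/(m + z^2)$ and half-width $\tfrac{z}{m + z^2}\sqrt{m\hat p(1-\hat p) + z^2/4}$,
where $m$ is the trial count and $z$ the $1-\alpha/2$ normal quantile. Both
denominators use $m + z^2$, the Wilson-score form; we verified empirically
(and the test suite asserts) that this form attains close to nominal
coverage — about 95% at $p = 0.3$, $m = 50$ — whereas an $m + z^4$
denominator in the shrink factor distorts the centre for small $m$.

A likelihood ratio is a ratio of two *independent* binomial proportions (one
per disease group), i.e. a relative risk. Its interval is the approximate
score interval computed after adding $0.5$ to the four margins involved
(with $+1$ on the group totals), which has the best reported coverage among
ratio intervals; when a limit of the quadratic form falls outside its
admissible range, or on the wrong side of the point estimate, the closed-form
single-proportion bound replaces it. Zero margins are therefore harmless for
interval estimation, although the point estimate itself may be reported `NA`
(a degenerate ratio).

## Simultaneous comparisons

For each family the package tests the *global* null (both parameters of the
family equal across tests) at level $\alpha$, and only investigates the
individual hypotheses when the global test is significant — the analogue of
an omnibus ANOVA followed by post-hoc contrasts. The two individual p-values
are resolved by the Holm step-down method (smaller p-value against
$\alpha/2$, then the larger against $\alpha$), which dominates Bonferroni.
For each individual null that is rejected, an oriented confidence interval
(difference or ratio arranged to be positive, naming the test with the larger
parameter) is reported; when the global null is retained no contrast interval
is produced.

*Accuracies.* The individual Wald statistics are
$\chi^2_{Se} = s(s_{10}-s_{01})^2 / \{4 s_{10}s_{01} + (s_{11}+s_{00})(s_{10}+s_{01})\}$
(1 df) and its non-diseased analogue; the global statistic is their sum
(2 df) — an identity the test suite asserts on fuzzed tables. A deviance
(likelihood-ratio) version built from the discordant cells is reported
alongside when all discordant cells are positive; each individual deviance is
referred to a chi-square with 1 df, the natural reference for a deviance, and
its signed root is attached for users who want a normal deviate. Simulation
evidence on which these methods rest makes the choice of procedure depend on
prevalence and sample size: with estimated prevalence at most 10% and
$n \le 100$ the global step is skipped and the two individual Wald tests are
Holm-resolved directly; otherwise the global test runs first and significant
results are resolved by individual Wald tests when $n \le 100$ or
$n \ge 1000$ and by McNemar tests with continuity correction,
$(|s_{10}-s_{01}|-1)^2/(s_{10}+s_{01})$, for intermediate $n$. The boundary
$n = 1000$ belongs to the Wald branch. Sensitivity (specificity) differences
get the adjusted Wald interval with Laplace-type smoothing, centred at
$(a-b)/(t+2)$, which has closed form and near-Tango performance.

*Likelihood ratios.* The contrast is
$\omega = (\ln(PLR_1/PLR_2), \ln(NLR_1/NLR_2))$. Its covariance follows by
the delta method from the conditional binomial variances of
$\hat{Se}_i, \hat{Sp}_i$ and the within-group covariances
$\widehat{Cov}(\hat{Se}_1,\hat{Se}_2) = (s_{11}/s - \hat{Se}_1\hat{Se}_2)/s$ and
$\widehat{Cov}(\hat{Sp}_1,\hat{Sp}_2) = (r_{00}/r - \hat{Sp}_1\hat{Sp}_2)/r$;
the groups are independent. The global statistic is
$\omega' \Sigma^{-1} \omega$ (2 df); the individual statistics are the
standardized log-ratios. The test suite checks the whole covariance against a
10,000-replicate multinomial bootstrap (agreement within 10%). The
post-hoc interval for the PLR ratio is on the log scale,
$\widehat{ratio}\cdot\exp(\pm z\sqrt{V})$; for the NLR ratio a Wald-type form
$\widehat{ratio}\cdot(1 \pm z\sqrt{V})$ is used, in both cases with $V$ the
delta-method variance of the log-ratio (the relative variance). The NLR form
is not inversion-equivariant, so the ratio is always oriented larger over
smaller before the interval is built, and the lower limit is floored at 0.

*Predictive values.* The individual tests are weighted generalized score
statistics: for the PPVs,
$T = (\hat{PPV}_1-\hat{PPV}_2)^2 / [\{\hat{PPV}_p(1-\hat{PPV}_p)-2C_p\}(1/n_{1\cdot}+1/n_{\cdot 1})]$
with pooled $\hat{PPV}_p = (2s_{11}+s_{10}+s_{01})/(2n_{11}+n_{10}+n_{01})$
and overlap correction
$C_p = \{s_{11}(1-\hat{PPV}_p)^2 + r_{11}\hat{PPV}_p^2\}/(2n_{11}+n_{10}+n_{01})$;
the NPV statistic is symmetric, with
$C_p = \{s_{00}\hat{NPV}_p^2 + r_{00}(1-\hat{NPV}_p)^2\}/(2n_{00}+n_{01}+n_{10})$.
Note both $C_p$ terms square a *complement*; the symmetry between the PPV and
NPV forms pins the expression down. The global test treats the eight cell
proportions as one multinomial (prevalence random, since predictive values
mix the two groups), propagates the covariance of
$\eta = (PPV_1, PPV_2, NPV_1, NPV_2)$ by the delta method, and refers
$\eta'\varphi'(\varphi\Sigma\varphi')^{-1}\varphi\eta$ with
$\varphi = \bigl(\begin{smallmatrix}1&-1&0&0\\0&0&1&-1\end{smallmatrix}\bigr)$
to a chi-square with 2 df. Difference intervals invert the score statistic:
$\hat{PV}_1-\hat{PV}_2 \pm z\sqrt{\text{variance term}}$, so the interval
width is exactly $2z$ times the root of the statistic's denominator.

When the two tests give identical results on every subject the contrasts are
exactly zero while their variance estimates also degenerate to zero; the
statistics then take their null value 0 by convention rather than `NA`.

## Retrospective power and the type II error

When a global test is significant the package reports its estimated power;
when it is retained (and the estimates differ), the estimated probability of
a type II error — valuable evidence about whether a negative finding is
trustworthy, with values above roughly 20% signalling an underpowered
comparison. Both are estimated by Monte Carlo: `reps` multinomial samples of
size $n$ are drawn with the observed relative frequencies as cell
probabilities, the family's global test is applied to each at level
$\alpha$, and the rejection fraction (or its complement) is returned together
with its binomial Monte Carlo standard error. Replicates on which the
statistic cannot be computed (degenerate denominators, boundary margins, a
singular contrast covariance) are discarded and redrawn, with a cap of
$100 \times$ `reps` total draws; the count of regenerated replicates is
reported. The replicate analysis deliberately reuses the decision-rule
branch selected by the *observed* table (e.g. the global Wald branch at
$n = 871$, or the Holm-resolved individual pair under the low-prevalence
small-sample rule), because the quantity of interest is the operating
characteristic of the test actually applied; per-replicate re-selection of
the branch would estimate a different, composite procedure. The default is
10,000 replicates with a fixed seed (1234) so that reports are reproducible;
power estimates for two tests with *identical* observed estimates are refused
as non-identifiable, since no observed alternative defines them.

The same engine, `mc_rejection_rate()`, accepts arbitrary cell
probabilities, which is how the test suite checks calibration: under a null
configuration (two tests with equal $Se = 0.85$, $Sp = 0.75$, prevalence
$0.4$, within-group correlation $0.3$ — a realistic mid-range setting for
paired diagnostic studies) at $n = 500$, each global test's empirical
rejection rate stays within 1.5 percentage points of the nominal 5% over
5,000 replicates.

## Numerical and design notes

* Proportion intervals are clipped to $[0,1]$, difference intervals to
  $[-1,1]$, ratio intervals floored at 0.
* Chi-square p-values are always recomputable from the statistic and its
  stated reference distribution; a zero statistic has p-value 1.
* Tiny p-values print as `< 0.001` (at the default `decip = 3`) rather than
  as a misleading `0.000`; the underlying numeric values are kept in the
  returned object.
* Infeasible statistics never abort a run: `feasibility()` enumerates, per
  statistic, what the zero pattern of the table allows, the comparison
  functions report "not computable" notes for the rest, and the remaining
  output is produced. Only structurally invalid input (negative,
  non-integer, empty group, non-informative test) is an error.
* Under case-control sampling (`design = "case_control"`), the group sizes
  are fixed by design, so the prevalence and all predictive-value output are
  suppressed and replaced by an explanatory note; accuracies and likelihood
  ratios, which condition on disease status, are unaffected.
* Monte Carlo problem sizes used by the shipped test suite — 10,000
  power replicates, 5,000 calibration replicates per family at $n = 500$,
  2,000 coverage replicates, 1,000 fuzzed tables — were chosen to keep the
  binomial standard error of every checked rate well below the asserted
  tolerance.

## What the checks do and do not show

The simulation checks draw from ideal multinomial models: a perfectly
accurate gold standard, no missing test results, no covariate structure, and
within-group dependence fully described by the joint cells. Passing them
shows the statistics are computed correctly and are well calibrated under
those conditions; it does not address verification bias, an imperfect
reference standard, or clustered sampling, none of which the method models.
All tests are asymptotic: with very sparse discordant cells the Wald and
score statistics remain computable but their nominal levels degrade, which is
why the feasibility rules and the published decision thresholds (prevalence
at most 10%, $n$ at 100 and 1000) gate which statistic is used.
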