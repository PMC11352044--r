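---
title: "Fold-change estimators under distributional stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fold-change estimators under distributional stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcbench)
```

## The model

A fold change compares the expected value of a variable between a treatment
group `b` and a reference group `a` as a ratio, communicated on the log2
scale,

$$\mathrm{logRatio} = \log_2 E_b - \log_2 E_a,$$

and converted to a signed symmetric fold,
$FC = 2^{\mathrm{logRatio}}$ for non-negative log ratios and
$FC = -2^{-\mathrm{logRatio}}$ otherwise, so that $|FC| \ge 1$ and a
one-third ratio reads as $-3$. All ambiguity lives in $E$. fcbench
implements the full registry — arithmetic mean, median, geometric mean
(mean of logs), median of logs, and all-combinations pairwise ratios with
mean, median and bootstrap aggregation — behind one fitting function,
`fold_change()`, and scores recovery against a known truth with the signed
fold-scale error

$$\mathrm{Error}_{FC} = \operatorname{sign}(\log_2 FC_{\mathrm{calc}})\,
2^{|\log_2 FC_{\mathrm{calc}}|} -
\operatorname{sign}(\log_2 FC_{\mathrm{true}})\,
2^{|\log_2 FC_{\mathrm{true}}|}.$$

Two algebraic facts anchor the test suite:

1. **Pairs–geometric identity.** The mean over all ordered cross pairs of
   $\log_2(b_i/a_j)$ equals $\overline{\log_2 b} - \overline{\log_2 a}$
   exactly, so `pairs_mean` and `mean_of_logs` are the same estimator
   computed two ways.
2. **Log-normal bias of the arithmetic mean.** If
   $a \sim \mathrm{LogNormal}(\ln m, s_a)$ and
   $b \sim \mathrm{LogNormal}(\ln(FC\,m), s_b)$, then
   $E[b]/E[a] = FC \cdot e^{(s_b^2 - s_a^2)/2}$, so the ratio of
   arithmetic means is biased by $(s_b^2 - s_a^2)/(2\ln 2)$ bits while the
   median, the geometric mean and the paired median all target
   $\log_2 FC$ itself. Every qualitative failure this package demonstrates
   — error trends across a variance sweep, regulation-direction crossovers
   on volcano plots, divergence on permuted matrices — is this one bias
   expressed in different designs.

A subtlety of the error metric: because $\mathrm{Error}_{FC}$ is a signed
difference of signed folds, a constant *negative* log-ratio bias (the
$s_b < s_a$ case) makes $\mathrm{Error}_{FC}$ negative on *both* sides of
$FC = 1$ — below 1 the fold magnitude is over-estimated, above 1 it is
under-estimated. The classical "error reverses direction at FC = 1"
description refers to over- versus under-estimation of the fold magnitude,
i.e. to $\operatorname{sign}(\log_2 FC_{\mathrm{true}})\cdot
\mathrm{Error}_{FC}$. The sweep report therefore carries both columns
(`error` and `mag_error`), and the reversal tests assert on the latter.

## Estimator internals and numerical choices

* **Log base.** log2 throughout, including inside the mean/median-of-logs
  estimators.
* **Positivity.** All estimators work in the log domain and reject
  non-positive measurements with an error naming the variable. No
  pseudo-count option is offered: silently shifting data changes the
  estimand. Matrix-level scans can instead record offending variables as
  `NA` rows (`on_error = "na"`), which is what the simulation experiments
  use, since a normal generator with a generous spread occasionally
  produces non-positive draws — those are flagged, never truncated.
* **Medians** of even-length vectors are the midpoint of the two central
  order statistics, R's convention.
* **Pairwise estimators.** Below `pair_cap` (default $10^7$) cross pairs
  the pair set is enumerated. Above it nothing is subsampled: the pairs
  mean collapses algebraically to a difference of means, and the pairs
  median — the two-sample Hodges–Lehmann estimator on the log scale — is
  found exactly by rank-counting bisection over the value axis followed by
  enumeration of the narrow band containing the middle ranks. When massive
  ties pin the middle rank inside a band narrower than one ulp, the band
  endpoint is returned (exact for tied data). This keeps $10^8$-pair
  problems at a few milliseconds with no Monte-Carlo error.
* **Bootstrap variants** resample `a` and `b` independently with
  replacement to their original sizes, recompute the pair aggregate, and
  average over `bootstrap_reps = 100` replicates. The replicate count is a
  package convention (a widely used default magnitude for smoothing a
  resampled statistic), as is the case-resampling scheme; both are
  explicit arguments. On identical non-degenerate groups the bootstrap
  estimators are therefore zero only in expectation, with noise shrinking
  as replicates grow.
* **Seeding.** Every stochastic function takes a `seed`; child seeds for
  replicates and cells are drawn from the master seed and recorded in the
  output, so any single cell is independently recomputable. Seeded calls
  restore the caller's RNG state.

## What the generators emulate

`sim_spec()`/`generate_sample()` draw one variable's two groups from seven
families: degenerate identity, uniform on $(0, m)$, normal $(m, s)$ in
measurement units, log-normal with natural-log location $\ln m$ and
log-scale spread $s$, the two cross-family mixtures (one group normal, the
other log-normal), and a per-element random mixture of the four base
families. The log-normal parameterisation makes `fc_true` the ratio of
medians and geometric means — deliberately *not* of arithmetic means;
that asymmetry is the whole point of the comparison. Location defaults to
`m_a = 100`, chosen so normal draws at the default spread
(`s_normal = 10`) stay positive with overwhelming probability; both are
arguments.

`generate_panel()` emulates a multi-omics-like panel: `d` independent
variables with per-variable parameters drawn from predefined ranges
(log-normal: $m \sim U(30,40)$, $s \sim U(1,5)$; normal:
$m \sim U(500,600)$, $s \sim U(20,200)$; true ratios uniform on
$[1/3, 3]$), group sizes defaulting to 50 + 50 (configurable, e.g.
95 + 50 to mirror a case/control cohort shape). Panels serialise to plain
TSV plus a JSON sidecar of every generating parameter.

What the generators do **not** emulate: count data (no negative-binomial
RNA-seq model), missingness, batch effects, or between-variable
correlation. Passing stress tests here shows robustness to distribution
shape and variance inequality — not to those other realities of omics
data.

## The four studies and their scales

All replicate counts and group sizes below are the package defaults,
chosen to keep Monte-Carlo standard errors well inside the asserted
tolerances; each `run_*` driver accepts smaller values for exploration.

* **Distribution stress** (`run_distribution_stress`): 7 families × group
  sizes {10, 10000} × 8 methods × 25 replicates. At $n = 10{,}000$ the
  identity/uniform/normal rows recover the truth to within 0.05 fold
  units for every estimator, while in the cross-family mixtures the
  arithmetic-mean method's error strictly dominates all others. At
  $n = 10$ nothing is reliable — small samples defeat every estimator.
  The re-logged variant recomputes everything on log2-transformed data,
  emulating fold changes accidentally taken on already-logged pipeline
  output: rankings survive on clean data, magnitudes stop meaning "times
  expression", so no truth-error is attributed there.
* **Variance sweep** (`run_variance_sweep`): log-normal data on the grid
  FC ∈ [0.1, 6] (20 points) × $s_b/s_a \in \{0.1,0.5,1,2,4,8\}$ ×
  $s_a \in \{0.1, 1\}$, $n = 10{,}000$, 25 replicates per cell, with OLS
  trend lines of error against true FC per panel. The closed-form bias is
  verified two ways: directly at $n = 10^5$ within three Monte-Carlo
  standard errors, and as a regression of observed log-ratio error on
  predicted bias across sweep cells with $\sigma \le 2$, whose slope must
  be 1 within 0.05. Cells with $\sigma_b \in \{4, 8\}$ are excluded from
  that regression on first principles: the relative standard error of a
  log-normal sample mean grows like $e^{\sigma^2/2}/\sqrt{n}$, so at
  $\sigma = 4$ and $n = 10^4$ the sample mean is orders of magnitude away
  from convergence and the expectation bias is unobservable at any
  desk-scale $n$. The bootstrap estimators are excluded from the sweep's
  default method list purely for runtime; they are arguments away.
* **Significance panels** (`run_significance_panel`): $d = 99$ variables
  per family, all methods × Wilcoxon-Mann-Whitney and Welch t, Spearman ρ
  of $|\log_2 FC|$ against $-\log_{10} p$ and against the true effect,
  plus crossover detection between the arithmetic-mean and geometric-mean
  estimators. A variable counts as a crossover only when both log ratios
  exceed 0.1 bits in magnitude with opposite signs — the floor guards
  against sign flips at numerical zero and is a documented convention.
  On normal panels all method × test combinations give concordant,
  mutually similar correlations; on log-normal panels with $s \sim U(1,5)$
  the bias reaches many bits and crossovers are essentially certain.
* **Permutation stress** (`run_permutation_stress`): fold changes and
  tests computed before and after globally shuffling every matrix entry
  across both dimensions. Global entry shuffling (rather than independent
  row/column reordering, which would leave each variable's distribution
  intact) is the interpretation that actually destroys per-variable
  structure: each variable becomes an arbitrary mixture of the pooled
  matrix while the pooled value multiset — and hence pooled skewness and
  kurtosis — is conserved exactly. Reported are between-method Spearman
  matrices and each method's concordance with the rank-sum test.

## Distribution profiling

`profile_distribution()` estimates the Box-Cox exponent by profile maximum
likelihood over $\lambda \in [-3, 3]$ (grid step 0.01, via the standard
`MASS` profiling), snaps it to Tukey's ladder
$\{-2, -1, -\tfrac12, 0, \tfrac12, 1, 2\}$ with ties broken toward 1, and
tests normality of raw and log2 values with Shapiro-Wilk at
$\alpha = 0.05$. The normality test and level are package conventions —
reported normality fractions depend on them, which is precisely why such
fractions from other studies should not be compared numerically without
knowing the test. Two practical notes: above 5000 observations the
Shapiro-Wilk test is applied to 5000 evenly spaced order statistics
(deterministic, no resampling); and $\lambda$ is only identified when the
coefficient of variation is appreciable (roughly > 0.1) — for nearly
constant positive data far from the origin every power transform is
almost affine and the fitted exponent is noise. Constant variables return
a degeneracy flag rather than an error.

Degenerate significance inputs follow the same philosophy: a constant
pooled variable yields $p = 1$ with a `degenerate` flag instead of an
exception, so matrix-wide scans never abort. P-values are reported without
multiplicity correction by default (the volcano-plot convention); a
`p_adjust` argument exposes `stats::p.adjust` for those who want it.

## Design choices that were genuinely open

* **Exact pairwise median instead of subsampling.** Above the enumeration
  cap a seeded pair subsample would have been simpler, but introduces
  Monte-Carlo error into a deterministic estimator exactly where group
  sizes are largest; the selection algorithm is exact, faster than
  sorting a subsample of comparable accuracy, and keeps the
  pairs/geometric identity testable to machine precision.
* **Failure records over aborts.** Experiment grids never stop on a
  single bad cell: generator pathologies (non-positive normal draws)
  become flagged rows carrying the error message, and summaries report
  failure counts per cell.
* **Welch by default.** The package's entire subject is unequal
  variances, so the unequal-variance t-test is the sensible parametric
  default; the pooled Student form is one argument away.
* **Both error columns.** Reporting Error_FC alongside the fold-magnitude
  error resolves the sign-convention ambiguity described above without
  choosing a side silently.

## Known limitations

Single-cell-scale moderation (shrinkage estimators), count models,
missing-value handling and multi-group designs are out of scope. The
median- and geometric-mean-based estimators recommended here are robust to
variance inequality and mixed distributions, not to everything: on
strongly right-skewed data whose scientific target really is the
arithmetic mean (e.g. total load), the median answers a different
question. Small groups ($n \approx 10$) defeat every estimator in the
registry; no method choice substitutes for sample size.
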