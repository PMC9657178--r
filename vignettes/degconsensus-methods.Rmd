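---
title: "Statistical methods behind degconsensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind degconsensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degconsensus)
```

## The problem and the design of the package

No single statistical test for differential expression in RNA-seq count
data dominates the others: parametric negative-binomial (NB) tests,
nonparametric signal-vs-noise tests and empirical-Bayes mixtures each
have regimes where they win, and each produces its own false positives.
Intersecting the DEG calls of several statistically distinct tests trades
sensitivity for precision: a gene has to convince every selected test
before it is reported. When follow-up of each reported gene is expensive
(qRT-PCR validation, knockout experiments), precision is usually the
metric a lab wants to maximize, and the intersection is the natural
estimator for it.

`degconsensus` implements that strategy as a library plus a small CLI.
Four testing engines — one per statistical family — run on a harmonized
two-condition count table, each producing a uniform per-gene record
(log2 fold change, raw score, FDR-like score, regulatory status). The
calls are thresholded per method, intersected, checked for direction
consistency, partitioned into Venn regions, and optionally scored
against a gold standard. A seeded NB simulator with known truth makes
every stage testable at desk scale.

The engines are native implementations of one representative test per
family, not wrappers around the field's packages. They deliberately
simplify relative to those packages (no quantile-adjusted conditional
likelihood, no Cox–Reid adjusted profile likelihood, no GLMs beyond two
groups, single-round empirical-Bayes hyperparameter estimation): the
consensus contract only needs a sound per-gene `{log2fc, score, status}`
from each family, and the simplified forms are deterministic,
closed-form and independently testable. Agreement with any specific
external package is a validation nicety, not a contract, although the
TMM and median-of-ratios normalizers do reproduce `edgeR` and `DESeq2`
factors on test fixtures.

## Input contract and harmonization

Two TSV files define a run. The read-counts table has gene identifiers
in column 1 (free-text header) and one integer column per sample.
The sample-information table has `sample_name` and `condition` columns;
`condition` must take exactly two values. Validation is strict —
duplicate ids, negative, missing or non-integer counts, extra condition
levels and mismatched sample sets each raise a distinct, named error —
because silent coercion at this stage is the classic source of wrong
DE results.

Sample names are matched between the two files case-insensitively (with
a warning), since real submissions routinely disagree in capitalization
between the counts header and the metadata table; a strict mode is
available. Condition *levels*, in contrast, are case-sensitive strings:
they are user-chosen labels, and folding their case could merge two
distinct levels. The reference (denominator) condition defaults to the
first level in file order and can be overridden; all log2 fold changes
are treatment over reference.

## Shared plumbing

**Expression filter.** All engines test the same universe: genes with
CPM > 1 in at least `min(n_ref, n_trt)` samples. Unexpressed genes carry
no information and break every engine (zero totals, undefined ratios),
and a shared filter keeps the per-method universes identical, which the
consensus set algebra relies on.

**Pseudocount.** Every engine computes its reported log2 fold change as
`log2((mean_trt + 0.5) / (mean_ref + 0.5))` on normalized counts. The
0.5 prior keeps the fold change finite and total, so the regulatory
status (`up` / `down` / `zero_value`, by the sign of the fold change) is
always defined.

**Score unification.** The per-method `fdr` column holds BH-adjusted
p-values for the two frequentist engines and `1 − probability of DE`
for the nonparametric and empirical-Bayes engines. A single FDR cut is
then applied across all selected methods. These scales are *not* the
same quantity — a posterior probability is not a frequentist FDR — and
the run log states this prominently; the unification is what makes a
single user-facing threshold possible.

**Dispersion.** Both NB engines use moment estimates on normalized
counts, `phi_g = max(0, (s²_pooled − mu) / mu²)` with the pooled
within-condition variance, then shrink: the exact-test engine towards
the median (`phi~ = 0.7·common + 0.3·phi_g`), the Wald engine towards a
fitted `a/mu + b` trend in log space with the same weight 0.7 (the
weight is a fixed package constant, chosen once as a middle ground
between fully moderated and fully per-gene estimates). Moment + fixed
shrinkage is deliberately simple: deterministic, closed-form, and
directly testable against its own definition.

## The four engines

**NB exact test** (TMM-normalized). For each gene the two group sums of
library-size-equalized counts are modeled as NB with means proportional
to replicate numbers and size `n_c / phi`. Conditioning on the total
`s`, every split `(a, s − a)` is enumerated; the two-sided p-value sums
the probabilities of all splits no more likely than the observed one
(ties included, no doubling). As `phi → 0` the conditional law is
exactly `Binomial(s, n_ref/(n_ref + n_trt))`, which the tests use as an
independent oracle. Library-size equalization is done by scaling each
sample to the geometric-mean effective (TMM × library size) depth and
rounding the group sums.

**NB Wald test** (median-of-ratios normalized). Condition means of
size-factor-normalized counts; `Var(y_i/s_i) ≈ mu/s_i + phi·mu²`
propagated to the log2 fold change by the delta method;
`z = log2FC / SE`, `p = 2Φ(−|z|)`. The normal reference is the usual
large-sample approximation; with few replicates its tails are optimistic
for low-count genes, which the trend-shrunk dispersion tempers.

**Noise test** (nonparametric). Signal per gene: `M = log2` ratio and
`D =` absolute difference of condition-mean CPM (prior 0.5). Noise: the
same statistics for every within-condition replicate pair, pooled over
pairs and genes. The probability of DE is the fraction of noise points
strictly dominated in both `|M|` and `D`. Strict domination means a
gene identical to the noise cloud scores 0, and the probability is an
empirical quantile, not a calibrated frequentist level — hence its
score enters the unified `fdr` column as `1 − probability`. The
dominance counts are computed exactly with a Fenwick-tree sweep,
`O((n+G) log n)`, so pooled noise sets of 10^5 points are cheap. At
least one condition must have two or more replicates; without any
replicate pair the engine refuses rather than fabricating technical
noise.

**Empirical-Bayes test.** Counts are NB with per-sample size
`r_g·s_j` and success probability `q_g` drawn from `Beta(alpha, beta)`.
Two hypotheses per gene: equal expression (one shared `q` across all
samples) vs DE (independent `q` per condition). The Beta-NB marginals
are closed-form Beta-function ratios (the combinatorial constant cancels
between hypotheses). `r_g` comes from moments, `(alpha, beta)` from
pooled moments of the `q` estimates, and the mixture weight `pi` from an
EM over the posterior probabilities (deterministic start at 0.5,
tolerance 1e-6 on `pi`, at most 100 iterations, warning + last iterate
on non-convergence). `PPDE = pi·L_DE / (pi·L_DE + (1−pi)·L_EE)`.

## Consensus, thresholds, Venn

A method's DEG set is `{|log2FC| ≥ lfc_cut and fdr < fdr_cut}` —
inclusive on the fold-change boundary, strict on the score boundary.
Thresholds are applied per method *before* intersection, so the
displayed table and the Venn partition are consistent by construction;
a post-hoc mode thresholding the mean log2FC instead is available. The
consensus table carries the common status or `Inconsistent` when the
selected methods disagree in sign, the mean and sample (n−1) standard
deviation of the selected methods' fold changes (SD is `NA` for a single
method), then each method's fold change, then each method's score.
Genes filtered out of one method's universe count as not-DEG for that
method and therefore cannot enter the consensus.

Because the consensus is an intersection, two inequalities hold by set
algebra against any gold standard evaluated on a common universe:
consensus specificity ≥ each method's specificity, and consensus
sensitivity ≤ each method's sensitivity. The test suite verifies both
across simulation seeds; they are the mechanism behind the
precision-first use case above.

## Evaluation protocol

The gold standard is a per-gene label table (DEG yes/no, direction).
The evaluation universe defaults to the intersection of the tested
universe with the gold genes. The confusion matrix takes "called DEG"
as the positive class; sensitivity, specificity and precision are
reported as percentages, with `NA` (never 0) when a denominator
vanishes. Direction agreement is reported as a separate
direction-accuracy column and does not affect the headline metrics,
which are presence/absence only.

## The simulator

`simulate_dataset()` draws a two-condition NB experiment with known
truth from one seeded RNG stream (baseline means → DE subset → library
factors → counts, in that documented order, so seeds are portable).
Defaults: 2000 genes, 5 vs 5 replicates, 10% DE at |log2FC| = 2,
dispersion 0.1, lognormal baselines with meanlog 4.6 and sdlog 1.3
(median ≈ 100 counts, a realistic bulk RNA-seq depth profile), library
sizes varying ±30%. The DE count is realized exactly
(`round(G·pi_de)`, signs balanced up to rounding) so truth counts are
assertable, and the fold change is split symmetrically
(`2^{±lfc/2}`) so conditions keep comparable depth.

What it emulates: NB sampling noise, a mean–variance law `v = mu +
phi·mu²`, depth variation, and a clean planted-truth gold standard.
What it does not: outlier samples, batch effects, correlated genes,
GC/length bias, or read-level artifacts. Passing the recovery tests
therefore demonstrates the statistical machinery is correct, not that
any engine is robust to real-data pathologies.

## Problem sizes and numerical choices

The shipped tests exercise the pipeline at desk scale, chosen as the
smallest sizes at which the statistical properties are stable: null
calibration on a 5000-gene all-null simulation (empirical size of both
NB engines in [0.03, 0.07] at nominal 0.05; mean posterior PPDE below
0.2), parameter recovery and precision on the 2000-gene default design,
and the consensus inequalities across twenty 300-gene simulations.
Worked numeric examples (binomial-limit exact p-values, hand-computed
BH adjustments, median-of-ratios factors, confusion-matrix ratios) are
frozen in the unit tests next to the brute-force oracles that produced
them.

Numerical conventions worth knowing: exact-test p-values are clamped at
1 after summing tied splits (with a 1e-12 log-probability tie
tolerance); the Beta moment fit clamps the pooled variance into the
feasible `(0, m(1−m))` range; dispersion trend coefficients are floored
at 0 (slope) and 1e-8 (intercept); TMM falls back to factor 1 with a
warning when a sample shares no positive gene with the reference; ties
in the TMM reference choice go to the first sample in file order.

## Known limitations

Two-condition, single-factor designs only; no paired or multi-factor
models. The unified score column mixes frequentist FDR with posterior
probabilities, as discussed. The exact test enumerates splits, so its
cost grows with per-gene totals (vectorized, this is still ~seconds for
10-sample, 2000-gene tables). The consensus is intersection-only — no
union, majority-vote or rank-aggregation modes, and no p-value
combination — because the intersection is the estimator whose
precision/specificity guarantees the package exists to provide.
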