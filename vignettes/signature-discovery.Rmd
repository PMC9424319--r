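---
title: "Prognostic signature discovery with sigforge: models, parameters and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prognostic signature discovery with sigforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigforge)
```

`sigforge` implements the portal-style workflow used to derive and
evaluate compact prognostic expression signatures: reference-relative
z-scoring and alteration calling, survival statistics, risk-score
stratification with minimum-p-value cut-point search, greedy single-gene
removal (SGR), k-top-scoring-pairs (k-TSP) selection, and hypergeometric
over-representation. This vignette documents the underlying models, the
tunable parameters and their defaults, the design of the synthetic cohort
generator, and the statistical limitations a user should understand before
trusting a derived signature.

## Alteration model

Expression is z-scored per gene against a designated reference ("diploid")
panel: $z_{gs} = (x_{gs} - \bar{x}^{ref}_g)/s^{ref}_g$, with the reference
standard deviation using the $n-1$ denominator (at least two reference
samples are required, and genes with zero reference variance are reported
as errors naming the gene, never silently dropped). A gene is *altered* in
a sample when $|z_{gs}| > \tau$ with threshold $\tau = 2$ by default; the
boundary is deliberately strict, so $z = \pm 2$ exactly is non-altered. A
sample is *signature-altered* when at least one signature gene is altered
— the altered/unaltered cohort convention of cBioPortal-style survival
comparisons. Because z-scoring is equivariant under per-gene affine
transforms $x \mapsto ax + b$ ($a > 0$), alteration calls are invariant to
linear changes of expression units; inputs are otherwise taken as already
on the analysis scale (no log-transform is applied), and missing values
are rejected rather than imputed so that calls stay well defined.

## Survival engine

Kaplan–Meier curves use the product-limit estimator, with the median
defined as the smallest event time at which $S(t) \le 0.5$ (first
crossing; undefined when the curve never reaches 0.5). Group comparisons
use the standard $k$-sample log-rank test with the hypergeometric variance
at each distinct event time and $k-1$ degrees of freedom. Hazard ratios
come from Cox proportional-hazards fits with the Efron correction for tied
event times — the best standard choice for month-resolution follow-up —
reporting Wald 95% confidence intervals and p-values. Monotone partial
likelihoods (perfect separation) and iteration-limit failures are flagged
with `converged = FALSE` rather than returned silently; constant
covariates are errors. These operations delegate to the `survival`
package, and the test suite additionally verifies the log-rank statistic
against an independent O/E/V tabulation exhaustively on all small
two-group datasets.

## Risk scores and cohort splitting

The prognostic index is $PI_s = \sum_g \beta_g z_{gs}$ over signature
genes, with $\beta$ typically taken from a multivariate Cox fit; an
equal-weight meta-gene mean is available where coefficients are not
wanted. Four splitters are provided:

* **Maximized risk groups** (`maximize_risk_groups`): an exhaustive scan
  of candidate cut-points — midpoints between consecutive distinct sorted
  scores, all pairs for three groups — keeping the partition with the
  minimum log-rank p subject to every group holding at least `min_frac`
  (default 0.1) of the samples. Midpoint candidates exhaust all distinct
  partitions, and tied scores fall deterministically on the lower side of
  a cut. The median-split p is always reported alongside for comparison,
  and the number of groups (2 or 3) is a caller choice.
* **Quantile splits** (`quantile_split`): median; Q1 vs Q4 with the middle
  half excluded; T1 vs T3 with the middle third excluded.
* **Best-cutoff scan** (`best_cutoff_fdr`): every candidate cutoff between
  the lower and upper quartiles of the score, a log-rank p per candidate,
  and Benjamini–Hochberg adjustment across the scanned family (per-scan
  correction); the selection is the minimum raw p, reported with both its
  raw and adjusted p.

All splitters depend on the score vector only through ranks, so they are
invariant under strictly increasing transformations (except the cut-point
coordinates themselves).

**Caution — minimum-p selection.** Optimizing a cut-point for
significance is anti-conservative: on null data the selected raw p falls
below 0.05 far more often than 5% of the time (the package's acceptance
script measures roughly a five-fold inflation at $n = 60$), which is why
`best_cutoff_fdr` reports the BH-adjusted p of the selection. The
*location* of a maximized cut-point is also intrinsically variable: with
scores drawn from a 50/50 mixture of $N(0,1)$ and $N(3,1)$ and hazard
doubled in the upper component at $n = 400$, the recovered cut
concentrates only loosely around the component boundary (roughly
two-thirds of runs land within ±0.5 of it, with a slight upward bias, and
this changes little with the event rate or `min_frac`). Cut-points chosen
this way should be treated as exploratory, not as reproducible thresholds.

## SGR and k-TSP signature search

`sgr_refine` performs greedy backward elimination: at each step every
single-gene removal is scored by the log-rank p of the remaining
signature's altered-vs-unaltered status, and the removal with the lowest p
is applied, stopping at a target size or when no removal improves the
current p. Ties between candidates are broken lexicographically by gene id
and recorded; a removal that makes the status vector constant scores
p = 1 rather than erroring. The trace (removed gene, remaining signature
and p per step) is returned in full and is bit-reproducible — there is no
randomness inside the loop.

**Caution — what SGR optimizes.** The greedy objective is survival
association of the *union* status, and its optimum need not be the truly
prognostic gene set. Two mechanisms matter. First, a union over several
moderately prevalent genes labels a large fraction of the cohort altered,
diluting contrast relative to a single strong gene; the minimizer can then
be one strong gene padded with low-prevalence genes. Second, once a
genuinely prognostic gene is dropped mid-path, its hazard signal persists
in the cohort and a noise gene whose few calls happen to align with those
high-risk samples can inherit it — the same selection bias as minimum-p
cut-points, here acting on subsets. On synthetic cohorts with three
planted genes (hazard doubling per altered gene, 25% prevalence,
$n = 300$) the greedy recovers the exact planted trio in only a minority
of runs even though per-gene inclusion clearly separates planted from
noise genes (the acceptance script reports both fractions). Compact
signatures from SGR should therefore be read as *a* near-optimal
association, not *the* causal gene set, and validated on independent data.

`ktsp_score_pairs` scores every unordered gene pair by
$\Delta = |P(X_i < X_j \mid \text{class 1}) - P(X_i < X_j \mid
\text{class 2})|$, counting within-sample ties as 0.5, with the secondary
score $\gamma$ the absolute between-class difference in mean within-sample
rank difference, following the original k-TSP literature. Both depend only
on within-sample orderings, hence are invariant to any monotone per-sample
transformation (no normalization sensitivity). `ktsp_select` greedily
takes pairs in decreasing $(\Delta, \gamma)$ order skipping shared genes;
$k$ is odd so the majority vote of `ktsp_classify` is always decided
(within-sample ties in a pair vote for class 2, deterministically). For
survival data the two classes are event-before-$T$ versus event-free
follow-up of at least $T$, with $T = 120$ months by default and samples
censored before $T$ excluded — the horizon is a configurable stand-in
since portal analyses rarely state theirs.

`combine_candidates` unions the SGR core, the genes of the selected k-TSP
pairs, and single-marker genes, de-duplicated in that deterministic order.
The union is kept even if a member fails single-gene significance. The
packaged ET-9 fixture (`et9_signature()`) has exactly this structure: a
seven-gene SGR/k-TSP core plus two single markers.

## Over-representation

`hypergeom_overlap` computes the upper-tail hypergeometric probability of
an overlap of $k$ query genes with a $K$-gene set in an $N$-gene universe,
$p = \sum_{i \ge k} \binom{K}{i}\binom{N-K}{n-i}/\binom{N}{n}$ (evaluated
through `phyper`, which works in log space). The universe must be supplied
explicitly — implicit portal universes are not reproducible offline — and
query or set genes outside it are dropped with counts reported, mirroring
portal behavior. `enrich_collection` applies BH across a GMT collection
and filters at q ≤ 0.05 by default. Zero overlap gives exactly p = 1, and
a single-set collection gives q = p.

## The synthetic cohort generator

`simulate_cohort` emulates the statistical structure the pipeline assumes,
not any particular dataset:

* a reference panel of standard-normal expression per gene
  (`n_reference = 100` by default — the order of a portal diploid panel;
  much smaller panels make the $|z| > 2$ boundary noticeably noisy through
  the estimated reference sd);
* tumor samples standard normal, except each prognostic gene is shifted by
  `alteration_shift` (default 3) in its own independent Bernoulli
  `highrisk_fraction` (default 0.25) subset of tumors, so planted genes
  cross the alteration threshold at ~25% prevalence and are
  *non-redundant* markers — a shared all-genes-at-once subgroup would make
  the planted genes interchangeable and the reduction problem
  ill-defined;
* exponential event times with hazard $h_0 \exp(\sum_g \beta_g x_{gs})$
  over the prognostic genes (constant baseline — the simplest law
  satisfying proportional hazards; the shape is irrelevant to the
  rank-based downstream tests), $h_0 = 0.01$/month;
* independent exponential censoring (0.004/month) truncated at a 240-month
  administrative horizon, giving roughly 30% censoring at the default
  effect size.

The default effect `effect_beta = 0.7` per expression unit makes the demo
cohort strongly planted. For "hazard ratio $r$ per altered gene"
scenarios, set `effect_beta = log(r)/alteration_shift`, since an altered
sample sits about `alteration_shift` reference-sd units above the mean
(the conditional per-gene hazard ratio is then $r$; the *marginal*
altered-vs-unaltered ratio is attenuated below $r$ by the unmodeled
heterogeneity from the other planted genes — standard non-collapsibility
of hazard ratios). All draws happen under one seed in a fixed order
(reference matrix, tumor matrix, shift indicators, event times,
censoring) with R's default Mersenne–Twister generator, so identical
configurations are bit-identical across platforms.

`simulate_two_class` labels tumors by survival class at the configured
horizon and can inject a "switched pair" whose within-sample order inverts
between classes with configurable fidelity (fidelity 1 yields
$\Delta = 1$; 0.5 an uninformative pair) for k-TSP validation.

What the generator does **not** emulate: microarray probe effects, batch
structure, copy-number-driven expression, correlated gene modules,
non-proportional hazards, informative censoring, or clinical covariates
correlated with expression. Tests passing on these cohorts therefore
validate the *statistical machinery* under its stated assumptions; they do
not certify behavior on real cohorts where those assumptions fail.

## Numerical and edge-case conventions

* Strict alteration boundary: $|z| > \tau$; $|z| = \tau$ is non-altered.
* KM median: first event time with $S(t) \le 0.5$.
* Log-rank requires at least one event and two non-empty groups; the
  statistic is reported with its $\chi^2$ upper-tail p.
* Cox fits: Efron ties, convergence tolerance $10^{-9}$, at most 100
  Newton iterations; non-convergence and monotone likelihoods are flagged.
* Cut-point candidates are midpoints between consecutive distinct sorted
  scores; tied samples go to the lower group; the first minimum (lowest
  cut) wins exact p ties.
* `min_frac` must allow at least 2 samples per group and
  `n_groups * min_frac <= 1`.
* SGR candidate ties break lexicographically by gene id; constant-status
  candidates score p = 1; an all-censored cohort errors at the log-rank
  stage.
* BH q-values are the standard step-up, capped at 1, in input order.

## Problem sizes used by the packaged checks

The test-suite and acceptance-script simulations use the scales at which
each property is naturally defined: exhaustive oracle sweeps at $n \le 8$
(log-rank), $N \le 12$ (hypergeometric enumeration) and $n \le 20$,
$G \le 6$ (k-TSP); 300–500 replicate cohorts for null-calibration KS
tests; $n = 2000$ for Cox coefficient recovery; 100 runs at $n = 400$ for
cut-point concentration; and 50 cohorts at $n = 300$ for SGR feature
recovery. These sizes were chosen as the smallest at which the binomial or
KS error of the measured fraction is comfortably below the margins being
asserted.

## Known limitations

* Minimum-p procedures (maximized risk groups, best-cutoff scans, SGR)
  are exploratory by construction; their outputs require independent
  validation. The package quantifies this honestly rather than hiding it.
* The Cox engine covers time-fixed covariates only — no stratification,
  time-varying effects, or competing risks.
* k-TSP's class horizon discards samples censored before $T$, which can
  bias class composition when censoring is heavy and outcome-dependent.
* The hypergeometric universe is the user's responsibility; results are
  only as meaningful as that choice.
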