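# sigforge

Prognostic gene-signature discovery and survival stratification for
transcriptomic cohorts.

Breast-cancer expression signatures are typically derived by combining
portal-style building blocks: per-gene expression z-scores relative to a
"diploid" reference panel, binary alteration calls, Kaplan–Meier /
log-rank / Cox survival statistics, risk-score stratification with
minimum-p-value cut-point optimization, greedy signature reduction, and
rank-based two-class gene-pair selection. `sigforge` implements that whole
workflow as tested, scriptable R functions, together with a synthetic
cohort generator with planted prognostic structure so that every stage can
be validated end-to-end without any external data download.

It is aimed at biostatisticians and computational biologists who want to
derive compact prognostic signatures from gene-by-sample expression
matrices with clinical follow-up, or to study the statistical behavior
(power, selection bias, false-discovery control) of these widely used
portal procedures under known ground truth.

## What it computes

* **Alteration calling.** For gene *g* and tumor sample *s*,
  *z*<sub>gs</sub> = (*x*<sub>gs</sub> − mean<sub>ref</sub>(*g*)) /
  sd<sub>ref</sub>(*g*) over a reference ("diploid") panel (sd with the
  *n*−1 denominator); a call is *altered* iff |*z*<sub>gs</sub>| > 2
  (strict; values in [−2, 2] are non-altered). A sample is
  signature-altered when at least one signature gene is altered.
* **Survival engine.** Product-limit (Kaplan–Meier) curves with the first
  crossing of *S*(*t*) ≤ 0.5 as the median; *k*-sample log-rank tests with
  the hypergeometric variance; Cox proportional-hazards fits with the
  Efron tie correction, Wald 95% CIs and p-values.
* **Risk models.** Prognostic index PI<sub>s</sub> = Σ<sub>g</sub>
  β<sub>g</sub> *z*<sub>gs</sub>; equal-weight meta-gene scores; maximized
  risk groups (exhaustive scan of cut-points minimizing the log-rank p,
  2 or 3 groups, group-size constraint); median / quartile / tertile
  splits; best-cutoff scans in the interquartile window with
  Benjamini–Hochberg correction across the scanned family.
* **Signature search.** Single-gene survival significance; single-gene
  removal (SGR) — greedy backward elimination minimizing the log-rank p of
  the remaining signature's altered-vs-unaltered status; *k*-top-scoring
  pairs (k-TSP) — pair scores Δ = |P(X<sub>i</sub> < X<sub>j</sub> |
  class 1) − P(X<sub>i</sub> < X<sub>j</sub> | class 2)| with a
  rank-difference tie-break γ, greedy disjoint selection and majority-vote
  classification; and the combination rule uniting the SGR core, k-TSP
  genes and single markers (the packaged nine-gene ET-9 signature follows
  exactly this 7 + 2 structure).
* **Over-representation.** Hypergeometric upper-tail tests of a query list
  against GMT gene-set collections with an explicit universe and BH
  q-values.
* **Synthetic cohorts.** Exponential proportional-hazards survival driven
  by planted prognostic genes that are mean-shifted in latent high-risk
  tumor subsets, with exponential + administrative censoring, seeded and
  bit-reproducible.

## Worked example

```r
library(sigforge)

coh <- simulate_cohort(cohort_config(seed = 1))   # demo cohort
coh
#> SyntheticCohort: 300 tumors, 100 reference samples, 10 genes (3 prognostic); 84% events observed

z   <- zscore_vs_reference(coh$expression)
alt <- call_alterations(z)                        # |z| > 2
alt
#> AlterationMatrix: 10 genes x 300 samples, |z| > 2; 10.3% altered calls

trace <- sgr_refine(alt, coh$clinical,
                    gene_signature(rownames(alt$calls), "panel"),
                    target_size = 3)
trace
#> SGR trace: 7 removal step(s), p 1.55e-07 -> 1.28e-17
#>   removed: G07, G10, G09, G08, G05, G04, G06
#> GeneSignature 'panel_sgr' (3 genes): G01, G02, G03

fit <- cox_fit(t(z$values[trace$final_signature$genes, ]),
               coh$clinical$time_months, coh$clinical$event)
pi  <- prognostic_index(setNames(fit$beta, trace$final_signature$genes),
                        z, trace$final_signature)
maximize_risk_groups(pi, coh$clinical, n_groups = 2, min_frac = 0.1)
#> RiskPartition (maximized): groups [low=231, high=69], cutpoint(s) 2.788
#> Log-rank test: chisq = 323 on 1 df, p = 3.15e-72
#> Cox proportional-hazards fit (n = 300, 251 events)
#>   risk_high: HR = 17.4 (95% CI 11.7-25.9), beta = 2.86, p = 2.17e-45
```

The SGR loop recovers the three planted prognostic genes (G01–G03), and
the maximized two-group split of their prognostic index isolates a
high-risk group with a hazard ratio of ~17 on this strongly planted demo
cohort. The whole workflow is also available as one call,
`run_pipeline(demo_config())`, which writes a versioned JSON report, TSV
tables and Kaplan–Meier plots, or from a shell via `exec/sigforge.R`
(subcommands `simulate`, `zscore`, `alter`, `enrich`, `sgr`, `ktsp`,
`stratify`, `run`).

The packaged nine-gene breast-cancer signature is available as a fixture:

```r
et9_signature()
#> GeneSignature 'ET-9' (9 genes): ADGRG1, FIBCD1, GDPD5, SUSD2, CACNG4, CX3CL1, IGFBP5, MAP6, CCDC69
```

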