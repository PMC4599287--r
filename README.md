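# prognosix

Discovery and clinical use of **aberrantly activated, normally silent
genes** as survival markers in acute lymphoblastic leukemia (ALL) — for
computational biologists and biostatisticians who want the full procedure
as tested, composable R functions rather than a one-off analysis script.

Many genes are expressed only in male germline cells, embryonic stem (ES)
cells or placenta, and are silent in healthy bone marrow. When leukemic
blasts switch such genes on, their activation status carries prognostic
information. The pipeline:

1. calls a gene **predominant** in germline/ES/placenta when its maximum
   compendium expression exceeds the somatic reference mean + 3 SD
   (x<sub>g</sub><sup>max</sup> > μ<sub>g</sub> + 3σ<sub>g</sub>) outside
   the somatic group, then discards genes with any above-threshold signal
   in non-leukemic bone marrow;
2. binarizes tumor expression at per-gene thresholds T<sub>g</sub> =
   μ<sub>g</sub> + 3σ<sub>g</sub> and keeps genes activated in ≥ 10% of
   the patients of **every** cohort;
3. screens each gene with a Mantel–Cox logrank test and a univariate Cox
   hazard ratio (expressers vs non-expressers) per cohort, keeps genes
   direction-consistent and significant (p < 0.05) in all cohorts, and
   selects the top 3 per direction;
4. classifies patients from the six genes: **P3** (poorest survival) if
   ≥ 1 negative gene and ≤ 1 positive gene is expressed, **P1** if no
   negative and ≥ 2 positive genes, **P2** otherwise; P1 and P2 merge into
   **P1&2** against P3;
5. characterizes P3 biology via Mann–Whitney differential expression and a
   weighted Kolmogorov–Smirnov (WKS) permutation enrichment test, and
   ships a multivariate Cox workflow (univariate p < 0.20 screen, AIC/BIC
   backward elimination, likelihood-ratio model comparisons, Schoenfeld
   diagnostics);
6. implements the RT-qPCR assay arm: testis-relative ratios
   2^(Ct<sub>testis</sub> − Ct<sub>sample</sub>) normalized by four
   control genes, QC gates (no-RT Ct ≥ 36, duplicate spread < 0.5),
   mean + 2 SD aberrancy thresholds from ten normal samples, and the same
   six-gene classifier for new patients.

A seeded synthetic-data module (`sim_config()`, `simulate_bundle()`,
`simulate_ct_table()`) generates every input with planted ground truth, so
the whole pipeline runs end to end offline. To run on real data, point the
readers (`read_expression_tsv()`, `read_survival_tsv()`, `read_ct_csv()`,
`read_gmt()`) at normalized matrices such as the study's GEO series
(GSE11877, GSE7440, GSE13159, GSE34861, GSE3526, ...).

## Worked example

```r
library(prognosix)

bundle   <- simulate_bundle(sim_config(seed = 3,
              cohort_sizes = c(learning = 200, validation = 200)))
pipeline <- run_pipeline(bundle)
print(pipeline)
#> <prognosix_pipeline>
#>   predominant genes: 120 of 600
#>   marrow-silent genes: 108
#>   frequency-filtered genes: 32
#>   selected positive: G0062, G0266, G0135
#>   selected negative: G0374, G0073, G0065
#>   learning-cohort P3 vs P1&2 logrank p = <2e-16
#> Prognosis report (n = 200)
#>   P1: 24/200 (12%)
#>   P2: 83/200 (42%)
#>   P3: 93/200 (47%)
#>   P1&2: 107/200 (54%)
```

Of the 600 simulated genes, 120 were planted as germline/ES/placenta
predominant; 108 survive the marrow-silence filter and 32 are aberrantly
activated in ≥ 10% of both cohorts. The six selected genes are exactly the
planted prognostic ones (`bundle$truth$signature`), and the P3 group
(93/200 patients, 47%) has sharply reduced survival:

```r
glance(pipeline$km)
#> # A tibble: 1 × 6
#>   n_p12  n_p3 logrank_p hr_p3 stratum testable
#>   <int> <int>     <dbl> <dbl> <chr>   <lgl>
#> 1   107    93  4.26e-21  5.01 <NA>    TRUE
```

i.e. P3 patients die about 5 times faster (HR 5.01), logrank p ≈ 4e-21.
Downstream pieces compose the same way: `compare_groups_km(assignments,
surv, stratum = MLL == 0)` re-tests the classifier within a molecular
stratum, `multivariate_cox()` runs the covariate-adjusted analysis,
`differential_expression()` + `wks_enrichment()` profile P3 biology, and
`classify_qpcr()` classifies new patients from Ct tables. Result objects
carry `tidy()`/`glance()` methods and `autoplot()`/`plot_*()` figures.

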