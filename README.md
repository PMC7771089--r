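# pathmeta

Pathway-level analysis of multi-cohort tumor expression data: survival
prognosis from a composite gene expression score, cross-cohort meta-analysis
of differential co-expression, and paired tumor-versus-normal differential
expression — with a synthetic multi-cancer cohort generator that makes every
claim testable against known ground truth.

The package is aimed at analysts who have, per cancer cohort, a processed
gene-by-sample expression table, per-sample metadata (subject, tumor/normal
tissue), survival records (overall or disease-specific), and a GMT file of
pathway gene sets — and who want pathway-level answers rather than
gene-level lists.

## The statistics at the core

**Composite gene expression score (CGES).** Per pathway and cohort, each
member gene *i* is weighted by its univariate Cox coefficient β<sub>i</sub>
(log hazard ratio per unit of standardized log2 expression
x<sub>i</sub>), and each subject is scored

> CGES = 1 / (1 + exp(−(Σ<sub>i</sub> β<sub>i</sub> x<sub>i</sub> − m)))

with m the cohort median of the linear term, so scores lie in (0, 1) with
the median subject at 0.5. Prognostic value is the log-rank chi-square of
the median-score split; because the weights are fitted on the same cohort,
significance comes from a permutation test that reshuffles the survival
records and refits the *entire* pipeline each time (default 1000
permutations), with Benjamini–Hochberg adjustment across all
pathway × cancer cells per endpoint.

**Differential co-expression (GSNCA-type) with meta-analysis.** Per pathway
and cohort, each condition's absolute gene–gene correlation matrix (zeroed
diagonal) yields a principal-eigenvector weight vector scaled to mean 1;
the test statistic is the L1 distance between the tumor and normal weight
vectors, with label-permutation significance. Each cohort's permutation p
becomes the effect size ES = ln(p/(1−p)) with a bootstrap standard error
(within-group resampling, nested permutations); cohorts are pooled with a
DerSimonian–Laird random-effects model and the pooled ES is back-transformed
into a single **meta p-value** per pathway.

**Paired differential expression.** For subjects with both tissues, each
sample's pathway expression is its mean log2(x+1) over member genes; a
paired t-test on tumor − normal differences per pathway × cancer cell,
BH-adjusted jointly, with up/down direction counts.

Gene-set curation utilities implement same-name merging (secondary sets
absorbed when they share > 70% of their genes with the largest set) and
pairwise overlap enforcement (|A∩B|/min(|A|,|B|) ≤ 0.7, report or
drop-smaller).

## Worked example

Everything below is driven by the bundled simulator, which plants known
truths: pathway `MPSIM01` has its co-expression hub severed in tumor,
`MPSIM02` drives hazard (γ = 1), and `MPSIM03` is shifted up in tumor by
1.5 log2 units; the other three pathways are null.

```r
library(pathmeta)
library(dplyr)

cfg <- sim_config(
  seed = 7, cancers = c("CA1", "CA2", "CA3"), n_tumor = 60, n_normal = 15,
  n_genes = 60, n_pathways = 6, genes_per_pathway = 8,
  hub_rewired_pathways = "MPSIM01", hub_r_normal = 0.8, hub_r_tumor = 0,
  prognostic_pathways = "MPSIM02", gamma = 1,
  shifted_pathways = "MPSIM03", delta = 1.5)
study <- simulate_study(cfg)
res <- run_pipeline(study, n_perm = 500, gsnca_perm = 500,
                    n_boot = 100, inner_perm = 50, seed = 7)

filter(res$survival, endpoint == "OS",
       pathway %in% c("MPSIM01", "MPSIM02", "MPSIM03")) %>%
  select(cancer, pathway, k, observed_stat, perm_p, adj_p)
#> # A tibble: 9 × 6
#>   cancer pathway     k observed_stat  perm_p  adj_p
#>   <chr>  <chr>   <int>         <dbl>   <dbl>  <dbl>
#> 1 CA1    MPSIM01     8       0.609   0.741   0.891
#> 2 CA1    MPSIM02     8      20.4     0.00200 0.0359
#> 3 CA1    MPSIM03     8       1.39    0.854   0.905
#> 4 CA2    MPSIM01     8       1.95    0.385   0.770
#> 5 CA2    MPSIM02     8       4.64    0.347   0.770
#> 6 CA2    MPSIM03     8       3.18    0.501   0.820
#> 7 CA3    MPSIM01     8       0.00356 0.984   0.984
#> 8 CA3    MPSIM02     8      13.1     0.0140  0.126
#> 9 CA3    MPSIM03     8       5.24    0.317   0.770

res$meta %>% select(pathway, k, pooled_es, tau2, meta_p, significant)
#> # A tibble: 6 × 6
#>   pathway     k pooled_es  tau2  meta_p significant
#>   <chr>   <int>     <dbl> <dbl>   <dbl> <lgl>
#> 1 MPSIM01     3    -5.83  0.266 0.00293 TRUE
#> 2 MPSIM02     3     1.23  0     0.773   FALSE
#> 3 MPSIM03     3    -4.28  1.61  0.0137  TRUE
#> 4 MPSIM04     3    -1.32  7.78  0.211   FALSE
#> 5 MPSIM05     3     1.65  0     0.839   FALSE
#> 6 MPSIM06     3    -0.927 0     0.283   FALSE

res$de_summary %>% select(pathway, n_significant, n_up_in_tumor, n_down_in_tumor)
#> # A tibble: 6 × 4
#>   pathway n_significant n_up_in_tumor n_down_in_tumor
#>   <chr>           <int>         <int>           <int>
#> 1 MPSIM01             0             0               0
#> 2 MPSIM02             0             0               0
#> 3 MPSIM03             3             3               0
#> 4 MPSIM04             0             0               0
#> 5 MPSIM05             0             0               0
#> 6 MPSIM06             0             0               0
```

Reading the output: the survival layer recovers the planted prognostic
pathway (`MPSIM02`: permutation p 0.002 in CA1, adjusted p 0.036; the
higher-score group has worse survival), the meta layer flags the rewired
pathway (`MPSIM01`, meta p 0.003), and the paired-DE layer finds the
planted up-shift in all three cohorts for `MPSIM03` and nothing else. Note
the meta layer also calls `MPSIM03` at meta p 0.014 — with only three
cohorts the pooled logit is noisy, a small-k caveat that disappears at
realistic cohort counts (the vignette discusses calibration).

Plotting: `autoplot()` works on `km_curve()` output, pooled meta results
(forest plots), `pathway_patient_mean()` output (paired violins) and
`cluster_pvalue_matrix()` output (clustered heatmaps); `tidy()` and
`glance()` give per-observation and one-row summaries of fitted objects.

A tiny synthetic GMT ships for format examples:

```r
gmt <- read_gmt(system.file("extdata", "synthetic_pathways.gmt", package = "pathmeta"))
merge_same_name(gmt)   # absorbs the PANTHER-like duplicate (5/5 > 70% shared)
```

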