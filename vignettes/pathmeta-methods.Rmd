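---
title: "Pathway-level prognosis, co-expression rewiring and paired differential expression with pathmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-level prognosis, co-expression rewiring and paired differential expression with pathmeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathmeta)
library(dplyr)
```

pathmeta asks three questions of a pathway (a curated gene set) across
multiple cancer cohorts of bulk expression data:

1. Does the pathway's overall expression predict patient survival?
2. Is the pathway's co-expression network rewired between tumor and normal
   tissue, consistently across cohorts?
3. Is the pathway's overall expression level shifted between paired tumor
   and adjacent-normal samples?

This vignette explains the statistical machinery behind each question, the
design choices that were genuinely open, and what the bundled synthetic
cohort generator does and does not emulate.

## Gene-set curation

Pathway collections assembled from several curation sources carry duplicate
and overlapping entries. `merge_same_name()` merges sets sharing a
(case-insensitively, whitespace-trimmed) identical name: the largest set
becomes the primary, and a secondary set's genes are absorbed only when more
than 70% of them are already in the primary — the secondary then genuinely
describes the same pathway, and its few extra members are worth keeping.
Otherwise the secondary's extras are discarded as likely annotation noise.
The absorption fraction is computed on the *secondary* set's size, because
the rule is about what the secondary contributes.

`enforce_pairwise_overlap()` then checks every pair of surviving sets under
the symmetric overlap `|A ∩ B| / min(|A|, |B|)` — the conservative choice, as
it flags a small set nested inside a large one. Pairs above the threshold
(default 0.7) are reported; nothing is dropped silently. An explicit
`action = "drop_smaller"` removes the smaller set of the worst pair,
rescanning until clean, with deterministic tie-breaks.

## Composite gene expression score (CGES)

For one pathway in one cohort, each member gene $i$ gets a weight
$\beta_i$: the coefficient of a univariate Cox proportional-hazards
regression (Efron tie handling) of survival on that gene's standardized log
expression $x_i = (\log_2(\mathrm{expr}+1) - \mu_g)/\sigma_g$, standardized
within the cohort. Each subject is then scored

$$\mathrm{CGES} = \frac{1}{1 + \exp\!\left(-\left(\sum_{i=1}^{k}\beta_i x_i - m\right)\right)},$$

where $m$ is the cohort median of the linear term $\sum_i \beta_i x_i$, so
scores lie strictly in $(0,1)$ with the median subject at exactly $0.5$, and
are invariant to any constant shift of the linear predictor. The cohort is
split at the median score and the two groups compared with the log-rank
chi-square statistic.

Because the Cox weights are estimated on the same cohort that is then
scored, this statistic is optimistically biased. The permutation test
removes the bias by jointly shuffling the `(time, event)` records across
subjects and re-running the *entire* pipeline per permutation — per-gene Cox
refits, new weights, new scores, new median split (and a new $m$), new
log-rank statistic. Refitting is the point: permuting only the final group
labels would not capture the overfitting. The p-value uses the pseudo-count
convention $(1 + \#\{\text{perm} \ge \text{obs}\})/(1 + B)$, so it is a
valid p-value bounded below by $1/(B+1)$, never zero. Default $B = 1000$.

Degenerate per-gene fits — constant expression, zero events, monotone
likelihood with $|\beta|$ beyond a cap of 10 — contribute $\beta = 0$, which
simply removes the gene from the weighted sum. A pathway needs at least 3
genes present in the dataset; smaller intersections are skipped with a
logged reason. "Low" at the median split means score $\le$ median, with the
interpolated median for even cohort sizes.

Adjusted p-values use Benjamini–Hochberg, with the family defined as all
pathway × cancer cells of one endpoint (OS or DSS) analyzed together; a
per-cancer family is available by adjusting subsets yourself, since
`bh_adjust()` simply operates on whatever family it is given.

The per-gene Cox fits inside the permutation loop use a batched
Newton–Raphson (all pathway genes in one call, Efron ties, damped steps,
$|\beta| \le 10$ guard) written for this package; it agrees with
`survival::coxph()` to $10^{-6}$ in the test suite and makes a
1000-permutation run over a 29-pathway × 30-cohort grid tractable on one
CPU. The log-rank statistic in the loop is likewise a vectorized
implementation validated against `survival::survdiff()`.

## GSNCA-type differential co-expression

The two-condition test compares *net correlation* structure. For each
condition, take the gene–gene correlation matrix of the pathway (Pearson on
$\log_2(x+1)$ values by default — correlation is scale-invariant, so
z-scoring is unnecessary; Spearman by flag), take absolute values, zero the
diagonal, and compute the principal eigenvector. By Perron–Frobenius it can
be chosen non-negative; rescaled to mean 1 it is the condition's weight
vector $w$, a gene's share of the pathway's total co-expression
connectivity. The test statistic is $\sum_i |w^{(1)}_i - w^{(2)}_i|$, and
significance comes from permuting condition labels over the pooled samples
(preserving group sizes), with the same pseudo-count p-value. Tumor–normal
pairing is ignored in the shuffle — the standard unpaired label permutation.

Two-gene pathways are structurally uninformative (both weight vectors are
forced to $(1,1)$), so a minimum of 3 genes with nonzero variance in both
groups is enforced; each group needs at least 10 samples. If the top
eigenvalue is tied within $10^{-12}$ (only realistic for degenerate,
near-zero correlation matrices), the eigenvector with the largest absolute
component is taken and a warning logged.

## Meta-analysis across cohorts

A permutation p-value has no natural effect size or standard error, which a
meta-analysis needs. Each cohort's p becomes the logit effect size
$ES = \ln\!\left(p/(1-p)\right)$: strongly negative when co-expression is
strongly rewired, 0 at $p = 0.5$. The pseudo-count keeps $p > 0$; the
mirror-image clamp $p \le B/(B+1)$ keeps the logit finite at the top end.

The standard error comes from a bootstrap: resample samples with replacement
*within* each condition (sizes preserved), re-run the co-expression test
with a smaller inner permutation count, and record the replicate effect
sizes; their standard deviation is the SE and their 2.5/97.5 percentiles the
interval. Degenerate replicates (a resampled group losing all gene variance)
are redrawn up to a cap. Within-group resampling was chosen over pooled or
pair-wise resampling because the test's sampling unit is the sample within a
condition. Defaults (200 bootstrap × 100 inner permutations) keep a
29-pathway × 17-cohort run at desk scale; both knobs are arguments.

Cohort effects are pooled with a DerSimonian–Laird random-effects model:
$w_i = 1/se_i^2$, $Q = \sum w_i (ES_i - \bar{ES}_w)^2$,
$\tau^2 = \max\!\left(0, (Q - (k-1))/(\sum w_i - \sum w_i^2/\sum w_i)\right)$,
random-effects weights $1/(se_i^2 + \tau^2)$. DL was chosen over an
iterative GLMM because it is closed-form and deterministic — there is no
convergence ambiguity to document — and the tests cross-check it against
`metafor::rma(method = "DL")` to $10^{-8}$. The *meta p-value* is the
inverse-logit back-transform of the pooled effect size; a pathway is called
consistently rewired when it falls below 0.05. Forest tables report every
cohort and the pooled summary on both the logit and probability scales.

## Paired differential expression

For cohorts with enough adjacent normals (at least 10, i.e. "more than 9"),
subjects owning both a tumor and a normal sample are paired (duplicate
aliquots resolved by the lexicographically smallest sample id, for
determinism). Each sample's pathway expression is the mean $\log_2(x+1)$
over member genes — deliberately *not* z-scored, since standardizing across
pooled tumor + normal samples would shrink exactly the paired differences
being tested. A one-sample t-test on the per-subject differences
(tumor − normal) gives the cell's p-value; the sign of the mean difference
gives the direction. One test per pathway × cancer cell, BH-adjusted over
all cells jointly. The all-identical-differences corner (zero variance,
nonzero mean) is off the t scale; it is flagged degenerate and reported at
the machine-minimum p rather than silently dropped.

## Synthetic cohorts and what passing tests mean

`sim_config()`/`simulate_study()` generate the study conditions used in the
test suite: multiple cancer cohorts, log2-scale expression drawn from a
multivariate normal with block structure (within-pathway correlation per
condition, independence elsewhere), mapped to non-negative raw scale by
$2^z - 1$; exponential survival with hazard
$\lambda_0 \exp(\gamma \cdot \text{pathway mean z-score})$ and uniform
censoring calibrated by root-finding to the requested expected censoring
fraction; and tumor mean shifts of $\delta$ log2 units on designated
pathways. A multivariate normal on the log scale was chosen over
negative-binomial counts because the pipeline consumes processed
abundances, and the MVN gives exact control of the correlation structure
the co-expression test examines. Exponential survival gives closed-form
calibration of censoring and effect size. Every stream derives a sub-seed
from (master seed, cancer, condition, stage), so regenerating one cohort
never shifts another's draws.

Co-expression rewiring is modelled as a hub gene losing its edges: in the
reference condition the hub correlates at $h$ (default 0.8) with every other
member, which geometrically forces the members to correlate at about $h^2$
among themselves (a hub at 0.8 with mutually independent members is not a
positive-definite correlation structure); in the rewired condition the hub's
edges are severed while the member module persists. This is the scenario
under which the weight-vector test has its advertised power — the hub's
connectivity share collapses. A rewiring that dissolved the entire module
would change overall correlation magnitude much more than the *shape* of
the weight vector, and the test is deliberately less sensitive to it.

Default study conditions in the tests: cohorts of 20–200 tumor samples with
10–20 normals, 6–20-gene pathways, within-pathway correlation 0.3, noise sd
1 log2 unit, baseline hazard 1/1000 per day, 30% censoring, $\gamma = 1$,
$\delta = 1$–1.5, with 200–500 permutations and 200 or fewer Monte-Carlo
replicates per property. The generator does **not** emulate count-level
noise, library-size or batch effects, gene-length bias, overlapping
pathways' shared covariance, or non-proportional hazards — so passing tests
demonstrate the statistics are implemented correctly and calibrated under
their own assumptions, not that those assumptions hold in any particular
real cohort.

## Numerical conventions

- Log transform: $\log_2(x+1)$; standardization with the sample sd
  ($n-1$); zero-variance genes flagged and set to all-zero rather than
  dropped, so pathway indexing is stable (they are excluded from
  correlation computations, which reject zero-variance input).
- Permutation p-values: pseudo-count convention, strictly in $(0, 1]$;
  logit transforms clamp the upper end symmetrically.
- RNG: every analysis cell derives an independent 32-bit sub-seed by
  hashing (master seed, cell labels), so cells are reproducible
  independently and in any order; all generators restore the caller's RNG
  state.
- Clustering of adjusted-p matrices: Euclidean distance, average linkage by
  default (complete by flag); skipped cells imputed as $p = 1$ — the
  conservative "not significant" reading; rows and columns are fed to
  `hclust` in sorted label order so leaf orders are permutation-invariant.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(
  seed = 7, cancers = c("CA1", "CA2", "CA3"), n_tumor = 60, n_normal = 15,
  n_genes = 60, n_pathways = 6, genes_per_pathway = 8,
  hub_rewired_pathways = "MPSIM01", hub_r_normal = 0.8, hub_r_tumor = 0,
  prognostic_pathways = "MPSIM02", gamma = 1,
  shifted_pathways = "MPSIM03", delta = 1.5)
study <- simulate_study(cfg)
res <- run_pipeline(study, n_perm = 500, gsnca_perm = 500,
                    n_boot = 100, inner_perm = 50, seed = 7)
res$survival   # pathway x cancer x endpoint permutation results
res$meta       # pooled co-expression rewiring per pathway
res$de_summary # per-pathway up/down counts
```

Plotting helpers: `autoplot()` on `km_curve()` output, on a pooled meta
result (forest plot), on `pathway_patient_mean()` output (paired violins),
and on `cluster_pvalue_matrix()` output (clustered heatmap).

## Known limitations

- The survival layer fits univariate, unadjusted Cox models; covariate
  adjustment and competing risks are out of scope.
- The meta model pools logit-transformed permutation p-values; with very
  small inner permutation counts the effect-size grid is coarse and
  bootstrap SEs conservative.
- The co-expression permutation ignores tumor–normal pairing; a paired
  shuffle is not currently implemented.
- P-value-based clustering inherits the discreteness of permutation
  p-values at small permutation counts.
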