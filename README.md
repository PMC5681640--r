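# spagm

Subpathway activity inference integrating gene and miRNA expression, with
robust survival-signature discovery.

Most pathway-activity methods score whole pathways from gene expression
alone, ignoring both the local structure of pathway maps and the repressive
regulation exerted by microRNAs. `spagm` addresses both at once. It is aimed
at cancer transcriptomics analyses where matched gene and miRNA expression
profiles and clinical follow-up are available (e.g. TCGA-style cohorts), and
where the goal is to find *subpathway*-resolution prognostic signatures.

The package provides four building blocks, usable separately or as a
pipeline:

1. **Subpathway reconstruction.** Each pathway is an undirected graph of
   gene nodes. A subpathway is a maximal set of genes with pairwise
   shortest-path distance ≤ *k* (a maximal clique of the *k*-th graph
   power; default *k* = 3). A miRNA is embedded into a subpathway when it
   has ≥ *t* experimentally verified targets among the member genes
   (default *t* = 1, low-throughput evidence only). Subpathways with fewer
   than one miRNA or three genes are discarded.

2. **sPA scoring.** For each sample *s*, all measured features of one type
   (genes *N<sub>g</sub>*, miRNAs *N<sub>mi</sub>*) are ranked ascending by
   expression and weighted

   *w* = *r* · e^( *r* / |*N*| ),

   so highly expressed features dominate. The raw subpathway activity at
   each level is the mean weight over member features minus the mean weight
   over the complement; rows are then z-normalized across samples, and the
   integrated score is

   sPA = sPAg_norm − sPAmi_norm,

   reflecting that high member-miRNA expression represses the subpathway.
   Gene-only (sPAg_norm) and miRNA-only (−sPAmi_norm) variants are
   available.

3. **Robust signature discovery.** 1,000 stratified resamples draw 80% of
   samples (preserving the good/poor ratio at the median survival time);
   in each, every subpathway is screened with a univariate Cox
   proportional-hazards model at α = 0.05. A subpathway's *significance
   count* is the number of resamples in which it was significant;
   signatures are the top-ranked counts (dense rank ≤ 25, or a count
   threshold). A hypergeometric-enrichment baseline over prognostic
   genes/miRNAs (Benjamini–Hochberg corrected) is included for comparison.

4. **Evaluation.** K-means (K = 2) risk grouping on the signature profile
   (the lower-activity cluster is labelled high risk), Kaplan–Meier /
   log-rank comparison, survival-time permutation calibration of the
   resulting p-value, and tumor-vs-normal Wilcoxon contrasts.

A seeded synthetic-data generator (`simulate_spagm_study()`) produces
pathways, verified interactions, matched expression, condition labels, and
survival times with known ground truth, so the whole pipeline is testable
offline.

## Worked example

```r
library(spagm)

sim <- simulate_spagm_study(simulation_config(seed = 1))
sim$subpathways
#> <subpathway_list> 54 subpathways from 50 pathways
#>   mean per subpathway: 7.9 genes, 5.1 miRNAs, 9.9 miRNA-gene edges

spa <- spa_scores(sim$gene_expr, sim$mirna_expr, sim$subpathways)
round(spa[1:3, 1:4], 3)
#>            s001   s002   s003   s004
#> path01_1  0.937  0.654 -0.669 -0.165
#> path02_1 -1.089 -1.891 -0.403  0.486
#> path03_1 -0.457 -0.581  2.403  0.747

rk <- rank_subpathways(spa, sim$survival, resample_plan(n_reps = 200, seed = 1))
head(rk, 7)
#>   subpathway_id count dense_rank
#> 1      path11_1   200          1
#> 2      path24_1   200          1
#> 3      path30_1   200          1
#> 4      path34_1   200          1
#> 5      path45_1   200          1
#> 6      path19_1   146          2
#> 7      path10_1   136          3

sim$truth$effect_ids   # the five truly prognostic subpathways
#> [1] "path11_1" "path24_1" "path30_1" "path34_1" "path45_1"
```

The five subpathways carrying the injected survival program are exactly the
five with the maximal significance count (200/200 resamples). Selecting a
signature and evaluating it:

```r
sig <- select_signature(rk, min_count = 100)
grp <- kmeans_risk_groups(spa[sig, , drop = FALSE], seed = 1)
grp
#> <risk_grouping> 150 high / 150 low risk samples
logrank_compare(grp, sim$survival)
#> <logrank_result> chi-square 85.366, p = 2.48e-20
permutation_pvalue(spa[sig, , drop = FALSE], sim$survival,
                   n_perm = 1000, seed = 1)$p_empirical
#> [1] 0
```

The two activity-defined risk groups differ sharply in survival, and none
of 1,000 survival-time permutations reaches the observed log-rank p-value.
(Risk labels follow activity by convention — the lower-activity cluster is
called "high risk"; in this simulation the injected program is adverse, so
the *high-activity* group is the one with shorter survival. The log-rank
test is unaffected by the label direction.)

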