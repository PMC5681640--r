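---
title: "Methods: subpathway activity scoring and robust signature discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subpathway activity scoring and robust signature discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `spagm`, the choices
made where the method leaves room for interpretation, what the synthetic
data generator does and does not emulate, and the package's known
limitations.

## The model

### Subpathway reconstruction

Pathway maps are treated as simple undirected graphs with gene products as
nodes. A *k-clique subpathway* is a maximal gene set whose members are
pairwise within shortest-path distance $k$ of each other, i.e. a maximal
clique of the $k$-th graph power. Distances are computed on the gene-only
graph, per connected component (cross-component distances are infinite);
miRNAs never alter topology because embedding happens afterwards. We remove
singleton and containment-redundant sets: maximality is what makes a
"region" of a pathway well defined, and subsets would duplicate their
superset's member list.

A miRNA is embedded into a subpathway when it has at least $t$
experimentally verified targets among the member genes. By default only
low-throughput-verified interactions (reporter assays and similar focused
experiments) are used, because high-throughput target catalogues have
substantially higher false-positive rates; a flag admits all verified
interactions. Finally, subpathways with fewer than `min_mirnas` (1) miRNAs
or `min_genes` (3) genes are discarded: below that scale a "subpathway" is
not meaningfully different from a single interaction.

Defaults $k = 3$, $t = 1$ balance locality against miRNA coverage: larger
$k$ merges neighbourhoods into near-whole pathways, while larger $t$
rapidly empties the embeddable miRNA set.

### Per-sample activity scores

For one sample $s$, let $N$ be all measured features of one type (genes or
miRNAs). Features are ranked ascending by expression, $r \in \{1, \dots,
|N|\}$, and weighted

$$w = r \cdot e^{r/|N|},$$

an exponentially increasing weighting of the expression order, so that the
top of the expression profile dominates. For a subpathway with member set
$M$ the raw component score is the mean member weight minus the mean weight
of the complement $N \setminus M$:

$$\mathrm{sPA}^{raw}_{M,s} = \frac{1}{|M|}\sum_{f \in M} w_{f,s}
  - \frac{1}{|N \setminus M|}\sum_{f \notin M} w_{f,s}.$$

Each subpathway row is then z-normalized across samples, and the integrated
score subtracts the miRNA level from the gene level,

$$\mathrm{sPA} = \mathrm{sPAg}^{norm} - \mathrm{sPAmi}^{norm},$$

encoding miRNA repression: a subpathway whose member miRNAs are highly
expressed is inferred less active. Because only within-sample ranks enter,
the score is invariant to any strictly increasing per-sample transform of
expression — between-sample normalization of the raw data is consequently
*assumed upstream* and not performed here.

Interpretation choices the method statement leaves open, and how this
package resolves them:

* **Ties.** Tied expression values receive the average rank (fractional
  ranks are allowed in the weight formula). This is deterministic,
  permutation-invariant, and necessary for zero-inflated RNA-seq data;
  breaking ties by input order would make scores depend on file order.
* **Unmeasured members.** Member sets are intersected with the measured
  features; the complement is taken over measured features only. Nothing
  is imputed.
* **Coverage.** A subpathway is scorable at the gene level only with ≥ 3
  measured member genes and at the miRNA level with ≥ 1 measured member
  miRNA — mirroring the construction-time size filter. Unscorable rows are
  `NA` ("missing sentinel"), and an integrated cell is missing when either
  level is.
* **Standard deviation.** Normalization uses the sample SD ($n-1$); the
  population SD is available via `sd_type = "population"`. With hundreds
  of samples the difference is negligible; the choice is recorded so
  results are exactly reproducible.
* **Constant rows** (zero variance across samples) map to all-zero rows
  and are flagged in the `constant_rows` attribute rather than producing
  division-by-zero artifacts.
* **miRNA-only sign.** The standalone miRNA-only variant is
  $-\mathrm{sPAmi}^{norm}$, so that for *every* variant a larger score
  means larger inferred activity under the repression assumption. The
  gene-only variant is $\mathrm{sPAg}^{norm}$, and the identity
  `integrated = gene_only + mirna_only` holds by construction.

### Robust signature discovery

Given an activity profile and survival data, each of `n_reps` (default
1,000) iterations draws 80% of samples *without replacement*, stratified so
the proportion of samples above/below the cohort median survival time is
preserved (the procedure is often called a bootstrap, but the described
mechanics — an 80/20 split — are subsampling, which is what we implement).
Dichotomization uses observed time regardless of censoring status, as the
procedure is defined; a censoring-aware variant would require a different
stratification rule and is intentionally not the default. Per-stratum
training sizes take the floor of the fraction, with the remainder assigned
to the larger stratum.

Within each training subset every subpathway is screened by a univariate
Cox proportional-hazards fit; the Wald p-value is compared to `alpha`
(0.05). Wald was chosen because it is what `survival` reports directly and
is standard for screening; the likelihood-ratio alternative differs only in
pathological fits. Failed fits (constant scores, too few events,
non-convergence) count as *non-significant* rather than being dropped, so
every subpathway's count has the same denominator `n_reps`.

The *significance count* over all iterations dense-ranks the subpathways;
the signature is every subpathway with dense rank ≤ 25 (ties therefore
admit more than 25 subpathways, which is how a "top 25" can contain 55
members) or, alternatively, with count above a threshold (e.g. > 500 of
1,000). Multivariate proportional-hazards fits of the risk group plus
clinical covariates quantify independence from standard prognostic factors.

### Enrichment baseline

The conventional alternative scores a subpathway by the overlap of its
members with individually prognostic features. Genes and miRNAs are pooled
into one urn of size $m$; with $t$ subpathway features, $n$ prognostic
features and $r$ in the overlap, the enrichment p-value is the upper
hypergeometric tail $P(X \ge r)$, Benjamini–Hochberg corrected across
subpathways. The universe defaults to the *measured* features; a
`universe_size` override reproduces the whole-genome/miRNAome convention
when desired (the two differ only in how conservative the p-values are).

### Evaluation

Samples are clustered on their signature activity vectors with K-means
(K = 2, Euclidean distance, 10 seeded restarts keeping the best inertia;
K-means runs on samples as points over subpathway dimensions). The cluster
with the lower mean signature activity is labelled **high risk** — a
labelling convention tied to the empirical observation that low subpathway
activity marks poor prognosis in the melanoma setting this method was
developed for; the label is invariant to cluster index permutation, and no
downstream test depends on its direction. Group survival is compared by
the two-group log-rank test with Kaplan–Meier curves serialized for
plotting.

The permutation calibration permutes the (time, event) pairs jointly across
samples `n_perm` (1,000) times, keeping the profile — and hence the
grouping, which does not depend on survival — fixed, and recomputes the
log-rank p-value each time. The empirical p is the fraction of permuted
p-values *strictly below* the observed one, so a strong association yields
exactly 0; add-one smoothing is deliberately not applied, to preserve that
behaviour.

Tumor-versus-normal contrasts use the two-sided Wilcoxon rank-sum test per
subpathway with a three-state call (tumor-high / normal-high / ns at 0.05).

## The synthetic data generator

`simulate_spagm_study()` generates every input the pipeline needs with a
known ground truth, all randomness derived from one seed:

* **Pathways**: 50 random connected graphs of 8 genes each (a random
  spanning tree plus extra edges at density 0.35). Small dense graphs each
  collapse into essentially one 3-clique subpathway, so the reconstructed
  units (~50 subpathways) are topologically separable — a deliberate
  choice so that "null" subpathways really are null (see below).
* **Interactions**: 250 miRNAs, each assigned to one pathway and given 2
  verified targets inside it, all flagged low-throughput. Pathway-focused
  targeting reflects that miRNAs co-regulate functional modules, and it
  prevents a regulated miRNA from being a member of an unrelated
  subpathway.
* **Expression**: Gaussian log2 baseline (feature means $\sim N(6, 1.5)$,
  noise SD 1) over the pathway features plus ~8,000 background genes and
  ~2,000 background miRNAs, matching the scale of a genome-wide assay.
* **Effects**: five subpathways share one standardized latent activity
  program per sample; per unit of activity their member genes shift up by
  1.5 (log2 SD units) and their member miRNAs down by 1.5 — the coordinated
  pattern the integrated score is designed to detect. A single shared
  program (rather than independent per-subpathway latents) represents a
  coordinated prognostic axis; with independent latents and a hazard on
  their mean, no individual subpathway could dominate the screening even
  in principle, because each latent's correlation with the hazard is
  bounded by $1/\sqrt{5}$.
* **Survival**: exponential with log-hazard $\beta \cdot$ latent
  ($\beta = 1$), baseline median 1,200 days (about 40 months), independent
  censoring at rate 0.3 (censored times are uniform fractions of the event
  time). With
  $\beta > 0$ high activity is adverse; the risk-group *labels* still
  follow the low-activity-is-high-risk convention, which only affects
  naming, never test statistics.
* **Conditions**: optionally a fraction of samples is labelled normal and
  the latent program gains a tumor-vs-normal offset (re-standardized), for
  contrast testing. The default cohort is all-tumor.

Two properties of real data the generator deliberately does **not**
emulate: count-based RNA-seq noise (library sizes, negative-binomial
dispersion — the scoring only consumes ranks, so monotone distributional
details are immaterial), and overlapping subpathways. Real k-clique
subpathways within one pathway overlap heavily, and a survival program
injected into one of them genuinely propagates to its siblings; recovery
there is not identifiable subpathway-by-subpathway, which is why the
generator's reference configuration uses separable units. Passing recovery
tests therefore demonstrate ranking correctness under separable ground
truth, not deduplication of overlapping signals.

A related, subtler point: because the score contrasts members against the
complement of *all* measured features, any sufficiently large coordinated
shift couples weakly into every other subpathway's score through the
complement mean and rank displacement. At genome scale (the default
background) this coupling is negligible; with only a few hundred measured
features it is not, and apparently "null" subpathways become genuinely
survival-associated. This is an intrinsic property of complement-based
scoring worth remembering when applying the method to small panels.

## Numerical choices and degenerate inputs

* Constant-row detection uses a relative tolerance of $10^{-12}$ on the
  centred sum of squares.
* Dense ranks break count ties; serialization orders ties by subpathway id
  so output files are stable.
* Stratified splits, K-means restarts and permutations restore the
  caller's RNG state; every seeded routine derives per-replicate streams
  from (seed, index) with a 32-bit linear map.
* Duplicate expression rows/columns are averaged at load time; profiles
  serialize missing cells as `NA`.
* Empty interaction tables, pathways without qualifying subpathways, and
  all-censored cohorts degrade to empty results or missing sentinels, not
  errors; genuinely unusable inputs (empty feature space, single sample,
  single risk group, infeasible enrichment counts, singular multivariate
  designs) raise informative errors.

## Validation problem sizes

The package's own test suite validates scoring against brute-force
evaluation on 200 random instances (≤ 20 features, ≤ 5 samples), k-clique
extraction against exhaustive enumeration on 100 random graphs of up to 12
nodes for $k \in \{2,3,4\}$, hypergeometric p-values against complete draw
enumeration for universes up to 12, screening calibration on 500 null
cohorts of 200 samples, and recovery/direction/null-uniformity on twenty
seeded replicates of the reference configuration with 200 resampling
iterations each — a scaled-down analogue of the 1,000-iteration procedure,
chosen as the smallest study size at which counts separate cleanly. The
acceptance script runs the full 1,000-iteration screen on one seed.

## Known limitations

* Pathway graphs are undirected and unsigned; activating versus inhibiting
  edges and compound nodes are out of scope, as is KGML parsing.
* One node = one gene id; gene-family or complex nodes must be expanded
  upstream.
* Identical subpathway node sets arising in different pathways are kept
  separate, keyed by their parent pathway.
* The proportional-hazards screen assumes proportional hazards per
  subpathway score; no time-dependent effects.
* Penalized multivariate signature construction (e.g. L1-regularized Cox)
  is out of scope; the signature is defined by marginal robustness counts.
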