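---
title: "Pneumotype analysis of longitudinal infant airway microbiota: methods and design"
author: "pneumotyper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pneumotype analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pneumotyper)
```

## The problem

The infant hypopharynx is colonised within days of birth, and its bacterial
community reorganises rapidly over the first months of life: an early
*Staphylococcus*-dominated state gives way to communities led by
*Streptococcus*, *Moraxella* and *Corynebacterium*. Analogous to gut
enterotypes, samples can be grouped into a small number of discrete community
state types — "pneumotypes" — by clustering on a beta-diversity distance.
`pneumotyper` implements the downstream analysis for a longitudinal cohort
design with three visits (1 week, 1 month, 3 months; coded `W1`, `M1`, `M3`):
quality control and rarefaction of an OTU count table, alpha diversity,
weighted UniFrac and Jensen–Shannon beta diversity, PAM clustering with
silhouette-based choice of the number of clusters, permutation validation of
the clustering, indicator-OTU analysis, per-subject core-microbiota
statistics, pneumotype transition and stability tests, and a
within-versus-between-subject distance-ratio permutation test.

Because the cohort data this design comes from are not publicly deposited,
the package ships a synthetic-cohort generator with known ground truth; every
stage of the pipeline is validated against it.

## Quality control and rarefaction

Samples with fewer than 2000 reads are excluded (a sample at exactly the
threshold is kept), and samples whose Shannon diversity exceeds the cohort
mean by more than 5 standard deviations are removed as likely artefacts. The
outlier rule is a single pass — mean and standard deviation are computed once
over all samples, not re-estimated after removals — and only the high tail is
trimmed, since contamination and index hopping inflate diversity rather than
depress it.

Rarefaction draws, for each sample, a uniform subsample of exactly 2000 reads
*without replacement* (one multivariate-hypergeometric draw per sample,
through `vegan::rrarefy`), so rarefied counts of an OTU have the
hypergeometric mean `depth * count / total`. The draw is seeded; the same
seed reproduces the table bit for bit. All downstream analyses run on the
even-depth table.

## Beta diversity

**Weighted UniFrac.** For samples with relative tip abundances `p` and `q`
on a rooted tree with branch lengths `l_b`, the raw statistic is
`W = sum_b l_b * |A_b - B_b|`, where `A_b` (resp. `B_b`) is the fraction of
the sample's reads descending from branch `b`. The normalised variant
divides by `D = sum_j d_j (p_j + q_j)` with `d_j` the root-to-tip path
length, which is the largest value `W` can attain for the given abundances,
so the distance lies in `[0, 1]`. The implementation computes per-sample
branch fractions with a single tip-by-edge incidence pass, after which the
whole distance matrix is one matrix product plus a Manhattan distance; its
contract is equality (to `1e-12`) with a brute-force branch-enumeration
oracle, which the test suite enforces on random trees, alongside a
cross-check against `phyloseq::UniFrac`.

The **normalised** variant is the default: bounded distances make average
silhouette widths comparable across cluster numbers and metrics. The raw
statistic is available with `normalized = FALSE`; which variant the original
enterotype-style analyses used is generally not stated, so both are exposed.

**Jensen–Shannon divergence** uses natural logarithms and the convention
`0 * log 0 = 0`: `JSD = (KL(p||m) + KL(q||m)) / 2`, `m = (p+q)/2`, bounded
by `log 2`. `sqrt(JSD)` (a metric) is available for the distance matrix.
Both kernels accept raw counts and renormalise internally.

## Pneumotype model

`pneumotype()` fits PAM (k-medoids) directly on the distance matrix and, by
default, scans `k = 2..10`, choosing the `k` with the largest average
silhouette width (ASW); ties go to the smaller `k`. The returned object
carries labels, medoids, per-sample silhouette widths and the ASW-by-k
curve, with `print`, `summary`, `plot`, `labels` and `fitted` methods.

Two numerical choices deserve note:

* **Exact small instances.** PAM's BUILD + SWAP local search can land in a
  non-global optimum even for toy problems (on random 8-point instances it
  misses the exhaustive optimum several percent of the time). `pam_medoids()`
  therefore enumerates all medoid subsets whenever `choose(n, k) <= 5000` —
  exact, deterministic, with lexicographic tie-breaking (lowest sample
  indices) — and delegates to `cluster::pam`'s deterministic BUILD + SWAP
  above that size. The crossover only affects problems far below cohort
  scale.
* **Silhouette conventions.** `s(i) = (b(i) - a(i)) / max(a(i), b(i))`;
  samples in singleton clusters get `s(i) = 0`, and so does the degenerate
  all-distances-zero case (`a = b = 0`).

**Cluster optimality.** The permutation test asks whether any equally-sized
random regrouping achieves smaller within-cluster spread. The statistic is
`T = sum_c W_c / n_c` (within-cluster pairwise distance sums, normalised by
cluster size so that tiny clusters cannot game the sum — the source analysis
does not state its statistic, so this is the package's choice, and it is
printed in the result's `scheme` field). The null permutes labels preserving
cluster sizes; `p = (1 + #{T_perm <= T_obs}) / (1 + n_perm)`, the standard
conservative add-one form used by every permutation test in the package.
The default is 10^4 permutations; reproducing a quoted `P < 1e-6` requires
at least 10^6, which is configurable but not the default for desk-scale
runtime.

**Indicator OTUs.** IndVal.g scores OTU–cluster pairs by
`sqrt(A * B)`: `A` (specificity) is the cluster's mean relative abundance
divided by the sum of all clusters' means — means, not sums, so unequal
cluster sizes do not bias it (the "g" correction) — and `B` (fidelity) is
the fraction of the cluster's samples containing the OTU. Each OTU is
assigned its best single cluster; combinations of clusters are not
considered, because one dominant genus per pneumotype is the phenomenon of
interest. Permutation p-values shuffle labels and compare each OTU's best
indval against its permuted best.

## Core microbiota

A subject's core microbiota is the set of OTUs present (count >= 1 in the
rarefied table) in all three of its samples; subjects missing any visit are
excluded. Core abundance at a visit is the fraction of reads from core OTUs,
so core and transient abundance sum to one exactly. The decline of core
abundance over visits is tested with two-sided paired Wilcoxon signed-rank
tests between consecutive visits; the stable-versus-changing comparison
(subjects keeping one pneumotype at all three visits versus the rest) uses a
Wilcoxon rank-sum test per visit plus a one-way ANOVA overall.

## Trajectories

Transition tables between consecutive visits are tested for dependence with
Pearson's chi-squared (expected counts from margins; Yates correction on
2x2 tables only; zero-margin rows/columns dropped with a warning). The
stability test compares the observed share of subjects with one pneumotype
at all three visits against the product-of-marginals expectation
`sum_k p_k(W1) p_k(M1) p_k(M3)` — not the uniform `k^-2` — because the
marginal pneumotype frequencies shift considerably between visits; a 1-df
goodness-of-fit test on (stable, not stable) follows, overall and per
pneumotype.

The **distance-ratio test** asks whether subjects stay closer to themselves
than to others over a time span: for subject `s`,
`r_s = d(s@t1, s@t2) / median { d(s@t1, s'@t2), s' != s }`, and the cohort
statistic is the median of `r_s`. The median denominator is the default for
robustness (the mean is available); the statistic is invariant to global
rescaling of the distance matrix. The permutation null reassigns each
subject's "own" `t2` column to a uniformly random `t2` sample —
independently across subjects, with the true column included — which makes
the null exactly exchangeable with the observed assignment; the one-sided
add-one p tests `median ratio < 1`, and a two-sided variant doubles the
smaller tail. Both the denominator and the permutation scheme are recorded
in the output.

## The synthetic cohort generator

`default_config()` encodes the study conditions the analysis assumes:

* **Design**: 300 subjects by default, three visits, ~14% of visits missing
  at random, so ~64% of subjects have all three samples.
* **Pneumotypes**: five types — four dominated (65% of reads) by
  *Staphylococcus*, *Streptococcus*, *Moraxella* and *Corynebacterium*
  respectively, plus one mixed type that is pure background. Visit-level
  marginal frequencies are taken from the published per-pneumotype sample
  counts.
* **Succession**: the background composition at each visit is solved so that
  the marginal mixture of type profiles reproduces the genus trajectories
  exactly in expectation — Staphylococcus 49/22/10%, Streptococcus
  17/31/29%, Moraxella 9/13/23% at the three visits (the Corynebacterium
  trajectory, not published at this granularity, is set to 5/6/5%).
* **Transitions**: sticky Markov matrices `T = a*I + (1-a) 1 q'` solved so
  that both the next visit's marginals and the consecutive-visit agreement
  (28% and 34%) hold in expectation. The implied three-visit stability is
  ~8%, against a product-of-marginals expectation of ~4%.
* **Covariates**: prevalences for siblings (56%), caesarean section (22%),
  maternal asthma (26%), sex, per-visit antibiotics and exclusive
  breastfeeding. Having siblings shifts 1-week membership log-odds towards
  the *Moraxella* and mixed types (+0.8); effects enter only through
  membership, never composition directly, and the base probabilities are
  re-solved so cohort marginals still match.
* **Strain structure**: each genus has 10 OTUs. Per subject and genus, a
  persistent allocation (Dirichlet with one shared dominant OTU at
  concentration 2.8 — the planted indicator OTU — and up to six
  subject-specific secondary strains at 0.3) is drawn once; per visit, a
  sparse transient allocation is drawn over the remaining OTUs, which
  rotate through visit-specific pools so transient OTUs do not recur. The
  two are blended at the visit's core share (0.90, 0.81, 0.63), making the
  observed per-subject core abundance match the configured medians by
  construction.
* **Noise and depth**: Dirichlet-multinomial composition noise at
  concentration 1000, log-normal depths (meanlog 9.25, sdlog 1, floor 500)
  of which ~5% fall below the 2000-read cut, exercising the depth filter.
  Depths are an order of magnitude below the original study's (~52k mean),
  a deliberate desk-scale choice that leaves every analysed quantity
  rarefied to the same 2000 reads regardless.
* **Phylogeny**: a near-star backbone over genera (deep splits collapsed to
  negligible internal branches, as short 16S fragments resolve them poorly)
  with exponential genus branch lengths and coalescent within-genus
  subtrees at half the backbone scale. A fully coalescent backbone was
  rejected deliberately: its deepest split dominates weighted UniFrac and
  makes two clusters silhouette-optimal regardless of the planted five.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: compositional gradients between types
(planted types are crisp, so recovery statistics such as ARI ≈ 1 and ASW ≈
0.7 are upper bounds; the original report's ASW was ~0.35), contamination
and batch structure in low-biomass samples, seasonal effects, taxonomic
misclassification, and covariate effects on composition within a pneumotype.
Parameter-recovery tests demonstrate correctness of the estimators under the
model's assumptions, not robustness to their violation.

## Problem sizes and runtime choices

The test suite validates UniFrac against its oracle on 120 random 10-tip
instances, PAM against exhaustive search on 200 instances with `n <= 8`,
parameter recovery on a 300-subject cohort (≈ 750 samples after QC), core
recovery on 200 subjects, and null calibration of the four permutation tests
on 500 replicate nulls each at 199 permutations (the add-one p-value grid at
199 permutations is exactly uniform under exchangeability, and 500
replicates keep the Monte-Carlo error of the empirical type-I rate near
0.01). `scripts/acceptance.R` re-runs the full analysis on a fresh
300-subject cohort with 10^4 permutations for the optimality and ratio
tests. These sizes were chosen so the whole validation runs in minutes on a
single core while leaving every comparison statistically meaningful.

## Known limitations

* Pneumotype labels are per-sample; no temporal smoothing or hidden-Markov
  structure is imposed, matching the source design but discarding
  information a longitudinal model could use.
* The exact-PAM crossover creates a (documented, deterministic) behavioural
  seam at `choose(n, k) = 5000`.
* `indicator_analysis` evaluates single clusters only; a `multipatt`-style
  combination search is out of scope.
* The distance-ratio permutation includes the true column in the uniform
  reassignment (making the minimum attainable p `1/(n_perm+1)`); excluding
  it would shift p-values by at most `1/n` per subject.
* Published cohort-level numbers (ASW 0.35/0.39, core medians 90/81/63%,
  ratios 0.93/0.87, 9.4% stable) depend on the unreleased data; the
  generator reproduces their structure, not their exact values, and the
  package treats them as qualitative references only.
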