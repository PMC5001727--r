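---
title: "Scoring agreement between regional expression and a brain-region ontology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring agreement between regional expression and a brain-region ontology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brotree)
```

## The model and its assumptions

A brain-region ontology is a rooted tree whose upper branches follow the
embryonic vesicle divisions and whose lower branches follow
cytoarchitecture. `brotree` asks, gene by gene, whether the spatial pattern
of expression across tissue samples respects that tree: samples from
regions that sit close in the ontology should, for a tree-agreeing gene,
have similar expression.

The score operationalises this with two pairwise distances. For samples
$a, b$ annotated to regions $r(a), r(b)$:

* ontology distance $d_{tree}(a,b)$ — the number of edges on the unique
  path between $r(a)$ and $r(b)$ (all edges weight 1; within-region pairs
  have distance 0 and are included);
* expression distance $d_{expr}(a_i,b_i) = |a_i - b_i|$ for gene $i$.

$$\mathrm{BRO}(i) = \rho_{Spearman}\big(d_{tree}(a,b),\; d_{expr}(a_i,b_i)\big)
\quad \text{over all } \tbinom{n}{2} \text{ sample pairs.}$$

Assumptions worth making explicit: expression is already log-scaled and
positive (no transform is applied); samples may be annotated to internal
ontology nodes, which the distance treats uniformly; and the pair
observations are *not* independent (every sample participates in $n-1$
pairs), which is why inference is permutation-based rather than analytic.

A triplet variant draws sample triplets $(a,b,c)$, keeps those with
$d_{tree}(a,b) < d_{tree}(a,c)$ (tree-distance ties are excluded from the
denominator), and reports the fraction for which
$d_{expr}(a,b) < d_{expr}(a,c)$. It is an ordering statistic in $[0,1]$
that needs no rank machinery on the 6.85M-pair scale and tracks the
pairwise score closely (tested).

## Significance

The null is generated by shuffling a gene's expression values across
samples, breaking the sample-to-region link while preserving the value
distribution, and rescoring. Defaults follow the statistic's original use:

* 100 permutations per gene, pooled across genes into one null (a
  region-level shuffle — permuting which region carries which mean profile —
  is available via `unit = "region"` as a coarser null);
* add-one empirical p-values $p = (1 + \#\{null \ge obs\})/(1 + N)$, so
  $p \ge 1/(N+1)$ and never 0;
* Benjamini–Hochberg FDR on the empirical p-values with $q < 0.01$, and,
  separately, the "top 1 % of permuted scores" rule. Both flags are
  reported; they agree closely on simulated data.

One caveat the simulations exposed: when donor intercepts are present, the
fraction of same-donor pairs differs between within-region and cross-region
pairs, giving the observed score a small negative bias that a full-exchange
permutation null does not replicate. Calibration checks therefore use the
exact-null world ($\sigma_{tree} = \sigma_{donor} = 0$), where empirical
p-values are uniform (KS p = 0.58 at the tested seed) and the top-1 % rule
flags 0.5 % of null genes. On real data the practical consequence is that
donor structure makes the sample-shuffling null slightly conservative for
positive scores; the per-subject scoring mode sidesteps it entirely.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_permutations` | 100 | permutations per gene; pooled null size = 100 × genes |
| `fdr_q` | 0.01 | BH threshold for `significant_fdr` |
| top-1 % rule | fixed | observed > 99th percentile of the pooled null |
| `combine` | pooled | `pooled` scores all samples at once; `per_subject_mean` averages per-donor scores (donors need ≥ 2 samples in ≥ 2 regions) |
| `n_triplets` | 1e5 | sampled triplets for the triplet score |
| `normalize` | none | optional division of each sample by its mean over all genes, or over an 11-gene highly-stable reference set |

Tree distances are cached once per ontology as a region × region integer
matrix (computed from node depths and shared-ancestor counts via one matrix
product), so per-gene work is the two rank vectors only.

## The synthetic world

`simulate_expression()` draws, per gene, Brownian increments on the
ontology tree: the root effect is 0 and each child adds
$N(0, \sigma_{tree}^2(g))$ per edge. A sample's value is
$\mu_g + \text{region effect} + \text{donor intercept}
(N(0, \sigma_{donor}^2)) + N(0, \sigma_{noise}^2)$. This is the minimal
generative model that makes the statistic's target quantifiable in closed
form:

$$E[(x_a - x_b)^2] = \sigma_{tree}^2 \, d_{tree}(a,b) + 2\sigma_{noise}^2
\;(+\, 2\sigma_{donor}^2 \text{ across donors}),$$

verified by Monte-Carlo in the test suite. Genes with $\sigma_{tree}=0$
are exact nulls. Age series scale $\sigma_{tree}$ per group with disjoint
donors (a cross-sectional design); listed gene pairs draw their per-edge
increments jointly with a target correlation, leaving marginals unchanged.

Defaults are chosen once to emulate the source-data structure at desk
scale: 6 donors, baseline log-intensity 8, $\sigma_{donor} = 0.5$ (donor
effects visibly smaller than regional effects, as in the real data's PCA),
$\sigma_{noise} = 1$, samples at the tree's leaves.

What a green simulation test does **not** establish: the generator has no
probe-level noise, no batch structure, no heavy-tailed expression, no
spatial autocorrelation beyond the tree, and its regional effects are
exchangeable across genes. Recovery results (power, clustering, hourglass)
are statements about this stated world, not about any real dataset.

## Numerical choices

* **Spearman ties** — mid-ranks throughout; large pair vectors are ranked
  by `rank()`'s sort-based path, and the tree-rank vector is computed once
  per dataset and reused across genes and permutations.
* **Score ceiling under the Brownian model** — even with zero noise the
  per-gene score does not approach 1: expression distance is a
  $\sqrt{t}$-scaled half-normal, so ranks retain intrinsic scatter at every
  tree distance (means ~0.45–0.50 on 16–64-node paths at
  $\sigma_{tree}/\sigma_{noise} = 10$). Tests therefore assert saturation
  relative to the same world's noiseless ceiling rather than an absolute
  value near 1. Real regional profiles are not Brownian, which is how
  individual genes in real data reach scores like 0.65.
* **Undefined scores** — zero-variance genes are flagged
  (`status = "zero_variance"`, score `NA`) and excluded from the null and
  the significance calls, never dropped silently.
* **Probe collapse** — for multi-probe genes, each probe's (region, donor)
  mean profile is rank-correlated between every donor pair over shared
  regions; the probe with the highest mean correlation wins, ties going to
  the lexicographically smallest probe id; genes whose probes have no
  cross-donor variance keep their first probe with a warning.
* **ANOVA across subjects** — computed within donor and summarised as the
  average F with the average of per-donor p-values (the literal "average
  score"); a Fisher combination is available but non-default.
* **Clustering tie-break** — region columns are sorted lexicographically
  before average-linkage `hclust`, making equal-distance merges
  deterministic.
* **PCA determinism** — component signs are fixed by making the
  largest-magnitude gene loading positive.
* **Explained variance** — R² from QR residuals of one-hot designs, clamped
  to [0, 1]; a single-level factor reports R² = 0 with a flag. For
  isotropic noise the eigenvalue spread follows Marchenko–Pastur, so "no
  structure" is asserted as fractions within the MP support, not as equal
  fractions.
* **Pair conventions** — pairs are stored in canonical sorted order;
  "signed log p" is $\mathrm{sign}(\tilde\rho)\cdot(-\log_{10} p)$ of the
  donor whose correlation is closest to the median, so anti-correlation is
  a left shift; the pair-level BRO score is the minimum of the two genes'
  scores (a product variant is a one-line change on the caller's side).
* **Trend tests** — F statistic of the linear-vs-constant model,
  $F = (RSS_0 - RSS_1)/(RSS_1/(n-2))$, BH-corrected across pairs; an exact
  constant series returns F = 0, p = 1 rather than 0/0.

## Open design points and how they were resolved

* Distances at coarser granularity are measured on the **pruned** tree
  (each kept region re-parented to its nearest kept ancestor), with the
  full-tree measurement available by simply not pruning. The pruned tree is
  the default because the coarse analysis treats the kept regions as the
  ontology.
* The permutation unit defaults to **samples** (the finer, more
  conservative null); region-level shuffling is behind a flag.
* Gene-set and pair lists are **inputs** in the data's gene namespace;
  no orthology mapping or pathway retrieval is attempted.
* The `run_pipeline()` orchestrator and the numbered `analysis/` drivers
  are the command-line surface; every output table carries a provenance
  header (config hash + seed) and reruns are byte-identical.

## Known limitations

* The pairwise stage materialises $\binom{n}{2}$ doubles per vector
  (~55 MB at n = 3702); very large cohorts should use the triplet score or
  per-subject scoring.
* Permutation cost scales as permutations × genes × $n \log n$ pair ranks;
  the defaults target hundreds-of-genes desk runs, and `n_permutations`
  should grow with the number of genes when per-gene nulls are requested.
* The ANOVA p-value summary (mean of per-donor p-values) is a reporting
  convention, not a calibrated combined test; use the Fisher mode when a
  single calibrated p is needed.
* DAG ontologies (multiple parents) are rejected; the hierarchy must be a
  tree.
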