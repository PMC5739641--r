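---
title: "miRNA co-expression networks from paired tumour/normal profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{miRNA co-expression networks from paired tumour/normal profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis this package implements

`mirnet` models the situation of a small paired oncology profiling study:
each subject contributes one tumour and one adjacent-normal tissue sample,
expression of ~1000 miRNAs is measured on log2 scale, and the scientific
questions are (i) which miRNAs shift between tissues, (ii) how the
*co-expression structure* — which miRNAs move together — differs between
normal and diseased tissue, and (iii) which dense groups of co-expressed
miRNAs plausibly co-regulate target-gene programmes.

The pipeline is:

1. **Paired differential expression.** Per miRNA, a two-sided Student
   t-test on the within-subject log2 differences (tumour − normal),
   `df = n_pairs − 1`. Fold-changes use the sign-encoded linear convention
   common in microarray tables: `signed_fc = 2^|Δ|` with the sign of the
   mean log2 difference Δ, so a 1.5-fold drop prints as −1.50 and no value
   can fall in (−1, 1). Benjamini–Hochberg q-values are always computed,
   but selection gates on raw p < α by default (with `use_q = TRUE` as the
   stricter switch): small paired designs rarely clear an FDR threshold,
   and per-feature candidate tables in this field conventionally report
   raw p.
2. **Significance-gated Spearman networks.** Within a sample stratum
   (e.g. tumour samples of one cohort), all pairwise Spearman correlations
   (midranks for ties) are tested; an undirected edge joins two miRNAs iff
   the correlation is significant at `alpha_corr`. Edges carry rho as
   weight and a direct/inverse sign. Spearman is used because log2
   microarray intensities are not reliably normal at n ≤ 10.
3. **Topology.** Global geometric attributes and per-node centralities
   (details below).
4. **MCODE.** Molecular-complex detection on the unweighted topology,
   plus a binomial null for cluster density.
5. **Comparison.** Set algebra between condition networks, preservation
   and sign concordance against an independent correlation table, and a
   census of small-component motifs (pairs, triangles, chains).
6. **Enrichment.** miRNA → validated-target mapping and hypergeometric
   over-representation against GMT gene sets with Bonferroni control —
   a local, reproducible stand-in for web enrichment services.

## Statistical and numerical choices

### Correlation p-values at very small n

The usual t approximation for Spearman's rho,
`t = rho * sqrt((n−2)/(1−rho^2))`, is unreliable for strata as small as 4
subjects. For strata of `n ≤ exact_limit` (default 9) the package
enumerates the exact permutation distribution of rho over all n!
orderings, keeping the observed midranks, and reports the two-sided tail
`P(|rho_perm| ≥ |rho_obs|)`; the identity permutation is one of the n!
cases, so p ≥ 1/n! and p is never anti-conservative. Beyond 9 the t
approximation is used (9! = 362,880 rows is the practical ceiling for the
enumerated null). Ties in the permutation tail comparison use an absolute
tolerance of 1e−9 on the sum-of-products statistic. Constant features have
no defined correlation: they are recorded as rho 0, p 1 with a warning and
therefore never form edges.

### Raw-p versus FDR-gated edges

Edge inclusion defaults to raw p < α with no multiplicity correction,
matching the convention of building "significant-correlation" graphs over
a candidate miRNA list of modest size. For *dense all-pairs discovery*
(hundreds of features, 10^4–10^5 tested pairs) the expected 5% false
edges are numerous enough to wire spurious bridges between genuinely
distinct modules, and any growth-based clustering will merge them. For
that regime `build_network(..., adjust = "BH")` gates edges on BH
q-values instead; the module-recovery analyses in the test suite and the
acceptance script use this mode. Both gates respect edge-set nesting in α.

### Global versus local path metrics

Global reachability attributes — diameter, characteristic path length,
the count of ordered reachable pairs and its percentage of N(N−1) — are
computed on the **unweighted** graph, the convention of interactive
network-analysis panels. Local centralities that traverse paths use edge
lengths `1/|rho|`: strongly correlated miRNAs are close, regardless of
correlation sign (a strong inverse correlation is as informative a link
as a direct one). Consequences:

* betweenness counts weighted shortest paths and is normalised by
  `(N−1)(N−2)/2`, so it lies in [0,1];
* closeness is `(number of reachable nodes) / (sum of weighted
  distances)`, which lies in [0,1] because every edge length is ≥ 1; an
  isolated node reports 0 and `avg_shortest_path` 0 with an
  `unreachable` flag;
* the clustering coefficient ignores weights (it counts neighbour
  links), and is defined as 0 for degree < 2;
* the topological coefficient of v averages
  `J(v,u)/degree(v)` over all u sharing ≥ 1 neighbour with v, where
  J counts shared neighbours plus 1 if u,v are adjacent; 0 when no node
  shares a neighbour.

Degree centralization is Freeman's index
`(N/(N−2)) (k_max/(N−1) − density)`: exactly 1 for a star, 0 for any
degree-regular graph. Heterogeneity is the coefficient of variation of
the degree sequence with the **population** standard deviation (n, not
n−1, in the denominator), the convention of network-analyzer panels.

### MCODE

Vertex weight = `k_max × density` of the highest k-core of the closed
neighbourhood; published defaults (degree cutoff 2, node-score cutoff
0.2, haircut on, fluff off, depth 100) are exposed in `mcode_params()`.
Growth is breadth-first from the highest-weighted unassigned seed,
admitting neighbours with weight ≥ `seed_weight × (1 − cutoff)`; ties in
seed order break lexicographically by miRNA id, which makes the procedure
fully deterministic. Haircut is iterated to a fixpoint (the 2-core of the
complex), so applying it twice changes nothing. Every node consumed
during growth stays assigned even if haircut later removes it; complexes
are therefore disjoint. One behavioural consequence worth knowing: two
equally dense complexes joined by a single bridge edge are grown into
*one* complex, because the far side's members pass the weight threshold —
a depth limit (`max_depth = 1`) is the parameter that keeps them apart.

Cluster density significance uses an analytic null by default: with k
members, the number of internal edges is compared to
`Binomial(C(k,2), p0)` with p0 the global network density. This is
intentionally simple and slightly liberal (it ignores degree structure);
a degree-preserving rewiring null (`method = "permutation"`, seeded,
add-one p-value) is available as the cross-check. Printed cluster
p-values from any particular study are not reproduction targets — the
null behind published values of this kind is generally unstated.

### Cross-cohort contrast

Cohorts are compared on the *subject-level paired log2 differences* with
a Welch two-sample t-test: cohort sizes in this design are small and
unequal (9 vs 4 in the motivating design), where pooling variances is
hard to defend. The reported fold-change is the ratio of the cohorts'
linear fold-changes under the same sign-encoded convention; swapping the
cohorts flips its sign and leaves p unchanged.

## What the generator emulates — and what it does not

`sim_config()` defaults mirror the motivating design: 9 subject pairs,
1105 features, 101 differentially expressed features with |log2FC| in
[0.3, 3.95] (the published fold-change tables span 1.10 to 15.43-fold),
baseline log2 intensities uniform in [4, 12]. The model is additive on
log2 scale:

```
x[f, (subject, tissue)] = baseline[f] + subject_effect[f, subject]
                         + lfc[f] * [tissue == tumour]
                         + loading[f] * z[module(f), sample] + noise
```

* the subject effect (SD = `noise_sd` by default, per-feature,
  per-subject, shared by the two tissues of a pair) induces exactly the
  within-pair correlation a paired test exploits, and cancels from the
  paired differences;
* each planted module has one Gaussian latent factor per sample; the
  loading `lambda = sqrt(rho/(1−rho)) * sigma_total` makes the pairwise
  *Pearson* correlation of same-sign members equal `rho_target`, and
  under Gaussianity Spearman ≈ `6/π·asin(rho/2)` — about 0.89 for a
  target of 0.9, which is why tests assert recovery thresholds below the
  target rather than the target itself. Inverse-sign members take
  negated loadings;
* background features are independent given their own subject effect,
  so their correlations are honestly null;
* `noise_sd` defaults to 0.5 log2 units, a typical residual scale for
  processed two-colour/oligo array data; the reference recovery
  scenario uses 0.3 where the published design's effect sizes
  (|log2FC| ≥ 1) should be comfortably detectable.

Identical seeds give bit-identical studies, and the generator restores
the caller's RNG state.

Deliberately **not** emulated: probe-level effects, normalisation
artefacts, batch effects, heavy-tailed or intensity-dependent noise,
correlated background beyond the planted modules, missing values. Passing
recovery tests on this generator shows the estimators and algorithms are
correct and calibrated under the stated model — not that real microarray
data satisfies that model.

## Validation scenarios and problem sizes

The test-suite reference scenarios, chosen once as realistic for this
design family:

* **Calibration**: 10 independent null studies of 1000 features at 9
  pairs (10,000 p-values); type-I error must sit within 0.05 ± 0.01. Ten
  replicates are used because a single 1000-feature draw has Monte-Carlo
  SD ≈ 0.007 — too noisy to certify a ±0.01 band.
* **Recovery**: 50 pairs, 3 modules of 8 at rho 0.9 over 500 background
  features, 60 DE features with |log2FC| in [1, 3] at noise 0.3; DE
  recall ≥ 0.9 and ≥ 2 of 3 modules recovered at Jaccard ≥ 0.75 from the
  BH-gated network.
* **Oracle sweeps**: every path-based centrality, the topological
  coefficient, triangle enumeration and MCODE vertex weights are checked
  against exhaustive brute-force enumeration (all simple paths / all
  triples / all vertex subsets) on 200 random connected graphs of ≤ 8
  nodes, with edge weights drawn from a dyadic set so tied path lengths
  compare exactly.
* **Published-scale geometry**: density `2E/(N(N−1))`, mean degree
  `2E/N` and reachable-pair counts are analytic in (N, E), so the
  published values (98 nodes/1232 edges → density 0.26, 25.14 neighbours,
  9506 ordered pairs; 100/1434 → 0.29, 28.68) are reproduced exactly from
  any connected graph at those sizes.

## Known limitations

* Correlation networks are discovery tools: an edge is a marginal
  association, not a direct interaction (no partial correlations or
  graphical models are attempted).
* With 4 subject pairs the exact permutation p-value cannot fall below
  `2/4! ≈ 0.083` two-sided for distinct ranks at the extremes — at such
  sizes an α of 0.05 on exact p-values yields very sparse networks, which
  is a property of the design, not a bug.
* The hypergeometric enrichment inherits every bias of its inputs: the
  packaged demo GMT and target map are illustrative fixtures assembled
  from published per-pathway gene parentheticals, not a faithful export
  of any target database, and the default universe (all genes in the
  collection) is much smaller than a genome-wide background.
* The binomial density null treats node pairs as exchangeable; for
  hub-dominated networks the permutation null is the safer choice.
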