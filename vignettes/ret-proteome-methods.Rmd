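---
title: "Methods: differential screening, minimum networks and phospho analysis for pooled iTRAQ studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential screening, minimum networks and phospho analysis for pooled iTRAQ studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retproteome)
options(retproteome.quiet = TRUE)
```

## The design being analysed

`retproteome` analyses a pooled 4-plex iTRAQ experiment on the sarcoplasmic
fraction of human skeletal muscle: all volunteers of a condition are pooled
into a single labelled sample, one per condition (young pre-RET, old pre-RET,
young post-RET, old post-RET; reporter ions 114–117). Relative quantification
therefore yields *one* fold-change ratio and P-value per protein per
contrast, not per-subject measurements. Three contrasts are fixed throughout
(`ret_contrasts()`), always oriented numerator = the later or older
condition: old/young at baseline and post/pre within each age group, so a
ratio above 1 reads as "higher in old" or "higher after training".

Two consequences of pooling shape the whole package. First, there is no
between-subject variance to model: the screening stage is a deterministic
rule on the reported ratio and P-value, not a model fit. Second, replication
only exists at the spectral level, which is where the phosphopeptide t-tests
operate.

## Screening rules

A protein table is first filtered: reverse-library hits, suspected
contaminants (gene symbols starting with `HB` or `KRT` — haemoglobins and
keratins, the classic blood and skin contaminants of muscle biopsies), and
proteins identified by fewer than 2 peptides are excluded, each record
counted under one reason.

Regulation calls are fold-change-first: UP if ratio > 1.2, DOWN if
ratio < 0.8, strict inequalities, so a ratio of exactly 1.2 or 0.8 is
UNCHANGED. We read the cut-offs literally as strict because they are stated
as "> 1.2" and "< 0.8"; the choice is visible only for exact boundary values,
which are vanishingly rare in real ratio data. The P-value annotates a tier —
SIGNIFICANT (*P* < 0.05), TREND (0.05 ≤ *P* ≤ 0.1), else FC_ONLY — but does
not gate differential status by default. The display convention this mirrors
shows *every* fold-change-crossing protein with asterisks for significance,
so "differential" is a fold-change property; for stricter analyses
`screening_thresholds(require_significance = TRUE)` gates differential
status on tier ∈ {SIGNIFICANT, TREND}. Both behaviours are first-class and
tested, because the gating convention is a genuine judgment call in this
kind of analysis.

## Over-representation analysis

Enrichment uses the one-sided hypergeometric upper tail (equivalently
one-sided Fisher), computed through the log-space distribution function for
stability, with Benjamini–Hochberg adjustment applied *within* each category
collection (GO BP, GO CC, GO MF, KEGG, Reactome) and significance at
FDR < 1%. Adjusting per collection mirrors how such results are reported per
database and keeps q-values comparable within a panel.

The background universe defaults to the union of all annotation members,
which is the convention of list-based web tools. With a detected proteome of
only ~164 proteins this choice is material: a whole-annotation universe
overstates *N* and flatters p-values, so `enrich_list(universe = ...)`
accepts the detected-protein symbol set instead. Query symbols outside the
universe are dropped with a warning rather than an error, since accession
mapping regularly strands a few symbols.

## Minimum interaction networks and hubs

The network stage reproduces the common web-tool workflow locally. From an
undirected interactome (edge list or SIF), the *first-order* subnetwork of a
seed list is the seeds, their direct interactors, and all edges among that
node set. The *minimum interaction network* keeps the seeds plus only the
connectors needed to link them — a node-weighted Steiner tree problem, which
is NP-hard, so we use the Kou–Markowsky–Berman 2-approximation with unit
edge weights: metric closure over the seed terminals, minimum spanning tree
of the closure, expansion of closure edges into concrete shortest paths, a
spanning tree of the expanded subgraph, then iterative pruning of non-seed
leaves. Each connected component with ≥ 2 seeds is reduced independently; a
component with a single reachable seed collapses to that seed alone, and
seeds missing from the interactome are reported as orphans. Unit weights are
used because typical interactome exports carry no confidence scores; the
search is restricted to the first-order subnetwork, which matches the
workflow being reproduced and bounds the cost.

Hubs are the top 5 nodes by betweenness centrality — unnormalized, each
unordered pair counted once, fractional credit across equal-length shortest
paths. Normalization divides every score by the same constant within a
network and cannot change ranks, so the raw scores are reported. Ties are
broken by node degree and then
lexicographically by symbol, purely so the ranking is a deterministic total
order. Tests verify the betweenness against a naive all-pairs enumeration
oracle and the Steiner heuristic against exhaustive search on all instances
up to 14 nodes (50 and 100 random instances respectively — sizes at which
the brute-force oracles are exact yet fast).

Hub *identities* on real data depend on the interactome snapshot and the
minimum-network heuristic of whatever tool produced a published figure;
this package makes no claim to reproduce a specific tool's node-for-node
output, only the stated procedure.

## Reversal and concordance logic

For RET-response concordance, every protein differential in at least one of
the two within-age RET contrasts is cross-classified by its (young, old)
direction pair into eight categories (both up, both down, four
one-age-only, two opposite). Directions only — tiers are ignored, matching
the binary shading such comparisons are presented with.

For reversal, every baseline-dysregulated protein (old vs. young ≠
UNCHANGED) is classified by whether RET in old muscle called the *opposite*
direction: UP_REVERSED, UP_NOT_REVERSED, DOWN_REVERSED, DOWN_NOT_REVERSED.
The default requires the RET response itself to cross the opposite
fold-change cut-off, because reversal heatmaps use the same up/down palette
as the screening figure, implying threshold-crossing calls; `mode =
"lenient"` instead accepts any opposite-side movement of the RET ratio
relative to 1. Both operations partition their eligible input — an invariant
the tests check exhaustively over all direction pairs. The per-category
symbol lists are written as files and feed the network stage as seed lists.

## Phosphopeptide analysis

Phosphopeptide tables carry a 0–100 confidence score, flags for
non-phosphorylated and mis-allocated peptides (mis-allocation is modelled as
an input flag, since it is an upstream search-engine judgment), and
replicate-level normalized measurements per pooled condition. The filter
removes non-phospho, mis-allocated, and confidence < 10 records — strictly
below, so confidence 10 is retained.

Fold-changes are normalized to the parent protein by linear division
(ratio of ratios), isolating phosphorylation change from protein-level
change. Per contrast, the replicate sets of the numerator and denominator
conditions are compared with a pooled-variance Student's t-test (Welch
selectable), significant at *P* ≤ 0.05 *inclusive* — this stage's stated
convention, unlike the strict *P* < 0.05 of the screening tiers, and the
boundary is honoured per stage. Degenerate inputs are defined rather than
left to error: identical groups give t = 0, P = 1; zero variance with
unequal means reports P = 0 with a warning; fewer than 2 replicates per
group is a domain error.

## The synthetic-data generator

The generator exists so that every downstream stage has a testable ground
truth without any download. Its defaults *are* the study conditions of the
motivating design: 164 analysis-ready proteins; planted up/down counts per
contrast of 29/31 (baseline), 21/16 (young RET), 26/19 (old RET); 40
phosphopeptides of which a quarter are decoys; three replicate measurements
per pooled condition.

Design choices, each made once:

- **Null ratios are lognormal around 1** (`null_log_sd`, default 0.08 —
  roughly the spread that keeps null proteins inside the 0.8–1.2 band ~98%
  of the time). Ratio data are strictly positive and multiplicative, so
  symmetric-in-log noise is the natural null.
- **Planted effects** draw ratios uniformly from (1.3, 2.5) and (0.4, 0.75)
  — clear of the cut-offs so planted truth is recoverable exactly when noise
  is switched off — with P ≤ 0.05; a configurable `trend_frac` places a
  share of planted P-values in the (0.05, 0.1] trend band so the tier
  machinery is independently testable.
- **A shared responsive pool** (`responsive_frac`, default 73/164): planted
  effects for all three contrasts are sampled from one pool of proteins, so
  differential sets overlap across contrasts the way repeated measurements
  of the same biology do, rather than being independent draws.
- **The interactome** is two preferential-attachment communities joined
  *only* through planted connector nodes, so every inter-community shortest
  path crosses a connector (removing the connectors provably disconnects
  the graph — a tested invariant). Connectors attach to `bridge_degree = 8`
  nodes per community: a bottleneck joining two modules is only a bottleneck
  worth planting if it actually carries the cross-traffic, and a weakly
  attached bridge is regularly out-scored in betweenness by internal
  preferential-attachment hubs. At this attachment the planted connector is
  the top-ranked hub in ≥ 95% of replicate networks, which is the
  recovery contract the generator is tested against.
- **Planted gene sets** are ≥ 80% planted-UP members (default 13 of 15) for
  a designated contrast; all other sets sample the symbol universe
  uniformly.
- **Phospho effects** shift the numerator condition's replicate mean in log
  space by the same effect-size ranges as the protein table; the old
  post-RET condition inherits the baseline age shift plus the old RET
  effect, keeping the three contrasts mutually consistent. Replicate noise
  is lognormal with sd 0.1, giving the 3-replicate t-test high power at the
  planted effect sizes.
- **Determinism**: each generator seeds the RNG from `seed` plus a fixed
  per-stage offset and restores the caller's RNG state, so a bundle is
  byte-identical for a fixed config and independent of call order.

What the generator does *not* emulate: spectrum-level noise, missing values
(the pooled design quantifies every protein in every condition), correlated
annotation structure (real GO terms overlap hierarchically; random sets do
not), interactome degree correlations beyond preferential attachment, and
any form of batch effect. Passing tests on synthetic data therefore
demonstrate the correctness of the *computations*, not the biological
validity of any particular real-data finding.

## Numerical and implementation notes

- Hypergeometric tails are computed in log space (`phyper(log.p = TRUE)`),
  then exponentiated; tests require agreement with exhaustive enumeration to
  1e−12 for every instance with universe ≤ 12.
- BH adjustment is the standard step-up (`p.adjust`), checked against a
  naive O(m²) implementation of the defining formula on 1000 random vectors.
- Betweenness comes from igraph's Brandes implementation, checked against a
  naive path-counting oracle to 1e−9 on graphs up to 30 nodes.
- All tie-breaks (hub ranking, enrichment ordering) use locale-independent
  radix ordering so results are identical across platforms.
- Pipeline outputs are plain TSV/JSON/GraphML with no timestamps; two runs
  with the same config and seed are byte-identical, which the test suite
  asserts file by file. The provenance block records the package version,
  seed and an MD5 of the serialized config (the output directory is
  deliberately excluded from that hash, as it does not affect the results).
- Problem sizes in the test suite (graphs ≤ 30 nodes for betweenness
  oracles, ≤ 14 for exact Steiner search, 100 replicate networks and
  enrichment simulations, 1000-replicate type-I simulations) are chosen so
  each oracle is exact and each Monte-Carlo estimate has small enough error
  to make the asserted bounds meaningful.

## Known limitations

- The screening stage trusts the upstream quantification: it does not model
  reporter-ion compression or re-derive P-values from spectra.
- Accession-to-symbol mapping is a static user-supplied table; no live
  database lookups.
- Enrichment will not numerically replicate web tools whose backgrounds and
  rank-deviation adjustments are proprietary or undocumented; the test is
  the plain hypergeometric.
- The Steiner reduction is a 2-approximation; on adversarial graphs the
  minimum network can contain up to twice the optimal number of connectors
  (tests verify the bound, and the exact optimum is used only at oracle
  scale).
- With one pooled sample per condition, the phospho t-test's replicates are
  technical (spectral), so its P-values speak to measurement precision, not
  biological variation between people.
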