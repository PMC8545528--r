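---
title: "Methods: typed ceRNA networks, MCODE modules and variant disturbance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: typed ceRNA networks, MCODE modules and variant disturbance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernet)
```

This vignette documents the models, conventions and numerical choices behind
the package, in the spirit of the methods sections that accompany the major
omics analysis packages. It is the reference for *why* each default is what
it is; the README shows *how* to run things.

## The network model

The central container is a **typed graph**: an undirected simple-per-kind
graph whose nodes carry one of five labels (`lncRNA`, `diabetes`, `DR`,
`common`, `other`) and whose edges are either protein–protein interactions
(`ppi`) or ceRNA regulations (`cerna`, each annotated with the comma-joined
ids of the miRNAs shared by the lncRNA and its coding partner). Three
structural rules are enforced at construction: no self-loops, no duplicated
(node pair, kind) edge, and every `cerna` edge joins exactly one lncRNA to
one non-lncRNA node. A pair connected by both a `ppi` and a `cerna` edge
keeps both, because the downstream topology computes a single degree over
the integrated network and that degree should count both regulatory
contexts.

Network construction follows the order used for comprehensive
lncRNA–mRNA disease networks: disease genes are mapped onto the PPI by
exact, case-sensitive symbol equality (an upper-casing hook is available
but off by default — silent identifier munging causes more harm than
missed matches it repairs); the largest connected component is extracted
*before* ceRNA integration; ceRNA edges whose coding gene is absent from
the component are dropped and reported rather than silently discarded.
Largest-component ties are broken by the lexicographically smallest member
id, which makes the operation deterministic and idempotent.

## Topology

* **Degree** counts all incident edges, both kinds.
* **Betweenness centrality** is the exact Brandes computation (via igraph)
  on the simplified graph (parallel `ppi`/`cerna` edges collapsed — BC is a
  shortest-path notion and a parallel edge adds no path), normalised by
  `(n−1)(n−2)/2`. Unreachable pairs contribute nothing, and graphs with
  fewer than three nodes have all-zero BC. The test suite holds this
  implementation to ≤ 1e−9 agreement with an explicit
  enumerate-all-shortest-paths oracle over the full graph-atlas enumeration
  of small graphs plus random batteries.
* **Topological coefficient** of a node `n` with degree `k_n ≥ 2` is the
  mean of `J(n, m) / k_n` over all nodes `m ≠ n` sharing at least one
  neighbour with `n`, where `J` counts shared neighbours plus 1 if `n` and
  `m` are adjacent. This is the NetworkAnalyzer definition, chosen because
  the tooling tradition this workflow comes from uses it; nodes with degree
  ≤ 1 (or no sharing partner) get TC = 0.
* **Power-law fits** regress `log N(k)` on `log k` over the distinct
  degrees with non-zero frequency (degree 0 excluded — its log is
  undefined). Frequency, not density, is used on the y-axis, and the log
  base cancels in both slope and `R²`. A fit needs at least three distinct
  positive degrees; fewer is an error, not a silent `NA`. `R²` is computed
  from the residual and total sums of squares directly, so an exact
  power law returns `R² = 1` to machine precision. The slope is reported
  signed, exactly as fitted.
* **Group comparisons** use the two-sided Mann–Whitney U test
  (`stats::wilcox.test`), exact in the small tie-free case and
  normal-approximated with tie correction otherwise; groups with fewer
  than two members are skipped with a warning rather than producing
  meaningless p-values.
* **Hubs** are the top 50 nodes by degree (the workflow's convention),
  ties broken by node id for determinism. Regulating proportions of hub
  lncRNAs are computed over ceRNA neighbours only and normalised over the
  disease-typed neighbours; `other` neighbours are counted separately so
  the three reported proportions always sum to 1 when defined.

## MCODE-style module detection

The detector follows the canonical Bader–Hogue formulation. Each node is
weighted by `k_max × density` of the highest-k-core of its closed
neighbourhood; seeds are visited in descending weight (ties by id); a
breadth-first expansion admits a neighbour `v` iff
`w(v) > w(seed) · (1 − node_score_cutoff)` and `v` is unclaimed (complexes
do not share nodes; first claim in seed order wins). The haircut removes
members with exactly one within-complex edge, iterated to a fixed point;
complexes whose induced minimum core number falls below `k_core` are
discarded; the score is induced density × member count. Defaults are the
classic parameters: `k_core = 2`, cutoff `0.2`, depth `100`, haircut on,
fluff off. The k-core numbers themselves are computed by iterative
minimum-degree peeling written in-package (they are an internal of the
weighting), and are cross-checked in tests against both igraph's coreness
and a brute-force repeated-subgraph oracle.

A structural property worth knowing: because admission is relative to the
*seed's* weight, two dense regions of comparable weight that are connected
by even a single bridge edge are absorbed into one complex. On synthetic
backbones with several planted cliques this means bridged cliques of
similar size frequently surface as a single merged module (each clique
fully contained in it) rather than as separate modules. That is the
canonical algorithm's behaviour, not an artefact; the planted-clique tests
therefore check containment of each clique in a detected module, and the
measured separate-recovery rate is reported honestly by the acceptance
script.

## Enrichment

Over-representation uses the upper-tail hypergeometric probability
`P(X ≥ overlap)` with Benjamini–Hochberg correction across all sets of the
collection (BH rather than Bonferroni: it is the standard ORA correction
and the workflow names none). The default universe is the union of the
collection's genes (plus the query); when analysing a graph, the
recommended background is its coding genes, and lncRNA ids are excluded
from queries — enrichment collections describe coding genes. Rows are
sorted by adjusted p, ties by set name, so permuting the collection leaves
the output identical.

## Expression

Differential expression runs a per-gene two-sided **pooled-variance
Student's t-test on log2(x + 1) values**, with the fold change computed on
linear-scale group means and a two-sided gate (FC ≥ 1.5 or ≤ 1/1.5). The
pooled test was chosen over Welch deliberately: the emulated design is 25
cases vs 5 controls, and at that imbalance the Welch approximation is
measurably liberal (Monte-Carlo type-I ≈ 0.057 at nominal 0.05 under the
generator's equal-variance log-normal model) while the pooled test is
exact; it also matches the named test of the workflow. Welch remains one
flag away (`var_equal = FALSE`). Significance uses the raw p-value
(p < 0.05) — the workflow's stated rule — with BH-adjusted values emitted
for reference only. Degenerate genes are handled by convention: both
groups constant and equal gives p = 1, a zero control mean gives
FC = +∞ (flagged, not an error). Coexpression is plain Pearson correlation
with the `t = r√((n−2)/(1−r²))` test; constant vectors yield `NA` with a
warning.

## Variant overlay

LD filtering keeps lead SNPs (no r²) and LD SNPs with `r² > 0.8`
**strictly** — the threshold is printed as a strict inequality in the
tradition this follows; an inclusive mode is a flag. Region intervals are
0-based half-open (`[start, end)`, the BED convention) and assignment is
multi-label: regulatory catalogs overlap, so a SNP inside both a TFBS and
a DHS interval counts once in each class.

A miRNA "binding site" is operationalised as an exact match to the reverse
complement of miRNA positions 2–8 (**7mer-m8**), with 6mer and 8mer modes
selectable; no thermodynamic or PWM scoring is attempted. Calls substitute
each allele into the transcript (the FASTA is taken as the lncRNA's sense
strand), scan a ±7 nt window around the SNP, and emit a `gain` when the
site exists under the alternate allele only, a `loss` under the reference
only — a site that does not overlap the SNP is present under both alleles
and produces no event by construction. TF motifs are IUPAC consensus
matches within motif-length−1 of the SNP, same gain/loss semantics.

Consequences for the network: an existing ceRNA edge is **disrupted** only
when losses remove *all* of its shared miRNAs (losing one of two shared
miRNAs leaves the sponge intact); a **created** relation needs at least one
gained miRNA shared with the target gene's annotated miRNA set (`rule =
"any"`; a strict `"all"` mode requires the full annotated set, for the
scenario where one variant generates two sites at once).

## The synthetic-data generator

The generator emulates the shapes of the emulated study, not its content:

* **Backbone**: preferential attachment (Barabási–Albert) with
  `attach_m = 7` by default — the emulated human interactome has ≈ 7.1
  interactions per protein, and at much sparser settings the
  disease-induced subgraph of a 300-node backbone fragments, which would
  misrepresent the study's construction step. Checks whose stated
  conditions require an `m = 2` background (planted-clique recovery, the
  n = 5000 power-law property) pass that explicitly.
* **Disease sets**: 45 diabetes / 12 DR / 9 common labels on 300 nodes —
  the catalog proportions (1,349 / 371 / 269 on a 9,064-protein network)
  at desk scale.
* **ceRNA edges**: Poisson(1.5) partners per lncRNA (the catalog ratio of
  regulations to lncRNAs), each with 1–3 shared miRNAs from a 20-miRNA
  pool.
* **Expression**: log-normal, `2^(base + Δ·case + N(0, σ))` with
  `base ~ U(6, 10)` in log2 units, planted `|Δ| = 1.5`, `σ = 0.4`, 25 vs 5
  samples. This is the minimal model under which "t-test + fold change
  1.5" is meaningful.
* **Variants**: each SNP samples a region class from configurable weights;
  half of the `lncRNA`- and `TFBS`-class SNPs are planted so exactly one
  allele completes a seed site or motif. Every planted window is certified
  by an independent character-level scan (no regex, none of the package's
  calling code): exactly the planted event, nothing else, and non-planted
  SNPs certified event-free; the certification redraws flanking bases
  deterministically under the seed until clean.

All generators derive their streams from one master seed, so identical
configs are byte-identical; ground truth (cliques, DE genes, site events,
labels) always references emitted entities.

What the generator does **not** emulate — and hence what green tests do not
show about real data: realistic LD haplotype structure (r² values are
sampled attributes), miRNA expression, count-based sequencing noise
(values are treated as already-normalised abundances; no dispersion
estimation or library-size normalisation), identifier mapping problems,
and database-version effects. The printed results of the original study
depend on versioned downloads (DisGeNET, HuRI, LncACTdb, LincSNP, GEO) and
are out of reproduction scope; validation is therefore property-based
against planted truth.

## Problem sizes and numerical conventions

The test battery uses: exhaustive betweenness verification over the
graph-atlas enumeration of all graphs on ≤ 7 nodes (≈ 1000 connected
cases) plus 200 random ≤ 8-node graphs at 1e−9; 20-seed recovery runs for
modules (n = 300) and variant events (≈ 80 planted events per seed);
200 null matrices × 50 genes for t-test calibration; n = 5000
preferential-attachment graphs for power-law behaviour; and a full
pipeline determinism check (two runs, byte-identical JSON reports). These
sizes were chosen as the smallest at which the distributional statements
are stable.

Ties are always broken by id (hubs, seeds, components, module ranking:
score desc, then size desc, then smallest member id). JSON reports are
written with fixed numeric precision so determinism is byte-level.

## Known limitations

* Seed-relative MCODE expansion merges bridge-connected dense regions of
  comparable weight (see above); if separated modules are essential,
  raising `node_score_cutoff` sensitivity or pre-cutting bridges is the
  user's call, not a default.
* The ceRNA "created"-relation call requires a gene→miRNA annotation
  table; without it only disruptions are assessed.
* `run_all(resume = TRUE)` reuses stage report blocks from disk; the
  in-memory objects are recomputed (cheap and deterministic by design).
* Enrichment assumes unweighted membership (no ranked GSEA variant).
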