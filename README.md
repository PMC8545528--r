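# cernet

Typed ceRNA–PPI network construction, dense-module detection and variant
disturbance mapping for case/control transcriptomics — built around the
systems-biology workflow used to dissect long non-coding RNA (lncRNA)
regulation in diabetic retinopathy (DR).

## The problem

Competing endogenous RNAs (ceRNAs) are transcripts — here lncRNAs — that
regulate an mRNA indirectly by sponging the miRNAs whose binding sites both
share. A common way to study a disease through this lens is to:

1. intersect disease gene catalogs (diabetes vs DR) and map the genes onto a
   protein–protein interaction (PPI) network, keeping the largest connected
   component;
2. integrate lncRNA–mRNA ceRNA regulations (edges annotated with the shared
   miRNAs) into that backbone, giving a typed network whose nodes are
   `lncRNA`, `diabetes`, `DR` or `common` genes;
3. characterise topology: degree, betweenness centrality
   (BC, normalised by `(n−1)(n−2)/2`), topological coefficient (TC), and
   log–log power-law fits of the degree distribution
   (`log N(k) = α + β log k`, reporting the slope `β` and `R²`);
4. find dense modules with the MCODE algorithm (k-core–based vertex
   weighting `w(v) = k_max · density` of the highest-k-core of the closed
   neighbourhood, seeded expansion admitting `w(v) > w(seed)(1 − cutoff)`,
   haircut post-processing; score = density × size) and test modules and
   hubs for over-representation against gene-set collections
   (hypergeometric upper tail + Benjamini–Hochberg);
5. test differential expression between DR and normal samples (Student's
   t-test on log2 values, fold-change gate at 1.5) and ceRNA coexpression
   (Pearson, p < 0.05);
6. overlay disease-associated SNPs (LD r² > 0.8) on the lncRNAs' regulatory
   geography (enhancer, TFBS, lncRNA body, DHS, open chromatin, footprint,
   TAD) and call allele-dependent gain/loss of 7mer-m8 miRNA seed sites and
   IUPAC TF motifs, propagating the consequences to ceRNA edges
   ("created" / "disrupted" relations).

Every step is implemented here as a tested, seedable, tabular (tibble in /
tibble out) API, together with a synthetic-data generator that plants ground
truth (cliques, expression shifts, binding-site events) so the whole
pipeline can be validated end to end without any database downloads.

## Worked example

```r
library(cernet)

cfg <- synth_config(seed = 1)          # desk-scale synthetic study
res <- run_all(pipeline_config(input = cfg))

res$objects$clmn
#> <typed_graph> 42 nodes, 49 edges
#>   node types: lncRNA=5 diabetes=28 DR=2 common=7 other=0
#>   edge kinds: ppi=43 cerna=6

res$objects$backbone_fit
#> <powerlaw_fit> slope = -1.7625, R2 = 0.8547 (40 degree values)

res$objects$modules
#> # A tibble: 5 × 6
#>   module seed  n_members density score members
#>    <int> <chr>     <int>   <dbl> <dbl> <list>
#> 1      1 G0003        21   0.519 10.9  <chr [21]>
#> 2      2 G0030        11   0.727  8    <chr [11]>
#> 3      3 G0002         9   0.639  5.75 <chr [9]>
#> 4      4 G0025         3   1      3    <chr [3]>
#> 5      5 G0061         3   1      3    <chr [3]>

head(res$objects$enrichment, 2)
#> # A tibble: 2 × 8
#>   set            source  overlap set_size query_size universe_size  p_value p_adjust
#> 1 planted_cliqu… synthe…      11       11         21           123 2.29e-10  2.52e-9
#> 2 planted_cliqu… synthe…      10       10         21           123 2.35e- 9  1.29e-8
```

Reading the output: the typed network keeps the 37 disease genes that
survive the largest-component step plus 5 integrated lncRNAs; the backbone
degree distribution is scale-free-like (negative log–log slope, high `R²`);
the top MCODE module (score 10.9 = density × members) contains the densest
planted structure, and enrichment recovers the planted clique sets with
BH-adjusted p ≈ 1e−9. `res$objects` also carries the per-node metrics
(`node_metrics()` columns `degree`, `bc`, `tc`), hub table, DE and
coexpression tables and the variant-overlay results; `autoplot()` /
`plot_*()` functions draw the standard figures for each.

Individual stages are plain functions over data frames —
`intersect_gene_sets()`, `build_network()`, `node_metrics()`,
`fit_power_law()` (+ `tidy()` / `glance()`), `predict_complexes()`,
`enrich()`, `differential_expression()`, `coexpression()`, `ld_filter()`,
`classify_regions()`, `mirna_site_call()`, `tfbs_call()`,
`cerna_disruption()`, `build_snp_map()` — and compose with the pipe.
`inst/scripts/netdissect-run.R` is a thin command-line wrapper over
`run_all()`.

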