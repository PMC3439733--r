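# genesetnet

Gene-set similarity, enrichment search and association networks for
user-supplied gene-set collections.

Curated biology comes packaged as *gene sets* — disease gene lists, pathway
memberships, expression signatures, microRNA target lists, network modules.
Once sets from many sources are pooled into one collection, the questions a
systems biologist asks are: which sets resemble each other, which sets are
over-represented in my gene list, which sets move most in my experiment, and
how do the sets relate as a network? `genesetnet` answers these four
questions on any collection supplied in GMT or tabular form, with a seeded
synthetic-data generator so every analysis can be exercised and validated
without access to proprietary database snapshots.

## The statistics at the core

**Gene-set similarity.** For two distinct sets \(P_i, P_j\) with weight
\(\alpha \in [0,1]\) (default 0.8):

    S_ij = α · |P_i ∩ P_j| / |P_i ∪ P_j|  +  (1 − α) · |P_i ∩ P_j| / min(|P_i|, |P_j|)

The first term is the Jaccard coefficient; the second is the cover
coefficient, which equals 1 whenever one set contains the other, so a large
pathway that swallows a small signature still scores high. Since
`min(|P_i|,|P_j|) ≤ |P_i ∪ P_j|`, the score is non-increasing in α.

**Over-representation.** A query gene list is tested against every set with
the one-sided Fisher's exact test (upper-tail hypergeometric), filtered at
`hits ≥ 2` and `p < 0.05`, Benjamini–Hochberg adjusted, and ranked by
decreasing hits.

**Differential gene-set expression.** Per-gene absolute fold changes
`ABS_FC` are aggregated over a set's measured members with the normalised
p-norm (default `p = 6`):

    NORM_ABS_FC = ( (1/n) Σ_i x_i^p )^(1/p)

a power mean between the arithmetic mean (`p = 1`) and the maximum
(`p → ∞`); large `p` accentuates the most strongly differential genes.

**Gene-set association network (GSAN).** Nodes are gene sets (size = scale,
color = NORM_ABS_FC, line color = source); edges are similarity associations
(width = score) between overlapping pairs, kept when `score ≥ 0.1` and the
overlap passes an edge-level Fisher test with p and FDR `< 0.05`. Networks
export to SIF/GraphML for Cytoscape, plus plain node/edge tables.

**Scale distributions.** The frequency of each gene-set scale (member
count), with an ordinary least-squares fit on log10–log10 axes summarising
the power-law-like decay.

## Worked example

```r
library(genesetnet)

# a 50-set collection with block-community overlap structure
spec <- synth_spec(seed = 42, n_sets = 50, universe_size = 200,
                   max_scale = 40, overlap_model = "block", n_blocks = 5)
coll <- generate_collection(spec)
coll
#> <gene_set_collection> synth_seed42: 50 sets, universe of 179 genes
#>   scales: min 5, median 10.5, max 37

# enrichment search with a query of 10 genes from SET0023 + 10 background
q <- generate_query(spec, coll, "SET0023", 10, 10)
res <- search_by_genes(q, coll)
head(res[, c("set_id", "hits", "set_scale", "p_value", "fdr", "rank")], 3)
#>    set_id hits set_scale    p_value        fdr rank
#> 1 SET0023   10        37 0.00180534 0.01263738    1
#> 2 SET0044    8        33 0.01430445 0.03388300    2
#> 3 SET0013    7        27 0.01599450 0.03388300    3
```

The planted source set ranks first with all 10 in-set genes recovered as
hits; its block-mates (which share a gene core) follow with weaker overlap.

```r
# plant a 3x differential signal in the smallest set and prioritize
spec2 <- synth_spec(seed = 42, n_sets = 50, universe_size = 200,
                    max_scale = 40, overlap_model = "block", n_blocks = 5,
                    target_sets = "SET0008", effect_size = 3)
expr <- generate_expression(spec2, coll)
head(prioritize_sets(coll, expr, norm_params(p = 6)), 3)
#>    set_id ... scale n_measured norm_abs_fc rank
#> 1 SET0008 ...     5          5    3.824993    1
#> 2 SET0041 ...     7          7    3.156418    2
#> 3 SET0043 ...     5          5    2.909961    3

# association network, annotated and exported for Cytoscape
net <- annotate_expression(build_gsan(coll, similarity_params(0.8)),
                           coll, expr)
net
#> <gsan> 50 nodes, 168 edges (0 isolated)
#>   alpha 0.8, min similarity 0.1, universe 179,
#>   edge Fisher p < 0.05 & FDR < 0.05
export_gsan(net, "crc_net", format = c("tables", "sif", "graphml"))
```

The boosted set tops the NORM_ABS_FC ranking (3.82 against a background
around 1.2–1.5), and the network keeps the 168 candidate associations that
survive the similarity and significance filters.

A command-line wrapper over the same functions ships in
`inst/cli/genesetnet.R`:

```sh
Rscript inst/cli/genesetnet.R synth --seed 17 --out-dir fixtures/
Rscript inst/cli/genesetnet.R search --query genes.txt \
    --gmt fixtures/collection.gmt --out results.csv
```

Every run writes a JSON manifest recording the configuration (including the
background universe actually used), input checksums and filter-stage counts.

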