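---
title: "Methods: gene-set similarity, enrichment and association networks"
author: "genesetnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-set similarity, enrichment and association networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genesetnet)
```

`genesetnet` analyses collections of gene sets — named groups of official
gene symbols at any level of biological organisation (disease gene lists,
pathways, expression signatures, microRNA targets, network modules). This
vignette documents the statistical models, the parameter defaults and why
they are what they are, the synthetic-data generator used for validation,
and the numerical and design choices a maintainer should know about.

## Gene sets and symbol normalization

All symbols are trimmed, uppercased and de-duplicated on entry; empty
tokens are dropped. Collections derive their *universe* as the exact union
of member genes, and the *scale* of a set is its unique-member count.
Alias-to-official-symbol maps can be applied with `apply_symbol_map()`;
unmapped symbols pass through verbatim rather than being dropped, because
real source databases come with incomplete mappings and silent shrinkage of
sets would bias every downstream statistic. Sets that end up empty after
normalization are removed with a warning — a scale-0 set can participate in
no similarity, enrichment or expression computation.

GMT is the primary carrier (id, description, members, tab-separated); a
tabular membership dialect (`set_id, name, source, organism, gene`) carries
per-set source and organism annotation that GMT cannot. Name search is
case-insensitive *substring* matching — the least surprising semantics for
disease-term lookup — with results ordered by decreasing scale, ties broken
by set id.

## The similarity score

For distinct sets $P_i, P_j$ and weight $\alpha \in [0, 1]$:

$$S_{i,j} \;=\; \alpha\,\frac{|P_i \cap P_j|}{|P_i \cup P_j|}
  \;+\; (1-\alpha)\,\frac{|P_i \cap P_j|}{\min(|P_i|, |P_j|)}$$

The Jaccard term measures overall agreement; the cover term rescues the
biologically meaningful case of containment, where a large pathway includes
a small signature and Jaccard alone would be near zero. Useful facts, all
enforced by tests:

* $0 \le S_L \le S_R \le 1$, hence $S$ is **non-increasing in** $\alpha$
  for every pair;
* $S = 1$ iff the sets are equal, $S = 0$ iff disjoint;
* under strict containment $P_a \subset P_b$:
  $S = \alpha |P_a|/|P_b| + (1-\alpha)$.

**Default $\alpha = 0.8$.** Small $\alpha$ lets the cover term inflate
scores (every containment pair scores near 1, flooding the right of the
score distribution); large $\alpha$ deflates them until low scores are
indistinguishable. Weighting the Jaccard term at 0.8 keeps the distribution
over realistic collections well-shaped between those extremes, and
`alpha_sensitivity()` lets a user reproduce that comparison on their own
collection: it reports, per candidate $\alpha$, the histogram of all
pairwise scores (20 bins over $[0,1]$ by default) and the sample skewness.
The distribution shape is reported descriptively, not tested against a
reference distribution — the judgement is visual by nature.

All-pairs computation (`pairwise_similarity()`) counts overlaps through a
sparse set-by-gene incidence matrix (`Matrix::tcrossprod`), so memory is
proportional to the number of *overlapping* pairs rather than $n^2$; pairs
with zero overlap are omitted entirely rather than emitted with score 0,
since only overlapping pairs are candidate associations.

## Enrichment search

A query list of $q$ genes is tested against a set of scale $s$ in a
universe of $N$ genes by the one-sided Fisher's exact test: the p-value is
the upper hypergeometric tail $P(X \ge \text{hits})$, computed with
`stats::phyper`. Results are filtered at `hits ≥ 2` and `p < 0.05`
(defaults), adjusted by Benjamini–Hochberg over the *retained* family, and
ranked by hits descending, then p ascending, then set id. The hit floor is
applied before the FDR family is formed; single-gene overlaps are too
fragile to interpret and would only dilute the adjustment.

**The universe matters.** The default background (`universe = "auto"`) is
the size of the union of all loaded collection universes — the widest
population the data itself defines. This is the single most
result-changing parameter with no canonical value: a larger universe makes
every overlap look more surprising. It is therefore configurable
everywhere, and the CLI manifest records the value actually used in every
run. Query genes absent from the universe still count in the query size but
are reported, since they can only make the test conservative.

`disease_profile_search()` composes the two stages of disease-centric
querying: name-match sets in designated disease sources, pool their members
into a profile, then run the profile as a query against all *other*
sources — the disease sources are excluded so the answer is not dominated
by the sets that defined the profile.

**Calibration and discreteness.** The hypergeometric test is discrete: its
achievable p-values form a finite set, so $P(p < 0.05)$ under the null is
at most 0.05 and can be far below it when margins are small. For sets of
scale 5–10 in a universe of 1,000 the exact pooled rejection probability is
about 0.02 — conservative, which is still valid type-I control. The
calibration test in the suite therefore evaluates the rejection rate where
the null distribution has adequate support: 100 sets of scale 100–300 in a
universe of 1,000, null queries of 200 genes, 1,000 replicates. In that
regime the exact rejection probability (computable directly from
`dhyper`/`phyper`) is 0.040, and the simulated rate is required to fall
within the 99% binomial band around the nominal 0.05. Small-margin
conservatism is a property of the exact test itself, not of this
implementation.

## Differential gene-set expression

Per-gene fold changes are ingested as given (no log transform by default;
`abs_log2 = TRUE` interprets them as ratios and uses $|\log_2 FC|$), with
duplicate genes — typically multiple probes — resolved by keeping the row
with maximal $|FC|$. The differential gene-set expression of a set with
measured member values $x_1..x_n$ is the normalised p-norm

$$\mathrm{NORM\_ABS\_FC} = \Big(\tfrac1n \sum_i x_i^p\Big)^{1/p},$$

a power mean: $p = 1$ is the arithmetic mean, $p \to \infty$ the maximum.
The default $p = 6$ accentuates the most strongly differential genes
without reducing the set to its single best gene. "Measured members" means
the intersection of the set with the expression table; a set with *no*
measured member gets an undefined score (`NA`) and sorts last — never 0,
which would silently outrank nothing.

Numerical note: $x^6$ overflows double precision for large inputs, so the
implementation factors out $\max(x)$ before powering
($\max(x)\cdot(\tfrac1n\sum (x_i/\max x)^p)^{1/p}$), which is exact and
stable.

Two properties deserve emphasis because they shape experimental design:

* The bound $\mathrm{NORM} \ge (1/n)^{1/p} \max(x)$ means the "approaches
  the max at large $p$" intuition is quantitative only for short vectors:
  at $p = 200$, agreement with $\max(x)$ within 1% is guaranteed only for
  $n \le e^2 \approx 7$. Tests of the large-$p$ limit use that regime.
* **Signal dilution.** If a *large* set's genes are boosted, every small
  set sharing one of its high-$|FC|$ genes concentrates that gene more
  strongly (the $(1/n)^{1/p}$ penalty is milder for small $n$), and can
  out-rank the truly differential set. Recovery simulations therefore plant
  the signal in a minimal-scale set; for users this is a real caveat of
  max-weighted aggregation: top-ranked small sets may be riding one or two
  genes of a larger differential program (the reported `n_measured` column
  helps spot this).

## Association networks

`build_gsan()` forms candidate edges from all overlapping pairs, scores
them with the similarity above, and (by default) requires
`score ≥ 0.1`, edge-Fisher `p < 0.05` and BH `FDR < 0.05`, with the FDR
family being *all* candidates. The edge-level Fisher test needs a 2×2
orientation: the smaller set is treated as the drawn sample against the
larger (configurable via `orientation`); overlap counts are identical
either way, only the margins differ. Isolated nodes are kept — an
unconnected set is still part of the displayed selection — and flagged via
a degree column. Node and edge tables, SIF (interaction type `gsan`, bare
lines for isolates) and GraphML are written deterministically: nodes and
edges are held in canonical id order so repeated runs are byte-identical,
and the table export round-trips to an equal graph.

## Scale distributions

`scale_distribution()` counts sets per distinct scale (no binning — one
point per scale), and `loglog_fit()` runs ordinary least squares on
$(\log_{10}\text{scale}, \log_{10}\text{frequency})$, requiring at least 3
distinct scales. A frequency law $\propto s^{-\gamma}$ yields slope
$-\gamma$. When all frequencies are equal the response has zero variance
and $R^2$ is undefined; the fit is flagged degenerate and $R^2$ reported as
`NA` rather than a misleading 0 or 1. No maximum-likelihood power-law
machinery is attempted — the straight-line summary is the analysis, not a
formal goodness-of-fit claim.

## The synthetic-data generator

`synth_spec()` fixes every generator parameter so identical specs give
identical outputs; all randomness flows from the single integer seed.

* **Scales** are drawn from a truncated discrete power law
  $P(s) \propto s^{-2}$ on $[5, 200]$ by default, over a universe of 1,000
  synthetic symbols (`G000001`…) and 200 sets — the heavy-tailed regime
  (many small sets, few large ones) that integrated curated collections
  display.
* **Overlap models**: `independent` (uniform membership; expected pairwise
  overlap $s^2/N$), `nested` (a chain of strict supersets, so every
  consecutive pair has cover coefficient 1 — the fixture for
  alpha-sensitivity direction), and `block` (sets within a block share a
  common prefix of a block core, `core_fraction = 0.5` of each set's
  scale — community structure for network tests).
* **Expression**: background $|FC|$ is log-normal with median 1.2 and
  $\sigma = 0.31$, placing roughly 5% of genes above $|FC| = 2$ — a typical
  microarray fold-change regime, chosen as a documented stand-in, not a
  claim about any particular dataset. Signs are random; p-values uniform.
  Genes of target sets get $|FC|$ multiplied by the effect size and
  p-values below 0.05. At effect size 1 the target and background $|FC|$
  laws coincide.
* **Queries**: `k_inside` genes from a target set plus `k_outside` from the
  rest of the universe; `k_inside = 0` gives pure null queries.

What the generator does *not* emulate: correlated expression within
pathways, probe-level noise, symbol aliasing errors, organism mixtures, or
the curation biases of real source databases. Passing the planted-signal
recovery tests therefore demonstrates the *machinery* (counting, testing,
ranking, thresholding) is correct — not that real collections will separate
as cleanly.

## Simulation designs used by the validation suite

Chosen once, stated here as the package's own experimental choices:

* Similarity is checked against a brute-force element-enumeration oracle on
  1,000 random pairs over a 30-symbol alphabet, with bounds and
  $\alpha$-monotonicity asserted per pair.
* Fisher p-values are checked against exhaustive enumeration of all draws
  for every margin with universe ≤ 12, and calibrated as described above.
* Enrichment recovery plants 30 in-target + 70 background genes (universe
  1,000, 200 sets) and requires the target at rank 1 in ≥ 95/100
  replicates; prioritization recovery uses a 3× effect on a minimal-scale
  set with the same 95/100 bar.
* Network construction is compared edge-for-edge with a brute-force
  all-pairs oracle (independent `fisher.test` route, hand-rolled BH) on
  fixtures of up to 50 sets across all three overlap models.
* The scale fit is checked exactly on an analytic power law and within
  ±0.1 of the exponent on a seeded noisy power law over ~200 scales.

## Known limitations

* The Fisher background is a modelling choice the data cannot make for the
  user; results should always be reported with the universe used.
* Similarity thresholds near 0.1 interact with the scale distribution: for
  two scale-5 sets a single shared gene already scores 0.29 at
  $\alpha = 0.8$, while large-set pairs need substantial overlap — the
  similarity filter is effectively more permissive for small sets (the
  edge-level Fisher filter compensates).
* NORM_ABS_FC rankings favour small sets containing a few extreme genes
  (see signal dilution above); `n_measured` should accompany any reported
  ranking.
* Organism handling is annotation-only: cross-organism pairs are scored
  unless filtering is requested.
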