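# mrmrnet

Case/control transcriptomic profiling of joint mRNA + long noncoding RNA
(lncRNA) panels — for example peripheral-blood microarray profiles of an
autoimmune disease cohort against matched healthy controls — typically asks
four questions: which transcripts discriminate the groups without being
redundant with each other, how do the groups separate globally, which
functional categories are over-represented among the discriminative mRNAs,
and which lncRNA–mRNA pairs are co-expressed tightly enough to suggest
regulation? `mrmrnet` implements that pipeline end to end, with a
synthetic-data module that plants known signal so every stage can be tested
without access to raw array data.

## What it computes

**mRMR feature ranking.** Expression is discretized per feature into three
states (below μ − t·σ, between, above μ + t·σ; default t = 0.5). Dependence
is measured by plug-in mutual information in bits,

    I(x; y) = Σ p(x,y) log2[ p(x,y) / (p(x) p(y)) ],

with relevance D(f) = I(f; c) against the class vector c and redundancy
R(f) = (1/m) Σ_{s ∈ S} I(f; s) against the already-selected set S. Greedy
selection maximizes D − R per round (MID; the quotient variant
D/(R + ε), MIQ, is available), yielding the mRMR table (feature, selection
round h, D, R, score) alongside the relevance-only MaxRel table.

**Two-group summaries.** Per-feature log2 fold changes (case − control)
with linear folds 2^|log2FC|; average-linkage hierarchical clustering on
correlation distance 1 − r for heatmap leaf ordering; and 2^−ΔΔCt relative
qPCR quantification against a reference gene for validation panels.

**Enrichment.** Hypergeometric upper-tail (or DAVID-style EASE)
over-representation of a gene list in GMT-style category collections, with
counts, percent of the mapped list, −log10 p and Benjamini–Hochberg FDR,
ranked by −lg P.

**Co-expression network.** Sample Pearson correlation for every
(lncRNA, mRNA) pair; pairs with |r| ≥ 0.8 (inclusive at the boundary;
signed mode available) form a bipartite network with degree summaries,
pathway subnetwork extraction, and SIF / GraphML / edge-TSV export for
Cytoscape.

## Worked example

```r
library(mrmrnet)

sim <- generate_expression(synthetic_config(
  n_case = 15, n_control = 15, n_informative = 20, n_redundant = 10,
  n_noise = 1970, n_coexpressed = 10, effect_size = 2, noise_sd = 1,
  seed = 42))
sel <- mrmr_select(discretize(sim$matrix), sim$labels, k = 10)
sel
#> mrmr_selection (MID): 10 of 2000 features
#>    h feature_id biotype         D         R     score
#> 1   1  MRNA_0004    mRNA 0.7701134 0.0000000 0.7701134
#> 2   2  MRNA_0015    mRNA 0.6253634 0.4412329 0.1841305
#> 3   3   LNC_0003  lncRNA 0.7026772 0.4976425 0.2050347
#> ...

mean(sim$ground_truth$informative_ids %in%
       mrmr_select(discretize(sim$matrix), sim$labels, k = 40)$selected$feature_id)
#> [1] 0.85

net <- build_network(sim$matrix, threshold = 0.8)
net
#> coexpression_network: 16 edges over 1001 lncRNA / 999 mRNA candidates
#>   (absolute |r| >= 0.8)
#> connected: 16 lncRNA, 16 mRNA
```

The first mRMR round picks the single most class-relevant feature (here a
planted informative mRNA, D ≈ 0.77 bits); later rounds trade relevance
against redundancy, so duplicated or correlated features are pushed down.
On this realization 85% of the 20 informative features land in the top 40
of 2,000 (the average over seeds is ≈ 0.94; see the acceptance script).
The network's 16 edges are the 10 planted co-expressed lncRNA–mRNA pairs
plus cross-biotype correlations induced by the shared class signal of
informative features and their redundant copies.

qPCR validation arithmetic:

```r
tab <- generate_ct_table(planted_fold_changes = c(8.1, 1 / 4.58),
                         noise_sd = 0, seed = 1)
ddct_fold_change(tab)
#>      gene delta_delta_ct fold_change fold_magnitude direction
#> 1 GENE_01      -3.017922   8.1000000           8.10        up
#> 2 GENE_02       2.195348   0.2183406           4.58      down
```

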