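---
title: "Methods: mRMR ranking and lncRNA-mRNA co-expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mRMR ranking and lncRNA-mRNA co-expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmrnet)
```

`mrmrnet` re-implements, as a reusable and fully tested pipeline, the
analysis chain commonly applied to two-group (case vs control) joint
mRNA/lncRNA expression profiles: minimum-redundancy maximum-relevance
feature ranking, two-group summaries with hierarchical clustering, qPCR
validation arithmetic, gene-set over-representation, and a thresholded
Pearson co-expression network. This vignette documents the models, the
tunable parameters, and the design decisions taken where the published
analysis convention leaves choices open.

## The mRMR model

Expression vectors are continuous, so mutual information is estimated
after discretization. Each feature is reduced to three states relative to
its own distribution: with per-feature mean $\mu$ and standard deviation
$\sigma$, values below $\mu - t\sigma$ map to $-1$, above $\mu + t\sigma$
to $+1$, and to $0$ otherwise. The multiplier $t$ (unitless, default
$0.5$) is the convention of the mRMR literature for microarray
intensities; a constant feature ($\sigma = 0$) maps entirely to state 0
and therefore carries zero information. `t` is exposed in `discretize()`
because no single value is canonical.

Dependence between discrete vectors is the plug-in mutual information

$$I(x;y) = \sum_{x,y} p(x,y)\,\log_2\frac{p(x,y)}{p(x)\,p(y)},$$

with probabilities estimated by empirical frequencies and $0\log 0 = 0$.
We report bits (base 2); since only rankings enter the selection, the base
is immaterial. Tiny negative rounding residues are clamped to zero so the
estimator is non-negative, symmetric, and satisfies $I(x;x) = H(x)$
exactly — properties the test suite checks against an exact-arithmetic
oracle over all small joint distributions.

Relevance of a candidate feature $f$ is $D(f) = I(f; c)$ with $c$ the
class vector; redundancy is the mean MI against the selected set $S$,
$R(f) = |S|^{-1}\sum_{s \in S} I(f; s)$, with $R = 0$ for the empty set.
Selection is greedy: round $h$ picks the maximizer of the combined
criterion among the not-yet-selected features, recording $h$, $D$, $R$
and the score. Two standard combinations exist, the difference
(MID, $D - R$) and the quotient (MIQ, $D / (R + \varepsilon)$ with
$\varepsilon = 10^{-12}$ as a division guard). Which variant the original
analyses of this kind used is generally not stated; MID is the default
here and MIQ an option, and the choice is recorded in the output object.
The companion MaxRel table ranks all candidates by $D$ alone.

Two numerical conventions matter for reproducibility. Ties are broken by
input order: the earliest candidate whose score is within a relative
$10^{-9}$ of the round maximum is taken, so mathematically tied
candidates (for instance exact duplicates) resolve deterministically and
independently of floating-point summation order. And mRNAs and lncRNAs
are ranked in one joint candidate pool by default; analyses that report
separate tables per biotype can simply subset the input matrix, which is
equivalent because relevance and redundancy are computed pairwise.

The number of selected features `k` is an explicit argument. Published
mRMR tables often fix counts per biotype (e.g. a few hundred mRNAs and
~100 lncRNAs); such counts are presentation choices, not properties of
the algorithm, so the package does not hard-code any.

## Two-group summaries and qPCR arithmetic

`fold_change()` reports per-feature case-minus-control differences of
log2 means, the linear fold $2^{|\mathrm{log2FC}|}$, and a direction call
at a declared cutoff (default $|\mathrm{log2FC}| \ge 1$, i.e. two-fold —
a reporting convention, not a test). `hierarchical_cluster()` uses
correlation distance $1 - r$ with average linkage, the standard heatmap
ordering for microarray data; the published figures this emulates do not
state their linkage, so the conventional choice is made once and
documented. A constant vector has undefined correlation and is placed at
distance 1 from everything, with a warning rather than an error, because
dropping rows silently would desynchronize leaf orders.

`ddct_fold_change()` implements relative quantification: per-sample
$\Delta C_t = C_t^{target} - C_t^{ref}$, group difference
$\Delta\Delta C_t = \overline{\Delta C_t}_{case} -
\overline{\Delta C_t}_{control}$, fold $= 2^{-\Delta\Delta C_t}$. Group
means of per-sample $\Delta C_t$ are used (not per-sample pairing)
because case/control designs are unpaired. `fold_magnitude` additionally
reports the "$x$-fold higher / $x$-fold lower" convention (reciprocal
for folds below 1) used when quoting validation results.

## Enrichment

`hypergeom_p()` is the upper tail $P(X \ge k)$ of the hypergeometric law;
`mode = "EASE"` substitutes $k - 1$ (floored at 0), the conservative
variant used by DAVID. `enrich()` tests every category containing at
least one mapped list gene, computes percent with the mapped-list-size
denominator (list genes outside the annotation universe are dropped with
a message — the DAVID convention, which is why published percent columns
often imply a denominator smaller than the submitted list), adjusts by
Benjamini–Hochberg across all tested categories *before* any filtering,
and then sorts by $-\log_{10} p$ and applies the `neg_lg_p` cutoff and
`top_k` truncation. The conventional stringent cutoff is
$-\lg P > 2.5$ ($p < 0.0032$). The universe is user-supplied; no live
GO/KEGG service is queried and no GO-graph propagation is performed.

## Co-expression network

Only across-biotype (lncRNA, mRNA) pairs are tested, so the graph is
bipartite by construction. The sample Pearson coefficient is computed for
every pair and an edge kept when it meets the threshold (default 0.8),
inclusively: an $r$ exactly at the threshold is an edge. Because the
canonical boundary example ($x = (1,2,3,4)$, $y = (1,3,2,4)$,
$r = 4/5$) must pass a literal `0.8`, the comparison subtracts a
$10^{-12}$ guard — strictly a protection against double rounding, not a
loosened threshold. The published convention ("coefficients equal to or
greater than 0.8") does not mention negative correlations; the default
mode therefore thresholds $|r|$, with a `signed` option, and the mode is
stored in the network object. No correlation p-value filter is applied —
the convention states only a coefficient threshold. Degree summaries
follow the "one lncRNA correlates with $a$ to $b$ mRNAs" reporting
format; `pathway_subnetwork()` restricts to a pathway's mRNAs, their
incident edges, and the lncRNA endpoints. Exports (SIF, GraphML with
`biotype`/`r` attributes, edge TSV) are Cytoscape-readable.

## The synthetic-data generator

No raw data accompany the analyses this pipeline descends from, so the
generator defines the study conditions for all tests. It emulates a
15-case / 15-control design on a mixed mRNA/lncRNA panel at a desk scale
of 2,000 features (the real arrays carry ~57k probes; scale enters only
runtime, not the tested properties). All values are Gaussian on the log2
scale — the standard microarray intensity model — with per-feature
baselines $N(8, 1.5)$ and within-group noise $N(0, \sigma)$, default
$\sigma = 1$ log2 unit. The defaults are conventions chosen once, not
reconstructions: no variance or effect-size estimates were published for
the arrays this emulates.

* **Informative features** shift the case mean by `effect_size` (default
  2 log2 units) with alternating sign, so both over- and under-expressed
  features exist.
* **Redundant features** are an informative source plus
  $N(0, 0.2\sigma)$ perturbation, giving source–copy correlation > 0.95 —
  strong, controllable redundancy for exercising the $R$ penalty.
* **Co-expressed pairs** mix a shared latent factor $z \sim N(0,1)$ with
  weight $\sqrt{\rho}$ (and independent noise with $\sqrt{1-\rho}$), so
  the population correlation equals the target $\rho$ (default 0.9). The
  published configuration type does not include a count of planted
  pairs, so the generator adds `n_coexpressed`; pairs are carved out of
  the noise block — they carry no class signal, keeping the block-count
  arithmetic (`n_informative + n_redundant + n_noise` features) and the
  null distribution of noise features intact — and each pair is forced
  to straddle the biotype partition so it is a candidate network edge.
* **Annotations**: planted-enriched categories draw 80% of their members
  (default `enriched_overlap`) from the informative set; the rest are
  uniform draws from the universe.
* **Ct tables**: control-group $\Delta C_t$ values are drawn uniformly
  in 2–8 cycles, the case group is shifted by $-\log_2(\mathrm{fold})$,
  and well noise is Gaussian in cycles; with zero noise the planted fold
  is recovered exactly, which pins down the arithmetic.

What the generator does **not** emulate: probe-level array artifacts,
batch or dye effects, heavy-tailed intensity distributions, and
correlated noise beyond the planted pairs. Passing tests therefore
demonstrate correctness of the computations and recoverability of planted
signal under idealized Gaussian conditions — not performance on real
arrays.

## Verification strategy and problem sizes

Every non-trivial computation is checked against an independent oracle:
plug-in MI against an exact-arithmetic evaluation (prime-exponent
accumulation of the count products) over *all* joint 3×3 tables with up
to 8 samples; greedy selection against a brute-force per-round rescan
built on the entropy-form MI estimator; the hypergeometric tail against
exhaustive enumeration of all draws for universes up to 12; the network
against a double-loop over all pairs. Recovery properties run at the
design scale (15 + 15 samples; 2,000 features for mRMR recovery, 20
seeds; 60 features with 10 planted pairs for the network, 50 seeds; 100
seeds for noisy ΔΔCt) — sizes chosen to make the Monte-Carlo estimates
stable at a few percent while keeping the whole suite fast.

## Known limitations

* The plug-in MI estimator is positively biased at small $n$; this
  affects absolute $D$/$R$ values, not the rankings the pipeline reports.
* Greedy mRMR is a heuristic; it matches the per-round optimum by
  construction but not a global subset optimum.
* With `mode = "absolute"`, strongly anti-correlated pairs enter the
  network; in signed mode they are excluded. Neither mode tests
  significance of $r$.
* Quantile normalization assumes samples share a common intensity
  distribution; it is exposed as an explicit step (`quantile_normalize`)
  rather than applied implicitly, since the upstream normalization of
  published array data is often unstated.
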