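---
title: "Methods behind sacscreen: screen scoring, panel association and severity statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind sacscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sacscreen)
```

# Scope

`sacscreen` implements the statistics of a resistance study built around the
spindle assembly checkpoint (SAC): a pooled CRISPR knockout screen read out
by sequencing, scored for genes whose loss confers resistance to an MPS1
(SAC kinase) inhibitor, followed by cell-line-panel analytics that relate a
candidate gene's expression to drug sensitivity and to aneuploidy, and by a
severity scoring scheme for chromosome-missegregation phenotypes observed in
time-lapse imaging. Every stage can be exercised end to end on synthetic
data with planted effects, so each statistical claim in the pipeline has a
ground truth it can be checked against.

# Guide quantification from raw reads

Screen reads have a fixed construct layout: the first six bases are a
sample barcode, a variable-length stuffer follows, then the key sequence
`CGAAACACC`, occasionally a single G artifact, and the 20-nt guide.
`quantify_screen()` applies three rules:

1. **Demultiplexing** is exact: a read belongs to the sample whose barcode
   equals its first six bases; anything else is unassigned.
2. **Key search** scans for the key's first base at 1-based positions 16-44
   inclusive (protocol prose is conventionally 1-based; the window is a
   configurable argument). The first occurrence wins when the key appears
   twice.
3. **Candidate extraction and matching**: candidate A is the 20-mer after
   the key; when the base after the key is G, candidate B is the 20-mer
   after that G. Candidates are matched exactly (case-folded, no mismatch
   tolerance, `N` never matches) against the library. If exactly one
   candidate matches, the read counts for that guide. If both candidates
   match *different* guides — possible only when one library guide equals G
   plus the 19-nt prefix of another — the read is tallied `ambiguous` and
   candidate A is counted, a deterministic priority documented in the
   per-sample report. Nothing in the exact-match design resolves this case
   on biological grounds; the rule simply keeps counting reproducible.

The per-sample report partitions every read into
`no_key + unmatched + ambiguous + assigned`, so column sums of the count
matrix equal `assigned + ambiguous` and conservation can be asserted
mechanically.

# Screen scoring

## Normalization

Size factors use the median-of-ratios estimator: each sample's factor is
the median, over guides with positive counts in every sample, of the
guide's count divided by its across-sample geometric mean. We take the
arithmetic median of the ratios themselves; the common alternative
`exp(median(log ratio))` coincides with it whenever the reference set has
odd size, and the tests cross-check against DESeq2 under that condition.
Note the factors are defined only relative to the geometric-mean
pseudo-reference: multiplying one sample by `c` multiplies its factor by
`c` only in ratio to the other samples' factors (each absolute factor picks
up `c^(1/S)` from the reference).

Guides with zero counts in all samples are removed before any statistic;
normalization errors out (suggesting a pseudocount) when no guide is
positive everywhere.

## Paired differential statistic

The screen design pairs each treated sample with a control sample in the
same replicate. Per guide, the replicate log-ratio is
`d_i = log2(treated_i + 0.5) - log2(control_i + 0.5)` on normalized counts;
`log2fc = mean(d)`. Two statistics are exposed:

* **Plain paired t** (`method = "t"`): `stat = mean(d) / (sd(d)/sqrt(m))`,
  two-sided p on `m - 1` df. With the study's own `m = 2` replicates this
  is a 1-df t — Cauchy-tailed under the null — which is exactly calibrated
  (its null p-values are uniform) but rank-unstable: null guides routinely
  produce enormous statistics and flood the top of the ranking.
* **Moderated paired t** (`method = "moderated"`, the pipeline default):
  limma's empirical-Bayes machinery fitted to the per-replicate log ratios
  (an intercept-only model), which shrinks each guide's variance toward a
  pooled prior and adds prior degrees of freedom. At two replicates this is
  the field's standard remedy for exactly this instability. Its null
  p-values are only approximately uniform (the prior df is itself
  estimated), which we accept because the downstream rank aggregation
  consumes *ranks*, and gene-level inference rests on the permutation
  p-value below. The log2 fold change is identical under both methods.

Degenerate guides (`sd(d) = 0`) get `stat = 0, p = 1` when the fold change
is also zero, and otherwise have their sd clamped to the smallest positive
sd observed, avoiding infinities on constructed fixtures.

## Alpha-robust rank aggregation

Guides are ranked by the statistic (most enriched or most depleted on top;
ties broken by guide id) and converted to normalized ranks `r = pos/n`. For
a gene with sorted ranks `r(1) <= ... <= r(k)`, only ranks below the
selection threshold `alpha` contribute, and

```
rho = min over selected j of  P( Beta(j, k - j + 1) <= r(j) )
```

— the probability that the j-th order statistic of k uniform variables
falls at or below the observed rank. `rho = 1` when no rank clears
`alpha`. By default `alpha` is the proportion of guides whose statistic is
positive (enriched) or negative (depleted), the usual maximum-percentile
convention; the commonly used `p <= 0.25` cutoff for reporting screen hits
is a filter applied to the output table, not part of the score.

The permutation p-value redraws `k` ranks (with replacement — the pool is
three orders of magnitude larger than `k`) from the pooled rank list,
sharing one null sample per distinct `k` across genes, and uses the
`(1 + b)/(n_perm + 1)` estimator; `n_perm` defaults to 100 and is raised in
tests. Benjamini-Hochberg FDR is computed across genes via
`stats::p.adjust`.

Two calibration facts are worth stating precisely. First, for `alpha < 1`
the null distribution of `rho` has a point mass at 1 of size
`(1 - alpha)^k` (the genes none of whose guides clear `alpha`); their
p-values are exactly 1, which is conservative, and it means the p-value
distribution under the null is uniform only below `1 - (1 - alpha)^k`.
Calibration of the permutation machinery is therefore assessed at
`alpha = 1`, where `rho` is continuous. Second, with a shared null the
p-values of different genes are correlated through the null sample's own
estimation error, which decays as `n_perm` grows; the test suite uses
`n_perm = 10^4` for the calibration check.

## Cross-screen intersection, enrichment scores, coverage arithmetic

`top_fraction_intersection()` reproduces the two-screen comparison: each
screen's top quarter of genes by permutation p, intersected, with both
screens' `-log10 p` reported for the shared genes.

`gsea_enrichment()` is the preranked weighted Kolmogorov-Smirnov running
sum: walking down the ranking, set members add `|score|^weight` (normalized
over the set), non-members subtract `1/(n - m)`; the enrichment score is
the maximal signed deviation, and significance comes from redrawing the set
labels. `ssgsea()` is its single-sample analogue for expression profiles:
genes are ranked within one sample and the score is the accumulated
difference between the rank-weighted in-set ECDF (weights `rank^0.25` by
default) and the out-of-set ECDF. Because only ranks enter, the score is
invariant under any strictly monotone transform of the profile — the
property the tests assert.

`required_cells(coverage, library_size, surviving_fraction)` is the
planning arithmetic `ceiling(coverage * library_size / surviving_fraction)`
— e.g. 500x coverage of a 188,509-guide library at a 25% post-transduction
surviving fraction needs 377,018,000 cells, and maintenance at full
survival needs 94,254,500.

# Panel association analytics

The panel bundle holds genes x lines expression, drugs x lines response,
a per-line aneuploidy score and per-drug class labels, inner-joined on
shared lines. Response follows the panel convention **lower = more
sensitive** (log-fold-change viability), stated here once and assumed
everywhere.

* **Quartile split**: bottom group = values at or below the 25th
  percentile, top = at or above the 75th (type-7 linear-interpolation
  quantiles, boundary ties included on both sides). A constant or heavily
  tied vector whose quartiles coincide cannot be split and errors out.
* **Quartile t-test**: Welch by default (`var_equal = TRUE` for the pooled
  variant); `delta` is top-mean minus bottom-mean. Zero-variance groups
  with equal means give `t = 0, p = 1`.
* **Partialization**: OLS residuals of response on a covariate (with
  intercept), exactly orthogonal to the covariate; re-testing the
  aneuploidy quartile split on the residuals asks whether the covariate
  accounts for the association.
* **Gene-drug ranking percentile**: for each drug, the quartile t-test is
  run for every gene (a moment-based vectorized engine — group masks are
  precomputed per gene, so each drug costs two matrix-vector products; the
  tests verify it against the scalar implementation), genes are ranked by
  ascending p (ties broken by gene id), and the target gene's percentile is
  `100 * (1 - (rank - 1)/n)`, so 100 = the drug's most significantly
  associated gene. The reverse convention (`direction = "rank"`) is
  available; the output records which was used. Missing values are handled
  by pairwise deletion per (gene, drug) with a minimum group size of 10 at
  panel scale (2 for toy fixtures).
* **Class comparison**: two-sample t of the percentiles, class versus all
  other drugs.

# Mitotic severity statistics

The 0-5 severity scheme is a fixed table over thirteen canonical
categories:

| score | categories |
|---|---|
| 0 | correct segregation |
| 1 | DNA bridge; micronucleus; lagging chromosome |
| 2 | bridge or lagging with micronucleus; metaphase misalignment |
| 3 | misalignment with micronucleus; misalignment with lagging or bridge |
| 4 | metaphase skipping; cytokinesis failure; misalignment with lagging or bridge and micronuclei |
| 5 | skipping with DNA bridge; skipping with micronucleus |

An alias map absorbs the long annotation-sheet phrasings ("DNA Bridge
Formation", "Chromosomal Lagging", ...). Scores 3 and 4 overlap at the
margin — misalignment with lagging/bridge scores 3, and only the additional
emergence of micronuclei raises it to 4; the table encodes that reading and
the test suite snapshots it. Events outside the vocabulary are category
`"other"`, carry a manual 1-5 score, are excluded from the statistics, and
are retained (flagged) in exports for plotting.

Distributions are compared with the tie-corrected Kruskal-Wallis H
(mid-ranks) via `stats::kruskal.test`; the test is inherently upper-tailed,
which is how a "one-sided" reading of it is implemented — `p` is the upper
tail of chi-square on `groups - 1` df. Metaphase durations use a Welch t
for two groups and one-way ANOVA beyond. The western-blot fold change
normalizes the target band to a mitotic marker that is itself normalized to
the loading control, per lane, before taking the treated/control ratio —
the double normalization that separates per-lane loading from mitotic
fraction.

# Synthetic data and what it does (not) show

All generators are bit-reproducible given a seed and return a ground-truth
ledger.

* **Counts**: control counts are negative binomial with mean
  `depth_per_guide` (default 500, the screen's coverage) and variance
  `mu + phi mu^2`, `phi = 0.1` — a typical sgRNA-level overdispersion for a
  well-executed screen. Treated means of planted genes are scaled by
  `2^effect` before sampling. A per-replicate log-normal factor
  (`sdlog = 0.2`) is shared between the two samples of a replicate — the
  coupling the paired statistic exploits — and an independent per-sample
  factor (`sdlog = 0.15`) emulates library-size variation for the
  normalization step to remove. `dispersion = 0` disables count noise
  entirely (counts = rounded means) for exactness tests.
* **Reads**: single-end, length 75, constant quality `I`; the key start is
  drawn uniformly from the window, the post-key G appears with probability
  0.2, and stuffers are redrawn in the (about 3 in 10^5) event they would
  create an earlier in-window key occurrence, so the round trip
  simulate-then-count is the identity by construction.
* **Panel**: 200 lines x 2,000 genes x 100 drugs by default, expression
  standard normal. The target gene's standardized expression `z` drives
  both the aneuploidy score (`coupling * z` plus noise, coupling 0.8) and
  the response of the 5 planted-class drugs (`-effect * z` plus unit noise,
  effect 1.0). This is deliberately a *full mediation* structure — the
  aneuploidy-response association exists only through `z` — because it is
  the simplest linear-Gaussian model in which partializing the mediator
  provably abolishes the marginal association, which is the behavior the
  mediation analysis is meant to detect. Setting the coupling to 0
  decouples aneuploidy entirely (the negative control).
* **Events**: severity scores drawn per condition from stated
  distributions, mapped to canonical categories uniformly within a score;
  durations normal truncated at zero by resampling.

What passing on these generators shows: the statistics recover planted
effects of realistic size at realistic depth, are calibrated under their
own null, and the deterministic stages are exact. What it does not show:
robustness to sequencing error, PCR jackpotting, guide-efficiency
heterogeneity, copy-number confounding, non-Gaussian panel noise or
non-linear mediation — all deliberately outside the generators, and listed
as non-goals of the counting and association designs.

# Problem sizes and determinism

The test suite runs the full recovery study at the study scale it emulates:
500 genes x 4 guides, 2 paired replicates, depth 500, one planted gene at
log2 effect 2, RRA with 1,000 permutations, across 50 seeds; calibration
uses 1,000 null guides/genes and 1,000 null panels; oracle equivalence uses
100 random instances per statistic. Every stochastic step takes an explicit
seed, ties break lexicographically by identifier, and reruns are
bit-identical. The numbered scripts under `analysis/` run the same pipeline
as a narrative, writing their tables under `results/`.

# Known limitations

* Exact matching only: reads whose guide carries a sequencing error are
  unmatched; quantification accuracy on error-prone data is not modeled.
* The moderated statistic's p-values are approximate at two replicates;
  treat guide-level p as a ranking device and rely on gene-level
  permutation p/FDR.
* The RRA permutation p is bounded below by `1/(n_perm + 1)`; with the
  default 100 permutations, BH-adjusted values saturate quickly, and strong
  hits should be re-scored with more permutations.
* Single-covariate partialization only; multivariable adjustment is out of
  scope.
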