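---
title: "Tissue specificity of cis-eQTLs affecting dosage-sensitive genes: methods"
author: "eqtlBreadth authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eQTL tissue breadth and dosage sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqtlBreadth)
```

# The scientific question

Dosage-sensitive genes carry an expression constraint in at least one of the
tissues where they are expressed. A copy-number change alters the gene's
output in every tissue at once, so dosage-sensitive genes are depleted from
benign CNVs, conserved in copy number across mammals, retained in duplicate
only after whole-genome duplication (ohnologs), and often haploinsufficient.
A cis-eQTL, by contrast, can modulate expression in a single tissue and may
therefore slip past the constraint. The analysis implemented here contrasts,
across five proxies for dosage sensitivity, (i) the probability of being
affected by at least one eQTL, (ii) the per-tissue probability of being
affected, (iii) the cross-tissue overlap of affected gene sets, (iv) the
proportion of expressed tissues affected, (v) depletion for broad-breadth
eQTLs, and (vi) eQTL effect sizes.

The key structural observation is a pooled/per-tissue paradox: a gene class
can be *more* likely to be eQTL-affected when tissues are pooled while being
*less* likely to be affected in every individual tissue, provided its eQTLs
are narrow and hit distinct tissue subsets in different genes. All of the
package's directional tests are built around that geometry.

# eQTL calling

Two call sets are supported, sharing the identity convention that an eQTL
is a (variant, gene) pair and that its *tissue breadth* is the number of
tissues in which it remains significant.

**Bonferroni mode.** Each nominal per-tissue p-value is multiplied by the
tissue-panel size (default 48) and capped at 1; a tissue is significant iff
the adjusted value is strictly below `alpha` (default 0.05). Pairs with no
significant tissue are never emitted. The correction factor is the panel
size — not the number of variant–gene pairs — because the per-tissue input
tables of this kind have already undergone per-tissue significance control
upstream; the residual multiplicity is across tissues. `alpha` is exposed
because only the correction, not the level, is dictated by the procedure;
0.05 is the conventional default.

**Posterior mode.** A tissue is significant iff its m-value (the posterior
probability, from a cross-tissue meta-analysis, that the effect is present
in that tissue) strictly exceeds 0.9. The meta-analysis itself is out of
scope: m-values are consumed as input.

Both thresholds are strict inequalities; a nominal p with adjusted value
exactly `alpha`, or an m-value of exactly 0.9, does not call. The same
strictness convention is applied to the pLI cutoff (below), so boundary
values never silently switch groups.

# Gene classification

Five axes are assigned per gene, each dropping its own unknowns only:

* **Duplication status**: a gene in the ohnolog list is `ohnolog` even if it
  also has other paralogs (small-scale duplicates are defined as genes with
  paralogs *not* classed as ohnologs, so the ohnolog label takes
  precedence); otherwise `ssd` if it has a protein-coding paralog,
  `singleton` if it has none, `unknown` if absent from the paralogy map.
  The ohnolog-vs-nonohnolog contrast pools `ssd` and `singleton`.
* **CNV-region membership**: inside iff the gene interval shares at least
  one base with a region, on either strand (strand is carried but ignored
  for overlap). Coordinates are 0-based half-open on disk (BED convention)
  and converted at the boundary.
* **Exome-CNV status**: `affected` if the gene has a confident call,
  `free` if it was assayed without one, `unknown` if outside the assayed
  universe — absence from a call list is not evidence of being CNV-free.
* **Haploinsufficiency**: pLI > 0.9 is haploinsufficient, pLI < 0.9
  haplosufficient; a score of exactly 0.9, or no score, is `unknown` and
  excluded. Excluding the boundary is the only reading compatible with
  strict inequalities on both sides.
* **Copy-number conservation**: membership in a list of genes with no
  copy-number change across a mammalian phylogeny.

Gene ids are normalized by stripping a trailing `.digits` version suffix,
since association tables and annotation releases disagree on versions; the
operation is idempotent and duplicate ids after stripping are an error, not
a silent merge.

# Breadth, overlap and broad-breadth depletion

**Expression breadth.** A gene is "expressed in a tissue" when its median
TPM across that tissue's samples strictly exceeds 0.1 TPM. The threshold is
a conventional detectability floor for bulk RNA-seq and is configurable;
expression breadth has no canonical definition, so the choice is surfaced
in the configuration and in outputs.

**Affected proportion.** Per gene, the number of eQTL-affected tissues
(union over all the gene's eQTLs — a proportion of tissues only makes sense
on the union, not on summed per-eQTL breadths) divided by the number of
expressed tissues, capped at 1. The cap is needed because an eQTL can be
detected in a tissue whose median expression sits below the expression
threshold; capping keeps the quantity a proportion. Genes expressed in zero
tissues are excluded.

**Jaccard overlap.** For each tissue pair, J = |S₁∩S₂| / |S₁∪S₂| over the
eQTL-affected genes of a stratum; the Jaccard of two empty sets is defined
as 0 to avoid an undefined division, and the diagonal is 1 wherever the
tissue's set is non-empty. A 48-tissue panel yields 1,128 unordered pairs
per stratum; the two strata's upper-triangle distributions are compared by
Mann–Whitney U.

**Broad-breadth threshold.** The cutoff t* is the smallest integer t such
that the fraction of eQTLs with breadth ≥ t is ≤ 10%. This integer-stable
rule reproduces "the top decile of eQTLs affect t* or more tissues"
exactly, is monotone in the tail fraction, and degenerates sensibly (all
breadths 1 gives t* = 2: nothing is broad). A gene is in the *focal set*
when its affected-tissue union reaches the cutoff (it could get there via
many single-tissue eQTLs), and is *broad-affected* when at least one of its
eQTLs individually reaches it.

For the depletion test on synthetic data the package contrasts
broad-affected status across classes over all eQTL-affected genes rather
than within the focal set. At desk scale (2,000 genes with one to a few
eQTLs each) essentially no narrow-breadth-class gene accumulates a
14-tissue union, so the focal-set universe is degenerate by construction;
at biobank scale, where genes carry hundreds of eQTLs, the focal set is the
sharper universe. Both flags are computed and reported.

# Statistical machinery

* **χ² tests** use the Pearson statistic with Yates continuity correction
  on 2×2 tables by default (R's own default; configurable off), and a
  Bonferroni adjustment whose count defaults to 10 for the pooled
  enrichment table — five gene-group splits times two call sets — and is
  always explicit in the output.
* **Mann–Whitney U** uses the exact null distribution when both groups have
  at most 8 values and no ties, and the tie-corrected normal approximation
  otherwise, so small-sample tests are reproducible against exhaustive
  enumeration.
* **CV** is sd/mean of log₂(TPM + 1) per gene per tissue, with the sample
  (n − 1) standard deviation. Base and pseudocount are configurable; genes
  with non-positive mean transformed expression are dropped with a count.
  Per-tissue class comparisons use Wilcoxon rank-sum tests with
  Benjamini–Hochberg correction across the axis's tests.
* **Expression bins** are rank-based with sizes differing by at most one
  (remainder to the lowest bins) and ties broken by gene id, making the
  assignment deterministic across runs.
* **The logistic model** is affected ~ expression + duplication status
  (+ interaction), binomial GLM, ohnolog reference. The expression
  covariate is mean-centered by default: with an interaction term present,
  uncentered status main effects would be extrapolations to zero TPM, far
  outside the data, with inflated variance; centering evaluates the status
  odds ratios at the mean expression level, where they are the quantity of
  interest. Non-convergence is an error; coefficient magnitudes above 15
  raise a separation flag.
* **Top eQTL per gene and tissue** is the calling association with minimal
  nominal p, with exact ties broken by the lexicographically smallest
  variant id — an arbitrary but deterministic rule.

# The synthetic-data generator

`simulationConfig()` fixes the study conditions; `simulateDataset()` is
deterministic given the seed, to the bytes of the emitted text files.

The generator works at the summary-statistic level: it emits nominal
p-values and slopes directly rather than genotypes and expression-residual
regressions, because the analysis consumes summary associations — a
genotype-level simulation would add an eQTL-mapping stage the pipeline
never performs. Planted structure, per duplication class:

| Quantity | ohnolog | ssd | singleton | role |
|---|---|---|---|---|
| P(≥ 1 eQTL) | 0.90 | 0.72 | 0.75 | pooled enrichment |
| extra eQTLs (Poisson rate) | 0.8 | 0.3 | 0.3 | enrichment via count |
| breadth (truncated-geometric p) | 0.5 | 0.125 | 0.125 | mean ≈ 2 vs ≈ 8 tissues |
| median TPM (log-normal) | shared meanlog 2.1, sdlog 1.0 | | | baseline expression |
| &#124;slope&#124; (log-normal median) | 0.30 | 0.45 | 0.45 | effect sizes |
| CV multiplier | 0.8 | 1.2 | 1.0 | expression stability |

The truncated geometric on [1, nTissues] gives the long-tailed breadth
profile a top-decile cutoff implies with a single parameter per class. The
incidence and breadth parameters jointly produce the pooled/per-tissue
paradox: ohnologs are affected more often overall (0.90 vs ≈ 0.74) but
cover ≈ 3 of 48 tissues per affected gene against ≈ 10 for nonohnologs, so
every individual tissue sees fewer affected ohnologs. Other axes (CNVR
membership, exome-CNV status, pLI, copy-number conservation) are sampled
with probabilities conditioned on ohnolog status, reflecting the
substantial overlap between dosage-sensitivity proxies, and the CNV-region
axis is realized geometrically: gene intervals are laid out non-overlapping
and each planted inside-gene is wrapped by a region, so recomputing
membership from the emitted BED reproduces the planted labels exactly.

Planted eQTLs draw nominal p uniformly below alpha/nTissues in their
planted tissues and uniformly above it elsewhere, so Bonferroni calling
recovers them with sensitivity 1 and exact breadths; null variant–gene
pairs draw uniform p everywhere, making the false-call count binomial with
per-row rate alpha/nTissues — the basis of the calibration check. The
posterior channel plants m-values above 0.9 in exactly the planted tissues
and below 0.9 elsewhere; it is deliberately noiseless, and it reuses the
Bonferroni channel's breadth distribution rather than a broader one, since
no desk-scale dataset can reproduce the power gain that pushes a full-size
meta-analysis's broad-breadth cutoff to 43 of 48 tissues.

What the generator does **not** emulate: linkage disequilibrium between
variants, tissue–tissue expression correlation, sample-size differences
between tissues, winner's-curse inflation of slopes, or confounding between
expression level and eQTL discovery power. Passing directional tests on
this generator therefore demonstrates that the pipeline's machinery
computes the intended quantities and detects planted structure of realistic
magnitude — not that real data must show these patterns.

Default problem sizes (2,000 genes, 48 tissues, 30 samples per tissue,
200 null pairs) keep a full pipeline run within seconds while leaving every
directional contrast many standard errors from zero; the test suite uses
smaller instances (150–500 genes, 5–12 tissues) for module-level checks.

# Known limitations

* The pipeline treats the input association table as the universe to
  correct; it cannot reconstruct whatever per-tissue filtering produced it.
* Genes on unplaced scaffolds or sex chromosomes are not treated specially;
  callers can pre-filter the annotation set.
* The Jaccard comparison reports the upper-triangle distributions as
  independent observations, as is conventional; tissue pairs sharing a
  tissue are in fact correlated, so the Mann–Whitney p-value is
  anti-conservative and should be read as a ranking device.
* Effect-size and logistic analyses require the nominal association table
  (slopes); the posterior call set alone cannot support them.
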