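---
title: "Pooled-reference proteome integration, protein-space PCA and elimination enrichment"
author: "ProteoPool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled-reference proteome integration, protein-space PCA and elimination enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProteoPool)
```

## The analysis problem

Isobaric labelling (iTRAQ 8-plex) quantifies up to eight samples in one
LC-MS/MS run through reporter-ion channels, but a comparative study of many
cell types — here human fetal hepatocytes, adult hepatocytes, HepG2 cells and
their cultured derivatives — needs more samples than one run carries.
ProteoPool implements the pooled-reference strategy: every run dedicates one
channel to a common reference pool mixed from all study samples, every
reporter quantity is divided by the same protein's pool quantity in the same
run, and the resulting pool-relative ratios are comparable across runs.
Downstream, the package characterises the integrated matrix by hierarchical
clustering of samples, principal component analysis with proteins as
observations, Gene Ontology enrichment with an elimination algorithm, and
marker signatures derived from component score rankings.

## Integration model

Within a run, the reporter quantity of protein $p$ in channel $c$ is treated
as proportional to abundance, so the pool-relative ratio

$$r_{ps} = \frac{q_{p,c(s)}}{q_{p,\mathrm{pool}}}$$

cancels run-level effects (labelling efficiency, instrument response) that
act multiplicatively on both channels. Merging runs is then a pure union:
ratios are never re-scaled at merge, because the pool normalisation is the
only cross-run calibration the design justifies.

Identification evidence is filtered before quantification is used: a protein
enters the analysis if it passes the run-level 1% FDR cutoff and is
identified either by at least two peptides at >= 90% confidence or by a
single peptide at >= 99% confidence. The FDR flag is consumed as input
metadata; decoy-search FDR estimation happens upstream of the quantification
tables and is not recomputed here.

Detection in shotgun proteomics is run-level: a protein not identified in a
run has no value in any of that run's channels. The only missing-data
mechanism in the package is therefore the *common-protein filter*: all
analyses of sample relationships use exactly the proteins quantified in every
sample, and nothing is ever imputed. After filtering, each sample column is
rescaled to arithmetic mean 1. Equal per-sample means are expected of
pool-relative data under equivalent total labelling; the pipeline enforces
the property and reports the pre-normalisation means as a QC diagnostic, so a
sample whose raw mean sits far from the others is visible in the manifest.
Rescaling preserves within-sample ratios exactly.

## Clustering and PCA conventions

Sample relationships are summarised by the Euclidean distance between sample
columns, computed by default on log2 ratios so that a doubling and a halving
are equidistant from no change; raw-ratio mode is retained for sensitivity
analysis. No per-protein standardisation is applied. The linkage is
configurable (`complete`, the common default of heatmap tools, `average`,
`single`); agglomeration is delegated to `stats::hclust`, whose tie handling
is deterministic. Group cohesion is quantified as cut purity: the dendrogram
is cut into $k$ clusters and the fraction of samples belonging to their
cluster's majority group is reported.

PCA follows the convention in which **proteins are observations and samples
are variables**: `proteinScores()` places each protein on a component and
`sampleLoadings()` gives the orthonormal sample weights that define it.
Columns are mean-centred after the chosen transform (log2 by default, again
configurable) and never variance-scaled — scaling would equalise samples and
distort the variance-fraction decomposition that the analysis reports. The
solver is a full deterministic SVD (`prcomp`), giving
$\min(n_\mathrm{proteins}-1, n_\mathrm{samples})$ components that are
bit-stable across runs. Because component signs are arbitrary,
`orientComponents()` fixes them against anchor groups (adult hepatocytes
positive on PC1, fresh fetal positive on PC2, ECM-sandwich positive on PC3
by default) so that direction words in downstream marker criteria are
meaningful.

## Enrichment

Two complementary questions are asked of the ontology annotation.

**Detection test.** Is a term over-represented among the detected proteins
relative to an annotated background universe? This is the one-sided
hypergeometric upper tail; the universe is whatever the annotation input
covers and is deliberately never hard-coded, so the same code runs on
synthetic universes and on a full human annotation. The foreground defaults
to the common-protein set.

**PC score tests.** Do a term's proteins sit at unusual positions along a
principal component? Three rank tests are available: `absWilcox`, a
one-sided Wilcoxon rank-sum on absolute scores (the alternative being that
annotated proteins are more *extreme*, in either direction), `wilcox`, the
two-sided rank-sum on raw scores, and `ks`, the two-sample
Kolmogorov-Smirnov. Rank-sum p-values use the exact permutation null when
both group sizes are at most 8 and there are no ties, and the
tie-corrected normal approximation otherwise.

Because annotation is propagated up the is_a graph (true-path rule), a
specific signal automatically contaminates every ancestor. The elimination
algorithm decorrelates the graph: terms are visited most-specific-first
(reverse topological order, ties broken by term id), and when a term tests
below `elimThreshold` its current proteins are removed from all its
ancestors' sets before those are tested. Defaults: `elimThreshold` and
`reportThreshold` both 0.001 — the reporting rule is "all terms with
unadjusted P < 0.001 after elimination" and using the same value for the
elimination step is the parsimonious coupling, though the two are
independent configuration — and `minTermSize` 3, below which a rank test is
meaningless. Raw p-values are the inferential quantity; Benjamini–Hochberg
q-values are emitted as an extra convenience column. Overlapping significant
terms (e.g. many ribosome-related terms sharing one protein set) are grouped
by single-linkage on the Jaccard similarity of their post-elimination sets,
and a long-format score table (with an "All Proteins" baseline row and set
medians) is exported for violin plotting.

## Marker signatures

A cell type's signature is the intersection of top-$k$ lists from signed
component rankings — most-negative PC1 with most-positive PC2 for fresh
fetal hepatocytes, most-negative PC1 and PC2 for HepG2, most-positive PC1
with most-negative PC3 for fresh adult hepatocytes — with $k = 75$ by
default. Ties at the $k$-th rank are broken by accession order and flagged,
since membership is then convention rather than data. `extremeProtein()`
locates single indicator proteins, e.g. the lowest-PC1 protein with a
positive PC2 score.

## The synthetic generator

`generateExperiment()` emulates the statistical structure of the study so
the whole pipeline is testable without external data. The generative model
on the log2 scale is

$$\log_2 q_{psr} = b_p + E_{p,g(s)} + u_r + \varepsilon,\qquad
\varepsilon \sim N(0, \sigma_\mathrm{noise}),$$

with per-protein baselines $b_p \sim N(6, 2^2)$ (log2 reporter units),
per-run offsets $u_r \sim N(0, 0.3^2)$ and channel noise
$\sigma_\mathrm{noise} = 0.25$ by default — a log-normal noise model, the
standard choice for ratio-scale quantification. The pool channel carries the
equal-weight mean of the group mean abundances plus its own channel noise;
the mixing proportions of the real pool are unknown, so equal weights are
the neutral choice. Group effects $E$ are sums of centred group contrasts
with per-protein coefficients: an adult-vs-rest axis (weight 1.0, the
dominant biological separation), a HepG2 axis (0.6), an
ECM-dedifferentiation axis (0.5) and two smaller culture-retention axes
(0.3 each), so that all six groups — fresh fetal, fresh adult, HepG2, fetal
ALI-3D, adult ALI-3D, adult ECM-sandwich — are distinguishable, in that
order of strength. Centred contrasts leave the pool mean invariant, so a
planted effect changes ratios, not the reference.

The default layout places 24 samples (8 fresh fetal, 4 fresh adult, 3 each
of the remaining groups) across 4 runs of 8-plex labelling with one pool
channel per run; fresh adult samples are spread one per run to decouple that
group from run effects, other groups are packed run by run, and the
donor-to-run assignment is exposed as configuration. Detection is run-level
and abundance-dependent: a non-core protein is missing from an entire run
with probability $1 - \mathrm{logit}^{-1}(b_p - 6)$, while a core fraction
(default 25%) is always detected. Detection draws share one uniform variate
per protein and run, so detection is monotone in the logistic parameters
under a fixed seed. At the 1500-protein default this yields roughly 400–500
proteins quantified in every sample, the scale of the real study's
common set.

Planted score-enriched terms add an extra contrast effect (default scenario:
3.0 log2 on a term with at least 8 commonly quantified members) to the
term's annotated proteins, representing a strongly coherent functional
module whose score distribution is clearly displaced from the bulk — the
kind of module the enrichment stage exists to find. `generateOntology()`
supplies a small rooted is_a DAG with direct annotations propagated under
the true-path rule.

What the generator does *not* emulate: peptide-level aggregation and
isotope-impurity effects (quantities are drawn at the protein level),
correlated annotation between functionally related proteins beyond the
planted terms, realistic GO term-size distributions, and shared-donor
correlation between fresh and cultured samples from the same preparation.
Passing tests therefore demonstrate the correctness and statistical
behaviour of the pipeline under the stated model, not the biological
fidelity of any particular real-data result.

## Numerical choices and problem sizes

All stochastic steps derive from one root seed and every solver is
deterministic, so a pipeline run is byte-reproducible. Ratios are kept on
the positive scale with missingness explicit (`NA`); a zero or missing pool
quantity makes a protein un-normalisable in that run and the record is
dropped and counted. Degenerate inputs fail loudly: all-constant matrices
for PCA, cyclic graphs for the ontology, empty constraint sets for extreme
proteins.

The test suite exercises oracle equivalences (naive $O(n^3)$ agglomeration,
covariance eigendecomposition, exhaustive hypergeometric and
rank-permutation enumeration) at small sizes where enumeration is exact, and
statistical behaviour at study scale: 400 simulated proteins for
parameter-recovery checks, 1200 for marker-signature precision (so that
$k = 75$ is a minority of the common set, as 75-of-432 was in the motivating
design), 20 replicate seeds for median-based assertions, and 1000 null score
vectors for type-I control of the elimination test. These sizes are the
package's choices for a thorough-but-quick default suite; all of them are
configuration, not constants.

## Known limitations

- The elimination algorithm's visiting order within a topological level is
  fixed by term id; a different ontology serialisation with different ids
  can reorder eliminations among exact ties.
- `hclust` tie-breaking among exactly equal merge heights follows its own
  deterministic convention rather than a documented lowest-index rule;
  with continuous data ties essentially never occur.
- The detection test conditions on the annotation universe supplied; an
  incomplete annotation biases it exactly as it would any hypergeometric
  over-representation analysis.
- No isoform collapsing is attempted: accessions are compared as exact
  strings.
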