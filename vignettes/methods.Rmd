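---
title: "Methods: nitrogen time-course transcriptomics on fragmented assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nitrogen time-course transcriptomics on fragmented assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragtx)
```

## The experimental design being modelled

The pipeline analyses a bulk mRNA-seq time course of an oleaginous green
alga cultivated through three stages of nitrogen availability: a
pre-starvation reference sample N_0 taken under exponential growth, an
early-starvation stage e−N (samples after 2, 4 and 8 h of −N, when starch
accumulates and membrane acyl chains begin to be recycled into
triacylglycerol), a late-starvation stage l−N (24, 48, 56 and 96 h, TAG and
total-lipid hyperaccumulation) and a resupply stage r+N (2, 4, 8 and 14 h
after nitrogen re-addition, when storage compounds are degraded). Input is a
dense loci × 12 matrix of normalized abundances (FPKM); one pooled library
per time point, so there is no replicate structure and no differential
expression statistics — the design works with fold changes and explicitly
does not attach significance to them.

## Fold-change classification

For time point t, `log2_fold_change()` returns log2(FPKM_t / FPKM_N0) only
when both values are at least the reliability floor (`fpkm_floor`, default
1.0 FPKM); otherwise the cell is NA. The NA state is carried as an explicit
mask, never as a sentinel value, so each downstream consumer states its own
NA policy. A gene is responsive at t when |log2-FC| > 1 (strict inequality;
exactly 1.0 is "none"), with direction by sign. For display, values beyond
|log2-FC| = 4 are clamped and flagged "highly regulated"; capping never
changes the responsiveness class (tested as a property).

Stage-level responsiveness averages first: A_stage is the arithmetic mean of
the stage's FPKM values, R_stage = A_stage / FPKM_N0, and |log2 R_stage| > 1
defines the six stage sets (up/down × three stages). Two points here were
genuinely open and are package decisions:

* The reliability floor is applied analogously to the pair (FPKM_N0,
  A_stage), for consistency with the single-time-point rule; it can be
  disabled with `apply_floor = FALSE`.
* The housekeeping stability criterion ("at most one −N exceedance of
  |log2-FC| > 1") is evaluated over the seven −N samples N_2…N_96. The
  reference N_0 is excluded: its fold change against itself is identically
  zero, so its inclusion could never change the verdict.

## Fragment-pair detection and collapse

Draft assemblies split genes across scaffold ends, producing two partial
gene models of one true gene. Detection requires all three of:

1. Pearson correlation r > 0.9 between the two expression profiles. The
   correlation substrate is log2(FPKM + 1) over all 12 time points rather
   than log2-FC, so that below-floor cells do not punch holes in the
   profiles; a pairwise-complete FC-based alternative would discard exactly
   the low-abundance points where fragments (with their halved read
   support) live. A constant profile has no defined correlation; such
   candidates are skipped.
2. Both gene models within 500 nt of a scaffold margin, boundary inclusive:
   margin distance min(start − 1, scaffold_length − end) ≤ 500, with
   1-based inclusive GFF3 coordinates.
3. A shared domain id with complementary truncations — one hit C-terminally
   truncated (the 5′ half of the protein) and the other N-terminally
   truncated. This formalizes what is otherwise a visual inspection of
   domain architectures.

Candidates are matched one-to-one greedily by descending correlation, ties
broken on the lexicographic id pair, so no locus joins two pairs and the
result is independent of input row order. Per pair the retained member is
the 5′ fragment: the one with the start codon; if that does not decide, the
one whose shared-domain hit is N-terminally intact; if still tied, the
lexicographically smaller id. `collapse_fragments()` then removes the 3′
rows, leaving retained rows bit-identical.

## Sample and gene-family clustering

Samples are compared by Jensen–Shannon distance: each column is normalized
to a probability distribution over loci and the distance is the square root
of the JSD with base-2 logarithms, so the maximum (disjoint support) is
exactly 1 and the quantity is a metric — symmetry, identity and the
triangle inequality are property-tested. The dendrogram uses complete
linkage; the upstream tooling this emulates delegates linkage to a plotting
package's defaults, so complete linkage is a package convention chosen to
match the gene-family clustering, not an inherited fact.

Gene families (the motivating case is putative lipases, selected by defline
keywords — "lipase", or "hydrolase" and "beta" — or by GO terms GO:0016298,
or GO:0016787 together with GO:0016042) are clustered on their log2-FC
profiles with Euclidean distance and complete linkage. NA cells from the
floor are imputed as 0 for the distance computation (the mask is kept for
display); the alternative pairwise-complete distance, rescaled to the full
profile dimension, is available via `na_policy = "pairwise"`. Zero is the
"no change" point of the log2-FC scale, which makes the imputation neutral
rather than extreme, but it does shrink genuinely regulated below-floor
genes toward flatness — a known limitation.

The number of clusters is chosen by the average silhouette width over
k = 3–7: s(i) = (b − a)/max(a, b), singletons contribute 0, and the
degenerate all-identical case resolves 0/0 to 0. Ties in the argmax go to
the smallest k. An explicit `k` override supports fixing the cut from
inspection of the dendrogram (the motivating analysis fixed four clusters,
supported by the silhouette values). Agglomeration itself is delegated to
`stats::hclust`, whose tie handling is deterministic; this replaces a
hand-specified lexicographic merge tie-break with an equally deterministic
convention.

## GO over-representation

Annotations are propagated by the true-path rule (a gene annotated to a
term is annotated to all ancestors, set semantics across DAG diamonds),
restricted to the biological_process namespace, and each term with at least
one in-set gene is tested with the upper-tail hypergeometric probability
P(X ≥ x) — the one-sided Fisher exact test. Following the source protocol,
no multiple-testing correction is applied and p < 10⁻⁴ flags significance.
The universe defaults to all loci with at least one propagated BP
annotation (configurable), since the exact universe of the original
analysis is not stated. The original analysis used a decorrelating variant
("weight01") of the Fisher test; this package deliberately implements the
classic test on propagated annotations, so p-values on real data will
differ from that variant — generally in the direction of more significant
ancestors of enriched terms.

## Pathway-candidate validation

Per enzymatic step, forward-homology candidates are kept only if (a) their
best (rank-1: e-value ascending, ties by bit score descending, then subject
id) reverse hit in each of two model organisms maps to the step's template
sequences — "both" is the default, "either" is available since the source
protocol is ambiguous — and (b) they carry a required domain, with
truncated hits counting. Survivors are run through fragment-pair detection
restricted to the candidate list and collapsed to the 5′ member. Every
input candidate ends with exactly one provenance label (retained /
failed-reciprocal / failed-domain / collapsed-into-pair), and the
reciprocal and domain filters commute.

## Abundance categories and pictograms

Category boundaries are the P50/P75/P90/P99 linear-interpolation (type 7)
quantiles of the N_0 FPKM distribution — the quantile type is unstated
upstream and fixed here as R's default. Published category ranges overlap
at their endpoints (e.g. "1 ≤ FPKM ≤ 11" and "11 ≤ FPKM ≤ 24"), so ties are
resolved to the higher category; a fully degenerate distribution therefore
lands everything in category V, with a warning. The pictogram SVG encodes,
per locus, the localization letter, the category numeral (bold when the
gene is likely not fragmented), and one bar per time point coloured on a
symmetric diverging scale over [−4, 4] with a white band at |log2-FC| ≤ 1
and "NA" tags for masked cells; a companion TSV carries identical values.

## The synthetic-data generator

`synth_config()` defines the study conditions used for validation: 500
loci, 20 fragment pairs (frac_fragment_pairs = 0.08), 25 up- and 25
down-regulated genes per stage with effect size 2 log2 units, 50
housekeeping genes (half with a transient +1.5 excursion at R_2, mimicking
the transient resupply response that stable genes are reported to show),
four planted profile clusters of 12–13 lipase-annotated loci, additive
Gaussian noise of sd 0.1 on log2(FPKM) — a multiplicative noise model
matching mRNA-seq variability, since the upstream work states none — and a
lognormal baseline (log2-scale mean 3, sd 3) whose span exceeds four orders
of magnitude, as reported for the real abundance distribution. Planted
loci draw baselines from a higher band (log2 between effect + 2 and 8) so
that down-regulation cannot push them under the reliability floor; planted
effects must exceed 1 log2 unit so truth is recoverable in the zero-noise
limit. Fragment-pair members share one latent profile and baseline, sit at
opposite scaffold margins, and carry complementary truncated hits to a
shared domain; margin decoys with non-complementary truncations and
candidates failing reciprocal validation are planted to exercise the
filters. One designated GO term per stage is planted in that stage's up-set
at frequency 0.8 against a 0.05 background.

What the generator does **not** emulate: read-level sampling noise and its
mean–variance relation, gene length/GC biases, correlated co-regulation
beyond the planted clusters, isoforms, real GO topology (the synthetic DAG
has ~47 BP terms), or genuine biological variability between replicates
(the emulated design pools replicates before sequencing). Passing tests
therefore demonstrate correctness of the computations and recoverability of
planted structure under the stated noise — not performance on real data,
where effect sizes, fragmentation patterns and annotation quality are far
less tidy.

Determinism: a single integer seed fully determines the dataset (the RNG
state is restored afterwards), and the pipeline manifest hashes every
artifact, so a rerun with the same configuration is byte-identical.

## Problem sizes used in validation

The test suite and the acceptance script run on the default 500-locus
study; oracle comparisons use 100 random silhouette datasets (n ≤ 50),
exhaustive hypergeometric enumeration up to universe 12, 200 random
distribution pairs for the Jensen–Shannon properties, 100 null enrichment
simulations, and 10,000 lognormal draws for category occupancy. These sizes
were chosen so the whole validation runs in well under a minute while
keeping every comparison statistically meaningful.

## Known limitations

* Fold-change classification carries no error model; a gene at FC 2.05 vs
  1.95 is a hard class boundary, and the original design explicitly warns
  that fold change is not statistical significance.
* Fragment detection is annotation-bound: pairs without domain hits, or
  with domains truncated on the same side by annotation error, are
  invisible; strand/orientation constraints are not imposed.
* The classic Fisher test on propagated annotations inflates ancestor
  terms relative to decorrelated variants.
* Jensen–Shannon sample clustering is sensitive to the overall magnitude
  distribution of a sample, which can split biologically coherent stages —
  visible in the emulated study as the resupply stage dividing by
  technical magnitude differences.
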