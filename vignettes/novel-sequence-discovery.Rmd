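---
title: "Discovering novel sequences in population-scale assemblies with novoseqkit"
author: "novoseqkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering novel sequences in population-scale assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(novoseqkit)
```

## The problem

When short-read genomes are assembled de novo, a fraction of the assembled
contigs cannot be placed on the reference genome. Pooled across a
population, these unmappable contigs contain *novel sequences* (NS):
DNA carried by individuals but absent from the reference, much of it
ancestral sequence that is present in the chimpanzee genome and was deleted
on the lineage leading to the reference. Characterizing NS requires a chain
of analyses — quality control, clustering into alleles, allele-frequency
estimation, classification against references and catalogs, repeat
composition, genomic positioning, and population statistics — each of which
is usually assembled ad hoc from command-line tools.

`novoseqkit` implements that chain as a tested R package. Because the
cohorts such studies are built on are access-restricted and enormous, the
package ships a fully specified synthetic-cohort generator with truth
tables, so every stage can be verified end-to-end on a desk machine: the
clustering against a brute-force oracle, the allele frequencies against
planted carrier counts, the statistics against closed forms and
calibration runs.

## Pipeline overview

1. **QC and clustering** (`greedyCluster`, `classifyContaminants`,
   `filterClustersBySize`, `clusterAlleleFrequencies`): contigs named
   `IndividualXYZ_I` are clustered greedily; clusters whose representative
   has a significant BLAST-like match to a non-primate but none to a
   primate are contaminants; clusters represented by sequences shorter than
   301 bp are dropped; the allele frequency of a cluster is the fraction of
   cohort individuals contributing at least one contig, and a cluster is
   *rare* below 5%.
2. **Classification** (`alignToReference`, `classifyClusters`,
   `catalogMembership`): representatives are aligned to the human-like and
   chimp-like references; a hit with identity > 95% and query coverage >
   90% is *confident*; a cluster is NS iff no hit against the human
   reference has identity > 80% **and** coverage > 50%.
3. **Repeat enrichment** (`repeatComposition`, `repeatPermutationTest`,
   `sampleBackground`): base-weighted repeat-class composition, compared by
   a nonparametric permutation test.
4. **Positioning** (`dbscan1d`, `mergeInsertions`, `featureEnrichment`):
   per-individual insertion breakpoints are merged by one-dimensional
   DBSCAN (eps 150 bp, 3 neighbours), events with fewer than 5 carriers or
   hybrid co-locations are dropped, and feature enrichment is tested by
   region simulation plus exact binomial tests.
5. **Unmapped-read mapping** (`countReads`, `depletionCurve`,
   `populationAnovaTukey`): flag-filtered read counting, per-population
   mapping fractions, allele-frequency depletion curves, Mann-Whitney and
   ANOVA/Tukey comparisons.
6. **Ancestral deletions** (`filterDeletions`, `mergeDeletions`,
   `craFrequency`): deletions called against the chimp-like reference are
   PASS/DEL-filtered, merged by 0.7 reciprocal overlap (single linkage),
   intersected with NS intervals, checked for novelty, and summarized as
   chimpanzee-reference-allele (CRA) carrier frequencies, where a carrier
   is any individual that is heterozygous or has no deletion call.

`runPipeline()` executes all stages on a `SimConfig`; every stochastic
stage draws from a named substream of the master seed, so a rerun is
byte-identical.

```{r tiny-run, eval = FALSE}
res <- runPipeline(simConfig(seed = 1), nPermutations = 10000)
res$report
```

## The clustering join rule and its shortcuts

Clustering follows the greedy longest-first scheme of CD-HIT-EST with its
default parameters: a contig joins the first existing cluster whose
representative aligns at identity >= 0.95 with >= 0.90 coverage of both
sequences, on either strand, else founds a new cluster. CD-HIT's internal
word-filter heuristics are not reproduced; the contract is the documented
join rule, with identity and coverage taken from a full local alignment
(match +1, mismatch -1, gap -2).

Two shortcuts accelerate the rule without being able to change its outcome,
and the test suite checks the final partition against a brute-force oracle
that uses neither:

* **Shared 11-mer prefilter.** If a pair satisfies the join rule, at least
  `0.9 L - 11 L/19 - 10 = 0.321 L - 10` query positions carry an 11-mer
  that occurs in the representative (with L the shorter length: coverage
  >= 0.9 bounds the aligned span, identity >= 0.95 bounds the number of
  error columns at `L/19`, and each error destroys at most 11 k-mer
  positions). Candidates below `floor(0.32 L) - 11` shared positions
  (floored at 1) can therefore be skipped. Random same-length sequences
  share a handful of positions at most, so nearly all hopeless comparisons
  are skipped.
* **Equal-length Hamming fast path.** If two equal-length sequences agree
  ungapped at >= 98% of positions, the full-span alignment scores at least
  `0.96 L`, hence any best-scoring local alignment spans >= 0.96 L with at
  most 0.02 L mismatches — identity >= 0.979 and coverage >= 0.96, so the
  rule is satisfied without running the DP. This is what makes clustering
  thousands of multi-kilobase near-identical copies (including 22-60 kb
  contaminants) affordable.

## The anchor aligner

Classification uses a minimal seed-and-extend aligner: exact 31-mer
anchors on both strands, grouped per target and strand into diagonal bands
(single linkage with a +-50 bp tolerance), each band extended ungapped
along its most anchor-supported diagonal across the full query extent
(clipped to the target). Identity is computed over the extended columns
and query coverage is the extended span over the query length. Seeds
occurring more than 100 times in a target are masked, as in any
seed-based mapper. The aligner is deliberately ungapped: on the short,
colinear queries handled here it agrees with a full local-alignment oracle
to within two identity points (tested), but it will fragment alignments
across large indels — hence the package never uses it to *measure*
divergence, only to test the confident/NS thresholds, and precomputed
`show-coords` tables can be substituted via `readCoordsTable()`.

## The permutation test

For two sequence sets A and B (|A| >= 2|B|; sets are swapped otherwise),
the observed statistic per repeat class is the absolute difference of the
base-weighted percentages, `Diff = |A% - B%|`. For each of 10,000
permutations a subset R of A with |R| = |B| is drawn without replacement
and `Diff_R = |A% - R%|` computed; the p-value per class is the fraction
of permutations with `Diff_R > Diff`, strictly greater, so ties do not
count and the resolution is 1/10,000. Two consequences are documented
rather than "fixed": the strictness makes the test slightly
anti-conservative at coarse resolutions (an optional `(k+1)/(n+1)`
estimator is available behind `addOne`), and R is compared against the
full set A exactly as the statistic is defined, even though R being a
subset of A induces dependence. Percentages are pooled over bases, not
averaged per contig, because the quantity of interest is the fraction of
sequence in each class.

## What the synthetic cohort emulates

The generator's defaults are the package's study conditions; they are not
tuned per test.

* **Cohort**: N = 100 individuals, 300 planted NS, a 2 Mb human-like
  reference over two chromosomes with a planted repeat landscape, and a
  chimp-like reference equal to it with the ancestral NS (30% of the
  catalog) inserted verbatim.
* **Allele-frequency spectrum**: 90% of NS rare with carrier frequency
  uniform on (1/N, 0.05), 10% uniform on (0.05, 0.5). Carrier counts are
  `round(AF x N)`, at least 1.
* **NS lengths**: a shifted exponential, 301 bp + Exp(mean 150 bp),
  truncated at 22,701 bp. The bounds are the observed size range of
  quality-controlled unmappable contigs; the mean matches the observed
  average NS contig size (about 0.6 Mb of NS over about 1,400 contigs per
  individual, i.e. roughly 450 bp). Sub-threshold contigs (73-300 bp) and
  viral-like contaminants (22.7-60 kb, removed by the taxonomy rule, not
  by size) are planted alongside.
* **Repeat composition**: per-NS class proportions drawn from a Dirichlet
  around the target mix (simple repeats 28%, satellites 15%, LINE 10%,
  SINE 3%, unmasked 44%) and realized as class-pure blocks; the
  annotation is recorded, not re-detected, since running a repeat masker
  is out of scope. Per-NS simple-repeat content is capped at 45% so that a
  non-ancestral NS can never reach the 50% NS-blocking coverage against
  the human-like reference through shared short tandem motifs alone.
* **Assembly error**: per-base substitution rate 0.005 and a 10%
  probability that a carried NS contig is emitted as two fragments of at
  least 301 bp. With both knobs at zero, carrier contigs equal their NS
  exactly and recovery must be exact — the tests assert this.
* **Distinctness**: candidate NS are redrawn until pairwise non-joinable
  under the clustering rule, so "one cluster per planted NS" is a
  well-defined truth.
* **Emissions**: insertion calls at the true site plus Normal(0, 30 bp)
  jitter with a Poisson background of spurious calls and deliberate hybrid
  co-locations; deletion calls over the padded (Uniform(0, 2 kb) per side)
  deleted region with diploid genotypes implied by the carrier frequency;
  unmapped-read records with a 7.4% mapped fraction and duplicated
  secondary/supplementary records that flag-filtered counting must ignore.

What the generator does **not** emulate: read-level sequencing error and
coverage fluctuation, realistic repeat-family phylogenies, assembly
collapse of near-identical repeats, reference gaps, and population
structure in the UR mapping fractions. Passing tests therefore demonstrate
the correctness of the analysis chain under its stated model, not the
biological completeness of that model on real cohorts.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; `show-coords` and VCF
  coordinates are converted at the boundary (a VCF record with POS = 101,
  END = 200 becomes [100, 200)). Overlap always means sharing at least one
  base; adjacent half-open intervals do not overlap.
* Classification thresholds are strict inequalities exactly as printed:
  a (95, 91) hit is not confident, an (80, 60) hit does not block NS
  status. A hit with identity 85% but coverage 30% is not a significant
  match and does not block NS status either (per-hit conjunction).
* In DBSCAN, `minNeighbors` counts *other* points within eps; border
  points join their leftmost core neighbour; ties in position are
  harmless. Merged-insertion spans are reported as `[min, max+1)` so every
  event has at least 1 bp.
* The reciprocal-overlap merge uses single linkage; the representative is
  the longest member (leftmost on ties) and an individual with several
  linked calls keeps its most deleted genotype. Merging the merged set
  again is a no-op (tested).
* Missing genotypes and individuals without a deletion call count as CRA
  carriers: absence of evidence for the deletion is treated as presence of
  at least one copy of the chimp allele, and the package flags this
  reading explicitly by also emitting an allele-frequency estimate
  `(2N - 2 hom - het) / 2N`.
* Mann-Whitney comparisons are exact for up to 20 tie-free observations
  and use the tie-corrected normal approximation otherwise; the ANOVA is
  ordinary one-way fixed effects with Tukey HSD on all pairs.
* `binomialEnrichment` is an exact two-sided binomial test against the
  pooled simulated fraction; the per-iteration structure of the null
  simulation is retained only for a Monte-Carlo standard error. No
  multiple-testing correction is applied across feature tracks by
  default, matching how such per-feature tables are usually reported;
  Bonferroni is a one-liner on the output column.

## Problem sizes used by the tests

The default study conditions (N = 100, 300 NS, 2 Mb reference) run in a
few minutes; the test suite uses them for the recovery checks and smaller
cohorts (about 12 individuals, 10 NS, 80 kb reference) for structural and
round-trip checks. Calibration runs use 200 null replicates at 1,000
permutations for the permutation test, 500 replicate tracks for the
binomial test and 500 replicates for the ANOVA; oracle-equivalence checks
use 200 contigs, 500 DBSCAN points, 200 deletions and 1,000 x 1,000
intervals. These sizes were chosen so each property is measured with
useful statistical resolution while the whole suite stays convenient to
run routinely.

## Known limitations

* The anchor aligner does not chain across large indels and reports
  ungapped identity; queries with substantial internal structure against a
  reference should be aligned externally and imported as `show-coords`
  tables.
* The greedy clustering is first-fit, as in CD-HIT; a contig similar to
  two representatives joins the earlier-founded cluster even if the later
  one fits slightly better.
* With fragmentation enabled, fragments found their own clusters (their
  coverage against the full-length representative fails the rule); this
  mirrors the real fragmentation-driven underestimation of allele
  frequencies and is intentional, not corrected.
* The permutation test treats contigs as exchangeable units; it does not
  model within-contig spatial autocorrelation of repeat classes.
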