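# novoseqkit

Discovery and characterization of **novel sequences (NS)** — assembled DNA
carried by individuals of a population but absent from the reference
genome — from per-individual de novo assembly contigs.

When whole-genome assemblies of many individuals are aligned back to a
reference, the unmappable contigs pooled across the cohort contain
megabases of sequence the reference lacks. Much of it is ancestral: present
in the chimpanzee genome and deleted on the lineage leading to the human
reference. Characterizing this sequence requires a chain of analyses that
is usually glued together from shell tools. `novoseqkit` implements the
chain as one tested R package:

* **QC + clustering** — CD-HIT-style greedy clustering of contigs (a
  contig joins the first cluster whose representative aligns at identity
  ≥ 0.95 with ≥ 0.90 coverage of both sequences, either strand),
  contaminant removal by the BLAST taxonomy rule (significant non-primate
  hit, no significant primate hit, E < 1e-40), a 301 bp size filter, and
  allele frequencies as the fraction of individuals contributing contigs
  (`greedyCluster`, `classifyContaminants`, `clusterAlleleFrequencies`).
* **Classification** — a k-mer anchor aligner places cluster
  representatives on references and catalogs; hits with identity > 95%
  and coverage > 90% are *confident*, and a cluster is **NS** iff no hit
  to the human reference has identity > 80% and coverage > 50%
  (`alignToReference`, `classifyClusters`, `catalogMembership`).
* **Repeat enrichment** — base-weighted repeat-class composition and a
  nonparametric permutation test: per class, `Diff = |A% − B%|` against
  10,000 random subsets R ⊂ A with |R| = |B|, p = fraction of
  `Diff_R > Diff` (`repeatComposition`, `repeatPermutationTest`,
  `sampleBackground`).
* **Positioning** — per-individual insertion breakpoints merged by 1-D
  DBSCAN (eps 150 bp, minimum 3 neighbours), events in < 5 individuals and
  hybrid co-locations removed; genomic-feature enrichment by simulating
  10,000 iterations of n random 1 kb regions and exact binomial tests
  (`dbscan1d`, `mergeInsertions`, `featureEnrichment`).
* **Unmapped-read mapping** — flag-filtered read counting (secondary
  0x100 and supplementary 0x800 records never counted), per-population
  mapping fractions, allele-frequency depletion curves, Mann–Whitney and
  ANOVA/Tukey comparisons (`countReads`, `depletionCurve`,
  `populationAnovaTukey`).
* **Ancestral deletions** — deletions called against a chimp-like
  reference are PASS/DEL-filtered, merged by 0.7 reciprocal overlap,
  intersected with NS intervals, novelty-checked, and summarized as
  **chimpanzee reference allele (CRA)** carrier frequencies, a carrier
  being any individual retaining ≥ 1 copy (heterozygous or no deletion)
  (`filterDeletions`, `mergeDeletions`, `craFrequency`).

Because the real cohorts behind such studies are access-restricted, the
package includes a fully specified **synthetic-cohort generator**
(`simConfig`, `simulateCohort`) with truth tables: planted NS with a
skewed allele-frequency spectrum (90% rare), recorded repeat composition,
contaminants, fragmented contigs, positioned insertions, ancestral
deletions and unmapped-read records. Every pipeline stage is tested
against this truth, against brute-force oracles, and against closed-form
statistics.

## Worked example

```r
library(novoseqkit)

cfg <- simConfig(seed = 7, nIndividuals = 20, nNs = 30, refLength = 200000L,
                 nContaminants = 2, urIndividuals = 8, readsPerIndividual = 500)
cohort <- simulateCohort(cfg)
cohort
#> SyntheticCohort: N = 20 | 30 planted NS | 256 contigs
#>   ancestral NS: 9 | positioned NS: 8
#>   insertion calls: 44 | deletion calls: 186 | UR records: 4034

res <- runPipeline(cohort, nPermutations = 1000, enrichIterations = 500,
                   backgroundN = 300, verbose = FALSE)
res$clusters
#> SequenceClusterSet with 61 clusters / 212 member contigs
#>   cohort N = 20; 0.0% of clusters rare (AF < 5%)

tt <- res$repeatTest$table
tt[order(-tt$diff), ][1:4, ]
#>           class     pct_a     pct_b      diff p_value
#> 5 Simple_repeat  2.340084 24.702119 22.362035   0.000
#> 1          LINE 20.685032  9.356257 11.328774   0.141
#> 6     Satellite  1.862245 11.979208 10.116963   0.000
#> 2          SINE 12.315451  3.150740  9.164712   0.003

str(res$report[c("n_clusters", "n_ns_clusters", "mean_mapped_fraction",
                 "n_cra_events", "n_cra_common")])
#> List of 5
#>  $ n_clusters          : int 61
#>  $ n_ns_clusters       : int 31
#>  $ mean_mapped_fraction: num 0.0745
#>  $ n_cra_events        : int 18
#>  $ n_cra_common        : int 18
```

Reading the output: the 256 contigs of the 20 simulated individuals
collapse into 61 clusters after contaminant and size filtering; 31 are
classified NS (the 30 planted NS plus one fragment-founded cluster —
decoy contigs copied from the human-like reference are correctly excluded).
The NS set is strongly enriched in simple repeats (24.7% of bases vs 2.3%
in the reference background, permutation p below the 1/1000 resolution)
and satellites, while LINEs are relatively depleted. On average 7.45% of
the unmapped reads align back to the NS catalog (7.4% planted), and all 18
merged, novelty-checked deletions against the chimp-like reference have a
common (> 5%) CRA carrier frequency.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/novoseqkit.R`
(`Rscript novoseqkit.R {simulate|all} --seed 1 --out dir`).

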