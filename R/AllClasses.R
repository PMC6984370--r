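#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

## ---------------------------------------------------------------------------
## ContigSet
## ---------------------------------------------------------------------------

#' Set of assembled contigs with individual ownership
#'
#' A \code{ContigSet} wraps a \code{\link[Biostrings]{DNAStringSet}} whose
#' names follow the \code{IndividualXYZ_I} convention: everything before the
#' last underscore is the individual id, the trailing token is the
#' per-individual contig id. Individual ids may themselves contain
#' underscores.
#'
#' @slot sequences A named \code{DNAStringSet}; names are contig names.
#'
#' @export
setClass("ContigSet", representation(sequences = "DNAStringSet"))

setValidity("ContigSet", function(object) {
  s <- object@sequences
  if (length(s) == 0L) return(TRUE)
  if (is.null(names(s)) || anyNA(names(s)) || any(names(s) == ""))
    return("all contigs must be named")
  if (anyDuplicated(names(s))) return("contig names must be unique")
  if (any(Biostrings::width(s) == 0L)) return("contigs must be non-empty")
  if (!all(grepl("_", names(s), fixed = TRUE)))
    return("contig names must contain an underscore (IndividualXYZ_I)")
  TRUE
})

#' Construct a ContigSet
#'
#' @param sequences A named \code{DNAStringSet} (or named character vector)
#'   of uppercase DNA sequences; names follow \code{IndividualXYZ_I}.
#' @return A \code{ContigSet}.
#' @export
#' @examples
#' cs <- ContigSet(c(Ind01_1 = "ACGTACGT", Ind01_2 = "GGGTTTAA"))
#' individualIds(cs)
ContigSet <- function(sequences) {
  if (is.character(sequences)) {
    nm <- names(sequences)
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
    names(sequences) <- nm
  }
  new("ContigSet", sequences = sequences)
}

#' @describeIn ContigSet Number of contigs.
#' @param x A \code{ContigSet}.
#' @export
setMethod("length", "ContigSet", function(x) length(x@sequences))

#' @describeIn ContigSet Contig names.
#' @export
setMethod("names", "ContigSet", function(x) names(x@sequences))

#' @describeIn ContigSet Subset by index or name.
#' @param i index
#' @param j,drop,... ignored
#' @export
setMethod("[", "ContigSet", function(x, i, j, ..., drop = TRUE)
  new("ContigSet", sequences = x@sequences[i]))

#' Contig sequences
#' @param x A \code{ContigSet}.
#' @return The underlying named \code{DNAStringSet}.
#' @export
contigSequences <- function(x) x@sequences

#' Individual ids of contigs
#' @param x A \code{ContigSet}.
#' @return Character vector, one id per contig (prefix before last underscore).
#' @export
individualIds <- function(x) {
  if (length(x) == 0L) return(character(0))
  splitContigName(names(x))$individual
}

#' Contig lengths in bp
#' @param x A \code{ContigSet}.
#' @return Integer vector of sequence lengths.
#' @export
contigLengths <- function(x) stats::setNames(Biostrings::width(x@sequences), names(x))

setMethod("show", "ContigSet", function(object) {
  cat("ContigSet with", length(object), "contigs from",
      length(unique(individualIds(object))), "individuals\n")
  if (length(object) > 0L) {
    w <- Biostrings::width(object@sequences)
    cat("  length range:", min(w), "-", max(w), "bp\n")
  }
})

## ---------------------------------------------------------------------------
## SequenceClusterSet
## ---------------------------------------------------------------------------

#' Clusters of contigs representing candidate alleles
#'
#' Result of \code{\link{greedyCluster}}: a partition of contigs into
#' clusters, each with a representative (the longest member), the set of
#' contributing individuals, and -- after
#' \code{\link{clusterAlleleFrequencies}} -- an allele frequency defined as
#' the fraction of cohort individuals contributing at least one contig.
#'
#' @slot clusters \code{DataFrame} with one row per cluster: \code{cluster_id},
#'   \code{representative} (contig name), \code{rep_length}, \code{n_members},
#'   \code{n_individuals}, \code{af} (NA until frequencies are computed).
#' @slot members \code{DataFrame} mapping every contig to its cluster:
#'   \code{contig}, \code{cluster_id}, \code{individual}.
#' @slot representatives Named \code{DNAStringSet} of representative
#'   sequences (names are cluster ids).
#' @slot nCohort Integer cohort size used for allele frequencies (NA until set).
#'
#' @export
setClass("SequenceClusterSet",
         representation(clusters = "DataFrame", members = "DataFrame",
                        representatives = "DNAStringSet", nCohort = "integer"))

setValidity("SequenceClusterSet", function(object) {
  cl <- object@clusters
  need <- c("cluster_id", "representative", "rep_length", "n_members",
            "n_individuals", "af")
  if (!all(need %in% colnames(cl))) return("missing cluster columns")
  if (anyDuplicated(cl$cluster_id)) return("cluster ids must be unique")
  if (anyDuplicated(object@members$contig))
    return("each contig must belong to exactly one cluster")
  if (!all(object@members$cluster_id %in% cl$cluster_id))
    return("membership refers to unknown cluster")
  if (!identical(sort(names(object@representatives)), sort(cl$cluster_id)))
    return("representative sequences must be keyed by cluster id")
  TRUE
})

#' @describeIn SequenceClusterSet Number of clusters.
#' @param x A \code{SequenceClusterSet}.
#' @export
setMethod("length", "SequenceClusterSet", function(x) nrow(x@clusters))

#' Per-cluster summary table
#' @param x A \code{SequenceClusterSet}.
#' @return \code{DataFrame} with one row per cluster.
#' @export
clusterTable <- function(x) x@clusters

#' Contig-to-cluster membership
#' @param x A \code{SequenceClusterSet}.
#' @return \code{DataFrame} with columns contig, cluster_id, individual.
#' @export
clusterMembers <- function(x) x@members

#' Representative sequences
#' @param x A \code{SequenceClusterSet}.
#' @return Named \code{DNAStringSet}, one representative per cluster.
#' @export
representatives <- function(x) x@representatives

#' Cluster allele frequencies
#' @param x A \code{SequenceClusterSet} after
#'   \code{\link{clusterAlleleFrequencies}}.
#' @return Named numeric vector of allele frequencies.
#' @export
alleleFrequencies <- function(x)
  stats::setNames(x@clusters$af, x@clusters$cluster_id)

setMethod("show", "SequenceClusterSet", function(object) {
  cat("SequenceClusterSet with", length(object), "clusters /",
      nrow(object@members), "member contigs\n")
  if (!is.na(object@nCohort)) {
    rare <- mean(object@clusters$af < 0.05)
    cat(sprintf("  cohort N = %d; %.1f%% of clusters rare (AF < 5%%)\n",
                object@nCohort, 100 * rare))
  }
})

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' Synthetic-cohort configuration
#'
#' Parameters of the synthetic cohort generator. Defaults emulate the study
#' conditions of a desk-scale population NS survey: 100 individuals, 300
#' planted NS with a strongly skewed allele-frequency spectrum (90\% rare,
#' AF < 5\%), NS lengths 301-22,701 bp with mean about 450 bp, per-NS
#' repeat-class mix dominated by simple repeats and satellites, viral-like
#' contaminant contigs of 22.7-60 kb, per-base assembly error 0.005 and
#' 10\% probability that a carried NS contig is emitted fragmented.
#'
#' @slot seed master seed; every emission draws from a named substream.
#' @slot nIndividuals cohort size N.
#' @slot refLength total human-like reference length (bp, split over
#'   \code{nChromosomes} chromosomes).
#' @slot nChromosomes number of reference chromosomes.
#' @slot nNs number of planted novel sequences.
#' @slot afSpectrum list(pRare, rareRange, commonRange): mixture spec of the
#'   carrier-frequency spectrum.
#' @slot nsLengthRange inclusive NS length bounds (bp).
#' @slot nsLengthExpMean mean of the shifted-exponential NS length
#'   distribution above the minimum (bp).
#' @slot repeatMix named numeric, target repeat-class base proportions per NS.
#' @slot nContaminants number of contaminant contig clusters.
#' @slot fragmentationProb probability a carried NS contig is emitted as two
#'   fragments (each at least the minimum contig size).
#' @slot mutationRate per-base substitution rate emulating assembly error.
#' @slot contaminantLenRange contaminant length bounds (bp).
#' @slot ancestralFraction fraction of NS planted verbatim in the chimp-like
#'   reference (ancestral sequences deleted in the human-like reference).
#' @slot positionedFraction fraction of non-ancestral NS with a recorded
#'   insertion position on the human-like reference.
#' @slot nDecoyLoci,decoysPerIndividual decoy contigs copied from the
#'   human-like reference (mappable sequence that must not classify as NS).
#' @slot smallPerIndividual sub-threshold (<301 bp) contigs per individual.
#' @slot insertionJitterSd s.d. (bp) of Gaussian breakpoint jitter on
#'   emitted insertion calls.
#' @slot falseCallsPerIndividual Poisson mean of spurious insertion calls.
#' @slot hybridFraction fraction of positioned NS co-located pairwise at a
#'   shared site to emulate hybrid insertion calls.
#' @slot lowQualFraction fraction of deletion records labeled LowQual.
#' @slot delPadMax maximum per-side Uniform padding (bp) of deletion calls
#'   around the true deleted interval.
#' @slot urIndividuals,readsPerIndividual,readLength unmapped-read emission:
#'   number of profiled individuals, reads per individual, read length.
#' @slot urMappedFraction target fraction of URs drawn from carried NS.
#' @slot urDupFraction fraction of mapped reads duplicated as secondary and
#'   supplementary records.
#'
#' @export
setClass("SimConfig", representation(
  seed = "integer", nIndividuals = "integer", refLength = "integer",
  nChromosomes = "integer", nNs = "integer", afSpectrum = "list",
  nsLengthRange = "integer", nsLengthExpMean = "numeric",
  repeatMix = "numeric", nContaminants = "integer",
  fragmentationProb = "numeric", mutationRate = "numeric",
  contaminantLenRange = "integer", ancestralFraction = "numeric",
  positionedFraction = "numeric", nDecoyLoci = "integer",
  decoysPerIndividual = "integer", smallPerIndividual = "integer",
  insertionJitterSd = "numeric", falseCallsPerIndividual = "numeric",
  hybridFraction = "numeric", lowQualFraction = "numeric",
  delPadMax = "integer", urIndividuals = "integer",
  readsPerIndividual = "integer", readLength = "integer",
  urMappedFraction = "numeric", urDupFraction = "numeric"))

setValidity("SimConfig", function(object) {
  if (abs(sum(object@repeatMix) - 1) > 1e-9)
    return("repeatMix proportions must sum to 1")
  if (!all(names(object@repeatMix) %in% REPEAT_CLASSES))
    return("repeatMix classes must be in repeatClasses()")
  if (object@nsLengthRange[1] < 1L || diff(object@nsLengthRange) < 0L)
    return("invalid nsLengthRange")
  if (object@nIndividuals < 1L) return("nIndividuals must be >= 1")
  rates <- c(object@fragmentationProb, object@mutationRate,
             object@ancestralFraction, object@positionedFraction,
             object@hybridFraction, object@lowQualFraction,
             object@urMappedFraction, object@urDupFraction)
  if (any(rates < 0 | rates > 1)) return("rates must lie in [0, 1]")
  TRUE
})

#' Create a synthetic-cohort configuration
#'
#' See \code{\linkS4class{SimConfig}} for the meaning and rationale of each
#' parameter. All defaults are the package's study conditions; tests and the
#' acceptance runs use them unchanged apart from the explicitly varied error
#' knobs (\code{mutationRate}, \code{fragmentationProb}).
#'
#' @param seed master seed (integer).
#' @param nIndividuals cohort size (default 100).
#' @param refLength human-like reference length in bp (default 2e6).
#' @param nChromosomes chromosomes the reference is split over (default 2).
#' @param nNs number of planted NS (default 300).
#' @param afSpectrum carrier-frequency mixture; by default 90\% of NS have
#'   AF ~ Uniform(1/N, 0.05) and 10\% have AF ~ Uniform(0.05, 0.5).
#' @param nsLengthRange NS length bounds in bp (default c(301, 22701)).
#' @param nsLengthExpMean mean excess length over the minimum (default 150,
#'   giving mean NS length about 450 bp).
#' @param repeatMix target per-NS repeat-class proportions.
#' @param nContaminants,contaminantLenRange contaminant contigs.
#' @param fragmentationProb,mutationRate assembly-error knobs.
#' @param ancestralFraction,positionedFraction NS placement fractions.
#' @param nDecoyLoci,decoysPerIndividual,smallPerIndividual nuisance contigs.
#' @param insertionJitterSd,falseCallsPerIndividual,hybridFraction insertion
#'   call emission.
#' @param lowQualFraction,delPadMax deletion call emission.
#' @param urIndividuals,readsPerIndividual,readLength,urMappedFraction,urDupFraction
#'   unmapped-read emission.
#' @return A validated \code{SimConfig}.
#' @export
#' @examples
#' cfg <- simConfig(seed = 1, nIndividuals = 10, nNs = 5, refLength = 50000L)
simConfig <- function(seed = 1L,
                      nIndividuals = 100L,
                      refLength = 2000000L,
                      nChromosomes = 2L,
                      nNs = 300L,
                      afSpectrum = list(pRare = 0.9,
                                        rareRange = c(NA_real_, 0.05),
                                        commonRange = c(0.05, 0.5)),
                      nsLengthRange = c(301L, 22701L),
                      nsLengthExpMean = 150,
                      repeatMix = c(Simple_repeat = 0.28, Satellite = 0.15,
                                    LINE = 0.10, SINE = 0.03, Unmasked = 0.44),
                      nContaminants = 10L,
                      fragmentationProb = 0.1,
                      mutationRate = 0.005,
                      contaminantLenRange = c(22701L, 60000L),
                      ancestralFraction = 0.3,
                      positionedFraction = 0.25,
                      nDecoyLoci = 30L,
                      decoysPerIndividual = 8L,
                      smallPerIndividual = 2L,
                      insertionJitterSd = 30,
                      falseCallsPerIndividual = 1,
                      hybridFraction = 0.05,
                      lowQualFraction = 0.1,
                      delPadMax = 2000L,
                      urIndividuals = 40L,
                      readsPerIndividual = 2000L,
                      readLength = 150L,
                      urMappedFraction = 0.074,
                      urDupFraction = 0.05) {
  if (is.na(afSpectrum$rareRange[1]))
    afSpectrum$rareRange[1] <- min(1 / nIndividuals, afSpectrum$rareRange[2])
  new("SimConfig", seed = as.integer(seed),
      nIndividuals = as.integer(nIndividuals),
      refLength = as.integer(refLength), nChromosomes = as.integer(nChromosomes),
      nNs = as.integer(nNs), afSpectrum = afSpectrum,
      nsLengthRange = as.integer(nsLengthRange),
      nsLengthExpMean = nsLengthExpMean, repeatMix = repeatMix,
      nContaminants = as.integer(nContaminants),
      fragmentationProb = fragmentationProb, mutationRate = mutationRate,
      contaminantLenRange = as.integer(contaminantLenRange),
      ancestralFraction = ancestralFraction,
      positionedFraction = positionedFraction,
      nDecoyLoci = as.integer(nDecoyLoci),
      decoysPerIndividual = as.integer(decoysPerIndividual),
      smallPerIndividual = as.integer(smallPerIndividual),
      insertionJitterSd = insertionJitterSd,
      falseCallsPerIndividual = falseCallsPerIndividual,
      hybridFraction = hybridFraction, lowQualFraction = lowQualFraction,
      delPadMax = as.integer(delPadMax),
      urIndividuals = as.integer(urIndividuals),
      readsPerIndividual = as.integer(readsPerIndividual),
      readLength = as.integer(readLength),
      urMappedFraction = urMappedFraction, urDupFraction = urDupFraction)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: N =", object@nIndividuals, "| NS =", object@nNs,
      "| ref =", object@refLength, "bp over", object@nChromosomes,
      "chromosomes\n")
  cat("  mutation =", object@mutationRate,
      "| fragmentation =", object@fragmentationProb,
      "| seed =", object@seed, "\n")
})

## ---------------------------------------------------------------------------
## SyntheticCohort
## ---------------------------------------------------------------------------

#' A fully generated synthetic cohort with truth tables
#'
#' Container produced by \code{\link{simulateCohort}} holding the references,
#' the planted NS truth table, every per-individual emission (contigs,
#' insertion calls, deletion calls, unmapped-read records) and the feature /
#' repeat tracks downstream stages consume.
#'
#' @slot config The \code{SimConfig} used.
#' @slot humanRef,chimpRef Named \code{DNAStringSet} references; the
#'   chimp-like reference equals the human-like one with ancestral NS
#'   inserted.
#' @slot deletedRegions \code{GRanges} on the chimp-like reference: one range
#'   per ancestral NS (the deletion relative to chimpanzee), with
#'   \code{ns_id} and \code{novelty_status} metadata.
#' @slot truth \code{DataFrame}, one row per NS: id, length, true allele
#'   (carrier) frequency, carrier count, ancestral / positioned flags,
#'   insertion position on the human-like reference (NA if unpositioned)
#'   and the NS sequence.
#' @slot carriers named list: ns_id -> character vector of carrier ids.
#' @slot contigs Pooled \code{ContigSet} over all individuals.
#' @slot contigOrigin \code{DataFrame}: contig name, origin class
#'   (ns / decoy / small / contaminant), source ns_id or locus.
#' @slot blastHits data.frame of BLAST-like hits (query_id, taxon_group,
#'   e_value) for contaminant classification.
#' @slot humanRepeatTrack \code{GRanges} repeat annotation of the human-like
#'   reference (label = repeat class).
#' @slot featureTracks named list of \code{GRanges} feature tracks on the
#'   human-like reference (genes, exons, segmental duplications).
#' @slot insertionCalls data.frame of per-individual insertion breakpoints.
#' @slot deletionCalls data.frame of per-individual deletion records against
#'   the chimp-like reference.
#' @slot urReads data.frame of SAM-flag records of unmapped-read alignments.
#' @slot sampleSheet data.frame (individual, population).
#'
#' @export
setClass("SyntheticCohort", representation(
  config = "SimConfig", humanRef = "DNAStringSet", chimpRef = "DNAStringSet",
  deletedRegions = "GRanges", truth = "DataFrame", carriers = "list",
  contigs = "ContigSet", contigOrigin = "DataFrame", blastHits = "data.frame",
  humanRepeatTrack = "GRanges", featureTracks = "list",
  insertionCalls = "data.frame", deletionCalls = "data.frame",
  urReads = "data.frame", sampleSheet = "data.frame"))

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort: N =", object@config@nIndividuals, "|",
      nrow(object@truth), "planted NS |", length(object@contigs),
      "contigs\n")
  cat("  ancestral NS:", sum(object@truth$ancestral),
      "| positioned NS:", sum(object@truth$positioned), "\n")
  cat("  insertion calls:", nrow(object@insertionCalls),
      "| deletion calls:", nrow(object@deletionCalls),
      "| UR records:", nrow(object@urReads), "\n")
})

#' Truth table of a synthetic cohort
#' @param x A \code{SyntheticCohort}.
#' @return \code{DataFrame} with one row per planted NS.
#' @export
cohortTruth <- function(x) x@truth

#' Pooled contigs of a synthetic cohort
#' @param x A \code{SyntheticCohort}.
#' @return A \code{ContigSet}.
#' @export
cohortContigs <- function(x) x@contigs
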