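## End-to-end orchestration: simulate -> cluster -> QC -> classify ->
## repeats -> position/enrich -> UR mapping -> ancestral deletions, with a
## machine-readable report. Plain data.frames move between stages so any
## stage can be swapped for real-data outputs (genuine show-coords tables,
## RepeatMasker files, VCFs) read through the same readers.

#' Align cluster representatives to a set of references
#'
#' Runs \code{\link{alignToReference}} for every representative against each
#' named reference and returns the pooled hit table.
#'
#' @param clusters A \code{SequenceClusterSet}.
#' @param references Named list of references (each a named
#'   \code{DNAStringSet} or named character vector).
#' @param k Anchor length (default 31).
#' @return data.frame of hits with columns cluster_id, reference and the
#'   \code{alignToReference} columns.
#' @export
alignClustersToReferences <- function(clusters, references, k = 31L,
                                      bandWidth = 50L, maxOcc = 100L) {
  stopifnot(!is.null(names(references)))
  reps <- representatives(clusters)
  refSets <- lapply(references, function(r) {
    if (is.character(r)) {
      nm <- names(r); r <- Biostrings::DNAStringSet(r); names(r) <- nm
    }
    r
  })
  emptyOut <- data.frame(cluster_id = character(0), reference = character(0),
                         identity_pct = numeric(0), query_cov_pct = numeric(0),
                         target_id = character(0), target_start = integer(0),
                         target_end = integer(0), stringsAsFactors = FALSE)
  keep <- Biostrings::width(reps) >= k
  reps <- reps[keep]
  if (length(reps) == 0L) return(emptyOut)
  ## one pooled k-mer dictionary over all representatives and both strands;
  ## each pattern remembers (cluster, strand, query position)
  qseq <- as.character(reps)
  rcseq <- vapply(qseq, revcompChar, "", USE.NAMES = FALSE)
  kmerList <- list(); meta <- list()
  for (i in seq_along(qseq)) {
    for (st in c("+", "-")) {
      s <- if (st == "+") qseq[i] else rcseq[i]
      km <- seqKmers(s, k)
      kmerList[[length(kmerList) + 1L]] <- km
      meta[[length(meta) + 1L]] <- data.frame(
        rep = i, strand = st, qpos = seq_along(km) - 1L)
    }
  }
  meta <- do.call(rbind, meta)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(unlist(kmerList)))
  out <- list()
  for (rf in names(refSets)) {
    for (t in names(refSets[[rf]])) {
      tseq <- as.character(refSets[[rf]][[t]])
      mi <- Biostrings::matchPDict(pd, refSets[[rf]][[t]])
      counts <- S4Vectors::elementNROWS(mi)
      use <- which(counts > 0L & counts <= maxOcc)
      if (length(use) == 0L) next
      tposL <- Biostrings::startIndex(mi)[use]
      anc <- data.frame(rep = rep(meta$rep[use], lengths(tposL)),
                        strand = rep(meta$strand[use], lengths(tposL)),
                        qpos = rep(meta$qpos[use], lengths(tposL)),
                        tpos = unlist(tposL, use.names = FALSE) - 1L)
      for (grp in split(anc, list(anc$rep, anc$strand), drop = TRUE)) {
        i <- grp$rep[1]; st <- grp$strand[1]
        L <- nchar(qseq[i])
        h <- chainBand(grp[, c("qpos", "tpos")],
                       if (st == "+") qseq[i] else rcseq[i], tseq, k,
                       bandWidth, L)
        if (is.null(h) || nrow(h) == 0L) next
        if (st == "-") {
          qs0 <- h$query_start
          h$query_start <- L - h$query_end
          h$query_end <- L - qs0
        }
        h$cluster_id <- names(reps)[i]; h$reference <- rf
        h$query_id <- names(reps)[i]
        h$target_id <- t; h$strand <- st
        out[[length(out) + 1L]] <- h
      }
    }
  }
  if (length(out) == 0L) return(emptyOut)
  do.call(rbind, out)
}

## map each truth NS id to the cluster holding its (non-fragment, else any)
## contigs; NA when none of its contigs survived to `clusters`
nsToClusterMap <- function(cohort, clusters) {
  mb <- clusterMembers(clusters)
  org <- as.data.frame(cohort@contigOrigin)
  org <- org[org$origin == "ns", , drop = FALSE]
  org$cluster <- mb$cluster_id[match(org$contig, mb$contig)]
  map <- rep(NA_character_, nrow(cohort@truth))
  names(map) <- cohort@truth$ns_id
  for (id in names(map)) {
    rows <- org[org$source_id == id & !is.na(org$cluster), , drop = FALSE]
    if (nrow(rows) == 0L) next
    full <- rows[!rows$fragment, , drop = FALSE]
    pick <- if (nrow(full) > 0L) full$cluster else rows$cluster
    map[id] <- names(sort(table(pick), decreasing = TRUE))[1]
  }
  map
}

#' Run the full novel-sequence discovery pipeline on a synthetic cohort
#'
#' Executes every stage in dependency order and returns the stage outputs
#' plus a compact numeric report: clustering and QC (contaminant + size
#' filters on clusters), allele frequencies, reference classification
#' (human-like and chimp-like references), repeat-class permutation
#' enrichment of the NS set against a background sample of the human-like
#' reference, insertion-call merging and feature enrichment, unmapped-read
#' mapping statistics with depletion curves, and the ancestral-deletion /
#' CRA analysis. All stage randomness derives from the configuration seed,
#' so a rerun with the same configuration is identical.
#'
#' @param config A \code{\link{simConfig}} (or a prebuilt
#'   \code{SyntheticCohort} to skip simulation).
#' @param nPermutations Permutations for the repeat test (default 10000).
#' @param enrichIterations Iterations for the feature-enrichment null
#'   simulation (default 10000).
#' @param backgroundN Background sequences sampled from the human-like
#'   reference for the repeat comparison (default 2000).
#' @param verbose Log stage progress to stderr.
#' @return list with elements cohort, clusters (QC-passed, with AFs),
#'   contaminantClusters, hits, classification, membership, repeatTest,
#'   mergedInsertions, enrichment, urFractions, depletion, depletionStats,
#'   deletions and report (named list of headline numbers).
#' @export
runPipeline <- function(config = simConfig(), nPermutations = 10000L,
                        enrichIterations = 10000L, backgroundN = 2000L,
                        verbose = TRUE) {
  log <- function(...) if (verbose) message("[novoseqkit] ", ...)
  cohort <- if (methods::is(config, "SyntheticCohort")) config
  else {
    log("simulating cohort")
    simulateCohort(config)
  }
  cfg <- cohort@config
  N <- cfg@nIndividuals

  log("clustering ", length(cohort@contigs), " contigs")
  cl0 <- greedyCluster(cohort@contigs)
  log("QC: contaminant and size filters on ", length(cl0), " clusters")
  cc <- classifyContaminants(cl0, cohort@blastHits)
  sz <- filterClustersBySize(cc$clean, minLen = cfg@nsLengthRange[1])
  clusters <- clusterAlleleFrequencies(sz$kept, N)
  afs <- afSummary(clusters)

  log("classifying ", length(clusters), " representatives")
  refs <- list(human = cohort@humanRef, chimp = cohort@chimpRef)
  hits <- alignClustersToReferences(clusters, refs)
  ids <- clusterTable(clusters)$cluster_id
  cls <- classifyClusters(hits, ids, humanRef = "human")
  mem <- catalogMembership(cls$confident, ids,
                           references = names(refs))
  nsIds <- cls$classification$cluster_id[cls$classification$is_ns]
  nsClusters <- subsetClusters(clusters, nsIds)
  nsAf <- afSummary(nsClusters)

  log("repeat enrichment (", nPermutations, " permutations)")
  nsMap <- nsToClusterMap(cohort, clusters)
  ann <- nsAnnotations(cohort)
  tab <- clusterTable(clusters)
  org <- as.data.frame(cohort@contigOrigin)
  repRows <- match(tab$representative, org$contig)
  nsRepAnn <- list(); nsRepLen <- integer(0)
  for (i in which(tab$cluster_id %in% nsIds)) {
    if (org$origin[repRows[i]] != "ns" || org$fragment[repRows[i]]) next
    nsRepAnn[[tab$cluster_id[i]]] <- ann[[org$source_id[repRows[i]]]]
    nsRepLen[tab$cluster_id[i]] <- tab$rep_length[i]
  }
  chromLen <- stats::setNames(Biostrings::width(cohort@humanRef),
                              names(cohort@humanRef))
  bg <- sampleBackground(chromLen, sizeDistribution = unname(nsRepLen),
                         n = backgroundN,
                         seed = substreamSeed(cfg@seed, "pipeline_background"),
                         repeatTrack = cohort@humanRepeatTrack)
  mB <- repeatBaseMatrix(nsRepAnn, nsRepLen)
  repeatTest <- repeatPermutationTest(bg$baseMatrix, mB,
                                      nPermutations = nPermutations,
                                      seed = substreamSeed(cfg@seed,
                                                           "pipeline_perm"))

  log("merging insertion calls")
  nsClass <- data.frame(cluster_id = cohort@truth$ns_id,
                        matches_human = FALSE, stringsAsFactors = FALSE)
  mapped <- !is.na(nsMap)
  nsClass$matches_human[mapped] <-
    !cls$classification$is_ns[match(nsMap[mapped],
                                    cls$classification$cluster_id)]
  merged <- mergeInsertions(cohort@insertionCalls, nsClass)
  enrichment <- if (nrow(merged) > 0L)
    featureEnrichment(merged, cohort@featureTracks, chromLen,
                      iterations = enrichIterations,
                      seed = substreamSeed(cfg@seed, "pipeline_enrich"))
  else NULL

  log("unmapped-read mapping statistics")
  ur <- cohort@urReads
  urFractions <- mappingFractions(ur, cohort@sampleSheet)
  afVec <- alleleFrequencies(clusters)
  primary <- bitwAnd(ur$flag, 256L + 2048L) == 0L & bitwAnd(ur$flag, 4L) == 0L
  mappedReads <- ur[primary, , drop = FALSE]
  mappedReads$cluster <- unname(nsMap[mappedReads$ns_id])
  mappedReads <- mappedReads[!is.na(mappedReads$cluster), , drop = FALSE]
  curves <- do.call(rbind, lapply(unique(mappedReads$individual),
    function(ind) {
      m <- mappedReads[mappedReads$individual == ind, , drop = FALSE]
      dc <- depletionCurve(m$cluster, afVec)
      dc$individual <- ind
      dc$population <- cohort@sampleSheet$population[
        match(ind, cohort@sampleSheet$individual)]
      dc
    }))
  depletionStats <- tryCatch(depletionAnova(curves),
                             error = function(e) NULL)

  log("ancestral deletions / CRA")
  recs <- filterDeletions(cohort@deletionCalls)
  mergedDel <- mergeDeletions(recs)
  chimpNs <- cls$best[cls$best$reference == "chimp" &
                        cls$best$cluster_id %in% nsIds &
                        cls$best$identity_pct > 95 &
                        cls$best$query_cov_pct > 90, , drop = FALSE]
  nsIntervals <- data.frame(chrom = chimpNs$target_id,
                            start = chimpNs$target_start,
                            end = chimpNs$target_end,
                            ns_id = chimpNs$cluster_id,
                            stringsAsFactors = FALSE)
  dr <- cohort@deletedRegions
  novelty <- data.frame(chrom = as.character(GenomicRanges::seqnames(dr)),
                        start = GenomicRanges::start(dr) - 1L,
                        end = GenomicRanges::end(dr),
                        status = dr$novelty_status, stringsAsFactors = FALSE)
  cra <- intersectWithNS(mergedDel, nsIntervals)
  cra <- checkNovelty(cra, novelty)
  cra <- craFrequency(cra, N)

  report <- list(
    n_contigs = length(cohort@contigs),
    n_clusters_raw = length(cl0),
    n_contaminant_clusters = length(cc$contaminant),
    n_small_clusters_removed = length(sz$removed),
    n_clusters = length(clusters),
    fraction_rare = afs$fraction_rare,
    n_ns_clusters = length(nsClusters),
    fraction_rare_ns = nsAf$fraction_rare,
    n_confident_any = mem$n_any,
    repeat_p = stats::setNames(repeatTest$table$p_value,
                               repeatTest$table$class),
    n_merged_insertions = nrow(merged),
    mean_mapped_fraction = mean(urFractions$fraction),
    n_merged_deletions = nrow(mergedDel),
    n_cra_events = nrow(cra),
    n_cra_common = sum(cra$common))
  log("done")
  list(cohort = cohort, clusters = clusters,
       contaminantClusters = cc$contaminant, hits = hits,
       classification = cls, membership = mem, nsClusters = nsClusters,
       repeatTest = repeatTest, mergedInsertions = merged,
       enrichment = enrichment, urFractions = urFractions,
       depletion = curves, depletionStats = depletionStats,
       deletions = cra, report = report)
}
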