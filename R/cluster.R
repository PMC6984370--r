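## Contig QC and CD-HIT-style greedy clustering.
##
## The join rule is the documented contract: a contig joins the FIRST existing
## cluster (in founding order) whose representative aligns with identity >=
## `c` and coverage >= `aS` of the shorter and >= `aL` of the longer sequence,
## on either strand; otherwise it founds a new cluster. Identity and coverage
## come from a full dynamic-programming local alignment (match +1, mismatch
## -1, gap -2). A conservative shared 11-mer prefilter skips hopeless
## comparisons without ever changing the partition (see vignette).

PREFILTER_K <- 11L

localAlignMatrix <- function() {
  if (is.null(.novoseq_cache$submat))
    .novoseq_cache$submat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE)
  .novoseq_cache$submat
}
.novoseq_cache <- new.env(parent = emptyenv())

## Batched local alignment of several patterns against one subject.
## Returns data.frame(score, identity, cov_pattern, cov_subject).
alignStatsBatch <- function(patterns, subject) {
  pa <- Biostrings::pairwiseAlignment(
    patterns, subject, type = "local",
    substitutionMatrix = localAlignMatrix(), gapOpening = 0, gapExtension = 2)
  cols <- Biostrings::nchar(pa)
  ident <- ifelse(cols > 0, Biostrings::nmatch(pa) / cols, 0)
  ap <- Biostrings::pattern(pa); as_ <- Biostrings::subject(pa)
  spanP <- BiocGenerics::end(ap) - BiocGenerics::start(ap) + 1L
  spanS <- BiocGenerics::end(as_) - BiocGenerics::start(as_) + 1L
  data.frame(score = Biostrings::score(pa), identity = ident,
             cov_pattern = spanP / Biostrings::width(patterns),
             cov_subject = spanS / nchar(as.character(subject)))
}

#' Pairwise identity and coverage of two sequences
#'
#' Best local alignment (match +1, mismatch -1, gap -2) between \code{a} and
#' \code{b}, also trying the reverse complement of \code{b}; the
#' higher-scoring strand is reported. Identity is matches over alignment
#' columns; coverages are the aligned span divided by the shorter
#' (respectively longer) sequence length.
#'
#' @param a,b DNA sequences (character or \code{DNAString}).
#' @return Named numeric: identity, cov_short, cov_long, strand (1 = plus,
#'   -1 = minus).
#' @export
#' @examples
#' pairwiseIdentityCoverage("ACGTACGTACGT", "ACGTACGTACGT")
pairwiseIdentityCoverage <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  if (a == b || a == revcompChar(b))
    return(c(identity = 1, cov_short = 1, cov_long = 1,
             strand = if (a == b) 1 else -1))
  pats <- Biostrings::DNAStringSet(c(b, revcompChar(b)))
  st <- alignStatsBatch(pats, Biostrings::DNAString(a))
  best <- which.max(st$score)
  la <- nchar(a); lb <- nchar(b)
  covA <- st$cov_subject[best]; covB <- st$cov_pattern[best]
  if (la <= lb)
    c(identity = st$identity[best], cov_short = covA, cov_long = covB,
      strand = if (best == 1L) 1 else -1)
  else
    c(identity = st$identity[best], cov_short = covB, cov_long = covA,
      strand = if (best == 1L) 1 else -1)
}

#' Partition contigs by a minimum-length filter
#'
#' @param contigs A \code{ContigSet}.
#' @param minLen Minimum retained length in bp (default 301; contigs of
#'   300 bp and below are removed).
#' @return list(kept, removed): two \code{ContigSet}s forming an exact
#'   partition of the input.
#' @export
filterBySize <- function(contigs, minLen = 301L) {
  keep <- contigLengths(contigs) >= minLen
  list(kept = contigs[keep], removed = contigs[!keep])
}

## Internal: subset a SequenceClusterSet to the given cluster ids.
subsetClusters <- function(x, ids) {
  cl <- x@clusters[x@clusters$cluster_id %in% ids, , drop = FALSE]
  mb <- x@members[x@members$cluster_id %in% ids, , drop = FALSE]
  new("SequenceClusterSet", clusters = cl, members = mb,
      representatives = x@representatives[cl$cluster_id],
      nCohort = x@nCohort)
}

#' Remove size-failing clusters
#'
#' Drops clusters whose representative is shorter than \code{minLen}
#' (clusters represented by sub-threshold sequences).
#'
#' @param clusters A \code{SequenceClusterSet}.
#' @param minLen Minimum representative length (default 301).
#' @return list(kept, removed) of \code{SequenceClusterSet}s.
#' @export
filterClustersBySize <- function(clusters, minLen = 301L) {
  tab <- clusterTable(clusters)
  keep <- tab$cluster_id[tab$rep_length >= minLen]
  list(kept = subsetClusters(clusters, keep),
       removed = subsetClusters(clusters, setdiff(tab$cluster_id, keep)))
}

#' Classify contaminant clusters from BLAST-like hits
#'
#' A cluster is a contaminant iff its representative has a significant
#' (E-value below \code{eThreshold}) hit to a non-primate AND no significant
#' hit to a primate. Clusters without hits are clean.
#'
#' @param clusters A \code{SequenceClusterSet}.
#' @param hits data.frame with columns \code{query_id} (representative contig
#'   name), \code{taxon_group} ("primate" / "non_primate"), \code{e_value}.
#' @param eThreshold Significance threshold on the E-value (default 1e-40).
#' @return list(clean, contaminant) of \code{SequenceClusterSet}s.
#' @export
classifyContaminants <- function(clusters, hits, eThreshold = 1e-40) {
  stopifnot(all(c("query_id", "taxon_group", "e_value") %in% colnames(hits)),
            all(hits$e_value > 0))
  sig <- hits[hits$e_value < eThreshold, , drop = FALSE]
  tab <- clusterTable(clusters)
  nonpr <- unique(sig$query_id[sig$taxon_group == "non_primate"])
  pr <- unique(sig$query_id[sig$taxon_group == "primate"])
  contam <- tab$cluster_id[tab$representative %in% setdiff(nonpr, pr)]
  list(clean = subsetClusters(clusters, setdiff(tab$cluster_id, contam)),
       contaminant = subsetClusters(clusters, contam))
}

## Ungapped (Hamming) identity of two equal-length sequences.
hammingIdentity <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  if (length(ra) != length(rb)) return(0)
  sum(ra == rb) / length(ra)
}

## Equal-length fast path for the join decision. If two equal-length
## sequences agree ungapped at >= 98% identity, the best local alignment
## must satisfy the default join rule: the full-span score is >= 0.96 L, so
## any best-scoring local alignment spans >= 0.96 L (coverage >= 0.96 on
## both) with at most 0.02 L mismatches (identity >= 0.979). Skipping the
## DP therefore never changes the partition (verified against the
## no-shortcut oracle in the tests).
HAMMING_FAST <- 0.98

## Shared k-mer position counts of `kms` against the representative index.
## Returns integer vector of counts per rep id found.
prefilterCounts <- function(kms, kmerIndex) {
  hits <- unlist(mget(kms, envir = kmerIndex, ifnotfound = list(NULL)),
                 use.names = FALSE)
  if (is.null(hits) || length(hits) == 0L) return(integer(0))
  tabulate(hits)
}

#' Greedy identity/coverage clustering of contigs
#'
#' CD-HIT-style greedy clustering: contigs are sorted by decreasing length
#' (ties broken lexicographically by name) and each contig joins the first
#' existing cluster whose representative satisfies identity >= \code{c},
#' coverage of the shorter sequence >= \code{aS} and coverage of the longer
#' sequence >= \code{aL} under the best local alignment on either strand;
#' otherwise it founds a new cluster. The exact word-filter heuristics of
#' CD-HIT are not reproduced; the contract is this documented join rule, and
#' the shared 11-mer prefilter used to skip hopeless representative
#' comparisons is provably conservative for the default thresholds, so the
#' partition equals the brute-force application of the rule.
#'
#' @param contigs A \code{ContigSet} (QC-passed contigs).
#' @param c Minimum identity fraction (default 0.95).
#' @param aS Minimum coverage of the shorter sequence (default 0.90).
#' @param aL Minimum coverage of the longer sequence (default 0.90).
#' @param prefilter Use the conservative shared-k-mer candidate filter
#'   (default TRUE; FALSE forces the O(n^2) comparison schedule).
#' @return A \code{\linkS4class{SequenceClusterSet}} in founding order, with
#'   allele frequencies unset (see \code{\link{clusterAlleleFrequencies}}).
#' @export
greedyCluster <- function(contigs, c = 0.95, aS = 0.90, aL = 0.90,
                          prefilter = TRUE) {
  n <- length(contigs)
  if (n == 0L)
    return(new("SequenceClusterSet",
               clusters = DataFrame(cluster_id = character(0),
                                    representative = character(0),
                                    rep_length = integer(0),
                                    n_members = integer(0),
                                    n_individuals = integer(0),
                                    af = numeric(0)),
               members = DataFrame(contig = character(0),
                                   cluster_id = character(0),
                                   individual = character(0)),
               representatives = Biostrings::DNAStringSet(),
               nCohort = NA_integer_))
  lens <- contigLengths(contigs)
  ord <- order(-lens, names(contigs), method = "radix")
  seqs <- as.character(contigSequences(contigs))[ord]
  nms <- names(contigs)[ord]
  lens <- unname(lens[ord])

  repSeq <- character(0); repName <- character(0); repLen <- integer(0)
  assignment <- integer(n)
  kmerIndex <- new.env(parent = emptyenv())
  k <- PREFILTER_K

  addRepKmers <- function(seq, id) {
    for (km in unique(seqKmers(seq, k))) {
      cur <- kmerIndex[[km]]
      kmerIndex[[km]] <- if (is.null(cur)) id else c(cur, id)
    }
  }

  for (i in seq_len(n)) {
    s <- seqs[i]; rc <- revcompChar(s); L <- lens[i]
    nrep <- length(repSeq)
    cand <- integer(0)
    if (nrep > 0L) {
      if (prefilter && L >= k) {
        ## conservative bound: any pair satisfying the join rule shares at
        ## least max(1, floor(0.32 L) - 11) k-mer positions (see vignette)
        thr <- max(1L, as.integer(floor(0.32 * L)) - 11L)
        cf <- prefilterCounts(seqKmers(s, k), kmerIndex)
        cr <- prefilterCounts(seqKmers(rc, k), kmerIndex)
        m <- max(length(cf), length(cr))
        counts <- integer(m)
        if (length(cf)) counts[seq_along(cf)] <- cf
        if (length(cr))
          counts[seq_along(cr)] <- pmax(counts[seq_along(cr)], cr)
        cand <- which(counts >= thr)
      } else cand <- seq_len(nrep)
    }
    joined <- 0L
    if (length(cand) > 0L) {
      cand <- sort(cand)  # founding order
      nc <- length(cand)
      ## equal-length Hamming fast path (either strand)
      fastOk <- vapply(cand, function(j)
        repLen[j] == L && (hammingIdentity(repSeq[j], s) >= HAMMING_FAST ||
                             hammingIdentity(repSeq[j], rc) >= HAMMING_FAST),
        TRUE)
      firstFast <- if (any(fastOk)) which(fastOk)[1] else nc + 1L
      ## a candidate joins when EITHER strand's alignment satisfies the
      ## rule; DP is only evaluated for candidates that could still win
      ## first-fit (the contig is never longer than the representative
      ## thanks to the length sort)
      passes <- function(st) st$identity >= c & st$cov_subject >= aS &
        st$cov_pattern >= aL
      needDp <- seq_len(min(firstFast - 1L, nc))
      firstF <- nc + 1L
      if (length(needDp) > 0L) {
        okF <- passes(alignStatsBatch(
          Biostrings::DNAStringSet(repSeq[cand[needDp]]),
          Biostrings::DNAString(s)))
        if (any(okF)) firstF <- which(okF)[1]
      }
      needRc <- seq_len(min(firstFast - 1L, firstF - 1L, nc))
      firstR <- nc + 1L
      if (length(needRc) > 0L) {
        okR <- passes(alignStatsBatch(
          Biostrings::DNAStringSet(repSeq[cand[needRc]]),
          Biostrings::DNAString(rc)))
        if (any(okR)) firstR <- which(okR)[1]
      }
      win <- min(firstFast, firstF, firstR)
      if (win <= nc) joined <- cand[win]
    }
    if (joined > 0L) {
      assignment[i] <- joined
    } else {
      repSeq <- c(repSeq, s); repName <- c(repName, nms[i])
      repLen <- c(repLen, L)
      assignment[i] <- length(repSeq)
      if (prefilter) addRepKmers(s, length(repSeq))
    }
  }

  ids <- sprintf("cluster_%05d", seq_along(repName))
  indiv <- splitContigName(nms)$individual
  members <- DataFrame(contig = nms, cluster_id = ids[assignment],
                       individual = indiv)
  nMembers <- tabulate(assignment, nbins = length(repName))
  nIndiv <- vapply(seq_along(repName), function(j)
    length(unique(indiv[assignment == j])), 0L)
  reps <- Biostrings::DNAStringSet(repSeq)
  names(reps) <- ids
  new("SequenceClusterSet",
      clusters = DataFrame(cluster_id = ids, representative = repName,
                           rep_length = repLen, n_members = nMembers,
                           n_individuals = nIndiv,
                           af = rep(NA_real_, length(ids))),
      members = members, representatives = reps, nCohort = NA_integer_)
}

#' Compute cluster allele frequencies
#'
#' The allele frequency of a cluster is the number of distinct individuals
#' among its members divided by the cohort size; a cluster is "rare" when its
#' frequency is below 5\%.
#'
#' @param clusters A \code{SequenceClusterSet}.
#' @param nIndividuals Cohort size N.
#' @return The \code{SequenceClusterSet} with \code{af} filled in and the
#'   cohort size recorded.
#' @export
clusterAlleleFrequencies <- function(clusters, nIndividuals) {
  stopifnot(nIndividuals >= 1L)
  tab <- clusters@clusters
  if (any(tab$n_individuals > nIndividuals))
    stop("a cluster has more member individuals than the cohort size")
  tab$af <- tab$n_individuals / nIndividuals
  new("SequenceClusterSet", clusters = tab, members = clusters@members,
      representatives = clusters@representatives,
      nCohort = as.integer(nIndividuals))
}

#' Fraction of rare clusters and the frequency histogram
#'
#' @param clusters A \code{SequenceClusterSet} with allele frequencies set.
#' @param threshold Rarity threshold (default 0.05; rare means AF < 5\%).
#' @param breaks Histogram bin edges on the AF axis.
#' @return list(fraction_rare, histogram) where histogram is a data.frame of
#'   bin edges and cluster counts.
#' @export
afSummary <- function(clusters, threshold = 0.05,
                      breaks = c(0, 0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1)) {
  af <- alleleFrequencies(clusters)
  stopifnot(!anyNA(af))
  h <- graphics::hist(af, breaks = breaks, plot = FALSE, right = FALSE)
  list(fraction_rare = mean(af < threshold),
       histogram = data.frame(lower = utils::head(breaks, -1),
                              upper = utils::tail(breaks, -1),
                              count = h$counts))
}

#' Write cluster output files
#'
#' Emits a CD-HIT \file{.clstr}-style text file plus a TSV summary
#' (cluster_id, representative, rep_length, n_members, n_individuals, af).
#'
#' @param clusters A \code{SequenceClusterSet}.
#' @param prefix Output path prefix; writes \code{<prefix>.clstr} and
#'   \code{<prefix>.tsv}.
#' @return The two paths, invisibly.
#' @export
writeClusters <- function(clusters, prefix) {
  tab <- as.data.frame(clusterTable(clusters))
  mb <- as.data.frame(clusterMembers(clusters))
  con <- file(paste0(prefix, ".clstr"), "w")
  for (i in seq_len(nrow(tab))) {
    writeLines(paste0(">Cluster ", i - 1L), con)
    m <- mb[mb$cluster_id == tab$cluster_id[i], , drop = FALSE]
    rep1 <- m$contig == tab$representative[i]
    writeLines(sprintf("%d\t%s %s", seq_len(nrow(m)) - 1L,
                       paste0(m$contig, "..."),
                       ifelse(rep1, "*", "at +/100.00%")), con)
  }
  close(con)
  utils::write.table(tab, paste0(prefix, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(paste0(prefix, ".clstr"), paste0(prefix, ".tsv")))
}
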