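## Alignment of cluster representatives to references and NS classification.
##
## The aligner is a minimal k-mer anchor chainer: exact 31-mer matches on
## both strands are grouped per (target, strand) into diagonal bands (+-50
## bp, single linkage on the diagonal), each band is extended ungapped along
## its anchor-supported diagonal and reported as one hit with identity over
## the extended columns and query coverage = extended span / query length.
## Gapped chaining across large indels is out of scope; for the short,
## mostly colinear sequences handled here the ungapped caveat is documented
## in the vignette.

#' Classification thresholds
#'
#' Confident alignment requires identity > 95 and query coverage > 90
#' (strict inequalities; boundary values fail). A cluster is a novel
#' sequence (NS) iff no hit against the designated human reference has
#' identity > 80 AND coverage > 50.
#'
#' @param confidentIdentity,confidentCoverage thresholds (percent) for a
#'   confident alignment.
#' @param nsIdentity,nsCoverage per-hit thresholds (percent) for a
#'   significant (NS-blocking) match.
#' @return Named numeric vector of the four thresholds.
#' @export
classificationThresholds <- function(confidentIdentity = 95,
                                     confidentCoverage = 90,
                                     nsIdentity = 80, nsCoverage = 50) {
  stopifnot(nsIdentity <= confidentIdentity, nsCoverage <= confidentCoverage,
            confidentIdentity <= 100, confidentCoverage <= 100,
            nsIdentity > 0, nsCoverage > 0)
  c(confident_identity = confidentIdentity,
    confident_coverage = confidentCoverage,
    ns_identity = nsIdentity, ns_coverage = nsCoverage)
}

emptyHits <- function() {
  data.frame(query_id = character(0), target_id = character(0),
             query_start = integer(0), query_end = integer(0),
             target_start = integer(0), target_end = integer(0),
             strand = character(0), identity_pct = numeric(0),
             query_cov_pct = numeric(0), n_anchors = integer(0),
             stringsAsFactors = FALSE)
}

## Anchors of `qseq` (character) against one target sequence; returns
## data.frame(qpos, tpos) of 0-based k-mer start positions. Seeds occurring
## more than maxOcc times in the target are masked (repeat-seed masking).
anchorPositions <- function(qkmers, target, maxOcc) {
  pd <- Biostrings::PDict(qkmers)
  mi <- Biostrings::matchPDict(pd, target)
  counts <- S4Vectors::elementNROWS(mi)
  use <- which(counts > 0L & counts <= maxOcc)
  if (length(use) == 0L) return(data.frame(qpos = integer(0), tpos = integer(0)))
  tpos <- Biostrings::startIndex(mi)[use]
  data.frame(qpos = rep(use - 1L, lengths(tpos)),
             tpos = unlist(tpos, use.names = FALSE) - 1L)
}

## Chain anchors of one (target, strand) into diagonal bands and emit hits.
chainBand <- function(anchors, qseq, tseq, k, bandWidth, L) {
  d <- anchors$tpos - anchors$qpos
  o <- order(d)
  d <- d[o]; qp <- anchors$qpos[o]
  brk <- c(0L, which(diff(d) > bandWidth), length(d))
  out <- vector("list", length(brk) - 1L)
  tlen <- nchar(tseq)
  for (b in seq_len(length(brk) - 1L)) {
    sel <- (brk[b] + 1L):brk[b + 1L]
    ## representative diagonal: the most anchor-supported one (ties: smallest)
    dt <- table(d[sel])
    d0 <- as.integer(names(dt)[which.max(dt)])
    ## ungapped extension to the full query extent, clipped to the target
    qlo <- max(0L, -d0)
    qhi <- min(L, tlen - d0)
    if (qhi - qlo < k) next
    qs <- substring(qseq, qlo + 1L, qhi)
    ts <- substring(tseq, qlo + d0 + 1L, qhi + d0)
    matches <- sum(strsplit(qs, "")[[1]] == strsplit(ts, "")[[1]])
    cols <- qhi - qlo
    out[[b]] <- data.frame(query_start = qlo, query_end = qhi,
                           target_start = qlo + d0, target_end = qhi + d0,
                           identity_pct = 100 * matches / cols,
                           query_cov_pct = 100 * cols / L,
                           n_anchors = length(sel))
  }
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}

#' Align a query against a reference sequence set
#'
#' Minimal anchor aligner (see the file-level description): exact
#' \code{k}-mer anchors on both strands are chained per (target, strand,
#' diagonal band of +-\code{bandWidth} bp), each band extended ungapped and
#' reported as one hit. Hits are sorted by descending query coverage.
#'
#' @param query Query sequence (character or \code{DNAString}).
#' @param reference Named \code{DNAStringSet} (or named character vector) of
#'   target sequences.
#' @param k Anchor length (default 31).
#' @param bandWidth Diagonal tolerance within a chain (default 50 bp).
#' @param maxOcc Seed-masking threshold: k-mers occurring more often than
#'   this in a target are not used as anchors (default 100).
#' @param queryId Query name placed in the output (default "query").
#' @return data.frame of hits with 0-based half-open coordinates: query_id,
#'   target_id, query_start, query_end, target_start, target_end, strand,
#'   identity_pct, query_cov_pct, n_anchors. Minus-strand hits report query
#'   coordinates on the original (plus) query. Empty (with a warning) when
#'   the query is shorter than \code{k}.
#' @export
alignToReference <- function(query, reference, k = 31L, bandWidth = 50L,
                             maxOcc = 100L, queryId = "query") {
  qseq <- toupper(as.character(query))
  L <- nchar(qseq)
  if (L < k) {
    warning("query shorter than k = ", k, "; no hits")
    return(emptyHits())
  }
  if (is.character(reference)) {
    nm <- names(reference)
    reference <- Biostrings::DNAStringSet(reference)
    names(reference) <- nm
  }
  stopifnot(!is.null(names(reference)))
  qk <- Biostrings::DNAStringSet(seqKmers(qseq, k))
  rcq <- revcompChar(qseq)
  qkrc <- Biostrings::DNAStringSet(seqKmers(rcq, k))
  hits <- list()
  for (t in names(reference)) {
    tseq <- as.character(reference[[t]])
    for (strand in c("+", "-")) {
      qs <- if (strand == "+") qseq else rcq
      anc <- anchorPositions(if (strand == "+") qk else qkrc,
                             reference[[t]], maxOcc)
      if (nrow(anc) == 0L) next
      h <- chainBand(anc, qs, tseq, k, bandWidth, L)
      if (is.null(h) || nrow(h) == 0L) next
      if (strand == "-") {
        qs0 <- h$query_start
        h$query_start <- L - h$query_end
        h$query_end <- L - qs0
      }
      h$query_id <- queryId; h$target_id <- t; h$strand <- strand
      hits[[length(hits) + 1L]] <- h
    }
  }
  if (length(hits) == 0L) return(emptyHits())
  out <- do.call(rbind, hits)
  out <- out[order(-out$query_cov_pct, -out$identity_pct, out$target_id,
                   out$target_start), ]
  rownames(out) <- NULL
  out[, colnames(emptyHits())]
}

#' Classify clusters from per-reference alignment hits
#'
#' A reference is confidently hit iff some hit has identity > 95 AND
#' coverage > 90 (strict). A cluster is NS iff no hit against the designated
#' human reference has identity > 80 AND coverage > 50: a hit with, say,
#' identity 85 but coverage 30 is not a significant match and does not block
#' NS status. Clusters absent from \code{hits} have no hits anywhere and are
#' NS.
#'
#' @param hits data.frame with columns cluster_id, reference, identity_pct,
#'   query_cov_pct (and optionally target_id, target_start, target_end).
#' @param clusterIds Character vector of all cluster ids (the classification
#'   universe).
#' @param humanRef Name of the human reference in \code{hits$reference}.
#' @param thresholds Output of \code{\link{classificationThresholds}}.
#' @return list with elements \code{classification} (data.frame cluster_id,
#'   is_ns), \code{confident} (data.frame cluster_id, reference pairs) and
#'   \code{best} (best hit per cluster and reference: maximum coverage, ties
#'   by identity, then leftmost target position).
#' @export
classifyClusters <- function(hits, clusterIds, humanRef = "human",
                             thresholds = classificationThresholds()) {
  stopifnot(all(c("cluster_id", "reference", "identity_pct",
                  "query_cov_pct") %in% colnames(hits)))
  unknown <- setdiff(unique(hits$cluster_id), clusterIds)
  if (length(unknown) > 0L)
    stop("hits refer to unknown cluster(s): ",
         paste(utils::head(unknown, 3L), collapse = ", "))
  conf <- hits[hits$identity_pct > thresholds["confident_identity"] &
                 hits$query_cov_pct > thresholds["confident_coverage"], ,
               drop = FALSE]
  confident <- unique(conf[, c("cluster_id", "reference")])
  rownames(confident) <- NULL
  blocking <- hits[hits$reference == humanRef &
                     hits$identity_pct > thresholds["ns_identity"] &
                     hits$query_cov_pct > thresholds["ns_coverage"], ,
                   drop = FALSE]
  isNs <- !(clusterIds %in% blocking$cluster_id)
  if (!"target_start" %in% colnames(hits))
    hits$target_start <- rep(NA_integer_, nrow(hits))
  if (!"target_id" %in% colnames(hits))
    hits$target_id <- rep(NA_character_, nrow(hits))
  o <- order(hits$cluster_id, hits$reference, -hits$query_cov_pct,
             -hits$identity_pct, hits$target_start)
  hs <- hits[o, , drop = FALSE]
  best <- hs[!duplicated(hs[, c("cluster_id", "reference")]), , drop = FALSE]
  rownames(best) <- NULL
  list(classification = data.frame(cluster_id = clusterIds, is_ns = isNs,
                                   stringsAsFactors = FALSE),
       confident = confident, best = best)
}

#' Cross-catalog membership sets
#'
#' For each cluster, the subset of references it aligns to confidently, plus
#' aggregate counts per subset (the membership-diagram set sizes) and the
#' number of clusters confident in at least one reference.
#'
#' @param confident data.frame of (cluster_id, reference) confident pairs, as
#'   returned by \code{\link{classifyClusters}}.
#' @param clusterIds All cluster ids.
#' @param references Reference names defining the subset universe (defaults
#'   to those present in \code{confident}).
#' @return list(membership, counts, n_any): per-cluster subset string
#'   ("+"-joined sorted reference names, "" for none), a table of subset
#'   sizes, and the count of clusters confident somewhere.
#' @export
catalogMembership <- function(confident, clusterIds,
                              references = sort(unique(confident$reference))) {
  stopifnot(all(confident$reference %in% references))
  subsets <- vapply(clusterIds, function(cl) {
    refs <- sort(intersect(references,
                           confident$reference[confident$cluster_id == cl]))
    paste(refs, collapse = "+")
  }, "")
  counts <- table(factor(subsets))
  list(membership = data.frame(cluster_id = clusterIds, subset = unname(subsets),
                               stringsAsFactors = FALSE),
       counts = as.data.frame(counts, responseName = "n",
                              stringsAsFactors = FALSE),
       n_any = sum(subsets != ""))
}

#' Bin confidently placed clusters along a reference
#'
#' Each placed cluster is assigned to the fixed-size bin containing its best
#' hit's target midpoint; reports per-bin percentage density and the
#' fraction of empty bins.
#'
#' @param best data.frame of one best hit per cluster on one reference
#'   (needs target_id, target_start, target_end).
#' @param chromLengths Named integer vector of target sequence lengths.
#' @param binSize Bin width in bp (default 3e6).
#' @return list(bins, zero_bin_fraction): per-bin data.frame (target, bin
#'   start, count, density_pct) over all bins of all targets, and the
#'   fraction with zero clusters.
#' @export
binPositions <- function(best, chromLengths, binSize = 3000000L) {
  stopifnot(!is.null(names(chromLengths)))
  binSize <- as.integer(binSize)
  allBins <- do.call(rbind, lapply(names(chromLengths), function(ch) {
    starts <- seq(0L, max(0L, chromLengths[[ch]] - 1L), by = binSize)
    data.frame(target = ch, bin_start = starts, stringsAsFactors = FALSE)
  }))
  allBins$count <- 0L
  if (nrow(best) > 0L) {
    mid <- as.integer((best$target_start + best$target_end) %/% 2)
    binStart <- as.integer(mid %/% binSize) * as.integer(binSize)
    key <- paste(best$target_id, binStart)
    tb <- table(key)
    idx <- match(names(tb), paste(allBins$target, allBins$bin_start))
    if (anyNA(idx)) stop("best hit outside the provided chromosome lengths")
    allBins$count[idx] <- as.integer(tb)
  }
  total <- sum(allBins$count)
  allBins$density_pct <- if (total > 0) 100 * allBins$count / total else 0
  list(bins = allBins, zero_bin_fraction = mean(allBins$count == 0L))
}

#' Subset clusters by minimum allele frequency
#'
#' Retains clusters with AF >= \code{minAf} (boundary inclusive: "minimum
#' allele frequency"). Subsets are nested in the threshold.
#'
#' @param clusters A \code{SequenceClusterSet} with frequencies set.
#' @param minAf Minimum allele frequency.
#' @return A \code{SequenceClusterSet}.
#' @export
subsetByAF <- function(clusters, minAf) {
  af <- alleleFrequencies(clusters)
  stopifnot(!anyNA(af))
  subsetClusters(clusters, names(af)[af >= minAf])
}
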