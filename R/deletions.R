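## Ancestral-deletion analysis: deletions called against a chimp-like
## reference are quality-filtered, merged across individuals by reciprocal
## overlap (single linkage), intersected with NS intervals, checked for
## novelty versus the human reference, and summarized as chimpanzee
## reference allele (CRA) carrier frequencies.

#' Filter deletion records to PASS deletions
#'
#' Keeps records with \code{filter_status == "PASS"} and
#' \code{svtype == "DEL"}.
#'
#' @param records data.frame as from \code{\link{readDeletionVcf}}.
#' @return The filtered data.frame, with attribute \code{removed} giving the
#'   counts of records dropped by each predicate.
#' @export
filterDeletions <- function(records) {
  keep <- records$filter_status == "PASS" & records$svtype == "DEL"
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- c(
    non_pass = sum(records$filter_status != "PASS"),
    non_del = sum(records$svtype != "DEL"))
  out
}

#' Merge deletions across individuals by reciprocal overlap
#'
#' Two deletions are linked iff their overlap covers at least
#' \code{minOverlap} of BOTH intervals (reciprocal overlap); merged variants
#' are the connected components under single linkage. The representative
#' coordinates come from the longest member (ties: leftmost), and each
#' individual keeps one genotype per merged variant, the most deleted one
#' (hom_alt > het > missing > hom_ref) if it contributed several calls.
#'
#' @param records data.frame of deletion records (individual, chrom, start,
#'   end, genotype).
#' @param minOverlap Reciprocal overlap threshold (default 0.7).
#' @return data.frame of merged deletions: variant_id, chrom, start, end,
#'   n_calls, n_individuals, plus a \code{genotypes} list-column of named
#'   per-individual genotype vectors.
#' @export
mergeDeletions <- function(records, minOverlap = 0.7) {
  n <- nrow(records)
  if (n == 0L)
    return(data.frame(variant_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_calls = integer(0), n_individuals = integer(0)))
  gr <- GenomicRanges::GRanges(records$chrom,
                               IRanges::IRanges(records$start + 1L,
                                                records$end))
  ov <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                    drop.redundant = TRUE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  if (length(qh) > 0L) {
    w <- overlapLen(records$start[qh], records$end[qh],
                    records$start[sh], records$end[sh])
    la <- records$end[qh] - records$start[qh]
    lb <- records$end[sh] - records$start[sh]
    ok <- w / la >= minOverlap & w / lb >= minOverlap
    qh <- qh[ok]; sh <- sh[ok]
  }
  ## single-linkage components via union-find
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_along(qh)) {
    a <- find(qh[i]); b <- find(sh[i])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  comp <- vapply(seq_len(n), find, 0L)
  gtRank <- c(hom_alt = 3L, het = 2L, missing = 1L, hom_ref = 0L)
  out <- lapply(unique(comp), function(cc) {
    m <- records[comp == cc, , drop = FALSE]
    len <- m$end - m$start
    rep1 <- order(-len, m$start)[1]
    gts <- vapply(split(m$genotype, m$individual), function(g)
      g[which.max(gtRank[g])], "")
    df <- data.frame(chrom = m$chrom[rep1], start = m$start[rep1],
                     end = m$end[rep1], n_calls = nrow(m),
                     n_individuals = length(gts), stringsAsFactors = FALSE)
    df$genotypes <- list(gts)
    df
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  out <- cbind(variant_id = sprintf("delvar_%04d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Intersect merged deletions with NS intervals
#'
#' Attaches the set of NS ids sharing at least one base with each merged
#' deletion (half-open arithmetic); deletions overlapping no NS are dropped
#' from downstream CRA analysis when \code{drop = TRUE}.
#'
#' @param merged data.frame from \code{\link{mergeDeletions}}.
#' @param nsIntervals data.frame (chrom, start, end, ns_id) of NS positions
#'   on the chimp-like reference, or a \code{GRanges} with a \code{label}
#'   column.
#' @param drop Drop deletions with no overlapping NS (default TRUE).
#' @return \code{merged} with an \code{overlapping_ns} list-column.
#' @export
intersectWithNS <- function(merged, nsIntervals, drop = TRUE) {
  if (methods::is(nsIntervals, "GRanges"))
    nsIntervals <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(nsIntervals)),
      start = GenomicRanges::start(nsIntervals) - 1L,
      end = GenomicRanges::end(nsIntervals),
      ns_id = S4Vectors::mcols(nsIntervals)$label,
      stringsAsFactors = FALSE)
  merged$overlapping_ns <- lapply(seq_len(nrow(merged)), function(i) {
    sel <- nsIntervals$chrom == merged$chrom[i] &
      nsIntervals$start < merged$end[i] & nsIntervals$end > merged$start[i]
    unique(nsIntervals$ns_id[sel])
  })
  if (drop) merged <- merged[lengths(merged$overlapping_ns) > 0L, ,
                             drop = FALSE]
  rownames(merged) <- NULL
  merged
}

#' Flag merged deletions as novel versus the human reference
#'
#' The novelty status table maps chimp-reference intervals to
#' \code{"deleted_in_new"} (the interval has no human counterpart; the
#' liftover verdict consumed as a flag) or \code{"lifts_over"}. A merged
#' deletion is novel iff it overlaps a \code{deleted_in_new} interval.
#' Non-novel deletions are excluded from CRA reporting when
#' \code{drop = TRUE}.
#'
#' @param merged data.frame of merged deletions.
#' @param noveltyTable data.frame (chrom, start, end, status).
#' @param drop Drop non-novel deletions (default TRUE).
#' @return \code{merged} with a logical \code{novel_vs_human} column.
#' @export
checkNovelty <- function(merged, noveltyTable, drop = TRUE) {
  stopifnot(all(c("chrom", "start", "end", "status") %in%
                  colnames(noveltyTable)),
            all(noveltyTable$status %in% c("deleted_in_new", "lifts_over")))
  del <- noveltyTable[noveltyTable$status == "deleted_in_new", , drop = FALSE]
  merged$novel_vs_human <- vapply(seq_len(nrow(merged)), function(i) {
    any(del$chrom == merged$chrom[i] & del$start < merged$end[i] &
          del$end > merged$start[i])
  }, TRUE)
  if (drop) merged <- merged[merged$novel_vs_human, , drop = FALSE]
  rownames(merged) <- NULL
  merged
}

#' CRA carrier counts and frequencies
#'
#' The chimpanzee reference allele (CRA) is carried by every individual
#' retaining at least one copy of the deleted sequence: those heterozygous,
#' hom-ref or without a deletion call. Carriers = N - #hom_alt; individuals
#' absent from the genotype map and missing genotypes count as carriers.
#' Also emits an allele-frequency estimate (2N - 2 hom_alt - het) / 2N for
#' completeness.
#'
#' @param merged data.frame from \code{\link{mergeDeletions}} (with the
#'   \code{genotypes} list-column).
#' @param nIndividuals Cohort size N.
#' @param commonThreshold Carrier frequency above which the CRA is called
#'   common (default 0.05, strict >).
#' @return \code{merged} with columns cra_carriers, cra_carrier_freq,
#'   cra_allele_freq and common.
#' @export
craFrequency <- function(merged, nIndividuals, commonThreshold = 0.05) {
  stopifnot(nIndividuals >= 1L)
  nHom <- vapply(merged$genotypes, function(g) sum(g == "hom_alt"), 0L)
  nHet <- vapply(merged$genotypes, function(g) sum(g == "het"), 0L)
  if (any(vapply(merged$genotypes, length, 0L) > nIndividuals))
    stop("genotype map larger than the cohort")
  merged$cra_carriers <- nIndividuals - nHom
  merged$cra_carrier_freq <- merged$cra_carriers / nIndividuals
  merged$cra_allele_freq <-
    (2 * nIndividuals - 2 * nHom - nHet) / (2 * nIndividuals)
  merged$common <- merged$cra_carrier_freq > commonThreshold
  merged
}
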