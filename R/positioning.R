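## Population-level insertion merging (1-D DBSCAN) and genomic-feature
## enrichment by region simulation + binomial tests.

#' One-dimensional DBSCAN
#'
#' Standard DBSCAN on the line. A core point has at least
#' \code{minNeighbors} OTHER points within \code{eps} (the point itself is
#' not counted). Clusters are the connected components of core points (cores
#' within \code{eps} of each other are linked); border points (non-core
#' within \code{eps} of a core) join the cluster of the first core reached
#' in left-to-right order (their leftmost core neighbour). All remaining
#' points are noise, labeled -1.
#'
#' @param positions Integer (or numeric) positions.
#' @param eps Neighbourhood radius (default 150).
#' @param minNeighbors Minimum number of other points within \code{eps} for
#'   a core point (default 3).
#' @return Integer labels in input order: cluster numbers 1, 2, ... in
#'   left-to-right order of cluster start, or -1 for noise.
#' @export
#' @examples
#' dbscan1d(c(0, 50, 100, 160))          # one cluster of four
#' dbscan1d(c(0, 1000, 2000))            # all noise
dbscan1d <- function(positions, eps = 150, minNeighbors = 3L) {
  n <- length(positions)
  if (n == 0L) return(integer(0))
  o <- order(positions)
  p <- positions[o]
  ## neighbours within eps via sorted two-pointer bounds
  lo <- findInterval(p - eps, p, left.open = TRUE) + 1L
  hi <- findInterval(p + eps, p)
  nNeigh <- hi - lo  # excludes the point itself
  core <- nNeigh >= minNeighbors
  lab <- rep(-1L, n)
  cid <- 0L
  lastCorePos <- -Inf; lastCoreLab <- -1L
  for (i in seq_len(n)) {
    if (!core[i]) next
    if (p[i] - lastCorePos <= eps) {
      lab[i] <- lastCoreLab
    } else {
      cid <- cid + 1L
      lab[i] <- cid
    }
    lastCorePos <- p[i]; lastCoreLab <- lab[i]
  }
  ## border points: leftmost core within eps
  corePos <- p[core]; coreLab <- lab[core]
  if (length(corePos) > 0L) {
    for (i in which(!core)) {
      j <- findInterval(p[i] - eps, corePos, left.open = TRUE) + 1L
      if (j <= length(corePos) && corePos[j] <= p[i] + eps)
        lab[i] <- coreLab[j]
    }
  }
  out <- integer(n)
  out[o] <- lab
  out
}

#' Merge per-individual insertion calls into population events
#'
#' Pipeline: calls whose NS matches the human reference are dropped; the
#' rest are grouped by (chromosome, NS) so only insertions of the same NS
#' merge; each group is clustered with \code{\link{dbscan1d}}; clusters with
#' fewer than \code{minIndividuals} distinct individuals are discarded; and
#' hybrid events -- surviving clusters of DIFFERENT NS whose spans come
#' within \code{eps} of each other on the same chromosome -- are all
#' removed.
#'
#' @param calls data.frame: individual, chrom, position (0-based bp), ns_id.
#' @param classification data.frame with \code{cluster_id} (the NS ids used
#'   in \code{calls}) and \code{matches_human} (logical: confidently present
#'   in the human reference); unknown ns ids in \code{calls} are an error.
#' @param eps,minNeighbors DBSCAN parameters (defaults 150 bp, 3).
#' @param minIndividuals Minimum distinct carriers per merged event
#'   (default 5).
#' @return data.frame of merged insertions: chrom, start, end (the
#'   breakpoint span as a half-open interval of length >= 1), ns_id,
#'   n_individuals, n_calls, individuals (comma-collapsed).
#' @export
mergeInsertions <- function(calls, classification, eps = 150,
                            minNeighbors = 3L, minIndividuals = 5L) {
  stopifnot(all(c("individual", "chrom", "position", "ns_id") %in%
                  colnames(calls)))
  unknown <- setdiff(unique(calls$ns_id), classification$cluster_id)
  if (length(unknown) > 0L)
    stop("insertion call with unknown NS id: ",
         paste(utils::head(unknown, 3L), collapse = ", "))
  drop <- classification$cluster_id[classification$matches_human]
  calls <- calls[!(calls$ns_id %in% drop), , drop = FALSE]
  if (nrow(calls) == 0L) return(emptyMerged())
  out <- list()
  for (key in unique(paste(calls$chrom, calls$ns_id, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    g <- calls[calls$chrom == parts[1] & calls$ns_id == parts[2], ,
               drop = FALSE]
    lab <- dbscan1d(g$position, eps = eps, minNeighbors = minNeighbors)
    for (l in setdiff(unique(lab), -1L)) {
      m <- g[lab == l, , drop = FALSE]
      ind <- unique(m$individual)
      if (length(ind) < minIndividuals) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = parts[1], start = min(m$position),
        end = max(m$position) + 1L, ns_id = parts[2],
        n_individuals = length(ind), n_calls = nrow(m),
        individuals = paste(sort(ind), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(emptyMerged())
  ev <- do.call(rbind, out)
  ## hybrid removal: events of different NS whose spans come within eps
  keep <- rep(TRUE, nrow(ev))
  for (i in seq_len(nrow(ev))) {
    near <- ev$chrom == ev$chrom[i] & ev$ns_id != ev$ns_id[i] &
      ev$start <= ev$end[i] + eps & ev$end >= ev$start[i] - eps
    if (any(near)) keep[i] <- FALSE
  }
  ev <- ev[keep, , drop = FALSE]
  ev <- ev[order(ev$chrom, ev$start, ev$ns_id), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

emptyMerged <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             ns_id = character(0), n_individuals = integer(0),
             n_calls = integer(0), individuals = character(0),
             stringsAsFactors = FALSE)
}

#' Intersect events with a feature track
#'
#' Half-open interval arithmetic: two intervals overlap iff they share at
#' least one base; touching intervals ([10,20) vs [20,30)) do not overlap.
#'
#' @param events data.frame with chrom, start, end (0-based half-open) and
#'   optionally ns_id.
#' @param features data.frame with chrom, start, end (or a \code{GRanges};
#'   converted internally).
#' @return list(pairs, n_overlapping, unique_ns): the overlap pair indices
#'   (event, feature), the number of events overlapping >= 1 feature, and
#'   the number of distinct ns ids among them (NA when events carry no
#'   ns_id).
#' @export
intersectFeatures <- function(events, features) {
  if (methods::is(features, "GRanges"))
    features <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(features)),
      start = GenomicRanges::start(features) - 1L,
      end = GenomicRanges::end(features), stringsAsFactors = FALSE)
  if (nrow(events) == 0L || nrow(features) == 0L)
    return(list(pairs = data.frame(event = integer(0), feature = integer(0)),
                n_overlapping = 0L, unique_ns = 0L))
  lev <- unique(c(events$chrom, features$chrom))
  ge <- GenomicRanges::GRanges(factor(events$chrom, lev),
                               IRanges::IRanges(events$start + 1L,
                                                events$end))
  gf <- GenomicRanges::GRanges(factor(features$chrom, lev),
                               IRanges::IRanges(features$start + 1L,
                                                features$end))
  ov <- GenomicRanges::findOverlaps(ge, gf)
  qh <- S4Vectors::queryHits(ov)
  un <- if ("ns_id" %in% colnames(events))
    length(unique(events$ns_id[unique(qh)])) else NA_integer_
  list(pairs = data.frame(event = qh, feature = S4Vectors::subjectHits(ov)),
       n_overlapping = length(unique(qh)), unique_ns = un)
}

#' Null overlap fraction by region simulation
#'
#' For \code{iterations} iterations, draws \code{nRegions} regions of
#' \code{regionSize} bp uniformly across the genome (chromosome chosen with
#' probability proportional to its number of valid start positions, start
#' uniform over them) and computes the fraction of all drawn regions
#' overlapping at least one feature interval. The binomial null probability
#' is the pooled fraction over all iterations x regions; the per-iteration
#' structure is kept only for a Monte-Carlo standard error.
#'
#' @param chromLengths Named integer vector of chromosome lengths.
#' @param features Feature track (data.frame chrom/start/end 0-based
#'   half-open, or \code{GRanges}).
#' @param nRegions Regions per iteration (the observed event count).
#' @param regionSize Region size in bp (default 1000).
#' @param iterations Number of iterations (default 10000).
#' @param seed Seed.
#' @return list(simulated_pct, se_pct, n_draws).
#' @export
simulateNullOverlap <- function(chromLengths, features, nRegions,
                                regionSize = 1000L, iterations = 10000L,
                                seed = 1L) {
  stopifnot(regionSize <= min(chromLengths), nRegions >= 1L)
  if (methods::is(features, "GRanges"))
    features <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(features)),
      start = GenomicRanges::start(features) - 1L,
      end = GenomicRanges::end(features), stringsAsFactors = FALSE)
  lev <- unique(c(names(chromLengths), features$chrom))
  gf <- if (nrow(features) > 0L)
    GenomicRanges::GRanges(factor(features$chrom, lev),
                           IRanges::IRanges(features$start + 1L,
                                            features$end)) else NULL
  nValid <- chromLengths - regionSize + 1L
  prob <- nValid / sum(as.numeric(nValid))
  perIter <- numeric(iterations)
  withSubstream(seed, "null_overlap", {
    chunk <- max(1L, min(iterations, ceiling(200000 / nRegions)))
    done <- 0L
    while (done < iterations) {
      it <- min(chunk, iterations - done)
      nd <- it * nRegions
      chrom <- sample(names(chromLengths), nd, replace = TRUE, prob = prob)
      start0 <- floor(stats::runif(nd, 0, nValid[chrom]))
      hit <- if (is.null(gf)) rep(FALSE, nd) else
        IRanges::overlapsAny(
          GenomicRanges::GRanges(factor(chrom, lev),
                                 IRanges::IRanges(start0 + 1L,
                                                  width = regionSize)), gf)
      perIter[done + seq_len(it)] <-
        colMeans(matrix(hit, nrow = nRegions))
      done <- done + it
    }
  })
  pooled <- mean(perIter)
  list(simulated_pct = 100 * pooled,
       se_pct = 100 * stats::sd(perIter) / sqrt(iterations),
       n_draws = as.numeric(iterations) * nRegions)
}

#' Exact binomial test of observed versus simulated overlap
#'
#' Two-sided exact binomial test of \code{k} overlapping events out of
#' \code{n} against the simulated null probability.
#'
#' @param observedK Number of events overlapping the feature.
#' @param n Total number of events.
#' @param simulatedPct Null overlap percentage (0-100).
#' @return list(p_value, direction): direction is "enriched", "depleted" or
#'   "none" (observed fraction exactly equal to the null).
#' @export
binomialEnrichment <- function(observedK, n, simulatedPct) {
  stopifnot(n > 0L, observedK >= 0L, observedK <= n,
            simulatedPct >= 0, simulatedPct <= 100)
  p0 <- simulatedPct / 100
  p <- stats::binom.test(observedK, n, p = p0,
                         alternative = "two.sided")$p.value
  frac <- observedK / n
  dir <- if (frac > p0) "enriched" else if (frac < p0) "depleted" else "none"
  list(p_value = p, direction = dir)
}

#' Feature enrichment table for a set of events
#'
#' For each feature track: counts the events overlapping the track and the
#' distinct NS involved, simulates the null overlap fraction with
#' \code{\link{simulateNullOverlap}} (n = the observed event count, regions
#' of \code{regionSize} bp) and tests the difference with
#' \code{\link{binomialEnrichment}}.
#'
#' @param events data.frame of events (chrom, start, end, ns_id).
#' @param featureTracks Named list of feature tracks.
#' @param chromLengths Named chromosome lengths.
#' @param regionSize,iterations,seed Simulation parameters.
#' @return data.frame with one row per track: feature, unique_ns,
#'   observed_events, observed_pct, simulated_pct, p_value, direction.
#' @export
featureEnrichment <- function(events, featureTracks, chromLengths,
                              regionSize = 1000L, iterations = 10000L,
                              seed = 1L) {
  stopifnot(nrow(events) > 0L, length(featureTracks) > 0L,
            !is.null(names(featureTracks)))
  n <- nrow(events)
  rows <- lapply(names(featureTracks), function(nm) {
    ix <- intersectFeatures(events, featureTracks[[nm]])
    sim <- simulateNullOverlap(chromLengths, featureTracks[[nm]],
                               nRegions = n, regionSize = regionSize,
                               iterations = iterations,
                               seed = substreamSeed(seed, nm))
    be <- binomialEnrichment(ix$n_overlapping, n, sim$simulated_pct)
    data.frame(feature = nm, unique_ns = ix$unique_ns,
               observed_events = ix$n_overlapping,
               observed_pct = 100 * ix$n_overlapping / n,
               simulated_pct = sim$simulated_pct, p_value = be$p_value,
               direction = be$direction, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
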