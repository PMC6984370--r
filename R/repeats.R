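## Repeat-class composition and the nonparametric permutation enrichment
## test. Percentages are base-weighted (pooled bases over the whole set),
## not per-contig means.

## Per-sequence base counts over the class vocabulary, Unmasked implicit.
## `annotations`: named list of data.frame(start, end, class) (0-based
## half-open, non-overlapping); `seqLengths`: named lengths covering them.
#' Per-sequence repeat-class base-count matrix
#'
#' @param annotations Named list (one per sequence) of data.frames with
#'   0-based half-open \code{start}, \code{end} and \code{class} columns of
#'   non-overlapping annotated intervals (the output of
#'   \code{\link{readRepeatMaskerOut}} or the simulator's truth).
#' @param seqLengths Named integer vector of sequence lengths.
#' @return Integer matrix, one row per sequence and one column per class in
#'   \code{\link{repeatClasses}}; \code{Unmasked} is the per-sequence
#'   complement of the annotated bases.
#' @export
repeatBaseMatrix <- function(annotations, seqLengths) {
  stopifnot(all(names(annotations) %in% names(seqLengths)))
  ids <- names(seqLengths)
  m <- matrix(0L, nrow = length(ids), ncol = length(REPEAT_CLASSES),
              dimnames = list(ids, REPEAT_CLASSES))
  for (id in names(annotations)) {
    a <- annotations[[id]]
    if (is.null(a) || nrow(a) == 0L) next
    if (any(a$start < 0L) || any(a$end > seqLengths[[id]]) ||
        any(a$start >= a$end))
      stop("annotation outside [0, length) for sequence ", id)
    w <- tapply(a$end - a$start, a$class, sum)
    m[id, names(w)] <- as.integer(w)
  }
  m[, "Unmasked"] <- as.integer(seqLengths[ids]) - rowSums(m)
  if (any(m[, "Unmasked"] < 0L))
    stop("annotated bases exceed sequence length (overlapping annotation?)")
  m
}

#' Pooled repeat-class composition of a sequence set
#'
#' Per class, percent = total masked bases of that class across all
#' sequences / total sequence bases x 100 (pooled, not averaged per contig).
#'
#' @param x Either a base-count matrix from \code{\link{repeatBaseMatrix}} or
#'   a named annotation list (then \code{seqLengths} is required).
#' @param seqLengths Named lengths when \code{x} is an annotation list.
#' @return Named numeric vector of percentages over
#'   \code{\link{repeatClasses}} (summing to 100), with attribute
#'   \code{total_bases}.
#' @export
#' @examples
#' ann <- list(c1 = data.frame(start = 0, end = 100, class = "LINE"))
#' repeatComposition(ann, c(c1 = 400))["LINE"]  # 25
repeatComposition <- function(x, seqLengths = NULL) {
  if (!is.matrix(x)) {
    stopifnot(!is.null(seqLengths))
    x <- repeatBaseMatrix(x, seqLengths)
  }
  if (nrow(x) == 0L) stop("empty sequence set")
  tot <- sum(x)
  if (tot == 0) stop("sequence set has zero total length")
  p <- 100 * colSums(x) / tot
  attr(p, "total_bases") <- tot
  p
}

#' Absolute per-class composition difference
#'
#' \code{|A_rep\% - B_rep\%|} per repeat class; symmetric and nonnegative.
#'
#' @param a,b Composition percent vectors from
#'   \code{\link{repeatComposition}}.
#' @return Named numeric vector of absolute differences.
#' @export
diffRep <- function(a, b) {
  stopifnot(identical(names(a), names(b)))
  d <- abs(unclass(a) - unclass(b))
  attr(d, "total_bases") <- NULL
  d
}

#' Permutation test for repeat-class composition differences
#'
#' Nonparametric test of whether set B's repeat composition differs from set
#' A's. Set A must contain at least twice as many sequences as B (the sets
#' are swapped when the ordering is reversed; an error is raised when
#' neither ordering qualifies). For each of \code{nPermutations} draws, a
#' random subset R of A with |R| = |B| is taken without replacement and
#' \code{Diff_Rrep = |A\% - R\%|} computed per class; the p-value per class
#' is the fraction of permutations with \code{Diff_Rrep > Diff_rep}
#' (strictly greater, as ties do not count; the resolution is
#' 1/nPermutations). An optional add-one correction (k+1)/(n+1) is available
#' but off by default.
#'
#' @param mA,mB Base-count matrices (\code{\link{repeatBaseMatrix}}) of the
#'   two sets.
#' @param nPermutations Number of random subsets (default 10000).
#' @param seed Seed for the subset draws.
#' @param addOne Use the (k+1)/(n+1) estimator (default FALSE).
#' @return list of class \code{"permutationResult"}: \code{table}
#'   (data.frame class, pct_a, pct_b, diff, p_value), \code{n_permutations},
#'   \code{seed}, \code{swapped}.
#' @export
repeatPermutationTest <- function(mA, mB, nPermutations = 10000L, seed = 1L,
                                  addOne = FALSE) {
  if (nrow(mB) == 0L) stop("set B is empty")
  swapped <- FALSE
  if (nrow(mA) < 2L * nrow(mB)) {
    tmp <- mA; mA <- mB; mB <- tmp
    swapped <- TRUE
    if (nrow(mA) < 2L * nrow(mB))
      stop("neither ordering gives |A| >= 2|B|")
  }
  pctA <- repeatComposition(mA)
  pctB <- repeatComposition(mB)
  obs <- diffRep(pctA, pctB)
  nA <- nrow(mA); nB <- nrow(mB)
  rowTot <- rowSums(mA)
  exceed <- numeric(length(obs))
  withSubstream(seed, "repeat_permutation", {
    for (i in seq_len(nPermutations)) {
      idx <- sample.int(nA, nB)
      pctR <- 100 * colSums(mA[idx, , drop = FALSE]) / sum(rowTot[idx])
      exceed <- exceed + (abs(unclass(pctA) - pctR) > obs)
    }
  })
  p <- if (addOne) (exceed + 1) / (nPermutations + 1) else exceed / nPermutations
  structure(list(
    table = data.frame(class = names(obs), pct_a = unclass(pctA),
                       pct_b = unclass(pctB), diff = unname(unclass(obs)),
                       p_value = unname(p), row.names = NULL,
                       stringsAsFactors = FALSE),
    n_permutations = as.integer(nPermutations), seed = seed,
    swapped = swapped), class = "permutationResult")
}

#' @export
print.permutationResult <- function(x, ...) {
  cat("Repeat-class permutation test (", x$n_permutations,
      " permutations, resolution ", format(1 / x$n_permutations), ")\n",
      sep = "")
  print(x$table, digits = 4)
  invisible(x)
}

#' Sample background sequences from a reference
#'
#' Represents a reference genome as \code{n} random intervals whose starts
#' are uniform over the valid positions (chromosomes weighted by their
#' number of valid starts) and whose lengths are drawn with replacement from
#' an empirical size distribution. Repeat annotation is looked up from the
#' reference's repeat track.
#'
#' @param chromLengths Named integer vector of reference sequence lengths.
#' @param sizeDistribution Integer vector of sizes to resample (e.g. the
#'   observed cluster sizes).
#' @param n Number of intervals (default 500000).
#' @param seed Seed for the draws.
#' @param repeatTrack \code{GRanges} with a \code{label} column giving the
#'   repeat class of each annotated reference interval (may be NULL: all
#'   bases unmasked).
#' @return list(intervals, baseMatrix): the sampled \code{GRanges} and the
#'   per-interval repeat base-count matrix.
#' @export
sampleBackground <- function(chromLengths, sizeDistribution, n = 500000L,
                             seed = 1L, repeatTrack = NULL) {
  stopifnot(n > 0L, length(sizeDistribution) > 0L,
            !is.null(names(chromLengths)))
  if (max(sizeDistribution) > max(chromLengths))
    stop("reference shorter than the largest sampled size")
  sizePool <- as.integer(sizeDistribution)
  drawSizes <- function(k) sizePool[sample.int(length(sizePool), k,
                                               replace = TRUE)]
  withSubstream(seed, "background_sampling", {
    sizes <- drawSizes(n)
    nValid <- vapply(names(chromLengths),
                     function(ch) chromLengths[[ch]], 0L)
    chrom <- sample(names(chromLengths), n, replace = TRUE,
                    prob = nValid / sum(nValid))
    maxStart <- chromLengths[chrom] - sizes
    ## redraw sizes that do not fit their chromosome
    bad <- which(maxStart < 0L)
    while (length(bad) > 0L) {
      sizes[bad] <- drawSizes(length(bad))
      maxStart <- chromLengths[chrom] - sizes
      bad <- which(maxStart < 0L)
    }
    start0 <- floor(stats::runif(n, 0, maxStart + 1))
    gr <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(start0 + 1L,
                                                  width = sizes))
    m <- matrix(0L, nrow = n, ncol = length(REPEAT_CLASSES),
                dimnames = list(NULL, REPEAT_CLASSES))
    if (!is.null(repeatTrack) && length(repeatTrack) > 0L) {
      ov <- GenomicRanges::findOverlaps(gr, repeatTrack)
      if (length(ov) > 0L) {
        qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
        w <- IRanges::width(IRanges::pintersect(
          IRanges::ranges(gr)[qh], IRanges::ranges(repeatTrack)[sh]))
        cls <- S4Vectors::mcols(repeatTrack)$label[sh]
        agg <- tapply(w, list(qh, cls), sum)
        ri <- as.integer(rownames(agg))
        for (cl in colnames(agg)) {
          v <- agg[, cl]
          ok <- !is.na(v)
          m[ri[ok], cl] <- m[ri[ok], cl] + as.integer(v[ok])
        }
      }
    }
    m[, "Unmasked"] <- sizes - rowSums(m)
    list(intervals = gr, baseMatrix = m)
  })
}
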