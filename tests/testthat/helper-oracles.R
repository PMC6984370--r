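## Independent brute-force oracles and fixture builders shared by the tests.

randDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))[1]

mutate <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

## Brute-force greedy clustering: same documented join rule, no prefilter,
## no shortcuts, identity/coverage always from the full DP local alignment
## on both strands (a candidate joins when either strand satisfies the
## rule). Returns an integer assignment in the canonical sorted order.
bruteGreedyCluster <- function(seqs, nms, c = 0.95, aS = 0.90, aL = 0.90) {
  lens <- nchar(seqs)
  ord <- order(-lens, nms, method = "radix")
  seqs <- seqs[ord]; nms <- nms[ord]
  repIdx <- integer(0)
  assignment <- integer(length(seqs))
  ruleOk <- function(a, b) {
    for (bb in c(b, revcomp(b))) {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(bb), Biostrings::DNAString(a), type = "local",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
          match = 1, mismatch = -1, baseOnly = FALSE),
        gapOpening = 0, gapExtension = 2)
      ident <- Biostrings::nmatch(pa) / Biostrings::nchar(pa)
      spanB <- BiocGenerics::end(Biostrings::pattern(pa)) -
        BiocGenerics::start(Biostrings::pattern(pa)) + 1L
      spanA <- BiocGenerics::end(Biostrings::subject(pa)) -
        BiocGenerics::start(Biostrings::subject(pa)) + 1L
      covShort <- (if (nchar(a) <= nchar(b)) spanA / nchar(a)
                   else spanB / nchar(b))
      covLong <- (if (nchar(a) <= nchar(b)) spanB / nchar(b)
                  else spanA / nchar(a))
      if (ident >= c && covShort >= aS && covLong >= aL) return(TRUE)
    }
    FALSE
  }
  for (i in seq_along(seqs)) {
    joined <- 0L
    for (j in seq_along(repIdx)) {
      if (ruleOk(seqs[i], seqs[repIdx[j]])) { joined <- j; break }
    }
    if (joined == 0L) {
      repIdx <- c(repIdx, i)
      joined <- length(repIdx)
    }
    assignment[i] <- joined
  }
  names(assignment) <- nms
  assignment
}

## Same brute-force rule, evaluated with batched alignment calls (one call
## per contig and strand against every current representative, no
## prefilter, no shortcuts). Semantics identical to bruteGreedyCluster.
bruteGreedyClusterBatch <- function(seqs, nms, c = 0.95, aS = 0.90,
                                    aL = 0.90) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  lens <- nchar(seqs)
  ord <- order(-lens, nms, method = "radix")
  seqs <- seqs[ord]; nms <- nms[ord]
  repIdx <- integer(0)
  assignment <- integer(length(seqs))
  stats <- function(pats, subj) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(pats), Biostrings::DNAString(subj),
      type = "local", substitutionMatrix = mat, gapOpening = 0,
      gapExtension = 2)
    list(ident = Biostrings::nmatch(pa) / Biostrings::nchar(pa),
         spanP = BiocGenerics::end(Biostrings::pattern(pa)) -
           BiocGenerics::start(Biostrings::pattern(pa)) + 1L,
         spanS = BiocGenerics::end(Biostrings::subject(pa)) -
           BiocGenerics::start(Biostrings::subject(pa)) + 1L)
  }
  for (i in seq_along(seqs)) {
    joined <- 0L
    if (length(repIdx) > 0L) {
      pats <- seqs[repIdx]
      for (subj in c(seqs[i], revcomp(seqs[i]))) {
        st <- stats(pats, subj)
        ## contig i is never longer than a representative
        ok <- st$ident >= c & st$spanS / nchar(seqs[i]) >= aS &
          st$spanP / nchar(pats) >= aL
        if (any(ok)) {
          cand <- which(ok)[1]
          joined <- if (joined == 0L) cand else min(joined, cand)
        }
      }
    }
    if (joined == 0L) {
      repIdx <- c(repIdx, i)
      joined <- length(repIdx)
    }
    assignment[i] <- joined
  }
  names(assignment) <- nms
  assignment
}

## partition of contig names -> canonical signature for comparison
partitionSignature <- function(groups) {
  sig <- vapply(groups, function(g) paste(sort(g), collapse = ","), "")
  sort(unname(sig))
}

## Brute-force DBSCAN on the line (O(n^2)), same conventions as dbscan1d:
## core = >= minNeighbors OTHER points within eps; clusters = components of
## cores; border joins its leftmost core neighbour.
bruteDbscan1d <- function(positions, eps = 150, minNeighbors = 3L) {
  n <- length(positions)
  core <- vapply(seq_len(n), function(i)
    sum(abs(positions - positions[i]) <= eps) - 1L >= minNeighbors, TRUE)
  lab <- rep(-1L, n)
  cid <- 0L
  for (i in order(positions)) {
    if (!core[i] || lab[i] != -1L) next
    cid <- cid + 1L
    queue <- i
    while (length(queue) > 0L) {
      x <- queue[1]; queue <- queue[-1]
      if (lab[x] != -1L) next
      lab[x] <- cid
      nb <- which(abs(positions - positions[x]) <= eps & core & lab == -1L)
      queue <- c(queue, nb)
    }
  }
  for (i in which(!core)) {
    cand <- which(core & abs(positions - positions[i]) <= eps)
    if (length(cand) > 0L)
      lab[i] <- lab[cand[which.min(positions[cand])]]
  }
  lab
}

## label vectors -> comparable partitions (noise kept as singleton marker)
labelPartition <- function(lab) {
  out <- split(seq_along(lab), lab)
  noise <- out[["-1"]]
  out[["-1"]] <- NULL
  c(partitionSignature(out),
    if (!is.null(noise)) paste0("noise:", paste(sort(noise), collapse = ",")))
}

## Brute-force reciprocal-overlap components (pairwise predicate +
## breadth-first components), independent of the union-find implementation.
bruteReciprocalComponents <- function(records, minOverlap = 0.7) {
  n <- nrow(records)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || records$chrom[i] != records$chrom[j]) next
    w <- max(0L, min(records$end[i], records$end[j]) -
               max(records$start[i], records$start[j]))
    if (w / (records$end[i] - records$start[i]) >= minOverlap &&
        w / (records$end[j] - records$start[j]) >= minOverlap)
      adj[i, j] <- TRUE
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue) > 0L) {
      x <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[x])) next
      comp[x] <- cid
      queue <- c(queue, which(adj[x, ] & is.na(comp)))
    }
  }
  comp
}

## Naive double-loop half-open interval intersection.
naiveIntersect <- function(a, b) {
  pairs <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] == b$chrom[j] && a$start[i] < b$end[j] &&
        a$end[i] > b$start[j])
      pairs[[length(pairs) + 1L]] <- c(i, j)
  }
  if (length(pairs) == 0L)
    return(data.frame(event = integer(0), feature = integer(0)))
  m <- do.call(rbind, pairs)
  data.frame(event = m[, 1], feature = m[, 2])
}

## A small planted-cluster contig mixture: `nClusters` source sequences,
## each emitted by several individuals with the given divergence; returns a
## named character vector of contigs plus the true source of each.
plantedContigMixture <- function(nClusters = 20, maxCopies = 6,
                                 lenRange = c(301, 600), divergence = 0.01) {
  src <- vapply(seq_len(nClusters), function(i)
    randDna(sample(lenRange[1]:lenRange[2], 1)), "")
  seqs <- character(0); origin <- integer(0)
  cnt <- 0L
  for (i in seq_len(nClusters)) {
    for (k in seq_len(sample(1:maxCopies, 1))) {
      cnt <- cnt + 1L
      s <- mutate(src[i], divergence)
      if (stats::runif(1) < 0.5) s <- revcomp(s)
      seqs <- c(seqs, s)
      origin <- c(origin, i)
      names(seqs)[cnt] <- sprintf("Ind%03d_%d", k, cnt)
    }
  }
  list(seqs = seqs, origin = origin)
}

## tiny default-like config for fast cohort tests; `...` overrides defaults
tinyConfig <- function(seed = 3, ...) {
  args <- utils::modifyList(
    list(seed = seed, nIndividuals = 12L, nNs = 10L, refLength = 80000L,
         nChromosomes = 2L, nContaminants = 1L, nDecoyLoci = 4L,
         decoysPerIndividual = 2L, smallPerIndividual = 1L,
         urIndividuals = 4L, readsPerIndividual = 150L),
    list(...))
  do.call(simConfig, args)
}
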