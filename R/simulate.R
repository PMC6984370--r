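## Synthetic cohort generator.
##
## One master seed feeds a named RNG substream per emission stage
## (references, carriers, individuals, hits, calls, deletions, urreads), so
## any stage can be regenerated independently and a fixed seed yields
## byte-identical output. Repeat composition of planted NS is realized by
## concatenating class-pure blocks; the annotation is recorded, not
## re-detected. The generator guarantees that distinct planted NS are
## pairwise non-joinable under the default clustering rule and that
## non-ancestral NS cannot reach the NS-blocking coverage threshold against
## the human-like reference (simple-repeat content per NS is capped), so
## truth-table comparisons are exact when the error knobs are off.

## substitute bases at `rate`; returns character scalar
mutateSeq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  if (length(hit) > 0L) {
    for (i in hit) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
    seq <- paste(ch, collapse = "")
  }
  seq
}

tandemRepeat <- function(motif, len, subRate = 0.02) {
  s <- substr(strrep(motif, ceiling(len / nchar(motif))), 1L, len)
  mutateSeq(s, subRate)
}

## a diverged copy of a consensus: random-start subsequence of `len` bases
libraryCopy <- function(consensus, len, divergence) {
  L <- nchar(consensus)
  len <- min(len, L)
  s <- sample.int(L - len + 1L, 1L)
  mutateSeq(substr(consensus, s, s + len - 1L), divergence)
}

makeRepeatLibraries <- function() {
  list(human = list(LINE = replicate(3, randomDna(6000)),
                    SINE = replicate(3, randomDna(300)),
                    LTR = replicate(2, randomDna(1000)),
                    DNA = replicate(2, randomDna(800)),
                    Satellite = replicate(3, randomDna(171))),
       ns = list(LINE = replicate(3, randomDna(6000)),
                 SINE = replicate(2, randomDna(300)),
                 Satellite = replicate(5, randomDna(171))))
}

## paint non-overlapping repeat intervals onto a chromosome character vector
## until per-class base budgets are exhausted; returns list(chars, track df)
plantHumanRepeats <- function(chars, lib, mix) {
  L <- length(chars)
  occupied <- rep(FALSE, L)
  rows <- list()
  lenDraw <- list(LINE = c(500, 6000), SINE = c(150, 300), LTR = c(300, 1000),
                  DNA = c(200, 800), Simple_repeat = c(100, 500),
                  Satellite = c(342, 1710))
  for (cl in names(mix)) {
    budget <- mix[[cl]] * L
    tries <- 0L
    while (budget > 0 && tries < 5000L) {
      tries <- tries + 1L
      w <- sample(seq(lenDraw[[cl]][1], lenDraw[[cl]][2]), 1L)
      if (w > L) next
      s <- sample.int(L - w + 1L, 1L)
      if (any(occupied[s:(s + w - 1L)])) next
      seq <- switch(cl,
        Simple_repeat = tandemRepeat(paste(sample(DNA_BASES,
          sample(2:6, 1L), replace = TRUE), collapse = ""), w, 0.03),
        Satellite = tandemRepeat(sample(lib$Satellite, 1L), w, 0.05),
        libraryCopy(sample(lib[[cl]], 1L), w, 0.10))
      w <- nchar(seq)
      chars[s:(s + w - 1L)] <- strsplit(seq, "", fixed = TRUE)[[1]]
      occupied[s:(s + w - 1L)] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(start = s - 1L, end = s + w - 1L,
                                              class = cl)
      budget <- budget - w
    }
  }
  list(chars = chars, track = if (length(rows)) do.call(rbind, rows)
       else data.frame(start = integer(0), end = integer(0),
                       class = character(0)))
}

## one planted NS: class-pure blocks matching a Dirichlet draw around the
## target mix (simple-repeat fraction capped at 0.45); returns
## list(seq, annotation df)
makeNsSequence <- function(len, mix, lib) {
  for (attempt in 1:100) {
    a <- stats::rgamma(length(mix), shape = 8 * mix)
    prop <- a / sum(a)
    names(prop) <- names(mix)
    if (is.na(prop["Simple_repeat"]) || prop[["Simple_repeat"]] <= 0.45)
      break
  }
  classes <- setdiff(names(mix), "Unmasked")
  blockLen <- round(prop[classes] * len)
  blockLen <- blockLen[blockLen >= 30L]
  ord <- sample(seq_along(blockLen))
  pieces <- character(0); ann <- list(); pos <- 0L
  addPiece <- function(seq, cl) {
    pieces[[length(pieces) + 1L]] <<- seq
    if (!is.null(cl))
      ann[[length(ann) + 1L]] <<- data.frame(start = pos, end = pos + nchar(seq),
                                             class = cl)
    pos <<- pos + nchar(seq)
  }
  ## unmasked spacers divide the remaining budget around the blocks
  spacer <- len - sum(blockLen)
  while (spacer < 0L && length(blockLen) > 0L) {
    big <- which.max(blockLen)
    blockLen[big] <- blockLen[big] + spacer
    blockLen <- blockLen[blockLen >= 30L]
    spacer <- len - sum(blockLen)
  }
  cuts <- if (length(blockLen) > 0L)
    sort(sample.int(spacer + 1L, length(blockLen), replace = TRUE) - 1L)
  else integer(0)
  widths <- diff(c(0L, cuts, spacer))
  if (widths[1] > 0L) addPiece(randomDna(widths[1]), NULL)
  for (i in seq_along(ord)) {
    cl <- names(blockLen)[ord[i]]
    w <- blockLen[[ord[i]]]
    seq <- switch(cl,
      Simple_repeat = tandemRepeat(paste(sample(DNA_BASES, sample(2:6, 1L),
        replace = TRUE), collapse = ""), w, 0.03),
      Satellite = tandemRepeat(sample(lib$Satellite, 1L), w, 0.08),
      LINE = libraryCopy(sample(lib$LINE, 1L), w, 0.10),
      SINE = libraryCopy(sample(lib$SINE, 1L), w, 0.10),
      randomDna(w))
    addPiece(seq, cl)
    if (widths[i + 1L] > 0L) addPiece(randomDna(widths[i + 1L]), NULL)
  }
  seq <- paste(unlist(pieces), collapse = "")
  if (nchar(seq) < len) {
    addPiece(randomDna(len - nchar(seq)), NULL)
    seq <- paste0(seq, pieces[[length(pieces)]])
  } else if (nchar(seq) > len) seq <- substr(seq, 1L, len)
  ann <- if (length(ann)) do.call(rbind, ann)
  else data.frame(start = integer(0), end = integer(0), class = character(0))
  ann <- ann[ann$end <= len, , drop = FALSE]
  list(seq = seq, annotation = ann)
}

## would two sequences join under the default clustering rule?
wouldJoin <- function(a, b, c = 0.95, aS = 0.90, aL = 0.90) {
  st <- pairwiseIdentityCoverage(a, b)
  st[["identity"]] >= c && st[["cov_short"]] >= aS && st[["cov_long"]] >= aL
}

#' Build the human-like and chimp-like references and the NS catalog
#'
#' The human-like reference is random sequence with a planted repeat
#' landscape (recorded as a repeat track); the chimp-like reference equals
#' it with the ancestral NS inserted verbatim at recorded positions, whose
#' chimp-coordinate intervals form the deleted-region table (deletions
#' relative to chimpanzee). Also drawn here: the NS catalog (sequences,
#' repeat-block annotations, guaranteed pairwise non-joinable under the
#' clustering rule), insertion positions of positioned NS (with deliberate
#' hybrid co-locations), decoy loci, contaminant sequences and the feature
#' tracks.
#'
#' @param config A \code{\linkS4class{SimConfig}}.
#' @return list: humanRef, chimpRef (named character vectors), nsCatalog
#'   (data.frame ns_id, length, ancestral, positioned, chrom, position,
#'   sequence), nsAnnotations, deletedRegions (data.frame with chimp
#'   coordinates, ns_id, status), humanRepeatTrack (data.frame chrom, start,
#'   end, class), featureTracks, decoyLoci, contaminants.
#' @export
buildReferences <- function(config) {
  withSubstream(config@seed, "references", {
    nChrom <- config@nChromosomes
    chromLen <- rep(config@refLength %/% nChrom, nChrom)
    chromLen[nChrom] <- config@refLength - sum(chromLen[-nChrom])
    chromNames <- paste0("chr", seq_len(nChrom))
    lib <- makeRepeatLibraries()
    humanMix <- c(LINE = 0.20, SINE = 0.13, LTR = 0.07, DNA = 0.03,
                  Simple_repeat = 0.03, Satellite = 0.03)
    humanRef <- character(nChrom); names(humanRef) <- chromNames
    trackRows <- list()
    for (i in seq_len(nChrom)) {
      pr <- plantHumanRepeats(sample(DNA_BASES, chromLen[i], replace = TRUE),
                              lib$human, humanMix)
      humanRef[i] <- paste(pr$chars, collapse = "")
      if (nrow(pr$track) > 0L) {
        pr$track$chrom <- chromNames[i]
        trackRows[[length(trackRows) + 1L]] <- pr$track
      }
    }
    humanRepeatTrack <- do.call(rbind, trackRows)[, c("chrom", "start",
                                                      "end", "class")]

    ## NS catalog: lengths from a shifted exponential (mean ~ minimum + 150,
    ## matching the observed mean NS contig size), truncated at the
    ## contaminant boundary; pairwise non-joinable by construction
    nNs <- config@nNs
    nsSeq <- character(nNs); nsLen <- integer(nNs)
    nsAnn <- vector("list", nNs)
    kmerIdx <- new.env(parent = emptyenv())
    kk <- PREFILTER_K
    for (j in seq_len(nNs)) {
      ok <- FALSE
      for (attempt in 1:1000) {
        L <- min(config@nsLengthRange[1] +
                   round(stats::rexp(1, 1 / config@nsLengthExpMean)),
                 config@nsLengthRange[2])
        ns <- makeNsSequence(L, config@repeatMix, lib$ns)
        ## collision check against already accepted NS
        cand <- integer(0)
        for (s in c(ns$seq, revcompChar(ns$seq))) {
          ct <- prefilterCounts(seqKmers(s, kk), kmerIdx)
          if (length(ct) > 0L) cand <- union(cand, which(
            ct >= pmax(1L, floor(0.32 * pmin(L, nsLen[seq_along(ct)])) - 11L)))
        }
        clash <- FALSE
        for (j2 in cand) if (wouldJoin(ns$seq, nsSeq[j2])) { clash <- TRUE; break }
        if (!clash) { ok <- TRUE; break }
      }
      if (!ok) stop("could not draw a non-colliding NS after 1000 attempts")
      nsSeq[j] <- ns$seq; nsLen[j] <- nchar(ns$seq); nsAnn[[j]] <- ns$annotation
      for (km in unique(seqKmers(ns$seq, kk))) {
        cur <- kmerIdx[[km]]
        kmerIdx[[km]] <- if (is.null(cur)) j else c(cur, j)
      }
    }
    nsId <- sprintf("ns_%04d", seq_len(nNs))
    names(nsAnn) <- nsId

    ## ancestral subset -> chimp-like reference with insertions
    nAnc <- round(config@ancestralFraction * nNs)
    ancestral <- rep(FALSE, nNs)
    if (nAnc > 0L) ancestral[sample.int(nNs, nAnc)] <- TRUE
    insChrom <- rep(NA_character_, nNs); insPosH <- rep(NA_integer_, nNs)
    taken <- list()
    for (j in which(ancestral)) {
      placed <- FALSE
      for (attempt in 1:1000) {
        ch <- sample(chromNames, 1L)
        pos <- sample.int(chromLen[match(ch, chromNames)] - 1L, 1L)
        prev <- taken[[ch]]
        if (is.null(prev) || all(abs(prev - pos) > 100L)) {
          taken[[ch]] <- c(prev, pos)
          insChrom[j] <- ch; insPosH[j] <- pos
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place ancestral NS after 1000 attempts")
    }
    chimpRef <- humanRef
    delRows <- list()
    for (ch in chromNames) {
      idx <- which(ancestral & insChrom == ch)
      if (length(idx) == 0L) next
      idx <- idx[order(insPosH[idx])]
      pieces <- character(0)
      prevEnd <- 0L; offset <- 0L
      for (j in idx) {
        pieces <- c(pieces, substr(humanRef[[ch]], prevEnd + 1L, insPosH[j]),
                    nsSeq[j])
        delRows[[length(delRows) + 1L]] <- data.frame(
          chrom = ch, start = insPosH[j] + offset,
          end = insPosH[j] + offset + nsLen[j], ns_id = nsId[j],
          status = "deleted_in_new", stringsAsFactors = FALSE)
        offset <- offset + nsLen[j]
        prevEnd <- insPosH[j]
      }
      pieces <- c(pieces, substr(humanRef[[ch]], prevEnd + 1L,
                                 nchar(humanRef[[ch]])))
      chimpRef[[ch]] <- paste(pieces, collapse = "")
    }
    deletedRegions <- if (length(delRows)) do.call(rbind, delRows)
    else data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), ns_id = character(0),
                    status = character(0), stringsAsFactors = FALSE)

    ## positioned NS (insertion sites on the human-like reference), with
    ## deliberate hybrid co-locations
    nPos <- round(config@positionedFraction * nNs)
    positioned <- rep(FALSE, nNs)
    if (nPos > 0L) positioned[sample.int(nNs, nPos)] <- TRUE
    posIdx <- which(positioned)
    bias <- 0.6  # fraction of sites placed inside the repeat track
    sites <- matrix(NA_integer_, nrow = 0, ncol = 0)
    sitePos <- integer(0); siteChrom <- character(0)
    for (j in posIdx) {
      for (attempt in 1:1000) {
        if (stats::runif(1) < bias && nrow(humanRepeatTrack) > 0L) {
          r <- sample.int(nrow(humanRepeatTrack), 1L,
                          prob = humanRepeatTrack$end - humanRepeatTrack$start)
          ch <- humanRepeatTrack$chrom[r]
          pos <- humanRepeatTrack$start[r] +
            sample.int(humanRepeatTrack$end[r] - humanRepeatTrack$start[r], 1L) - 1L
        } else {
          ch <- sample(chromNames, 1L)
          pos <- sample.int(chromLen[match(ch, chromNames)], 1L) - 1L
        }
        same <- siteChrom == ch
        if (!any(same) || all(abs(sitePos[same] - pos) > 2000L)) break
      }
      siteChrom <- c(siteChrom, ch); sitePos <- c(sitePos, pos)
      insChrom[j] <- ch; insPosH[j] <- pos
    }
    ## hybrids: co-locate pairs of positioned NS at a shared site
    nHyb <- floor(config@hybridFraction * nPos / 2)
    if (nHyb > 0L && length(posIdx) >= 2L * nHyb) {
      pick <- sample(posIdx, 2L * nHyb)
      for (h in seq_len(nHyb)) {
        a <- pick[2L * h - 1L]; b <- pick[2L * h]
        insChrom[b] <- insChrom[a]
        insPosH[b] <- max(0L, insPosH[a] +
                            sample(seq(-50L, 50L), 1L))
      }
    }

    ## decoy loci (mappable human sequence) and contaminants
    decoyLoci <- do.call(rbind, lapply(seq_len(config@nDecoyLoci), function(d) {
      w <- min(config@nsLengthRange[1] +
                 round(stats::rexp(1, 1 / config@nsLengthExpMean)),
               config@nsLengthRange[2])
      ch <- sample(chromNames, 1L)
      s <- sample.int(chromLen[match(ch, chromNames)] - w, 1L)
      data.frame(locus = sprintf("decoy_%03d", d), chrom = ch, start = s,
                 end = s + w, stringsAsFactors = FALSE)
    }))
    contaminants <- if (config@nContaminants > 0L)
      vapply(seq_len(config@nContaminants), function(i)
        randomDna(sample(seq(config@contaminantLenRange[1],
                             config@contaminantLenRange[2]), 1L)), "")
    else character(0)
    if (length(contaminants) > 0L)
      names(contaminants) <- sprintf("contam_%03d", seq_along(contaminants))

    ## feature tracks on the human-like reference
    featureTracks <- makeFeatureTracks(chromNames, chromLen)
    featureTracks$repeat_elements <-
      humanRepeatTrack[, c("chrom", "start", "end")]

    list(humanRef = humanRef, chimpRef = chimpRef,
         nsCatalog = data.frame(ns_id = nsId, length = nsLen,
                                ancestral = ancestral,
                                positioned = positioned, chrom = insChrom,
                                position = insPosH, sequence = nsSeq,
                                stringsAsFactors = FALSE),
         nsAnnotations = nsAnn, deletedRegions = deletedRegions,
         humanRepeatTrack = humanRepeatTrack, featureTracks = featureTracks,
         decoyLoci = decoyLoci, contaminants = contaminants)
  })
}

makeFeatureTracks <- function(chromNames, chromLen) {
  genes <- list(); exons <- list(); segdup <- list(); centro <- list()
  for (i in seq_along(chromNames)) {
    L <- chromLen[i]
    nGenes <- max(3L, round(15 * L / 1e6))
    gwMax <- max(2000L, min(50000L, L %/% 10L))
    gs <- sort(sample.int(L - gwMax, nGenes))
    gw <- sample(seq(max(1000L, gwMax %/% 10L), gwMax), nGenes,
                 replace = TRUE)
    ge <- pmin(gs + gw, L)
    genes[[i]] <- data.frame(chrom = chromNames[i], start = gs, end = ge)
    ex <- lapply(seq_len(nGenes), function(g) {
      k <- sample(2:8, 1L)
      es <- sort(sample(seq(gs[g], max(gs[g] + 1L, ge[g] - 300L)), k))
      data.frame(chrom = chromNames[i], start = es,
                 end = pmin(es + sample(100:300, k, replace = TRUE), ge[g]))
    })
    exons[[i]] <- do.call(rbind, ex)
    sdMax <- max(1000L, min(20000L, L %/% 20L))
    ss <- sample.int(L - sdMax, 5L)
    segdup[[i]] <- data.frame(chrom = chromNames[i], start = ss,
                              end = ss + sample(seq(sdMax %/% 4L, sdMax), 5L,
                                                replace = TRUE))
    cs <- round(L * stats::runif(1, 0.4, 0.6))
    centro[[i]] <- data.frame(chrom = chromNames[i], start = cs,
                              end = min(cs + min(30000L, L %/% 10L), L))
  }
  genes <- do.call(rbind, genes)
  nMim <- max(1L, round(0.3 * nrow(genes)))
  mimIdx <- sample.int(nrow(genes), nMim)
  mim <- genes[mimIdx, , drop = FALSE]
  exons <- do.call(rbind, exons)
  inMim <- vapply(seq_len(nrow(exons)), function(e)
    any(mim$chrom == exons$chrom[e] & mim$start <= exons$start[e] &
          mim$end >= exons$end[e]), TRUE)
  list(genes = genes, exons = exons, mim_genes = mim,
       mim_exons = exons[inMim, , drop = FALSE],
       segmental_duplication = do.call(rbind, segdup),
       centromere = do.call(rbind, centro))
}

#' Draw the carrier structure of the cohort
#'
#' Allele (carrier) frequencies follow the configured mixture: with
#' probability \code{pRare} uniform on (1/N, 0.05), otherwise uniform on
#' (0.05, 0.5). The carrier count is round(AF x N) (at least 1) and the
#' recorded true AF is that count over N. Contaminant carriers (1-3
#' individuals each) are also drawn here.
#'
#' @param config A \code{SimConfig}.
#' @param refs Output of \code{\link{buildReferences}}.
#' @return list(individuals, truthAf, carriers, contamCarriers).
#' @export
drawCarriers <- function(config, refs) {
  withSubstream(config@seed, "carriers", {
    N <- config@nIndividuals
    individuals <- sprintf("Ind%03d", seq_len(N))
    nNs <- config@nNs
    sp <- config@afSpectrum
    rare <- stats::runif(nNs) < sp$pRare
    af <- ifelse(rare,
                 stats::runif(nNs, sp$rareRange[1], sp$rareRange[2]),
                 stats::runif(nNs, sp$commonRange[1], sp$commonRange[2]))
    nCar <- pmax(1L, as.integer(round(af * N)))
    carriers <- lapply(nCar, function(k) sort(sample(individuals, k)))
    names(carriers) <- refs$nsCatalog$ns_id
    contamCarriers <- lapply(seq_along(refs$contaminants), function(i)
      sort(sample(individuals, sample(1:3, 1L))))
    if (length(refs$contaminants) > 0L)
      names(contamCarriers) <- names(refs$contaminants)
    list(individuals = individuals, drawnAf = af, nCarriers = nCar,
         trueAf = nCar / N, carriers = carriers,
         contamCarriers = contamCarriers)
  })
}

#' Emit per-individual contigs
#'
#' Each individual's contigs are: its carried NS (mutated at the configured
#' per-base rate, emitted on a random strand, fragmented into two pieces of
#' at least the minimum contig size with the configured probability), decoy
#' contigs copied from the human-like reference, sub-threshold (<301 bp)
#' contigs, and its contaminant contigs. Names follow IndividualXYZ_I.
#'
#' @param config A \code{SimConfig}.
#' @param refs Output of \code{\link{buildReferences}}.
#' @param car Output of \code{\link{drawCarriers}}.
#' @return list(contigs = \code{ContigSet}, origin = \code{DataFrame}
#'   (contig, origin, source_id, fragment)).
#' @export
simulateIndividuals <- function(config, refs, car) {
  withSubstream(config@seed, "individuals", {
    cat <- refs$nsCatalog
    minLen <- config@nsLengthRange[1]
    seqs <- character(0); nms <- character(0)
    origin <- character(0); src <- character(0); frag <- logical(0)
    for (ind in car$individuals) {
      counter <- 0L
      emit <- function(seq, org, id, fr = FALSE) {
        counter <<- counter + 1L
        nms <<- c(nms, paste0(ind, "_", counter))
        seqs <<- c(seqs, seq)
        origin <<- c(origin, org); src <<- c(src, id); frag <<- c(frag, fr)
      }
      maybeFlip <- function(s)
        if (stats::runif(1) < 0.5) revcompChar(s) else s
      for (j in seq_len(nrow(cat))) {
        if (!(ind %in% car$carriers[[cat$ns_id[j]]])) next
        s <- mutateSeq(cat$sequence[j], config@mutationRate)
        L <- nchar(s)
        if (L >= 2L * minLen && stats::runif(1) < config@fragmentationProb) {
          cut <- sample(seq(minLen, L - minLen), 1L)
          emit(substr(s, 1L, cut), "ns", cat$ns_id[j], TRUE)
          emit(substr(s, cut + 1L, L), "ns", cat$ns_id[j], TRUE)
        } else emit(s, "ns", cat$ns_id[j])
      }
      dl <- refs$decoyLoci
      for (d in sample.int(nrow(dl), min(config@decoysPerIndividual,
                                         nrow(dl)))) {
        s <- substr(refs$humanRef[[dl$chrom[d]]], dl$start[d] + 1L, dl$end[d])
        emit(maybeFlip(mutateSeq(s, config@mutationRate)), "decoy",
             dl$locus[d])
      }
      for (k in seq_len(config@smallPerIndividual))
        emit(randomDna(sample(73:300, 1L)), "small",
             sprintf("small_%s_%d", ind, k))
      for (cm in names(car$contamCarriers)) {
        if (!(ind %in% car$contamCarriers[[cm]])) next
        emit(maybeFlip(mutateSeq(refs$contaminants[[cm]],
                                 config@mutationRate)), "contaminant", cm)
      }
    }
    names(seqs) <- nms
    list(contigs = ContigSet(seqs),
         origin = DataFrame(contig = nms, origin = origin, source_id = src,
                            fragment = frag))
  })
}

## BLAST-like hits: contaminant contigs get significant non-primate hits
## (occasionally plus a weak primate hit); decoys and a fraction of NS get
## significant primate hits.
emitBlastHits <- function(config, origin) {
  withSubstream(config@seed, "hits", {
    rows <- list()
    for (i in seq_len(nrow(origin))) {
      ct <- origin$contig[i]
      if (origin$origin[i] == "contaminant") {
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = ct, taxon_group = "non_primate",
          e_value = 10^-stats::runif(1, 45, 120), stringsAsFactors = FALSE)
        if (stats::runif(1) < 0.3)
          rows[[length(rows) + 1L]] <- data.frame(
            query_id = ct, taxon_group = "primate",
            e_value = 10^-stats::runif(1, 5, 35), stringsAsFactors = FALSE)
      } else if (origin$origin[i] == "decoy") {
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = ct, taxon_group = "primate",
          e_value = 10^-stats::runif(1, 45, 150), stringsAsFactors = FALSE)
      } else if (origin$origin[i] == "ns" && stats::runif(1) < 0.3) {
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = ct, taxon_group = "primate",
          e_value = 10^-stats::runif(1, 41, 90), stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Emit per-individual insertion calls
#'
#' For every positioned NS and carrier, one breakpoint at the true position
#' plus rounded Normal(0, jitter) noise, plus a Poisson background of
#' spurious calls at random positions with random NS labels. Hybrid sites
#' (two NS sharing a position) were already built into the catalog by
#' \code{\link{buildReferences}}.
#'
#' @param config A \code{SimConfig}.
#' @param refs,car Outputs of \code{\link{buildReferences}} /
#'   \code{\link{drawCarriers}}.
#' @return data.frame: individual, chrom, position, ns_id.
#' @export
emitInsertionCalls <- function(config, refs, car) {
  withSubstream(config@seed, "calls", {
    cat <- refs$nsCatalog
    chromLen <- nchar(refs$humanRef)
    rows <- list()
    for (j in which(cat$positioned)) {
      for (ind in car$carriers[[cat$ns_id[j]]]) {
        p <- cat$position[j] + round(stats::rnorm(1, 0,
                                                  config@insertionJitterSd))
        p <- min(max(p, 0L), chromLen[[cat$chrom[j]]] - 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          individual = ind, chrom = cat$chrom[j], position = as.integer(p),
          ns_id = cat$ns_id[j], stringsAsFactors = FALSE)
      }
    }
    for (ind in car$individuals) {
      nf <- stats::rpois(1, config@falseCallsPerIndividual)
      for (k in seq_len(nf)) {
        ch <- sample(names(chromLen), 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          individual = ind, chrom = ch,
          position = sample.int(chromLen[[ch]], 1L) - 1L,
          ns_id = sample(cat$ns_id, 1L), stringsAsFactors = FALSE)
      }
    }
    if (length(rows) == 0L)
      return(data.frame(individual = character(0), chrom = character(0),
                        position = integer(0), ns_id = character(0),
                        stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Emit per-individual deletion calls against the chimp-like reference
#'
#' Individuals carrying fewer than two copies of an ancestral NS get a DEL
#' record over the deleted-region interval padded by Uniform(0, delPadMax)
#' bp per side: hom_alt for zero copies, het for one. Copy number per
#' carrier follows the diploid carrier model (a carrier has two copies with
#' probability a/(2-a), a the per-allele frequency implied by the carrier
#' frequency). A configurable fraction of records is labeled LowQual, and a
#' sprinkle of background records (PASS DUPs; DELs over ordinary reference
#' sequence that lift over) exercises the downstream filters.
#'
#' @param config A \code{SimConfig}.
#' @param refs,car Outputs of \code{\link{buildReferences}} /
#'   \code{\link{drawCarriers}}.
#' @return data.frame: individual, chrom, start, end, filter_status, svtype,
#'   genotype, ns_id (NA for background records).
#' @export
emitDeletionCalls <- function(config, refs, car) {
  withSubstream(config@seed, "deletions", {
    dr <- refs$deletedRegions
    chromLenC <- nchar(refs$chimpRef)
    rows <- list()
    for (r in seq_len(nrow(dr))) {
      nsId <- dr$ns_id[r]
      q <- car$trueAf[match(nsId, refs$nsCatalog$ns_id)]
      a <- 1 - sqrt(max(0, 1 - q))           # per-allele frequency
      pTwo <- if (a > 0) a / (2 - a) else 0  # P(two copies | carrier)
      isCar <- car$individuals %in% car$carriers[[nsId]]
      copies <- ifelse(isCar,
                       ifelse(stats::runif(length(isCar)) < pTwo, 2L, 1L), 0L)
      sel <- which(copies < 2L)
      if (length(sel) == 0L) next
      pad1 <- sample(0:config@delPadMax, length(sel), replace = TRUE)
      pad2 <- sample(0:config@delPadMax, length(sel), replace = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        individual = car$individuals[sel], chrom = dr$chrom[r],
        start = pmax(0L, dr$start[r] - pad1),
        end = pmin(chromLenC[[dr$chrom[r]]], dr$end[r] + pad2),
        filter_status = ifelse(
          stats::runif(length(sel)) < config@lowQualFraction,
          "LowQual", "PASS"),
        svtype = "DEL",
        genotype = ifelse(copies[sel] == 0L, "hom_alt", "het"),
        ns_id = nsId, stringsAsFactors = FALSE)
    }
    for (ind in car$individuals) {
      if (stats::runif(1) < 0.2) {   # background duplication (filtered out)
        ch <- sample(names(chromLenC), 1L)
        s <- sample.int(chromLenC[[ch]] - 5000L, 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          individual = ind, chrom = ch, start = s,
          end = s + sample(500:3000, 1L), filter_status = "PASS",
          svtype = "DUP", genotype = "het", ns_id = NA_character_,
          stringsAsFactors = FALSE)
      }
      if (stats::runif(1) < 0.2) {   # non-novel deletion (lifts over)
        ch <- sample(names(chromLenC), 1L)
        s <- sample.int(chromLenC[[ch]] - 5000L, 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          individual = ind, chrom = ch, start = s,
          end = s + sample(500:3000, 1L), filter_status = "PASS",
          svtype = "DEL", genotype = "het", ns_id = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows) == 0L)
      return(data.frame(individual = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        filter_status = character(0), svtype = character(0),
                        genotype = character(0), ns_id = character(0),
                        stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Emit unmapped-read SAM-flag records
#'
#' For each profiled individual, reads are either 150 bp windows of a
#' carried NS (mapped, flag 0, target = the NS or its mapped catalog entry)
#' with probability \code{urMappedFraction}, or unplaceable reads (flag 4).
#' A fraction of mapped reads is duplicated as secondary (0x100) and
#' supplementary (0x800) records, which must never change flag-filtered
#' counts. Populations are assigned round-robin from the four-group set.
#'
#' @param config A \code{SimConfig}.
#' @param refs,car Outputs of \code{\link{buildReferences}} /
#'   \code{\link{drawCarriers}}.
#' @param targetMap Optional named map ns_id -> target name (e.g. cluster
#'   id); identity by default.
#' @return list(reads = data.frame(individual, read_id, flag, target_id,
#'   ns_id), sampleSheet = data.frame(individual, population)).
#' @export
emitUnmappedReads <- function(config, refs, car, targetMap = NULL) {
  withSubstream(config@seed, "urreads", {
    cat <- refs$nsCatalog
    pops <- c("ACB", "CEU", "FIN", "YRI")
    inds <- car$individuals[seq_len(min(config@urIndividuals,
                                        length(car$individuals)))]
    sheet <- data.frame(individual = inds,
                        population = rep(pops, length.out = length(inds)),
                        stringsAsFactors = FALSE)
    carriedBy <- lapply(inds, function(ind)
      which(vapply(cat$ns_id, function(id) ind %in% car$carriers[[id]], TRUE)))
    names(carriedBy) <- inds
    rows <- list()
    for (ind in inds) {
      js <- carriedBy[[ind]]
      nR <- config@readsPerIndividual
      rid <- sprintf("%s_r%05d", ind, seq_len(nR))
      mapped <- length(js) > 0L & stats::runif(nR) < config@urMappedFraction
      nsIdx <- rep(NA_integer_, nR)
      if (any(mapped))
        nsIdx[mapped] <- if (length(js) == 1L) js else
          sample(js, sum(mapped), replace = TRUE, prob = cat$length[js])
      tgt <- ifelse(mapped, cat$ns_id[nsIdx], NA_character_)
      if (!is.null(targetMap)) tgt[mapped] <- unname(targetMap[tgt[mapped]])
      df <- data.frame(individual = ind, read_id = rid,
                       flag = ifelse(mapped, 0L, 4L), target_id = tgt,
                       ns_id = ifelse(mapped, cat$ns_id[nsIdx],
                                      NA_character_),
                       stringsAsFactors = FALSE)
      dup <- mapped & stats::runif(nR) < config@urDupFraction
      rows[[length(rows) + 1L]] <- df
      if (any(dup)) {
        d <- df[dup, , drop = FALSE]
        d2 <- d; d2$flag <- 256L
        d3 <- d; d3$flag <- 2048L
        rows[[length(rows) + 1L]] <- rbind(d2, d3)
      }
    }
    reads <- do.call(rbind, rows)
    rownames(reads) <- NULL
    list(reads = reads, sampleSheet = sheet)
  })
}

#' Generate a complete synthetic cohort
#'
#' Runs every emission stage of the generator under its named substream and
#' assembles a \code{\linkS4class{SyntheticCohort}}.
#'
#' @param config A \code{\link{simConfig}}.
#' @return A \code{SyntheticCohort}.
#' @export
#' @examples
#' co <- simulateCohort(simConfig(seed = 7, nIndividuals = 8, nNs = 6,
#'                                refLength = 60000L, nContaminants = 1L,
#'                                urIndividuals = 4L,
#'                                readsPerIndividual = 50L))
#' co
simulateCohort <- function(config) {
  refs <- buildReferences(config)
  car <- drawCarriers(config, refs)
  sim <- simulateIndividuals(config, refs, car)
  hits <- emitBlastHits(config, sim$origin)
  calls <- emitInsertionCalls(config, refs, car)
  dels <- emitDeletionCalls(config, refs, car)
  ur <- emitUnmappedReads(config, refs, car)
  truth <- DataFrame(refs$nsCatalog)
  truth$true_af <- car$trueAf
  truth$n_carriers <- car$nCarriers
  humanSet <- Biostrings::DNAStringSet(refs$humanRef)
  chimpSet <- Biostrings::DNAStringSet(refs$chimpRef)
  dr <- refs$deletedRegions
  delGr <- if (nrow(dr) > 0L)
    GenomicRanges::GRanges(dr$chrom, IRanges::IRanges(dr$start + 1L, dr$end),
                           ns_id = dr$ns_id, novelty_status = dr$status)
  else GenomicRanges::GRanges()
  hrt <- refs$humanRepeatTrack
  trackGr <- GenomicRanges::GRanges(hrt$chrom,
                                    IRanges::IRanges(hrt$start + 1L, hrt$end),
                                    label = hrt$class)
  S4Vectors::metadata(truth)$annotations <- refs$nsAnnotations
  new("SyntheticCohort", config = config, humanRef = humanSet,
      chimpRef = chimpSet, deletedRegions = delGr, truth = truth,
      carriers = car$carriers, contigs = sim$contigs,
      contigOrigin = sim$origin, blastHits = hits,
      humanRepeatTrack = trackGr, featureTracks = refs$featureTracks,
      insertionCalls = calls, deletionCalls = dels,
      urReads = ur$reads, sampleSheet = ur$sampleSheet)
}

#' Per-NS repeat annotations of a cohort
#' @param x A \code{SyntheticCohort}.
#' @return Named list (ns_id) of annotation data.frames (start, end, class).
#' @export
nsAnnotations <- function(x) S4Vectors::metadata(x@truth)$annotations

#' Write a synthetic cohort to disk
#'
#' Emits everything a file-based run of the pipeline consumes: references
#' (FASTA), per-individual contig FASTA, insertion-call BED and deletion
#' VCF, unmapped-read SAM, the feature-track BEDs, the truth/novelty TSVs
#' and the sample sheet.
#'
#' @param cohort A \code{SyntheticCohort}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "individuals"), showWarnings = FALSE)
  Biostrings::writeXStringSet(cohort@humanRef, file.path(dir, "human.fa"))
  Biostrings::writeXStringSet(cohort@chimpRef, file.path(dir, "chimp.fa"))
  inds <- unique(individualIds(cohort@contigs))
  ci <- individualIds(cohort@contigs)
  for (ind in inds) {
    writeContigFasta(cohort@contigs[ci == ind],
                     file.path(dir, "individuals", paste0(ind, ".fa")))
    calls <- cohort@insertionCalls
    calls <- calls[calls$individual == ind, , drop = FALSE]
    writeLines(paste(calls$chrom, calls$position, calls$position + 1L,
                     calls$ns_id, sep = "\t"),
               file.path(dir, "individuals", paste0(ind, ".calls.bed")))
    dels <- cohort@deletionCalls
    dels <- dels[dels$individual == ind, , drop = FALSE]
    writeDeletionVcf(dels, file.path(dir, "individuals",
                                     paste0(ind, ".del.vcf")), sample = ind)
    ur <- cohort@urReads
    ur <- ur[ur$individual == ind, , drop = FALSE]
    if (nrow(ur) > 0L)
      writeSamFlags(ur, file.path(dir, "individuals", paste0(ind, ".ur.sam")),
                    targets = unique(stats::na.omit(ur$target_id)))
  }
  for (nm in names(cohort@featureTracks)) {
    tr <- cohort@featureTracks[[nm]]
    writeLines(paste(tr$chrom, tr$start, tr$end, sep = "\t"),
               file.path(dir, paste0(nm, ".bed")))
  }
  tr <- as.data.frame(cohort@truth)
  tr$annotation <- NULL
  utils::write.table(tr, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dr <- cohort@deletedRegions
  if (length(dr) > 0L)
    writeLines(paste(as.character(GenomicRanges::seqnames(dr)),
                     GenomicRanges::start(dr) - 1L, GenomicRanges::end(dr),
                     dr$ns_id, dr$novelty_status, sep = "\t"),
               file.path(dir, "novelty.tsv"))
  utils::write.table(cohort@sampleSheet, file.path(dir, "sample_sheet.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
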