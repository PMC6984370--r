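test_that("reference construction conserves length and plants NS verbatim", {
  cfg <- tinyConfig(seed = 60)
  refs <- buildReferences(cfg)
  cat0 <- refs$nsCatalog
  anc <- cat0[cat0$ancestral, , drop = FALSE]
  expect_equal(sum(nchar(refs$chimpRef)) - sum(nchar(refs$humanRef)),
               sum(anc$length))
  ## every deleted-region slice of the chimp-like reference equals its NS
  dr <- refs$deletedRegions
  for (i in seq_len(nrow(dr))) {
    slice <- substr(refs$chimpRef[[dr$chrom[i]]], dr$start[i] + 1L,
                    dr$end[i])
    expect_equal(slice,
                 cat0$sequence[match(dr$ns_id[i], cat0$ns_id)])
  }
  ## zero ancestral NS: the references coincide
  refs0 <- buildReferences(tinyConfig(seed = 60, ancestralFraction = 0))
  expect_identical(refs0$chimpRef, refs0$humanRef)
})

test_that("NS lengths respect the configured range and annotations are valid", {
  cfg <- tinyConfig(seed = 61, nNs = 20L)
  refs <- buildReferences(cfg)
  expect_true(all(refs$nsCatalog$length >= 301L &
                    refs$nsCatalog$length <= 22701L))
  for (id in refs$nsCatalog$ns_id) {
    a <- refs$nsAnnotations[[id]]
    L <- refs$nsCatalog$length[match(id, refs$nsCatalog$ns_id)]
    if (nrow(a) == 0L) next
    expect_true(all(a$start >= 0L & a$end <= L & a$start < a$end))
    expect_true(all(a$class %in% repeatClasses()))
  }
})

test_that("carrier counts follow round(AF x N) and contigs are exact copies without error", {
  cfg <- tinyConfig(seed = 62, mutationRate = 0, fragmentationProb = 0)
  refs <- buildReferences(cfg)
  car <- drawCarriers(cfg, refs)
  expect_true(all(lengths(car$carriers) == car$nCarriers))
  expect_true(all(car$nCarriers >= 1L))
  expect_equal(car$trueAf, car$nCarriers / cfg@nIndividuals)
  sim <- simulateIndividuals(cfg, refs, car)
  org <- as.data.frame(sim$origin)
  nsRows <- org[org$origin == "ns", ]
  seqs <- as.character(contigSequences(sim$contigs))
  for (i in seq_len(nrow(nsRows))) {
    truthSeq <- refs$nsCatalog$sequence[
      match(nsRows$source_id[i], refs$nsCatalog$ns_id)]
    expect_identical(seqs[[nsRows$contig[i]]], truthSeq)
  }
  ## contig accounting: carried + decoys + small + contaminants
  nContam <- sum(lengths(car$contamCarriers))
  expect_equal(length(sim$contigs),
               sum(car$nCarriers) + cfg@nIndividuals *
                 (cfg@decoysPerIndividual + cfg@smallPerIndividual) + nContam)
})

test_that("fragmented contigs come in pairs of at least the minimum size", {
  cfg <- tinyConfig(seed = 63, mutationRate = 0, fragmentationProb = 1)
  refs <- buildReferences(cfg)
  car <- drawCarriers(cfg, refs)
  sim <- simulateIndividuals(cfg, refs, car)
  org <- as.data.frame(sim$origin)
  fr <- org[org$fragment, ]
  lens <- contigLengths(sim$contigs)
  if (nrow(fr) > 0L) {
    expect_true(all(lens[fr$contig] >= 301L))
    ## fragments of one carried NS pair up to the full length
    key <- paste(splitContigName(fr$contig)$individual, fr$source_id)
    sums <- tapply(lens[fr$contig], key, sum)
    truthLen <- refs$nsCatalog$length[
      match(sub("^\\S+ ", "", names(sums)), refs$nsCatalog$ns_id)]
    expect_equal(as.vector(sums), truthLen)
  }
})

test_that("insertion call jitter is centred with the configured spread", {
  cfg <- simConfig(seed = 64, nIndividuals = 60L, nNs = 40L,
                   refLength = 300000L, positionedFraction = 1,
                   hybridFraction = 0, falseCallsPerIndividual = 0,
                   nContaminants = 0L, nDecoyLoci = 2L,
                   decoysPerIndividual = 1L, urIndividuals = 2L,
                   readsPerIndividual = 10L)
  refs <- buildReferences(cfg)
  car <- drawCarriers(cfg, refs)
  calls <- emitInsertionCalls(cfg, refs, car)
  truthPos <- refs$nsCatalog$position[match(calls$ns_id,
                                            refs$nsCatalog$ns_id)]
  resid <- calls$position - truthPos
  expect_gt(nrow(calls), 100L)
  se <- 30 / sqrt(nrow(calls))
  expect_lt(abs(mean(resid)), 3 * se)
  expect_lt(abs(stats::sd(resid) - 30), 5)
  ## jitter-free calls are exact, and all calls are truthful carriers
  cfg0 <- simConfig(seed = 64, nIndividuals = 60L, nNs = 40L,
                    refLength = 300000L, positionedFraction = 1,
                    hybridFraction = 0, falseCallsPerIndividual = 0,
                    insertionJitterSd = 0, nContaminants = 0L,
                    nDecoyLoci = 2L, decoysPerIndividual = 1L,
                    urIndividuals = 2L, readsPerIndividual = 10L)
  calls0 <- emitInsertionCalls(cfg0, refs, car)
  expect_true(all(calls0$position ==
                    refs$nsCatalog$position[match(calls0$ns_id,
                                                  refs$nsCatalog$ns_id)]))
  ok <- vapply(seq_len(nrow(calls0)), function(i)
    calls0$individual[i] %in% car$carriers[[calls0$ns_id[i]]], TRUE)
  expect_true(all(ok))
})

test_that("deletion calls pad the truth interval and match the diploid model", {
  cfg <- tinyConfig(seed = 65)
  refs <- buildReferences(cfg)
  car <- drawCarriers(cfg, refs)
  dels <- emitDeletionCalls(cfg, refs, car)
  dr <- refs$deletedRegions
  nsDel <- dels[!is.na(dels$ns_id), , drop = FALSE]
  for (i in seq_len(nrow(nsDel))) {
    r <- dr[dr$ns_id == nsDel$ns_id[i], ]
    expect_equal(nsDel$chrom[i], r$chrom)
    ## padded interval contains the truth interval
    expect_lte(nsDel$start[i], r$start)
    expect_gte(nsDel$end[i], r$end)
    expect_lte(r$start - nsDel$start[i], cfg@delPadMax)
  }
  ## non-carriers are hom_alt, carriers with a record are het
  for (i in seq_len(nrow(nsDel))) {
    isCar <- nsDel$individual[i] %in% car$carriers[[nsDel$ns_id[i]]]
    expect_equal(nsDel$genotype[i], if (isCar) "het" else "hom_alt")
  }
})

test_that("unmapped-read emission hits the planted mapped fraction", {
  cfg <- tinyConfig(seed = 66, urIndividuals = 8L,
                    readsPerIndividual = 600L, urDupFraction = 0.1)
  refs <- buildReferences(cfg)
  car <- drawCarriers(cfg, refs)
  ur <- emitUnmappedReads(cfg, refs, car)
  ct <- countReads(ur$reads$flag)
  expect_equal(unname(ct["n_total"]), 8L * 600L)  # duplicates never counted
  ## the planted fraction applies to individuals carrying at least one NS
  carriersOf <- unique(unlist(car$carriers))
  profiled <- unique(ur$reads$individual)
  withNs <- intersect(profiled, carriersOf)
  sub <- ur$reads[ur$reads$individual %in% withNs, ]
  ctNs <- countReads(sub$flag)
  f <- ctNs[["n_mapped"]] / ctNs[["n_total"]]
  se <- sqrt(0.074 * (1 - 0.074) / ctNs[["n_total"]])
  expect_lt(abs(f - 0.074), 3 * se)
  ## mapped reads target NS the individual actually carries
  mapped <- ur$reads[ur$reads$flag == 0L, ]
  ok <- vapply(seq_len(nrow(mapped)), function(i)
    mapped$individual[i] %in% car$carriers[[mapped$ns_id[i]]], TRUE)
  expect_true(all(ok))
})

test_that("the generator is deterministic and emissions are independently regenerable", {
  cfg <- tinyConfig(seed = 67)
  co1 <- simulateCohort(cfg)
  co2 <- simulateCohort(cfg)
  expect_identical(as.character(contigSequences(cohortContigs(co1))),
                   as.character(contigSequences(cohortContigs(co2))))
  expect_identical(co1@insertionCalls, co2@insertionCalls)
  expect_identical(co1@deletionCalls, co2@deletionCalls)
  expect_identical(co1@urReads, co2@urReads)
  ## a single stage can be regenerated without rerunning the rest
  refs <- buildReferences(cfg)
  car <- drawCarriers(cfg, refs)
  expect_identical(emitInsertionCalls(cfg, refs, car), co1@insertionCalls)
  ## golden-file style: the on-disk emission is byte-identical across runs
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeCohort(co1, d1); writeCohort(co2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("written cohort files read back consistently", {
  cfg <- tinyConfig(seed = 68)
  co <- simulateCohort(cfg)
  d <- withr::local_tempdir()
  writeCohort(co, d)
  ind <- co@sampleSheet$individual[1]
  cs <- readContigFasta(file.path(d, "individuals", paste0(ind, ".fa")))
  expect_true(all(individualIds(cs) == ind))
  dels <- readDeletionVcf(file.path(d, "individuals",
                                    paste0(ind, ".del.vcf")))
  orig <- co@deletionCalls[co@deletionCalls$individual == ind, ]
  expect_equal(nrow(dels), nrow(orig))
  if (nrow(orig) > 0L) {
    expect_equal(dels$start, orig$start)
    expect_equal(dels$end, orig$end)
    expect_equal(dels$genotype, orig$genotype)
  }
  sam <- readSamFlags(file.path(d, "individuals", paste0(ind, ".ur.sam")))
  expect_equal(countReads(sam),
               countReads(co@urReads$flag[co@urReads$individual == ind]))
})
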