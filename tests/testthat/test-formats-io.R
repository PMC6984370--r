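test_that("FASTA contigs parse the IndividualXYZ_I naming convention", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">SweGen0010_1572", "acgt",
               ">A_B_7", "GGGAAA",
               ">Ind1_2 extra comment", "TTTT"), f)
  cs <- readContigFasta(f)
  expect_s4_class(cs, "ContigSet")
  expect_equal(names(cs), c("SweGen0010_1572", "A_B_7", "Ind1_2"))
  expect_equal(individualIds(cs), c("SweGen0010", "A_B", "Ind1"))
  expect_equal(unname(contigLengths(cs)), c(4L, 6L, 4L))
  expect_equal(as.character(contigSequences(cs)[[1]]), "ACGT")

  empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  expect_length(readContigFasta(empty), 0L)

  bad <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">nounderscore", "ACGT"), bad)
  expect_error(readContigFasta(bad), "nounderscore")
})

test_that("contig FASTA writing round-trips", {
  cs <- ContigSet(c(Ind01_1 = "ACGTACGTAA", Ind02_1 = "GGGTTTCCAA"))
  f <- withr::local_tempfile(fileext = ".fa")
  writeContigFasta(cs, f)
  back <- readContigFasta(f)
  expect_equal(as.character(contigSequences(back)),
               as.character(contigSequences(cs)))
})

test_that("show-coords tables convert 1-based inclusive to 0-based half-open", {
  f <- withr::local_tempfile()
  writeLines(c(paste(201, 300, 1, 100, 100, 100, "96.00", "10.00", "91.00",
                     "chr1", "q1", sep = "\t"),
               paste(500, 301, 5, 204, 200, 200, "88.00", "2.00", "50.00",
                     "chr2", "q2", sep = "\t")), f)
  h <- readCoordsTable(f)
  expect_equal(h$query_start[1], 0L)
  expect_equal(h$query_end[1], 100L)
  expect_equal(h$target_start[1], 200L)
  expect_equal(h$identity_pct[1], 96)
  expect_equal(h$query_cov_pct[1], 91)
  ## reversed target coordinates mean a minus-strand hit, swapped ascending
  expect_equal(h$strand[2], "-")
  expect_equal(h$target_start[2], 300L)
  expect_equal(h$target_end[2], 500L)

  empty <- withr::local_tempfile()
  writeLines(character(0), empty)
  expect_equal(nrow(readCoordsTable(empty)), 0L)

  bad <- withr::local_tempfile()
  writeLines("1\t2\t3", bad)
  expect_error(readCoordsTable(bad), "line 1")
})

test_that("coords writing is the inverse of reading", {
  f <- withr::local_tempfile()
  lines <- c(paste(201, 300, 1, 100, 100, 100, "96.00", "10.00", "91.00",
                   "chr1", "q1", sep = "\t"),
             paste(500, 301, 5, 204, 200, 200, "88.00", "2.00", "50.00",
                   "chr2", "q2", sep = "\t"))
  writeLines(lines, f)
  h <- readCoordsTable(f)
  f2 <- withr::local_tempfile()
  writeCoordsTable(h, f2)
  expect_identical(readCoordsTable(f2), h)
})

test_that("RepeatMasker .out parsing maps classes and resolves overlaps by score", {
  f <- withr::local_tempfile(fileext = ".out")
  writeLines(c(
    "   SW  perc perc perc  query     position in query",
    "score  div. del. ins.  sequence  begin end",
    "",
    "  500  10.0  0.0  0.0  c1  1  100  (300)  +  L1PA3  LINE/L1  1 100 (0) 1",
    "  300  12.0  0.0  0.0  c1  81 150  (250)  +  AluY   SINE/Alu 1 70  (0) 2",
    "  200   5.0  0.0  0.0  c2  11  40  (60)   +  (CA)n  Simple_repeat 1 30 (0) 3"),
    f)
  ann <- readRepeatMaskerOut(f, c(c1 = 400L, c2 = 100L, c3 = 50L))
  a1 <- ann$c1
  ## score 500 wins the 81-100 overlap; SINE keeps 100-150
  expect_equal(a1$class, c("LINE", "SINE"))
  expect_equal(a1$start, c(0L, 100L))
  expect_equal(a1$end, c(100L, 150L))
  expect_equal(ann$c2$class, "Simple_repeat")
  expect_equal(nrow(ann$c3), 0L)  # unannotated contig stays fully unmasked
  expect_error(readRepeatMaskerOut(f, c(c1 = 400L)), "c2")
})

test_that("BED4 round-trips losslessly and rejects invalid intervals", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20\tgene", "chr2\t0\t5\tx"), f)
  gr <- readBedFile(f)
  expect_equal(GenomicRanges::start(gr) - 1L, c(10L, 0L))
  expect_equal(GenomicRanges::end(gr), c(20L, 5L))
  expect_equal(gr$label, c("gene", "x"))
  f2 <- withr::local_tempfile(fileext = ".bed")
  writeBedFile(gr, f2)
  expect_identical(readLines(f2), readLines(f))

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t20\t10\tx", bad)
  expect_error(readBedFile(bad), "line 1")
  neg <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t-5\t10\tx", neg)
  expect_error(readBedFile(neg), "line 1")
})

test_that("deletion VCF reading converts coordinates and genotypes", {
  recs <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                     start = c(100L, 500L, 40L), end = c(200L, 700L, 90L),
                     filter_status = c("PASS", "LowQual", "PASS"),
                     svtype = c("DEL", "DEL", "DUP"),
                     genotype = c("het", "missing", "hom_alt"),
                     stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".vcf")
  writeDeletionVcf(recs, f, sample = "IndX")
  back <- readDeletionVcf(f)
  expect_equal(back$individual, rep("IndX", 3))
  expect_equal(back$start, recs$start)    # POS=101 END=200 -> [100, 200)
  expect_equal(back$end, recs$end)
  expect_equal(back$filter_status, recs$filter_status)
  ## non-DEL structural types collapse to "other"
  expect_equal(back$svtype, c("DEL", "DEL", "other"))
  expect_equal(back$genotype, recs$genotype)
})

test_that("SAM flag streams parse headers, flags and unmapped targets", {
  recs <- data.frame(read_id = c("r1", "r2", "r3", "r4"),
                     flag = c(0L, 4L, 2048L, 256L),
                     target_id = c("t1", NA, "t1", "t2"),
                     stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".sam")
  writeSamFlags(recs, f, targets = c("t1", "t2"))
  back <- readSamFlags(f)
  expect_equal(back$flag, recs$flag)
  expect_true(is.na(back$target_id[2]))  # unmapped bit set -> target unset
  expect_equal(back$target_id[3], "t1")

  bad <- withr::local_tempfile(fileext = ".sam")
  writeLines("r1\tnotaflag\tt1", bad)
  expect_error(readSamFlags(bad), "flag")
})
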