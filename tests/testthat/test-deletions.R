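mkRec <- function(ind, chrom, start, end, gt = "het", filt = "PASS",
                  sv = "DEL") {
  data.frame(individual = ind, chrom = chrom, start = start, end = end,
             filter_status = filt, svtype = sv, genotype = gt,
             stringsAsFactors = FALSE)
}

test_that("deletion filtering keeps only PASS DEL records", {
  recs <- rbind(mkRec("a", "c1", 0L, 100L),
                mkRec("b", "c1", 0L, 100L, filt = "LowQual"),
                mkRec("c", "c1", 0L, 100L, sv = "DUP"))
  out <- filterDeletions(recs)
  expect_equal(out$individual, "a")
  expect_equal(unname(attr(out, "removed")), c(1L, 1L))
})

test_that("reciprocal-overlap merging follows the 0.7 rule", {
  two <- rbind(mkRec("a", "c1", 0L, 100L), mkRec("b", "c1", 0L, 100L))
  m <- mergeDeletions(two)
  expect_equal(nrow(m), 1L)
  expect_equal(m$n_calls, 2L)
  ## [0,100) vs [65,165): overlap 35 < 70 -> two variants
  m2 <- mergeDeletions(rbind(mkRec("a", "c1", 0L, 100L),
                             mkRec("b", "c1", 65L, 165L)))
  expect_equal(nrow(m2), 2L)
  ## representative is the longest member
  m3 <- mergeDeletions(rbind(mkRec("a", "c1", 10L, 100L),
                             mkRec("b", "c1", 0L, 110L)))
  expect_equal(m3$start, 0L)
  expect_equal(m3$end, 110L)
  ## an individual with two linked calls keeps the most deleted genotype
  m4 <- mergeDeletions(rbind(mkRec("a", "c1", 0L, 100L, gt = "het"),
                             mkRec("a", "c1", 2L, 102L, gt = "hom_alt")))
  expect_equal(unname(m4$genotypes[[1]]["a"]), "hom_alt")
})

test_that("merging equals the brute-force component oracle and is idempotent", {
  set.seed(50)
  n <- 200L
  recs <- data.frame(individual = sprintf("i%03d", sample.int(50L, n, TRUE)),
                     chrom = sample(c("c1", "c2"), n, TRUE),
                     start = s <- sample.int(50000L, n, TRUE),
                     stringsAsFactors = FALSE)
  recs$end <- recs$start + sample(200:3000, n, TRUE)
  recs$filter_status <- "PASS"; recs$svtype <- "DEL"
  recs$genotype <- sample(c("het", "hom_alt"), n, TRUE)
  m <- mergeDeletions(recs)
  comp <- bruteReciprocalComponents(recs)
  expect_equal(nrow(m), length(unique(comp)))
  expect_equal(sum(m$n_calls), n)
  ## component sizes match
  expect_equal(sort(m$n_calls), sort(unname(as.integer(table(comp)))))
  ## idempotence: merging representatives again changes nothing
  reps <- m[, c("chrom", "start", "end")]
  reps$individual <- sprintf("r%04d", seq_len(nrow(reps)))
  reps$genotype <- "het"
  m2 <- mergeDeletions(reps)
  expect_equal(nrow(m2), nrow(m))
  expect_equal(m2[, c("chrom", "start", "end")],
               m[, c("chrom", "start", "end")])
})

test_that("NS intersection and novelty flags gate the CRA analysis", {
  m <- mergeDeletions(rbind(mkRec("a", "c1", 1000L, 3000L),
                            mkRec("b", "c2", 500L, 900L)))
  ns <- data.frame(chrom = "c1", start = 1500L, end = 2000L, ns_id = "ns1")
  mi <- intersectWithNS(m, ns)
  expect_equal(nrow(mi), 1L)
  expect_equal(mi$overlapping_ns[[1]], "ns1")
  ## adjacent half-open intervals do not overlap
  nsAdj <- data.frame(chrom = "c2", start = 900L, end = 1200L, ns_id = "ns2")
  expect_equal(nrow(intersectWithNS(m, nsAdj)), 0L)
  nov <- data.frame(chrom = "c1", start = 1500L, end = 2000L,
                    status = "deleted_in_new")
  mn <- checkNovelty(mi, nov)
  expect_true(all(mn$novel_vs_human))
  novNo <- data.frame(chrom = "c1", start = 1500L, end = 2000L,
                      status = "lifts_over")
  expect_equal(nrow(checkNovelty(mi, novNo)), 0L)
})

test_that("CRA carriers are everyone but hom_alt individuals", {
  m <- mergeDeletions(rbind(
    mkRec("a", "c1", 0L, 1000L, gt = "hom_alt"),
    mkRec("b", "c1", 0L, 1000L, gt = "het"),
    mkRec("c", "c1", 0L, 1000L, gt = "missing")))
  cf <- craFrequency(m, 96L)
  expect_equal(cf$cra_carriers, 95L)           # only "a" lacks the CRA
  expect_true(cf$common)
  expect_equal(cf$cra_allele_freq, (192 - 2 - 1) / 192)
  ## no hom_alt anywhere: present in all individuals
  m0 <- mergeDeletions(mkRec("b", "c1", 0L, 1000L, gt = "het"))
  expect_equal(craFrequency(m0, 96L)$cra_carriers, 96L)
  ## everyone hom_alt in a cohort of 10: zero carriers
  mAll <- mergeDeletions(do.call(rbind, lapply(sprintf("i%02d", 1:10),
    function(i) mkRec(i, "c1", 0L, 1000L, gt = "hom_alt"))))
  cfAll <- craFrequency(mAll, 10L)
  expect_equal(cfAll$cra_carriers, 0L)
  expect_equal(cfAll$cra_carrier_freq, 0)
  expect_error(craFrequency(mAll, 5L), "cohort")
})

test_that("missing genotypes never reduce carrier counts", {
  m <- mergeDeletions(rbind(mkRec("a", "c1", 0L, 1000L, gt = "missing"),
                            mkRec("b", "c1", 0L, 1000L, gt = "missing")))
  expect_equal(craFrequency(m, 20L)$cra_carriers, 20L)
})
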