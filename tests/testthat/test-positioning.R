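test_that("dbscan1d matches hand-worked cases", {
  ## 50 and 100 are core; the chain connects 0 and 160 into one cluster
  expect_equal(dbscan1d(c(0, 50, 100, 160)), rep(1L, 4))
  expect_equal(dbscan1d(c(0, 1000, 2000)), rep(-1L, 3))
  expect_equal(dbscan1d(integer(0)), integer(0))
  ## two well-separated dense groups
  lab <- dbscan1d(c(0, 10, 20, 30, 5000, 5010, 5020, 5030))
  expect_equal(lab, c(rep(1L, 4), rep(2L, 4)))
  ## labels are reported in input order
  lab2 <- dbscan1d(c(5000, 0, 5010, 10, 5020, 20, 5030, 30))
  expect_equal(lab2, c(2L, 1L, 2L, 1L, 2L, 1L, 2L, 1L))
})

test_that("dbscan1d equals the brute-force oracle on random points", {
  set.seed(30)
  for (rep in 1:5) {
    pos <- sample.int(20000L, 300L, replace = TRUE)
    mine <- dbscan1d(pos, eps = 150, minNeighbors = 3)
    ref <- bruteDbscan1d(pos, eps = 150, minNeighbors = 3)
    expect_equal(labelPartition(mine), labelPartition(ref))
  }
})

test_that("insertion merging applies the support and human-match filters", {
  cls <- data.frame(cluster_id = c("nsA", "nsB", "nsC"),
                    matches_human = c(FALSE, FALSE, TRUE))
  mk <- function(ns, inds, pos) data.frame(
    individual = inds, chrom = "chr1", position = pos, ns_id = ns)
  ## 6 individuals within 150 bp -> one merged event
  calls <- mk("nsA", paste0("I", 1:6), c(100, 120, 140, 160, 180, 200))
  m <- mergeInsertions(calls, cls)
  expect_equal(nrow(m), 1L)
  expect_equal(m$n_individuals, 6L)
  expect_equal(m$ns_id, "nsA")
  ## 4 individuals only -> discarded
  m4 <- mergeInsertions(mk("nsA", paste0("I", 1:4), c(100, 120, 140, 160)),
                        cls)
  expect_equal(nrow(m4), 0L)
  ## NS matching the human reference dropped before merging
  mH <- mergeInsertions(mk("nsC", paste0("I", 1:6),
                           c(100, 120, 140, 160, 180, 200)), cls)
  expect_equal(nrow(mH), 0L)
  expect_error(mergeInsertions(mk("nsZ", "I1", 5), cls), "unknown NS")
})

test_that("co-located events of different NS are removed as hybrids", {
  cls <- data.frame(cluster_id = c("nsA", "nsB"),
                    matches_human = c(FALSE, FALSE))
  callsA <- data.frame(individual = paste0("I", 1:6), chrom = "chr1",
                       position = c(100, 120, 140, 160, 180, 200),
                       ns_id = "nsA")
  callsB <- callsA
  callsB$ns_id <- "nsB"
  callsB$position <- callsB$position + 40
  both <- rbind(callsA, callsB)
  expect_equal(nrow(mergeInsertions(both, cls)), 0L)
  ## far apart they both survive
  callsB$position <- callsB$position + 100000
  expect_equal(nrow(mergeInsertions(rbind(callsA, callsB), cls)), 2L)
})

test_that("interval intersection uses half-open arithmetic and matches the naive oracle", {
  ev <- data.frame(chrom = "chr1", start = 10L, end = 20L, ns_id = "a")
  expect_equal(intersectFeatures(
    ev, data.frame(chrom = "chr1", start = 19L, end = 25L))$n_overlapping, 1L)
  expect_equal(intersectFeatures(
    ev, data.frame(chrom = "chr1", start = 20L, end = 30L))$n_overlapping, 0L)
  set.seed(31)
  evs <- data.frame(chrom = sample(c("c1", "c2"), 400, TRUE),
                    start = s <- sample.int(100000L, 400, TRUE))
  evs$end <- evs$start + sample(50:500, 400, TRUE)
  fts <- data.frame(chrom = sample(c("c1", "c2"), 400, TRUE),
                    start = s2 <- sample.int(100000L, 400, TRUE))
  fts$end <- fts$start + sample(50:500, 400, TRUE)
  mine <- intersectFeatures(evs, fts)$pairs
  ref <- naiveIntersect(evs, fts)
  o <- function(d) d[order(d$event, d$feature), ]
  expect_equal(unname(as.matrix(o(mine))), unname(as.matrix(o(ref))))
})

test_that("simulated null overlap matches the closed-form hit probability", {
  ## one 10 kb feature on a 1 Mb chromosome, 1 kb regions:
  ## P(hit) = (10000 + 1000 - 1) / (1e6 - 1000 + 1)
  ft <- data.frame(chrom = "chr1", start = 500000L, end = 510000L)
  sim <- simulateNullOverlap(c(chr1 = 1000000L), ft, nRegions = 50L,
                             regionSize = 1000L, iterations = 400L, seed = 4)
  pTrue <- 10999 / 999001
  se <- sqrt(pTrue * (1 - pTrue) / sim$n_draws)
  expect_lt(abs(sim$simulated_pct / 100 - pTrue), 3 * se)
  ## degenerate tracks
  full <- data.frame(chrom = "chr1", start = 0L, end = 1000000L)
  expect_equal(simulateNullOverlap(c(chr1 = 1000000L), full, 10L,
                                   iterations = 5L, seed = 1)$simulated_pct,
               100)
  expect_equal(simulateNullOverlap(c(chr1 = 1000000L), full[0, ], 10L,
                                   iterations = 5L, seed = 1)$simulated_pct,
               0)
})

test_that("binomial enrichment gives exact two-sided p-values and directions", {
  ## k = 0, n = 100, p0 = 0.5: both tails have mass 0.5^100
  b <- binomialEnrichment(0L, 100L, 50)
  expect_equal(b$p_value, 2 * 0.5^100, tolerance = 1e-12)
  expect_equal(b$direction, "depleted")
  b2 <- binomialEnrichment(85L, 100L, 4)
  expect_lt(b2$p_value, 1e-15)
  expect_equal(b2$direction, "enriched")
  b3 <- binomialEnrichment(50L, 100L, 50)
  expect_equal(b3$p_value, 1)
  expect_equal(b3$direction, "none")
  expect_error(binomialEnrichment(5L, 0L, 50))
})

test_that("planted in-feature bias is detected and only where planted", {
  set.seed(32)
  chromLen <- c(chr1 = 500000L)
  ftA <- data.frame(chrom = "chr1", start = seq(0L, 450000L, by = 50000L))
  ftA$end <- ftA$start + 10000L         # 20% of the genome
  ftB <- data.frame(chrom = "chr1", start = seq(25000L, 475000L,
                                                by = 50000L))
  ftB$end <- ftB$start + 10000L         # disjoint 20%
  ## events biased into track A: 70% inside A, 30% uniform
  n <- 200L
  inA <- stats::runif(n) < 0.7
  st <- ifelse(inA,
               ftA$start[sample.int(nrow(ftA), n, TRUE)] +
                 sample.int(9000L, n, TRUE),
               sample.int(499000L, n, TRUE))
  ev <- data.frame(chrom = "chr1", start = st, end = st + 100L,
                   ns_id = sprintf("ns%03d", seq_len(n)))
  enr <- featureEnrichment(ev, list(A = ftA, B = ftB), chromLen,
                           iterations = 300L, seed = 6)
  expect_lt(enr$p_value[enr$feature == "A"], 0.001 / 2)
  expect_equal(enr$direction[enr$feature == "A"], "enriched")
  ## the complement track is correspondingly depleted
  expect_equal(enr$direction[enr$feature == "B"], "depleted")
  ## and unbiased events flag neither track
  st0 <- sample.int(499000L, n, TRUE)
  ev0 <- data.frame(chrom = "chr1", start = st0, end = st0 + 100L,
                    ns_id = sprintf("ns%03d", seq_len(n)))
  enr0 <- featureEnrichment(ev0, list(A = ftA, B = ftB), chromLen,
                            iterations = 300L, seed = 6)
  expect_true(all(enr0$p_value > 0.001))
})
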