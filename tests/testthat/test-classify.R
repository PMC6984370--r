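test_that("anchor aligner finds exact substrings with full identity and coverage", {
  set.seed(10)
  ref <- c(chrA = randDna(20000), chrB = randDna(15000))
  q <- substr(ref[["chrA"]], 5001, 5600)
  h <- alignToReference(q, ref)
  expect_gt(nrow(h), 0L)
  expect_equal(h$identity_pct[1], 100)
  expect_equal(h$query_cov_pct[1], 100)
  expect_equal(h$target_id[1], "chrA")
  expect_equal(h$target_start[1], 5000L)
  expect_equal(h$strand[1], "+")
})

test_that("anchor aligner recovers reverse-strand and mutated queries", {
  set.seed(11)
  ref <- c(chrA = randDna(30000))
  q <- revcomp(substr(ref[["chrA"]], 1001, 1800))
  h <- alignToReference(q, ref)
  expect_equal(h$strand[1], "-")
  expect_equal(h$identity_pct[1], 100)
  expect_equal(h$query_cov_pct[1], 100)
  ## 0.5% mutations: the best hit stays confident
  qm <- mutate(substr(ref[["chrA"]], 10001, 11000), 0.005)
  hm <- alignToReference(qm, ref)
  expect_gte(hm$identity_pct[1], 98)
  expect_gte(hm$query_cov_pct[1], 90)
})

test_that("random queries produce no hits and short queries warn", {
  set.seed(12)
  ref <- c(chrA = randDna(20000))
  h <- alignToReference(randDna(500), ref)
  expect_equal(nrow(h), 0L)
  expect_warning(h2 <- alignToReference(randDna(20), ref), "shorter")
  expect_equal(nrow(h2), 0L)
})

test_that("aligner identity agrees with the local-alignment oracle on mutated queries", {
  set.seed(13)
  ref <- c(chrA = randDna(20000))
  for (div in c(0.005, 0.02)) {
    q <- mutate(substr(ref[["chrA"]], 2001, 3500), div)
    h <- alignToReference(q, ref)
    st <- pairwiseIdentityCoverage(q, substr(ref[["chrA"]], 2001, 3500))
    expect_lt(abs(h$identity_pct[1] - 100 * st[["identity"]]), 2)
  }
})

test_that("classification thresholds are strict as printed", {
  mk <- function(id, cov) data.frame(cluster_id = "c1", reference = "human",
                                     identity_pct = id, query_cov_pct = cov)
  ## (96, 91): confident, not NS
  r <- classifyClusters(mk(96, 91), "c1")
  expect_equal(nrow(r$confident), 1L)
  expect_false(r$classification$is_ns)
  ## boundary (95, 91): NOT confident
  r <- classifyClusters(mk(95, 91), "c1")
  expect_equal(nrow(r$confident), 0L)
  ## (96, 90): NOT confident either
  expect_equal(nrow(classifyClusters(mk(96, 90), "c1")$confident), 0L)
  ## (85, 40): not confident, still NS (coverage fails the blocking rule)
  r <- classifyClusters(mk(85, 40), "c1")
  expect_true(r$classification$is_ns)
  ## (85, 60): blocks NS status
  expect_false(classifyClusters(mk(85, 60), "c1")$classification$is_ns)
  ## boundary (80, 60) does not block (strict >)
  expect_true(classifyClusters(mk(80, 60), "c1")$classification$is_ns)
  ## no hits at all -> NS
  r <- classifyClusters(mk(96, 91)[0, ], "c1")
  expect_true(r$classification$is_ns)
})

test_that("raising thresholds never enlarges the confident set", {
  set.seed(14)
  hits <- data.frame(cluster_id = rep(sprintf("c%02d", 1:30), each = 2),
                     reference = "human",
                     identity_pct = runif(60, 80, 100),
                     query_cov_pct = runif(60, 60, 100))
  ids <- sprintf("c%02d", 1:30)
  base <- classifyClusters(hits, ids)
  for (k in 1:5) {
    thr <- classificationThresholds(
      confidentIdentity = 95 + k, confidentCoverage = 90 + k)
    tight <- classifyClusters(hits, ids, thresholds = thr)
    expect_true(all(paste(tight$confident$cluster_id, tight$confident$reference)
                    %in% paste(base$confident$cluster_id,
                               base$confident$reference)))
  }
})

test_that("catalog membership partitions clusters into reference subsets", {
  conf <- data.frame(cluster_id = c("c1", "c1", "c2"),
                     reference = c("human", "chimp", "chimp"))
  m <- catalogMembership(conf, c("c1", "c2", "c3"),
                         references = c("chimp", "human"))
  expect_equal(m$membership$subset, c("chimp+human", "chimp", ""))
  expect_equal(m$n_any, 2L)
  expect_equal(sum(m$counts$n), 3L)  # union of subsets covers all clusters
})

test_that("position binning densities sum to 100 and count empty bins", {
  best <- data.frame(cluster_id = c("c1", "c2", "c3"),
                     target_id = c("chr1", "chr1", "chr2"),
                     target_start = c(0L, 100L, 4000000L),
                     target_end = c(1000L, 1100L, 4001000L))
  b <- binPositions(best, c(chr1 = 6000000L, chr2 = 6000000L))
  expect_equal(sum(b$bins$count), 3L)
  expect_equal(sum(b$bins$density_pct), 100)
  expect_equal(b$zero_bin_fraction, 0.5)
  one <- binPositions(best[1, ], c(chr1 = 3000000L))
  expect_equal(one$bins$density_pct, 100)
})

test_that("AF subsets are nested and boundary-inclusive", {
  set.seed(15)
  seqs <- stats::setNames(replicate(6, randDna(400)),
                          sprintf("Ind%02d_1", 1:6))
  cl <- clusterAlleleFrequencies(greedyCluster(ContigSet(seqs)), 100)
  ths <- c(0, 0.005, 0.01, 0.025, 0.05, 0.075, 0.10)
  sizes <- vapply(ths, function(t) length(subsetByAF(cl, t)), 0L)
  expect_equal(sizes[1], length(cl))            # minAf 0 is the identity
  expect_true(all(diff(sizes) <= 0))            # monotone nesting
  expect_equal(length(subsetByAF(cl, 0.01)), 6L)  # AF = 0.01 kept at t = 0.01
  expect_equal(length(subsetByAF(cl, 0.011)), 0L)
})
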