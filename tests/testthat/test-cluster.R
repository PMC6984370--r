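test_that("size filter partitions contigs at the 301 bp boundary", {
  cs <- ContigSet(c(Ind1_1 = randDna(300), Ind1_2 = randDna(301),
                    Ind2_1 = randDna(5000)))
  out <- filterBySize(cs)
  expect_equal(names(out$kept), c("Ind1_2", "Ind2_1"))
  expect_equal(names(out$removed), "Ind1_1")
  expect_equal(length(out$kept) + length(out$removed), length(cs))

  empty <- ContigSet(Biostrings::DNAStringSet())
  out0 <- filterBySize(empty)
  expect_length(out0$kept, 0L)
  expect_length(out0$removed, 0L)

  allBig <- filterBySize(cs[2:3])
  expect_length(allBig$removed, 0L)
})

test_that("contaminant rule needs a significant non-primate hit and no primate hit", {
  set.seed(1)
  cs <- ContigSet(stats::setNames(replicate(4, randDna(400)),
                                  paste0("Ind", 1:4, "_1")))
  cl <- greedyCluster(cs)
  reps <- clusterTable(cl)$representative
  hits <- data.frame(
    query_id = c(reps[1], reps[2], reps[2], reps[3]),
    taxon_group = c("non_primate", "non_primate", "primate", "non_primate"),
    e_value = c(1e-50, 1e-50, 1e-45, 1e-30))
  out <- classifyContaminants(cl, hits)
  contamReps <- clusterTable(out$contaminant)$representative
  ## rep1: non-primate only -> contaminant; rep2: rescued by primate hit;
  ## rep3: non-primate hit not significant; rep4: no hits -> clean
  expect_equal(contamReps, reps[1])
  expect_equal(length(out$clean), 3L)
})

test_that("pairwise identity/coverage handles identity, mismatch and strand", {
  set.seed(2)
  a <- randDna(100)
  expect_equal(unname(pairwiseIdentityCoverage(a, a)[1:3]), c(1, 1, 1))
  ## one substitution mid-sequence: 99 matches over 100 columns
  b <- a
  substr(b, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                               substr(a, 50, 50))[1]
  st <- pairwiseIdentityCoverage(a, b)
  expect_equal(unname(st["identity"]), 0.99, tolerance = 1e-9)
  rc <- revcomp(a)
  expect_equal(unname(pairwiseIdentityCoverage(a, rc)[1:3]), c(1, 1, 1))
  expect_equal(unname(pairwiseIdentityCoverage(a, rc)["strand"]), -1)
})

test_that("unrelated random sequences form separate clusters, identical ones merge", {
  set.seed(3)
  cs <- ContigSet(c(IndA_1 = randDna(1000), IndB_1 = randDna(1000)))
  expect_length(greedyCluster(cs), 2L)

  s <- randDna(500)
  cs2 <- ContigSet(c(IndA_1 = s, IndB_1 = s, IndC_1 = s))
  cl2 <- greedyCluster(cs2)
  expect_length(cl2, 1L)
  expect_equal(clusterTable(cl2)$n_individuals, 3L)
  af <- clusterAlleleFrequencies(cl2, 100)
  expect_equal(unname(alleleFrequencies(af)), 0.03)
})

test_that("greedy clustering equals the brute-force join-rule oracle on a planted mixture", {
  set.seed(4)
  mix <- plantedContigMixture(nClusters = 15, maxCopies = 4,
                              lenRange = c(301, 500), divergence = 0.01)
  cl <- greedyCluster(ContigSet(mix$seqs))
  mine <- split(clusterMembers(cl)$contig, clusterMembers(cl)$cluster_id)
  oracle <- bruteGreedyCluster(unname(mix$seqs), names(mix$seqs))
  ref <- split(names(oracle), oracle)
  expect_equal(partitionSignature(mine), partitionSignature(ref))
})

test_that("clustering is a partition and invariant to input order", {
  set.seed(5)
  mix <- plantedContigMixture(nClusters = 8, maxCopies = 3,
                              lenRange = c(301, 450), divergence = 0.01)
  cl1 <- greedyCluster(ContigSet(mix$seqs))
  expect_setequal(clusterMembers(cl1)$contig, names(mix$seqs))
  expect_false(anyDuplicated(clusterMembers(cl1)$contig) > 0)
  perm <- sample(length(mix$seqs))
  cl2 <- greedyCluster(ContigSet(mix$seqs[perm]))
  sig <- function(x) partitionSignature(
    split(clusterMembers(x)$contig, clusterMembers(x)$cluster_id))
  expect_equal(sig(cl1), sig(cl2))
})

test_that("allele frequencies count distinct individuals and flag rare clusters", {
  s1 <- randDna(400); s2 <- randDna(400)
  cs <- ContigSet(c(A_1 = s1, B_1 = s1, A_2 = s1, C_1 = s2))
  cl <- clusterAlleleFrequencies(greedyCluster(cs), 100)
  af <- alleleFrequencies(cl)
  tab <- clusterTable(cl)
  ## members {A, B, A} -> AF 2/100, rare
  i <- which(tab$n_members == 3L)
  expect_equal(unname(af[tab$cluster_id[i]]), 0.02)
  s <- afSummary(cl)
  expect_equal(s$fraction_rare, 1)
  expect_error(clusterAlleleFrequencies(greedyCluster(cs), 1), "cohort")
})

test_that("cluster output files carry the summary columns", {
  s <- randDna(400)
  cl <- clusterAlleleFrequencies(
    greedyCluster(ContigSet(c(A_1 = s, B_1 = s, C_1 = randDna(350)))), 10)
  pre <- file.path(withr::local_tempdir(), "clusters")
  writeClusters(cl, pre)
  tsv <- read.delim(paste0(pre, ".tsv"))
  expect_equal(nrow(tsv), 2L)
  expect_true(all(c("cluster_id", "representative", "n_individuals", "af")
                  %in% colnames(tsv)))
  clstr <- readLines(paste0(pre, ".clstr"))
  expect_equal(sum(startsWith(clstr, ">Cluster")), 2L)
})

test_that("cluster-level size filter removes small-representative clusters", {
  cs <- ContigSet(c(Ind1_1 = randDna(250), Ind2_1 = randDna(400)))
  out <- filterClustersBySize(greedyCluster(cs))
  expect_equal(length(out$kept), 1L)
  expect_equal(clusterTable(out$kept)$rep_length, 400L)
})
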