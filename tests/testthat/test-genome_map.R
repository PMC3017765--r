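mkloci <- function(genes, chrom, starts, strands, fam = TRUE) {
  data.frame(gene_id = genes, chrom = chrom, start = starts,
             end = starts + 999L, strand = strands,
             in_family = fam, stringsAsFactors = FALSE)
}

test_that("a six-gene same-orientation array with one interloper forms one cluster", {
  fam <- mkloci(paste0("cce", 1:6), "chr25", seq(1000, by = 5000,
                                                 length.out = 6), "+")
  other <- mkloci("bystander", "chr25", 13500L, "-", fam = FALSE)
  cl <- detectClusters(rbind(fam, other))
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$n_members, 6L)
  expect_identical(cl$orientation_pattern, "++++++")
  expect_identical(cl$n_interlopers, 1L)
  expect_identical(cl$members[[1]], paste0("cce", 1:6))
})

test_that("mixed-orientation clusters keep their strand pattern and singletons form none", {
  fam <- mkloci(paste0("g", 1:4), "chr23", seq(1000, by = 3000,
                                               length.out = 4),
                c("-", "-", "+", "+"))
  cl <- detectClusters(rbind(fam, mkloci("x", "chr23", 90000L, "+",
                                         fam = FALSE)))
  expect_identical(cl$orientation_pattern, "--++")

  lone <- rbind(mkloci("a", "chr1", 1000L, "+"),
                mkloci("b", "chr2", 1000L, "+"))
  expect_identical(nrow(detectClusters(lone)), 0L)
})

test_that("chaining uses the interloper rule with annotation and the bp gap without", {
  # two family genes separated by two non-family genes: too many interlopers
  fam <- mkloci(c("f1", "f2"), "chr1", c(1000L, 20000L), "+")
  inter <- mkloci(c("n1", "n2"), "chr1", c(5000L, 10000L), "+", fam = FALSE)
  expect_identical(nrow(detectClusters(rbind(fam, inter))), 0L)
  expect_identical(detectClusters(rbind(fam, inter),
                                  maxInterlopers = 2)$n_members, 2L)
  # no annotation at all: fall back to the genomic gap
  expect_identical(detectClusters(fam)$n_members, 2L)
  farApart <- mkloci(c("f1", "f2"), "chr1", c(1000L, 500000L), "+")
  expect_identical(nrow(detectClusters(farApart)), 0L)
})

test_that("clusters are invariant to input row order and members are family loci", {
  set.seed(150)
  sim <- simulateFamily(simulationConfig(seed = 33, nGenes = 14,
                                         proteinLength = 120))
  loci <- sim$loci
  cl1 <- detectClusters(loci)
  cl2 <- detectClusters(loci[sample(nrow(loci)), ])
  expect_identical(cl1, cl2)
  expect_true(all(unlist(cl1$members) %in% loci$gene_id[loci$in_family]))
  # generator truth: the configured clusters are recovered
  expect_identical(nrow(cl1), 2L)
  expect_identical(sort(cl1$members[[which(cl1$n_members == 6)]]),
                   sort(sim$clusters[[1]]))
})

test_that("cluster/clade concordance distinguishes contained from split clusters", {
  clusters <- data.frame(chrom = "chr1", start = 1L, end = 10L,
                         n_members = 2L, orientation_pattern = "++",
                         n_interlopers = 0L)
  clusters$members <- list(c("a", "b"))
  expect_true(clusterTreeConcordance(clusters,
                                     list(c("a", "b", "c")))$concordant)
  expect_false(clusterTreeConcordance(clusters,
                                      list(c("a", "x"), c("b", "y")))$concordant)
  res <- clusterTreeConcordance(clusters, list(c("a", "b")))
  expect_identical(res$n_concordant, 1L)
  expect_identical(res$n_total, 1L)
})

test_that("recent tandem duplications are concordant with the tree", {
  cfg <- simulationConfig(seed = 55, nGenes = 12, proteinLength = 150)
  sim <- simulateFamily(cfg)
  cl <- detectClusters(sim$loci)
  # truth clades: the generator assigns clusters from contiguous tip blocks
  clades <- sim$clusters
  res <- clusterTreeConcordance(cl, clades)
  expect_identical(res$n_concordant, res$n_total)
})

test_that("the neuroligin-style toy maps yield exactly one duplication, one split and one fusion", {
  toy <- syntenyToyMaps()
  ev <- compareSynteny(toy$A, toy$B)
  expect_identical(sum(ev$kind == "duplication"), 1L)
  expect_identical(sum(ev$kind == "split"), 1L)
  expect_identical(sum(ev$kind == "fusion"), 1L)
  expect_identical(sum(ev$kind %in% c("loss", "conserved")), 0L)
  expect_identical(ev$groups[ev$kind == "duplication"], "Nlg4")
  expect_match(ev$detail[ev$kind == "split"], "\\{Nlg5\\}")
  expect_match(ev$detail[ev$kind == "fusion"], "chr_b2")
})

test_that("synteny of a map against itself is conserved and splits/fusions are label-symmetric", {
  toy <- syntenyToyMaps()
  self <- compareSynteny(toy$A, toy$A)
  expect_true(all(self$kind == "conserved"))
  ab <- compareSynteny(toy$A, toy$B)
  ba <- compareSynteny(toy$B, toy$A)
  expect_identical(sum(ab$kind == "split"), sum(ba$kind == "fusion"))
  expect_identical(sum(ab$kind == "fusion"), sum(ba$kind == "split"))
  expect_identical(sum(ab$kind == "duplication"), sum(ba$kind == "loss"))
  # a single shared group can never witness a split or fusion
  a1 <- toy$A[toy$A$ortholog_group == "Nlg4", ]
  b1 <- toy$B[toy$B$ortholog_group == "Nlg4", ]
  ev1 <- compareSynteny(a1, b1)
  expect_true(all(ev1$kind %in% c("duplication", "conserved")))
  expect_error(compareSynteny(toy$A[0, ], toy$B), "empty")
})

test_that("loci survive a BED round trip (0-based half-open on disk)", {
  dir <- withr::local_tempdir()
  loci <- mkloci(c("a", "b"), "chr1", c(101L, 5001L), c("+", "-"))
  f <- file.path(dir, "loci.bed")
  writeLociBED(loci, f)
  bed <- read.delim(f, header = FALSE)
  expect_identical(bed[[2]], c(100L, 5000L))   # converted at the boundary
  back <- readLoci(f)
  expect_identical(back$start, loci$start)
  expect_identical(back$end, loci$end)
})
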