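test_that("intron phase is the coding offset mod 3 and rejects non-positive offsets", {
  expect_identical(intronPhase(6L), 0L)
  expect_identical(intronPhase(7L), 1L)
  expect_identical(intronPhase(8L), 2L)
  expect_identical(intronPhase(1:300), vapply(1:300, function(o)
    as.integer(o - floor(o / 3) * 3), 0L))
  expect_error(intronPhase(0L), "positive")
})

test_that("projection is the identity on ungapped rows and shifts by 3 nt per gap column", {
  intr <- data.frame(gene_id = "g", ordinal = 1L, cds_offset = 9L)
  ung <- ProteinAlignment("g", "MKVLWAALLV")
  s <- projectIntrons(intr, ung)
  expect_identical(s$aln_nt_pos, 9L)        # identity mapping
  # two gap columns before the hosting residue add 6 nt
  gapped <- ProteinAlignment(c("g", "h"), c("MKV--LWAALLV", "MKVRRLWAALLV"))
  s2 <- projectIntrons(intr, gapped)
  expect_identical(s2$aln_nt_pos, 15L)
  expect_identical(s2$column, 6L)
})

test_that("projection agrees with a brute-force residue walk on random gapped rows", {
  set.seed(606)
  for (rep in 1:200) {
    row <- randomGappedRow()
    filler <- paste(rep("A", nchar(row)), collapse = "")  # keeps all columns
    nres <- nchar(gsub("-", "", row))
    off <- sample(seq_len(3 * nres - 3), 1)
    s <- projectIntrons(data.frame(gene_id = "g", ordinal = 1L,
                                   cds_offset = off),
                        ProteinAlignment(c("g", "f"), c(row, filler)))
    expect_identical(s$aln_nt_pos, as.integer(walkProjectIntron(row, off)))
    expect_identical(s$aln_nt_pos %% 3L, s$phase)
  }
})

test_that("projection preserves intron order within a gene and drops sites past the last residue", {
  row <- "MK--VLWA"
  aln <- ProteinAlignment(c("g", "f"), c(row, "MKRRVLWA"))
  intr <- data.frame(gene_id = "g", ordinal = 1:3,
                     cds_offset = c(4L, 10L, 18L))
  expect_message(s <- projectIntrons(intr, aln), "excluded")
  expect_identical(nrow(s), 2L)              # offset 18 is past the last residue
  expect_true(all(diff(s$aln_nt_pos) > 0))
})

test_that("conserved-site grouping merges jittered same-phase sites and respects the tolerance", {
  # alignment-jitter analogue: two phase-0 sites 1 nt... same phase sites 3 nt
  # apart merge at the default tolerance, distant sites do not
  sites <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"), ordinal = 1L,
    column = 1L,
    aln_nt_pos = c(228L, 231L, 900L, 2000L),
    phase = c(0L, 0L, 0L, 0L))
  gr <- findConservedSites(sites)
  expect_identical(nrow(gr), 1L)
  expect_identical(gr$canonical_pos, 228L)
  expect_identical(gr$n_members, 2L)
  expect_identical(gr$members[[1]], c("g1", "g2"))

  # same positions, different phase: never merged
  sites$phase <- c(0L, 0L, 0L, 0L)
  sites$aln_nt_pos <- c(228L, 229L, 228L, 229L)
  sites$phase <- c(0L, 1L, 0L, 1L)
  gr2 <- findConservedSites(sites)
  expect_identical(sort(gr2$phase), c(0L, 1L))

  # far-apart singletons: no groups
  far <- data.frame(gene_id = c("a", "b", "c"), ordinal = 1L, column = 1L,
                    aln_nt_pos = c(10L, 100L, 1000L), phase = 0L)
  expect_identical(nrow(findConservedSites(far)), 0L)
})

test_that("grouping is permutation-invariant and one gene contributes once per group", {
  set.seed(707)
  sites <- data.frame(
    gene_id = c("g1", "g2", "g3", "g1"), ordinal = c(1L, 1L, 1L, 2L),
    column = 1L, aln_nt_pos = c(100L, 101L, 102L, 103L), phase = 1L)
  gr <- findConservedSites(sites)
  expect_identical(gr$n_members, 3L)         # g1 counted once
  perm <- sites[sample(nrow(sites)), ]
  expect_identical(findConservedSites(perm)$members, gr$members)
})

test_that("with no intron loss every ancestral intron is recovered in every gene", {
  cfg <- simulationConfig(seed = 31, nGenes = 12, proteinLength = 250,
                          nAncestralIntrons = 4, intronLossProb = 0,
                          intronGainRate = 0, indelProb = 0)
  sim <- simulateFamily(cfg)
  dir <- withr::local_tempdir()
  writeFamily(sim, dir)
  genome <- readGenome(file.path(dir, "genome.fasta"))
  models <- readGeneModels(file.path(dir, "genes.gff3"), genome)
  sites <- projectIntrons(extractIntrons(models, genome), sim$alignment)
  gr <- findConservedSites(sites)
  expect_identical(nrow(gr), 4L)
  expect_true(all(gr$n_members == 12L))
  expect_true(all(gr$pos_max == gr$pos_min))
})

test_that("length statistics reproduce hand arithmetic and count intronless genes", {
  intr <- data.frame(gene_id = c("a", "a", "b"), ordinal = c(1L, 2L, 1L),
                     length = c(68L, 1372L, 13962L))
  models <- list()
  st <- intronLengthStats(intr)
  expect_identical(st$n_introns, 3L)
  expect_identical(st$min_length, 68L)
  expect_identical(st$max_length, 13962L)
  expect_equal(round(st$mean_length), 5134)
  expect_identical(sum(st$histogram$count), 3L)
  # empty input
  st0 <- intronLengthStats(intr[0, ])
  expect_identical(st0$n_introns, 0L)
  expect_true(is.na(st0$mean_length))
})

test_that("shared-intron summary equals a brute-force set union", {
  genes <- paste0("g", 1:10)
  groups <- data.frame(canonical_pos = c(10L, 50L, 90L), phase = 0L,
                       n_members = c(5L, 4L, 3L),
                       pos_min = c(10L, 50L, 90L), pos_max = c(10L, 50L, 90L))
  groups$members <- list(paste0("g", 1:5), paste0("g", 4:7), paste0("g", 8:10))
  sm <- sharedIntronMatrix(groups, genes, k = 2)
  expect_identical(sm$n_genes_with_top_k,
                   length(union(groups$members[[1]], groups$members[[2]])))
  expect_identical(unname(rowSums(sm$matrix)["g4"]), 2)
  # disjoint groups, k = 2: summary is the sum of sizes
  groups$members <- list(paste0("g", 1:5), paste0("g", 6:9), "g10")
  expect_identical(sharedIntronMatrix(groups, genes, 2)$n_genes_with_top_k, 9L)
})
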