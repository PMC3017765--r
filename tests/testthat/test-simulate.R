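test_that("identical seed and config give byte-identical outputs", {
  cfg <- simulationConfig(seed = 99, nGenes = 8, proteinLength = 100,
                          clusterSpec = list(c(size = 3L, interlopers = 1L), c(size = 2L, interlopers = 0L)))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulateFamily(cfg, outDir = d1)
  simulateFamily(cfg, outDir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})

test_that("impossible configurations are rejected", {
  expect_error(simulationConfig(nGenes = 5,
                                clusterSpec = list(c(size = 6, interlopers = 0))),
               "impossible")
  expect_error(simulationConfig(intronLengthRange = c(2, 100)))
  expect_error(simulationConfig(intronLossProb = 1.2))
  expect_error(simulationConfig(clusterSpec = list(c(size = 4,
                                                     interlopers = 4))),
               "interlopers")
})

test_that("the degenerate no-change limit reproduces the ancestor in every gene", {
  cfg <- simulationConfig(seed = 3, nGenes = 6, proteinLength = 80,
                          branchScale = 0, indelProb = 0,
                          intronLossProb = 0, intronGainRate = 0,
                          nAncestralIntrons = 3,
                          clusterSpec = list(c(size = 3L, interlopers = 1L), c(size = 2L, interlopers = 0L)))
  sim <- simulateFamily(cfg)
  expect_identical(length(unique(sim$proteins)), 1L)
  expect_false(any(grepl("-", alignmentRows(sim$alignment), fixed = TRUE)))
  # every ancestral intron present in every gene, and found conserved
  expect_identical(nrow(sim$introns), 6L * 3L)
  dir <- withr::local_tempdir()
  writeFamily(sim, dir)
  genome <- readGenome(file.path(dir, "genome.fasta"))
  models <- readGeneModels(file.path(dir, "genes.gff3"), genome)
  gr <- findConservedSites(projectIntrons(extractIntrons(models, genome),
                                          sim$alignment))
  expect_identical(nrow(gr), 3L)
  expect_true(all(gr$n_members == 6L))
})

test_that("per-intron survivor counts under loss match the branch-process envelope", {
  q <- 0.2
  counts <- integer(0); lo <- numeric(0); hi <- numeric(0)
  for (seed in 1:10) {
    cfg <- simulationConfig(seed = seed, nGenes = 15, proteinLength = 120,
                            nAncestralIntrons = 4, intronLossProb = q,
                            intronGainRate = 0, indelProb = 0)
    sim <- simulateFamily(cfg)
    surv <- table(factor(sim$introns$origin_id,
                         levels = sim$ancestralIntrons$id))
    env <- survivorEnvelope(sim$tree, q, nrep = 4000)
    counts <- c(counts, as.integer(surv))
    lo <- c(lo, rep(env[1], 4)); hi <- c(hi, rep(env[2], 4))
  }
  inside <- mean(counts >= lo & counts <= hi)
  expect_gte(inside, 0.9)   # 99% envelope; 40 draws
})

test_that("the non-canonical splice fraction behaves binomially", {
  noncan <- 0L; total <- 0L
  for (seed in 11:14) {
    cfg <- simulationConfig(seed = seed, nGenes = 15, proteinLength = 150,
                            nAncestralIntrons = 6, intronLossProb = 0,
                            intronGainRate = 0, fracNoncanonical = 0.1)
    sim <- simulateFamily(cfg)
    noncan <- noncan + sum(!sim$introns$canonical)
    total <- total + nrow(sim$introns)
  }
  env <- qbinom(c(0.005, 0.995), total, 0.1)
  expect_gte(noncan, env[1])
  expect_lte(noncan, env[2])
})

test_that("expected intron counts match the loss-thinned prediction over seeds", {
  q <- 0.1
  obs <- numeric(0); expd <- numeric(0)
  for (seed in 21:35) {
    cfg <- simulationConfig(seed = seed, nGenes = 10, proteinLength = 100,
                            nAncestralIntrons = 5, intronLossProb = q,
                            intronGainRate = 0, indelProb = 0)
    sim <- simulateFamily(cfg)
    obs <- c(obs, nrow(sim$introns))
    # expectation: sum over genes of n_anc * (1-q)^depth(gene)
    depth <- vapply(seq_along(sim$tree$tip.label), function(tip) {
      node <- tip; d <- 0L
      repeat {
        e <- which(sim$tree$edge[, 2] == node)
        if (!length(e)) break
        d <- d + 1L; node <- sim$tree$edge[e, 1]
      }
      d
    }, 0L)
    expd <- c(expd, sum(5 * (1 - q)^depth))
  }
  se <- sd(obs - expd) / sqrt(length(obs))
  expect_lt(abs(mean(obs - expd)), 3 * max(se, 1))
})

test_that("emitted truth files are consistent with the in-memory object", {
  sim <- simulateFamily(simulationConfig(seed = 8, nGenes = 6,
                                         proteinLength = 90,
                                         clusterSpec = list(c(size = 3L, interlopers = 1L), c(size = 2L, interlopers = 0L))))
  dir <- withr::local_tempdir()
  f <- writeFamily(sim, dir)
  tr <- ape::read.tree(f[["tree"]])
  expect_identical(sort(tr$tip.label), sort(sim$tree$tip.label))
  al <- readAlignedFasta(f[["alignment"]])
  expect_identical(alignmentRows(al)[alignmentIDs(sim$alignment)],
                   alignmentRows(sim$alignment))
  est <- readESTTable(f[["est"]])
  expect_identical(nrow(est), nrow(sim$est))
  truth <- jsonlite::read_json(f[["truth"]])
  expect_identical(truth$config$seed, 8L)
})
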