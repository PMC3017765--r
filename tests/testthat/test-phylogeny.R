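test_that("JTT distance is zero for identical rows, errors without shared columns, caps at saturation", {
  expect_equal(as.numeric(jttDistance("MKVLW", "MKVLW")), 0)
  expect_error(jttDistance("MK---", "--VLW"), "no shared")
  expect_warning(jttDistance("WWWWW", "LLLLL"), "saturated")
  d <- suppressWarnings(jttDistance("WWWWW", "LLLLL"))
  expect_equal(as.numeric(d), 10)
  expect_true(attr(d, "saturated"))
})

test_that("JTT distance matches phangorn's independent implementation", {
  set.seed(808)
  for (t_true in c(0.1, 0.6)) {
    p <- simulateProteinPair(t_true, 600)
    mine <- as.numeric(jttDistance(p$a, p$b))
    pd <- phangorn::phyDat(matrix(c(strsplit(p$a, "")[[1]],
                                    strsplit(p$b, "")[[1]]),
                                  nrow = 2, byrow = TRUE,
                                  dimnames = list(c("a", "b"), NULL)),
                           type = "AA")
    ref <- as.matrix(phangorn::dist.ml(pd, model = "JTT"))[1, 2]
    expect_equal(mine, ref, tolerance = 1e-4)
  }
})

test_that("JTT distance recovery is nearly unbiased on simulated pairs", {
  set.seed(909)
  for (t_true in c(0.1, 1.0)) {
    est <- replicate(40, {
      p <- simulateProteinPair(t_true, 500)
      as.numeric(jttDistance(p$a, p$b))
    })
    expect_lt(abs(mean(est) / t_true - 1), 0.05)
  }
})

test_that("NJ reconstructs the hand-computed 4-taxon additive tree exactly", {
  ## tree ((A:1,B:2):1,(C:3,D:4)): dAB=3 dAC=5 dAD=6 dBC=6 dBD=7 dCD=7
  dm <- matrix(c(0, 3, 5, 6,
                 3, 0, 6, 7,
                 5, 6, 0, 7,
                 6, 7, 7, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- njTree(dm)
  expect_identical(sort(tr$tip.label), LETTERS[1:4])
  bl <- setNames(tr$edge.length[tr$edge[, 2] <= 4],
                 tr$tip.label[tr$edge[tr$edge[, 2] <= 4, 2]])
  expect_equal(bl[c("A", "B", "C", "D")], c(A = 1, B = 2, C = 3, D = 4))
  expect_equal(tr$edge.length[tr$edge[, 2] > 4], 1)   # internal branch
  # and the recovered tree is additive-consistent
  expect_equal(unname(ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]),
               unname(dm))
})

test_that("3 taxa resolve to the closed-form star and n < 3 errors", {
  dm <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- njTree(dm)
  expect_identical(tr$Nnode, 1L)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("a", "b", "c")], c(a = 1, b = 2, c = 3))
  expect_error(njTree(dm[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers random additive topologies and agrees with ape", {
  set.seed(110)
  hits <- 0L
  for (rep in 1:30) {
    true <- ape::rtree(8)
    true$edge.length <- runif(nrow(true$edge), 0.2, 1.5)
    dm <- ape::cophenetic.phylo(true)
    est <- njTree(dm)
    if (phangorn::RF.dist(ape::unroot(true), est) == 0) hits <- hits + 1L
    expect_equal(phangorn::RF.dist(ape::nj(dm), est), 0)
  }
  expect_identical(hits, 30L)
})

test_that("asymmetric or negative matrices are rejected, all-zero gives an unresolved star", {
  dm <- matrix(c(0, 1, 2, 1.5, 0, 1, 2, 1, 0), 3, 3)
  expect_error(njTree(dm), "symmetric")
  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  st <- njTree(z)
  expect_identical(st$Nnode, 1L)
  expect_true(all(st$edge.length == 0))
})

test_that("minimum-evolution refinement restores an NNI-perturbed additive topology and never lengthens the tree", {
  set.seed(120)
  true <- ape::unroot(ape::rtree(6))
  true$edge.length <- runif(nrow(true$edge), 0.3, 1.2)
  dm <- ape::cophenetic.phylo(true)
  expect_equal(phangorn::RF.dist(meRefine(njTree(dm), dm), true), 0)
  # perturb away from the optimum
  wrong <- phangorn::nni(true)[[1]]
  refined <- meRefine(wrong, dm)
  expect_equal(phangorn::RF.dist(refined, true), 0)
  expect_lte(sum(refined$edge.length),
             famarch:::.olsTreeLength(wrong, dm) + 1e-9)
  # additive input is already optimal: returned unchanged
  nj <- njTree(dm)
  expect_identical(ape::write.tree(meRefine(nj, dm)), ape::write.tree(nj))
})

test_that("bootstrap supports are deterministic given a seed and flag well-separated clades", {
  set.seed(130)
  aln <- simulateProteins(twoCladeTree(), 200)
  t1 <- bootstrapSupport(aln, nReps = 60, seed = 42)
  t2 <- bootstrapSupport(aln, nReps = 60, seed = 42)
  expect_identical(t1$node.label, t2$node.label)
  clades <- flagSupportedClades(t1, threshold = 50)
  tips <- t1$tip.label
  expect_true(hasBipartition(clades, paste0("a", 1:4), tips))
  expect_true(hasBipartition(clades, paste0("b", 1:4), tips))
  expect_error(bootstrapSupport(aln, nReps = 10), "seed")
})

test_that("identical sequences carry no resolved bipartitions and no support", {
  aln <- ProteinAlignment(paste0("s", 1:4), rep("MKVLWAAL", 4))
  tr <- bootstrapSupport(aln, nReps = 20, seed = 1)
  expect_identical(tr$Nnode, 1L)
  expect_identical(flagSupportedClades(tr), list())
})

test_that("bootstrap supports are invariant to leaf-order permutation", {
  set.seed(140)
  aln <- simulateProteins(twoCladeTree(), 150)
  rows <- alignmentRows(aln)
  perm <- sample(length(rows))
  aln2 <- ProteinAlignment(names(rows)[perm], unname(rows)[perm])
  t1 <- bootstrapSupport(aln, nReps = 50, seed = 9)
  t2 <- bootstrapSupport(aln2, nReps = 50, seed = 9)
  sup <- function(tr) {
    cl <- lapply(seq_len(tr$Nnode)[-1] + length(tr$tip.label),
                 function(n) sort(ape::extract.clade(tr, n)$tip.label))
    o <- order(vapply(cl, paste, "", collapse = ","))
    setNames(tr$node.label[-1][o],
             vapply(cl, paste, "", collapse = ",")[o])
  }
  expect_identical(sup(t1), sup(t2))
})

test_that("clade flagging respects the threshold exactly", {
  tr <- ape::read.tree(text = "((a:1,b:1)x:1,(c:1,d:1)y:1,e:1);")
  tr$node.label <- c("", "100", "40")
  cl <- flagSupportedClades(tr, threshold = 50)
  expect_identical(cl, list(c("a", "b")))
  tr$node.label <- c("", "100", "90")
  expect_length(flagSupportedClades(tr, 50), 2L)
  tr$node.label <- c("", "40", "40")
  expect_length(flagSupportedClades(tr, 50), 0L)
  tr$node.label <- NULL
  expect_error(flagSupportedClades(tr), "no support")
})
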