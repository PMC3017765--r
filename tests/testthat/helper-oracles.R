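# Independent brute-force oracles and tiny fixture builders used across the
# suite. These deliberately use naive algorithms (full enumeration,
# character-by-character walks) so they share no code path with the package.

# ---- brute-force global alignment score ------------------------------------
# Enumerates every global alignment of a and b and scores it with the
# package's gap convention (a run of k gaps costs open + (k - 1) * ext).
bruteForceAlignScore <- function(a, b, submat, open, ext) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  best <- -Inf
  # columns encoded as 2-col matrix of indices (0 = gap)
  rec <- function(i, j, cols) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, scoreCols(cols))
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv))
      rec(i + 1, j + 1, rbind(cols, c(i, j)))
    if (i <= length(av)) rec(i + 1, j, rbind(cols, c(i, 0)))
    if (j <= length(bv)) rec(i, j + 1, rbind(cols, c(0, j)))
    invisible()
  }
  gapRunCost <- function(isgap) {
    if (!any(isgap)) return(0)
    runs <- rle(isgap)
    sum(vapply(runs$lengths[runs$values], function(k)
      open + (k - 1) * ext, 0))
  }
  scoreCols <- function(cols) {
    if (is.null(cols)) return(0)
    s <- 0
    for (r in seq_len(nrow(cols))) {
      if (cols[r, 1] > 0 && cols[r, 2] > 0)
        s <- s + submat[av[cols[r, 1]], bv[cols[r, 2]]]
    }
    s + gapRunCost(cols[, 1] == 0) + gapRunCost(cols[, 2] == 0)
  }
  rec(1, 1, NULL)
  best
}

# ---- brute-force intron projection (residue-by-residue homology walk) ------
walkProjectIntron <- function(gappedRow, cds_offset) {
  p <- cds_offset %% 3
  r_target <- cds_offset %/% 3 + 1   # hosting / following residue
  chars <- strsplit(gappedRow, "")[[1]]
  seen <- 0
  for (col in seq_along(chars)) {
    if (chars[col] != "-") {
      seen <- seen + 1
      if (seen == r_target) return(3 * (col - 1) + p)
    }
  }
  NA_integer_
}

# random gapped row whose ungapped length is at least minRes
randomGappedRow <- function(minRes = 5, maxRes = 40, maxGapRun = 4) {
  nres <- sample(minRes:maxRes, 1)
  res <- sample(famarch::AA_ORDER, nres, replace = TRUE)
  out <- character(0)
  for (r in res) {
    if (runif(1) < 0.3)
      out <- c(out, rep("-", sample(seq_len(maxGapRun), 1)))
    out <- c(out, r)
  }
  if (runif(1) < 0.3) out <- c(out, rep("-", sample(seq_len(maxGapRun), 1)))
  paste(out, collapse = "")
}

# ---- toy two-exon locus ----------------------------------------------------
# A 30-codon gene split by one intron; returns paths of a FASTA + GFF3 pair
# written to dir, plus the expected CDS/protein/intron facts.
writeToyLocus <- function(dir, strand = "+", donor = "GT") {
  # CDS: ATG + 28 codons + TAA = 90 nt; intron after cds offset 9
  set.seed(99)
  codons <- c("ATG", replicate(28, paste(sample(c("GCT", "GAA", "AAA", "CTG",
    "TGG", "TTC", "CCA", "AGT"), 1), collapse = "")), "TAA")
  cds <- paste(codons, collapse = "")
  intron <- paste0(donor, paste(rep("A", 87), collapse = ""), "AG")  # 91 nt
  upstream <- paste(rep("C", 10), collapse = "")
  sense_locus <- paste0(substr(cds, 1, 9), intron, substr(cds, 10, 90))
  chromPlus <- paste0(upstream, sense_locus, upstream)
  exon1 <- c(11, 19)                    # genomic, 1-based closed, plus strand
  exon2 <- c(111, 191)
  if (strand == "+") {
    chrom <- chromPlus
    ex <- list(exon1, exon2)
  } else {
    L <- nchar(chromPlus)
    chrom <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(chromPlus)))
    flip <- function(iv) c(L - iv[2] + 1, L - iv[1] + 1)
    ex <- list(flip(exon2), flip(exon1))  # ascending genomic order
  }
  fa <- file.path(dir, "toy.fasta")
  gff <- file.path(dir, "toy.gff3")
  writeLines(c(">chrT", chrom), fa)
  writeLines(c("##gff-version 3",
    sprintf("chrT\ttoy\tgene\t%d\t%d\t.\t%s\t.\tID=toy1", ex[[1]][1],
            ex[[2]][2], strand),
    sprintf("chrT\ttoy\tmRNA\t%d\t%d\t.\t%s\t.\tID=toy1.t1;Parent=toy1",
            ex[[1]][1], ex[[2]][2], strand),
    sprintf("chrT\ttoy\tCDS\t%d\t%d\t.\t%s\t0\tID=toy1.c;Parent=toy1.t1",
            ex[[1]][1], ex[[1]][2], strand),
    sprintf("chrT\ttoy\tCDS\t%d\t%d\t.\t%s\t0\tID=toy1.c;Parent=toy1.t1",
            ex[[2]][1], ex[[2]][2], strand)), gff)
  prot <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  list(fasta = fa, gff3 = gff, cds = cds,
       protein = substr(prot, 1, nchar(prot) - 1),
       intron_length = 91L, cds_offset = 9L, donor = donor)
}

# two-clade tree used by the bootstrap checks: internal branch 0.5 subs/site
twoCladeTree <- function() {
  ape::read.tree(text = paste0(
    "(((a1:0.05,a2:0.05):0.05,(a3:0.05,a4:0.05):0.05):0.25,",
    "((b1:0.05,b2:0.05):0.05,(b3:0.05,b4:0.05):0.05):0.25);"))
}

# does a supported-clade list contain the bipartition splitting `side` from
# the rest of `all_tips`?
hasBipartition <- function(clades, side, all_tips) {
  side <- sort(side)
  other <- sort(setdiff(all_tips, side))
  any(vapply(clades, function(cl) {
    s <- sort(cl)
    identical(s, side) || identical(s, other)
  }, TRUE))
}

# Monte-Carlo envelope of per-intron survivor counts under per-branch loss q
# on a given tree: returns c(lo, hi) of the central 99% of the count
# distribution (brute-force simulation of the loss process itself).
survivorEnvelope <- function(tree, q, nrep = 10000) {
  ntip <- length(tree$tip.label)
  nb <- nrow(tree$edge)
  # path membership: tips x branches
  M <- matrix(FALSE, ntip, nb)
  for (tip in seq_len(ntip)) {
    node <- tip
    repeat {
      e <- which(tree$edge[, 2] == node)
      if (!length(e)) break
      M[tip, e] <- TRUE
      node <- tree$edge[e, 1]
    }
  }
  lost <- matrix(runif(nrep * nb) < q, nrep, nb)
  nLostOnPath <- lost %*% t(M)          # reps x tips
  counts <- rowSums(nLostOnPath == 0)
  quantile(counts, c(0.005, 0.995), names = FALSE)
}
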