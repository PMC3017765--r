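## Gene-family simulator: evolves a protein family along a Yule tree under
## the JTT model with codon-aligned indels, inherits ancestral introns
## subject to per-branch loss and gain, back-translates tip proteins, plants
## GT..AG (or non-canonical) intron sequences, lays the genes out on
## chromosomes in tandem clusters with interloper genes, and draws
## tissue-biased EST clone counts. Every stage's ground truth is returned
## alongside the emitted standard files.
##
## One RNG stream seeded once, consumed in a fixed order (tree, sequences and
## indels, introns, back-translation, splice sites and intron sequences,
## genome layout, EST counts), so identical seed + config give byte-identical
## outputs.

.SIM_TISSUES <- c("midgut", "fat_body", "silk_gland", "ovary", "testis",
                  "brain", "epidermis", "hemocyte", "antenna", "wing",
                  "malpighian_tubule", "pheromone_gland")

#' Configuration for the family simulator
#'
#' Defaults describe a medium-sized esterase-like family: 20 genes of 550
#' residues, a Yule tree scaled to 0.5 expected substitutions per site mean
#' root-to-tip, 6 ancestral introns with a 5% per-branch loss probability and
#' 0.2 expected gains per branch, rare codon-aligned indels, intron lengths
#' 68-2000 nt with 2% non-canonical splice sites, two tandem clusters (one of
#' six genes harbouring one interloper, one of four), and negative-binomial
#' EST clone counts spread over eight tissues with a concentration-0.5
#' Dirichlet (strongly tissue-biased).
#'
#' @param seed integer RNG seed.
#' @param nGenes number of family genes (tips), >= 2.
#' @param proteinLength ancestral protein length in residues.
#' @param birthRate Yule birth rate (tree shape only).
#' @param branchScale mean root-to-tip depth in expected substitutions/site.
#' @param nAncestralIntrons introns present in the family ancestor.
#' @param intronLossProb per-branch probability an intron is lost.
#' @param intronGainRate per-branch expected number of gained introns.
#' @param indelProb per-residue per-branch probability of an indel event.
#' @param intronLengthRange integer \[min, max\] intron length (min >= 4).
#' @param fracNoncanonical fraction of introns with non-GT/AG (GC..AG) ends.
#' @param nChromosomes chromosomes to lay genes on (>= number of clusters).
#' @param clusterSpec list of `c(size=, interlopers=)` tandem clusters;
#'   interlopers < size; sizes must sum to <= nGenes.
#' @param nTissues number of EST tissue libraries (<= 12).
#' @param tissueConcentration Dirichlet concentration of per-gene tissue
#'   profiles (small = tissue-biased).
#' @param clonesMean,clonesDispersion negative-binomial mean and dispersion
#'   (size) of clones per gene.
#' @return a validated config (classed list `famSimConfig`).
#' @export
simulationConfig <- function(seed = 1L, nGenes = 20L, proteinLength = 550L,
                             birthRate = 1, branchScale = 0.5,
                             nAncestralIntrons = 6L, intronLossProb = 0.05,
                             intronGainRate = 0.2, indelProb = 0.005,
                             intronLengthRange = c(68L, 2000L),
                             fracNoncanonical = 0.02, nChromosomes = 5L,
                             clusterSpec = list(c(size = 6L, interlopers = 1L),
                                                c(size = 4L, interlopers = 0L)),
                             nTissues = 8L, tissueConcentration = 0.5,
                             clonesMean = 5, clonesDispersion = 0.5) {
  cfg <- list(seed = as.integer(seed), nGenes = as.integer(nGenes),
              proteinLength = as.integer(proteinLength),
              birthRate = birthRate, branchScale = branchScale,
              nAncestralIntrons = as.integer(nAncestralIntrons),
              intronLossProb = intronLossProb,
              intronGainRate = intronGainRate, indelProb = indelProb,
              intronLengthRange = as.integer(intronLengthRange),
              fracNoncanonical = fracNoncanonical,
              nChromosomes = as.integer(nChromosomes),
              clusterSpec = clusterSpec, nTissues = as.integer(nTissues),
              tissueConcentration = tissueConcentration,
              clonesMean = clonesMean, clonesDispersion = clonesDispersion)
  with(cfg, {
    stopifnot(nGenes >= 2L, proteinLength >= 30L, branchScale >= 0,
              nAncestralIntrons >= 0L,
              intronLossProb >= 0, intronLossProb <= 1,
              intronGainRate >= 0, indelProb >= 0, indelProb <= 1,
              fracNoncanonical >= 0, fracNoncanonical <= 1,
              length(intronLengthRange) == 2L, intronLengthRange[1L] >= 4L,
              intronLengthRange[1L] <= intronLengthRange[2L],
              nChromosomes >= 1L, nTissues >= 1L,
              nTissues <= length(.SIM_TISSUES), tissueConcentration > 0,
              clonesMean >= 0, clonesDispersion > 0)
  })
  sizes <- vapply(cfg$clusterSpec, function(x) as.integer(x[["size"]]), 0L)
  inter <- vapply(cfg$clusterSpec,
                  function(x) as.integer(x[["interlopers"]]), 0L)
  if (any(sizes < 2L)) stop("cluster sizes must be >= 2")
  if (any(inter < 0L) || any(inter > sizes - 1L))
    stop("cluster interlopers must fit between members")
  if (sum(sizes) > cfg$nGenes)
    stop("cluster sizes exceed nGenes: impossible configuration")
  if (length(sizes) > cfg$nChromosomes)
    stop("more clusters than chromosomes")
  structure(cfg, class = "famSimConfig")
}

.randDNA <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

## synonymous-codon table, stop codons excluded
.codonTable <- function() {
  if (is.null(.famarch_cache$codons)) {
    gc <- Biostrings::GENETIC_CODE
    .famarch_cache$codons <- split(names(gc), unname(gc))
  }
  .famarch_cache$codons
}

.backTranslate <- function(protein) {
  tab <- .codonTable()
  res <- strsplit(protein, "")[[1L]]
  codons <- vapply(res, function(a) {
    opts <- tab[[a]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, "")
  paste(c(codons, "TAA"), collapse = "")
}

#' Simulate a gene family with full ground truth
#'
#' See [simulationConfig()] for the generative model. With `outDir` the
#' standard input files (genome FASTA, GFF3, loci/EST/ortholog TSVs) and
#' truth files are also written via [writeFamily()].
#'
#' @param cfg a [simulationConfig()].
#' @param outDir optional output directory.
#' @return a `FamilySimulation` (classed list) with elements config, tree,
#'   alignment (true [ProteinAlignment-class]), proteins, cds, introns
#'   (per-gene truth table), ancestralIntrons, genome
#'   ([Biostrings::DNAStringSet]), gff (feature table), loci, est (records),
#'   estCounts, orthologMap, files (when written).
#' @export
simulateFamily <- function(cfg = simulationConfig(), outDir = NULL) {
  stopifnot(inherits(cfg, "famSimConfig"))
  set.seed(cfg$seed)
  n <- cfg$nGenes
  L <- cfg$proteinLength

  ## 1. Yule tree, scaled to the target mean root-to-tip depth
  tree <- ape::rphylo(n, birth = cfg$birthRate, death = 0)
  tree$tip.label <- sprintf("g%03d", seq_len(n))
  depths <- ape::node.depth.edgelength(tree)[seq_len(n)]
  tree$edge.length <- if (cfg$branchScale == 0 || mean(depths) == 0)
    rep(0, length(tree$edge.length))
  else tree$edge.length * cfg$branchScale / mean(depths)

  ## 2. ancestral introns anchored to root residues (key, phase), offsets
  ##    at least 4 nt apart so truth groups stay unambiguous
  anc <- data.frame(id = character(), key = numeric(), phase = integer())
  if (cfg$nAncestralIntrons > 0L) {
    repeat {
      r <- sort(sample(2:(L - 1L), cfg$nAncestralIntrons))
      p <- sample(0:2, cfg$nAncestralIntrons, replace = TRUE)
      off <- 3L * (r - 1L) + p
      if (cfg$nAncestralIntrons == 1L || min(diff(sort(off))) > 3L) break
    }
    anc <- data.frame(id = sprintf("anc%02d", seq_along(r)),
                      key = as.numeric(r), phase = as.integer(p))
  }

  ## 3. evolve sequences (substitutions + codon-aligned indels) and introns
  ##    down the tree; keys are homology coordinates (root residue i has key
  ##    i; insertions draw fresh keys inside the host interval)
  ntip <- n
  nnode <- tree$Nnode
  states <- vector("list", ntip + nnode)
  root <- ntip + 1L
  states[[root]] <- list(aa = .jttRootSeq(L), keys = as.numeric(seq_len(L)),
                         introns = anc)
  gainCounter <- 0L
  eo <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(eo$edge))) {
    par <- eo$edge[k, 1L]; chi <- eo$edge[k, 2L]
    t <- eo$edge.length[k]
    st <- states[[par]]
    aa <- .jttEvolve(st$aa, t)
    keys <- st$keys
    ## codon-aligned indels
    nev <- rbinom(1L, length(aa), cfg$indelProb)
    for (ev in seq_len(nev)) {
      len <- sample(1:3, 1L, prob = c(0.6, 0.3, 0.1))
      if (runif(1) < 0.5) {          # deletion
        if (length(aa) - len < 30L) next
        p0 <- sample.int(length(aa) - len + 1L, 1L)
        drop <- p0:(p0 + len - 1L)
        aa <- aa[-drop]; keys <- keys[-drop]
      } else {                       # insertion
        p0 <- sample.int(length(aa) + 1L, 1L) - 1L   # insert after p0
        lo <- if (p0 == 0L) keys[1L] - 1 else keys[p0]
        hi <- if (p0 == length(aa)) keys[length(aa)] + 1 else keys[p0 + 1L]
        newkeys <- sort(runif(len, lo, hi))
        newaa <- sample.int(20L, len, replace = TRUE, prob = .jtt_freq)
        aa <- append(aa, newaa, after = p0)
        keys <- append(keys, newkeys, after = p0)
      }
    }
    ## introns: prune hosts lost to deletion, then per-branch loss, then gain
    intr <- st$introns
    intr <- intr[intr$key %in% keys, , drop = FALSE]
    if (nrow(intr) && cfg$intronLossProb > 0 && t >= 0) {
      intr <- intr[runif(nrow(intr)) >= cfg$intronLossProb, , drop = FALSE]
    }
    ngain <- rpois(1L, cfg$intronGainRate)
    for (gi in seq_len(ngain)) {
      curOff <- 3L * (match(intr$key, keys) - 1L) + intr$phase
      for (try in seq_len(20L)) {
        r <- sample(2:(length(aa) - 1L), 1L)
        p <- sample(0:2, 1L)
        off <- 3L * (r - 1L) + p
        if (!length(curOff) || min(abs(curOff - off)) > 3L) {
          gainCounter <- gainCounter + 1L
          intr <- rbind(intr, data.frame(id = sprintf("gain%03d", gainCounter),
                                         key = keys[r], phase = p))
          break
        }
      }
    }
    states[[chi]] <- list(aa = aa, keys = keys, introns = intr)
  }

  ## 4. true alignment from homology keys
  allkeys <- sort(unique(unlist(lapply(seq_len(ntip),
                                       function(i) states[[i]]$keys))))
  rows <- vapply(seq_len(ntip), function(i) {
    st <- states[[i]]
    row <- rep("-", length(allkeys))
    row[match(st$keys, allkeys)] <- AA_ORDER[st$aa]
    paste(row, collapse = "")
  }, "")
  alignment <- ProteinAlignment(tree$tip.label, rows)
  proteins <- ungappedSeqs(alignment)

  ## 5. back-translation and per-tip intron realisation
  cds <- vapply(proteins, .backTranslate, "")
  intronRows <- list()
  for (i in seq_len(ntip)) {
    st <- states[[i]]
    intr <- st$introns
    if (!nrow(intr)) next
    off <- 3L * (match(intr$key, st$keys) - 1L) + intr$phase
    ok <- off > 0L                       # phase-0 site at residue 1 is no site
    intr <- intr[ok, , drop = FALSE]; off <- off[ok]
    ord <- order(off)
    intr <- intr[ord, , drop = FALSE]; off <- off[ord]
    kk <- nrow(intr)
    len <- sample(cfg$intronLengthRange[1L]:cfg$intronLengthRange[2L], kk,
                  replace = TRUE)
    noncan <- runif(kk) < cfg$fracNoncanonical
    seqs <- vapply(seq_len(kk), function(j) {
      paste0(if (noncan[j]) "GC" else "GT", .randDNA(len[j] - 4L), "AG")
    }, "")
    intronRows[[tree$tip.label[i]]] <- data.frame(
      gene_id = tree$tip.label[i], ordinal = seq_len(kk),
      origin_id = intr$id, cds_offset = off, phase = intr$phase,
      length = len, canonical = !noncan, seq = seqs,
      stringsAsFactors = FALSE)
  }
  introns <- if (length(intronRows)) do.call(rbind, intronRows) else
    data.frame(gene_id = character(), ordinal = integer(),
               origin_id = character(), cds_offset = integer(),
               phase = integer(), length = integer(), canonical = logical(),
               seq = character(), stringsAsFactors = FALSE)
  rownames(introns) <- NULL

  ## 6. chromosome layout: clusters first (cluster 1 all '+', emulating a
  ##    same-orientation tandem array), then singletons with double spacers
  sizes <- vapply(cfg$clusterSpec, function(x) as.integer(x[["size"]]), 0L)
  ninter <- vapply(cfg$clusterSpec,
                   function(x) as.integer(x[["interlopers"]]), 0L)
  tipOrder <- tree$tip.label[eo$edge[eo$edge[, 2L] <= ntip, 2L]]
  assign <- list()
  used <- 0L
  for (ci in seq_along(sizes)) {
    assign[[ci]] <- tipOrder[(used + 1L):(used + sizes[ci])]
    used <- used + sizes[ci]
  }
  singletons <- tipOrder[seq_len(ntip) > used]
  strandOf <- stats::setNames(sample(c("+", "-"), ntip, replace = TRUE),
                              tree$tip.label)
  if (length(sizes) >= 1L) strandOf[assign[[1L]]] <- "+"

  chromNames <- sprintf("chr%d", seq_len(cfg$nChromosomes))
  chromSeq <- stats::setNames(rep("", cfg$nChromosomes), chromNames)
  loci <- list(); gff <- list()
  interCounter <- 0L

  geneLocus <- function(gene) {
    offs <- introns$cds_offset[introns$gene_id == gene]
    iseq <- introns$seq[introns$gene_id == gene]
    cdsg <- cds[[gene]]
    starts <- c(1L, offs + 1L)
    ends <- c(offs, nchar(cdsg))
    exons <- substring(cdsg, starts, ends)
    pieces <- character(2L * length(exons) - 1L)
    pieces[seq_along(exons) * 2L - 1L] <- exons
    if (length(iseq)) pieces[seq_along(iseq) * 2L] <- iseq
    ilen <- if (length(iseq)) nchar(iseq) else integer(0)
    cumI <- c(0L, cumsum(ilen))
    list(seq = paste(pieces, collapse = ""),
         exon_start = starts + cumI, exon_end = ends + cumI)
  }

  placeGene <- function(ch, gene, family = TRUE) {
    if (family) {
      loc <- geneLocus(gene)
      strand <- strandOf[[gene]]
    } else {
      loc <- list(seq = paste0("ATG", .randDNA(294L), "TAA"),
                  exon_start = 1L, exon_end = 300L)
      strand <- sample(c("+", "-"), 1L)
    }
    spacer <- .randDNA(sample(2000:4000, 1L))
    o <- nchar(chromSeq[[ch]]) + nchar(spacer) + 1L
    Lg <- nchar(loc$seq)
    inserted <- if (strand == "+") loc$seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(loc$seq)))
    chromSeq[[ch]] <<- paste0(chromSeq[[ch]], spacer, inserted)
    es <- loc$exon_start; ee <- loc$exon_end
    if (strand == "+") {
      gs <- o + es - 1L; ge <- o + ee - 1L
    } else {
      gs <- o + (Lg - ee); ge <- o + (Lg - es)
    }
    loci[[length(loci) + 1L]] <<- data.frame(
      gene_id = gene, chrom = ch, start = o, end = o + Lg - 1L,
      strand = strand, in_family = family, stringsAsFactors = FALSE)
    if (family) {
      ordTx <- if (strand == "+") order(gs) else order(-gs)
      cum <- c(0L, cumsum((ge - gs + 1L)[ordTx]))[seq_along(gs)]
      gffPhase <- (3L - cum %% 3L) %% 3L
      gff[[length(gff) + 1L]] <<- rbind(
        data.frame(seqid = ch, type = "gene", start = o, end = o + Lg - 1L,
                   strand = strand, phase = ".",
                   attr = sprintf("ID=%s", gene), stringsAsFactors = FALSE),
        data.frame(seqid = ch, type = "mRNA", start = o, end = o + Lg - 1L,
                   strand = strand, phase = ".",
                   attr = sprintf("ID=%s.t1;Parent=%s", gene, gene),
                   stringsAsFactors = FALSE),
        data.frame(seqid = ch, type = "CDS", start = gs[ordTx],
                   end = ge[ordTx], strand = strand,
                   phase = as.character(gffPhase),
                   attr = sprintf("ID=%s.cds;Parent=%s.t1", gene, gene),
                   stringsAsFactors = FALSE))
    }
  }

  for (ci in seq_along(sizes)) {
    ch <- chromNames[ci]
    members <- assign[[ci]]
    gapIdx <- if (ninter[ci] > 0L)
      sort(sample.int(length(members) - 1L, ninter[ci])) else integer(0)
    for (mi in seq_along(members)) {
      placeGene(ch, members[mi], family = TRUE)
      if (mi %in% gapIdx) {
        interCounter <- interCounter + 1L
        placeGene(ch, sprintf("interloper%02d", interCounter),
                  family = FALSE)
      }
    }
  }
  freeChroms <- chromNames[seq_along(chromNames) > length(sizes)]
  if (!length(freeChroms)) freeChroms <- chromNames
  for (si in seq_along(singletons)) {
    ch <- freeChroms[(si - 1L) %% length(freeChroms) + 1L]
    # two interlopers ahead of each singleton keep them from chaining
    for (j in 1:2) {
      interCounter <- interCounter + 1L
      placeGene(ch, sprintf("interloper%02d", interCounter), family = FALSE)
    }
    placeGene(ch, singletons[si], family = TRUE)
  }
  for (ch in chromNames)   # terminal spacer
    chromSeq[[ch]] <- paste0(chromSeq[[ch]], .randDNA(1000L))
  loci <- do.call(rbind, loci); rownames(loci) <- NULL
  gff <- do.call(rbind, gff); rownames(gff) <- NULL
  genome <- Biostrings::DNAStringSet(chromSeq)

  ## 7. EST clone records: NB totals, Dirichlet-multinomial tissue spread
  tissues <- .SIM_TISSUES[seq_len(cfg$nTissues)]
  totals <- rnbinom(ntip, size = cfg$clonesDispersion, mu = cfg$clonesMean)
  estCounts <- matrix(0L, ntip, cfg$nTissues,
                      dimnames = list(tree$tip.label, tissues))
  for (i in seq_len(ntip)) {
    g <- rgamma(cfg$nTissues, cfg$tissueConcentration)
    p <- if (sum(g) > 0) g / sum(g) else rep(1 / cfg$nTissues, cfg$nTissues)
    if (totals[i] > 0L)
      estCounts[i, ] <- as.integer(rmultinom(1L, totals[i], p))
  }
  est <- data.frame(clone_id = character(), gene_id = character(),
                    tissue = character(), stringsAsFactors = FALSE)
  if (sum(estCounts) > 0L) {
    idx <- which(estCounts > 0L, arr.ind = TRUE)
    est <- do.call(rbind, lapply(seq_len(nrow(idx)), function(k) {
      data.frame(gene_id = rownames(estCounts)[idx[k, 1L]],
                 tissue = colnames(estCounts)[idx[k, 2L]],
                 n = estCounts[idx[k, 1L], idx[k, 2L]],
                 stringsAsFactors = FALSE)
    }))
    est <- est[order(est$gene_id, est$tissue), ]
    est <- data.frame(
      clone_id = sprintf("clone%05d", seq_len(sum(est$n))),
      gene_id = rep(est$gene_id, est$n), tissue = rep(est$tissue, est$n),
      stringsAsFactors = FALSE)
  }

  fam <- loci[loci$in_family, , drop = FALSE]
  orthologMap <- data.frame(ortholog_group = fam$gene_id,
                            gene_id = fam$gene_id, chrom = fam$chrom,
                            start = fam$start, end = fam$end,
                            strand = fam$strand, stringsAsFactors = FALSE)

  sim <- structure(list(
    config = cfg, tree = tree, alignment = alignment, proteins = proteins,
    cds = cds, introns = introns,
    ancestralIntrons = anc, clusters = assign, genome = genome, gff = gff,
    loci = loci, est = est, estCounts = estCounts,
    orthologMap = orthologMap), class = "FamilySimulation")
  if (!is.null(outDir)) sim$files <- writeFamily(sim, outDir)
  sim
}

#' @export
print.FamilySimulation <- function(x, ...) {
  cat("FamilySimulation:", x$config$nGenes, "genes,",
      nrow(x$introns), "introns,",
      length(x$genome), "chromosomes,",
      nrow(x$est), "EST clones (seed", x$config$seed, ")\n")
  invisible(x)
}

#' Write a simulated family to standard files
#'
#' Emits genome.fasta, genes.gff3, loci.tsv, est.tsv, ortholog_map.tsv plus
#' truth files (truth_tree.nwk, truth_alignment.fasta, truth_introns.tsv,
#' truth.json).
#'
#' @param sim a `FamilySimulation` from [simulateFamily()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
writeFamily <- function(sim, dir) {
  stopifnot(inherits(sim, "FamilySimulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- c(genome = file.path(dir, "genome.fasta"),
         gff = file.path(dir, "genes.gff3"),
         loci = file.path(dir, "loci.tsv"),
         est = file.path(dir, "est.tsv"),
         ortholog = file.path(dir, "ortholog_map.tsv"),
         tree = file.path(dir, "truth_tree.nwk"),
         alignment = file.path(dir, "truth_alignment.fasta"),
         introns = file.path(dir, "truth_introns.tsv"),
         truth = file.path(dir, "truth.json"))
  Biostrings::writeXStringSet(sim$genome, f[["genome"]])
  g <- sim$gff
  lines <- c("##gff-version 3",
             sprintf("%s\tfamsim\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                     g$seqid, g$type, g$start, g$end, g$strand, g$phase,
                     g$attr))
  writeLines(lines, f[["gff"]])
  write.table(sim$loci, f[["loci"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$est, f[["est"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$orthologMap, f[["ortholog"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  ape::write.tree(sim$tree, f[["tree"]])
  writeAlignedFasta(sim$alignment, f[["alignment"]])
  write.table(sim$introns[, setdiff(names(sim$introns), "seq")],
              f[["introns"]], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    config = unclass(sim$config),
    ancestral_introns = sim$ancestralIntrons,
    clusters = sim$clusters,
    est_counts = as.data.frame(sim$estCounts)),
    f[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(f)
}
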