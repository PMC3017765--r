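## Genome FASTA + GFF3 gene-model input, spliced CDS extraction, translation
## and intron extraction with GT/AG splice-site validation. GFF3 coordinates
## are 1-based closed (the GFF3 and IRanges convention); BED export converts
## to 0-based half-open at the boundary.

#' Load a genome FASTA
#'
#' @param path FASTA file. Sequence names are the first whitespace-delimited
#'   token of each header; duplicates are an error; sequences are uppercased.
#' @return a [Biostrings::DNAStringSet] keyed by chromosome name.
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)   # errors on non-IUPAC characters
  names(ss) <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(names(ss)))
    stop("duplicate sequence id(s): ",
         paste(unique(names(ss)[duplicated(names(ss))]), collapse = ", "))
  Biostrings::DNAStringSet(toupper(ss))
}

## splice exon ranges (ascending genomic order) off a chromosome; sense strand
.spliceCDS <- function(chromSeq, exons, strand) {
  parts <- Biostrings::extractAt(chromSeq, exons)
  cds <- unlist(parts)
  if (strand == "-") cds <- Biostrings::reverseComplement(cds)
  as.character(cds)
}

.translateCDS <- function(cds) {
  ncodon <- nchar(cds) %/% 3L
  if (ncodon == 0L) return(list(protein = "", flags = "incomplete_cds"))
  flags <- character()
  if (nchar(cds) %% 3L != 0L) flags <- c(flags, "incomplete_cds")
  dna <- Biostrings::DNAString(substr(cds, 1L, 3L * ncodon))
  # the fuzzy-codon path is only needed for ambiguity codes and is much slower
  aa <- tryCatch(as.character(Biostrings::translate(dna,
                                                    no.init.codon = TRUE)),
                 error = function(e) suppressWarnings(as.character(
                   Biostrings::translate(dna, no.init.codon = TRUE,
                                         if.fuzzy.codon = "X"))))
  if (substr(aa, ncodon, ncodon) == "*") aa <- substr(aa, 1L, ncodon - 1L)
  if (grepl("*", aa, fixed = TRUE)) flags <- c(flags, "internal_stop")
  list(protein = aa, flags = flags)
}

#' Load gene models from GFF3
#'
#' Reads gene/mRNA/CDS features, builds one [GeneModel-class] per mRNA
#' (splicing the CDS segments off the genome, reverse-complementing on the
#' minus strand) and by default collapses alternative transcripts to the one
#' with the longest CDS per gene.
#'
#' @param path GFF3 file (CDS coordinates 1-based closed).
#' @param genome a [Biostrings::DNAStringSet] from [readGenome()].
#' @param collapse keep only the longest-CDS transcript per gene
#'   (default `TRUE`).
#' @return named list of [GeneModel-class] objects (by gene id when collapsed,
#'   transcript id otherwise).
#' @export
readGeneModels <- function(path, genome, collapse = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  mrna <- gr[typ == "mRNA"]
  cds <- gr[typ == "CDS"]
  if (length(mrna) == 0L) stop("no mRNA features in ", path)
  if (length(cds) == 0L) stop("no CDS features in ", path)
  mrnaParent <- vapply(mrna$Parent, function(p)
    if (length(p)) p[[1L]] else NA_character_, "")
  cdsParent <- vapply(cds$Parent, function(p)
    if (length(p)) p[[1L]] else NA_character_, "")
  cdsByTx <- split(seq_along(cds), cdsParent)
  models <- list()
  for (k in seq_along(mrna)) {
    tx <- mrna$ID[k]
    gene <- if (!is.na(mrnaParent[k])) mrnaParent[k] else tx
    seg <- cds[cdsByTx[[tx]]]
    if (length(seg) == 0L) stop("mRNA without CDS: ", tx)
    chrom <- as.character(GenomicRanges::seqnames(seg))[1L]
    if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
    strand <- as.character(GenomicRanges::strand(seg))[1L]
    if (!strand %in% c("+", "-")) stop("CDS without strand: ", tx)
    ex <- IRanges::ranges(seg)
    ex <- ex[order(IRanges::start(ex))]
    if (max(IRanges::end(ex)) > length(genome[[chrom]]) ||
        min(IRanges::start(ex)) < 1L)
      stop("CDS outside chromosome bounds: ", tx)
    if (length(ex) > 1L &&
        any(IRanges::start(ex)[-1L] <= IRanges::end(ex)[-length(ex)]))
      stop("overlapping CDS segments: ", tx)
    cdsSeq <- .spliceCDS(genome[[chrom]], ex, strand)
    tr <- .translateCDS(cdsSeq)
    models[[tx]] <- new("GeneModel", geneID = gene, txID = tx, chrom = chrom,
                        strand = strand, exons = ex, cds = cdsSeq,
                        protein = tr$protein, flags = tr$flags)
  }
  if (collapse) {
    byGene <- split(models, vapply(models, geneID, ""))
    models <- lapply(byGene, function(ms) {
      ms[[which.max(vapply(ms, function(m) nchar(cdsSeq(m)), 0))]]
    })
  }
  models
}

#' Extract introns from gene models
#'
#' One intron per adjacent exon pair in transcription order. `cds_offset` is
#' the number of coding nucleotides upstream of the splice junction; `phase`
#' is `cds_offset mod 3`; `donor`/`acceptor` are the first/last intron
#' dinucleotides on the transcribed strand; `canonical` is the GT/AG rule.
#'
#' @param models a [GeneModel-class] or list thereof.
#' @param genome the [Biostrings::DNAStringSet] the models refer to.
#' @param minIntron smallest legal intron (default 4 nt: room for donor and
#'   acceptor); shorter is an error.
#' @return data.frame with columns gene_id, ordinal, chrom, start, end
#'   (1-based closed genomic), length, donor, acceptor, cds_offset, phase,
#'   canonical. Intronless genes contribute no rows.
#' @export
extractIntrons <- function(models, genome, minIntron = 4L) {
  if (is(models, "GeneModel")) models <- list(models)
  out <- vector("list", length(models))
  for (mi in seq_along(models)) {
    m <- models[[mi]]
    ex <- m@exons
    if (length(ex) < 2L) { out[[mi]] <- NULL; next }
    chromSeq <- genome[[m@chrom]]
    n <- length(ex)
    # gaps between consecutive exons in ascending genomic order
    gstart <- IRanges::end(ex)[-n] + 1L
    gend <- IRanges::start(ex)[-1L] - 1L
    len <- gend - gstart + 1L
    if (any(len < minIntron))
      stop("intron shorter than ", minIntron, " nt in ", m@geneID)
    widths <- IRanges::width(ex)
    if (m@strand == "+") {
      # gap i (between genomic exons i and i+1) is intron ordinal i
      ordinal <- seq_len(n - 1L)
      cdsOff <- cumsum(widths)[-n]
      donor <- as.character(Biostrings::extractAt(
        chromSeq, IRanges::IRanges(gstart, gstart + 1L)))
      acceptor <- as.character(Biostrings::extractAt(
        chromSeq, IRanges::IRanges(gend - 1L, gend)))
    } else {
      # transcription runs high -> low genomic: gap i is intron ordinal n - i
      ordinal <- rev(seq_len(n - 1L))
      txCum <- cumsum(rev(widths))[-n]     # offset of intron ordinal k
      cdsOff <- txCum[ordinal]
      donor <- as.character(Biostrings::reverseComplement(
        Biostrings::extractAt(chromSeq, IRanges::IRanges(gend - 1L, gend))))
      acceptor <- as.character(Biostrings::reverseComplement(
        Biostrings::extractAt(chromSeq, IRanges::IRanges(gstart, gstart + 1L))))
    }
    df <- data.frame(
      gene_id = m@geneID, ordinal = ordinal,
      chrom = m@chrom, start = gstart, end = gend, length = len,
      donor = donor, acceptor = acceptor, cds_offset = cdsOff,
      stringsAsFactors = FALSE)
    out[[mi]] <- df[order(df$ordinal), , drop = FALSE]
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene_id = character(), ordinal = integer(),
                      chrom = character(), start = integer(), end = integer(),
                      length = integer(), donor = character(),
                      acceptor = character(), cds_offset = integer(),
                      stringsAsFactors = FALSE)
  res$phase <- res$cds_offset %% 3L
  res$canonical <- res$donor == "GT" & res$acceptor == "AG"
  rownames(res) <- NULL
  res
}

#' Write an intron table as TSV
#'
#' @param introns data.frame from [extractIntrons()].
#' @param path output path.
#' @export
writeIntronTable <- function(introns, path) {
  write.table(introns, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
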