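#' GeneModel: a protein-coding gene model
#'
#' One transcript of a protein-coding gene: chromosome, strand, exon
#' (CDS-segment) ranges, the spliced coding sequence on the sense strand and
#' its translation. Exon ranges are stored in ascending genomic order
#' (1-based, closed, the IRanges convention); transcription order on the minus
#' strand is the reverse.
#'
#' @slot geneID gene identifier.
#' @slot txID transcript (mRNA) identifier.
#' @slot chrom chromosome / scaffold name.
#' @slot strand `"+"` or `"-"`.
#' @slot exons [IRanges::IRanges] of CDS segments, ascending genomic order,
#'   non-overlapping.
#' @slot cds spliced coding sequence (sense strand, includes the stop codon
#'   when the model is complete).
#' @slot protein translation of `cds` with the terminal stop trimmed.
#' @slot flags character vector; subset of `"incomplete_cds"` (CDS length not
#'   a multiple of 3) and `"internal_stop"`.
#'
#' @seealso [readGeneModels()], [extractIntrons()]
#' @export
setClass("GeneModel",
  representation(
    geneID = "character",
    txID = "character",
    chrom = "character",
    strand = "character",
    exons = "IRanges",
    cds = "character",
    protein = "character",
    flags = "character"
  )
)

setValidity("GeneModel", function(object) {
  msg <- character()
  if (length(object@geneID) != 1L || !nzchar(object@geneID))
    msg <- c(msg, "geneID must be a single non-empty string")
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  ex <- object@exons
  if (length(ex) == 0L) {
    msg <- c(msg, "gene must have at least one exon")
  } else {
    if (is.unsorted(IRanges::start(ex), strictly = TRUE))
      msg <- c(msg, "exons must be in strictly ascending genomic order")
    if (length(ex) > 1L &&
        any(IRanges::start(ex)[-1L] <= IRanges::end(ex)[-length(ex)]))
      msg <- c(msg, "exons must be non-overlapping and separated")
    if (nchar(object@cds) != sum(IRanges::width(ex)))
      msg <- c(msg, "cds length must equal the summed exon widths")
  }
  if (!("incomplete_cds" %in% object@flags) && nchar(object@cds) %% 3L != 0L)
    msg <- c(msg, "cds length not a multiple of 3 but not flagged incomplete")
  if (length(msg)) msg else TRUE
})

#' @describeIn GeneModel gene identifier
#' @param x,object a `GeneModel`
#' @export
setGeneric("geneID", function(x) standardGeneric("geneID"))

#' @rdname GeneModel
#' @export
setMethod("geneID", "GeneModel", function(x) x@geneID)

#' @describeIn GeneModel transcript identifier
#' @export
setGeneric("txID", function(x) standardGeneric("txID"))

#' @rdname GeneModel
#' @export
setMethod("txID", "GeneModel", function(x) x@txID)

#' @describeIn GeneModel chromosome name
#' @export
setGeneric("chromName", function(x) standardGeneric("chromName"))

#' @rdname GeneModel
#' @export
setMethod("chromName", "GeneModel", function(x) x@chrom)

#' @describeIn GeneModel strand ("+" or "-")
#' @export
setGeneric("geneStrand", function(x) standardGeneric("geneStrand"))

#' @rdname GeneModel
#' @export
setMethod("geneStrand", "GeneModel", function(x) x@strand)

#' @describeIn GeneModel exon ranges (IRanges, ascending genomic order)
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))

#' @rdname GeneModel
#' @export
setMethod("exonRanges", "GeneModel", function(x) x@exons)

#' @describeIn GeneModel spliced coding sequence (sense strand)
#' @export
setGeneric("cdsSeq", function(x) standardGeneric("cdsSeq"))

#' @rdname GeneModel
#' @export
setMethod("cdsSeq", "GeneModel", function(x) x@cds)

#' @describeIn GeneModel protein sequence (terminal stop trimmed)
#' @export
setGeneric("proteinSeq", function(x) standardGeneric("proteinSeq"))

#' @rdname GeneModel
#' @export
setMethod("proteinSeq", "GeneModel", function(x) x@protein)

#' @describeIn GeneModel quality flags
#' @export
setGeneric("geneFlags", function(x) standardGeneric("geneFlags"))

#' @rdname GeneModel
#' @export
setMethod("geneFlags", "GeneModel", function(x) x@flags)

#' @rdname GeneModel
#' @export
setMethod("show", "GeneModel", function(object) {
  cat("GeneModel", object@geneID,
      sprintf("(%s:%d-%d %s)", object@chrom,
              min(IRanges::start(object@exons)),
              max(IRanges::end(object@exons)), object@strand),
      "\n  exons:", length(object@exons),
      " CDS:", nchar(object@cds), "nt",
      " protein:", nchar(object@protein), "aa\n")
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
  invisible(NULL)
})

#' ProteinAlignment: a gapped protein multiple sequence alignment
#'
#' Equal-length gapped amino-acid rows (gap character `-`), uppercase.
#' Removing gaps from a row reproduces the input protein exactly; the
#' constructor drops all-gap columns (with a warning) so no column is empty.
#'
#' @slot ids sequence identifiers, unique.
#' @slot rows gapped rows, all the same width.
#'
#' @seealso [progressiveAlignment()], [readAlignedFasta()], [projectIntrons()]
#' @export
setClass("ProteinAlignment",
  representation(ids = "character", rows = "character")
)

setValidity("ProteinAlignment", function(object) {
  msg <- character()
  if (length(object@ids) != length(object@rows))
    msg <- c(msg, "ids and rows must have the same length")
  if (anyDuplicated(object@ids))
    msg <- c(msg, "sequence ids must be unique")
  w <- unique(nchar(object@rows))
  if (length(w) > 1L)
    msg <- c(msg, "all rows must have the same length")
  if (length(object@rows) && any(grepl("[^A-Z*\\-]", object@rows)))
    msg <- c(msg, "rows must be uppercase amino acids or '-'")
  if (length(msg)) msg else TRUE
})

#' Construct a ProteinAlignment
#'
#' @param ids character vector of sequence ids.
#' @param rows character vector of equal-length gapped rows (case-insensitive;
#'   normalised to uppercase). All-gap columns are removed with a warning.
#' @return a [ProteinAlignment-class] object.
#' @export
ProteinAlignment <- function(ids, rows) {
  rows <- toupper(as.character(rows))
  ids <- as.character(ids)
  if (length(rows) && length(unique(nchar(rows))) == 1L && nchar(rows[1L]) > 0L) {
    m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
    allgap <- colSums(m != "-") == 0L
    if (any(allgap)) {
      warning(sum(allgap), " all-gap column(s) removed")
      m <- m[, !allgap, drop = FALSE]
      rows <- apply(m, 1L, paste, collapse = "")
    }
  }
  new("ProteinAlignment", ids = ids, rows = rows)
}

#' @describeIn ProteinAlignment number of alignment columns
#' @param x,object a `ProteinAlignment`
#' @export
setGeneric("nColumns", function(x) standardGeneric("nColumns"))

#' @rdname ProteinAlignment
#' @export
setMethod("nColumns", "ProteinAlignment", function(x) {
  if (!length(x@rows)) 0L else nchar(x@rows[1L])
})

#' @describeIn ProteinAlignment sequence ids
#' @export
setGeneric("alignmentIDs", function(x) standardGeneric("alignmentIDs"))

#' @rdname ProteinAlignment
#' @export
setMethod("alignmentIDs", "ProteinAlignment", function(x) x@ids)

#' @describeIn ProteinAlignment named gapped rows
#' @export
setGeneric("alignmentRows", function(x) standardGeneric("alignmentRows"))

#' @rdname ProteinAlignment
#' @export
setMethod("alignmentRows", "ProteinAlignment", function(x)
  stats::setNames(x@rows, x@ids))

#' @describeIn ProteinAlignment ungapped input sequences (named)
#' @export
setGeneric("ungappedSeqs", function(x) standardGeneric("ungappedSeqs"))

#' @rdname ProteinAlignment
#' @export
setMethod("ungappedSeqs", "ProteinAlignment", function(x)
  stats::setNames(gsub("-", "", x@rows, fixed = TRUE), x@ids))

#' @rdname ProteinAlignment
#' @export
setMethod("length", "ProteinAlignment", function(x) length(x@ids))

#' @rdname ProteinAlignment
#' @export
setMethod("show", "ProteinAlignment", function(object) {
  cat("ProteinAlignment:", length(object@ids), "sequences x",
      nColumns(object), "columns\n")
  n <- min(5L, length(object@ids))
  for (i in seq_len(n)) {
    r <- object@rows[i]
    if (nchar(r) > 60L) r <- paste0(substr(r, 1L, 57L), "...")
    cat(sprintf("  %-12s %s\n", object@ids[i], r))
  }
  if (length(object@ids) > n) cat("  ...\n")
  invisible(NULL)
})
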