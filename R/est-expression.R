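## EST expression: tabulate clone hit records into gene x tissue counts,
## summarise clone-frequency and tissue distributions, and relate expression
## to phylogenetic clades.

#' Read an EST hit table
#'
#' TSV with columns clone_id, gene_id, tissue. Duplicate clone ids are an
#' error (each sequenced clone is one observation).
#'
#' @param path file path.
#' @return data.frame of EST records.
#' @export
readESTTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("clone_id", "gene_id", "tissue")
  if (!all(need %in% names(df)))
    stop("EST table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$clone_id))
    stop("duplicate clone_id(s): ",
         paste(unique(df$clone_id[duplicated(df$clone_id)]), collapse = ", "))
  df
}

#' Tabulate EST records into a gene x tissue count matrix
#'
#' Records for genes outside `familyGenes` are dropped with a message; family
#' genes without clones are retained as zero rows.
#'
#' @param records data.frame from [readESTTable()].
#' @param familyGenes character vector of family gene ids.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts` (genes x tissues).
#' @export
tabulateEST <- function(records, familyGenes) {
  if (anyDuplicated(records$clone_id)) stop("duplicate clone_id(s)")
  drop <- !(records$gene_id %in% familyGenes)
  if (any(drop)) {
    message(sum(drop), " record(s) for non-family genes ignored")
    records <- records[!drop, , drop = FALSE]
  }
  tissues <- sort(unique(records$tissue))
  if (!length(tissues)) tissues <- "none"
  counts <- matrix(0L, length(familyGenes), length(tissues),
                   dimnames = list(familyGenes, tissues))
  if (nrow(records)) {
    tab <- table(factor(records$gene_id, levels = familyGenes),
                 factor(records$tissue, levels = tissues))
    counts[] <- as.integer(tab)
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(tissue = tissues, row.names = tissues))
}

.estCounts <- function(x) {
  if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "counts") else as.matrix(x)
}

#' Frequency distribution of genes by total EST clone count
#'
#' Genes are binned by total clones: singleton bins 0..14 and a final ">15"
#' bin. The published layout has no bin for exactly 15 clones; totals of 15
#' are counted in ">15".
#'
#' @param x gene x tissue counts ([SummarizedExperiment::SummarizedExperiment]
#'   from [tabulateEST()], or a matrix).
#' @return data.frame with columns bin and n_genes; n_genes sums to the
#'   number of family genes.
#' @export
cloneFrequencyDistribution <- function(x) {
  counts <- .estCounts(x)
  tot <- rowSums(counts)
  bins <- c(as.character(0:14), ">15")
  n <- c(vapply(0:14, function(b) sum(tot == b), 0L), sum(tot >= 15L))
  data.frame(bin = bins, n_genes = n, stringsAsFactors = FALSE)
}

#' Per-tissue expression summary
#'
#' @param x gene x tissue counts (see [cloneFrequencyDistribution()]).
#' @return data.frame with columns tissue, n_genes (genes with >= 1 clone in
#'   the tissue) and n_clones, sorted by decreasing clone count.
#' @export
tissueSummary <- function(x) {
  counts <- .estCounts(x)
  out <- data.frame(tissue = colnames(counts),
                    n_genes = as.integer(colSums(counts >= 1L)),
                    n_clones = as.integer(colSums(counts)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_clones, out$tissue), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Clade-by-tissue expression association
#'
#' For each clade, the fraction of member genes with at least one clone in
#' `tissue`. With `test = TRUE` a two-sided Fisher exact test of clade
#' membership against tissue expression is added, Benjamini-Hochberg
#' corrected across clades. The test layer is an explicit extension beyond
#' descriptive EST tabulation and is off by default.
#'
#' @param clades list of leaf sets (e.g. from [flagSupportedClades()]); leaf
#'   ids must be row names of `x`.
#' @param x gene x tissue counts.
#' @param tissue tissue (column) name.
#' @param test add Fisher/BH enrichment columns (default `FALSE`).
#' @return data.frame with clade, n_members, n_expressed, fraction and
#'   optionally p_value, p_adj.
#' @export
cladeTissueAssociation <- function(clades, x, tissue, test = FALSE) {
  counts <- .estCounts(x)
  if (!tissue %in% colnames(counts)) stop("unknown tissue: ", tissue)
  if (!length(clades))
    return(data.frame(clade = character(), n_members = integer(),
                      n_expressed = integer(), fraction = numeric()))
  bad <- setdiff(unlist(clades), rownames(counts))
  if (length(bad))
    stop("clade gene(s) missing from table: ", paste(bad, collapse = ", "))
  expressed <- counts[, tissue] >= 1L
  out <- data.frame(
    clade = vapply(clades, function(cl) paste(sort(cl), collapse = ","), ""),
    n_members = vapply(clades, length, 0L),
    n_expressed = vapply(clades, function(cl) sum(expressed[cl]), 0L),
    stringsAsFactors = FALSE)
  out$fraction <- out$n_expressed / out$n_members
  if (test) {
    out$p_value <- vapply(clades, function(cl) {
      inC <- rownames(counts) %in% cl
      stats::fisher.test(table(factor(inC, c(FALSE, TRUE)),
                               factor(expressed, c(FALSE, TRUE))))$p.value
    }, 0)
    out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  }
  out
}

#' Bundled EST survey summary tables for the silkworm CCE family
#'
#' Two transcribed summary tables from a published EST survey of the 69
#' silkworm carboxyl/cholinesterase genes: `clone_frequency` (genes binned by
#' total clone count) and `tissue_counts` (per-tissue gene and clone counts).
#' They serve as worked-example fixtures for the tabulation layer.
#'
#' @return list of data.frames `clone_frequency` (bin, n_genes) and
#'   `tissue_counts` (tissue, n_genes, n_clones).
#' @export
estSummaryTables <- function() {
  dir <- system.file("extdata", package = "famarch", mustWork = TRUE)
  cf <- read.delim(file.path(dir, "silkworm_cce_est_clone_frequency.tsv"),
                   stringsAsFactors = FALSE, colClasses = c("character",
                                                            "integer"))
  tc <- read.delim(file.path(dir, "silkworm_cce_est_tissue_counts.tsv"),
                   stringsAsFactors = FALSE)
  list(clone_frequency = cf, tissue_counts = tc)
}
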