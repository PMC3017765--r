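## Intron architecture: splice-phase classification, projection of introns
## into alignment coordinates, conserved-position detection and length
## statistics.
##
## Coordinate convention: an intron site is reported as a nucleotide position
## in the codon-expanded alignment, aln_nt_pos = 3 * (column - 1) + phase,
## where `column` is the 1-based alignment column of the residue whose codon
## hosts (phase 1/2) or follows (phase 0) the splice junction. By construction
## aln_nt_pos mod 3 == phase.

#' Splice-site phase from a coding offset
#'
#' Phase 0 lies between two codons, phase 1 one base inside the codon in the
#' 3' direction, phase 2 two bases inside.
#'
#' @param cdsOffset positive integer vector: coding nucleotides upstream of
#'   the splice junction.
#' @return integer vector of phases in \{0, 1, 2\}.
#' @examples
#' intronPhase(c(6, 7, 8))   # 0 1 2
#' @export
intronPhase <- function(cdsOffset) {
  if (any(cdsOffset <= 0)) stop("cds_offset must be positive")
  as.integer(cdsOffset %% 3L)
}

#' Project introns into alignment coordinates
#'
#' Maps each intron's coding offset onto the protein alignment: with r
#' complete codons upstream and phase p, the hosting/following residue is
#' residue r + 1 of the ungapped protein; its alignment column c gives
#' `aln_nt_pos = 3 * (c - 1) + p`. Introns lying after the final aligned
#' residue (e.g. within the stop codon) cannot be projected and are dropped
#' with a message.
#'
#' @param introns data.frame from [extractIntrons()] (columns gene_id,
#'   ordinal, cds_offset, phase).
#' @param aln a [ProteinAlignment-class] containing every projected gene.
#' @return data.frame with columns gene_id, ordinal, column, aln_nt_pos,
#'   phase.
#' @export
projectIntrons <- function(introns, aln) {
  stopifnot(is(aln, "ProteinAlignment"))
  rows <- alignmentRows(aln)
  missing <- setdiff(unique(introns$gene_id), names(rows))
  if (length(missing))
    stop("gene(s) absent from alignment: ", paste(missing, collapse = ", "))
  # per gene: alignment column of each residue
  col_of_res <- lapply(rows, function(r) {
    which(strsplit(r, "")[[1L]] != "-")
  })
  r_up <- introns$cds_offset %/% 3L
  p <- intronPhase(introns$cds_offset)
  res_idx <- r_up + 1L
  nres <- vapply(col_of_res[introns$gene_id], length, 0L)
  ok <- res_idx <= nres
  if (any(!ok))
    message(sum(!ok), " intron(s) beyond the final aligned residue excluded")
  idx <- which(ok)
  column <- vapply(idx, function(i)
    col_of_res[[introns$gene_id[i]]][res_idx[i]], 0L)
  data.frame(gene_id = introns$gene_id[idx], ordinal = introns$ordinal[idx],
             column = column, aln_nt_pos = 3L * (column - 1L) + p[idx],
             phase = p[idx], stringsAsFactors = FALSE)
}

#' Conserved intron positions across a gene family
#'
#' Groups projected intron sites that share a splice phase and lie within
#' `toleranceNT` nucleotides of each other (single linkage on sorted
#' positions; chains wider than the tolerance are split at their largest
#' internal gaps so each group spans at most `toleranceNT`). A gene
#' contributes at most one intron per group (the one closest to the group
#' median is kept). Groups with at least `minMembers` distinct genes are
#' returned, largest first.
#'
#' @param sites data.frame from [projectIntrons()].
#' @param minMembers minimum distinct genes per group (default 2).
#' @param toleranceNT maximum within-group position spread in nucleotides
#'   (default 3, one codon of alignment jitter).
#' @return data.frame with columns canonical_pos (minimum member position),
#'   phase, n_members, pos_min, pos_max and a list column `members` of gene
#'   ids; sorted by decreasing n_members then canonical_pos.
#' @export
findConservedSites <- function(sites, minMembers = 2L, toleranceNT = 3L) {
  empty <- data.frame(canonical_pos = integer(), phase = integer(),
                      n_members = integer(), pos_min = integer(),
                      pos_max = integer())
  empty$members <- list()
  if (nrow(sites) == 0L) return(empty)
  sites <- sites[order(sites$phase, sites$aln_nt_pos, sites$gene_id), ]
  groups <- list()
  for (ph in sort(unique(sites$phase))) {
    s <- sites[sites$phase == ph, , drop = FALSE]
    pos <- s$aln_nt_pos
    # single linkage: break where adjacent gap exceeds tolerance
    brk <- c(0L, which(diff(pos) > toleranceNT), nrow(s))
    for (b in seq_len(length(brk) - 1L)) {
      seg <- s[(brk[b] + 1L):brk[b + 1L], , drop = FALSE]
      groups <- c(groups, .splitWide(seg, toleranceNT))
    }
  }
  res <- lapply(groups, function(g) {
    # one intron per gene: keep the site closest to the group median
    med <- stats::median(g$aln_nt_pos)
    g <- g[order(abs(g$aln_nt_pos - med), g$aln_nt_pos), , drop = FALSE]
    g <- g[!duplicated(g$gene_id), , drop = FALSE]
    list(canonical_pos = min(g$aln_nt_pos), phase = g$phase[1L],
         n_members = nrow(g), pos_min = min(g$aln_nt_pos),
         pos_max = max(g$aln_nt_pos),
         members = sort(g$gene_id))
  })
  res <- Filter(function(g) g$n_members >= minMembers, res)
  if (!length(res)) return(empty)
  out <- data.frame(
    canonical_pos = vapply(res, `[[`, 0L, "canonical_pos"),
    phase = vapply(res, `[[`, 0L, "phase"),
    n_members = vapply(res, `[[`, 0L, "n_members"),
    pos_min = vapply(res, `[[`, 0L, "pos_min"),
    pos_max = vapply(res, `[[`, 0L, "pos_max"))
  out$members <- lapply(res, `[[`, "members")
  ord <- order(-out$n_members, out$canonical_pos)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## split a single-linkage chain at its largest internal gaps until its span
## fits within the tolerance (deterministic)
.splitWide <- function(seg, toleranceNT) {
  if (max(seg$aln_nt_pos) - min(seg$aln_nt_pos) <= toleranceNT)
    return(list(seg))
  gaps <- diff(seg$aln_nt_pos)
  cut <- which.max(gaps)
  c(.splitWide(seg[seq_len(cut), , drop = FALSE], toleranceNT),
    .splitWide(seg[-seq_len(cut), , drop = FALSE], toleranceNT))
}

#' Intron length statistics
#'
#' @param introns data.frame from [extractIntrons()].
#' @param models the gene models the introns came from (list of
#'   [GeneModel-class]); used to count intronless genes.
#' @param binWidth histogram bin width in nucleotides (default 500).
#' @return list with n_introns, n_intronless_genes, mean_length (`NA` when
#'   there are no introns), min_length, max_length and a `histogram`
#'   data.frame (bin_start, bin_end, count).
#' @export
intronLengthStats <- function(introns, models = list(), binWidth = 500L) {
  if (is(models, "GeneModel")) models <- list(models)
  nIntronless <- if (length(models)) {
    sum(vapply(models, function(m) length(exonRanges(m)) == 1L, TRUE))
  } else 0L
  if (nrow(introns) == 0L) {
    return(list(n_introns = 0L, n_intronless_genes = nIntronless,
                mean_length = NA_real_, min_length = NA_integer_,
                max_length = NA_integer_,
                histogram = data.frame(bin_start = integer(),
                                       bin_end = integer(),
                                       count = integer())))
  }
  len <- introns$length
  lo <- (seq_len(ceiling((max(len) + 1) / binWidth)) - 1L) * binWidth
  counts <- vapply(lo, function(b) sum(len >= b & len < b + binWidth), 0L)
  list(n_introns = nrow(introns), n_intronless_genes = nIntronless,
       mean_length = mean(len), min_length = min(len), max_length = max(len),
       histogram = data.frame(bin_start = lo, bin_end = lo + binWidth - 1L,
                              count = counts))
}

#' Gene-by-group presence matrix for conserved introns
#'
#' @param groups data.frame from [findConservedSites()].
#' @param genes character vector of all family gene ids.
#' @param k how many of the most-populated groups to count in the summary
#'   (default 2, mirroring the two ancient family-wide introns).
#' @return list with `matrix` (logical genes x groups, group columns named by
#'   `phase<p>@<canonical_pos>`) and `n_genes_with_top_k`, the number of genes
#'   carrying at least one of the k most-populated groups.
#' @export
sharedIntronMatrix <- function(groups, genes, k = 2L) {
  m <- matrix(FALSE, length(genes), nrow(groups),
              dimnames = list(genes, if (nrow(groups)) paste0(
                "phase", groups$phase, "@", groups$canonical_pos) else NULL))
  for (j in seq_len(nrow(groups)))
    m[intersect(groups$members[[j]], genes), j] <- TRUE
  topk <- seq_len(min(k, ncol(m)))
  list(matrix = m,
       n_genes_with_top_k = if (length(topk))
         sum(rowSums(m[, topk, drop = FALSE]) > 0L) else 0L)
}
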