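## Protein multiple sequence alignment: affine-gap pairwise/profile aligner
## plus a progressive MSA over an NJ guide tree on k-mer distances. External
## (e.g. ClustalW/MAFFT) alignments read via readAlignedFasta() are
## first-class input everywhere an alignment is consumed.

.getBLOSUM62 <- function() {
  if (is.null(.famarch_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .famarch_cache$BLOSUM62 <- e$BLOSUM62[AA_ORDER, AA_ORDER]
  }
  .famarch_cache$BLOSUM62
}

## 20 x L indicator/frequency profile from gapped rows; gap mass is dropped so
## gap positions contribute zero score. Normalisation by the number of rows.
.profileFromRows <- function(rows) {
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  L <- ncol(m)
  prof <- matrix(0, 20L, L, dimnames = list(AA_ORDER, NULL))
  for (a in seq_along(AA_ORDER)) prof[a, ] <- colSums(m == AA_ORDER[a])
  prof / nrow(m)
}

.checkProteinString <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string")
  if (!nzchar(x)) stop(what, " must be non-empty")
  bad <- setdiff(strsplit(x, "")[[1L]], AA_ORDER)
  if (length(bad))
    stop("unknown residue character(s) in ", what, ": ",
         paste(unique(bad), collapse = ", "))
  invisible(TRUE)
}

## core: align two groups of gapped rows (profiles); returns merged rows
## in the order c(rowsA, rowsB) plus the DP score
.alignProfiles <- function(rowsA, rowsB, submat, gapOpen, gapExtend) {
  fa <- .profileFromRows(rowsA)
  fb <- .profileFromRows(rowsB)
  colscore <- t(fa) %*% submat %*% fb
  res <- .gotoh_align_cpp(colscore, gapOpen, gapExtend)
  path <- res$path
  nA <- ncol(fa); nB <- ncol(fb)
  ia <- integer(0); ib <- integer(0)   # source column (0 = gap) per out column
  ai <- 0L; bi <- 0L
  ia <- integer(length(path)); ib <- integer(length(path))
  for (k in seq_along(path)) {
    if (path[k] == 0L) { ai <- ai + 1L; bi <- bi + 1L; ia[k] <- ai; ib[k] <- bi }
    else if (path[k] == 1L) { ai <- ai + 1L; ia[k] <- ai; ib[k] <- 0L }
    else { bi <- bi + 1L; ia[k] <- 0L; ib[k] <- bi }
  }
  expand <- function(rows, idx) {
    m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
    out <- matrix("-", nrow(m), length(idx))
    out[, idx > 0L] <- m[, idx[idx > 0L], drop = FALSE]
    apply(out, 1L, paste, collapse = "")
  }
  list(rows = c(expand(rowsA, ia), expand(rowsB, ib)), score = res$score)
}

#' Global pairwise protein alignment (Needleman-Wunsch, affine gaps)
#'
#' Optimal global alignment under a substitution matrix with affine gap costs:
#' a gap run of length k costs `gapOpen + (k - 1) * gapExtend`. Traceback ties
#' are broken deterministically (diagonal, then up, then left).
#'
#' @param a,b protein sequences (single strings over the 20-letter alphabet).
#' @param submat substitution matrix with amino-acid dimnames
#'   (default BLOSUM62 from Biostrings).
#' @param gapOpen,gapExtend gap penalties (negative numbers).
#' @return list with gapped strings `a`, `b` and the optimal `score`.
#' @examples
#' pairwiseAlignProteins("MKV", "MV")
#' @export
pairwiseAlignProteins <- function(a, b, submat = .getBLOSUM62(),
                                  gapOpen = -10, gapExtend = -0.5) {
  .checkProteinString(a, "sequence a")
  .checkProteinString(b, "sequence b")
  res <- .alignProfiles(a, b, submat[AA_ORDER, AA_ORDER], gapOpen, gapExtend)
  list(a = res$rows[1L], b = res$rows[2L], score = res$score)
}

#' k-mer distance matrix between protein sequences
#'
#' Distance 1 - F where F is the fraction of shared k-mers relative to the
#' shorter sequence; the standard quick guide-tree distance.
#'
#' @param seqs named character vector of protein sequences.
#' @param k word size (default 3).
#' @return symmetric distance matrix.
#' @export
kmerDistanceMatrix <- function(seqs, k = 3L) {
  n <- length(seqs)
  kmerSet <- function(s) {
    L <- nchar(s)
    if (L < k) return(s)
    unique(substring(s, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L))
  }
  sets <- lapply(seqs, kmerSet)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    f <- length(intersect(sets[[i]], sets[[j]])) /
      max(1L, min(length(sets[[i]]), length(sets[[j]])))
    d[i, j] <- d[j, i] <- 1 - f
  }
  d
}

#' Progressive protein multiple sequence alignment
#'
#' Builds a guide tree by neighbor joining on 3-mer distances and merges
#' profiles in guide-tree postorder with the affine-gap profile aligner.
#' Stripping gaps from any output row reproduces the corresponding input
#' sequence exactly.
#'
#' @param seqs named character vector (>= 2 protein sequences).
#' @param submat substitution matrix (default BLOSUM62).
#' @param gapOpen,gapExtend affine gap penalties.
#' @return a [ProteinAlignment-class] with rows in input order.
#' @export
progressiveAlignment <- function(seqs, submat = .getBLOSUM62(),
                                 gapOpen = -10, gapExtend = -0.5) {
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names")
  seqs <- toupper(seqs)
  for (i in seq_along(seqs)) .checkProteinString(seqs[[i]], names(seqs)[i])
  submat <- submat[AA_ORDER, AA_ORDER]

  mergeGroups <- function(gA, gB) {
    res <- .alignProfiles(gA$rows, gB$rows, submat, gapOpen, gapExtend)
    list(ids = c(gA$ids, gB$ids), rows = res$rows)
  }
  leaf <- function(id) list(ids = id, rows = unname(seqs[[id]]))

  if (length(seqs) == 2L) {
    merged <- mergeGroups(leaf(names(seqs)[1L]), leaf(names(seqs)[2L]))
  } else {
    guide <- njTree(kmerDistanceMatrix(seqs))
    merged <- .mergePostorder(guide, leaf, mergeGroups)
  }
  ord <- match(names(seqs), merged$ids)
  ProteinAlignment(merged$ids[ord], merged$rows[ord])
}

## postorder profile merge over an (unrooted, possibly multifurcating) phylo
.mergePostorder <- function(tree, leaf, mergeGroups) {
  ntip <- length(tree$tip.label)
  rec <- function(node) {
    if (node <= ntip) return(leaf(tree$tip.label[node]))
    children <- tree$edge[tree$edge[, 1L] == node, 2L]
    groups <- lapply(children, rec)
    out <- groups[[1L]]
    for (g in groups[-1L]) out <- mergeGroups(out, g)
    out
  }
  rec(ntip + 1L)
}

#' Read / write an aligned FASTA file
#'
#' `readAlignedFasta()` validates that all rows have equal length (ragged
#' input is an error) and normalises to uppercase; `writeAlignedFasta()` is
#' its lossless inverse.
#'
#' @param path file path.
#' @return `readAlignedFasta()` returns a [ProteinAlignment-class].
#' @export
readAlignedFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  w <- unique(Biostrings::width(ss))
  if (length(w) > 1L)
    stop("ragged alignment: row lengths ", paste(w, collapse = ", "))
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L)
  ProteinAlignment(ids, as.character(ss))
}

#' @rdname readAlignedFasta
#' @param aln a [ProteinAlignment-class].
#' @export
writeAlignedFasta <- function(aln, path) {
  stopifnot(is(aln, "ProteinAlignment"))
  ss <- Biostrings::BStringSet(stats::setNames(aln@rows, aln@ids))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
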