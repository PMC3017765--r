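## Distance phylogeny: JTT maximum-likelihood pairwise distances, Saitou-Nei
## neighbor joining, minimum-evolution refinement by NNI over OLS branch
## lengths, and nonparametric bootstrap support.

.MAX_JTT_DIST <- 10

.aaIndex <- function(chars) match(chars, AA_ORDER)

## 20x20 count matrix of aligned residue pairs over shared (both non-gap,
## both standard-alphabet) columns of two gapped rows
.pairCounts <- function(rowA, rowB) {
  a <- .aaIndex(strsplit(rowA, "")[[1L]])
  b <- .aaIndex(strsplit(rowB, "")[[1L]])
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) return(NULL)
  matrix(tabulate((a[keep] - 1L) * 20L + b[keep], nbins = 400L),
         20L, 20L, byrow = TRUE)
}

#' Maximum-likelihood JTT distance between two aligned rows
#'
#' Estimates the scalar divergence t maximising the likelihood of the observed
#' residue pairs under the JTT model, sum over shared columns of
#' log(pi_i * P_ij(t)), by bounded (Brent) search on t in (0, 10\].
#' Columns where either row has a gap are excluded (pairwise deletion).
#' Saturated pairs are capped at 10 with a warning and carry attribute
#' `saturated = TRUE`.
#'
#' @param rowA,rowB equal-length gapped amino-acid strings.
#' @param tol convergence tolerance of the scalar search.
#' @return the distance (expected substitutions per site).
#' @export
jttDistance <- function(rowA, rowB, tol = 1e-6) {
  if (nchar(rowA) != nchar(rowB)) stop("rows must have equal length")
  N <- .pairCounts(rowA, rowB)
  if (is.null(N))
    stop("no shared residue columns: distance undefined")
  if (sum(N) == sum(diag(N))) return(structure(0, saturated = FALSE))
  nll <- function(t) -sum(N * log(jttProbMatrix(t) + 1e-300))
  opt <- stats::optimize(nll, c(1e-9, .MAX_JTT_DIST), tol = tol)
  t_hat <- opt$minimum
  saturated <- t_hat > .MAX_JTT_DIST - 1e-3 &&
    nll(.MAX_JTT_DIST) <= nll(t_hat) + 1e-9
  if (saturated) {
    warning("saturated distance capped at ", .MAX_JTT_DIST)
    t_hat <- .MAX_JTT_DIST
  }
  structure(t_hat, saturated = saturated)
}

#' JTT distance matrix from a protein alignment
#'
#' @param aln a [ProteinAlignment-class] (or named character vector of
#'   equal-length gapped rows).
#' @param tol scalar-search tolerance passed to [jttDistance()].
#' @return symmetric matrix with zero diagonal; attribute `saturated` holds
#'   the logical matrix of capped entries.
#' @export
jttDistanceMatrix <- function(aln, tol = 1e-6) {
  rows <- if (is(aln, "ProteinAlignment")) alignmentRows(aln) else aln
  n <- length(rows)
  ids <- names(rows)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  sat <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    dij <- jttDistance(rows[[i]], rows[[j]], tol = tol)
    d[i, j] <- d[j, i] <- as.numeric(dij)
    sat[i, j] <- sat[j, i] <- isTRUE(attr(dij, "saturated"))
  }
  structure(d, saturated = sat)
}

#' Neighbor-joining tree (Saitou & Nei)
#'
#' Classic NJ on a symmetric distance matrix. Negative branch lengths are
#' clamped to zero with the deficit moved to the adjacent (sister) branch so
#' path lengths are preserved. An all-zero matrix carries no information and
#' yields a star tree with no internal edges.
#'
#' @param dm symmetric numeric matrix with dimnames (n >= 3 taxa).
#' @return an unrooted [ape::phylo] tree.
#' @export
njTree <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  n <- nrow(dm)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  ids <- rownames(dm)
  if (is.null(ids)) ids <- paste0("t", seq_len(n))
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(dm < 0)) stop("distances must be non-negative")
  if (max(dm) == 0) {   # no signal: star tree
    txt <- paste0("(", paste0(ids, ":0", collapse = ","), ");")
    return(ape::read.tree(text = txt))
  }
  fmt <- function(x) format(max(0, x), digits = 15, scientific = FALSE)
  lab <- ids                      # newick fragment per active node
  D <- dm
  active <- seq_len(n)
  while (length(active) > 3L) {
    m <- length(active)
    Da <- D[active, active]
    r <- rowSums(Da)
    Qm <- (m - 2) * Da - outer(r, r, "+")
    diag(Qm) <- Inf
    k <- which.min(Qm)            # deterministic: first minimum column-major
    i <- (k - 1L) %% m + 1L
    j <- (k - 1L) %/% m + 1L
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    dij <- Da[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    ai <- active[i]; aj <- active[j]
    newlab <- paste0("(", lab[ai], ":", fmt(li), ",",
                     lab[aj], ":", fmt(lj), ")")
    dnew <- (D[ai, ] + D[aj, ] - dij) / 2
    D <- rbind(cbind(D, dnew), c(dnew, 0))
    u <- nrow(D)
    lab <- c(lab, newlab)
    active <- c(setdiff(active, c(ai, aj)), u)
  }
  a <- active[1L]; b <- active[2L]; c3 <- active[3L]
  la <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
  lb <- D[a, b] - la
  lc <- D[a, c3] - la
  if (la < 0) { lb <- lb + la; la <- 0 }
  if (lb < 0) { la <- la + lb; lb <- 0 }
  if (lc < 0) { la <- la + lc; lc <- 0 }
  txt <- paste0("(", lab[a], ":", fmt(la), ",", lab[b], ":", fmt(lb), ",",
                lab[c3], ":", fmt(lc), ");")
  ape::read.tree(text = txt)
}

## total tree length after OLS (non-negative least squares) branch fit
.olsTreeLength <- function(tree, dm) {
  fit <- phangorn::nnls.tree(dm, tree, method = "unrooted", trace = 0)
  sum(fit$edge.length)
}

#' Minimum-evolution refinement by nearest-neighbor interchange
#'
#' Hill climb over NNI rearrangements minimising the total tree length under
#' OLS (non-negative least squares) branch-length fitting to the distance
#' matrix. Returns the input tree unchanged when no rearrangement shortens it.
#'
#' @param tree an unrooted [ape::phylo], e.g. from [njTree()].
#' @param dm the distance matrix the tree was built from.
#' @param maxIter maximum hill-climb sweeps.
#' @return an [ape::phylo]; refitted branch lengths when refinement improved
#'   the tree, the input otherwise.
#' @export
meRefine <- function(tree, dm, maxIter = 20L) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 4L || !ape::is.binary(tree)) return(tree)
  dm <- dm[tree$tip.label, tree$tip.label]
  best <- tree
  bestLen <- .olsTreeLength(tree, dm)
  improved_any <- FALSE
  for (it in seq_len(maxIter)) {
    nbrs <- phangorn::nni(best)
    lens <- vapply(nbrs, .olsTreeLength, 0, dm = dm)
    if (min(lens) < bestLen - 1e-10) {
      k <- which.min(lens)
      best <- phangorn::nnls.tree(dm, nbrs[[k]], method = "unrooted",
                                  trace = 0)
      bestLen <- sum(best$edge.length)
      improved_any <- TRUE
    } else break
  }
  if (!improved_any) tree else best
}

## distance+NJ from a character matrix of alignment columns (bootstrap engine)
.njFromCharMatrix <- function(X, tol = 1e-4) {
  rows <- apply(X, 1L, paste, collapse = "")
  names(rows) <- rownames(X)
  njTree(jttDistanceMatrix(rows, tol = tol))
}

#' Bootstrap support for a distance tree
#'
#' Resamples alignment columns with replacement, rebuilds the JTT distance
#' matrix and NJ tree per replicate, and scores each internal edge of the main
#' tree by the percentage of replicates containing the same leaf bipartition.
#' Deterministic for a given seed.
#'
#' @param aln a [ProteinAlignment-class] with >= 4 sequences.
#' @param nReps number of bootstrap replicates (default 500).
#' @param seed integer RNG seed.
#' @param refine if `TRUE`, the main tree (not the replicates) is passed
#'   through [meRefine()].
#' @return the main [ape::phylo] with `node.label` holding support values in
#'   \[0, 100\] (root label empty).
#' @export
bootstrapSupport <- function(aln, nReps = 500L, seed, refine = FALSE) {
  stopifnot(is(aln, "ProteinAlignment"))
  if (length(aln) < 4L) stop("bootstrap needs >= 4 sequences")
  if (missing(seed)) stop("an integer seed is required")
  set.seed(seed)
  rows <- alignmentRows(aln)
  X <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  rownames(X) <- names(rows)
  dm <- jttDistanceMatrix(aln)
  main <- njTree(dm)
  if (refine) main <- meRefine(main, dm)
  if (main$Nnode <= 1L) {           # star tree: nothing to support
    main$node.label <- rep("", main$Nnode)
    return(main)
  }
  counts <- ape::boot.phylo(main, X, .njFromCharMatrix, B = nReps,
                            quiet = TRUE, rooted = FALSE)
  supp <- 100 * counts / nReps
  lab <- formatC(supp, format = "fg", digits = 3)
  lab[1L] <- ""                     # root bipartition is trivial
  main$node.label <- lab
  attr(main, "support") <- c(NA_real_, supp[-1L])
  main
}

#' Clades above a bootstrap support threshold
#'
#' @param tree an [ape::phylo] whose `node.label` holds bootstrap supports
#'   (as from [bootstrapSupport()]).
#' @param threshold minimum support; clades with support strictly greater are
#'   returned (default 50, the usual flagging convention).
#' @return list of character vectors (leaf sets), sorted by decreasing size.
#' @export
flagSupportedClades <- function(tree, threshold = 50) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$node.label))
    stop("tree has no support values; run bootstrapSupport() first")
  ntip <- length(tree$tip.label)
  supp <- suppressWarnings(as.numeric(tree$node.label))
  keep <- which(!is.na(supp) & supp > threshold)
  clades <- lapply(keep, function(k) {
    ape::extract.clade(tree, ntip + k)$tip.label
  })
  clades[order(vapply(clades, length, 0L), decreasing = TRUE)]
}
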