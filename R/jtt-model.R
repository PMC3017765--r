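## JTT amino-acid replacement model (Jones, Taylor & Thornton 1992,
## CABIOS 8:275-282), as distributed with PAML (jones.dat): symmetric
## exchangeabilities (lower triangle, column-major) and equilibrium
## frequencies, amino acids in the order ARNDCQEGHILKMFPSTWYV.

#' Amino-acid alphabet used throughout (PAML model order)
#' @export
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.jtt_exch <- c(
  58, 54, 81, 56, 57, 105, 179, 27, 36, 30, 35, 54, 15, 194, 378, 475, 9,
  11, 298, 45, 16, 113, 310, 29, 137, 328, 22, 38, 646, 44, 5, 74, 101, 64,
  126, 20, 17, 528, 34, 86, 58, 81, 391, 47, 12, 263, 30, 10, 15, 503, 232,
  8, 70, 16, 10, 49, 767, 130, 112, 11, 7, 26, 15, 4, 15, 59, 38, 4, 46,
  31, 9, 5, 59, 69, 17, 23, 7, 31, 78, 14, 223, 42, 115, 209, 62, 323, 26,
  597, 9, 72, 292, 43, 4, 164, 53, 51, 18, 24, 20, 119, 26, 12, 9, 181, 18,
  5, 18, 30, 32, 10, 7, 45, 23, 6, 6, 27, 14, 5, 24, 201, 33, 55, 8, 47,
  16, 56, 45, 33, 40, 115, 73, 46, 8, 573, 11, 229, 21, 479, 89, 10, 40,
  245, 9, 32, 961, 14, 388, 248, 102, 59, 25, 52, 24, 180, 65, 4, 21, 47,
  103, 10, 8, 14, 43, 16, 29, 226, 24, 18, 323, 17, 92, 12, 53, 536, 62,
  285, 118, 6, 10, 23, 477, 35, 63, 38, 12, 21, 112, 71, 25, 16)

.jtt_freq <- c(
  0.07674792325, 0.05169094831, 0.04264495736, 0.05154394846, 0.01980298020,
  0.04075195925, 0.06182993817, 0.07315192685, 0.02294397706, 0.05376094624,
  0.09190390810, 0.05867594132, 0.02382597617, 0.04012595987, 0.05090094910,
  0.06876493124, 0.05856494144, 0.01426098574, 0.03210196790, 0.06600493400)

.famarch_cache <- new.env(parent = emptyenv())

#' JTT equilibrium amino-acid frequencies
#'
#' @return named numeric vector of length 20 (order [AA_ORDER]), summing to 1.
#' @export
jttEquilibrium <- function() stats::setNames(.jtt_freq, AA_ORDER)

#' JTT instantaneous rate matrix
#'
#' The generator Q of the JTT model, Q\[i,j\] = s\[i,j\] * pi\[j\] off the
#' diagonal, rows summing to zero, scaled so the expected substitution rate at
#' equilibrium is 1 per site per unit time.
#'
#' @return 20 x 20 matrix with [AA_ORDER] dimnames.
#' @export
jttRateMatrix <- function() {
  if (!is.null(.famarch_cache$Q)) return(.famarch_cache$Q)
  S <- matrix(0, 20L, 20L, dimnames = list(AA_ORDER, AA_ORDER))
  S[lower.tri(S)] <- .jtt_exch
  S <- S + t(S)
  Q <- S * rep(.jtt_freq, each = 20L)
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(.jtt_freq * -diag(Q))   # one expected substitution per unit t
  .famarch_cache$Q <- Q
  Q
}

## Eigendecomposition of Q via the symmetrised B = D^(1/2) Q D^(-1/2),
## cached; P(t) = D^(-1/2) U exp(L t) U' D^(1/2).
.jttEigen <- function() {
  if (!is.null(.famarch_cache$eig)) return(.famarch_cache$eig)
  Q <- jttRateMatrix()
  sp <- sqrt(.jtt_freq)
  B <- Q * outer(sp, 1 / sp)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  .famarch_cache$eig <- list(
    values = e$values,
    left = e$vectors * (1 / sp),        # D^(-1/2) U  (row scaling)
    right = t(e$vectors * sp)           # U' D^(1/2)
  )
  .famarch_cache$eig
}

#' JTT transition probability matrix P(t)
#'
#' @param t evolutionary time in expected substitutions per site (>= 0).
#' @return 20 x 20 stochastic matrix; `P[i, j]` is the probability that amino
#'   acid i is observed as j after time t.
#' @export
jttProbMatrix <- function(t) {
  stopifnot(is.numeric(t), length(t) == 1L, t >= 0)
  e <- .jttEigen()
  P <- e$left %*% (exp(e$values * t) * e$right)
  P[P < 0] <- 0
  dimnames(P) <- list(AA_ORDER, AA_ORDER)
  P
}

## -- sequence simulation under JTT ------------------------------------------

## integer-coded ancestral sequence drawn from equilibrium
.jttRootSeq <- function(L) {
  sample.int(20L, L, replace = TRUE, prob = .jtt_freq)
}

## evolve integer-coded sequence for time t
.jttEvolve <- function(seq_int, t) {
  if (t <= 0) return(seq_int)
  P <- jttProbMatrix(t)
  cum <- t(apply(P, 1L, cumsum))
  u <- runif(length(seq_int))
  out <- integer(length(seq_int))
  for (a in unique(seq_int)) {
    idx <- which(seq_int == a)
    out[idx] <- findInterval(u[idx], cum[a, ]) + 1L
  }
  out
}

#' Simulate a pair of protein sequences at JTT divergence t
#'
#' Draws an ancestor from the JTT equilibrium and evolves one copy for time
#' `t` (equivalently, two copies for t/2). Used to validate distance recovery.
#'
#' @param t divergence in expected substitutions per site.
#' @param L sequence length.
#' @return list with character strings `a` and `b`.
#' @export
simulateProteinPair <- function(t, L) {
  root <- .jttRootSeq(L)
  desc <- .jttEvolve(root, t)
  list(a = paste(AA_ORDER[root], collapse = ""),
       b = paste(AA_ORDER[desc], collapse = ""))
}

#' Simulate an indel-free protein alignment along a tree
#'
#' Evolves a root sequence drawn from JTT equilibrium along `tree` (branch
#' lengths in expected substitutions per site). Without indels the true
#' alignment is the ungapped stack of tip sequences.
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @param L sequence length.
#' @return a [ProteinAlignment-class] with one row per tip.
#' @export
simulateProteins <- function(tree, L) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- .jttRootSeq(L)
  eo <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(eo$edge))) {
    par <- eo$edge[k, 1L]; chi <- eo$edge[k, 2L]
    seqs[[chi]] <- .jttEvolve(seqs[[par]], eo$edge.length[k])
  }
  rows <- vapply(seq_len(ntip),
                 function(i) paste(AA_ORDER[seqs[[i]]], collapse = ""), "")
  ProteinAlignment(tree$tip.label, rows)
}
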