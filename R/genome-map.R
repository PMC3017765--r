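## Chromosomal organisation: tandem cluster detection, concordance with
## phylogenetic clades, and cross-species microsynteny event inference.

#' Read a gene locus table
#'
#' Accepts a TSV with columns gene_id, chrom, start, end, strand and
#' optionally in_family (logical; default `TRUE`) and ortholog_group, or a
#' BED file (0-based half-open; converted to 1-based closed on input, name
#' column = gene_id).
#'
#' @param path file path; format picked by extension (`.bed` vs TSV).
#' @return data.frame of loci (coordinates 1-based closed).
#' @export
readLoci <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    df <- data.frame(gene_id = bed[[4L]], chrom = bed[[1L]],
                     start = bed[[2L]] + 1L, end = bed[[3L]],
                     strand = if (ncol(bed) >= 6L) bed[[6L]] else "+",
                     in_family = TRUE, stringsAsFactors = FALSE)
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE)
    if (!"in_family" %in% names(df)) df$in_family <- TRUE
    df$in_family <- as.logical(df$in_family)
  }
  stopifnot(all(df$start <= df$end))
  df
}

#' Write loci as BED (0-based half-open)
#'
#' @param loci data.frame as from [readLoci()].
#' @param path output path.
#' @export
writeLociBED <- function(loci, path) {
  bed <- data.frame(loci$chrom, loci$start - 1L, loci$end, loci$gene_id,
                    0L, loci$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Detect tandem clusters of family genes
#'
#' Two family loci are chained into one cluster when they lie on the same
#' chromosome and either at most `maxInterlopers` non-family genes lie
#' between them (used whenever the locus table carries non-family
#' annotation) or, in the absence of such annotation, their genomic gap is at
#' most `maxGapBP`. Clusters are maximal chains of two or more family genes.
#'
#' @param loci data.frame with gene_id, chrom, start, end, strand, in_family.
#' @param maxInterlopers maximum non-family genes between cluster neighbours
#'   (default 1, matching observed clusters harbouring one unrelated gene).
#' @param maxGapBP fallback chaining distance in bp (default 1e5).
#' @param chromLengths optional named vector of chromosome lengths; when
#'   given, each cluster is annotated with the relative distance of its
#'   midpoint to the nearer chromosome end (0 = at an end, 0.5 = centre).
#' @return data.frame with chrom, start, end, n_members, orientation_pattern,
#'   n_interlopers, a list column `members` (gene ids in positional order)
#'   and, when `chromLengths` is given, end_proximity.
#' @export
detectClusters <- function(loci, maxInterlopers = 1L, maxGapBP = 1e5,
                           chromLengths = NULL) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand",
                  "in_family") %in% names(loci)))
  hasAnnotation <- any(!loci$in_family)
  res <- list()
  for (ch in unique(loci$chrom[loci$in_family])) {
    sub <- loci[loci$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start, sub$gene_id), , drop = FALSE]
    fam <- which(sub$in_family)
    if (length(fam) < 2L) next
    link <- vapply(seq_len(length(fam) - 1L), function(k) {
      i <- fam[k]; j <- fam[k + 1L]
      if (hasAnnotation) {
        idx <- seq(i, j)
        between <- sum(!sub$in_family[idx] &
                         sub$start[idx] > sub$end[i] &
                         sub$end[idx] < sub$start[j])
        between <= maxInterlopers
      } else {
        (sub$start[j] - sub$end[i]) <= maxGapBP
      }
    }, TRUE)
    runs <- split(fam, cumsum(c(TRUE, !link)))
    for (run in runs) {
      if (length(run) < 2L) next
      mem <- sub[run, , drop = FALSE]
      span <- c(min(mem$start), max(mem$end))
      inter <- sum(!sub$in_family & sub$start >= span[1L] &
                     sub$end <= span[2L])
      cl <- list(chrom = ch, start = span[1L], end = span[2L],
                 n_members = nrow(mem),
                 orientation_pattern = paste(mem$strand, collapse = ""),
                 n_interlopers = inter, members = mem$gene_id)
      if (!is.null(chromLengths)) {
        L <- chromLengths[[ch]]
        mid <- mean(span)
        cl$end_proximity <- min(mid, L - mid) / L
      }
      res[[length(res) + 1L]] <- cl
    }
  }
  if (!length(res)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_members = integer(),
                      orientation_pattern = character(),
                      n_interlopers = integer())
    out$members <- list()
    return(out)
  }
  out <- data.frame(
    chrom = vapply(res, `[[`, "", "chrom"),
    start = vapply(res, function(x) as.integer(x$start), 0L),
    end = vapply(res, function(x) as.integer(x$end), 0L),
    n_members = vapply(res, `[[`, 0L, "n_members"),
    orientation_pattern = vapply(res, `[[`, "", "orientation_pattern"),
    n_interlopers = vapply(res, function(x) as.integer(x$n_interlopers), 0L),
    stringsAsFactors = FALSE)
  if (!is.null(chromLengths))
    out$end_proximity <- vapply(res, `[[`, 0, "end_proximity")
  out$members <- lapply(res, `[[`, "members")
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Concordance between chromosomal clusters and supported clades
#'
#' A cluster is concordant when all its members fall inside a single flagged
#' clade.
#'
#' @param clusters data.frame from [detectClusters()].
#' @param clades list of leaf sets from [flagSupportedClades()].
#' @return list with per-cluster logical `concordant` and counts
#'   `n_concordant` / `n_total`.
#' @export
clusterTreeConcordance <- function(clusters, clades) {
  conc <- vapply(clusters$members, function(mem) {
    any(vapply(clades, function(cl) all(mem %in% cl), TRUE))
  }, TRUE)
  list(concordant = conc, n_concordant = sum(conc),
       n_total = length(conc))
}

#' Read an ortholog map
#'
#' TSV with columns ortholog_group, gene_id, chrom, start, end, strand.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readOrthologMap <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("ortholog_group", "gene_id", "chrom")
  if (!all(need %in% names(df)))
    stop("ortholog map needs columns: ", paste(need, collapse = ", "))
  df
}

#' Infer microsynteny events between two species
#'
#' Compares per-ortholog-group copy numbers and the partition of shared
#' groups over chromosomes. Copy-number increases in B are duplications,
#' decreases losses; a chromosome of A whose groups land on two or more
#' chromosomes of B is a split; two or more chromosomes of A merging onto one
#' chromosome of B is a fusion; an A chromosome whose group set maps
#' bijectively (same groups, same copy numbers) onto a single B chromosome is
#' conserved. The comparison is a direct partition contrast, not a minimal
#' rearrangement solver; splits of B relative to A are fusions of A relative
#' to B by construction.
#'
#' @param mapA,mapB ortholog maps (data.frames as from [readOrthologMap()]):
#'   species A is the reference.
#' @return data.frame with columns kind (duplication, loss, split, fusion or
#'   conserved), groups (comma-joined ortholog groups) and detail.
#' @export
compareSynteny <- function(mapA, mapB) {
  if (nrow(mapA) == 0L || nrow(mapB) == 0L) stop("empty ortholog map")
  events <- list()
  add <- function(kind, groups, detail)
    events[[length(events) + 1L]] <<- data.frame(
      kind = kind, groups = paste(sort(unique(groups)), collapse = ","),
      detail = detail, stringsAsFactors = FALSE)

  cnA <- table(mapA$ortholog_group)
  cnB <- table(mapB$ortholog_group)
  shared <- intersect(names(cnA), names(cnB))
  for (g in sort(union(names(cnA), names(cnB)))) {
    a <- if (g %in% names(cnA)) cnA[[g]] else 0L
    b <- if (g %in% names(cnB)) cnB[[g]] else 0L
    if (b > a) add("duplication", g,
                   sprintf("%s: %d copies in A, %d in B", g, a, b))
    if (b < a) add("loss", g,
                   sprintf("%s: %d copies in A, %d in B", g, a, b))
  }

  sA <- mapA[mapA$ortholog_group %in% shared, , drop = FALSE]
  sB <- mapB[mapB$ortholog_group %in% shared, , drop = FALSE]
  chromOfB <- function(g) unique(sB$chrom[sB$ortholog_group == g])
  chromOfA <- function(g) unique(sA$chrom[sA$ortholog_group == g])

  for (ch in sort(unique(sA$chrom))) {
    ga <- sort(unique(sA$ortholog_group[sA$chrom == ch]))
    if (length(ga) < 2L) next   # one group cannot witness a separation
    bchroms <- sort(unique(unlist(lapply(ga, chromOfB))))
    if (length(bchroms) >= 2L) {
      parts <- vapply(bchroms, function(bc) {
        paste0("{", paste(sort(ga[vapply(ga, function(g)
          bc %in% chromOfB(g), TRUE)]), collapse = ","), "}")
      }, "")
      add("split", ga, sprintf("%s of A separates into %s in B",
                               ch, paste(parts, collapse = " + ")))
    }
  }
  for (ch in sort(unique(sB$chrom))) {
    gb <- sort(unique(sB$ortholog_group[sB$chrom == ch]))
    if (length(gb) < 2L) next
    achroms <- sort(unique(unlist(lapply(gb, chromOfA))))
    if (length(achroms) >= 2L) {
      add("fusion", gb,
          sprintf("chromosomes %s of A fuse onto %s in B",
                  paste(achroms, collapse = "+"), ch))
    }
  }
  # conserved: A chromosome <-> single B chromosome, same groups and copies
  for (ch in sort(unique(sA$chrom))) {
    ga <- sort(unique(sA$ortholog_group[sA$chrom == ch]))
    bchroms <- unique(unlist(lapply(ga, chromOfB)))
    if (length(bchroms) != 1L) next
    gb <- sort(unique(sB$ortholog_group[sB$chrom == bchroms]))
    if (!identical(ga, gb)) next
    if (!all(cnA[ga] == cnB[ga])) next
    add("conserved", ga, sprintf("%s of A corresponds to %s of B",
                                 ch, bchroms))
  }
  if (!length(events))
    return(data.frame(kind = character(), groups = character(),
                      detail = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}

#' Two-species toy ortholog maps for a neuroligin-like locus
#'
#' A small worked example shaped like the insect neuroligin (Nlg-1..5)
#' comparison: species A keeps Nlg-1/3/4/5 together with Nlg-2 alone, while
#' species B duplicated Nlg-4, separated Nlg-5 from the Nlg-1/3/4 segment and
#' fused it with the Nlg-2 segment. [compareSynteny()] on these maps yields
#' exactly one duplication, one split and one fusion.
#'
#' @return list with data.frames `A` and `B`.
#' @export
syntenyToyMaps <- function() {
  A <- data.frame(
    ortholog_group = c("Nlg1", "Nlg3", "Nlg4", "Nlg5", "Nlg2"),
    gene_id = c("A_nlg1", "A_nlg3", "A_nlg4", "A_nlg5", "A_nlg2"),
    chrom = c("chr_a1", "chr_a1", "chr_a1", "chr_a1", "chr_a2"),
    start = c(100L, 300L, 500L, 700L, 100L),
    end = c(200L, 400L, 600L, 800L, 200L),
    strand = c("+", "+", "+", "+", "+"), stringsAsFactors = FALSE)
  B <- data.frame(
    ortholog_group = c("Nlg3", "Nlg1", "Nlg4", "Nlg4", "Nlg2", "Nlg5"),
    gene_id = c("B_nlg3", "B_nlg1", "B_nlg4a", "B_nlg4b", "B_nlg2",
                "B_nlg5"),
    chrom = c("chr_b1", "chr_b1", "chr_b1", "chr_b1", "chr_b2", "chr_b2"),
    start = c(100L, 300L, 500L, 700L, 100L, 300L),
    end = c(200L, 400L, 600L, 800L, 200L, 400L),
    strand = c("+", "+", "+", "+", "+", "-"), stringsAsFactors = FALSE)
  list(A = A, B = B)
}
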