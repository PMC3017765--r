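## End-to-end orchestration: genome/GFF3 -> introns -> alignment ->
## {intron architecture, phylogeny} -> clusters -> EST -> synteny, with
## per-stage TSV/JSON outputs and a consolidated deterministic report.

#' Read and validate a pipeline run configuration
#'
#' The config is a YAML or JSON mapping (or an R list) with input paths
#' (`genome`, `gff3`; optional `alignment`, `est`, `loci`, `ortholog_a`,
#' `ortholog_b`), an `out_dir`, and optional `params` overriding
#' tolerance_nt (3), min_members (2), bootstrap (500), seed, threshold (50),
#' max_interlopers (1), max_gap_bp (1e5), refine (TRUE), collapse (TRUE).
#' Referenced files must exist; a seed is required when bootstrapping.
#'
#' @param config path to a YAML/JSON file, or a list.
#' @return validated config list.
#' @export
readRunConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)   # YAML is a JSON superset
  }
  stopifnot(is.list(config))
  for (key in c("genome", "gff3")) {
    if (is.null(config[[key]])) stop("config is missing '", key, "'")
    if (!file.exists(config[[key]]))
      stop("config ", key, " file not found: ", config[[key]])
  }
  for (key in c("alignment", "est", "loci", "ortholog_a", "ortholog_b")) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]]))
      stop("config ", key, " file not found: ", config[[key]])
  }
  if (is.null(config$out_dir)) stop("config is missing 'out_dir'")
  defaults <- list(tolerance_nt = 3L, min_members = 2L, bootstrap = 500L,
                   seed = NULL, threshold = 50, max_interlopers = 1L,
                   max_gap_bp = 1e5, refine = TRUE, collapse = TRUE)
  p <- config$params
  if (is.null(p)) p <- list()
  for (k in names(defaults)) if (is.null(p[[k]])) p[[k]] <- defaults[[k]]
  if (p$bootstrap > 0L && is.null(p$seed))
    stop("a seed is required when bootstrap replicates are requested")
  config$params <- p
  config
}

.writeTSV <- function(df, path) {
  flat <- df
  for (col in names(flat)) if (is.list(flat[[col]]))
    flat[[col]] <- vapply(flat[[col]], paste, "", collapse = ",")
  write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full gene-family analysis pipeline
#'
#' Executes genome/GFF3 loading, intron extraction, alignment (read from
#' `alignment` when given, else the built-in progressive aligner), intron
#' projection and conserved-site detection, distance phylogeny with
#' bootstrap, cluster detection, EST tabulation and (when two ortholog maps
#' are given) microsynteny inference. Per-stage tables and a consolidated
#' `report.json` are written under `out_dir`; the report is a pure function
#' of inputs and parameters (no timestamps), so same-seed reruns are
#' byte-identical.
#'
#' @param config a config list or YAML/JSON path (see [readRunConfig()]).
#' @return the report list, invisibly.
#' @export
runPipeline <- function(config) {
  cfg <- readRunConfig(config)
  p <- cfg$params
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(cfg$out_dir, "run.log")
  logLine <- function(...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
    cat(msg, "\n", file = logFile, append = TRUE, sep = "")
    message(msg)
  }
  nWarnings <- 0L
  stage <- function(name, expr) {
    logLine("stage ", name)
    tryCatch(withCallingHandlers(expr, warning = function(w) {
      nWarnings <<- nWarnings + 1L
      logLine("  warning [", name, "]: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    }), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  cat("", file = logFile)
  logLine("famarch ", as.character(utils::packageVersion("famarch")),
          " | seed ", if (is.null(p$seed)) "none" else p$seed)
  logLine("params: ", paste(names(p), vapply(p, function(x)
    paste(format(x), collapse = ","), ""), sep = "=", collapse = " "))

  genome <- stage("genome_io", readGenome(cfg$genome))
  models <- stage("gene_models",
                  readGeneModels(cfg$gff3, genome, collapse = p$collapse))
  introns <- stage("introns", extractIntrons(models, genome))
  writeIntronTable(introns, file.path(cfg$out_dir, "introns.tsv"))

  complete <- Filter(function(m)
    !"incomplete_cds" %in% geneFlags(m), models)
  aln <- stage("alignment", {
    if (!is.null(cfg$alignment)) readAlignedFasta(cfg$alignment)
    else progressiveAlignment(vapply(complete, proteinSeq, ""))
  })
  writeAlignedFasta(aln, file.path(cfg$out_dir, "alignment.fasta"))

  phaseIntrons <- introns[introns$gene_id %in% alignmentIDs(aln), ,
                          drop = FALSE]
  sites <- stage("intron_projection", projectIntrons(phaseIntrons, aln))
  .writeTSV(sites, file.path(cfg$out_dir, "intron_sites.tsv"))
  groups <- stage("conserved_sites",
                  findConservedSites(sites, minMembers = p$min_members,
                                     toleranceNT = p$tolerance_nt))
  .writeTSV(groups, file.path(cfg$out_dir, "conserved_introns.tsv"))
  lstats <- stage("length_stats", intronLengthStats(introns, models))
  shared <- stage("shared_introns",
                  sharedIntronMatrix(groups, alignmentIDs(aln)))

  tree <- NULL; clades <- list()
  if (length(aln) >= 4L && p$bootstrap > 0L) {
    tree <- stage("phylogeny",
                  bootstrapSupport(aln, nReps = p$bootstrap, seed = p$seed,
                                   refine = p$refine))
    ape::write.tree(tree, file.path(cfg$out_dir, "tree.nwk"))
    clades <- stage("supported_clades",
                    flagSupportedClades(tree, threshold = p$threshold))
  }

  clusters <- NULL; concordance <- NULL
  if (!is.null(cfg$loci)) {
    loci <- stage("loci", readLoci(cfg$loci))
    clusters <- stage("clusters",
                      detectClusters(loci, maxInterlopers = p$max_interlopers,
                                     maxGapBP = p$max_gap_bp))
    .writeTSV(clusters, file.path(cfg$out_dir, "clusters.tsv"))
    if (length(clades))
      concordance <- stage("concordance",
                           clusterTreeConcordance(clusters, clades))
  }

  estTab <- NULL; tissue <- NULL
  if (!is.null(cfg$est)) {
    records <- stage("est", readESTTable(cfg$est))
    estTab <- stage("est_tabulate",
                    tabulateEST(records, vapply(models, geneID, "")))
    tissue <- tissueSummary(estTab)
    .writeTSV(tissue, file.path(cfg$out_dir, "tissue_summary.tsv"))
    .writeTSV(cloneFrequencyDistribution(estTab),
              file.path(cfg$out_dir, "clone_frequency.tsv"))
  }

  events <- NULL
  if (!is.null(cfg$ortholog_a) && !is.null(cfg$ortholog_b)) {
    events <- stage("synteny",
                    compareSynteny(readOrthologMap(cfg$ortholog_a),
                                   readOrthologMap(cfg$ortholog_b)))
    .writeTSV(events, file.path(cfg$out_dir, "synteny_events.tsv"))
  }

  report <- list(
    params = p[order(names(p))],
    n_genes = length(models),
    n_introns = nrow(introns),
    n_intronless_genes = lstats$n_intronless_genes,
    mean_intron_length = lstats$mean_length,
    min_intron_length = lstats$min_length,
    max_intron_length = lstats$max_length,
    n_noncanonical_introns = sum(!introns$canonical),
    n_incomplete_models = length(models) - length(complete),
    alignment_columns = nColumns(aln),
    conserved_sites = if (nrow(groups)) lapply(seq_len(min(10L, nrow(groups))),
      function(i) list(canonical_pos = groups$canonical_pos[i],
                       phase = groups$phase[i],
                       n_members = groups$n_members[i])) else list(),
    n_conserved_sites = nrow(groups),
    n_genes_with_top2 = shared$n_genes_with_top_k,
    n_supported_clades = length(clades),
    clusters = if (!is.null(clusters)) nrow(clusters) else NA,
    cluster_concordance = if (!is.null(concordance))
      concordance[c("n_concordant", "n_total")] else NULL,
    est_total_clones = if (!is.null(estTab))
      sum(SummarizedExperiment::assay(estTab)) else NULL,
    top_tissue = if (!is.null(tissue) && nrow(tissue)) tissue$tissue[1L]
      else NULL,
    synteny_events = if (!is.null(events)) as.list(table(events$kind))
      else NULL,
    n_warnings = nWarnings)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  logLine("done")
  invisible(report)
}
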