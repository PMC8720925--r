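#' Read a pipeline configuration file
#'
#' The configuration is a flat YAML mapping; every key can be overridden
#' by the corresponding argument of [runSignalPipeline()] /
#' [runNetworkPipeline()] (and by CLI flags of the
#' `inst/scripts/pvnet-pipeline.R` wrapper).
#'
#' @param path YAML file.
#' @return named list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  cfg
}

.log_line <- function(con, ...) cat(sprintf(...), "\n", sep = "", file = con,
                                    append = TRUE)

.input_checksums <- function(paths) {
  paths <- paths[!vapply(paths, is.null, logical(1))]
  paths <- unlist(paths)
  paths <- paths[file.exists(paths)]
  tools::md5sum(paths)
}

#' Run the signal-detection pipeline
#'
#' Chains the spontaneous-report stages end to end: read the three report
#' tables, deduplicate to one report per case, restrict to primary-suspect
#' drug entries, map preferred terms to system organ classes (when a map
#' is supplied; required for `level = "SOC"`), and scan every event term
#' co-reported with the drug of interest. Writes `signals.tsv` and a
#' `signal_run_log.txt` with row counts, dedup statistics, parameters and
#' input checksums. Outputs are deterministic: the same inputs give
#' byte-identical files.
#'
#' @param config optional list (e.g. from [readPipelineConfig()]) supplying
#'   defaults for the remaining arguments, keyed by their names.
#' @param demoPath,drugPath,reacPath report tables.
#' @param dialect `"tsv"` or `"dollar"`.
#' @param termMapPath PT-to-SOC map TSV, or `NULL`.
#' @param drug drug of interest.
#' @param level `"PT"` or `"SOC"`.
#' @param minA minimum co-report count.
#' @param zeroCell zero-cell policy for [computeRor()].
#' @param roles drug role codes retained before table building.
#' @param outDir output directory.
#' @return invisibly, the signal data.frame.
#' @export
runSignalPipeline <- function(config = list(), demoPath = config$demoPath,
                              drugPath = config$drugPath,
                              reacPath = config$reacPath,
                              dialect = config$dialect %||% "tsv",
                              termMapPath = config$termMapPath,
                              drug = config$drug,
                              level = config$level %||% "PT",
                              minA = config$minA %||% 1L,
                              zeroCell = config$zeroCell %||% "undefined",
                              roles = config$roles %||% "PS",
                              outDir = config$outDir %||% ".") {
  if (is.null(drug)) stop("a drug of interest is required", call. = FALSE)
  if (level == "SOC" && is.null(termMapPath))
    stop("level = 'SOC' requires a term map (missing input: termMapPath)",
         call. = FALSE)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)

  store <- readFaersTables(demoPath, drugPath, reacPath, dialect = dialect)
  n_read <- nrow(reportDemo(store))
  store <- deduplicate(store)
  store <- filterByRole(store, roles)
  if (!is.null(termMapPath)) {
    map <- readTermMap(termMapPath)
    store <- applyTermMap(store, map, onMiss = "keep_unmapped")
  }
  signals <- scanEvents(store, drug, level = level, minA = minA,
                        zeroCell = zeroCell)
  out_path <- file.path(outDir, "signals.tsv")
  writeSignals(signals, out_path)

  log_path <- file.path(outDir, "signal_run_log.txt")
  cat("", file = log_path)
  prov <- provenance(store)
  .log_line(log_path, "pvnet signal pipeline")
  .log_line(log_path, "drug=%s level=%s minA=%d zeroCell=%s roles=%s",
            drug, level, as.integer(minA), zeroCell,
            paste(roles, collapse = ","))
  .log_line(log_path, "reports_read=%d reports_after_dedup=%d reports_after_role_filter=%d",
            n_read, prov$dedup$n_after, nrow(reportDemo(store)))
  .log_line(log_path, "dedup_removed=%d", prov$dedup$n_removed)
  .log_line(log_path, "signals_written=%d signal_positive=%d",
            nrow(signals), sum(signals$is_signal))
  sums <- .input_checksums(list(demoPath, drugPath, reacPath, termMapPath))
  for (i in seq_along(sums))
    .log_line(log_path, "input_md5 %s %s", names(sums)[i], sums[i])
  invisible(signals)
}

#' Run the drug-gene interaction network pipeline
#'
#' Chains the network stages: read the seed drug-gene list and the
#' PSI-MITAB interactome, expand the seeds to their one-hop induced
#' subnetwork, detect molecular complexes with MCODE, and run
#' over-representation analysis of each cluster's members against the
#' pathway (GMT) and disease collections — per-cluster enrichment
#' mirroring cluster-stratified functional profiling. Writes the expansion
#' (`expanded_edges.tsv`, `expanded_nodes.tsv`), `clusters.tsv`, one
#' member list per cluster, `enrichment_pathway.tsv` /
#' `enrichment_disease.tsv` (with a `cluster` column) and
#' `network_run_log.txt`. Deterministic for fixed inputs.
#'
#' @param config optional list of defaults, as in [runSignalPipeline()].
#' @param seedPath seed gene list.
#' @param mitabPath PSI-MITAB interactome.
#' @param taxon optional taxon filter for [readMitab()].
#' @param gmtPath optional GMT pathway collection.
#' @param diseasePath optional disease-gene TSV.
#' @param mcodeParams an [McodeParams-class].
#' @param pCutoff,qCutoff enrichment cutoffs.
#' @param outDir output directory.
#' @return invisibly, a list with `expansion`, `clusters`,
#'   `pathwayEnrichment`, `diseaseEnrichment`.
#' @export
runNetworkPipeline <- function(config = list(), seedPath = config$seedPath,
                               mitabPath = config$mitabPath,
                               taxon = config$taxon,
                               gmtPath = config$gmtPath,
                               diseasePath = config$diseasePath,
                               mcodeParams = pvnet::mcodeParams(),
                               pCutoff = config$pCutoff %||% 0.05,
                               qCutoff = config$qCutoff %||% 0.1,
                               outDir = config$outDir %||% ".") {
  if (is.null(seedPath) || is.null(mitabPath))
    stop("seedPath and mitabPath are required", call. = FALSE)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  log_path <- file.path(outDir, "network_run_log.txt")
  cat("", file = log_path)

  seeds <- readSeedGenes(seedPath)
  interactome <- readMitab(mitabPath, taxon = taxon)
  expansion <- expandSeed(interactome, seeds)
  .log_line(log_path, "pvnet network pipeline")
  .log_line(log_path, "seeds=%d interactome_nodes=%d interactome_edges=%d",
            length(seeds), numNodes(interactome), numEdges(interactome))
  .log_line(log_path, "expansion_nodes=%d expansion_edges=%d missing_seeds=%d",
            numNodes(expansion), numEdges(expansion),
            length(expansion@stats$missing_seeds))
  if (numNodes(expansion) == 0L) {
    .log_line(log_path, "empty expansion; stopping after network stage")
    return(invisible(list(expansion = expansion, clusters = list(),
                          pathwayEnrichment = NULL,
                          diseaseEnrichment = NULL)))
  }
  writeEdgeList(expansion, file.path(outDir, "expanded_edges.tsv"),
                file.path(outDir, "expanded_nodes.tsv"))

  clusters <- mcode(expansion, mcodeParams)
  ct <- clusterTable(clusters)
  .write_tsv(ct, file.path(outDir, "clusters.tsv"))
  .log_line(log_path, "mcode_clusters=%d", length(clusters))
  for (i in seq_along(clusters))
    writeLines(clusters[[i]]@members,
               file.path(outDir, sprintf("cluster_%02d_members.txt", i)))

  run_cluster_enrichment <- function(collection) {
    res <- lapply(seq_along(clusters), function(i) {
      r <- enrich(clusters[[i]]@members, collection, pCutoff = pCutoff,
                  qCutoff = qCutoff)
      if (nrow(r)) cbind(cluster = i, r) else NULL
    })
    res <- res[!vapply(res, is.null, logical(1))]
    if (!length(res)) return(cbind(cluster = integer(0),
                                   .empty_enrich_frame()))
    do.call(rbind, res)
  }

  path_enr <- dis_enr <- NULL
  if (!is.null(gmtPath)) {
    path_enr <- run_cluster_enrichment(readGmt(gmtPath))
    writeEnrichment(path_enr, file.path(outDir, "enrichment_pathway.tsv"))
    .log_line(log_path, "pathway_terms_reported=%d significant=%d",
              nrow(path_enr), sum(path_enr$significant))
  }
  if (!is.null(diseasePath)) {
    dis_enr <- run_cluster_enrichment(readDiseaseTsv(diseasePath))
    writeEnrichment(dis_enr, file.path(outDir, "enrichment_disease.tsv"))
    .log_line(log_path, "disease_terms_reported=%d significant=%d",
              nrow(dis_enr), sum(dis_enr$significant))
  }
  sums <- .input_checksums(list(seedPath, mitabPath, gmtPath, diseasePath))
  for (i in seq_along(sums))
    .log_line(log_path, "input_md5 %s %s", names(sums)[i], sums[i])

  invisible(list(expansion = expansion, clusters = clusters,
                 pathwayEnrichment = path_enr, diseaseEnrichment = dis_enr))
}
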