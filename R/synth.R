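# Evaluate code under a temporary RNG state seeded once; the caller's
# .Random.seed is restored afterwards, so generators never leak global
# RNG state.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Simulate spontaneous adverse-event reports
#'
#' Generates a spontaneous-report database with known ground truth. Each
#' report exposes each drug independently with its `exposure_prob`; each
#' event occurs with probability `odds / (1 + odds)` where
#' `odds = baseline_odds * prod(odds_ratio)` over the injected drug-event
#' associations whose drug is exposed in that report — so the injected
#' `odds_ratio` is exactly the estimand the reporting odds ratio targets
#' (for rare events, ROR ~ OR up to rare-event bias). One uniformly chosen
#' exposed drug per report is marked primary suspect (`PS`), the rest
#' concomitant (`C`); reports with no exposed drug carry no drug rows and
#' are later excluded by the PS role filter, mirroring real suspect-drug
#' restricted analyses. A configurable fraction of cases is additionally
#' emitted as an earlier case version, giving [deduplicate()] planted
#' duplicates to remove.
#'
#' Defaults correspond to the simulation conditions used throughout the
#' package's validation: 20,000 reports, five drugs at 5 percent exposure, six
#' preferred terms across two system organ classes at baseline odds 0.01,
#' one injected association of odds ratio 10, and a 20 percent duplicate
#' fraction.
#'
#' @param nReports number of distinct cases.
#' @param drugs data.frame with columns `name`, `exposure_prob`.
#' @param events data.frame with columns `pt`, `soc`, `baseline_odds`.
#' @param injected data.frame with columns `drug`, `pt`, `odds_ratio`
#'   (may have zero rows for a null simulation).
#' @param dupFrac fraction of cases also emitted as an earlier version.
#' @param seed integer seed; output is bit-reproducible given the
#'   configuration and seed.
#' @param dir when non-`NULL`, the store is written there in the
#'   tab-separated dialect (`demo.tsv`, `drug.tsv`, `reac.tsv`) together
#'   with `term_map.tsv` and a `truth.tsv` sidecar.
#' @return list with components `store` (a [ReportStore-class] including
#'   the planted duplicate versions), `truth` (data.frame per case:
#'   `report_key`, `case_id`, `ps_drug`, one logical `exposed.<drug>` and
#'   `event.<pt>` column per drug/PT), `termMap` (named vector), and
#'   `paths` when `dir` was given.
#' @export
simulateReports <- function(nReports = 20000L,
                            drugs = data.frame(
                              name = c("montelukast", paste0("comparator_",
                                                             letters[1:4])),
                              exposure_prob = rep(0.05, 5)),
                            events = data.frame(
                              pt = c("suicidal ideation", "depression",
                                     "nightmare", "headache", "nausea",
                                     "cough"),
                              soc = c("psychiatric disorders",
                                      "psychiatric disorders",
                                      "psychiatric disorders",
                                      "nervous system disorders",
                                      "gastrointestinal disorders",
                                      "respiratory disorders"),
                              baseline_odds = rep(0.01, 6)),
                            injected = data.frame(
                              drug = "montelukast", pt = "suicidal ideation",
                              odds_ratio = 10),
                            dupFrac = 0.2, seed = 1L, dir = NULL) {
  stopifnot(nReports >= 1, all(drugs$exposure_prob > 0),
            all(drugs$exposure_prob < 1), all(events$baseline_odds > 0),
            dupFrac >= 0, dupFrac < 1)
  if (nrow(injected) && (!all(injected$drug %in% drugs$name) ||
                         !all(injected$pt %in% events$pt)))
    stop("injected pairs must reference configured drugs and events",
         call. = FALSE)
  stopifnot(all(injected$odds_ratio > 0))
  drugs$name <- normalizeDrugName(drugs$name)

  .with_seed(seed, {
    n <- as.integer(nReports)
    nd <- nrow(drugs); ne <- nrow(events)
    exposed <- matrix(stats::runif(n * nd) <
                        rep(drugs$exposure_prob, each = n), n, nd)
    colnames(exposed) <- drugs$name

    log_odds <- matrix(rep(log(events$baseline_odds), each = n), n, ne)
    if (nrow(injected)) {
      for (i in seq_len(nrow(injected))) {
        di <- match(normalizeDrugName(injected$drug[i]), drugs$name)
        ei <- match(injected$pt[i], events$pt)
        log_odds[exposed[, di], ei] <-
          log_odds[exposed[, di], ei] + log(injected$odds_ratio[i])
      }
    }
    odds <- exp(log_odds)
    occurred <- matrix(stats::runif(n * ne) < odds / (1 + odds), n, ne)
    colnames(occurred) <- events$pt

    n_exposed <- rowSums(exposed)
    ps_idx <- rep(NA_integer_, n)
    some <- which(n_exposed > 0)
    ps_pick <- stats::runif(length(some))
    for (j in seq_along(some)) {
      i <- some[j]
      idx <- which(exposed[i, ])
      ps_idx[i] <- idx[[ceiling(ps_pick[j] * length(idx))]]
    }

    case_id <- sprintf("C%07d", seq_len(n))
    report_key <- sprintf("P%07d", seq_len(n))

    drug_rows <- which(exposed, arr.ind = TRUE)
    drug_df <- data.frame(
      report_key = report_key[drug_rows[, 1]],
      drug_name = drugs$name[drug_rows[, 2]],
      role = ifelse(ps_idx[drug_rows[, 1]] == drug_rows[, 2], "PS", "C"),
      stringsAsFactors = FALSE)

    ev_rows <- which(occurred, arr.ind = TRUE)
    event_df <- data.frame(
      report_key = report_key[ev_rows[, 1]],
      pt = events$pt[ev_rows[, 2]],
      soc = NA_character_, stringsAsFactors = FALSE)

    demo <- data.frame(report_key = report_key, case_id = case_id,
                       version_rank = 2, stringsAsFactors = FALSE)

    # Planted duplicates: re-emit an earlier version (rank 1) of the first
    # ceil(dupFrac * n) cases under a distinct report key.
    n_dup <- floor(dupFrac * n)
    if (n_dup > 0) {
      dup_cases <- sample.int(n, n_dup)
      dup_keys <- sprintf("P%07dV1", dup_cases)
      demo <- rbind(demo, data.frame(report_key = dup_keys,
                                     case_id = case_id[dup_cases],
                                     version_rank = 1,
                                     stringsAsFactors = FALSE))
      remap <- stats::setNames(dup_keys, report_key[dup_cases])
      dd <- drug_df[drug_df$report_key %in% names(remap), , drop = FALSE]
      if (nrow(dd)) dd$report_key <- unname(remap[dd$report_key])
      de <- event_df[event_df$report_key %in% names(remap), , drop = FALSE]
      if (nrow(de)) de$report_key <- unname(remap[de$report_key])
      drug_df <- rbind(drug_df, dd)
      event_df <- rbind(event_df, de)
    }

    ord_d <- order(drug_df$report_key, drug_df$drug_name, method = "radix")
    drug_df <- drug_df[ord_d, , drop = FALSE]
    ord_e <- order(event_df$report_key, event_df$pt, method = "radix")
    event_df <- event_df[ord_e, , drop = FALSE]
    ord_demo <- order(demo$report_key, method = "radix")
    demo <- demo[ord_demo, , drop = FALSE]
    rownames(demo) <- rownames(drug_df) <- rownames(event_df) <- NULL

    store <- new("ReportStore", demo = demo, drugs = drug_df,
                 events = event_df,
                 provenance = list(source = "simulateReports", seed = seed,
                                   n_cases = n, n_planted_duplicates = n_dup))

    truth <- data.frame(report_key = report_key, case_id = case_id,
                        ps_drug = ifelse(is.na(ps_idx), NA_character_,
                                         drugs$name[ps_idx]),
                        stringsAsFactors = FALSE)
    for (j in seq_len(nd))
      truth[[paste0("exposed.", drugs$name[j])]] <- exposed[, j]
    for (j in seq_len(ne))
      truth[[paste0("event.", events$pt[j])]] <- occurred[, j]

    term_map <- stats::setNames(as.character(events$soc), events$pt)

    out <- list(store = store, truth = truth, termMap = term_map)
    if (!is.null(dir)) {
      paths <- writeReportTables(store, dir)
      tm_path <- file.path(dir, "term_map.tsv")
      .write_tsv(data.frame(pt = names(term_map), soc = unname(term_map)),
                 tm_path)
      truth_path <- file.path(dir, "truth.tsv")
      .write_tsv(truth, truth_path)
      out$paths <- c(paths, term_map = tm_path, truth = truth_path)
    }
    out
  })
}

#' Simulate a planted-partition interactome
#'
#' Generates an undirected planted-partition graph over synthetic gene
#' symbols `GENE0001`, `GENE0002`, ...: the first `sum(moduleSizes)`
#' symbols are partitioned into dense modules whose internal vertex pairs
#' are edged independently with probability `pIn`; every other pair
#' (background-background, background-module and cross-module) is edged
#' with probability `pOut`. The first `seedGenesPerModule` members of each
#' module are designated seed genes. Defaults are the conditions used for
#' the package's module-recovery validation: two modules of 12 over 100
#' background nodes, `pIn = 0.9`, `pOut = 0.02`.
#'
#' @param nBackground number of background nodes.
#' @param moduleSizes integer vector of planted module sizes.
#' @param pIn,pOut within-module and background/cross edge probabilities
#'   (`0 <= pOut < pIn <= 1`).
#' @param seedGenesPerModule how many members per module to write as seeds.
#' @param seed integer seed.
#' @param dir when non-`NULL`, writes `interactome.mitab` (minimal
#'   PSI-MITAB with `taxid:9606`), `seed_genes.txt` and `modules.tsv`
#'   (gene, module) there.
#' @return list with `network` (a [GeneNetwork-class]), `seeds` (character),
#'   `modules` (list of member vectors, the ground truth), `nEdges`
#'   (internal tally for round-trip checks) and `paths` when `dir` given.
#' @export
simulatePpi <- function(nBackground = 100L, moduleSizes = c(12L, 12L),
                        pIn = 0.9, pOut = 0.02, seedGenesPerModule = 2L,
                        seed = 1L, dir = NULL) {
  stopifnot(pOut >= 0, pOut < pIn, pIn <= 1, nBackground >= 0,
            all(moduleSizes >= 1), seedGenesPerModule >= 1,
            all(seedGenesPerModule <= moduleSizes))
  n <- as.integer(nBackground + sum(moduleSizes))
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  genes <- sprintf("GENE%04d", seq_len(n))
  module_of <- rep(0L, n)
  offset <- 0L
  modules <- list()
  for (m in seq_along(moduleSizes)) {
    idx <- offset + seq_len(moduleSizes[m])
    module_of[idx] <- m
    modules[[m]] <- genes[idx]
    offset <- offset + moduleSizes[m]
  }

  .with_seed(seed, {
    pair <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    same <- module_of[pair[, 1]] != 0L &
      module_of[pair[, 1]] == module_of[pair[, 2]]
    p <- ifelse(same, pIn, pOut)
    keep <- stats::runif(nrow(pair)) < p
    edges <- data.frame(from = genes[pair[keep, 1]],
                        to = genes[pair[keep, 2]],
                        n_records = 1L, stringsAsFactors = FALSE)
    network <- .make_gene_network(edges, nodes = genes,
                                  stats = list(source = "simulatePpi",
                                               seed = seed))
    seeds <- unlist(lapply(modules, utils::head, seedGenesPerModule))

    out <- list(network = network, seeds = seeds, modules = modules,
                nEdges = nrow(edges))
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      mitab_path <- file.path(dir, "interactome.mitab")
      writeMitab(network, mitab_path)
      seed_path <- file.path(dir, "seed_genes.txt")
      writeLines(seeds, seed_path)
      mod_path <- file.path(dir, "modules.tsv")
      .write_tsv(data.frame(gene = genes, module = module_of), mod_path)
      out$paths <- c(mitab = mitab_path, seeds = seed_path,
                     modules = mod_path)
    }
    out
  })
}

#' Simulate gene-set collections aligned with planted modules
#'
#' Builds one "planted" gene set per module — its members plus 10 percent random
#' decoy genes — and `nNoiseSets` uniform random sets over all gene names,
#' emitted both as a GMT pathway collection and as a disease-gene TSV
#' collection (same sets, disease-style identifiers), so that enrichment
#' of a recovered module against either collection should rank the
#' module's planted set first.
#'
#' @param modules list of module member vectors (the `modules` component of
#'   [simulatePpi()]).
#' @param allGenes character vector of the full gene inventory to draw
#'   decoys and noise sets from.
#' @param nNoiseSets number of random noise sets (default 20).
#' @param noiseSetSize size of each noise set (default 15).
#' @param seed integer seed.
#' @param dir when non-`NULL`, writes `pathways.gmt` and `diseases.tsv`.
#' @return list with `pathways` and `diseases`
#'   ([GeneSetCollection-class]s), `plantedIds` (term ids of the planted
#'   sets, in module order) and `paths` when `dir` given.
#' @export
simulateGenesets <- function(modules, allGenes, nNoiseSets = 20L,
                             noiseSetSize = 15L, seed = 1L, dir = NULL) {
  stopifnot(length(modules) >= 1, length(allGenes) >= 2, nNoiseSets >= 0)
  allGenes <- toupper(allGenes)
  .with_seed(seed, {
    planted <- lapply(seq_along(modules), function(m) {
      mem <- toupper(modules[[m]])
      n_decoy <- ceiling(0.1 * length(mem))
      pool <- setdiff(allGenes, mem)
      decoys <- sample(pool, min(n_decoy, length(pool)))
      sort(unique(c(mem, decoys)))
    })
    planted_ids <- sprintf("PLANTED_M%02d", seq_along(modules))
    noise <- lapply(seq_len(nNoiseSets), function(i)
      sort(sample(allGenes, min(noiseSetSize, length(allGenes)))))
    noise_ids <- if (nNoiseSets > 0) sprintf("NOISE_%03d", seq_len(nNoiseSets))
                 else character(0)

    sets <- c(planted, noise)
    names(sets) <- c(planted_ids, noise_ids)
    term_names <- c(sprintf("planted module %d set", seq_along(modules)),
                    if (nNoiseSets > 0) sprintf("noise set %d",
                                                seq_len(nNoiseSets)))
    pathways <- new("GeneSetCollection", sets = sets,
                    termNames = term_names, kind = "pathway")
    diseases <- new("GeneSetCollection", sets = sets,
                    termNames = term_names, kind = "disease")

    out <- list(pathways = pathways, diseases = diseases,
                plantedIds = planted_ids)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      gmt_path <- file.path(dir, "pathways.gmt")
      writeLines(vapply(seq_along(sets), function(i)
        paste(c(names(sets)[i], term_names[i], sets[[i]]), collapse = "\t"),
        character(1)), gmt_path)
      dis_path <- file.path(dir, "diseases.tsv")
      dis_rows <- do.call(rbind, lapply(seq_along(sets), function(i)
        data.frame(disease_id = names(sets)[i], disease_name = term_names[i],
                   gene = sets[[i]], stringsAsFactors = FALSE)))
      .write_tsv(dis_rows, dis_path)
      out$paths <- c(gmt = gmt_path, diseases = dis_path)
    }
    out
  })
}
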