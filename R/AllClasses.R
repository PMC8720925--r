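#' @import methods
NULL

VALID_ROLES <- c("PS", "SS", "C", "I")

#' ReportStore: a normalized store of spontaneous adverse-event reports
#'
#' Container for case reports parsed from FAERS-dialect tables. Each report
#' is identified by a `report_key` (one per submitted case version) and a
#' `case_id` (one per patient case); the drug and event tables reference
#' reports by `report_key`.
#'
#' @slot demo data.frame with columns `report_key`, `case_id`,
#'   `version_rank` (numeric, higher = later case version).
#' @slot drugs data.frame with columns `report_key`, `drug_name`
#'   (normalized: case-folded, trimmed, internal whitespace collapsed) and
#'   `role`, one of `"PS"`, `"SS"`, `"C"`, `"I"`.
#' @slot events data.frame with columns `report_key`, `pt` (preferred term)
#'   and `soc` (system organ class, `NA` until a term map is applied).
#' @slot provenance list of source file names, row counts and
#'   deduplication statistics; maintained by the ingest and transform
#'   functions.
#'
#' @seealso [readFaersTables()], [deduplicate()], [filterByRole()],
#'   [applyTermMap()]
#' @export
setClass("ReportStore",
  representation(
    demo = "data.frame",
    drugs = "data.frame",
    events = "data.frame",
    provenance = "list"
  ),
  prototype(
    demo = data.frame(report_key = character(), case_id = character(),
                      version_rank = numeric(), stringsAsFactors = FALSE),
    drugs = data.frame(report_key = character(), drug_name = character(),
                       role = character(), stringsAsFactors = FALSE),
    events = data.frame(report_key = character(), pt = character(),
                        soc = character(), stringsAsFactors = FALSE),
    provenance = list()
  )
)

setValidity("ReportStore", function(object) {
  msg <- character()
  need <- function(df, cols, nm) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) sprintf("%s lacks column(s): %s", nm,
                              paste(miss, collapse = ", "))
  }
  msg <- c(msg,
           need(object@demo, c("report_key", "case_id", "version_rank"), "demo"),
           need(object@drugs, c("report_key", "drug_name", "role"), "drugs"),
           need(object@events, c("report_key", "pt", "soc"), "events"))
  if (length(msg)) return(msg)
  if (anyDuplicated(object@demo$report_key))
    msg <- c(msg, "duplicated report_key in demo")
  if (!all(object@drugs$report_key %in% object@demo$report_key))
    msg <- c(msg, "drug rows reference unknown report_key")
  if (!all(object@events$report_key %in% object@demo$report_key))
    msg <- c(msg, "event rows reference unknown report_key")
  if (nrow(object@drugs) && !all(object@drugs$role %in% VALID_ROLES))
    msg <- c(msg, sprintf("invalid drug role code(s): %s",
                          paste(unique(setdiff(object@drugs$role, VALID_ROLES)),
                                collapse = ", ")))
  if (nrow(object@drugs) && any(!nzchar(object@drugs$drug_name)))
    msg <- c(msg, "empty drug_name")
  if (nrow(object@events) && any(!nzchar(object@events$pt)))
    msg <- c(msg, "empty preferred term")
  if (length(msg)) msg else TRUE
})

#' ContingencyTable: 2x2 drug-event report counts
#'
#' The four cells of the standard pharmacovigilance two-by-two table:
#' `a` = reports with the target drug and the target event, `b` = drug
#' without event, `c` = event without drug, `d` = neither. Each
#' deduplicated report contributes to exactly one cell.
#'
#' @slot a,b,c,d non-negative integer counts.
#' @seealso [buildTable()], [computeRor()]
#' @export
setClass("ContingencyTable",
  representation(a = "integer", b = "integer", c = "integer", d = "integer"))

setValidity("ContingencyTable", function(object) {
  cells <- c(a = object@a, b = object@b, c = object@c, d = object@d)
  if (length(cells) != 4L || anyNA(cells)) return("all four cells required")
  if (any(cells < 0L)) return("negative cell count")
  TRUE
})

#' SignalResult: reporting odds ratio with confidence interval and signal flag
#'
#' @slot drug,event target drug and event term (may be empty strings when the
#'   table was supplied directly).
#' @slot level `"PT"` or `"SOC"`.
#' @slot table the [ContingencyTable-class] the statistic was computed from.
#' @slot ror point estimate `a*d/(b*c)`; `NA` when undefined (a zero cell
#'   under the `"undefined"` policy).
#' @slot ciLow,ciHigh Wald confidence limits on the log-odds scale;
#'   `NA` when undefined.
#' @slot z normal quantile used for the interval (default 1.959964, the
#'   97.5 percent point, i.e. a 95 percent interval).
#' @slot corrected TRUE when the Haldane-Anscombe 0.5 continuity correction
#'   was applied to all cells before estimation.
#' @slot isSignal TRUE iff the CI lower bound exceeds 1 and the observed
#'   (uncorrected) co-report count `a` is at least 2.
#' @seealso [computeRor()], [scanEvents()]
#' @export
setClass("SignalResult",
  representation(drug = "character", event = "character", level = "character",
                 table = "ContingencyTable", ror = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", z = "numeric",
                 corrected = "logical", isSignal = "logical"))

setValidity("SignalResult", function(object) {
  if (!object@level %in% c("PT", "SOC", "")) return("level must be PT or SOC")
  if (!is.na(object@ror) && !is.na(object@ciLow) && !is.na(object@ciHigh)) {
    if (object@ciLow > object@ror + 1e-12 || object@ror > object@ciHigh + 1e-12)
      return("confidence interval does not bracket the point estimate")
  }
  TRUE
})

#' GeneNetwork: a simple undirected gene-gene interaction network
#'
#' Thin S4 wrapper around an [igraph][igraph::igraph-package] graph. The
#' graph is always simple (no self-loops, no parallel edges) and undirected;
#' vertex names are uppercased gene symbols. Collapsed parallel source
#' records are retained as the `n_records` edge attribute. Subsetting
#' provenance (dropped-row counts, seeds missing from the interactome) lives
#' in the `stats` slot.
#'
#' @slot graph an igraph object.
#' @slot stats list of ingest / expansion statistics.
#' @seealso [readMitab()], [expandSeed()], [networkNodes()], [networkEdges()]
#' @export
setClass("GeneNetwork", representation(graph = "ANY", stats = "list"))

setValidity("GeneNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph slot must be an igraph object")
  if (igraph::is_directed(g)) return("graph must be undirected")
  if (!igraph::is_simple(g)) return("graph must be simple (no loops/multi-edges)")
  if (igraph::vcount(g) > 0 && is.null(igraph::V(g)$name))
    return("vertices must be named")
  TRUE
})

#' GeneSetCollection: named gene sets for over-representation analysis
#'
#' @slot sets named list (term id -> character vector of uppercased gene
#'   symbols); every set is non-empty and duplicate-free.
#' @slot termNames character vector of human-readable term names, parallel
#'   to `sets`.
#' @slot kind `"pathway"` (GMT-style) or `"disease"` (disease-gene TSV).
#' @seealso [readGmt()], [readDiseaseTsv()], [enrich()]
#' @export
setClass("GeneSetCollection",
  representation(sets = "list", termNames = "character", kind = "character"))

setValidity("GeneSetCollection", function(object) {
  if (!object@kind %in% c("pathway", "disease"))
    return("kind must be 'pathway' or 'disease'")
  if (length(object@sets) == 0L) return("collection is empty")
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    return("sets must be uniquely named by term id")
  if (length(object@termNames) != length(object@sets))
    return("termNames must parallel sets")
  if (any(!vapply(object@sets, length, 1L)))
    return("every gene set must be non-empty")
  TRUE
})

#' McodeParams: parameters of the MCODE complex-detection algorithm
#'
#' Defaults follow the Cytoscape plug-in's documented defaults and the
#' parameterization commonly used for drug-gene interaction networks:
#' degree cutoff 2, node score cutoff 0.2, k-core 2, maximum BFS depth from
#' the seed vertex 100, haircut on, fluff off.
#'
#' @slot degreeCutoff minimum vertex degree for a non-zero weight.
#' @slot nodeScoreCutoff admission band: a neighbour u joins a growing
#'   complex iff `weight(u) >= weight(seed) * (1 - nodeScoreCutoff)`.
#' @slot kCore discard candidate complexes whose induced subgraph has no
#'   k-core with k at least this value.
#' @slot maxDepth BFS depth bound from the seed vertex.
#' @slot haircut iteratively remove degree-<2 vertices from each complex.
#' @slot fluff add unvisited neighbours whose closed-neighbourhood density
#'   exceeds `fluffDensityCutoff` (fluffed vertices may appear in several
#'   complexes).
#' @slot fluffDensityCutoff density threshold for fluff.
#' @seealso [mcodeParams()], [predictComplexes()]
#' @export
setClass("McodeParams",
  representation(degreeCutoff = "integer", nodeScoreCutoff = "numeric",
                 kCore = "integer", maxDepth = "integer", haircut = "logical",
                 fluff = "logical", fluffDensityCutoff = "numeric"))

setValidity("McodeParams", function(object) {
  if (object@degreeCutoff < 0L) return("degreeCutoff must be >= 0")
  if (object@maxDepth < 0L) return("maxDepth must be >= 0")
  if (object@nodeScoreCutoff < 0 || object@nodeScoreCutoff > 1)
    return("nodeScoreCutoff must be in [0, 1]")
  if (object@fluffDensityCutoff < 0 || object@fluffDensityCutoff > 1)
    return("fluffDensityCutoff must be in [0, 1]")
  TRUE
})

#' @rdname McodeParams-class
#' @param degreeCutoff,nodeScoreCutoff,kCore,maxDepth,haircut,fluff,fluffDensityCutoff
#'   see the corresponding slots.
#' @return an `McodeParams` object.
#' @examples
#' mcodeParams()
#' mcodeParams(nodeScoreCutoff = 0.1, haircut = FALSE)
#' @export
mcodeParams <- function(degreeCutoff = 2L, nodeScoreCutoff = 0.2,
                        kCore = 2L, maxDepth = 100L, haircut = TRUE,
                        fluff = FALSE, fluffDensityCutoff = 0.2) {
  new("McodeParams",
      degreeCutoff = as.integer(degreeCutoff),
      nodeScoreCutoff = as.numeric(nodeScoreCutoff),
      kCore = as.integer(kCore),
      maxDepth = as.integer(maxDepth),
      haircut = isTRUE(haircut),
      fluff = isTRUE(fluff),
      fluffDensityCutoff = as.numeric(fluffDensityCutoff))
}

#' McodeCluster: one predicted molecular complex
#'
#' @slot members sorted character vector of member gene symbols (>= 2).
#' @slot seed the seed vertex the complex was grown from.
#' @slot score complex score: density of the induced subgraph times the
#'   number of members, with density `2E / (n (n - 1))`.
#' @slot nEdges edge count of the induced subgraph.
#' @seealso [predictComplexes()], [clusterTable()]
#' @export
setClass("McodeCluster",
  representation(members = "character", seed = "character",
                 score = "numeric", nEdges = "integer"))

setValidity("McodeCluster", function(object) {
  n <- length(object@members)
  if (n < 2L) return("a complex has at least 2 members")
  if (object@score <= 0 || object@score > n)
    return("score must lie in (0, n]")
  TRUE
})

# ---- show methods -----------------------------------------------------------

setMethod("show", "ReportStore", function(object) {
  cat(sprintf("ReportStore: %d reports (%d distinct cases), %d drug rows, %d event rows\n",
              nrow(object@demo), length(unique(object@demo$case_id)),
              nrow(object@drugs), nrow(object@events)))
  if (!is.null(object@provenance$dedup))
    cat(sprintf("  deduplicated: %d -> %d reports\n",
                object@provenance$dedup$n_before,
                object@provenance$dedup$n_after))
  invisible(NULL)
})

setMethod("show", "ContingencyTable", function(object) {
  m <- matrix(c(object@a, object@b, object@c, object@d), 2, 2, byrow = TRUE,
              dimnames = list(c("drug+", "drug-"), c("event+", "event-")))
  cat("2x2 contingency table (reports)\n")
  print(m)
  invisible(NULL)
})

setMethod("show", "SignalResult", function(object) {
  lab <- if (nzchar(object@drug)) sprintf("%s / %s [%s]", object@drug,
                                          object@event, object@level) else "(table)"
  if (is.na(object@ror)) {
    cat(sprintf("SignalResult %s: ROR undefined (zero cell), signal = FALSE\n", lab))
  } else {
    cat(sprintf("SignalResult %s: ROR = %.3g (%.3g-%.3g)%s, signal = %s\n",
                lab, object@ror, object@ciLow, object@ciHigh,
                if (object@corrected) " [0.5-corrected]" else "",
                object@isSignal))
  }
  invisible(NULL)
})

setMethod("show", "GeneNetwork", function(object) {
  cat(sprintf("GeneNetwork: %d nodes, %d edges\n",
              igraph::vcount(object@graph), igraph::ecount(object@graph)))
  if (length(object@stats$missing_seeds))
    cat(sprintf("  %d seed(s) absent from the interactome\n",
                length(object@stats$missing_seeds)))
  invisible(NULL)
})

setMethod("show", "GeneSetCollection", function(object) {
  cat(sprintf("GeneSetCollection (%s): %d sets, sizes %d-%d\n", object@kind,
              length(object@sets),
              min(lengths(object@sets)), max(lengths(object@sets))))
  invisible(NULL)
})

setMethod("show", "McodeCluster", function(object) {
  cat(sprintf("McodeCluster (seed %s): %d members, %d edges, score %.3f\n",
              object@seed, length(object@members), object@nEdges, object@score))
  invisible(NULL)
})

setMethod("show", "McodeParams", function(object) {
  cat(sprintf(paste0("McodeParams: degreeCutoff=%d nodeScoreCutoff=%.2f ",
                     "kCore=%d maxDepth=%d haircut=%s fluff=%s\n"),
              object@degreeCutoff, object@nodeScoreCutoff, object@kCore,
              object@maxDepth, object@haircut, object@fluff))
  invisible(NULL)
})
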