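#' @importFrom igraph graph_from_data_frame induced_subgraph V E vcount
#'   ecount degree neighbors coreness is_igraph is_directed is_simple
#'   make_empty_graph edge_density as_edgelist
NULL

.as_igraph <- function(x) {
  if (is(x, "GeneNetwork")) return(x@graph)
  if (igraph::is_igraph(x)) return(x)
  stop("expected a GeneNetwork or igraph object", call. = FALSE)
}

# Build a GeneNetwork from an edge data.frame (from, to, n_records),
# collapsing duplicate unordered pairs and dropping self-loops.
.make_gene_network <- function(edges, nodes = NULL, stats = list()) {
  if (nrow(edges)) {
    self <- edges$from == edges$to
    stats$n_self_loops <- sum(self) + (stats$n_self_loops %||% 0L)
    edges <- edges[!self, , drop = FALSE]
  }
  if (nrow(edges)) {
    lo <- pmin(edges$from, edges$to)
    hi <- pmax(edges$from, edges$to)
    key <- paste(lo, hi, sep = "\r")
    n_rec <- tapply(edges$n_records, key, sum)
    first <- !duplicated(key)
    stats$n_duplicate_pairs <- sum(!first) + (stats$n_duplicate_pairs %||% 0L)
    edges <- data.frame(from = lo[first], to = hi[first],
                        n_records = as.integer(n_rec[key[first]]),
                        stringsAsFactors = FALSE)
  }
  all_nodes <- sort(unique(c(nodes, edges$from, edges$to)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = all_nodes)
  new("GeneNetwork", graph = g, stats = stats)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a seed drug-gene list
#'
#' One gene symbol per line or comma-separated; `#` starts a comment.
#' Symbols are uppercased, trimmed and deduplicated. The package ships the
#' 26-symbol montelukast seed list as
#' `system.file("extdata", "montelukast_seed_genes.txt", package = "pvnet")`.
#'
#' @param path plain-text file of gene symbols.
#' @return character vector of unique, uppercased symbols, with the source
#'   path attached as attribute `"source"`.
#' @export
readSeedGenes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  symbols <- unlist(strsplit(lines, "[,[:space:]]+"))
  symbols <- toupper(trimws(symbols))
  symbols <- unique(symbols[nzchar(symbols)])
  if (!length(symbols))
    stop("no gene symbols found in ", path, call. = FALSE)
  structure(symbols, source = path)
}

# Resolve a gene symbol from MITAB alias / identifier fields: entries are
# |-separated db:value pairs; hgnc entries are preferred, then any other
# prefixed value. "-" denotes a missing field.
.resolve_symbol <- function(alias, alt, uid) {
  for (field in c(alias, alt, uid)) {
    if (is.na(field) || field == "-" || !nzchar(field)) next
    entries <- strsplit(field, "|", fixed = TRUE)[[1L]]
    vals <- sub("^[^:]*:", "", entries)
    vals <- sub("\\(.*\\)$", "", vals)
    vals <- trimws(vals)
    hgnc <- grepl("^hgnc:", entries)
    cand <- c(vals[hgnc], vals[!hgnc])
    cand <- cand[nzchar(cand) & cand != "-"]
    if (length(cand)) return(toupper(gsub("[[:space:]]+", "", cand[[1L]])))
  }
  NA_character_
}

#' Read a PSI-MITAB interactome into a GeneNetwork
#'
#' Parses a tab-separated PSI-MITAB 2.5/2.6 file (such as the iRefIndex
#' `9606.mitab` release) into a simple undirected gene-symbol network.
#' Symbols are taken from the alias columns (5/6), with fallback to the
#' alternative-identifier (3/4) and unique-identifier (1/2) columns,
#' stripped of their database prefixes; taxon identifiers are read from
#' columns 10/11. Self-interactions are dropped, repeated pairs collapsed
#' (the per-edge `n_records` attribute counts source records), and rows
#' whose interactors fail the taxon filter or carry no resolvable symbol
#' are dropped and counted.
#'
#' @param path MITAB file; a leading `#` header line is skipped.
#' @param taxon optional taxon filter such as `"taxid:9606"`; rows where
#'   either interactor's taxon does not start with this string are dropped.
#' @return a [GeneNetwork-class]; drop counts are in its `stats`.
#' @seealso [expandSeed()], [writeMitab()]
#' @export
readMitab <- function(path, taxon = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) && startsWith(lines[[1L]], "#")) lines <- lines[-1L]
  if (!length(lines)) stop("no interaction rows in ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)

  short <- lengths(parts) < 15L
  n_short <- sum(short)
  parts <- parts[!short]
  if (!length(parts))
    stop("no row of ", path, " has the 15 required MITAB columns",
         call. = FALSE)

  n_taxon_dropped <- 0L
  from <- character(length(parts)); to <- character(length(parts))
  ok <- logical(length(parts))
  n_unresolved <- 0L
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (!is.null(taxon) &&
        !(startsWith(p[[10L]], taxon) && startsWith(p[[11L]], taxon))) {
      n_taxon_dropped <- n_taxon_dropped + 1L
      next
    }
    s1 <- .resolve_symbol(p[[5L]], p[[3L]], p[[1L]])
    s2 <- .resolve_symbol(p[[6L]], p[[4L]], p[[2L]])
    if (is.na(s1) || is.na(s2)) {
      n_unresolved <- n_unresolved + 1L
      next
    }
    from[i] <- s1; to[i] <- s2; ok[i] <- TRUE
  }
  edges <- data.frame(from = from[ok], to = to[ok],
                      n_records = rep(1L, sum(ok)), stringsAsFactors = FALSE)
  .make_gene_network(edges, stats = list(
    file = path, n_rows = length(lines), n_short_rows = n_short,
    n_taxon_dropped = n_taxon_dropped, n_unresolved = n_unresolved))
}

#' Write a GeneNetwork as minimal PSI-MITAB
#'
#' Emits one 15-column MITAB row per collapsed edge (duplicated
#' `n_records` times so that re-reading reproduces the provenance counts),
#' with `hgnc:` symbol identifiers and `taxid:9606` taxon fields.
#' Re-reading with [readMitab()] reproduces the identical node and edge
#' sets.
#'
#' @param network a [GeneNetwork-class].
#' @param path output file.
#' @param taxon taxon string written to columns 10/11.
#' @return invisibly, `path`.
#' @export
writeMitab <- function(network, path, taxon = "taxid:9606(Homo sapiens)") {
  g <- .as_igraph(network)
  el <- igraph::as_edgelist(g)
  n_rec <- igraph::E(g)$n_records %||% rep(1L, nrow(el))
  if (is.null(igraph::E(g)$n_records)) n_rec <- rep(1L, nrow(el))
  rows <- character(0)
  if (nrow(el)) {
    base <- vapply(seq_len(nrow(el)), function(i) {
      a <- el[i, 1]; b <- el[i, 2]
      paste(c(paste0("hgnc:", a), paste0("hgnc:", b), "-", "-",
              paste0("hgnc:", a), paste0("hgnc:", b),
              "psi-mi:\"MI:0045\"(experimental)", "-", "-",
              taxon, taxon, "psi-mi:\"MI:0915\"(physical association)",
              "psi-mi:\"MI:0000\"(unspecified)", "-", "-"),
            collapse = "\t")
    }, character(1))
    rows <- rep(base, times = pmax(n_rec, 1L))
  }
  writeLines(c("#uidA\tuidB\taltA\taltB\taliasA\taliasB\tmethod\tauthor\tpmids\ttaxa\ttaxb\tinteractionType\tsourcedb\tinteractionIdentifier\tconfidence",
               rows), path)
  invisible(path)
}

#' One-hop seed-gene neighbourhood expansion
#'
#' Returns the subgraph of the interactome induced on the union of the
#' closed neighbourhoods of the seed genes: the seeds present in the
#' interactome plus every direct interactor, with *all* interactome edges
#' between those nodes (including neighbour-neighbour edges). Seeds present
#' but isolated within the selection are retained; seeds absent from the
#' interactome are reported in the result's `stats$missing_seeds`, not
#' added as nodes. This one-hop reading of "directly or indirectly
#' interacting" genes keeps the expansion at the sub-network scale;
#' transitive closure would engulf the interactome's giant component.
#'
#' @param network a [GeneNetwork-class] interactome.
#' @param seeds character vector of seed gene symbols (uppercased
#'   internally), e.g. from [readSeedGenes()].
#' @return a [GeneNetwork-class]; vertices carry a logical `is_seed`
#'   attribute.
#' @rdname expandSeed
#' @export
setMethod("expandSeed", "GeneNetwork", function(network, seeds) {
  seeds <- unique(toupper(trimws(as.character(seeds))))
  g <- network@graph
  present <- intersect(seeds, igraph::V(g)$name)
  missing <- setdiff(seeds, present)
  if (!length(present)) {
    empty <- .make_gene_network(
      data.frame(from = character(), to = character(),
                 n_records = integer(), stringsAsFactors = FALSE),
      stats = list(missing_seeds = missing, seeds = character()))
    warning("none of the ", length(seeds),
            " seed genes are present in the interactome", call. = FALSE)
    return(empty)
  }
  nb <- unique(unlist(lapply(present, function(s)
    igraph::V(g)$name[igraph::neighbors(g, s)])))
  keep <- sort(unique(c(present, nb)))
  sub <- igraph::induced_subgraph(g, keep)
  igraph::V(sub)$is_seed <- igraph::V(sub)$name %in% present
  new("GeneNetwork", graph = sub,
      stats = list(missing_seeds = missing, seeds = present,
                   n_seed_nodes = length(present),
                   n_neighbour_nodes = length(keep) - length(present)))
})

#' @rdname network-accessors
#' @export
setMethod("networkNodes", "GeneNetwork", function(x)
  sort(igraph::V(x@graph)$name))

#' @rdname network-accessors
#' @export
setMethod("networkEdges", "GeneNetwork", function(x) {
  el <- igraph::as_edgelist(x@graph)
  n_rec <- if (igraph::ecount(x@graph))
    igraph::E(x@graph)$n_records %||% rep(1L, nrow(el)) else integer(0)
  df <- data.frame(gene_a = pmin(el[, 1], el[, 2]),
                   gene_b = pmax(el[, 1], el[, 2]),
                   n_records = as.integer(n_rec), stringsAsFactors = FALSE)
  df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
  rownames(df) <- NULL
  df
})

#' @rdname network-accessors
#' @export
setMethod("numNodes", "GeneNetwork", function(x) igraph::vcount(x@graph))

#' @rdname network-accessors
#' @export
setMethod("numEdges", "GeneNetwork", function(x) igraph::ecount(x@graph))

#' Write an expansion as edge-list and node TSVs
#'
#' @param network a [GeneNetwork-class], typically from [expandSeed()].
#' @param edgePath edge list TSV (`gene_a`, `gene_b`, `n_records`).
#' @param nodePath node TSV (`gene`, `is_seed`); omitted when `NULL`.
#' @return invisibly, the path(s) written.
#' @export
writeEdgeList <- function(network, edgePath, nodePath = NULL) {
  .write_tsv(networkEdges(network), edgePath)
  if (!is.null(nodePath)) {
    g <- network@graph
    is_seed <- igraph::V(g)$is_seed
    if (is.null(is_seed)) is_seed <- rep(FALSE, igraph::vcount(g))
    nodes <- data.frame(gene = igraph::V(g)$name, is_seed = is_seed,
                        stringsAsFactors = FALSE)
    nodes <- nodes[order(nodes$gene), , drop = FALSE]
    .write_tsv(nodes, nodePath)
    return(invisible(c(edgePath, nodePath)))
  }
  invisible(edgePath)
}
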