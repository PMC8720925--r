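#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated as
#' `term_id TAB description TAB gene TAB gene ...`. Gene symbols are
#' uppercased and duplicates within a line collapsed.
#'
#' @param path GMT file.
#' @return a [GeneSetCollection-class] of kind `"pathway"`.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stop(sprintf("GMT line %d has fewer than 3 fields", short[[1L]]),
         call. = FALSE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicated term id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  sets <- lapply(parts, function(p)
    unique(toupper(trimws(p[-(1:2)][nzchar(p[-(1:2)])]))))
  names(sets) <- ids
  new("GeneSetCollection", sets = sets,
      termNames = vapply(parts, `[[`, character(1), 2L), kind = "pathway")
}

#' Read a disease-gene TSV as a gene-set collection
#'
#' A 3-column tab-separated file with header `disease_id`, `disease_name`,
#' `gene` (one gene association per row), emulating a DisGeNET-style
#' resource; rows sharing a `disease_id` are gathered into one set.
#'
#' @param path TSV file.
#' @return a [GeneSetCollection-class] of kind `"disease"`.
#' @export
readDiseaseTsv <- function(path) {
  raw <- .read_raw_table(path, "\t")
  .require_cols(raw$table, c("disease_id", "disease_name", "gene"),
                "disease", path)
  tab <- raw$table
  tab <- tab[nzchar(tab$gene) & nzchar(tab$disease_id), , drop = FALSE]
  if (!nrow(tab)) stop("no disease-gene rows in ", path, call. = FALSE)
  tab$gene <- toupper(tab$gene)
  ids <- unique(tab$disease_id)
  sets <- lapply(ids, function(id) unique(tab$gene[tab$disease_id == id]))
  names(sets) <- ids
  nm <- tab$disease_name[match(ids, tab$disease_id)]
  new("GeneSetCollection", sets = sets, termNames = nm, kind = "disease")
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` marked items when `n` items are drawn without
#' replacement from a universe of `N` items of which `K` are marked. This
#' is the over-representation p-value of an observed overlap of size `k`
#' between a query of size `n` and a gene set of size `K`. Computed in a
#' numerically stable way via the log-space survival function.
#'
#' @param k observed overlap (0 <= k <= min(n, K)).
#' @param K gene-set size within the universe.
#' @param n query size within the universe.
#' @param N universe size.
#' @return probability in (0, 1]; `k = 0` gives exactly 1.
#' @examples
#' hypergeomUpper(5, 5, 5, 20)   # 1 / choose(20, 5)
#' @export
hypergeomUpper <- function(k, K, n, N) {
  if (any(is.na(c(k, K, n, N)))) stop("NA argument", call. = FALSE)
  if (K < 0 || K > N || n < 0 || n > N || k < 0 || k > min(n, K))
    stop("hypergeometric bounds violated: need 0 <= K <= N, 0 <= n <= N, ",
         "0 <= k <= min(n, K)", call. = FALSE)
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic BH: sort ascending, multiply the i-th smallest p by `m/i`,
#' enforce monotonicity from the largest down, cap at 1, and return in the
#' input order. Input values must lie in (0, 1].
#'
#' @param pvals numeric vector of p-values.
#' @return adjusted p-values, same length and order.
#' @export
bhAdjust <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (anyNA(pvals) || any(pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

# Storey pi0 estimate with the smoother over a lambda grid; conservative
# fallback to 1 for tiny inputs.
.storey_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  m <- length(p)
  if (m < 10L) return(1)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  min(max(pi0, 1e-8), 1)
}

#' Hypergeometric over-representation analysis
#'
#' Tests a query gene list against every set of a collection with the
#' hypergeometric upper-tail probability, adjusting across *all* tested
#' terms by Benjamini-Hochberg. The universe defaults to the union of the
#' collection's genes (the behaviour of common enrichment tools when no
#' background is supplied) and can be overridden. The query is intersected
#' with the universe first; genes outside the universe cannot be enriched
#' and are discarded with a warning when the whole query falls outside.
#'
#' Terms are reported when at least one query gene overlaps; a term is
#' flagged `significant` when `p <= pCutoff` and `q <= qCutoff`. By
#' default the q-value equals the BH-adjusted p (Storey's estimator with
#' `pi0 = 1`); `qMethod = "storey"` rescales by a smoothed pi0 estimate.
#'
#' @param query character vector of gene symbols (uppercased internally).
#' @param collection a [GeneSetCollection-class].
#' @param universe optional character vector overriding the background.
#' @param pCutoff,qCutoff significance cutoffs (defaults 0.05 and 0.1).
#' @param qMethod `"bh"` (default) or `"storey"`.
#' @return data.frame sorted by ascending adjusted p (ties by term id)
#'   with columns `term_id`, `term_name`, `k`, `n`, `K`, `N`,
#'   `gene_ratio` (k/n), `bg_ratio` (K/N), `p`, `p_adj`, `q`,
#'   `significant`, `gene_hits` (comma-separated); the attribute
#'   `"n_query_in_universe"` records the intersection size.
#' @export
enrich <- function(query, collection, universe = NULL, pCutoff = 0.05,
                   qCutoff = 0.1, qMethod = c("bh", "storey")) {
  qMethod <- match.arg(qMethod)
  stopifnot(is(collection, "GeneSetCollection"))
  validObject(collection)
  if (!length(query)) stop("empty query gene list", call. = FALSE)
  if (any(c(pCutoff, qCutoff) <= 0) || any(c(pCutoff, qCutoff) > 1))
    stop("cutoffs must lie in (0, 1]", call. = FALSE)
  query <- unique(toupper(trimws(query)))

  sets <- collection@sets
  universe <- if (is.null(universe)) unique(unlist(sets, use.names = FALSE))
              else unique(toupper(trimws(universe)))
  N <- length(universe)
  query_u <- intersect(query, universe)
  n <- length(query_u)
  if (n == 0L) {
    warning("no query gene lies in the universe", call. = FALSE)
    out <- .empty_enrich_frame()
    attr(out, "n_query_in_universe") <- 0L
    return(out)
  }

  sets_u <- lapply(sets, function(s) intersect(s, universe))
  Ks <- lengths(sets_u)
  tested <- which(Ks >= 1L)
  hits <- lapply(sets_u[tested], function(s) sort(intersect(s, query_u)))
  ks <- lengths(hits)
  ps <- vapply(seq_along(tested), function(i)
    hypergeomUpper(ks[[i]], Ks[[tested[i]]], n, N), numeric(1))
  p_adj <- bhAdjust(ps)
  q <- if (qMethod == "storey") pmin(p_adj * .storey_pi0(ps), 1) else p_adj

  keep <- ks >= 1L
  if (!any(keep)) {
    out <- .empty_enrich_frame()
    attr(out, "n_query_in_universe") <- n
    return(out)
  }
  out <- data.frame(
    term_id = names(sets)[tested][keep],
    term_name = collection@termNames[tested][keep],
    k = unname(ks[keep]), n = n, K = unname(Ks[tested][keep]), N = N,
    gene_ratio = unname(ks[keep]) / n,
    bg_ratio = unname(Ks[tested][keep]) / N,
    p = ps[keep], p_adj = p_adj[keep], q = q[keep],
    stringsAsFactors = FALSE)
  out$significant <- out$p <= pCutoff & out$q <= qCutoff
  out$gene_hits <- vapply(hits[keep], paste, character(1), collapse = ",")
  ord <- order(out$p_adj, out$term_id, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_query_in_universe") <- n
  out
}

.empty_enrich_frame <- function() {
  data.frame(term_id = character(), term_name = character(), k = integer(),
             n = integer(), K = integer(), N = integer(),
             gene_ratio = numeric(), bg_ratio = numeric(), p = numeric(),
             p_adj = numeric(), q = numeric(), significant = logical(),
             gene_hits = character(), stringsAsFactors = FALSE)
}

#' Write enrichment results as TSV
#'
#' @param results data.frame from [enrich()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeEnrichment <- function(results, path) {
  out <- results
  for (col in c("gene_ratio", "bg_ratio", "p", "p_adj", "q"))
    out[[col]] <- as.character(signif(out[[col]], 6))
  .write_tsv(out, path)
  invisible(path)
}
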