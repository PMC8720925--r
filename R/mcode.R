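# Loop-free undirected density 2E/(n(n-1)); 0 for n < 2.
.graph_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2L) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

#' k-core subgraph
#'
#' The maximal subgraph in which every vertex has degree at least `k`
#' within the subgraph — the fixed point of iteratively deleting vertices
#' of degree below `k`. Returns an empty network when no such subgraph
#' exists (e.g. any tree for `k = 2`).
#'
#' @param network a [GeneNetwork-class] or igraph object.
#' @param k non-negative integer.
#' @return object of the same kind as the input, restricted to the k-core.
#' @export
kCoreSubgraph <- function(network, k) {
  stopifnot(k >= 0)
  g <- .as_igraph(network)
  core <- igraph::coreness(g)
  sub <- igraph::induced_subgraph(g, which(core >= k))
  if (is(network, "GeneNetwork"))
    new("GeneNetwork", graph = sub, stats = list(k = as.integer(k)))
  else sub
}

# Highest k-core of a graph: largest k with a non-empty k-core, plus that
# core's density. For an edgeless graph kmax = 0 and density 0.
.highest_core <- function(g) {
  core <- igraph::coreness(g)
  kmax <- max(core, 0L)
  sub <- igraph::induced_subgraph(g, which(core >= kmax))
  list(k = kmax, density = .graph_density(sub))
}

#' MCODE vertex weighting
#'
#' For every vertex `v` with degree at least `degreeCutoff`, the induced
#' subgraph on the closed neighbourhood `N[v]` is taken, its highest
#' k-core located (the largest `k` with a non-empty k-core), and the
#' weight set to `k * density` of that core — the "core-clustering
#' coefficient" scaled by the core number, which rewards membership in
#' large dense regions while damping the effect of low-degree satellite
#' vertices. Vertices below the degree cutoff get weight 0. For a
#' complete graph K_n every vertex weight is `n - 1`.
#'
#' @param network a [GeneNetwork-class] or igraph object.
#' @param degreeCutoff minimum degree (default 2).
#' @return named numeric vector of vertex weights.
#' @seealso [predictComplexes()]
#' @export
vertexWeighting <- function(network, degreeCutoff = 2L) {
  g <- .as_igraph(network)
  n <- igraph::vcount(g)
  w <- stats::setNames(numeric(n), igraph::V(g)$name)
  if (n == 0L) return(w)
  deg <- igraph::degree(g)
  for (v in which(deg >= degreeCutoff)) {
    nbhd <- c(v, as.integer(igraph::neighbors(g, v)))
    sub <- igraph::induced_subgraph(g, nbhd)
    hc <- .highest_core(sub)
    w[v] <- hc$k * hc$density
  }
  w
}

#' MCODE complex prediction
#'
#' Implements the molecular-complex detection procedure on a weighted
#' graph. Unvisited vertices are taken in order of decreasing weight
#' (ties: lexicographically smallest vertex name) as seeds; from each seed
#' a candidate complex is grown breadth-first up to `maxDepth`, admitting
#' an unvisited neighbour `u` iff
#' `weight(u) >= weight(seed) * (1 - nodeScoreCutoff)`. Admitted vertices
#' are marked visited (whether or not the candidate survives
#' post-processing). Each candidate is then post-processed: discarded
#' unless its induced subgraph contains a non-empty k-core with
#' `k >= kCore`; haircut iteratively removes vertices of degree < 2
#' within the complex; fluff adds unvisited neighbours whose
#' closed-neighbourhood density exceeds `fluffDensityCutoff` (fluffed
#' vertices may appear in several complexes). Complexes are scored as
#' subgraph density times member count and returned sorted by descending
#' score, ties by smaller seed name — a fully deterministic ordering.
#'
#' @param network a [GeneNetwork-class] or igraph object.
#' @param weights named weight vector from [vertexWeighting()], computed on
#'   the same graph; computed on the fly when `NULL`.
#' @param params an [McodeParams-class] (see [mcodeParams()]).
#' @return list of [McodeCluster-class] objects.
#' @examples
#' g <- igraph::make_full_graph(4)
#' igraph::V(g)$name <- paste0("G", 1:4)
#' predictComplexes(g)
#' @export
predictComplexes <- function(network, weights = NULL, params = mcodeParams()) {
  g <- .as_igraph(network)
  validObject(params)
  n <- igraph::vcount(g)
  if (n == 0L) return(list())
  nm <- igraph::V(g)$name
  if (is.null(weights)) weights <- vertexWeighting(g, params@degreeCutoff)
  if (!identical(sort(names(weights)), sort(nm)))
    stop("weights must be named for exactly the vertices of the network",
         call. = FALSE)
  w <- unname(weights[nm])

  adj <- igraph::as_adj_list(g)
  visited <- logical(n)
  seed_order <- order(-w, nm, method = "radix")
  clusters <- list()

  for (s in seed_order) {
    if (visited[s]) next
    visited[s] <- TRUE
    threshold <- w[s] * (1 - params@nodeScoreCutoff)
    members <- s
    frontier <- s
    depth <- 0L
    while (length(frontier) && depth < params@maxDepth) {
      nxt <- integer(0)
      for (f in frontier) {
        for (u in as.integer(adj[[f]])) {
          if (!visited[u] && w[u] >= threshold) {
            visited[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }

    if (length(members) < 2L) next
    sub <- igraph::induced_subgraph(g, members)
    if (max(igraph::coreness(sub), 0L) < params@kCore) next

    if (params@haircut) {
      repeat {
        dg <- igraph::degree(sub)
        low <- which(dg < 2)
        if (!length(low)) break
        sub <- igraph::induced_subgraph(sub, which(dg >= 2))
      }
      if (igraph::vcount(sub) < 2L) next
    }

    member_names <- igraph::V(sub)$name
    if (params@fluff) {
      cand <- unique(unlist(lapply(match(member_names, nm), function(v)
        as.integer(adj[[v]]))))
      cand <- cand[!visited[cand] & !(nm[cand] %in% member_names)]
      for (u in cand) {
        nbhd <- c(u, as.integer(adj[[u]]))
        dens <- .graph_density(igraph::induced_subgraph(g, nbhd))
        if (dens > params@fluffDensityCutoff)
          member_names <- c(member_names, nm[u])
      }
      sub <- igraph::induced_subgraph(g, member_names)
    }

    nmem <- igraph::vcount(sub)
    score <- .graph_density(sub) * nmem
    if (score <= 0) next
    clusters[[length(clusters) + 1L]] <-
      new("McodeCluster", members = sort(igraph::V(sub)$name),
          seed = nm[s], score = score,
          nEdges = as.integer(igraph::ecount(sub)))
  }

  if (!length(clusters)) return(clusters)
  scores <- vapply(clusters, function(cl) cl@score, numeric(1))
  seeds <- vapply(clusters, function(cl) cl@seed, character(1))
  clusters[order(-scores, seeds, method = "radix")]
}

#' Summarize MCODE clusters as a table
#'
#' @param clusters list of [McodeCluster-class] from [predictComplexes()].
#' @return data.frame with columns `rank`, `score`, `n_nodes`, `n_edges`,
#'   `seed`, `members` (comma-separated, sorted), in deterministic order
#'   (descending score, ties by seed name).
#' @export
clusterTable <- function(clusters) {
  if (!length(clusters)) {
    return(data.frame(rank = integer(), score = numeric(),
                      n_nodes = integer(), n_edges = integer(),
                      seed = character(), members = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    rank = seq_along(clusters),
    score = vapply(clusters, function(cl) cl@score, numeric(1)),
    n_nodes = vapply(clusters, function(cl) length(cl@members), integer(1)),
    n_edges = vapply(clusters, function(cl) cl@nEdges, integer(1)),
    seed = vapply(clusters, function(cl) cl@seed, character(1)),
    members = vapply(clusters, function(cl)
      paste(cl@members, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
}

#' One-shot MCODE: weighting plus complex prediction
#'
#' @inheritParams predictComplexes
#' @return list of [McodeCluster-class] objects.
#' @export
mcode <- function(network, params = mcodeParams()) {
  g <- .as_igraph(network)
  predictComplexes(g, vertexWeighting(g, params@degreeCutoff), params)
}
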