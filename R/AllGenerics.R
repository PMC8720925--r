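#' @rdname deduplicate
#' @export
setGeneric("deduplicate", function(store) standardGeneric("deduplicate"))

#' @rdname filterByRole
#' @export
setGeneric("filterByRole", function(store, roles) standardGeneric("filterByRole"))

#' @rdname applyTermMap
#' @export
setGeneric("applyTermMap",
           function(store, map, onMiss = c("drop", "keep_unmapped", "error"))
             standardGeneric("applyTermMap"))

#' @rdname buildTable
#' @export
setGeneric("buildTable",
           function(store, drug, event, level = c("PT", "SOC"))
             standardGeneric("buildTable"))

#' @rdname scanEvents
#' @export
setGeneric("scanEvents",
           function(store, drug, level = c("PT", "SOC"), minA = 1L,
                    z = 1.959964, zeroCell = c("undefined", "haldane"))
             standardGeneric("scanEvents"))

#' @rdname expandSeed
#' @export
setGeneric("expandSeed", function(network, seeds) standardGeneric("expandSeed"))

#' Network accessors
#'
#' `networkNodes` returns the sorted vertex (gene symbol) names,
#' `networkEdges` a data.frame of unordered edges with their collapsed
#' source-record counts, `numNodes`/`numEdges` the respective counts.
#'
#' @param x a [GeneNetwork-class].
#' @return see description.
#' @name network-accessors
NULL

#' @rdname network-accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname network-accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname network-accessors
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname network-accessors
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' Accessors for report stores
#'
#' Read-only views of the three normalized tables and the provenance of a
#' [ReportStore-class].
#'
#' @param x a `ReportStore`.
#' @return a data.frame (or list for `provenance`).
#' @name reportstore-accessors
NULL

#' @rdname reportstore-accessors
#' @export
setGeneric("reportDemo", function(x) standardGeneric("reportDemo"))

#' @rdname reportstore-accessors
#' @export
setGeneric("reportDrugs", function(x) standardGeneric("reportDrugs"))

#' @rdname reportstore-accessors
#' @export
setGeneric("reportEvents", function(x) standardGeneric("reportEvents"))

#' @rdname reportstore-accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
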