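#' Accessors for CoexpressionNetwork and LCCNullResult
#'
#' @param x a [CoexpressionNetwork-class] or [LCCNullResult-class] object.
#' @return \code{edges()} the edge data.frame; \code{networkName()} the label;
#'   \code{nEdges()} the edge count; \code{networkGenes()} the sorted set of
#'   endpoint genes; \code{edgeKeys()} canonical "geneA|geneB" identity
#'   strings; \code{observedLCC()}, \code{nullPValues()} the null-test
#'   statistics.
#' @name network-accessors
#' @aliases edges networkName nEdges networkGenes edgeKeys observedLCC
#'   nullPValues
#' @examples
#' net <- coexpressionNetwork("a", "b", 1, "toy")
#' networkGenes(net)
NULL

#' @rdname network-accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))
#' @rdname network-accessors
#' @export
setGeneric("networkName", function(x) standardGeneric("networkName"))
#' @rdname network-accessors
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))
#' @rdname network-accessors
#' @export
setGeneric("networkGenes", function(x) standardGeneric("networkGenes"))
#' @rdname network-accessors
#' @export
setGeneric("edgeKeys", function(x) standardGeneric("edgeKeys"))
#' @rdname network-accessors
#' @export
setGeneric("observedLCC", function(x) standardGeneric("observedLCC"))
#' @rdname network-accessors
#' @export
setGeneric("nullPValues", function(x) standardGeneric("nullPValues"))

#' @rdname network-accessors
setMethod("edges", "CoexpressionNetwork", function(x) x@edges)
#' @rdname network-accessors
setMethod("networkName", "CoexpressionNetwork", function(x) x@name)
#' @rdname network-accessors
setMethod("nEdges", "CoexpressionNetwork", function(x) nrow(x@edges))
#' @rdname network-accessors
setMethod("networkGenes", "CoexpressionNetwork", function(x)
  sort(unique(c(x@edges$geneA, x@edges$geneB))))
#' @rdname network-accessors
setMethod("edgeKeys", "CoexpressionNetwork", function(x)
  paste(x@edges$geneA, x@edges$geneB, sep = "|"))

#' @rdname network-accessors
setMethod("observedLCC", "LCCNullResult", function(x) x@observedLCC)
#' @rdname network-accessors
setMethod("nullPValues", "LCCNullResult", function(x)
  c(pGE = x@pGE, pLE = x@pLE))

setMethod("show", "CoexpressionNetwork", function(object) {
  cat(sprintf("CoexpressionNetwork '%s': %d edges over %d genes\n",
              object@name, nrow(object@edges),
              length(networkGenes(object))))
  if (nrow(object@edges)) {
    cat("top edges:\n")
    print(head(object@edges, 3L), row.names = FALSE)
  }
  invisible(NULL)
})

setMethod("show", "LCCNullResult", function(object) {
  cat(sprintf(paste0(
    "LCCNullResult '%s': observed LCC = %d genes (subset of %d edges)\n",
    "  null over %d replicates: mean %.2f, sd %.2f\n",
    "  P(null >= obs) = %.4g, P(null <= obs) = %.4g [add-one]\n"),
    object@networkName, object@observedLCC, object@subsetSize,
    object@nSims, object@nullMean, object@nullSD, object@pGE, object@pLE))
  invisible(NULL)
})
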