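#' @import methods
#' @importFrom stats rnbinom rnorm runif setNames sd phyper p.adjust
#' @importFrom utils read.delim write.table write.csv head combn
#'   packageVersion
#' @useDynLib coexpStrata, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' CoexpressionNetwork: a set of weighted, canonical gene pairs
#'
#' The unit of all network comparisons. Edges are unordered gene pairs stored
#' canonically (\code{geneA < geneB} lexicographically) with a mutual
#' information weight in nats. Edge identity for every set operation in this
#' package is the unordered pair only; weights are carried but never compared.
#'
#' @slot name single character, typically the stratum label (e.g. "FY").
#' @slot edges data.frame with character columns \code{geneA}, \code{geneB}
#'   and numeric \code{mi}; rows are unique canonical pairs, sorted by
#'   decreasing \code{mi} then lexicographic pair order.
#'
#' @seealso [inferNetwork()], [conservedEdges()], [uniqueEdges()]
#' @exportClass CoexpressionNetwork
setClass("CoexpressionNetwork",
  representation(name = "character", edges = "data.frame"),
  prototype(name = "network",
            edges = data.frame(geneA = character(), geneB = character(),
                               mi = numeric(), stringsAsFactors = FALSE)))

setValidity("CoexpressionNetwork", function(object) {
  msg <- character()
  e <- object@edges
  if (length(object@name) != 1L || is.na(object@name))
    msg <- c(msg, "'name' must be a single non-NA character")
  if (!all(c("geneA", "geneB", "mi") %in% colnames(e)))
    msg <- c(msg, "edges must have columns geneA, geneB, mi")
  else {
    if (any(e$geneA == e$geneB))
      msg <- c(msg, "self-pairs are not allowed")
    if (any(e$geneA > e$geneB))
      msg <- c(msg, "edges must be canonical: geneA < geneB")
    key <- paste(e$geneA, e$geneB, sep = "\r")
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate unordered gene pairs")
    if (any(e$mi < 0 | is.na(e$mi)))
      msg <- c(msg, "mi weights must be non-negative and non-missing")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CoexpressionNetwork from gene pairs
#'
#' Pairs are canonicalised (endpoints swapped so \code{geneA < geneB}),
#' de-duplicated (keeping the largest weight for a repeated pair) and sorted
#' by decreasing weight, then pair order.
#'
#' @param geneA,geneB character vectors of endpoint gene identifiers.
#' @param mi numeric vector of non-negative weights (nats); recycled scalar
#'   allowed.
#' @param name network label.
#' @return A [CoexpressionNetwork-class] object.
#' @examples
#' net <- coexpressionNetwork(c("G2", "G1"), c("G1", "G3"), c(0.5, 0.9), "toy")
#' nEdges(net)
#' @export
coexpressionNetwork <- function(geneA, geneB, mi = 0, name = "network") {
  geneA <- as.character(geneA); geneB <- as.character(geneB)
  if (length(geneA) != length(geneB))
    stop("geneA and geneB must have equal length")
  mi <- rep_len(as.numeric(mi), length(geneA))
  if (any(geneA == geneB))
    stop("self-pairs are not allowed in a CoexpressionNetwork")
  swap <- geneA > geneB
  tmp <- geneA[swap]; geneA[swap] <- geneB[swap]; geneB[swap] <- tmp
  o <- order(-mi, geneA, geneB, method = "radix")
  geneA <- geneA[o]; geneB <- geneB[o]; mi <- mi[o]
  key <- paste(geneA, geneB, sep = "\r")
  keep <- !duplicated(key)
  new("CoexpressionNetwork", name = name,
      edges = data.frame(geneA = geneA[keep], geneB = geneB[keep],
                         mi = mi[keep], stringsAsFactors = FALSE))
}

#' LCCNullResult: bootstrap null test of largest-component size
#'
#' Result of [lccNullTest()]: the observed largest-connected-component (LCC)
#' gene count of an edge subnetwork, against the empirical distribution of
#' LCC sizes of random same-size edge subsets of the parent network.
#'
#' @slot networkName label of the tested subnetwork.
#' @slot observedLCC observed LCC size (genes).
#' @slot subsetSize number of edges drawn per replicate.
#' @slot nSims number of replicates.
#' @slot seed integer seed used.
#' @slot nullMean,nullSD moments of the null LCC distribution.
#' @slot pGE empirical (add-one) P(null LCC >= observed).
#' @slot pLE empirical (add-one) P(null LCC <= observed).
#' @slot nullHistogram named integer vector, LCC size -> replicate count.
#' @exportClass LCCNullResult
setClass("LCCNullResult",
  representation(networkName = "character", observedLCC = "integer",
                 subsetSize = "integer", nSims = "integer", seed = "integer",
                 nullMean = "numeric", nullSD = "numeric",
                 pGE = "numeric", pLE = "numeric",
                 nullHistogram = "integer"))

setValidity("LCCNullResult", function(object) {
  msg <- character()
  if (sum(object@nullHistogram) != object@nSims)
    msg <- c(msg, "null histogram counts must sum to nSims")
  if (object@pGE <= 0 || object@pGE > 1 || object@pLE <= 0 || object@pLE > 1)
    msg <- c(msg, "p-values must lie in (0, 1]")
  if (object@pGE + object@pLE < 1)
    msg <- c(msg, "pGE + pLE must be >= 1 (tails overlap at equality)")
  if (length(msg)) msg else TRUE
})

#' GroundTruth: planted module structure of a simulated dataset
#'
#' @slot moduleAssignments named integer vector gene -> module id; genes with
#'   no module are absent.
#' @slot moduleActivity named list, module id -> character vector of strata in
#'   which the module's latent factor is active.
#' @slot truePairs named list, stratum -> data.frame(geneA, geneB) of
#'   canonical within-module pairs for modules active in that stratum.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(moduleAssignments = "integer", moduleActivity = "list",
                 truePairs = "list"))

setValidity("GroundTruth", function(object) {
  for (st in names(object@truePairs)) {
    tp <- object@truePairs[[st]]
    if (nrow(tp) && any(tp$geneA >= tp$geneB))
      return(sprintf("true pairs for stratum %s are not canonical", st))
  }
  TRUE
})
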