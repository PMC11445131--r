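#' Bootstrap null test for largest-connected-component size
#'
#' Tests whether the largest connected component (LCC) of an edge
#' subnetwork — typically the interactions unique to one stratum — is larger
#' or smaller than expected for a random edge subset of the same size drawn
#' from the parent network. Each replicate draws \code{subsetSize} edges
#' uniformly (without replacement by default) from the parent's edges and
#' records the LCC gene count; empirical p-values use the add-one rule
#' \eqn{p = (\#extreme + 1) / (nSims + 1)}, so a finite simulation never
#' reports p = 0. Both tails are returned.
#'
#' @param parent the parent [CoexpressionNetwork-class] (e.g. a stratum's
#'   top-k network).
#' @param subset optional [CoexpressionNetwork-class]; when given,
#'   \code{subsetSize} and \code{observedLCC} are computed from it.
#' @param subsetSize number of edges per replicate (1..nEdges(parent)).
#' @param observedLCC observed LCC gene count to test.
#' @param nSims number of replicates (default 1e5).
#' @param seed integer seed; identical inputs and seed reproduce the
#'   histogram exactly.
#' @param replace draw edges with replacement instead (default FALSE).
#' @param name label stored in the result.
#' @return an [LCCNullResult-class].
#' @examples
#' parent <- coexpressionNetwork(c("a", "b", "c"), c("b", "c", "a"), 1)
#' lccNullTest(parent, subsetSize = 2, observedLCC = 3, nSims = 100,
#'             seed = 1)
#' @export
lccNullTest <- function(parent, subset = NULL, subsetSize = NULL,
                        observedLCC = NULL, nSims = 100000L, seed = 1L,
                        replace = FALSE, name = NULL) {
  stopifnot(is(parent, "CoexpressionNetwork"))
  if (!is.null(subset)) {
    stopifnot(is(subset, "CoexpressionNetwork"))
    if (is.null(subsetSize)) subsetSize <- nEdges(subset)
    if (is.null(observedLCC))
      observedLCC <- networkComponents(subset)$lccGenes
    if (is.null(name)) name <- networkName(subset)
  }
  if (is.null(name)) name <- networkName(parent)
  m <- nEdges(parent)
  if (is.null(subsetSize) || subsetSize < 1L || subsetSize > m)
    stop(sprintf(
      "configuration error: subsetSize must lie in [1, %d]", m))
  if (is.null(observedLCC) || observedLCC < 0L)
    stop("observedLCC must be a non-negative integer")
  nSims <- as.integer(nSims)
  stopifnot(nSims >= 1L)

  genes <- networkGenes(parent)
  e <- edges(parent)
  sizes <- withSeed(as.integer(seed),
                    .lccNullSizes(match(e$geneA, genes) - 1L,
                                  match(e$geneB, genes) - 1L,
                                  length(genes), as.integer(subsetSize),
                                  nSims, isTRUE(replace)))
  hist <- table(sizes)
  new("LCCNullResult",
      networkName = as.character(name),
      observedLCC = as.integer(observedLCC),
      subsetSize = as.integer(subsetSize),
      nSims = nSims,
      seed = as.integer(seed),
      nullMean = mean(sizes),
      nullSD = sd(sizes),
      pGE = (sum(sizes >= observedLCC) + 1) / (nSims + 1),
      pLE = (sum(sizes <= observedLCC) + 1) / (nSims + 1),
      nullHistogram = setNames(as.integer(hist), names(hist)))
}

#' Serialise an LCCNullResult as JSON
#'
#' @param x an [LCCNullResult-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeNullResult <- function(x, path) {
  stopifnot(is(x, "LCCNullResult"))
  jsonlite::write_json(list(
    network = x@networkName, observed_lcc = x@observedLCC,
    subset_size = x@subsetSize, n_sims = x@nSims, seed = x@seed,
    null_mean = x@nullMean, null_sd = x@nullSD,
    p_ge = x@pGE, p_le = x@pLE,
    null_histogram = as.list(setNames(as.integer(x@nullHistogram),
                                      names(x@nullHistogram)))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
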