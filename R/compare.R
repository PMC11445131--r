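## Cross-network comparison: shared-element matrices, conserved and unique
## interaction sets, connected-component statistics.

elementSets <- function(networks, mode) {
  lapply(networks, function(nw) {
    stopifnot(is(nw, "CoexpressionNetwork"))
    if (mode == "edges") edgeKeys(nw) else networkGenes(nw)
  })
}

#' Pairwise shared-element matrices across networks
#'
#' Counts, for every pair of networks, the shared edges (identity = the
#' unordered gene pair; weights ignored) or shared endpoint genes, and the
#' corresponding Jaccard index
#' \eqn{|A \cap B| / |A \cup B|}. The diagonal holds each network's own
#' element count (Jaccard 1).
#'
#' @param networks list of [CoexpressionNetwork-class] with distinct names.
#' @param mode "edges" or "genes".
#' @return list with \code{labels}, integer matrix \code{counts} and numeric
#'   matrix \code{jaccard}.
#' @export
pairwiseOverlap <- function(networks, mode = c("edges", "genes")) {
  mode <- match.arg(mode)
  if (length(networks) < 2L) stop("need >= 2 networks")
  labels <- vapply(networks, networkName, character(1))
  if (anyDuplicated(labels))
    stop("labeling error: duplicate network names: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  sets <- elementSets(networks, mode)
  p <- length(sets)
  counts <- matrix(0L, p, p, dimnames = list(labels, labels))
  jacc <- matrix(0, p, p, dimnames = list(labels, labels))
  for (i in seq_len(p)) for (j in i:p) {
    shared <- length(intersect(sets[[i]], sets[[j]]))
    counts[i, j] <- counts[j, i] <- shared
    un <- length(sets[[i]]) + length(sets[[j]]) - shared
    jacc[i, j] <- jacc[j, i] <- if (un == 0L) 1 else shared / un
  }
  list(labels = labels, counts = counts, jaccard = jacc)
}

#' Interactions conserved across all networks
#'
#' Intersection of the edge sets (unordered-pair identity). The retained
#' weight of a conserved edge is the minimum of its weights across the
#' inputs.
#'
#' @param networks non-empty list of [CoexpressionNetwork-class].
#' @param name label for the result.
#' @return a [CoexpressionNetwork-class] of the conserved edges.
#' @export
conservedEdges <- function(networks, name = "conserved") {
  stopifnot(length(networks) >= 1L)
  keys <- lapply(networks, edgeKeys)
  common <- Reduce(intersect, keys)
  e1 <- edges(networks[[1L]])
  sel <- e1[match(common, keys[[1L]]), , drop = FALSE]
  w <- sel$mi
  for (nw in networks[-1L])
    w <- pmin(w, edges(nw)$mi[match(common, edgeKeys(nw))])
  new("CoexpressionNetwork", name = name,
      edges = {
        o <- order(-w, sel$geneA, sel$geneB, method = "radix")
        data.frame(geneA = sel$geneA[o], geneB = sel$geneB[o], mi = w[o],
                   stringsAsFactors = FALSE)
      })
}

#' Interactions unique to one network
#'
#' Edges of \code{target} present (as unordered pairs) in none of the
#' \code{others}.
#'
#' @param target a [CoexpressionNetwork-class].
#' @param others list of [CoexpressionNetwork-class] to subtract.
#' @param name label for the result; defaults to "<target>_unique".
#' @return a [CoexpressionNetwork-class].
#' @export
uniqueEdges <- function(target, others,
                        name = paste0(networkName(target), "_unique")) {
  stopifnot(is(target, "CoexpressionNetwork"))
  if (any(vapply(others, function(o) identical(o, target), logical(1))))
    stop("target must not be among the other networks")
  seen <- unique(unlist(lapply(others, edgeKeys)))
  keep <- !(edgeKeys(target) %in% seen)
  new("CoexpressionNetwork", name = name,
      edges = edges(target)[keep, , drop = FALSE])
}

#' Connected components of a network
#'
#' Standard undirected connected components of the edge-induced graph
#' (every gene is an edge endpoint by construction, so there are no
#' isolated vertices). Delegates to \pkg{igraph}.
#'
#' @param network a [CoexpressionNetwork-class].
#' @return list with \code{nComponents}, \code{lccGenes} (size of the
#'   largest component, in genes; 0 for an empty network),
#'   \code{lccMembership} (character vector of its genes) and
#'   \code{componentSizes} (decreasing integer vector).
#' @export
networkComponents <- function(network) {
  stopifnot(is(network, "CoexpressionNetwork"))
  e <- edges(network)
  if (nrow(e) == 0L)
    return(list(nComponents = 0L, lccGenes = 0L,
                lccMembership = character(), componentSizes = integer()))
  g <- igraph::graph_from_data_frame(e[, c("geneA", "geneB")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  lcc <- which.max(comp$csize)
  list(nComponents = comp$no,
       lccGenes = as.integer(max(comp$csize)),
       lccMembership = sort(names(comp$membership)[comp$membership == lcc]),
       componentSizes = sort(as.integer(comp$csize), decreasing = TRUE))
}

#' Write overlap matrices and component summaries
#'
#' @param overlap result of [pairwiseOverlap()].
#' @param prefix output path prefix; writes \code{<prefix>_counts.csv} and
#'   \code{<prefix>_jaccard.csv}.
#' @name compare-io
#' @return paths, invisibly.
#' @export
writeOverlap <- function(overlap, prefix) {
  pc <- paste0(prefix, "_counts.csv")
  pj <- paste0(prefix, "_jaccard.csv")
  write.csv(overlap$counts, pc)
  write.csv(round(overlap$jaccard, 6), pj)
  invisible(c(pc, pj))
}

#' @rdname compare-io
#' @param summary result of [networkComponents()].
#' @param path output JSON path.
#' @export
writeComponentSummary <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE)
  invisible(path)
}
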