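## Mutual-information network inference: equal-frequency (quantile) binning,
## plug-in MI in nats, DPI pruning, top-k edge retention.

#' Resolve the number of discretization bins
#'
#' The "auto" rule is floor(sqrt(n)) clamped to [2, 20]: a standard
#' root-n histogram rule bounded away from degenerate (1 bin) and
#' over-fragmented partitions.
#'
#' @param nBins "auto" or an integer >= 2.
#' @param n number of samples.
#' @return integer bin count.
#' @export
resolveBins <- function(nBins, n) {
  if (identical(nBins, "auto"))
    return(max(2L, min(20L, as.integer(floor(sqrt(n))))))
  nBins <- as.integer(nBins)
  if (is.na(nBins) || nBins < 2L)
    stop("configuration error: n_bins must be 'auto' or an integer >= 2")
  nBins
}

## Equal-frequency bin assignment. Average ranks first, then cut so that a
## tie group spanning a bin boundary falls entirely in the lower bin:
## bin = floor(nBins * (rank - 1) / n) + 1. Depends only on ranks, so any
## strictly monotone transform of x yields identical bins. A constant vector
## collapses to a single occupied bin.
discretizeQuantile <- function(x, nBins) {
  n <- length(x)
  r <- rank(x, ties.method = "average")
  pmin.int(as.integer(floor(nBins * (r - 1) / n)) + 1L, nBins)
}

#' Plug-in mutual information between two samples
#'
#' Both vectors are discretized into \code{nBins} equal-frequency (quantile)
#' bins; MI is the plug-in estimate over the joint histogram, in nats.
#' Symmetric and non-negative; invariant under strictly monotone transforms
#' of either argument (only ranks matter); exactly 0 when either vector is
#' constant.
#'
#' @param x,y numeric vectors of equal length n >= 4 * nBins.
#' @param nBins "auto" (\code{floor(sqrt(n))} clamped to [2, 20]) or an
#'   integer >= 2.
#' @return MI in nats (>= 0).
#' @examples
#' x <- c(1, 2, 3, 4, 5, 6, 7, 8)
#' mutualInformation(x, x, nBins = 2)  # log(2)
#' @export
mutualInformation <- function(x, y, nBins = "auto") {
  if (length(x) != length(y))
    stop("x and y must have equal length")
  n <- length(x)
  nb <- resolveBins(nBins, n)
  if (n < 4L * nb)
    stop(sprintf(
      "sample-size error: need >= %d samples for %d bins (got %d)",
      4L * nb, nb, n))
  joint <- tabulate(
    (discretizeQuantile(x, nb) - 1L) * nb + discretizeQuantile(y, nb),
    nbins = nb * nb)
  pluginMI(matrix(joint, nb, nb, byrow = TRUE), n)
}

## MI in nats from a joint count table.
pluginMI <- function(joint, n = sum(joint)) {
  nlogn <- function(v) sum(v[v > 0] * log(v[v > 0]))
  mi <- (nlogn(joint) - nlogn(rowSums(joint)) - nlogn(colSums(joint))) / n +
    log(n)
  max(mi, 0)
}

#' All-pairs mutual information matrix
#'
#' Computes the plug-in MI (see [mutualInformation()]) for every gene pair
#' of a genes x samples expression matrix. Rows are discretized once;
#' pairwise joint histograms are accumulated blockwise through sparse
#' indicator cross-products, so memory stays bounded for large gene sets.
#'
#' @param x numeric genes x samples matrix with rownames.
#' @param nBins see [mutualInformation()].
#' @param chunkSize genes per block in the blocked computation.
#' @return symmetric numeric matrix of MI values (nats) with NA diagonal.
#' @export
miMatrix <- function(x, nBins = "auto", chunkSize = 128L) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need >= 2 genes")
  n <- ncol(x)
  nb <- resolveBins(nBins, n)
  if (n < 4L * nb)
    stop(sprintf(
      "sample-size error: need >= %d samples for %d bins (got %d)",
      4L * nb, nb, n))
  G <- nrow(x)
  bins <- t(apply(x, 1L, discretizeQuantile, nBins = nb))

  ## per-gene marginal term (1/n) * sum_a n_a log n_a
  marg <- apply(bins, 1L, function(b) {
    cnt <- tabulate(b, nbins = nb)
    sum(cnt[cnt > 0] * log(cnt[cnt > 0])) / n
  })

  ## sparse one-hot indicator for a block of genes: (|block|*nb) x n
  indicator <- function(rows) {
    nr <- length(rows)
    Matrix::sparseMatrix(
      i = rep((seq_len(nr) - 1L) * nb, each = n) + as.vector(t(bins[rows, ,
        drop = FALSE])),
      j = rep.int(seq_len(n), nr),
      x = 1, dims = c(nr * nb, n))
  }
  blockAgg <- function(nr)  # block-sum aggregator: nr x (nr*nb)
    Matrix::sparseMatrix(i = rep(seq_len(nr), each = nb),
                         j = seq_len(nr * nb), x = 1,
                         dims = c(nr, nr * nb))

  out <- matrix(NA_real_, G, G, dimnames = list(rownames(x), rownames(x)))
  starts <- seq(1L, G, by = chunkSize)
  for (bi in seq_along(starts)) {
    ri <- starts[bi]:min(starts[bi] + chunkSize - 1L, G)
    Si <- indicator(ri)
    for (bj in bi:length(starts)) {
      rj <- starts[bj]:min(starts[bj] + chunkSize - 1L, G)
      Sj <- if (bj == bi) Si else indicator(rj)
      J <- as.matrix(Si %*% Matrix::t(Sj))          # joint counts, stacked
      P <- J; P[J > 0] <- J[J > 0] * log(J[J > 0])  # n log n, 0 log 0 = 0
      U <- as.matrix(blockAgg(length(ri)) %*% P %*%
                       Matrix::t(blockAgg(length(rj)))) / n
      mi <- U - outer(marg[ri], marg[rj], "+") + log(n)
      out[ri, rj] <- pmax(mi, 0)
    }
  }
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  diag(out) <- NA_real_
  out
}

#' Data-processing-inequality pruning of an MI table
#'
#' In every gene triple (i, j, k) whose three MIs are all present in the
#' input table, the edge (i, j) is marked for removal when
#' \code{MI(i,j) < min(MI(i,k), MI(j,k)) * (1 - tolerance)} for some k: the
#' weakest edge of a triangle is presumed an indirect interaction. All
#' removals are evaluated against the input table (mark-then-sweep), so the
#' result does not depend on gene enumeration order, and ties survive
#' (strict inequality).
#'
#' @param miMat symmetric MI matrix with NA marking absent entries.
#' @param tolerance epsilon >= 0; 0 reproduces the strict DPI.
#' @return the matrix with pruned entries set to NA.
#' @export
dpiPrune <- function(miMat, tolerance = 0) {
  if (tolerance < 0)
    stop("configuration error: dpi tolerance must be >= 0")
  if (!isTRUE(all.equal(miMat, t(miMat), check.attributes = FALSE)))
    stop("MI table must be symmetric")
  G <- nrow(miMat)
  drop <- matrix(FALSE, G, G)
  for (i in seq_len(G - 1L)) {
    wi <- miMat[i, ]
    for (j in (i + 1L):G) {
      mij <- miMat[i, j]
      if (is.na(mij)) next
      w <- pmin(wi, miMat[j, ])  # NA wherever either leg is absent
      w[c(i, j)] <- NA_real_
      if (any(w * (1 - tolerance) > mij, na.rm = TRUE))
        drop[i, j] <- TRUE
    }
  }
  miMat[drop | t(drop)] <- NA_real_
  miMat
}

#' Retain the k strongest edges of an MI table
#'
#' Selects the k largest present entries as a network; ties at the cutoff
#' are broken by canonical (geneA, geneB) lexicographic order so the result
#' is deterministic. Edge weights are the MI values.
#'
#' @param miMat symmetric MI matrix with NA marking absent entries.
#' @param k number of edges to retain (>= 1); fewer are returned when the
#'   table has fewer present pairs.
#' @param name network label.
#' @return a [CoexpressionNetwork-class] with \code{min(k, #pairs)} edges.
#' @export
topKEdges <- function(miMat, k, name = "network") {
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    stop("configuration error: k must be >= 1")
  genes <- rownames(miMat)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(miMat)))
  ut <- which(upper.tri(miMat) & !is.na(miMat), arr.ind = TRUE)
  if (nrow(ut) == 0L) stop("MI table has no present entries")
  a <- genes[ut[, 1L]]; b <- genes[ut[, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  mi <- miMat[ut]
  o <- order(-mi, a, b, method = "radix")
  take <- o[seq_len(min(as.integer(k), length(o)))]
  new("CoexpressionNetwork", name = name,
      edges = data.frame(geneA = a[take], geneB = b[take], mi = mi[take],
                         stringsAsFactors = FALSE))
}

#' Infer a co-expression network from an expression matrix
#'
#' Composition of [miMatrix()], optional [dpiPrune()], and [topKEdges()]:
#' all-pairs plug-in MI on quantile-binned expression, removal of the
#' presumed-indirect weakest edge of each triangle, and retention of the k
#' strongest interactions so networks of different strata are size-matched.
#'
#' @param x numeric genes x samples matrix, or a SummarizedExperiment
#'   (the \code{qnorm} assay is used when present).
#' @param k edges to retain (default 10000).
#' @param nBins see [mutualInformation()].
#' @param dpi logical, apply DPI pruning before the top-k cut.
#' @param dpiTolerance DPI epsilon (default 0).
#' @param name network label.
#' @return a [CoexpressionNetwork-class].
#' @export
setGeneric("inferNetwork",
  function(x, k = 10000L, nBins = "auto", dpi = TRUE, dpiTolerance = 0,
           name = "network") standardGeneric("inferNetwork"))

#' @rdname inferNetwork
setMethod("inferNetwork", "matrix",
  function(x, k = 10000L, nBins = "auto", dpi = TRUE, dpiTolerance = 0,
           name = "network") {
    mim <- miMatrix(x, nBins = nBins)
    if (dpi) mim <- dpiPrune(mim, tolerance = dpiTolerance)
    topKEdges(mim, k, name = name)
  })

#' @rdname inferNetwork
setMethod("inferNetwork", "SummarizedExperiment",
  function(x, k = 10000L, nBins = "auto", dpi = TRUE, dpiTolerance = 0,
           name = "network") {
    an <- if ("qnorm" %in% SummarizedExperiment::assayNames(x)) "qnorm" else 1L
    inferNetwork(SummarizedExperiment::assay(x, an), k = k, nBins = nBins,
                 dpi = dpi, dpiTolerance = dpiTolerance, name = name)
  })

#' Read and write edge lists
#'
#' TSV with columns \code{gene_a}, \code{gene_b}, \code{mi}
#' (\code{gene_a < gene_b}), sorted by decreasing MI then pair order.
#' \code{writeSIF()} emits the Cytoscape SIF dialect
#' (\code{gene_a mi gene_b}).
#'
#' @param network a [CoexpressionNetwork-class].
#' @param path file path.
#' @param name network label for the object read back.
#' @name edgelist-io
#' @return \code{readEdgeList()} a [CoexpressionNetwork-class]; the writers
#'   return the path invisibly.
#' @export
writeEdgeList <- function(network, path) {
  stopifnot(is(network, "CoexpressionNetwork"))
  e <- edges(network)
  write.table(
    data.frame(gene_a = e$geneA, gene_b = e$geneB,
               mi = sprintf("%.12g", e$mi), stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname edgelist-io
#' @export
readEdgeList <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  coexpressionNetwork(tab$gene_a, tab$gene_b, as.numeric(tab$mi),
                      name = name)
}

#' @rdname edgelist-io
#' @export
writeSIF <- function(network, path) {
  stopifnot(is(network, "CoexpressionNetwork"))
  e <- edges(network)
  writeLines(paste(e$geneA, "mi", e$geneB, sep = "\t"), path)
  invisible(path)
}
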