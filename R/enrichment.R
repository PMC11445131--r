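#' Read a GMT gene-set collection
#'
#' One set per line: \code{term<TAB>description<TAB>gene1<TAB>gene2...}.
#' Gene symbols are upper-cased and de-duplicated within a set; a line with
#' fewer than three fields is a format error reported with its line number.
#'
#' @param path GMT file path.
#' @return a list of class \code{GeneSetCollection_gmt} with elements
#'   \code{name}, \code{description} (named character) and \code{sets}
#'   (named list of character vectors).
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("format error in GMT line %d: expected >= 3 fields", i))
    term <- f[1L]
    if (term %in% names(sets))
      stop(sprintf("format error in GMT line %d: duplicate term '%s'",
                   i, term))
    sets[[term]] <- unique(toupper(f[-c(1L, 2L)]))
    desc[term] <- f[2L]
  }
  structure(list(name = basename(path), description = desc, sets = sets),
            class = "GeneSetCollection_gmt")
}

#' Hypergeometric over-representation of gene sets
#'
#' For each term, tests whether the query gene set overlaps the term more
#' than expected under sampling without replacement from the universe:
#' upper-tail \eqn{P(X \ge k)} of Hypergeometric(N, K, n) with N the
#' universe size, K the in-universe term size, n the query size and k the
#' overlap. P-values are Benjamini-Hochberg adjusted over all tested terms;
#' terms with no universe overlap are skipped. Query genes outside the
#' universe are dropped with a warning.
#'
#' @param query character vector of gene symbols.
#' @param collection a [readGMT()] collection (or a named list of gene
#'   sets).
#' @param universe character vector defining the background, typically the
#'   filtered transcriptome the networks were inferred from.
#' @param threshold adjusted-p significance cutoff (default 0.05).
#' @return data.frame with one row per tested term: term, description, k,
#'   K, n, N, p, p_adj, significant, overlap_genes
#'   (comma-separated), sorted by p.
#' @examples
#' sets <- list(S1 = c("A", "B", "C", "D", "E"))
#' enrichGenes(c("A", "B", "C", "D", "E"), sets, universe = LETTERS[1:10])
#' @export
enrichGenes <- function(query, collection, universe, threshold = 0.05) {
  sets <- if (inherits(collection, "GeneSetCollection_gmt"))
    collection$sets else collection
  desc <- if (inherits(collection, "GeneSetCollection_gmt"))
    collection$description else setNames(rep("", length(sets)), names(sets))
  universe <- unique(toupper(universe))
  if (length(universe) == 0L) stop("universe must be non-empty")
  query <- unique(toupper(query))
  out <- setdiff(query, universe)
  if (length(out)) {
    warning("dropping ", length(out), " query gene(s) not in the universe")
    query <- intersect(query, universe)
  }
  emptyResult <- function()
    data.frame(term = character(), description = character(),
               k = integer(), K = integer(), n = integer(), N = integer(),
               p = numeric(), p_adj = numeric(), significant = logical(),
               overlap_genes = character(), stringsAsFactors = FALSE)
  if (length(query) == 0L) {
    message("empty query: no enrichment computed")
    return(emptyResult())
  }
  N <- length(universe); n <- length(query)
  rows <- lapply(names(sets), function(term) {
    inUniv <- intersect(sets[[term]], universe)
    K <- length(inUniv)
    if (K == 0L) return(NULL)  # untestable term
    hits <- intersect(query, inUniv)
    k <- length(hits)
    ## upper tail P(X >= k); k = 0 gives p = 1 exactly
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, description = unname(desc[term]), k = k, K = K,
               n = n, N = N, p = p,
               overlap_genes = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(emptyResult())
  res$p_adj <- p.adjust(res$p, method = "BH")
  res$significant <- res$p_adj < threshold
  res <- res[order(res$p, res$term), c("term", "description", "k", "K",
                                       "n", "N", "p", "p_adj",
                                       "significant", "overlap_genes")]
  rownames(res) <- NULL
  res
}

#' Cross-network membership of significant terms
#'
#' Given the significant term sets of several networks, reports for every
#' term the exact subset of networks in which it is significant, plus
#' UpSet-style counts per network combination.
#'
#' @param significantTerms named list, network name -> character vector of
#'   significant term ids (e.g. from \code{enrichGenes()} rows with
#'   \code{significant == TRUE}).
#' @return list with \code{membership}, a data.frame (term, networks as a
#'   comma-separated combination, n_networks), and \code{combinationCounts},
#'   a named integer vector combination -> number of terms. Combination
#'   counts sum to the number of distinct significant terms.
#' @export
processMembership <- function(significantTerms) {
  stopifnot(length(significantTerms) >= 1L,
            !is.null(names(significantTerms)))
  allTerms <- sort(unique(unlist(significantTerms)))
  nets <- names(significantTerms)
  combo <- vapply(allTerms, function(tm)
    paste(nets[vapply(significantTerms, function(s) tm %in% s, logical(1))],
          collapse = ","), character(1))
  membership <- data.frame(
    term = allTerms, networks = unname(combo),
    n_networks = vapply(strsplit(unname(combo), ",", fixed = TRUE), length,
                        integer(1)),
    stringsAsFactors = FALSE)
  counts <- table(combo)
  list(membership = membership,
       combinationCounts = setNames(as.integer(counts),
                                    as.character(names(counts))))
}
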