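## Independent brute-force oracles. Each re-derives a quantity along a
## deliberately naive path (explicit loops, full enumeration) so the
## package's vectorised/compiled implementations are checked against code
## that shares none of their structure.

## Equal-frequency bin assignment, re-derived: average ranks, tie groups on
## a boundary fall in the lower bin.
oracleBins <- function(x, nb) {
  r <- rank(x, ties.method = "average")
  floor(nb * (r - 1) / length(x)) + 1
}

## Plug-in MI (nats) by explicit summation over every cell of the joint
## histogram.
oracleMI <- function(x, y, nb) {
  bx <- oracleBins(x, nb)
  by <- oracleBins(y, nb)
  n <- length(x)
  mi <- 0
  for (a in seq_len(nb)) for (b in seq_len(nb)) {
    nab <- sum(bx == a & by == b)
    if (nab > 0) {
      pab <- nab / n
      pa <- sum(bx == a) / n
      pb <- sum(by == b) / n
      mi <- mi + pab * log(pab / (pa * pb))
    }
  }
  mi
}

## DPI by exhaustive triple checking against the input table.
oracleDPI <- function(M, eps = 0) {
  G <- nrow(M)
  out <- M
  if (G < 3L) return(out)
  for (i in 1:(G - 2)) for (j in (i + 1):(G - 1)) for (k in (j + 1):G) {
    mij <- M[i, j]; mik <- M[i, k]; mjk <- M[j, k]
    if (is.na(mij) || is.na(mik) || is.na(mjk)) next
    if (mij < min(mik, mjk) * (1 - eps)) out[i, j] <- out[j, i] <- NA
    if (mik < min(mij, mjk) * (1 - eps)) out[i, k] <- out[k, i] <- NA
    if (mjk < min(mij, mik) * (1 - eps)) out[j, k] <- out[k, j] <- NA
  }
  out
}

## Top-k by full sort of all present pairs with the documented tie-break.
oracleTopK <- function(M, k) {
  genes <- rownames(M)
  ut <- which(upper.tri(M) & !is.na(M), arr.ind = TRUE)
  df <- data.frame(geneA = genes[ut[, 1]], geneB = genes[ut[, 2]],
                   mi = M[ut], stringsAsFactors = FALSE)
  df <- df[order(-df$mi, df$geneA, df$geneB), ]
  head(df, k)
}

## Connected-component sizes by plain union-find over an edge list.
oracleComponentSizes <- function(geneA, geneB) {
  verts <- sort(unique(c(geneA, geneB)))
  parent <- seq_along(verts)
  find <- function(v) {
    while (parent[v] != v) v <- parent[v]
    v
  }
  for (e in seq_along(geneA)) {
    ra <- find(match(geneA[e], verts))
    rb <- find(match(geneB[e], verts))
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_along(verts), find, integer(1))
  sort(as.integer(table(roots)), decreasing = TRUE)
}

## Benjamini-Hochberg step-up from scratch.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

## Random symmetric MI-like table over nGenes genes (all entries present).
randomMITable <- function(nGenes, seed) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(nGenes))
  M <- matrix(0, nGenes, nGenes, dimnames = list(genes, genes))
  vals <- runif(nGenes * (nGenes - 1) / 2)
  M[upper.tri(M)] <- vals
  M <- M + t(M)
  diag(M) <- NA_real_
  M
}

## Random network over a gene pool.
randomNetwork <- function(nGenes, nEdges, seed, name = "net") {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(nGenes))
  pairs <- t(combn(genes, 2))
  take <- sample(nrow(pairs), min(nEdges, nrow(pairs)))
  coexpressionNetwork(pairs[take, 1], pairs[take, 2],
                      runif(length(take)), name = name)
}
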