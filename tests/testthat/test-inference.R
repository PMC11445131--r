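test_that("plug-in MI reproduces hand-derived and degenerate cases", {
  ## perfect dependence at 2 bins: joint table [[4,0],[0,4]] -> ln 2
  x <- 1:8
  expect_equal(mutualInformation(x, x, nBins = 2), log(2), tolerance = 1e-12)
  expect_equal(mutualInformation(x, rev(x), nBins = 2), log(2),
               tolerance = 1e-12)
  ## a constant series occupies one bin: MI exactly 0
  expect_identical(mutualInformation(rep(2, 12), rnorm(12), nBins = 2), 0)
  ## errors: length mismatch, too few samples, bad bin count
  expect_error(mutualInformation(1:5, 1:6, 2), "equal length")
  expect_error(mutualInformation(1:7, 1:7, 2), "sample-size")
  expect_error(mutualInformation(1:8, 1:8, 1), "n_bins")
})

test_that("MI matches the brute-force joint-histogram oracle on small fixtures", {
  set.seed(60)
  for (i in 1:40) {
    n <- sample(8:12, 1)
    nb <- sample(2:3, 1)
    if (n < 4 * nb) next
    x <- sample(0:4, n, replace = TRUE)  # heavy ties on purpose
    y <- sample(0:4, n, replace = TRUE)
    expect_equal(mutualInformation(x, y, nb), oracleMI(x, y, nb),
                 tolerance = 1e-12)
    ## symmetry
    expect_equal(mutualInformation(x, y, nb), mutualInformation(y, x, nb),
                 tolerance = 1e-12)
  }
})

test_that("MI is invariant under strictly monotone transforms", {
  set.seed(61)
  x <- rnorm(40); y <- x + rnorm(40)
  base <- mutualInformation(x, y, 4)
  expect_gt(base, 0)
  expect_equal(mutualInformation(exp(x), y, 4), base, tolerance = 1e-12)
  expect_equal(mutualInformation(x, 3 * y - 7, 4), base, tolerance = 1e-12)
  expect_equal(mutualInformation(rank(x), atan(y), 4), base,
               tolerance = 1e-12)
})

test_that("the auto bin rule is floor(sqrt(n)) clamped to [2, 20]", {
  expect_equal(resolveBins("auto", 10), 3L)
  expect_equal(resolveBins("auto", 100), 10L)
  expect_equal(resolveBins("auto", 803), 20L)
  expect_equal(resolveBins("auto", 5), 2L)
  expect_equal(resolveBins(7, 100), 7L)
})

test_that("miMatrix agrees with independent pairwise calls and relabeling", {
  set.seed(62)
  m <- matrix(rnorm(5 * 30), 5, 30,
              dimnames = list(paste0("g", 1:5), NULL))
  M <- miMatrix(m, nBins = 3)
  expect_true(all(is.na(diag(M))))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(M[i, j], mutualInformation(m[i, ], m[j, ], 3),
                 tolerance = 1e-12)
    expect_equal(M[i, j], M[j, i])
  }
  ## permuting gene rows permutes but does not change the values
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(miMatrix(m[perm, ], nBins = 3), M[perm, perm])
  ## blocked evaluation is exact regardless of chunk size
  expect_equal(miMatrix(m, nBins = 3, chunkSize = 2L), M)
})

test_that("DPI removes the weakest edge of a triangle, respecting ties", {
  M <- matrix(NA_real_, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  M["a", "b"] <- M["b", "a"] <- 0.9
  M["b", "c"] <- M["c", "b"] <- 0.8
  M["a", "c"] <- M["c", "a"] <- 0.3
  pruned <- dpiPrune(M)
  expect_true(is.na(pruned["a", "c"]))
  expect_equal(pruned["a", "b"], 0.9)
  expect_equal(pruned["b", "c"], 0.8)

  ## equilateral triangle: strict inequality, nothing removed
  E <- M; E[!is.na(E)] <- 0.5
  expect_equal(dpiPrune(E), E)

  ## no complete triangle: unchanged
  P <- matrix(NA_real_, 3, 3, dimnames = dimnames(M))
  P["a", "b"] <- P["b", "a"] <- 0.2
  P["b", "c"] <- P["c", "b"] <- 0.9
  expect_equal(dpiPrune(P), P)

  expect_error(dpiPrune(M, tolerance = -0.1), "tolerance")
})

test_that("DPI and top-k match exhaustive oracles on random tables", {
  for (i in 1:30) {
    G <- sample(5:8, 1)
    M <- randomMITable(G, seed = 600 + i)
    eps <- sample(c(0, 0.1), 1)
    expect_equal(dpiPrune(M, eps), oracleDPI(M, eps))
    net <- topKEdges(M, 3)
    expect_equal(edges(net)[, c("geneA", "geneB", "mi")],
                 oracleTopK(M, 3), ignore_attr = TRUE)
  }
})

test_that("DPI never adds edges and ignores enumeration order", {
  M <- randomMITable(7, seed = 71)
  pruned <- dpiPrune(M)
  expect_true(all(is.na(pruned) | !is.na(M)))
  perm <- sample(7)
  expect_equal(dpiPrune(M[perm, perm]), pruned[perm, perm])
})

test_that("top-k selection is monotone in k with deterministic tie-breaks", {
  M <- randomMITable(6, seed = 72)
  ## ties at the cutoff: duplicate some weights
  M[1, 2] <- M[2, 1] <- M[3, 4] <- M[4, 3] <- 0.5
  for (k in 1:(choose(6, 2) - 1)) {
    ek <- edgeKeys(topKEdges(M, k))
    ek1 <- edgeKeys(topKEdges(M, k + 1))
    expect_true(all(ek %in% ek1))
    expect_equal(length(ek), k)
  }
  ## k beyond the pair count returns everything
  expect_equal(nEdges(topKEdges(M, 1000)), choose(6, 2))
  expect_error(topKEdges(M, 0), "k must be")
})

test_that("inferNetwork composes MI, DPI and top-k deterministically", {
  set.seed(73)
  m <- matrix(rnorm(8 * 40), 8, 40,
              dimnames = list(paste0("g", 1:8), NULL))
  ## DPI disabled: equals top-k of the raw MI table
  expect_equal(edges(inferNetwork(m, k = 5, nBins = 3, dpi = FALSE)),
               edges(topKEdges(miMatrix(m, nBins = 3), 5)))
  ## DPI enabled: equals the documented composition
  expect_equal(edges(inferNetwork(m, k = 5, nBins = 3)),
               edges(topKEdges(dpiPrune(miMatrix(m, nBins = 3)), 5)))

  ## byte-identical edgelists across repeated runs
  f1 <- tempfile(); f2 <- tempfile()
  writeEdgeList(inferNetwork(m, k = 10, nBins = 3), f1)
  writeEdgeList(inferNetwork(m, k = 10, nBins = 3), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("edge lists round-trip through TSV and export to SIF", {
  net <- randomNetwork(10, 12, seed = 74, name = "toy")
  f <- tempfile(fileext = ".tsv")
  writeEdgeList(net, f)
  back <- readEdgeList(f, name = "toy")
  expect_equal(edges(back)$geneA, edges(net)$geneA)
  expect_equal(edges(back)$geneB, edges(net)$geneB)
  expect_equal(edges(back)$mi, edges(net)$mi, tolerance = 1e-10)

  sif <- tempfile(fileext = ".sif")
  writeSIF(net, sif)
  lines <- readLines(sif)
  expect_length(lines, nEdges(net))
  expect_true(all(grepl("\tmi\t", lines, fixed = TRUE)))
})

test_that("canonical edge construction rejects self-pairs and de-duplicates", {
  net <- coexpressionNetwork(c("b", "a"), c("a", "b"), c(0.2, 0.9))
  expect_equal(nEdges(net), 1L)       # same unordered pair
  expect_equal(edges(net)$mi, 0.9)    # strongest weight kept
  expect_equal(edges(net)$geneA, "a") # canonical order
  expect_error(coexpressionNetwork("a", "a", 1), "self-pairs")
})
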