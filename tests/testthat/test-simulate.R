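test_that("simulated datasets honour the design, align metadata and are reproducible", {
  cfg <- simulationConfig(nGenes = 120, seed = 5)
  sim <- simulateCounts(cfg)
  se <- sim$se

  expect_equal(ncol(se), 803L)  # default six-stratum cohort layout
  cd <- SummarizedExperiment::colData(se)
  lab <- paste0(cd$SEX, cd$AGE_GROUP)
  expect_equal(as.vector(table(lab)[c("FY", "FM", "FE", "MY", "MM", "ME")]),
               c(39L, 134L, 87L, 93L, 245L, 205L))
  cnt <- SummarizedExperiment::assay(se)
  expect_true(is.integer(cnt))
  expect_true(all(cnt >= 0))
  expect_identical(rownames(cnt)[1], "G000001")
  expect_identical(colnames(cnt), rownames(cd))

  ## identical config + seed => bit-identical counts
  sim2 <- simulateCounts(simulationConfig(nGenes = 120, seed = 5))
  expect_identical(cnt, SummarizedExperiment::assay(sim2$se))

  ## a different seed changes the data
  sim3 <- simulateCounts(simulationConfig(nGenes = 120, seed = 6))
  expect_false(identical(cnt, SummarizedExperiment::assay(sim3$se)))
})

test_that("per-stratum RNG streams are independent of the stratum set", {
  a <- simulateCounts(simulationConfig(
    nGenes = 50, groupSizes = c(FY = 15), nModules = 1, moduleSize = 5,
    seed = 9))
  b <- simulateCounts(simulationConfig(
    nGenes = 50, groupSizes = c(FY = 15, MY = 12), nModules = 1,
    moduleSize = 5, seed = 9))
  mA <- SummarizedExperiment::assay(a$se)
  mB <- SummarizedExperiment::assay(b$se)
  expect_identical(mA, mB[, colnames(mA)])
})

test_that("invalid simulation configs name the offending field", {
  expect_error(simulationConfig(nGenes = 0), "nGenes")
  expect_error(simulationConfig(groupSizes = c(XX = 10)), "groupSizes")
  expect_error(simulationConfig(groupSizes = c(FY = -1)), "groupSizes")
  expect_error(simulationConfig(nGenes = 10, nModules = 3, moduleSize = 5),
               "nModules")
  expect_error(simulationConfig(dispersion = 0), "dispersion")
  expect_error(simulationConfig(stratumSpecificFraction = 1.2),
               "stratumSpecificFraction")
})

test_that("without planted modules, random gene pairs are uncorrelated", {
  sim <- simulateCounts(simulationConfig(
    nGenes = 100, groupSizes = c(FY = 100), nModules = 0, moduleSize = 2,
    libsizeSigma = 0, seed = 21))
  m <- SummarizedExperiment::assay(sim$se)
  set.seed(77)
  pairs <- replicate(500, sample(nrow(m), 2))
  r <- apply(pairs, 2, function(ij) cor(m[ij[1], ], m[ij[2], ]))
  expect_lt(mean(abs(r)), 0.1)
})

test_that("empirical per-gene means match the configured NB mean", {
  mu <- 50
  sim <- simulateCounts(simulationConfig(
    nGenes = 200, groupSizes = c(MM = 150), nModules = 0, moduleSize = 2,
    baseMeanLogRange = c(log(mu), log(mu)), libsizeSigma = 0.2, seed = 31))
  m <- SummarizedExperiment::assay(sim$se)
  n <- ncol(m)
  z <- abs(rowMeans(m) - mu) / (apply(m, 1, sd) / sqrt(n))
  expect_gte(mean(z < 3), 0.95)
})

test_that("moduleRecall is plain set arithmetic with an undefined-empty error", {
  truth <- new("GroundTruth",
               moduleAssignments = c(a = 1L, b = 1L, c = 1L),
               moduleActivity = list(`1` = "FY"),
               truePairs = list(
                 FY = data.frame(geneA = c("a", "a"), geneB = c("b", "c"),
                                 stringsAsFactors = FALSE),
                 MM = data.frame(geneA = character(), geneB = character(),
                                 stringsAsFactors = FALSE)))
  exact <- coexpressionNetwork(c("a", "a"), c("b", "c"), 1, "x")
  expect_equal(moduleRecall(exact, truth, "FY"), 1.0)
  half <- coexpressionNetwork(c("a", "c"), c("b", "d"), 1, "x")
  expect_equal(moduleRecall(half, truth, "FY"), 0.5)
  none <- coexpressionNetwork("c", "d", 1, "x")
  expect_equal(moduleRecall(none, truth, "FY"), 0.0)
  expect_error(moduleRecall(exact, truth, "MM"), "undefined")
})

test_that("ground truth pairs are canonical and restricted to active strata", {
  sim <- simulateCounts(simulationConfig(
    nGenes = 60, groupSizes = c(FY = 10, MM = 10), nModules = 2,
    moduleSize = 6, stratumSpecificFraction = 0.5, seed = 13))
  truth <- sim$truth
  expect_true(validObject(truth))
  ## module 1 is specific to the first configured stratum (FY)
  expect_identical(truth@moduleActivity[["1"]], "FY")
  expect_identical(truth@moduleActivity[["2"]], c("FY", "MM"))
  ## FY sees both modules, MM only the shared one
  expect_equal(nrow(truth@truePairs$FY), 2 * choose(6, 2))
  expect_equal(nrow(truth@truePairs$MM), choose(6, 2))
  ## every true pair's genes share a module
  tp <- truth@truePairs$FY
  ma <- truth@moduleAssignments
  expect_true(all(ma[tp$geneA] == ma[tp$geneB]))
  expect_true(all(tp$geneA < tp$geneB))
})

test_that("a stratum-specific module leaves no footprint in other strata", {
  sim <- simulateCounts(simulationConfig(
    nGenes = 100, groupSizes = c(FY = 100, MM = 100), nModules = 1,
    moduleSize = 20, beta = 1.5, stratumSpecificFraction = 1, seed = 11))
  strata <- splitStrata(quantileNormalize(filterGenes(sim$se)))
  ## k chosen so chance-level recall (k / #pairs ~ 0.04) sits well below
  ## the 0.1 bound: the test measures footprint, not the cutoff size
  netMM <- inferNetwork(strata$MM, k = 200, dpi = FALSE, name = "MM")
  expect_lt(moduleRecall(netMM, sim$truth, "FY"), 0.1)
  ## while the module's own stratum recovers it strongly
  netFY <- inferNetwork(strata$FY, k = 200, dpi = FALSE, name = "FY")
  expect_gt(moduleRecall(netFY, sim$truth, "FY"), 0.5)
})

test_that("count matrices and metadata round-trip through TSV and GCT", {
  sim <- simulateCounts(simulationConfig(
    nGenes = 30, groupSizes = c(FY = 4, ME = 3), nModules = 0,
    moduleSize = 2, seed = 2))
  tsv <- tempfile(fileext = ".tsv")
  gct <- tempfile(fileext = ".gct")
  metaF <- tempfile(fileext = ".tsv")
  writeCountsTSV(sim$se, tsv)
  writeCountsGCT(sim$se, gct)
  writeSampleMetadata(sim$se, metaF)

  seT <- readCountMatrix(tsv, metaF)
  seG <- readCountMatrix(gct, metaF, dialect = "gct")
  orig <- SummarizedExperiment::assay(sim$se)
  expect_equal(SummarizedExperiment::assay(seT), orig)
  expect_equal(SummarizedExperiment::assay(seG), orig)  # dialects agree
  expect_equal(as.data.frame(SummarizedExperiment::colData(seT)),
               as.data.frame(SummarizedExperiment::colData(sim$se)))

  truthF <- tempfile(fileext = ".json")
  writeGroundTruth(sim$truth, truthF)
  expect_true(jsonlite::validate(paste(readLines(truthF), collapse = "")))
})
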