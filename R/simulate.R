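#' Configuration for the stratified count simulator
#'
#' Defines a synthetic bulk RNA-seq cohort stratified into six sex x age
#' groups, mirroring a skeletal-muscle cohort design: negative-binomial
#' counts with log-normal library-size variation and latent-factor-induced
#' co-expression modules, some shared across strata and some active in a
#' single stratum.
#'
#' The default \code{groupSizes} reproduce the cohort layout
#' F: 39/134/87 and M: 93/245/205 across young (Y, 20-39), middle-aged
#' (M, 40-59) and elderly (E, 60-70+) groups, 803 samples in total.
#'
#' @param nGenes number of genes.
#' @param groupSizes named integer vector of samples per stratum; names from
#'   FY, FM, FE, MY, MM, ME.
#' @param nModules number of planted co-expression modules.
#' @param moduleSize genes per module.
#' @param beta latent-factor loading (dimensionless); 0 disables
#'   co-expression, ~1.5 is a strong signal.
#' @param dispersion NB dispersion phi > 0 (variance = mu + phi * mu^2).
#' @param baseMeanLogRange length-2 numeric, natural-log bounds of per-gene
#'   baseline mean counts.
#' @param libsizeSigma log-normal sd of the per-sample library-size factor
#'   (mean fixed at 1).
#' @param stratumSpecificFraction fraction of modules active in exactly one
#'   stratum; the rest are active in all strata.
#' @param seed integer root seed; per-stratum streams are derived with
#'   [deriveSeed()] so strata are independent of one another.
#' @return a validated list of class \code{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(nGenes = 50, groupSizes = c(FY = 20, MY = 20),
#'                         nModules = 1, moduleSize = 5)
#' @export
simulationConfig <- function(nGenes = 1000,
                             groupSizes = c(FY = 39, FM = 134, FE = 87,
                                            MY = 93, MM = 245, ME = 205),
                             nModules = 6,
                             moduleSize = 20,
                             beta = 1.0,
                             dispersion = 0.1,
                             baseMeanLogRange = c(log(5), log(1000)),
                             libsizeSigma = 0.2,
                             stratumSpecificFraction = 0.5,
                             seed = 1L) {
  fail <- function(field, why)
    stop(sprintf("invalid SimulationConfig: '%s' %s", field, why),
         call. = FALSE)
  if (!is.numeric(nGenes) || length(nGenes) != 1L || nGenes < 1)
    fail("nGenes", "must be a positive integer")
  if (is.null(names(groupSizes)) || !all(names(groupSizes) %in% STRATA))
    fail("groupSizes", "must be named with labels among FY/FM/FE/MY/MM/ME")
  if (anyDuplicated(names(groupSizes)))
    fail("groupSizes", "has duplicated stratum names")
  if (any(groupSizes < 0)) fail("groupSizes", "must all be >= 0")
  if (nModules < 0) fail("nModules", "must be >= 0")
  if (nModules > 0 && moduleSize < 2)
    fail("moduleSize", "must be >= 2 when modules are planted")
  if (nModules * moduleSize > nGenes)
    fail("nModules", sprintf(
      "x moduleSize (%d) exceeds nGenes (%d)",
      as.integer(nModules * moduleSize), as.integer(nGenes)))
  if (!is.numeric(dispersion) || dispersion <= 0)
    fail("dispersion", "must be > 0")
  if (length(baseMeanLogRange) != 2L ||
      baseMeanLogRange[1] > baseMeanLogRange[2])
    fail("baseMeanLogRange", "must be an increasing length-2 numeric")
  if (libsizeSigma < 0) fail("libsizeSigma", "must be >= 0")
  if (stratumSpecificFraction < 0 || stratumSpecificFraction > 1)
    fail("stratumSpecificFraction", "must lie in [0, 1]")
  cfg <- list(nGenes = as.integer(nGenes),
              groupSizes = setNames(as.integer(groupSizes),
                                    names(groupSizes)),
              nModules = as.integer(nModules),
              moduleSize = as.integer(moduleSize),
              beta = as.numeric(beta),
              dispersion = as.numeric(dispersion),
              baseMeanLogRange = as.numeric(baseMeanLogRange),
              libsizeSigma = as.numeric(libsizeSigma),
              stratumSpecificFraction = as.numeric(stratumSpecificFraction),
              seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  cfg
}

## Within-module canonical pair table for a set of gene names.
modulePairs <- function(genes) {
  if (length(genes) < 2L)
    return(data.frame(geneA = character(), geneB = character(),
                      stringsAsFactors = FALSE))
  cmb <- combn(sort(genes), 2L)
  data.frame(geneA = cmb[1L, ], geneB = cmb[2L, ], stringsAsFactors = FALSE)
}

#' Simulate a stratified count dataset with planted modules
#'
#' Generative mechanism, per stratum s and sample j: a library-size factor
#' \eqn{L_j} is drawn log-normal with mean 1; each module m active in s draws
#' a latent factor \eqn{z_{mj} \sim N(0,1)}; gene g in module m has mean
#' \eqn{\mu_{gj} = L_j \exp(\log m_g + \beta z_{mj})} (background genes use
#' \eqn{\beta = 0}) and counts are negative binomial with dispersion
#' \eqn{\phi}. Baseline means \eqn{m_g} are shared across strata.
#'
#' Identical \code{config} (including seed) reproduces the counts
#' bit-for-bit; each stratum uses its own derived RNG stream.
#'
#' @param config a [simulationConfig()] object.
#' @return a list with elements \code{se}, a
#'   \linkS4class{SummarizedExperiment} of integer counts with colData
#'   columns \code{SEX} and \code{AGE_GROUP}, and \code{truth}, a
#'   [GroundTruth-class] describing the planted modules.
#' @examples
#' sim <- simulateCounts(simulationConfig(nGenes = 40,
#'   groupSizes = c(FY = 10, MY = 10), nModules = 1, moduleSize = 5,
#'   seed = 7))
#' dim(sim$se)
#' @export
simulateCounts <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  nG <- config$nGenes
  genes <- sprintf("G%06d", seq_len(nG))
  strata <- names(config$groupSizes)

  ## gene-level stream: baseline log-means shared by every stratum
  logm <- withSeed(deriveSeed(config$seed, "genes"),
                   runif(nG, config$baseMeanLogRange[1],
                         config$baseMeanLogRange[2]))

  ## module layout: consecutive gene blocks; the first
  ## round(fraction * nModules) modules are stratum-specific, assigned by
  ## cycling through the configured strata in order
  nMod <- config$nModules
  assign <- rep(NA_integer_, nG)
  if (nMod > 0)
    assign[seq_len(nMod * config$moduleSize)] <-
      rep(seq_len(nMod), each = config$moduleSize)
  nSpecific <- as.integer(round(config$stratumSpecificFraction * nMod))
  activity <- lapply(seq_len(nMod), function(m) {
    if (m <= nSpecific) strata[(m - 1L) %% length(strata) + 1L] else strata
  })
  names(activity) <- as.character(seq_len(nMod))

  truePairs <- lapply(strata, function(st) {
    act <- which(vapply(activity, function(a) st %in% a, logical(1)))
    do.call(rbind, c(list(modulePairs(character())),
                     lapply(act, function(m) modulePairs(genes[
                       which(assign == m)]))))
  })
  names(truePairs) <- strata

  sigma <- config$libsizeSigma
  counts <- matrix(0L, nG, 0L)
  sex <- character(); age <- character()
  for (st in strata) {
    n <- config$groupSizes[[st]]
    if (n == 0L) next
    block <- withSeed(deriveSeed(config$seed, paste0("stratum:", st)), {
      libsize <- exp(rnorm(n, -sigma^2 / 2, sigma))
      z <- if (nMod > 0) matrix(rnorm(nMod * n), nMod, n) else NULL
      logmu <- matrix(logm, nG, n) + rep(log(libsize), each = nG)
      for (m in seq_len(nMod)) {
        if (!(st %in% activity[[m]])) next
        rows <- which(assign == m)
        logmu[rows, ] <- logmu[rows, ] +
          config$beta * rep(z[m, ], each = length(rows))
      }
      matrix(rnbinom(nG * n, mu = exp(logmu), size = 1 / config$dispersion),
             nG, n)
    })
    colnames(block) <- sprintf("%s-S%04d", st, seq_len(n))
    counts <- cbind(counts, block)
    sex <- c(sex, rep(substr(st, 1L, 1L), n))
    age <- c(age, rep(substr(st, 2L, 2L), n))
  }
  rownames(counts) <- genes
  storage.mode(counts) <- "integer"

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(SEX = sex, AGE_GROUP = age,
                                   row.names = colnames(counts)))
  truth <- new("GroundTruth",
               moduleAssignments = setNames(assign, genes)[!is.na(assign)],
               moduleActivity = activity,
               truePairs = truePairs)
  list(se = se, truth = truth)
}

#' Recall of planted module pairs by an inferred network
#'
#' Fraction of the ground-truth within-module pairs of a stratum that appear
#' (as unordered pairs) among the network's edges.
#'
#' @param network a [CoexpressionNetwork-class].
#' @param truth a [GroundTruth-class] from [simulateCounts()].
#' @param stratum stratum label, e.g. "FY".
#' @return a fraction in [0, 1]. A stratum with no planted pairs has no
#'   defined recall and raises an error.
#' @export
moduleRecall <- function(network, truth, stratum) {
  stopifnot(is(network, "CoexpressionNetwork"), is(truth, "GroundTruth"))
  tp <- truth@truePairs[[stratum]]
  if (is.null(tp) || nrow(tp) == 0L)
    stop(sprintf("recall is undefined: stratum '%s' has no true pairs",
                 stratum))
  truthKeys <- paste(tp$geneA, tp$geneB, sep = "|")
  sum(truthKeys %in% edgeKeys(network)) / length(truthKeys)
}

#' Write simulated data to plain-text files
#'
#' \code{writeCountsTSV()} writes a gene x sample table (first column
#' \code{gene_id}); \code{writeCountsGCT()} writes GCT v1.2 (header lines
#' \code{#1.2} and \code{rows<TAB>cols}, then Name/Description columns);
#' \code{writeSampleMetadata()} writes SAMPID/SEX/AGE_GROUP;
#' \code{writeGroundTruth()} serialises a [GroundTruth-class] as JSON.
#'
#' @param x a SummarizedExperiment or gene x sample matrix.
#' @param path output file path.
#' @name simulation-io
#' @return the path, invisibly.
#' @export
writeCountsTSV <- function(x, path) {
  m <- assayAndMeta(x)$matrix
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname simulation-io
#' @export
writeCountsGCT <- function(x, path) {
  m <- assayAndMeta(x)$matrix
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
  df <- data.frame(Name = rownames(m), Description = "na", m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname simulation-io
#' @export
writeSampleMetadata <- function(x, path) {
  if (is(x, "SummarizedExperiment")) {
    cd <- SummarizedExperiment::colData(x)
    x <- data.frame(SAMPID = rownames(cd), SEX = cd$SEX,
                    AGE_GROUP = cd$AGE_GROUP, stringsAsFactors = FALSE)
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname simulation-io
#' @param truth a [GroundTruth-class].
#' @export
writeGroundTruth <- function(truth, path) {
  stopifnot(is(truth, "GroundTruth"))
  obj <- list(
    module_assignments = as.list(truth@moduleAssignments),
    module_activity = truth@moduleActivity,
    true_pairs = lapply(truth@truePairs, function(tp)
      unname(apply(tp, 1L, as.list))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}
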