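#' Assemble a pipeline configuration
#'
#' Defaults follow the stratified-muscle study design: gene filters mean >=
#' 10 and <= 50% zeros, quantile normalization, six sex x age strata,
#' top-10,000 MI edges per network, 100,000 null-model replicates, FDR 0.05.
#' All randomness derives from the single \code{seed}.
#'
#' @param outDir output directory (created if absent).
#' @param counts,metadata paths to a counts TSV/GCT and sample-attribute
#'   TSV; when NULL, the \code{simulation} section is used to generate them.
#' @param gmt optional GMT path for the enrichment stage; for synthetic
#'   runs, a collection built from the planted modules is used when NULL.
#' @param simulation a [simulationConfig()]; only used when \code{counts}
#'   is NULL.
#' @param filter list(meanThreshold, maxZeroFraction).
#' @param inference list(k, nBins, dpi, dpiTolerance).
#' @param nullModel list(nSims, replace).
#' @param fdr adjusted-p significance cutoff for enrichment.
#' @param seed root seed recorded in the manifest.
#' @return list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(outDir,
                           counts = NULL, metadata = NULL, gmt = NULL,
                           simulation = simulationConfig(),
                           filter = list(meanThreshold = 10,
                                         maxZeroFraction = 0.5),
                           inference = list(k = 10000L, nBins = "auto",
                                            dpi = TRUE, dpiTolerance = 0),
                           nullModel = list(nSims = 100000L,
                                            replace = FALSE),
                           fdr = 0.05, seed = 1L) {
  cfg <- list(outDir = outDir, counts = counts, metadata = metadata,
              gmt = gmt, simulation = simulation, filter = filter,
              inference = inference, nullModel = nullModel,
              fdr = fdr, seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipelineConfig()] arguments; a
#' \code{simulation} mapping is passed to [simulationConfig()]
#' (\code{group_sizes} as a mapping stratum -> count). Unset keys take the
#' defaults.
#'
#' @param path YAML file.
#' @param outDir overrides the file's \code{out_dir} when given.
#' @return list of class \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path, outDir = NULL) {
  y <- yaml::read_yaml(path)
  simArgs <- y$simulation
  if (!is.null(simArgs$group_sizes))
    simArgs$group_sizes <- unlist(simArgs$group_sizes)
  names(simArgs) <- sub("^n_genes$", "nGenes",
    sub("^group_sizes$", "groupSizes",
    sub("^n_modules$", "nModules",
    sub("^module_size$", "moduleSize",
    sub("^base_mean_log_range$", "baseMeanLogRange",
    sub("^libsize_sigma$", "libsizeSigma",
    sub("^stratum_specific_fraction$", "stratumSpecificFraction",
        names(simArgs))))))))
  args <- list(
    outDir = if (!is.null(outDir)) outDir else y$out_dir,
    counts = y$counts, metadata = y$metadata, gmt = y$gmt,
    simulation = do.call(simulationConfig, as.list(simArgs)),
    fdr = if (!is.null(y$fdr)) y$fdr else 0.05,
    seed = if (!is.null(y$seed)) y$seed else 1L)
  for (sec in c("filter", "inference", "nullModel"))
    if (!is.null(y[[sec]])) args[[sec]] <- y[[sec]]
  do.call(pipelineConfig, args)
}

## Build a gene-set collection from planted modules plus size-matched
## decoy sets, so synthetic runs exercise the enrichment stage end to end.
truthGeneSets <- function(truth, universe, nDecoys = 20L, seed = 1L) {
  mods <- split(names(truth@moduleAssignments), truth@moduleAssignments)
  sets <- setNames(lapply(mods, toupper),
                   sprintf("MODULE_%s", names(mods)))
  sz <- if (length(sets)) max(lengths(sets)) else 20L
  decoys <- withSeed(seed, lapply(seq_len(nDecoys), function(i)
    toupper(sample(universe, min(sz, length(universe))))))
  names(decoys) <- sprintf("DECOY_%02d", seq_len(nDecoys))
  c(sets, decoys)
}

writeGMT <- function(sets, path, description = "synthetic") {
  writeLines(vapply(names(sets), function(tm)
    paste(c(tm, description, sets[[tm]]), collapse = "\t"),
    character(1)), path)
  invisible(path)
}

stageLog <- function(run, stage, t0, outputs) {
  message(sprintf("[%s] %.2fs -> %s", stage,
                  as.numeric(Sys.time()) - t0,
                  paste(basename(outputs), collapse = ", ")))
  run$stages[[stage]] <- list(outputs = basename(outputs))
  run
}

#' Run the full stratified co-expression pipeline
#'
#' Orchestrates simulate (when no counts are supplied) -> filter +
#' quantile-normalize -> six-way split -> per-stratum MI network inference
#' -> overlap / conserved / unique comparison -> bootstrap LCC null tests of
#' the unique subnetworks -> gene-set over-representation, writing every
#' result as plain text under \code{config$outDir} together with a JSON
#' manifest of parameters, seeds and MD5 checksums. Re-running an identical
#' config reproduces identical checksums.
#'
#' @param config a [pipelineConfig()] / [readPipelineConfig()] object.
#' @return the manifest, invisibly (list: parameters, seeds, stages, files
#'   with checksums).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outDir, ...)
  run <- list(package = as.character(utils::packageVersion("coexpStrata")),
              seed = config$seed, stages = list())
  truth <- NULL

  ## ---- input acquisition: real files or simulation
  t0 <- as.numeric(Sys.time())
  if (is.null(config$counts)) {
    sim <- simulateCounts(config$simulation)
    se <- sim$se; truth <- sim$truth
    writeCountsTSV(se, out("counts.tsv"))
    writeSampleMetadata(se, out("metadata.tsv"))
    writeGroundTruth(truth, out("ground_truth.json"))
    run <- stageLog(run, "simulate", t0,
                    out(c("counts.tsv", "metadata.tsv",
                          "ground_truth.json")))
  } else {
    se <- readCountMatrix(config$counts, config$metadata)
    run <- stageLog(run, "load", t0, c(config$counts, config$metadata))
  }

  ## ---- preprocessing: filter, quantile-normalize, split
  t0 <- as.numeric(Sys.time())
  se <- filterGenes(se, config$filter$meanThreshold,
                    config$filter$maxZeroFraction)
  se <- quantileNormalize(se)
  strata <- splitStrata(se)
  strata <- strata[vapply(strata, ncol, integer(1)) > 0L]
  universe <- rownames(se)
  writeLines(universe, out("universe.txt"))
  for (st in names(strata)) {
    m <- strata[[st]]
    write.table(data.frame(gene_id = rownames(m), m, check.names = FALSE),
                out(paste0(st, ".tsv")), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  run <- stageLog(run, "preprocess", t0,
                  out(c("universe.txt", paste0(names(strata), ".tsv"))))

  ## ---- per-stratum network inference
  t0 <- as.numeric(Sys.time())
  inf <- config$inference
  networks <- lapply(names(strata), function(st)
    inferNetwork(strata[[st]], k = inf$k, nBins = inf$nBins,
                 dpi = isTRUE(inf$dpi), dpiTolerance = inf$dpiTolerance,
                 name = st))
  names(networks) <- names(strata)
  for (st in names(networks))
    writeEdgeList(networks[[st]], out(paste0(st, "_edges.tsv")))
  run <- stageLog(run, "infer", t0,
                  out(paste0(names(networks), "_edges.tsv")))

  ## ---- comparison: overlaps, conserved, unique, components
  t0 <- as.numeric(Sys.time())
  cmpFiles <- character()
  if (length(networks) >= 2L) {
    writeOverlap(pairwiseOverlap(networks, "edges"), out("overlap_edges"))
    writeOverlap(pairwiseOverlap(networks, "genes"), out("overlap_genes"))
    cmpFiles <- c(cmpFiles,
                  out(c("overlap_edges_counts.csv",
                        "overlap_edges_jaccard.csv",
                        "overlap_genes_counts.csv",
                        "overlap_genes_jaccard.csv")))
    writeEdgeList(conservedEdges(networks, "conserved_all"),
                  out("conserved_all.tsv"))
    cmpFiles <- c(cmpFiles, out("conserved_all.tsv"))
    for (sx in c("F", "M")) {
      grp <- networks[startsWith(names(networks), sx)]
      if (length(grp) >= 2L) {
        writeEdgeList(conservedEdges(grp, paste0("conserved_", sx)),
                      out(paste0("conserved_", sx, ".tsv")))
        cmpFiles <- c(cmpFiles, out(paste0("conserved_", sx, ".tsv")))
      }
    }
  }
  uniques <- list()
  for (st in names(networks)) {
    u <- uniqueEdges(networks[[st]], networks[names(networks) != st],
                     name = st)
    uniques[[st]] <- u
    writeEdgeList(u, out(paste0(st, "_unique.tsv")))
    writeComponentSummary(networkComponents(u)[c("nComponents",
                                                 "lccGenes",
                                                 "componentSizes")],
                          out(paste0(st, "_unique_components.json")))
    cmpFiles <- c(cmpFiles, out(paste0(st, c("_unique.tsv",
                                             "_unique_components.json"))))
  }
  run <- stageLog(run, "compare", t0, cmpFiles)

  ## ---- bootstrap null tests of unique-subnetwork LCC sizes
  t0 <- as.numeric(Sys.time())
  nullFiles <- character()
  for (st in names(uniques)) {
    if (nEdges(uniques[[st]]) == 0L) next
    res <- lccNullTest(networks[[st]], subset = uniques[[st]],
                       nSims = config$nullModel$nSims,
                       seed = deriveSeed(config$seed, paste0("null:", st)),
                       replace = isTRUE(config$nullModel$replace))
    writeNullResult(res, out(paste0(st, "_null.json")))
    nullFiles <- c(nullFiles, out(paste0(st, "_null.json")))
  }
  run <- stageLog(run, "nulltest", t0, nullFiles)

  ## ---- over-representation of unique-subnetwork genes
  t0 <- as.numeric(Sys.time())
  sets <- if (!is.null(config$gmt)) {
    readGMT(config$gmt)
  } else if (!is.null(truth) && length(truth@moduleAssignments)) {
    gs <- truthGeneSets(truth, universe,
                        seed = deriveSeed(config$seed, "decoys"))
    writeGMT(gs, out("gene_sets.gmt"))
    readGMT(out("gene_sets.gmt"))
  } else NULL
  enrFiles <- character()
  if (!is.null(sets)) {
    sig <- list()
    for (st in names(uniques)) {
      res <- enrichGenes(networkGenes(uniques[[st]]), sets, universe,
                         threshold = config$fdr)
      write.csv(res, out(paste0(st, "_enrichment.csv")), row.names = FALSE)
      enrFiles <- c(enrFiles, out(paste0(st, "_enrichment.csv")))
      sig[[st]] <- res$term[res$significant]
    }
    mem <- processMembership(sig)
    write.csv(mem$membership, out("process_membership.csv"),
              row.names = FALSE)
    write.csv(data.frame(combination = names(mem$combinationCounts),
                         n_terms = mem$combinationCounts,
                         row.names = NULL),
              out("process_combinations.csv"), row.names = FALSE)
    enrFiles <- c(enrFiles, out(c("process_membership.csv",
                                  "process_combinations.csv")))
  }
  run <- stageLog(run, "enrich", t0, enrFiles)

  ## ---- manifest with checksums of everything written
  files <- setdiff(list.files(config$outDir), "manifest.json")
  run$parameters <- list(
    filter = config$filter, inference = config$inference,
    nullModel = config$nullModel, fdr = config$fdr,
    simulation = if (is.null(config$counts))
      unclass(config$simulation) else NULL)
  run$files <- as.list(tools::md5sum(file.path(config$outDir,
                                               sort(files))))
  names(run$files) <- sort(files)
  jsonlite::write_json(run, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(run)
}
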