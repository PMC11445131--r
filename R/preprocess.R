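#' Read a count matrix and sample metadata into a SummarizedExperiment
#'
#' Supports a plain TSV dialect (first column the gene id, header row of
#' sample ids) and GCT v1.2 (lines \code{#1.2}, \code{rows<TAB>cols}, then a
#' Name/Description table). Metadata is a TSV with columns SAMPID, SEX and
#' either AGE_GROUP (Y/M/E) or AGE / decade brackets, which are mapped with
#' [mapAgeGroup()].
#'
#' Columns are restricted to samples present in the metadata (extra count
#' columns are dropped with a warning) and ordered as in the counts file.
#'
#' @param countsPath path to the counts TSV or GCT file.
#' @param metadataPath path to the sample-attribute TSV.
#' @param dialect "auto" (sniff the \code{#1.2} header), "tsv" or "gct".
#' @return a \linkS4class{SummarizedExperiment} with integer assay
#'   \code{counts} and colData columns SEX and AGE_GROUP.
#' @export
readCountMatrix <- function(countsPath, metadataPath,
                            dialect = c("auto", "tsv", "gct")) {
  dialect <- match.arg(dialect)
  if (!file.exists(countsPath)) stop("counts file not found: ", countsPath)
  if (!file.exists(metadataPath))
    stop("metadata file not found: ", metadataPath)
  if (dialect == "auto")
    dialect <- if (startsWith(readLines(countsPath, n = 1L), "#1.2"))
      "gct" else "tsv"
  skip <- if (dialect == "gct") 2L else 0L
  tab <- read.delim(countsPath, header = TRUE, sep = "\t", skip = skip,
                    check.names = FALSE, stringsAsFactors = FALSE)
  dropCols <- if (dialect == "gct") 2L else 1L
  geneIds <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -seq_len(dropCols), drop = FALSE])
  if (anyDuplicated(geneIds))
    stop("format error: duplicated gene ids: ",
         paste(unique(geneIds[duplicated(geneIds)]), collapse = ", "))
  if (anyDuplicated(colnames(m)))
    stop("format error: duplicated sample ids: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (!is.numeric(m) || any(is.na(m)) || any(m < 0))
    stop("format error: counts must be non-negative numbers")
  rownames(m) <- geneIds

  meta <- readSampleMetadata(metadataPath)
  missing <- setdiff(colnames(m), meta$SAMPID)
  if (length(missing)) {
    warning("dropping ", length(missing),
            " sample(s) absent from metadata: ",
            paste(missing, collapse = ", "))
    m <- m[, setdiff(colnames(m), missing), drop = FALSE]
  }
  meta <- meta[match(colnames(m), meta$SAMPID), , drop = FALSE]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m),
    colData = S4Vectors::DataFrame(SEX = meta$SEX,
                                   AGE_GROUP = meta$AGE_GROUP,
                                   row.names = colnames(m)))
}

#' Read a sample-attribute table
#'
#' @param path TSV with columns SAMPID, SEX and AGE_GROUP (or AGE).
#' @param ageMapping passed to [mapAgeGroup()] when AGE_GROUP is absent.
#' @return data.frame with columns SAMPID, SEX, AGE_GROUP.
#' @export
readSampleMetadata <- function(path, ageMapping = defaultAgeMapping()) {
  meta <- read.delim(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("SAMPID", "SEX") %in% colnames(meta)))
    stop("format error: metadata needs columns SAMPID and SEX")
  meta$SAMPID <- as.character(meta$SAMPID)
  if (anyDuplicated(meta$SAMPID))
    stop("format error: duplicated sample ids in metadata: ",
         paste(unique(meta$SAMPID[duplicated(meta$SAMPID)]), collapse = ", "))
  if (!all(meta$SEX %in% c("F", "M")))
    stop("format error: SEX must be 'F' or 'M'")
  if (!"AGE_GROUP" %in% colnames(meta)) {
    if (!"AGE" %in% colnames(meta))
      stop("format error: metadata needs AGE_GROUP or AGE")
    meta$AGE_GROUP <- mapAgeGroup(meta$AGE, ageMapping,
                                  samples = meta$SAMPID)
  }
  if (!all(meta$AGE_GROUP %in% c("Y", "M", "E"))) {
    meta$AGE_GROUP <- mapAgeGroup(meta$AGE_GROUP, ageMapping,
                                  samples = meta$SAMPID)
  }
  meta[, c("SAMPID", "SEX", "AGE_GROUP")]
}

#' Map ages or decade brackets to the three age groups
#'
#' Default mapping: Y (young, 20-39), M (middle-aged, 40-59), E (elderly,
#' 60+). Decade bracket strings ("20-29" ... "70-79") are mapped by their
#' lower bound; numeric ages directly. The mapping is configurable because
#' the boundary between "elderly" cohort definitions (60-70) and decade
#' brackets (60-69, 70-79) is a study choice.
#'
#' @param x character brackets, Y/M/E labels, or numeric ages.
#' @param mapping named character vector bracket -> group, see
#'   \code{defaultAgeMapping()}.
#' @param samples optional sample ids used in error messages.
#' @return character vector of "Y"/"M"/"E".
#' @export
mapAgeGroup <- function(x, mapping = defaultAgeMapping(), samples = NULL) {
  x <- as.character(x)
  out <- ifelse(x %in% c("Y", "M", "E"), x, unname(mapping[x]))
  num <- is.na(out) & grepl("^[0-9]+(\\.[0-9]+)?$", x)
  if (any(num)) {
    age <- as.numeric(x[num])
    out[num] <- ifelse(age < 40, "Y", ifelse(age < 60, "M", "E"))
  }
  if (anyNA(out)) {
    bad <- which(is.na(out))
    who <- if (!is.null(samples)) samples[bad] else x[bad]
    stop("mapping error: unmapped age value(s) for: ",
         paste(unique(who), collapse = ", "))
  }
  out
}

#' @rdname mapAgeGroup
#' @export
defaultAgeMapping <- function() {
  c("20-29" = "Y", "30-39" = "Y",
    "40-49" = "M", "50-59" = "M",
    "60-69" = "E", "70-79" = "E")
}

#' Filter lowly expressed genes
#'
#' Retains genes with mean count >= \code{meanThreshold} AND a fraction of
#' zero counts <= \code{maxZeroFraction}; both rules are evaluated on the
#' same input matrix across all samples (before any stratification), and
#' retained gene order is preserved. Defaults follow the usual bulk RNA-seq
#' practice of removing genes with mean < 10 or zeros in more than half the
#' samples.
#'
#' @param x a SummarizedExperiment or numeric gene x sample matrix of raw
#'   counts.
#' @param meanThreshold minimum mean count (>= 0).
#' @param maxZeroFraction maximum tolerated fraction of zero counts in
#'   [0, 1]; strictly greater removes the gene.
#' @return the input type, with failing gene rows removed.
#' @export
setGeneric("filterGenes",
           function(x, meanThreshold = 10, maxZeroFraction = 0.5)
             standardGeneric("filterGenes"))

#' @rdname filterGenes
setMethod("filterGenes", "matrix",
  function(x, meanThreshold = 10, maxZeroFraction = 0.5) {
    stopifnot(meanThreshold >= 0,
              maxZeroFraction >= 0, maxZeroFraction <= 1)
    if (nrow(x) == 0L || ncol(x) == 0L) stop("empty count matrix")
    keep <- rowMeans(x) >= meanThreshold &
      rowMeans(x == 0) <= maxZeroFraction
    if (!any(keep))
      stop("empty result: every gene was removed by the filters")
    x[keep, , drop = FALSE]
  })

#' @rdname filterGenes
setMethod("filterGenes", "SummarizedExperiment",
  function(x, meanThreshold = 10, maxZeroFraction = 0.5) {
    m <- SummarizedExperiment::assay(x, 1L)
    kept <- rownames(filterGenes(m, meanThreshold, maxZeroFraction))
    x[kept, ]
  })

#' Quantile-normalize an expression matrix
#'
#' Forces every column (sample) to share the reference distribution given by
#' the across-column mean of sorted values, preserving within-column rank
#' order. Tied values receive the mean of the reference values at their tied
#' rank positions, so the result does not depend on sort stability. A
#' single-column matrix is returned unchanged. Delegates to
#' \code{limma::normalizeQuantiles}.
#'
#' @param x a SummarizedExperiment or numeric matrix (genes x samples).
#' @return the input type with normalized values (assay \code{qnorm} added
#'   for a SummarizedExperiment).
#' @export
setGeneric("quantileNormalize", function(x) standardGeneric("quantileNormalize"))

#' @rdname quantileNormalize
setMethod("quantileNormalize", "matrix", function(x) {
  if (!is.numeric(x)) stop("format error: matrix must be numeric")
  if (ncol(x) < 1L) stop("quantile normalization needs >= 1 column")
  if (ncol(x) == 1L) return(x)
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
})

#' @rdname quantileNormalize
setMethod("quantileNormalize", "SummarizedExperiment", function(x) {
  SummarizedExperiment::assay(x, "qnorm") <-
    quantileNormalize(SummarizedExperiment::assay(x, 1L))
  x
})

#' Split an expression matrix into the six sex x age strata
#'
#' Every sample is assigned to exactly one stratum (FY, FM, FE, MY, MM, ME);
#' empty strata are returned as zero-column matrices. The union of the
#' outputs is the input, up to column order.
#'
#' @param x a SummarizedExperiment (colData SEX/AGE_GROUP; the \code{qnorm}
#'   assay is used when present) or a numeric matrix.
#' @param meta for a matrix input, a data.frame with SAMPID, SEX, AGE_GROUP
#'   covering every column.
#' @return named list of matrices, one per stratum in the order FY, FM, FE,
#'   MY, MM, ME.
#' @export
splitStrata <- function(x, meta = NULL) {
  if (is(x, "SummarizedExperiment")) {
    an <- if ("qnorm" %in% SummarizedExperiment::assayNames(x)) "qnorm" else 1L
    am <- assayAndMeta(x, assayName = an)
  } else am <- assayAndMeta(x, meta)
  m <- am$matrix; meta <- am$meta
  if (is.null(meta)) stop("sample metadata required to split strata")
  idx <- match(colnames(m), meta$SAMPID)
  if (anyNA(idx))
    stop("mapping error: no metadata for sample(s): ",
         paste(colnames(m)[is.na(idx)], collapse = ", "))
  sex <- meta$SEX[idx]; age <- meta$AGE_GROUP[idx]
  if (!all(sex %in% c("F", "M")) || !all(age %in% c("Y", "M", "E"))) {
    bad <- !(sex %in% c("F", "M")) | !(age %in% c("Y", "M", "E"))
    stop("mapping error: sample(s) with unmapped sex/age group: ",
         paste(colnames(m)[bad], collapse = ", "))
  }
  lab <- paste0(sex, age)
  out <- lapply(STRATA, function(st) m[, lab == st, drop = FALSE])
  names(out) <- STRATA
  empty <- STRATA[vapply(out, ncol, integer(1)) == 0L]
  if (length(empty))
    message("empty strata: ", paste(empty, collapse = ", "))
  out
}
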