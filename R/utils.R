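## Shared constants and small helpers.

## Canonical stratum order: sex (F before M) crossed with age group
## Y (young), M (middle-aged), E (elderly).
STRATA <- c("FY", "FM", "FE", "MY", "MM", "ME")

#' Derive a child seed from a root seed and a string key
#'
#' Deterministic 31-bit stream derivation: every randomised stage of the
#' pipeline draws its own seed from the root seed and a fixed key, so e.g.
#' adding a stratum to a simulation does not perturb the counts of the
#' others.
#'
#' @param seed integer root seed.
#' @param key character key naming the stream (e.g. "stratum:FY").
#' @return an integer in [0, 2^31 - 2].
#' @export
deriveSeed <- function(seed, key) {
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  s <- as.numeric(seed) %% m
  for (c in utf8ToInt(as.character(key)))
    s <- (s * 31 + c) %% m
  as.integer(s)
}

## Evaluate expr under a temporary RNG state seeded with `seed`.
withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr,
                   .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion",
                   .rng_sample_kind = "Rejection")
}

## Canonical "a|b" keys for unordered pairs given two character vectors.
pairKeys <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  paste(a, b, sep = "|")
}

## Extract the numeric matrix + stratum metadata from either a plain matrix
## (with optional meta) or a SummarizedExperiment (colData SEX / AGE_GROUP).
assayAndMeta <- function(x, meta = NULL, assayName = 1L) {
  if (is(x, "SummarizedExperiment")) {
    m <- SummarizedExperiment::assay(x, assayName)
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    if (is.null(meta) && all(c("SEX", "AGE_GROUP") %in% colnames(cd)))
      meta <- data.frame(SAMPID = colnames(m), SEX = cd$SEX,
                         AGE_GROUP = cd$AGE_GROUP, stringsAsFactors = FALSE)
    list(matrix = m, meta = meta)
  } else {
    list(matrix = as.matrix(x), meta = meta)
  }
}
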