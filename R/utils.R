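#' @importFrom methods new validObject is as setClass setGeneric setMethod setValidity show
#' @importFrom stats cor cutree dist hclust median p.adjust pt qnorm quantile
#'   rnorm runif sd var wilcox.test fisher.test lm pf rpois complete.cases
#'   as.dist setNames coef
#' @importFrom utils head combn
NULL

## Deterministic sub-seed derivation: one RNG stream per generator stage,
## keyed by a fixed label so adding a stage never perturbs earlier draws.
## All arithmetic stays below 2^31.
deriveSeed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(label) == 1L)
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483647 + 1)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

## round-half-up to `digits` decimals (Table-style presentation rounding,
## as opposed to round()'s round-half-even)
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

isSingleString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

isSingleNumber <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

## shared closed vocabularies for the probe annotation
ISLAND_RELATIONS <- c("Island", "Shore", "Shelf", "OpenSea")
GENE_REGIONS <- c("TSS200", "TSS1500", "5'UTR", "1stExon", "Body", "3'UTR")
PROMOTER_REGIONS <- c("TSS200", "TSS1500", "5'UTR", "1stExon")
GRADES <- c("NETG1", "NETG2", "NETG3", "NEC", "NA")
SAMPLE_ROLES <- c("tumor", "normal", "reference_cell")
AUTOSOMES <- paste0("chr", 1:22)

## row-wise means/variances that honour an NA mask
rowMeansMasked <- function(x) {
  n <- rowSums(!is.na(x))
  out <- rowSums(x, na.rm = TRUE) / n
  out[n == 0] <- NA_real_
  out
}

rowVarsMasked <- function(x) {
  n <- rowSums(!is.na(x))
  m <- rowMeansMasked(x)
  v <- rowSums((x - m)^2, na.rm = TRUE) / (n - 1)
  v[n < 2] <- NA_real_
  v
}
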