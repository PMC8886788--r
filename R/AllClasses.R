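#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' BetaMatrix: methylation beta values with a missing-value mask
#'
#' The central measurement container: a probes x samples matrix of
#' methylation beta values (fraction methylated, in \[0, 1\]) stored as the
#' `"beta"` assay of a [SummarizedExperiment::SummarizedExperiment].
#' Missing values (detection failures) are represented as `NA`, never as
#' sentinel numbers; every downstream statistic uses complete-case or
#' pairwise-complete deletion as documented per function.
#'
#' @slot ... inherits all slots from `SummarizedExperiment`; the single
#'   assay is named `"beta"`.
#' @seealso [BetaMatrix()], [betaValues()], [betaToMValue()]
#' @exportClass BetaMatrix
setClass("BetaMatrix", contains = "SummarizedExperiment")

setValidity("BetaMatrix", function(object) {
  a <- SummarizedExperiment::assayNames(object)
  if (!identical(a, "beta"))
    return("BetaMatrix must carry exactly one assay named 'beta'")
  v <- SummarizedExperiment::assay(object, "beta")
  if (!is.numeric(v)) return("beta values must be numeric")
  bad <- which(!is.na(v) & (v < 0 | v > 1))
  if (length(bad))
    return(sprintf("%d beta value(s) outside [0, 1]", length(bad)))
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("probe (row) and sample (column) names are required")
  if (anyDuplicated(rownames(v))) return("duplicate probe ids")
  if (anyDuplicated(colnames(v))) return("duplicate sample ids")
  TRUE
})

#' MValueMatrix: log2-scale methylation values
#'
#' Result of the beta-to-M logit transform ([betaToMValue()]):
#' `M = log2(beta' / (1 - beta'))` with clipping, so all unmasked entries
#' are finite. Same axes as the source [BetaMatrix].
#'
#' @exportClass MValueMatrix
setClass("MValueMatrix", contains = "SummarizedExperiment")

setValidity("MValueMatrix", function(object) {
  a <- SummarizedExperiment::assayNames(object)
  if (!identical(a, "M"))
    return("MValueMatrix must carry exactly one assay named 'M'")
  v <- SummarizedExperiment::assay(object, "M")
  if (any(!is.na(v) & !is.finite(v)))
    return("unmasked M-values must be finite")
  TRUE
})

#' ConsensusResult: output of resampling consensus clustering
#'
#' @slot k cluster count used for the final cut.
#' @slot consensus symmetric sample x sample matrix of co-clustering
#'   frequencies in \[0, 1\] with unit diagonal.
#' @slot labels integer cluster assignment per sample (named, values 1..k).
#' @slot reps number of resampling repetitions.
#' @slot pItem fraction of samples drawn per repetition.
#' @slot seed RNG seed used.
#' @exportClass ConsensusResult
setClass("ConsensusResult",
  representation(k = "integer", consensus = "matrix", labels = "integer",
                 reps = "integer", pItem = "numeric", seed = "integer"))

setValidity("ConsensusResult", function(object) {
  m <- object@consensus
  if (!isSymmetric(unname(m))) return("consensus matrix must be symmetric")
  if (any(m < -1e-12 | m > 1 + 1e-12)) return("consensus entries outside [0, 1]")
  if (any(abs(diag(m) - 1) > 1e-12)) return("consensus diagonal must be 1")
  if (length(object@labels) != nrow(m))
    return("one label per sample required")
  if (!all(seq_len(object@k) %in% object@labels))
    return("each cluster in 1..k must be used at least once")
  TRUE
})

setMethod("show", "ConsensusResult", function(object) {
  cat(sprintf("ConsensusResult: %d samples, k = %d, reps = %d (pItem = %.2f)\n",
              nrow(object@consensus), object@k, object@reps, object@pItem))
  cat("cluster sizes:", paste(table(object@labels), collapse = ", "), "\n")
})

#' ReferenceAtlas: design matrix for cell-type deconvolution
#'
#' Mean reference methylation per cell type at a set of discriminating
#' probes; the design matrix `A` of the NNLS deconvolution. Entries are in
#' \[0, 1\] and complete (probes with a fully masked cell type are dropped
#' at build time).
#'
#' @slot profiles numeric matrix, probes x cell types.
#' @exportClass ReferenceAtlas
setClass("ReferenceAtlas", representation(profiles = "matrix"))

setValidity("ReferenceAtlas", function(object) {
  a <- object@profiles
  if (anyNA(a)) return("atlas must have no masked entries")
  if (any(a < 0 | a > 1)) return("atlas entries must be in [0, 1]")
  if (ncol(a) < 2) return("atlas needs at least two cell types")
  if (is.null(colnames(a)) || anyDuplicated(colnames(a)))
    return("unique cell-type column labels required")
  if (is.null(rownames(a)) || anyDuplicated(rownames(a)))
    return("unique probe row labels required")
  TRUE
})

setMethod("show", "ReferenceAtlas", function(object) {
  cat(sprintf("ReferenceAtlas: %d probes x %d cell types (%s)\n",
              nrow(object@profiles), ncol(object@profiles),
              paste(colnames(object@profiles), collapse = ", ")))
})

#' SampleDistance: pairwise distances between methylation profiles
#'
#' @slot d symmetric nonnegative distance matrix with zero diagonal.
#' @slot metric `"pearson"` (1 - r) or `"euclidean"`.
#' @slot nUsed matrix of pairwise-complete probe counts per pair.
#' @exportClass SampleDistance
setClass("SampleDistance",
  representation(d = "matrix", metric = "character", nUsed = "matrix"))

setValidity("SampleDistance", function(object) {
  d <- object@d
  if (!isSymmetric(unname(d))) return("distance matrix must be symmetric")
  if (any(d < -1e-12)) return("distances must be nonnegative")
  if (any(abs(diag(d)) > 1e-9)) return("diagonal must be zero")
  if (!object@metric %in% c("pearson", "euclidean"))
    return("metric must be 'pearson' or 'euclidean'")
  if (object@metric == "pearson" && any(d > 2 + 1e-9))
    return("pearson distances must lie in [0, 2]")
  TRUE
})

setMethod("show", "SampleDistance", function(object) {
  cat(sprintf("SampleDistance (%s): %d samples, probes used per pair %d-%d\n",
              object@metric, nrow(object@d),
              min(object@nUsed[upper.tri(object@nUsed)]),
              max(object@nUsed[upper.tri(object@nUsed)])))
})

## ---- constructors and accessors ----

#' Construct a BetaMatrix
#'
#' @param values numeric matrix of beta values with probe rownames and
#'   sample colnames; `NA` marks masked (missing) entries.
#' @return A [BetaMatrix-class] object.
#' @examples
#' m <- matrix(c(0.1, 0.9, 0.5, NA), 2, 2,
#'             dimnames = list(c("cg1", "cg2"), c("s1", "s2")))
#' b <- BetaMatrix(m)
#' betaValues(b)
#' @export
BetaMatrix <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  se <- SummarizedExperiment::SummarizedExperiment(assays = list(beta = values))
  new("BetaMatrix", se)
}

#' Construct an MValueMatrix
#'
#' Usually produced by [betaToMValue()] rather than directly.
#' @param values numeric matrix of M-values (finite where unmasked).
#' @return An [MValueMatrix-class] object.
#' @export
MValueMatrix <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  se <- SummarizedExperiment::SummarizedExperiment(assays = list(M = values))
  new("MValueMatrix", se)
}

#' Accessors for methylation matrices
#'
#' `betaValues()`/`mValues()` return the value matrix (`NA` = masked),
#' `probeIds()`/`sampleIds()` the axis labels, and `maskMatrix()` the
#' logical missingness mask.
#'
#' @param x a [BetaMatrix-class] or [MValueMatrix-class].
#' @return matrix or character vector as appropriate.
#' @name methylation-accessors
NULL

#' @rdname methylation-accessors
#' @export
betaValues <- function(x) {
  stopifnot(is(x, "BetaMatrix"))
  SummarizedExperiment::assay(x, "beta")
}

#' @rdname methylation-accessors
#' @export
mValues <- function(x) {
  stopifnot(is(x, "MValueMatrix"))
  SummarizedExperiment::assay(x, "M")
}

#' @rdname methylation-accessors
#' @export
probeIds <- function(x) rownames(x)

#' @rdname methylation-accessors
#' @export
sampleIds <- function(x) colnames(x)

#' @rdname methylation-accessors
#' @export
maskMatrix <- function(x) {
  is.na(SummarizedExperiment::assay(x, 1L))
}

#' Accessors for ConsensusResult
#' @param x a [ConsensusResult-class].
#' @return `consensusMatrix()` the co-clustering frequency matrix;
#'   `clusterLabels()` the named integer assignment vector.
#' @export
consensusMatrix <- function(x) {
  stopifnot(is(x, "ConsensusResult"))
  x@consensus
}

#' @rdname consensusMatrix
#' @export
clusterLabels <- function(x) {
  stopifnot(is(x, "ConsensusResult"))
  x@labels
}

#' Accessors for ReferenceAtlas
#' @param x a [ReferenceAtlas-class].
#' @return `atlasMatrix()` the probes x cell-types design matrix;
#'   `cellTypes()` its column labels; `atlasProbes()` its row labels.
#' @export
atlasMatrix <- function(x) {
  stopifnot(is(x, "ReferenceAtlas"))
  x@profiles
}

#' @rdname atlasMatrix
#' @export
cellTypes <- function(x) colnames(atlasMatrix(x))

#' @rdname atlasMatrix
#' @export
atlasProbes <- function(x) rownames(atlasMatrix(x))

#' Accessors for SampleDistance
#' @param x a [SampleDistance-class].
#' @return `distanceValues()` the symmetric distance matrix;
#'   `distanceMetric()` the metric name.
#' @export
distanceValues <- function(x) {
  stopifnot(is(x, "SampleDistance"))
  x@d
}

#' @rdname distanceValues
#' @export
distanceMetric <- function(x) x@metric
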