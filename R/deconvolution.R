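## Reference-atlas cell-type deconvolution by non-negative least squares.
## The atlas (mean reference beta per cell type at discriminating probes)
## is the design matrix; per tumor, nonnegative weights are fit by the
## Lawson-Hanson active-set algorithm and normalized to signature
## proportions.

#' Lawson-Hanson non-negative least squares
#'
#' Solves `min ||A x - b||_2` subject to `x >= 0` by the classic
#' active-set method. At convergence the KKT conditions hold to `tol`:
#' gradient components vanish where `x > 0` and are nonnegative where
#' `x = 0`.
#'
#' @param A numeric matrix (m x n), m >= 1.
#' @param b numeric vector of length m.
#' @param tol convergence tolerance on the dual vector (default 1e-10).
#' @return list with `x` (nonnegative coefficients), `residual_norm`.
#' @export
nnlsFit <- function(A, b, tol = 1e-10) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  stopifnot(nrow(A) == length(b))
  n <- ncol(A)
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- drop(crossprod(A, b - A %*% x))
  iter <- 0L
  maxIter <- 30L * n
  while (any(!passive) && any(w[!passive] > tol) && iter < maxIter) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      z <- numeric(n)
      z[P] <- qr.coef(qr(A[, P, drop = FALSE]), b)
      z[P][is.na(z[P])] <- 0  # rank-deficient passive set
      if (all(z[P] > tol)) break
      Q <- P[z[P] <= tol]
      alpha <- min(x[Q] / (x[Q] - z[Q]))
      x <- x + alpha * (z - x)
      passive[x <= tol & passive] <- FALSE
      x[!passive] <- 0
      if (!any(passive)) { z <- numeric(n); break }
    }
    x <- z
    w <- drop(crossprod(A, b - A %*% x))
  }
  list(x = pmax(x, 0), residual_norm = sqrt(sum((A %*% pmax(x, 0) - b)^2)))
}

#' Build the cell-type reference atlas
#'
#' Per cell type and probe, the mean of unmasked replicate beta values.
#' Probes with a fully masked cell type are dropped (logged). Column order
#' follows the sheet order of first appearance.
#'
#' @param b reference [BetaMatrix-class].
#' @param sheet sample sheet; `reference_cell` rows define the types.
#' @param probes atlas probe ids, typically [callReferenceDmps()] output
#'   or an externally supplied discriminating probe list.
#' @return a [ReferenceAtlas-class].
#' @export
buildAtlas <- function(b, sheet, probes) {
  stopifnot(is(b, "BetaMatrix"))
  ref <- sheet[sheet$role == "reference_cell", , drop = FALSE]
  types <- unique(ref$cell_type)
  if (length(types) < 2) stop("need at least two cell types")
  probes <- intersect(probes, probeIds(b))
  v <- betaValues(b)[probes, , drop = FALSE]
  A <- vapply(types, function(t)
    rowMeansMasked(v[, ref$sample_id[ref$cell_type == t], drop = FALSE]),
    numeric(length(probes)))
  rownames(A) <- probes
  drop <- rowSums(is.na(A)) > 0
  if (any(drop))
    message(sum(drop), " probe(s) dropped: fully masked in some cell type")
  new("ReferenceAtlas", profiles = A[!drop, , drop = FALSE])
}

#' NNLS deconvolution of one sample against the atlas
#'
#' Restricts atlas and sample to the probes unmasked in the sample
#' (pairwise-complete), requires at least `max(10, 2 * n_cell_types)` of
#' them, and solves the nonnegative least-squares problem; proportions are
#' the normalized weights. A fit with all-zero weights is flagged
#' degenerate (proportions undefined).
#'
#' @param atlas a [ReferenceAtlas-class].
#' @param b a [BetaMatrix-class] containing the sample.
#' @param sampleId sample to deconvolve.
#' @return one-row data.frame: sample_id, one proportion column per cell
#'   type, residual_norm, n_probes_used, degenerate.
#' @export
nnlsDeconvolve <- function(atlas, b, sampleId) {
  stopifnot(is(atlas, "ReferenceAtlas"), is(b, "BetaMatrix"))
  if (!sampleId %in% sampleIds(b)) stop("unknown sample: ", sampleId)
  A <- atlasMatrix(atlas)
  common <- intersect(rownames(A), probeIds(b))
  y <- betaValues(b)[common, sampleId]
  keep <- !is.na(y)
  need <- max(10, 2 * ncol(A))
  if (sum(keep) < need)
    stop("sample ", sampleId, ": only ", sum(keep),
         " usable atlas probes (need >= ", need, ")")
  fit <- nnlsFit(A[common, , drop = FALSE][keep, , drop = FALSE], y[keep])
  x <- fit$x
  degenerate <- sum(x) <= 0
  p <- if (degenerate) rep(NA_real_, length(x)) else x / sum(x)
  out <- data.frame(sample_id = sampleId, t(p),
                    residual_norm = fit$residual_norm,
                    n_probes_used = sum(keep), degenerate = degenerate,
                    stringsAsFactors = FALSE)
  colnames(out)[1 + seq_along(p)] <- colnames(A)
  out
}

#' Deconvolve every sample of a matrix
#'
#' @inheritParams nnlsDeconvolve
#' @return data.frame with one [nnlsDeconvolve()] row per sample.
#' @export
deconvolveCohort <- function(atlas, b) {
  do.call(rbind, lapply(sampleIds(b), function(s) nnlsDeconvolve(atlas, b, s)))
}

#' Compare signature proportions between groups
#'
#' Per cell type and unordered group pair, a two-sample Wilcoxon rank-sum
#' test on the proportions; BH correction across the full comparison
#' family. Groups whose results are all degenerate are excluded (logged).
#'
#' @param results [deconvolveCohort()] output.
#' @param labels group label per sample (named by sample id).
#' @return data.frame(cell_type, group1, group2, n1, n2, p_value, q_value).
#' @export
compareGroupProportions <- function(results, labels) {
  types <- setdiff(colnames(results),
                   c("sample_id", "residual_norm", "n_probes_used",
                     "degenerate"))
  res <- results[!results$degenerate, , drop = FALSE]
  grp <- labels[res$sample_id]
  if (anyNA(grp)) stop("labels must cover every non-degenerate sample")
  sizes <- table(grp)
  usable <- names(sizes)[sizes >= 2]
  if (length(usable) < length(sizes))
    message("excluding group(s) with < 2 non-degenerate results: ",
            paste(setdiff(names(sizes), usable), collapse = ", "))
  if (length(usable) < 2) stop("need >= 2 groups with >= 2 results")
  rows <- list()
  for (ct in types) {
    for (pair in combn(sort(usable), 2, simplify = FALSE)) {
      x <- res[[ct]][grp == pair[1]]
      y <- res[[ct]][grp == pair[2]]
      wt <- wilcoxonRankSum(x, y, mode = "auto")
      rows[[length(rows) + 1L]] <- data.frame(
        cell_type = ct, group1 = pair[1], group2 = pair[2],
        n1 = length(x), n2 = length(y), p_value = wt$p_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q_value <- bhAdjust(out$p_value)
  out
}
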