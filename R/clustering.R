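## Unsupervised class discovery: most-variable probe selection, Monti-style
## resampling consensus clustering, delta-area k selection, and the
## two-cluster mean-difference / promoter analysis.

#' Select the most variable probes
#'
#' Returns the `k` probes with the largest standard deviation of unmasked
#' beta values across samples, ordered by descending sd; ties are broken
#' by probe-id lexicographic order. The conventional feature filter before
#' class discovery (the "10K most variable probes").
#'
#' @param b a [BetaMatrix-class].
#' @param k number of probes to keep (default 10000).
#' @return character vector of probe ids (a probe set).
#' @export
selectVariableProbes <- function(b, k = 10000) {
  stopifnot(is(b, "BetaMatrix"))
  v <- betaValues(b)
  sds <- sqrt(rowVarsMasked(v))
  eligible <- which(!is.na(sds))
  if (k > length(eligible))
    stop("k = ", k, " exceeds the ", length(eligible),
         " probes with >= 2 unmasked values")
  ord <- eligible[order(-sds[eligible], rownames(v)[eligible])]
  rownames(v)[ord[seq_len(k)]]
}

#' Resampling consensus clustering
#'
#' Monti-style procedure: in each repetition a fraction `pItem` of samples
#' is drawn without replacement and clustered by average-linkage
#' hierarchical clustering on 1 - Pearson correlation over the probe set,
#' cut at `k`. The consensus index of a sample pair is the fraction of
#' co-sampled repetitions in which it co-clustered (0/0 counted as 0,
#' diagonal fixed at 1). Final labels come from average-linkage clustering
#' of 1 - consensus cut at `k`. Deterministic given `seed`.
#'
#' @param b a [BetaMatrix-class].
#' @param probes probe ids to cluster on (e.g. [selectVariableProbes()]).
#' @param k cluster count, `2 <= k < n` samples.
#' @param reps resampling repetitions (default 1000).
#' @param pItem fraction of samples per repetition (default 0.8).
#' @param seed RNG seed.
#' @return a [ConsensusResult-class].
#' @export
consensusCluster <- function(b, probes, k, reps = 1000, pItem = 0.8, seed = 1) {
  stopifnot(is(b, "BetaMatrix"))
  v <- betaValues(b)[probes, , drop = FALSE]
  n <- ncol(v)
  if (k < 2 || k >= n) stop("need 2 <= k < n samples")
  if (reps < 1) stop("reps must be >= 1")
  nSub <- ceiling(pItem * n)
  if (nSub < k) stop("pItem too small: resamples have fewer than k samples")
  co <- matrix(0, n, n)
  cnt <- matrix(0, n, n)
  withSeed(seed, {
    for (r in seq_len(reps)) {
      idx <- sort(sample.int(n, nSub))
      cc <- suppressWarnings(cor(v[, idx, drop = FALSE],
                                 use = "pairwise.complete.obs"))
      cc[!is.finite(cc)] <- 0
      cl <- cutree(hclust(as.dist(1 - cc), method = "average"), k)
      same <- outer(cl, cl, "==")
      co[idx, idx] <- co[idx, idx] + same
      cnt[idx, idx] <- cnt[idx, idx] + 1
    }
  })
  cons <- ifelse(cnt > 0, co / pmax(cnt, 1), 0)
  diag(cons) <- 1
  dimnames(cons) <- list(colnames(v), colnames(v))
  labels <- cutree(hclust(as.dist(1 - cons), method = "average"), k)
  new("ConsensusResult", k = as.integer(k), consensus = cons,
      labels = as.integer(labels) |> setNames(colnames(v)),
      reps = as.integer(reps), pItem = pItem, seed = as.integer(seed))
}

## area under the ECDF of off-diagonal consensus entries on [0, 1];
## equals 1 - mean(entries)
consensusCdfArea <- function(res) {
  m <- consensusMatrix(res)
  1 - mean(m[upper.tri(m)])
}

#' Choose the cluster count from consensus results
#'
#' For consecutive `k` the area under the empirical CDF of off-diagonal
#' consensus entries is computed (for entries on \[0, 1\] this integral
#' equals 1 minus the mean entry). Scanning k upward, values of k are
#' considered only while the relative area increase over `k - 1` stays at
#' or above `threshold`: the scan stops at the first increase below the
#' threshold, because beyond the true cluster count forced splits become
#' unstable under resampling and the area resumes growing for purely
#' mechanical reasons. The chosen `k` is the one with the largest relative
#' increase within the considered prefix; when no increase reaches the
#' threshold (no structure beyond `kmin`, e.g. identical or all-ones
#' consensus at every `k`), `kmin` is returned. Deterministic.
#'
#' @param results list of [ConsensusResult-class] over consecutive k
#'   starting at `kmin >= 2`.
#' @param threshold minimum relative area increase (default 0.1).
#' @return the chosen integer k.
#' @export
chooseK <- function(results, threshold = 0.1) {
  if (length(results) < 2) stop("need consensus results for at least two k")
  ks <- vapply(results, function(r) r@k, 0L)
  if (any(diff(ks) != 1L)) stop("k values must be consecutive")
  areas <- vapply(results, consensusCdfArea, 0)
  rel <- diff(areas) / ifelse(areas[-length(areas)] > 0,
                              areas[-length(areas)], Inf)
  rel[!is.finite(rel)] <- 0
  below <- which(rel < threshold)
  last <- if (length(below)) below[1] - 1L else length(rel)
  if (last < 1L) return(ks[1])
  ks[-1][which.max(rel[seq_len(last)])]
}

#' Two-cluster mean methylation differences with promoter filter
#'
#' For exactly two clusters, computes per-probe cluster mean beta values
#' over unmasked entries and keeps probes whose absolute mean difference
#' reaches `cutoff` (default 0.4); with `promoterOnly` the probe must also
#' carry a promoter gene-region feature (TSS200, TSS1500, 5'UTR, 1stExon).
#' Rows are sorted by descending absolute difference.
#'
#' @param b a [BetaMatrix-class].
#' @param labels two-level cluster assignment named by sample id.
#' @param ann probe-annotation `GRanges` (see [readProbeAnnotation()]).
#' @param cutoff minimum absolute mean difference (default 0.4).
#' @param promoterOnly keep promoter-associated probes only.
#' @return data.frame(probe_id, mean_beta_cluster1, mean_beta_cluster2,
#'   abs_difference, gene, gene_region, promoter_flag).
#' @export
clusterMeanDifference <- function(b, labels, ann, cutoff = 0.4,
                                  promoterOnly = FALSE) {
  stopifnot(is(b, "BetaMatrix"))
  labs <- labels[sampleIds(b)]
  if (anyNA(labs)) stop("labels must cover every sample")
  lev <- sort(unique(labs))
  if (length(lev) != 2)
    stop("labels define ", length(lev),
         " clusters; binarize to exactly two before calling")
  v <- betaValues(b)
  m1 <- rowMeansMasked(v[, labs == lev[1], drop = FALSE])
  m2 <- rowMeansMasked(v[, labs == lev[2], drop = FALSE])
  d <- abs(m1 - m2)
  ids <- probeIds(b)
  gene <- setNames(ann$gene, names(ann))[ids]
  region <- setNames(ann$gene_region, names(ann))[ids]
  promoter <- vapply(strsplit(ifelse(is.na(region), "", region), ";",
                              fixed = TRUE),
                     function(r) any(r %in% PROMOTER_REGIONS), TRUE)
  keep <- !is.na(d) & d >= cutoff
  if (promoterOnly) keep <- keep & promoter
  out <- data.frame(probe_id = ids, mean_beta_cluster1 = m1,
                    mean_beta_cluster2 = m2, abs_difference = d,
                    gene = ifelse(is.na(gene), "", gene),
                    gene_region = ifelse(is.na(region), "", region),
                    promoter_flag = promoter,
                    stringsAsFactors = FALSE, row.names = NULL)[keep, ]
  out[order(-out$abs_difference, out$probe_id), , drop = FALSE]
}
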