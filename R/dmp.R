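## Per-probe two-group differential methylation and the elementary tests
## used throughout (Wilcoxon rank-sum, Fisher's exact, BH correction).
## Tests run on M-values; effect sizes are reported on beta-scale group
## means (delta beta and a stabilized log2 fold change).

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction with monotonicity enforcement
#' (via [stats::p.adjust]); input order is preserved.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return vector of q-values, same order.
#' @export
bhAdjust <- function(p) {
  if (!is.numeric(p) || any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Two-sample Wilcoxon rank-sum test
#'
#' `mode = "auto"` uses exact enumeration when `n_x + n_y <= 20` and there
#' are no ties, otherwise the normal approximation with tie and continuity
#' correction (the behaviour of [stats::wilcox.test], which performs the
#' computation).
#'
#' @param x,y numeric samples (non-empty).
#' @param mode `"exact"`, `"normal"` or `"auto"`.
#' @return list with `statistic` (Mann-Whitney U for `x`) and `p_value`
#'   (two-sided).
#' @export
wilcoxonRankSum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(mode,
    auto = (length(x) + length(y) <= 20) && !ties,
    exact = TRUE,
    normal = FALSE)
  if (exact && ties) {
    warning("ties present; falling back to the normal approximation")
    exact <- FALSE
  }
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value as the sum of hypergeometric point probabilities not
#' exceeding that of the observed table (the standard convention,
#' computed by [stats::fisher.test] in log space).
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return two-sided p-value.
#' @export
fisherExactTest <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2)) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be nonnegative integers")
  if (sum(tab) == 0) stop("table total must be positive")
  fisher.test(tab)$p.value
}

#' Per-probe differential methylation test
#'
#' Welch-type t-test on M-values per probe. With `shrink = TRUE` (the
#' default) per-probe variances are moderated by a simple empirical-Bayes
#' scheme: the pooled per-probe variance is shrunk toward the median
#' pooled variance `s0` with 4 prior degrees of freedom, and the statistic
#' uses `n1 + n2 - 2 + 4` degrees of freedom. This is what makes the 2-3
#' replicate reference-cell contrasts usable. Without shrinkage a plain
#' Welch test (Satterthwaite df) is run. Effect sizes are computed on
#' beta-scale group means: `delta_beta = mean1 - mean2` and
#' `log2fc = log2((mean1 + 0.01) / (mean2 + 0.01))`.
#'
#' Probes with fewer than two unmasked values in either group are skipped
#' (reported via a message).
#'
#' @param b a [BetaMatrix-class].
#' @param group1,group2 disjoint sample-id vectors.
#' @param shrink moderate variances (default TRUE).
#' @param clip clipping bound for the M-value transform.
#' @return data.frame with columns probe_id, mean_beta_g1, mean_beta_g2,
#'   delta_beta, log2fc, t_stat, p_value, q_value, class (`NA` until
#'   [classifyTumorDmps()] is applied).
#' @export
dmpTest <- function(b, group1, group2, shrink = TRUE, clip = 0.001) {
  stopifnot(is(b, "BetaMatrix"))
  if (length(intersect(group1, group2)))
    stop("groups must be disjoint")
  miss <- setdiff(c(group1, group2), sampleIds(b))
  if (length(miss)) stop("unknown sample id(s): ", paste(miss, collapse = ", "))
  v <- betaValues(b)
  M <- mValues(betaToMValue(b, clip))
  m1i <- M[, group1, drop = FALSE]; m2i <- M[, group2, drop = FALSE]
  n1 <- rowSums(!is.na(m1i)); n2 <- rowSums(!is.na(m2i))
  ok <- n1 >= 2 & n2 >= 2
  if (!all(ok))
    message(sum(!ok), " probe(s) skipped: fewer than 2 unmasked values ",
            "in a group")
  mu1 <- rowMeansMasked(m1i); mu2 <- rowMeansMasked(m2i)
  v1 <- rowVarsMasked(m1i); v2 <- rowVarsMasked(m2i)
  if (shrink) {
    df0 <- 4
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    s0 <- median(sp[ok], na.rm = TRUE)
    smod <- (df0 * s0 + (n1 + n2 - 2) * sp) / (df0 + n1 + n2 - 2)
    tstat <- (mu1 - mu2) / sqrt(smod * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2 + df0
  } else {
    se2 <- v1 / n1 + v2 / n2
    tstat <- (mu1 - mu2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  p <- 2 * pt(-abs(tstat), df)
  bm1 <- rowMeansMasked(v[, group1, drop = FALSE])
  bm2 <- rowMeansMasked(v[, group2, drop = FALSE])
  out <- data.frame(
    probe_id = probeIds(b), mean_beta_g1 = bm1, mean_beta_g2 = bm2,
    delta_beta = bm1 - bm2,
    log2fc = log2((bm1 + 0.01) / (bm2 + 0.01)),
    t_stat = tstat, p_value = p, q_value = NA_real_,
    class = NA_character_, stringsAsFactors = FALSE, row.names = NULL)
  out <- out[ok, , drop = FALSE]
  out$q_value <- bhAdjust(out$p_value)
  out
}

#' Classify DMP records by the volcano cut-offs
#'
#' `significant` requires both an adjusted p-value below `adjPCut`
#' (default 1e-5, i.e. -log10(q) > 5; a 1e-6 variant is available via the
#' argument) and `|log2fc|` above `lfcCut` (default 0.25); `fc_only` and
#' `p_only` mark records passing a single cut-off, `ns` the rest.
#'
#' @param records output of [dmpTest()] with `q_value` populated.
#' @param adjPCut adjusted-p threshold (default 1e-5).
#' @param lfcCut absolute log2 fold-change threshold (default 0.25).
#' @return `records` with the `class` column set.
#' @export
classifyTumorDmps <- function(records, adjPCut = 1e-5, lfcCut = 0.25) {
  if (anyNA(records$q_value)) stop("q_value must be populated")
  sig <- records$q_value < adjPCut
  fc <- abs(records$log2fc) > lfcCut
  records$class <- ifelse(sig & fc, "significant",
                   ifelse(fc, "fc_only", ifelse(sig, "p_only", "ns")))
  records
}

#' Call reference cell-type DMPs
#'
#' Runs the moderated [dmpTest()] for every unordered pair of cell types
#' in the reference sheet; a probe enters the output union if in some pair
#' its q-value is below `adjPCut` (default 0.01) and `|delta_beta|`
#' exceeds `deltaCut` (default 0.2). Cell types with fewer than two
#' replicates are excluded from pairing (logged). Output is sorted by
#' probe id.
#'
#' @param b reference [BetaMatrix-class].
#' @param sheet sample sheet with `reference_cell` rows.
#' @param adjPCut,deltaCut selection thresholds.
#' @return character vector of probe ids (the atlas probe set).
#' @export
callReferenceDmps <- function(b, sheet, adjPCut = 0.01, deltaCut = 0.2) {
  ref <- sheet[sheet$role == "reference_cell", , drop = FALSE]
  types <- split(ref$sample_id, ref$cell_type)
  small <- names(types)[vapply(types, length, 0L) < 2]
  if (length(small)) {
    message("excluding cell type(s) with < 2 replicates: ",
            paste(small, collapse = ", "))
    types <- types[!names(types) %in% small]
  }
  if (length(types) < 2) stop("need >= 2 cell types with >= 2 replicates")
  hits <- character(0)
  for (pair in combn(names(types), 2, simplify = FALSE)) {
    rec <- dmpTest(b, types[[pair[1]]], types[[pair[2]]], shrink = TRUE)
    sel <- rec$q_value < adjPCut & abs(rec$delta_beta) > deltaCut
    hits <- union(hits, rec$probe_id[sel])
  }
  sort(hits)
}

#' Mean methylation of a probe set per sample
#'
#' Per-sample arithmetic mean of unmasked beta values over the probe set
#' (e.g. CpG-island probes, or stem-cell-associated hyper/hypomethylated
#' sets). Samples with every probe masked get `NA` (logged).
#'
#' @param b a [BetaMatrix-class].
#' @param probes non-empty character vector of probe ids.
#' @return named numeric vector, one mean per sample.
#' @export
probeSetScore <- function(b, probes) {
  stopifnot(is(b, "BetaMatrix"), length(probes) > 0)
  v <- betaValues(b)[intersect(probes, probeIds(b)), , drop = FALSE]
  if (!nrow(v)) stop("none of the probes are present in the matrix")
  n <- colSums(!is.na(v))
  out <- colSums(v, na.rm = TRUE) / n
  if (any(n == 0)) {
    message("sample(s) with all probes masked: ",
            paste(colnames(v)[n == 0], collapse = ", "))
    out[n == 0] <- NA_real_
  }
  out
}

#' Overlap significant DMPs with cell-type marker genes
#'
#' Joins `significant` DMP records to a marker table (gene to cell type)
#' through the probe annotation. Marker genes absent from the annotation
#' are dropped with a warning.
#'
#' @param records classified DMP records ([classifyTumorDmps()]).
#' @param ann probe-annotation `GRanges`.
#' @param markers data.frame with columns `gene` and `cell_type`.
#' @return list with `table` (probe_id, gene, cell_type, class) and
#'   `counts` (per cell type: probes and distinct genes).
#' @export
markerOverlap <- function(records, ann, markers) {
  if (!nrow(markers)) stop("marker table must be non-empty")
  annGenes <- unique(ann$gene)
  missing <- setdiff(markers$gene, annGenes)
  if (length(missing)) {
    warning(length(missing), " marker gene(s) absent from annotation; dropped")
    markers <- markers[!markers$gene %in% missing, , drop = FALSE]
  }
  sig <- records[!is.na(records$class) & records$class == "significant", ,
                 drop = FALSE]
  gene <- setNames(ann$gene, names(ann))[sig$probe_id]
  tab <- data.frame(probe_id = sig$probe_id, gene = unname(gene),
                    class = sig$class, stringsAsFactors = FALSE)
  tab <- merge(tab, markers, by = "gene")[, c("probe_id", "gene",
                                              "cell_type", "class")]
  tab <- tab[order(tab$cell_type, tab$gene, tab$probe_id), , drop = FALSE]
  counts <- do.call(rbind, lapply(split(tab, tab$cell_type), function(d)
    data.frame(cell_type = d$cell_type[1], n_probes = nrow(d),
               n_genes = length(unique(d$gene)), stringsAsFactors = FALSE)))
  rownames(counts) <- NULL
  list(table = tab, counts = if (is.null(counts))
    data.frame(cell_type = character(), n_probes = integer(),
               n_genes = integer()) else counts)
}
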