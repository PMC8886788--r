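## Relative copy number from methylation-array intensities: per-probe log2
## ratios against a normal panel, genomic binning, circular binary
## segmentation with a permutation test, whole-chromosome calls and
## signatures, focal recurrence, and FISH-concordance regression.

#' Total array intensity
#'
#' Elementwise sum of the methylated and unmethylated channels; masked
#' where either channel is masked.
#'
#' @param meth,unmeth nonnegative intensity matrices with identical axes.
#' @return total-intensity matrix.
#' @export
totalIntensity <- function(meth, unmeth) {
  if (!identical(dimnames(meth), dimnames(unmeth)) ||
      !identical(dim(meth), dim(unmeth)))
    stop("channel axes must match")
  meth + unmeth
}

#' Per-probe log2 copy-number ratios against a normal panel
#'
#' Each sample is scaled so its median total intensity equals the grand
#' median of the normal panel; the per-probe reference is the median
#' across normals; the ratio is `log2(sample / reference)`. Probes whose
#' reference is zero or masked are masked.
#'
#' @param total total-intensity matrix (tumors and normals as columns).
#' @param normalIds ids of the >= 2 normal-panel columns.
#' @return matrix of per-probe log2 ratios for the non-normal columns.
#' @export
log2Ratio <- function(total, normalIds) {
  if (length(normalIds) < 2) stop("need >= 2 normal samples")
  if (!all(normalIds %in% colnames(total)))
    stop("normal ids absent from the intensity matrix")
  med <- apply(total, 2, median, na.rm = TRUE)
  grand <- median(med[normalIds])
  scaled <- sweep(total, 2, grand / med, "*")
  ref <- apply(scaled[, normalIds, drop = FALSE], 1, median, na.rm = TRUE)
  ref[!is.finite(ref) | ref <= 0] <- NA_real_
  tumorIds <- setdiff(colnames(total), normalIds)
  log2(scaled[, tumorIds, drop = FALSE] / ref)
}

#' Bin probe-level ratios into genomic windows
#'
#' Fixed windows of `binBp` base pairs are merged forward until they hold
#' at least `minProbes` unmasked probes; a trailing window failing the
#' floor is merged backward into its neighbour. The bin value is the
#' median probe ratio. Chromosomes with fewer than `minProbes` usable
#' probes are skipped (logged).
#'
#' @param ratios per-probe log2-ratio matrix ([log2Ratio()]).
#' @param ann probe-annotation `GRanges` covering all probes.
#' @param minProbes minimum unmasked probes per bin (default 15).
#' @param binBp window width in bp (default 5e6).
#' @return data.frame(sample_id, chromosome, bin, start, end, n_probes,
#'   log2_ratio); bins are non-overlapping and sorted within chromosome.
#' @export
binProbes <- function(ratios, ann, minProbes = 15, binBp = 5e6) {
  ids <- rownames(ratios)
  missing <- setdiff(ids, names(ann))
  if (length(missing)) stop("annotation missing ", length(missing), " probe(s)")
  ann <- ann[ids]
  chrom <- as.character(GenomicRanges::seqnames(ann))
  pos <- GenomicRanges::start(ann)
  win <- probeWindow(pos, binBp)
  out <- list()
  for (s in colnames(ratios)) {
    x <- ratios[, s]
    for (ch in unique(chrom)) {
      sel <- chrom == ch
      xs <- x[sel]; ws <- win[sel]; ps <- pos[sel]
      usable <- !is.na(xs)
      if (sum(usable) < minProbes) {
        message("chromosome ", ch, " skipped for ", s,
                ": fewer than ", minProbes, " usable probes")
        next
      }
      ## forward-merge fixed windows until each bin reaches the floor
      bins <- list(); cur <- integer(0)
      for (w in sort(unique(ws))) {
        cur <- c(cur, which(ws == w & usable))
        if (length(cur) >= minProbes) {
          bins[[length(bins) + 1L]] <- cur
          cur <- integer(0)
        }
      }
      if (length(cur)) {
        if (length(bins)) {
          bins[[length(bins)]] <- c(bins[[length(bins)]], cur)
        } else bins[[1L]] <- cur
      }
      for (bi in seq_along(bins)) {
        idx <- bins[[bi]]
        out[[length(out) + 1L]] <- data.frame(
          sample_id = s, chromosome = ch, bin = bi,
          start = min(ps[idx]), end = max(ps[idx]),
          n_probes = length(idx), log2_ratio = median(xs[idx]),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

## maximum standardized circular-arc mean-difference statistic of a
## numeric segment; the scale factor (global sd) is permutation-invariant
## and therefore dropped. Returns the statistic and the best arc (i, j].
maxArcStat <- function(x, pairs) {
  S <- c(0, cumsum(x))
  tot <- S[length(S)]
  arc <- (S[pairs$j + 1L] - S[pairs$i + 1L])
  stat <- abs(arc / pairs$l - (tot - arc) / pairs$bl) * pairs$w
  best <- which.max(stat)
  list(stat = stat[best], i = pairs$i[best], j = pairs$j[best])
}

arcPairs <- function(b, minLen) {
  ij <- which(upper.tri(matrix(TRUE, b + 1, b + 1)), arr.ind = TRUE) - 1L
  i <- ij[, 1]; j <- ij[, 2]
  l <- j - i
  keep <- l >= minLen & (b - l) >= minLen &
    (i == 0L | i >= minLen) & (j == b | (b - j) >= minLen)
  i <- i[keep]; j <- j[keep]; l <- l[keep]
  list(i = i, j = j, l = l, bl = b - l, w = 1 / sqrt(1 / l + 1 / (b - l)))
}

segmentRecursive <- function(x, offset, alpha, nPerm, minSegBins) {
  b <- length(x)
  if (b < 2 * minSegBins)
    return(data.frame(start_bin = offset + 1L, end_bin = offset + b,
                      seg_mean = mean(x), n_bins = b))
  pairs <- arcPairs(b, minSegBins)
  obs <- maxArcStat(x, pairs)
  exceed <- 0L
  for (p in seq_len(nPerm)) {
    if (maxArcStat(sample(x), pairs)$stat >= obs$stat) exceed <- exceed + 1L
  }
  pval <- (1 + exceed) / (1 + nPerm)
  if (pval >= alpha)
    return(data.frame(start_bin = offset + 1L, end_bin = offset + b,
                      seg_mean = mean(x), n_bins = b))
  cuts <- sort(unique(c(0L, obs$i, obs$j, b)))
  do.call(rbind, lapply(seq_len(length(cuts) - 1L), function(k) {
    lo <- cuts[k] + 1L; hi <- cuts[k + 1L]
    segmentRecursive(x[lo:hi], offset + lo - 1L, alpha, nPerm, minSegBins)
  }))
}

#' Circular binary segmentation of a binned profile
#'
#' Per chromosome, recursively finds the arc `(i, j]` maximizing the
#' standardized mean-difference statistic between inside and outside and
#' accepts the split if its permutation p-value (from `nPerm` seeded label
#' permutations) is below `alpha`; recursion continues on both sides.
#' Splits creating segments shorter than `minSegBins` are not considered.
#' Deterministic given `seed`.
#'
#' @param profile [binProbes()] output (one or several samples).
#' @param alpha split acceptance level (default 0.01).
#' @param nPerm permutations per split test (default 1000).
#' @param minSegBins minimum bins per segment (default 3).
#' @param seed RNG seed for the permutations.
#' @param gainCut,lossCut call thresholds on the segment mean
#'   (defaults +0.15 / -0.15).
#' @return data.frame(sample_id, chromosome, start_bin, end_bin, start,
#'   end, n_bins, n_probes, seg_mean, call).
#' @export
cbsSegment <- function(profile, alpha = 0.01, nPerm = 1000, minSegBins = 3,
                       seed = 1, gainCut = 0.15, lossCut = -0.15) {
  out <- list()
  withSeed(seed, {
    for (s in unique(profile$sample_id)) {
      for (ch in unique(profile$chromosome[profile$sample_id == s])) {
        p <- profile[profile$sample_id == s & profile$chromosome == ch, ,
                     drop = FALSE]
        p <- p[order(p$bin), , drop = FALSE]
        if (nrow(p) < minSegBins) next
        segs <- segmentRecursive(p$log2_ratio, 0L, alpha, nPerm, minSegBins)
        segs$sample_id <- s
        segs$chromosome <- ch
        segs$start <- p$start[segs$start_bin]
        segs$end <- p$end[segs$end_bin]
        segs$n_probes <- vapply(seq_len(nrow(segs)), function(k)
          sum(p$n_probes[segs$start_bin[k]:segs$end_bin[k]]), 0L)
        out[[length(out) + 1L]] <- segs
      }
    }
  })
  segs <- do.call(rbind, out)
  segs$call <- ifelse(segs$seg_mean >= gainCut, "gain",
                      ifelse(segs$seg_mean <= lossCut, "loss", "neutral"))
  segs[, c("sample_id", "chromosome", "start_bin", "end_bin", "start",
           "end", "n_bins", "n_probes", "seg_mean", "call")]
}

#' Per-chromosome mean log2 ratio and gain/loss call
#'
#' The chromosome mean is the bin-count-weighted mean of its segment
#' means; calls use `gainCut`/`lossCut` (defaults +0.15 / -0.15, sitting
#' between the noise floor and the single-copy signal log2(3/2) = 0.585).
#'
#' @param segments [cbsSegment()] output.
#' @param gainCut,lossCut call thresholds.
#' @return data.frame(sample_id, chromosome, mean_log2_ratio, call).
#' @export
chromosomeCalls <- function(segments, gainCut = 0.15, lossCut = -0.15) {
  sp <- split(segments, list(segments$sample_id, segments$chromosome),
              drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    sample_id = d$sample_id[1], chromosome = d$chromosome[1],
    mean_log2_ratio = sum(d$seg_mean * d$n_bins) / sum(d$n_bins),
    stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out$call <- ifelse(out$mean_log2_ratio >= gainCut, "gain",
                     ifelse(out$mean_log2_ratio <= lossCut, "loss", "neutral"))
  out[order(out$sample_id, match(out$chromosome, AUTOSOMES)), ]
}

#' Whole-chromosome CNA signature of a sample
#'
#' `amplification-rich` requires at least `minEvents` chromosome gains and
#' strictly more gains than losses; `deletion-rich` symmetrically;
#' anything else (including ties) is `low-CNA`.
#'
#' @param calls [chromosomeCalls()] rows for one sample (>= 20
#'   chromosomes).
#' @param minEvents minimum event count (default 5).
#' @return one of "amplification-rich", "deletion-rich", "low-CNA".
#' @export
cnaSignature <- function(calls, minEvents = 5) {
  if (nrow(calls) < 20) stop("need calls for >= 20 chromosomes")
  g <- sum(calls$call == "gain"); l <- sum(calls$call == "loss")
  if (g >= minEvents && g > l) return("amplification-rich")
  if (l >= minEvents && l > g) return("deletion-rich")
  "low-CNA"
}

#' Per-bin gain/loss recurrence by group
#'
#' For every bin and group, the fraction of samples whose covering segment
#' passes the gain/loss cut-off — a descriptive recurrence table (no
#' focal-significance model).
#'
#' @param profile [binProbes()] output.
#' @param segments [cbsSegment()] output.
#' @param groups group label per sample (named by sample id).
#' @param gainCut,lossCut thresholds on the covering segment mean.
#' @return data.frame(chromosome, bin, start, end, group, n, gain_freq,
#'   loss_freq).
#' @export
focalRecurrence <- function(profile, segments, groups,
                            gainCut = 0.15, lossCut = -0.15) {
  grp <- groups[unique(profile$sample_id)]
  if (anyNA(grp)) stop("groups must cover every profiled sample")
  ## segment mean covering each (sample, chromosome, bin)
  segOf <- function(s, ch, bin) {
    d <- segments[segments$sample_id == s & segments$chromosome == ch, ]
    d$seg_mean[d$start_bin <= bin & d$end_bin >= bin][1]
  }
  bins <- unique(profile[, c("chromosome", "bin", "start", "end")])
  out <- list()
  for (g in sort(unique(grp))) {
    members <- names(grp)[grp == g]
    for (r in seq_len(nrow(bins))) {
      sm <- vapply(members, function(s)
        segOf(s, bins$chromosome[r], bins$bin[r]), 0)
      out[[length(out) + 1L]] <- data.frame(
        chromosome = bins$chromosome[r], bin = bins$bin[r],
        start = bins$start[r], end = bins$end[r], group = g,
        n = length(members),
        gain_freq = mean(sm >= gainCut, na.rm = TRUE),
        loss_freq = mean(sm <= lossCut, na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' FISH-concordance regression
#'
#' Ordinary least squares of the mean per-cell FISH signal count on the
#' chromosome mean log2 ratio, paired by (sample, autosome);
#' `R^2 = 1 - SSE/SST` with a two-sided t-test for the slope.
#'
#' @param fish data.frame(sample_id, autosome, mean_count).
#' @param calls [chromosomeCalls()] output.
#' @return list(slope, intercept, r_squared, p_slope, n).
#' @export
fishRegression <- function(fish, calls) {
  d <- merge(fish, calls, by.x = c("sample_id", "autosome"),
             by.y = c("sample_id", "chromosome"))
  if (nrow(d) < 3) stop("need >= 3 paired observations")
  if (var(d$mean_log2_ratio) == 0) stop("constant x: slope undefined")
  fit <- lm(mean_count ~ mean_log2_ratio, data = d)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p_slope = sm$coefficients["mean_log2_ratio", "Pr(>|t|)"],
       n = nrow(d))
}

#' Write segments in IGV SEG format
#'
#' Tab-separated with header
#' `sample<TAB>chrom<TAB>loc.start<TAB>loc.end<TAB>num.mark<TAB>seg.mean`.
#'
#' @param segments [cbsSegment()] output.
#' @param path output path.
#' @export
writeSegFile <- function(segments, path) {
  dt <- data.table::data.table(
    sample = segments$sample_id, chrom = segments$chromosome,
    loc.start = segments$start, loc.end = segments$end,
    num.mark = segments$n_probes, seg.mean = segments$seg_mean)
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}
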