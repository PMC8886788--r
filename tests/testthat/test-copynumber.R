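test_that("total intensity sums channels and propagates masks", {
  meth <- matrix(c(300, 500), 1, 2, dimnames = list("cg1", c("s1", "s2")))
  unmeth <- matrix(c(700, NA), 1, 2, dimnames = list("cg1", c("s1", "s2")))
  tot <- totalIntensity(meth, unmeth)
  expect_equal(tot[1, 1], 1000)
  expect_true(is.na(tot[1, 2]))
  expect_error(totalIntensity(meth, unmeth[, 2, drop = FALSE]), "axes")
})

test_that("log2 ratios are zero against the panel median and one after
           doubling", {
  set.seed(40)
  base <- runif(100, 900, 1100)
  ref <- matrix(base, 100, 3,  # identical normal replicates
                dimnames = list(sprintf("cg%03d", 1:100), paste0("N", 1:3)))
  total <- cbind(ref, t1 = base)
  r <- log2Ratio(total, paste0("N", 1:3))
  expect_equal(unname(r[, "t1"]), rep(0, 100), tolerance = 1e-12)
  ## doubling every probe is removed by median scaling unless anchored;
  ## anchor by doubling only half the genome
  tumorHalf <- base
  tumorHalf[1:50] <- 2 * base[1:50]
  total2 <- cbind(ref, t3 = tumorHalf)
  r2 <- log2Ratio(total2, paste0("N", 1:3))
  expect_equal(unname(r2[1:50, "t3"] - r2[51:100, "t3"]), rep(1, 50),
               tolerance = 1e-9)
  expect_error(log2Ratio(total[, c(1, 4)], "N1"), ">= 2 normal")
})

test_that("probe binning merges forward to the probe floor", {
  ## chr1: 20 probes in window 1, then 5 in window 2 followed by 25 in
  ## window 3 (forward merge), with minProbes = 15
  pos <- c(seq(1e6, 4.9e6, length.out = 20),            # window 1
           seq(5.1e6, 7e6, length.out = 5),             # window 2 (short)
           seq(10.1e6, 14.9e6, length.out = 25))        # window 3
  ids <- sprintf("cg%03d", seq_along(pos))
  ann <- GenomicRanges::GRanges(rep("chr1", length(pos)),
                                IRanges::IRanges(as.integer(pos), width = 1))
  names(ann) <- ids
  ann$island_relation <- "OpenSea"; ann$gene <- ""; ann$gene_region <- ""
  set.seed(41)
  ratios <- matrix(rnorm(length(pos), 0, 0.1), ncol = 1,
                   dimnames = list(ids, "t1"))
  prof <- binProbes(ratios, ann, minProbes = 15, binBp = 5e6)
  expect_equal(nrow(prof), 2)
  expect_equal(prof$n_probes, c(20, 30))  # 5 + 25 merged
  expect_equal(prof$log2_ratio[1], median(ratios[1:20, 1]))
  expect_equal(prof$log2_ratio[2], median(ratios[21:50, 1]))

  ## an all-masked chromosome is skipped with a message
  ratios2 <- ratios; ratios2[, 1] <- NA
  expect_message(prof2 <- binProbes(ratios2, ann, minProbes = 15,
                                    binBp = 5e6), "skipped")
  expect_null(prof2)
})

mkProfile <- function(x, sample = "t1", chrom = "chr1") {
  data.frame(sample_id = sample, chromosome = chrom, bin = seq_along(x),
             start = seq_along(x) * 10L, end = seq_along(x) * 10L + 9L,
             n_probes = 20L, log2_ratio = x, stringsAsFactors = FALSE)
}

test_that("CBS leaves flat profiles unsegmented and finds planted steps", {
  set.seed(42)
  flat <- mkProfile(rnorm(100, 0, 0.1))
  segs <- cbsSegment(flat, alpha = 0.01, nPerm = 200, seed = 1)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start_bin, 1)
  expect_equal(segs$end_bin, 100)

  step <- mkProfile(c(rnorm(50, 0, 0.1), rnorm(50, 1, 0.1)))
  segs2 <- cbsSegment(step, alpha = 0.01, nPerm = 200, seed = 2)
  expect_equal(nrow(segs2), 2)
  expect_lte(abs(segs2$end_bin[1] - 50), 1)
  expect_equal(segs2$seg_mean, c(0, 1), tolerance = 0.15)
  expect_equal(segs2$call, c("neutral", "gain"))

  twoStep <- mkProfile(c(rnorm(40, 0, 0.1), rnorm(30, -1, 0.1),
                         rnorm(30, 0, 0.1)))
  segs3 <- cbsSegment(twoStep, alpha = 0.01, nPerm = 200, seed = 3)
  expect_equal(nrow(segs3), 3)
  expect_equal(segs3$seg_mean, c(0, -1, 0), tolerance = 0.1)

  ## invariance to global additive shifts
  segs4 <- cbsSegment(transform(twoStep, log2_ratio = log2_ratio + 5),
                      alpha = 0.01, nPerm = 200, seed = 3)
  expect_equal(segs4$start_bin, segs3$start_bin)
  expect_equal(segs4$seg_mean, segs3$seg_mean + 5, tolerance = 1e-12)
})

test_that("chromosome calls weight segments by bin count", {
  segs <- data.frame(sample_id = "t1", chromosome = "chr1",
                     start_bin = c(1, 11), end_bin = c(10, 40),
                     start = c(1, 11), end = c(10, 40),
                     n_bins = c(10, 30), n_probes = c(100, 300),
                     seg_mean = c(1, 0), call = c("gain", "neutral"),
                     stringsAsFactors = FALSE)
  calls <- chromosomeCalls(segs)
  expect_equal(calls$mean_log2_ratio, 0.25)
  expect_equal(calls$call, "gain")
  segs$seg_mean <- c(0, 0)
  expect_equal(chromosomeCalls(segs)$call, "neutral")
})

test_that("CNA signatures follow the majority rule with ties low", {
  mkCalls <- function(g, l) data.frame(
    sample_id = "s", chromosome = paste0("chr", 1:22),
    mean_log2_ratio = 0,
    call = c(rep("gain", g), rep("loss", l), rep("neutral", 22 - g - l)))
  expect_equal(cnaSignature(mkCalls(10, 0)), "amplification-rich")
  expect_equal(cnaSignature(mkCalls(0, 7)), "deletion-rich")
  expect_equal(cnaSignature(mkCalls(0, 0)), "low-CNA")
  expect_equal(cnaSignature(mkCalls(5, 5)), "low-CNA")   # no strict majority
  expect_equal(cnaSignature(mkCalls(4, 0)), "low-CNA")   # below minEvents
})

test_that("focal recurrence counts match brute force on a toy cohort", {
  prof <- rbind(mkProfile(rep(0, 10), "s1"), mkProfile(rep(0, 10), "s2"),
                mkProfile(rep(0, 10), "s3"))
  segs <- rbind(
    data.frame(sample_id = "s1", chromosome = "chr1", start_bin = 1,
               end_bin = 10, start = 10, end = 109, n_bins = 10,
               n_probes = 200, seg_mean = -1, call = "loss"),
    data.frame(sample_id = "s2", chromosome = "chr1", start_bin = c(1, 6),
               end_bin = c(5, 10), start = c(10, 60), end = c(59, 109),
               n_bins = c(5, 5), n_probes = c(100, 100),
               seg_mean = c(0, 0.5), call = c("neutral", "gain")),
    data.frame(sample_id = "s3", chromosome = "chr1", start_bin = 1,
               end_bin = 10, start = 10, end = 109, n_bins = 10,
               n_probes = 200, seg_mean = 0, call = "neutral"))
  groups <- c(s1 = "G1", s2 = "G1", s3 = "G2")
  rec <- focalRecurrence(prof, segs, groups)
  g1bin1 <- rec[rec$group == "G1" & rec$bin == 1, ]
  expect_equal(g1bin1$loss_freq, 0.5)   # s1 of {s1, s2}
  expect_equal(g1bin1$gain_freq, 0)
  g1bin8 <- rec[rec$group == "G1" & rec$bin == 8, ]
  expect_equal(g1bin8$gain_freq, 0.5)   # s2's second segment
  g2 <- rec[rec$group == "G2", ]
  expect_true(all(g2$gain_freq == 0 & g2$loss_freq == 0))
})

test_that("FISH regression reproduces exact lines and guards inputs", {
  x <- seq(-1, 1, length.out = 10)
  fish <- data.frame(sample_id = "s1", autosome = paste0("chr", 1:10),
                     mean_count = 2 * x + 2)
  calls <- data.frame(sample_id = "s1", chromosome = paste0("chr", 1:10),
                      mean_log2_ratio = x, call = "neutral")
  fit <- suppressWarnings(fishRegression(fish, calls))  # exact fit warns
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 2)
  expect_error(fishRegression(fish[1:2, ], calls[1:2, ]), ">= 3")
  callsConst <- transform(calls, mean_log2_ratio = 0.3)
  expect_error(fishRegression(fish, callsConst), "constant")
})

test_that("SEG export carries the IGV columns", {
  segs <- data.frame(sample_id = "t1", chromosome = "chr1", start_bin = 1,
                     end_bin = 10, start = 1000, end = 9999, n_bins = 10,
                     n_probes = 150, seg_mean = -0.8, call = "loss")
  f <- withr::local_tempfile(fileext = ".seg")
  writeSegFile(segs, f)
  out <- read.delim(f)
  expect_identical(colnames(out),
                   c("sample", "chrom", "loc.start", "loc.end", "num.mark",
                     "seg.mean"))
  expect_equal(out$seg.mean, -0.8)
})
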