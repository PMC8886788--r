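test_that("BH adjustment matches brute-force step-up on a p-grid", {
  grid <- c(0.001, 0.04, 0.3, 1)
  for (len in 1:4) {
    combos <- expand.grid(rep(list(grid), len))
    for (r in seq_len(nrow(combos))) {
      p <- as.numeric(combos[r, ])
      expect_equal(bhAdjust(p), bruteBH(p))
    }
  }
  ## longer vectors, random draws
  set.seed(8)
  for (i in 1:50) {
    p <- sample(c(0.001, 0.01, 0.07, 0.2, 0.5, 0.9, 1), 6, replace = TRUE)
    expect_equal(bhAdjust(p), bruteBH(p))
  }
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(0.3, 5)), rep(0.3, 5))
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("BH is equivariant under input permutation", {
  set.seed(9)
  p <- runif(40)
  perm <- sample(40)
  expect_equal(bhAdjust(p)[perm], bhAdjust(p[perm]))
})

test_that("Wilcoxon exact p matches full rank enumeration", {
  x <- c(4, 5, 6); y <- c(1, 2, 3)
  ## enumerate all C(6,3) assignments of ranks to group x
  pooled <- c(x, y)
  obsU <- sum(rank(pooled)[1:3]) - 3 * 4 / 2
  us <- apply(combn(6, 3), 2, function(idx)
    sum(rank(pooled)[idx]) - 3 * 4 / 2)
  pEnum <- mean(abs(us - 4.5) >= abs(obsU - 4.5))
  wt <- wilcoxonRankSum(x, y, mode = "exact")
  expect_equal(wt$p_value, pEnum)
  expect_equal(wt$p_value, 0.1)
  expect_equal(wt$statistic, 9)

  ## exchangeable null: identical multisets give p = 1
  expect_equal(wilcoxonRankSum(c(1, 2, 3), c(3, 1, 2))$p_value, 1)
  expect_error(wilcoxonRankSum(numeric(0), 1), "non-empty")
})

test_that("normal-approximation mode tracks exact mode for n = 10 + 10", {
  set.seed(10)
  for (i in 1:5) {
    x <- rnorm(10); y <- rnorm(10, mean = 0.5)
    pe <- wilcoxonRankSum(x, y, mode = "exact")$p_value
    pn <- wilcoxonRankSum(x, y, mode = "normal")$p_value
    expect_lt(abs(pe - pn), 0.01)
  }
})

test_that("Fisher two-sided p matches hypergeometric enumeration", {
  expect_equal(fisherExactTest(matrix(c(1, 1, 1, 1), 2)), 1)
  expect_equal(fisherExactTest(matrix(c(5, 0, 0, 5), 2)), 2 / 252)
  sox9 <- matrix(c(9, 4, 2, 13), 2)  # positives 9/11 vs 4/17
  expect_equal(fisherExactTest(sox9), bruteFisher(sox9), tolerance = 1e-10)
  set.seed(11)
  for (i in 1:30) {
    tab <- matrix(rpois(4, 6), 2)
    expect_equal(fisherExactTest(tab), bruteFisher(tab), tolerance = 1e-9)
    ## symmetry under transposition and row/column swaps
    expect_equal(fisherExactTest(t(tab)), fisherExactTest(tab))
    expect_equal(fisherExactTest(tab[2:1, ]), fisherExactTest(tab))
    expect_equal(fisherExactTest(tab[, 2:1]), fisherExactTest(tab))
  }
  expect_error(fisherExactTest(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
})

test_that("dmpTest returns zero effect for identical groups and recovers
           planted shifts", {
  set.seed(12)
  base <- matrix(runif(200 * 4, 0.2, 0.8), 200, 4)
  m <- cbind(base, base)  # two identical groups by construction
  dimnames(m) <- list(sprintf("cg%03d", 1:200), sprintf("s%d", 1:8))
  b <- BetaMatrix(m)
  rec <- dmpTest(b, sprintf("s%d", 1:4), sprintf("s%d", 5:8))
  expect_equal(rec$delta_beta, rep(0, 200))
  expect_error(dmpTest(b, c("s1", "s2"), c("s2", "s3")), "disjoint")

  ## planted shift: 0.3 at 50 probes, n = 10 vs 10, noise 0.02
  set.seed(13)
  lvl <- runif(500, 0.25, 0.55)
  g1 <- sapply(1:10, function(i) lvl + rnorm(500, sd = 0.02))
  g2 <- sapply(1:10, function(i) lvl + c(rep(0.3, 50), rep(0, 450)) +
                 rnorm(500, sd = 0.02))
  m2 <- pmin(pmax(cbind(g1, g2), 0), 1)
  dimnames(m2) <- list(sprintf("cg%03d", 1:500),
                       c(sprintf("a%02d", 1:10), sprintf("b%02d", 1:10)))
  rec2 <- classifyTumorDmps(dmpTest(BetaMatrix(m2),
                                    sprintf("b%02d", 1:10),
                                    sprintf("a%02d", 1:10)))
  planted <- rec2[1:50, ]
  expect_true(all(planted$q_value < 1e-5))
  expect_true(all(abs(planted$log2fc) > 0.25))
  expect_true(all(planted$class == "significant"))
})

test_that("volcano classes follow the dual cut-off scheme", {
  rec <- data.frame(q_value = c(1e-7, 1e-7, 1e-2, 0.5),
                    log2fc = c(0.3, 0.1, 0.4, 0.1))
  cls <- classifyTumorDmps(rec)$class
  expect_identical(cls, c("significant", "p_only", "fc_only", "ns"))
})

test_that("p-values are calibrated under a global null", {
  set.seed(14)
  lvl <- runif(2000, 0.3, 0.7)
  m <- sapply(1:20, function(i) pmin(pmax(lvl + rnorm(2000, sd = 0.02), 0), 1))
  dimnames(m) <- list(sprintf("cg%04d", 1:2000), sprintf("s%02d", 1:20))
  rec <- dmpTest(BetaMatrix(m), sprintf("s%02d", 1:10), sprintf("s%02d", 11:20))
  frac <- mean(rec$p_value < 0.05)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
  ## super-uniformity sanity check (KS)
  ks <- suppressWarnings(stats::ks.test(rec$p_value, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("reference DMP calling recovers planted type-specific probes", {
  co <- smallCohort()
  dmps <- suppressMessages(callReferenceDmps(co$refs$beta, co$refs$sheet))
  planted <- sort(unlist(c(co$truth$specificSets, co$truth$lineageSets)))
  expect_true(all(planted %in% dmps))
  background <- setdiff(probeIds(co$refs$beta), planted)
  fpr <- length(intersect(dmps, background)) / length(background)
  expect_lt(fpr, 0.01)

  ## two identical cell types yield no DMPs between them
  v <- betaValues(co$refs$beta)
  dup <- cbind(v[, 1:2], v[, 1:2])
  colnames(dup) <- c("x_A", "x_B", "y_A", "y_B")
  sheet <- data.frame(sample_id = colnames(dup), role = "reference_cell",
                      grade = "NA", cell_type = rep(c("x", "y"), each = 2),
                      group_label = "", stringsAsFactors = FALSE)
  sheet$mutations <- rep(list(character()), 4)
  expect_length(callReferenceDmps(BetaMatrix(dup), sheet), 0)
})

test_that("probe-set scores are per-sample means over unmasked values", {
  m <- matrix(c(0.2, 0.8, NA,
                0.8, 0.8, NA), 2, 3, byrow = TRUE,
              dimnames = list(c("cg1", "cg2"), c("s1", "s2", "s3")))
  b <- BetaMatrix(m)
  expect_message(sc <- probeSetScore(b, c("cg1", "cg2")), "masked")
  expect_equal(unname(sc), c(0.5, 0.8, NA))
  bAll <- BetaMatrix(matrix(0.5, 3, 2, dimnames = list(paste0("cg", 1:3),
                                                       c("a", "b"))))
  expect_equal(unname(probeSetScore(bAll, paste0("cg", 1:3))), c(0.5, 0.5))
})

test_that("island hypermethylation separates the shifted group", {
  co <- smallCohort()
  islands <- names(co$ann$annotation)[
    co$ann$annotation$island_relation == "Island"]
  sc <- probeSetScore(co$tumors$beta, islands)
  gB <- co$tumors$sheet$sample_id[co$tumors$sheet$group_label == "B"]
  gA <- co$tumors$sheet$sample_id[co$tumors$sheet$group_label == "A"]
  expect_gt(mean(sc[gB]), mean(sc[gA]))
  expect_lt(wilcoxonRankSum(sc[gB], sc[gA])$p_value, 0.01)
})

test_that("marker overlap joins significant probes to marker genes only", {
  rec <- data.frame(probe_id = c("cg1", "cg2", "cg3"),
                    q_value = c(1e-8, 1e-8, 1e-8),
                    log2fc = c(0.5, 0.5, 0.1))
  rec <- classifyTumorDmps(rec)
  ann <- toyAnnotation(c("cg1", "cg2", "cg3"),
                       genes = c("IRX2", "OTHER", "IRX2"),
                       regions = c("TSS200", "Body", "Body"))
  markers <- data.frame(gene = c("IRX2", "ABSENT"), cell_type = "alpha")
  expect_warning(ov <- markerOverlap(rec, ann, markers), "absent")
  expect_identical(ov$table$probe_id, "cg1")  # cg3 not significant, cg2 off-list
  expect_equal(ov$counts$n_probes, 1)
  expect_equal(ov$counts$n_genes, 1)
})
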