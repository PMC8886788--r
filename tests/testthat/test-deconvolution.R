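test_that("atlas entries are replicate means and columns are separable", {
  m <- matrix(c(0.1, 0.2, 0.3, 0.8, 0.9, 0.7,
                0.9, 0.8, 0.7, 0.1, 0.2, 0.3), 2, 6, byrow = TRUE,
              dimnames = list(c("cg1", "cg2"), sprintf("r%d", 1:6)))
  sheet <- data.frame(sample_id = sprintf("r%d", 1:6), role = "reference_cell",
                      grade = "NA", cell_type = rep(c("x", "y"), each = 3),
                      group_label = "", stringsAsFactors = FALSE)
  atlas <- buildAtlas(BetaMatrix(m), sheet, c("cg1", "cg2"))
  expect_equal(unname(atlasMatrix(atlas)),
               matrix(c(0.2, 0.8, 0.8, 0.2), 2))

  ## one replicate per type: atlas equals the profiles
  atlas1 <- buildAtlas(BetaMatrix(m[, c(1, 4)]),
                       sheet[c(1, 4), ], c("cg1", "cg2"))
  expect_equal(unname(atlasMatrix(atlas1)), unname(m[, c(1, 4)]))

  ## synthetic references: between-type distance dwarfs replicate scatter
  co <- smallCohort()
  probes <- sort(unlist(co$truth$specificSets))
  atlasS <- buildAtlas(co$refs$beta, co$refs$sheet, probes)
  A <- atlasMatrix(atlasS)
  between <- as.matrix(dist(t(A)))
  v <- betaValues(co$refs$beta)[rownames(A), ]
  within <- mean(vapply(cellTypes(atlasS), function(t) {
    reps <- co$refs$sheet$sample_id[co$refs$sheet$cell_type == t]
    mean(dist(t(v[, reps])))
  }, 0))
  expect_gt(mean(between[upper.tri(between)]), 5 * within)
})

test_that("NNLS satisfies KKT and agrees with an independent solver", {
  set.seed(20)
  for (i in 1:25) {
    A <- matrix(runif(40), 10, 4)
    b <- runif(10)
    fit <- nnlsFit(A, b)
    expect_true(all(fit$x >= 0))
    grad <- drop(crossprod(A, A %*% fit$x - b))
    expect_true(all(abs(grad[fit$x > 1e-8]) < 1e-8))
    expect_true(all(grad[fit$x <= 1e-8] > -1e-8))
    ref <- pracma::lsqnonneg(A, b)
    expect_equal(fit$x, ref$x, tolerance = 1e-8)
    expect_equal(fit$residual_norm, sqrt(ref$resid.norm), tolerance = 1e-7)
  }
})

test_that("deconvolution recovers pure and mixed profiles exactly", {
  co <- smallCohort()
  probes <- sort(unlist(c(co$truth$specificSets, co$truth$lineageSets)))
  atlas <- buildAtlas(co$refs$beta, co$refs$sheet, probes)
  A <- atlasMatrix(atlas)
  pure <- BetaMatrix(matrix(A[, "acinar"], ncol = 1,
                            dimnames = list(rownames(A), "pureAcinar")))
  r <- nnlsDeconvolve(atlas, pure, "pureAcinar")
  expect_equal(unname(unlist(r[cellTypes(atlas)])), c(0, 0, 1, 0),
               tolerance = 1e-9)
  expect_false(r$degenerate)

  mix <- BetaMatrix(matrix(0.5 * A[, "alpha"] + 0.5 * A[, "beta"], ncol = 1,
                           dimnames = list(rownames(A), "mix")))
  r2 <- nnlsDeconvolve(atlas, mix, "mix")
  expect_equal(unname(unlist(r2[cellTypes(atlas)])), c(0.5, 0.5, 0, 0),
               tolerance = 1e-9)
  ## oracle: unconstrained least squares is already nonnegative here
  ols <- qr.coef(qr(A), 0.5 * A[, "alpha"] + 0.5 * A[, "beta"])
  expect_equal(unname(unlist(r2[cellTypes(atlas)])),
               unname(ols / sum(ols)), tolerance = 1e-9)
})

test_that("noisy mixture proportions are recovered within 0.05 MAE", {
  co <- smallCohort()
  probes <- suppressMessages(callReferenceDmps(co$refs$beta, co$refs$sheet))
  atlas <- buildAtlas(co$refs$beta, co$refs$sheet, probes)
  props <- deconvolveCohort(atlas, co$tumors$beta)
  est <- as.matrix(props[, cellTypes(atlas)])
  rownames(est) <- props$sample_id
  mae <- mean(abs(est - co$truth$proportions[rownames(est), colnames(est)]))
  expect_lt(mae, 0.05)
})

test_that("scale equivariance, duplicated columns and nested residuals", {
  set.seed(21)
  A <- matrix(runif(60), 20, 3, dimnames = list(sprintf("p%02d", 1:20),
                                                c("x", "y", "z")))
  b <- runif(20)
  f1 <- nnlsFit(A, b)
  f2 <- nnlsFit(A, 3 * b)
  expect_equal(f2$x, 3 * f1$x, tolerance = 1e-8)
  p1 <- f1$x / sum(f1$x); p2 <- f2$x / sum(f2$x)
  expect_equal(p1, p2, tolerance = 1e-8)

  ## duplicated column: summed weight over the duplicates is preserved
  Ad <- cbind(A, x2 = A[, "x"])
  fd <- nnlsFit(Ad, b)
  expect_equal(fd$x[1] + fd$x[4], f1$x[1], tolerance = 1e-6)

  ## adding a column never increases the residual
  f3 <- nnlsFit(A[, 1:2], b)
  expect_lte(f1$residual_norm, f3$residual_norm + 1e-12)
})

test_that("recovery error grows with noise", {
  cfg <- smallSimConfig(seed = 31)
  maes <- vapply(c(0, 0.02, 0.05, 0.1), function(sd) {
    cfg$noiseSd <- sd
    refs <- generateReferenceProfiles(cfg)
    tum <- generateTumorCohort(cfg, refs)
    probes <- sort(unlist(c(refs$truth$specificSets, refs$truth$lineageSets)))
    atlas <- buildAtlas(refs$beta, refs$sheet, probes)
    props <- deconvolveCohort(atlas, tum$beta)
    est <- as.matrix(props[, cellTypes(atlas)])
    rownames(est) <- props$sample_id
    mean(abs(est - tum$truth$proportions[rownames(est), colnames(est)]))
  }, 0)
  expect_true(all(diff(maes) >= -1e-6))
})

test_that("group comparisons flag the planted acinar enrichment", {
  co <- smallCohort()
  probes <- suppressMessages(callReferenceDmps(co$refs$beta, co$refs$sheet))
  atlas <- buildAtlas(co$refs$beta, co$refs$sheet, probes)
  props <- deconvolveCohort(atlas, co$tumors$beta)
  groups <- setNames(co$tumors$sheet$group_label, co$tumors$sheet$sample_id)
  tab <- compareGroupProportions(props, groups)
  ab <- tab[tab$cell_type == "acinar" & tab$group1 == "A" & tab$group2 == "B", ]
  expect_lt(ab$q_value, 0.01)

  ## label permutation within one group: no signal expected
  gA <- names(groups)[groups == "A"]
  fake <- groups
  fake[gA] <- rep(c("A", "Z"), length.out = length(gA))
  tab2 <- compareGroupProportions(props[props$sample_id %in% gA, ],
                                  fake[gA])
  expect_true(all(tab2$q_value >= 0.05))
})

test_that("degenerate inputs are rejected", {
  A <- matrix(c(0.1, 0.9), 2, 1, dimnames = list(c("cg1", "cg2"), "only"))
  expect_error(new("ReferenceAtlas", profiles = A), "two cell types")
  co <- smallCohort()
  probes <- sort(unlist(co$truth$specificSets))[1:30]
  atlas <- buildAtlas(co$refs$beta, co$refs$sheet, probes)
  masked <- betaValues(co$tumors$beta)
  masked[probes, "A01"] <- NA
  expect_error(nnlsDeconvolve(atlas, BetaMatrix(masked), "A01"),
               "A01")
})
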