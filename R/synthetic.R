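## Seeded synthetic cohorts with known ground truth.
##
## The generator emulates the measurement structure of an EPIC-style
## methylation study of pancreatic neuroendocrine neoplasms: sorted-cell
## reference profiles (alpha, beta, acinar, ductal), tumors as noisy
## purity-weighted mixtures of one origin cell type plus contamination,
## planted group DMP blocks, CpG-island and stem-cell probe-set shifts,
## intensity channels consistent with planted copy-number segments, and
## per-autosome FISH counts. One RNG stream per stage, each derived from
## the master seed by a fixed label, so adding a stage never perturbs
## earlier draws.

#' Simulation configuration
#'
#' Builds and validates the configuration all generators consume. Defaults
#' encode the study design the package models: four pancreatic cell types
#' with per-type hypomethylated probe blocks plus shared
#' endocrine (alpha+beta) and exocrine (acinar+ductal) lineage blocks, and
#' three tumor groups: A (n = 39, alpha origin), B (n = 14, acinar origin,
#' CpG-island and stem-cell-set hypermethylation), C (n = 4, beta origin,
#' island hypermethylation).
#'
#' @param nProbes total probe count (default 20000).
#' @param cellTypes reference cell types (fixed order).
#' @param nSpecificPerType probes hypomethylated specifically in one type
#'   (default 500 per type).
#' @param nLineageShared probes hypomethylated jointly in each lineage
#'   (endocrine, exocrine; default 500 each).
#' @param nReplicatesPerType named vector of reference replicate counts
#'   (default alpha 2, others 3).
#' @param groups list of per-group lists with elements `name`, `origin`,
#'   `nSamples`, `nDmp`, `dmpShift`, `islandShift`, `hescHyperShift`,
#'   `hescHypoShift`, and optionally `grades` (named counts).
#' @param purityRange tumor purity (lambda) range, default c(0.6, 0.9).
#' @param islandFraction fraction of probes annotated as CpG island
#'   (default 0.15).
#' @param hescSetSize size of each stem-cell (hESC) hyper/hypo probe set.
#' @param noiseSd truncated-Gaussian noise sd on the beta scale (0.02).
#' @param genesPerType,markerGenesPerType synthetic genes per cell type and
#'   how many of them enter the marker table.
#' @param promoterProb probability a gene-bearing probe gets a promoter
#'   gene-region feature (else Body).
#' @param intensityBaseline baseline total intensity T0 (default 5000).
#' @param intensityLogSd sd of the lognormal intensity noise (0.15).
#' @param fishCells cells counted per FISH measurement (mean of this many
#'   Poisson draws; default 50).
#' @param nNormals normal (copy-neutral) samples for the intensity panel.
#' @param binBp genomic bin width in bp for copy-number binning (5e6).
#' @param cnaPlan optional data.frame(sample_id, chromosome, start_bin,
#'   end_bin, copy_number); `NULL` means the built-in default plan.
#' @param seed master RNG seed.
#' @return a validated `SimulationConfig` list.
#' @export
simConfig <- function(nProbes = 20000,
                      cellTypes = c("alpha", "beta", "acinar", "ductal"),
                      nSpecificPerType = 500,
                      nLineageShared = 500,
                      nReplicatesPerType = c(alpha = 2, beta = 3,
                                             acinar = 3, ductal = 3),
                      groups = NULL,
                      purityRange = c(0.6, 0.9),
                      islandFraction = 0.15,
                      hescSetSize = 400,
                      noiseSd = 0.02,
                      genesPerType = 50,
                      markerGenesPerType = 20,
                      promoterProb = 0.7,
                      intensityBaseline = 5000,
                      intensityLogSd = 0.15,
                      fishCells = 50,
                      nNormals = 10,
                      binBp = 5e6,
                      cnaPlan = NULL,
                      seed = 1) {
  if (is.null(groups)) {
    groups <- list(
      list(name = "A", origin = "alpha", nSamples = 39, nDmp = 300,
           dmpShift = 0.4, islandShift = 0, hescHyperShift = 0,
           hescHypoShift = 0,
           grades = c(NETG1 = 18, NETG2 = 11, NETG3 = 10)),
      list(name = "B", origin = "acinar", nSamples = 14, nDmp = 300,
           dmpShift = 0.4, islandShift = 0.15, hescHyperShift = 0.15,
           hescHypoShift = -0.15,
           grades = c(NETG2 = 1, NEC = 13)),
      list(name = "C", origin = "beta", nSamples = 4, nDmp = 300,
           dmpShift = 0.4, islandShift = 0.15, hescHyperShift = 0,
           hescHypoShift = 0,
           grades = c(NETG2 = 1, NETG3 = 2, NEC = 1)))
  }
  if (length(nReplicatesPerType) == 1L)
    nReplicatesPerType <- setNames(rep(nReplicatesPerType, length(cellTypes)),
                                   cellTypes)
  cfg <- list(nProbes = as.integer(nProbes), cellTypes = cellTypes,
              nSpecificPerType = as.integer(nSpecificPerType),
              nLineageShared = as.integer(nLineageShared),
              nReplicatesPerType = nReplicatesPerType, groups = groups,
              purityRange = purityRange, islandFraction = islandFraction,
              hescSetSize = as.integer(hescSetSize), noiseSd = noiseSd,
              genesPerType = as.integer(genesPerType),
              markerGenesPerType = as.integer(markerGenesPerType),
              promoterProb = promoterProb,
              intensityBaseline = intensityBaseline,
              intensityLogSd = intensityLogSd,
              fishCells = as.integer(fishCells),
              nNormals = as.integer(nNormals), binBp = binBp,
              cnaPlan = cnaPlan, seed = as.integer(seed))
  validateSimConfig(cfg)
  class(cfg) <- "SimulationConfig"
  cfg
}

validateSimConfig <- function(cfg) {
  with(cfg, {
    if (nSpecificPerType * length(cellTypes) + 2L * nLineageShared > nProbes)
      stop("config error: structural probe blocks exceed nProbes")
    if (islandFraction < 0 || islandFraction > 1)
      stop("config error: islandFraction must be in [0, 1]")
    if (purityRange[1] > purityRange[2] ||
        purityRange[1] < 0 || purityRange[2] > 1)
      stop("config error: purity range must satisfy 0 <= lo <= hi <= 1")
    if (noiseSd < 0) stop("config error: noiseSd must be >= 0")
    for (g in groups) {
      if (!g$origin %in% cellTypes)
        stop("config error: group origin '", g$origin,
             "' not among cell types")
      if (g$nSamples < 1 || g$nDmp < 0)
        stop("config error: group counts must be positive")
      if (abs(g$dmpShift) > 1 || abs(g$islandShift) > 1)
        stop("config error: shifts must keep beta within [0, 1]")
    }
    if (!all(nReplicatesPerType >= 1))
      stop("config error: replicate counts must be >= 1")
  })
  invisible(cfg)
}

## Deterministic probe-level layout shared by every generator stage:
## category assignment, background levels, island labels, planted sets,
## genes and genomic positions. Depends only on (cfg, seed).
simLayout <- function(cfg) {
  withSeed(deriveSeed(cfg$seed, "layout"), {
    n <- cfg$nProbes
    probeIds <- sprintf("cg%08d", seq_len(n))
    perm <- sample.int(n)
    take <- function(k) {
      out <- perm[seq_len(k)]
      perm <<- perm[-seq_len(k)]
      out
    }
    specific <- lapply(cfg$cellTypes, function(t) sort(take(cfg$nSpecificPerType)))
    names(specific) <- cfg$cellTypes
    lineage <- list(endocrine = sort(take(cfg$nLineageShared)),
                    exocrine = sort(take(cfg$nLineageShared)))
    background <- sort(perm)

    bg <- numeric(n)
    hi <- runif(n) < 0.5
    bg[hi] <- stats::rbeta(sum(hi), 8, 2)
    bg[!hi] <- stats::rbeta(sum(!hi), 2, 8)

    islandIdx <- sort(sample.int(n, round(cfg$islandFraction * n)))
    islandRelation <- rep("OpenSea", n)
    islandRelation[islandIdx] <- "Island"
    rest <- setdiff(seq_len(n), islandIdx)
    shoreShelf <- sample(rest, round(0.25 * length(rest)))
    islandRelation[shoreShelf[seq_len(floor(length(shoreShelf) * 0.6))]] <- "Shore"
    islandRelation[shoreShelf[-seq_len(floor(length(shoreShelf) * 0.6))]] <- "Shelf"

    ## planted set pools come from background probes with headroom so that
    ## shifts never clamp (expected beta stays inside [0.02, 0.98])
    pool <- background[bg[background] > 0.05 & bg[background] < 0.95]
    pool <- sample(pool)  # random order, then carve disjoint sets
    carve <- function(k, keep) {
      cand <- pool[keep(bg[pool])]
      if (length(cand) < k) stop("config error: not enough background probes ",
                                 "with headroom for planted sets")
      out <- cand[seq_len(k)]
      pool <<- setdiff(pool, out)
      sort(out)
    }
    dmpSets <- list(); dmpDirs <- list()
    for (g in cfg$groups) {
      s <- abs(g$dmpShift)
      idx <- carve(g$nDmp, function(b) (b < 0.5 & b + s < 0.97) |
                                       (b >= 0.5 & b - s > 0.03))
      dmpSets[[g$name]] <- idx
      dmpDirs[[g$name]] <- ifelse(bg[idx] < 0.5, 1, -1)
    }
    hescHyper <- carve(cfg$hescSetSize, function(b) b < 0.75)
    hescHypo <- carve(cfg$hescSetSize, function(b) b > 0.25)
    islandShiftIdx <- sort(intersect(pool[bg[pool] < 0.8], islandIdx))

    ## synthetic genes: shared among the probes of a block so that marker
    ## genes have several probes each
    gene <- rep("", n)
    geneRegion <- rep("", n)
    mkGenes <- function(prefix, k) sprintf("%s_G%02d", prefix, seq_len(k))
    assignGenes <- function(idx, genes) {
      gene[idx] <<- sample(rep(genes, length.out = length(idx)))
      promo <- runif(length(idx)) < cfg$promoterProb
      geneRegion[idx] <<- ifelse(promo,
        sample(PROMOTER_REGIONS, length(idx), replace = TRUE), "Body")
    }
    markerTable <- NULL
    for (t in cfg$cellTypes) {
      genes <- mkGenes(toupper(t), cfg$genesPerType)
      assignGenes(specific[[t]], genes)
      markerTable <- rbind(markerTable, data.frame(
        gene = genes[seq_len(min(cfg$markerGenesPerType, length(genes)))],
        cell_type = t, stringsAsFactors = FALSE))
    }
    assignGenes(lineage$endocrine, mkGenes("ENDO", cfg$genesPerType))
    assignGenes(lineage$exocrine, mkGenes("EXO", cfg$genesPerType))

    ## genomic positions: contiguous probe blocks per autosome, strictly
    ## increasing positions (gaps 50-250 kb)
    chrom <- rep(AUTOSOMES, length.out = 0)
    per <- rep(n %/% 22L, 22L)
    per[22L] <- per[22L] + n %% 22L
    chrom <- rep(AUTOSOMES, times = per)
    position <- integer(n)
    off <- 0L
    for (c in seq_len(22L)) {
      gaps <- sample(50000:250000, per[c], replace = TRUE)
      position[off + seq_len(per[c])] <- 1000000L + cumsum(gaps)
      off <- off + per[c]
    }

    list(probeIds = probeIds, specific = specific, lineage = lineage,
         background = background, bg = bg,
         islandRelation = islandRelation, islandIdx = islandIdx,
         dmpSets = dmpSets, dmpDirs = dmpDirs,
         hescHyper = hescHyper, hescHypo = hescHypo,
         islandShiftIdx = islandShiftIdx,
         gene = gene, geneRegion = geneRegion,
         markerTable = markerTable, chrom = chrom, position = position)
  })
}

## latent (noise-free) reference profile per cell type
latentProfiles <- function(cfg, layout) {
  n <- cfg$nProbes
  L <- matrix(layout$bg, n, length(cfg$cellTypes),
              dimnames = list(layout$probeIds, cfg$cellTypes))
  for (t in cfg$cellTypes) {
    L[layout$specific[[t]], ] <- 0.9
    L[layout$specific[[t]], t] <- 0.1
  }
  endo <- intersect(c("alpha", "beta"), cfg$cellTypes)
  exo <- intersect(c("acinar", "ductal"), cfg$cellTypes)
  L[layout$lineage$endocrine, ] <- 0.9
  L[layout$lineage$endocrine, endo] <- 0.1
  L[layout$lineage$exocrine, ] <- 0.9
  L[layout$lineage$exocrine, exo] <- 0.1
  L
}

addNoise <- function(x, sd) {
  if (sd == 0) return(x)
  clamp01(x + matrix(rnorm(length(x), sd = sd), nrow(x), ncol(x)))
}

#' Generate sorted-cell reference profiles
#'
#' Each cell type has a latent profile (its specific probes near beta 0.1,
#' other types' specific probes near 0.9, lineage blocks shared within
#' endocrine/exocrine pairs, background probes from a bimodal mixture);
#' replicates add truncated-Gaussian noise clamped to \[0, 1\]. The same
#' config and seed give bit-identical output.
#'
#' @param cfg a [simConfig()].
#' @return list with `beta` ([BetaMatrix-class] of replicates), `sheet`
#'   (sample sheet data.frame) and `truth` (`SyntheticTruth` list carrying
#'   the planted layout and latent profiles).
#' @export
generateReferenceProfiles <- function(cfg) {
  validateSimConfig(cfg)
  layout <- simLayout(cfg)
  L <- latentProfiles(cfg, layout)
  cols <- unlist(lapply(cfg$cellTypes, function(t)
    paste(t, LETTERS[seq_len(cfg$nReplicatesPerType[[t]])], sep = "_")))
  types <- rep(cfg$cellTypes, times = cfg$nReplicatesPerType[cfg$cellTypes])
  reps <- withSeed(deriveSeed(cfg$seed, "references"), {
    m <- L[, types, drop = FALSE]
    colnames(m) <- cols
    addNoise(m, cfg$noiseSd)
  })
  sheet <- data.frame(sample_id = cols, role = "reference_cell", grade = "NA",
                      cell_type = types, group_label = "",
                      stringsAsFactors = FALSE)
  sheet$mutations <- rep(list(character()), nrow(sheet))
  sheet$tumor_type <- ""
  truth <- structure(list(
    layout = layout, latent = L,
    specificSets = lapply(layout$specific, function(i) layout$probeIds[i]),
    lineageSets = lapply(layout$lineage, function(i) layout$probeIds[i]),
    hescSets = list(hyper = layout$probeIds[layout$hescHyper],
                    hypo = layout$probeIds[layout$hescHypo]),
    dmpSets = lapply(layout$dmpSets, function(i) layout$probeIds[i]),
    markerTable = layout$markerTable), class = "SyntheticTruth")
  list(beta = BetaMatrix(reps), sheet = sheet, truth = truth)
}

#' Generate the tumor cohort as noisy cell-type mixtures
#'
#' Tumor beta = lambda * origin latent profile + (1 - lambda) * uniform
#' blend of the other cell types, plus planted group-DMP shifts, CpG-island
#' and stem-cell-set shifts for the configured groups, plus truncated
#' Gaussian noise, clamped to \[0, 1\]. Purity lambda is drawn per sample
#' from the configured range; the truth records lambda and the full
#' mixing-proportion vector (lambda for the origin, (1 - lambda)/3 for each
#' other type).
#'
#' @param cfg a [simConfig()].
#' @param references output of [generateReferenceProfiles()] (same cfg);
#'   regenerated internally when `NULL`.
#' @return list with `beta` (tumors, [BetaMatrix-class]), `sheet`, `truth`
#'   (adds `labels`, `origins`, `lambda`, `proportions`).
#' @export
generateTumorCohort <- function(cfg, references = NULL) {
  validateSimConfig(cfg)
  if (is.null(references)) references <- generateReferenceProfiles(cfg)
  truth <- references$truth
  layout <- truth$layout
  L <- truth$latent
  nT <- sum(vapply(cfg$groups, `[[`, 0, "nSamples"))
  ids <- character(0); origins <- character(0); labels <- integer(0)
  grades <- character(0)
  for (gi in seq_along(cfg$groups)) {
    g <- cfg$groups[[gi]]
    ids <- c(ids, sprintf("%s%02d", g$name, seq_len(g$nSamples)))
    origins <- c(origins, rep(g$origin, g$nSamples))
    labels <- c(labels, rep(gi, g$nSamples))
    gg <- if (!is.null(g$grades)) rep(names(g$grades), times = g$grades)
          else rep("NA", g$nSamples)
    if (length(gg) != g$nSamples) gg <- rep_len(gg, g$nSamples)
    grades <- c(grades, gg)
  }
  beta <- matrix(NA_real_, cfg$nProbes, nT,
                 dimnames = list(layout$probeIds, ids))
  lambda <- setNames(numeric(nT), ids)
  prop <- matrix(0, nT, length(cfg$cellTypes),
                 dimnames = list(ids, cfg$cellTypes))
  withSeed(deriveSeed(cfg$seed, "tumors"), {
    j <- 0L
    for (gi in seq_along(cfg$groups)) {
      g <- cfg$groups[[gi]]
      others <- setdiff(cfg$cellTypes, g$origin)
      blend <- rowMeans(L[, others, drop = FALSE])
      base <- numeric(cfg$nProbes)
      idx <- layout$dmpSets[[g$name]]
      base[idx] <- base[idx] + layout$dmpDirs[[g$name]] * abs(g$dmpShift)
      base[layout$islandShiftIdx] <- base[layout$islandShiftIdx] + g$islandShift
      base[layout$hescHyper] <- base[layout$hescHyper] + g$hescHyperShift
      base[layout$hescHypo] <- base[layout$hescHypo] + g$hescHypoShift
      for (s in seq_len(g$nSamples)) {
        j <- j + 1L
        lam <- runif(1, cfg$purityRange[1], cfg$purityRange[2])
        lambda[j] <- lam
        prop[j, g$origin] <- lam
        prop[j, others] <- (1 - lam) / length(others)
        mix <- lam * L[, g$origin] + (1 - lam) * blend + base
        beta[, j] <- clamp01(mix + rnorm(cfg$nProbes, sd = cfg$noiseSd))
      }
    }
  })
  nMet <- if (nT == 57L) 16L else round(0.281 * nT)
  nUnk <- if (nT == 57L) 1L else 0L
  tumorType <- c(rep("metastasis", nMet),
                 rep("primary", nT - nMet - nUnk),
                 rep("unknown", nUnk))
  sheet <- data.frame(sample_id = ids, role = "tumor", grade = grades,
                      cell_type = "",
                      group_label = vapply(cfg$groups, `[[`, "", "name")[labels],
                      stringsAsFactors = FALSE)
  sheet$mutations <- rep(list(character()), nT)
  sheet$tumor_type <- tumorType
  truth$labels <- setNames(labels, ids)
  truth$groupNames <- vapply(cfg$groups, `[[`, "", "name")
  truth$origins <- setNames(origins, ids)
  truth$lambda <- lambda
  truth$proportions <- prop
  list(beta = BetaMatrix(beta), sheet = sheet, truth = truth)
}

#' Generate probe annotation, marker table and stem-cell probe sets
#'
#' Probes are placed on the 22 autosomes with strictly increasing
#' positions; `islandFraction` of probes are labeled Island; each
#' cell-type-specific (and lineage) probe carries a synthetic gene with a
#' promoter gene-region feature with probability `promoterProb` (else
#' Body). The marker table maps a configurable subset of those genes to
#' their cell type; the hESC hyper/hypo sets are the disjoint probe sets
#' whose tumor-group shifts [generateTumorCohort()] plants.
#'
#' @param cfg a [simConfig()].
#' @return list with `annotation` (`GRanges`), `markers` (data.frame
#'   gene/cell_type), `hescSets` (list of two probe-id vectors).
#' @export
generateAnnotationAndSets <- function(cfg) {
  validateSimConfig(cfg)
  layout <- simLayout(cfg)
  gr <- GenomicRanges::GRanges(layout$chrom,
          IRanges::IRanges(layout$position, width = 1L))
  names(gr) <- layout$probeIds
  gr$island_relation <- layout$islandRelation
  gr$gene <- layout$gene
  gr$gene_region <- layout$geneRegion
  list(annotation = gr, markers = layout$markerTable,
       hescSets = list(hyper = layout$probeIds[layout$hescHyper],
                       hypo = layout$probeIds[layout$hescHypo]))
}

## windows of cfg$binBp bp; bin index of each probe on its chromosome
probeWindow <- function(position, binBp) (position - 1L) %/% binBp + 1L

#' Default copy-number plan for the synthetic cohort
#'
#' Group 1 splits into an amplification-rich block (whole-chromosome CN 3
#' on chr1/4/7/9/11), a deletion-rich block (CN 1 on chr2/6/10/16/21) and a
#' low-CNA remainder (one gain, one loss). Group 2 is deletion-rich (CN 1
#' on chr3/6/10/18/21) and half its samples additionally carry a four-bin
#' focal chr13 loss (the RB1-like region). Further groups are copy
#' neutral.
#'
#' @param cfg a [simConfig()].
#' @param tumorIds tumor sample ids in cohort order.
#' @param labels integer group index per tumor.
#' @param maxBins named vector of bin counts per chromosome (used to place
#'   the focal chr13 loss mid-chromosome); defaults assume the standard
#'   20000-probe layout.
#' @return data.frame(sample_id, chromosome, start_bin, end_bin,
#'   copy_number); `end_bin = NA` means the chromosome end.
#' @export
defaultCnaPlan <- function(cfg, tumorIds, labels, maxBins = NULL) {
  ## four bins (~20 Mb at the default binning): at 5 Mb resolution a
  ## three-bin event sits at the granularity floor of the alpha = 0.01
  ## permutation test (an adjacent triple recurs in ~0.8% of random
  ## permutations), so the smallest robustly segmentable focal event
  ## spans four bins
  m13 <- if (is.null(maxBins)) 12L else as.integer(maxBins[["chr13"]])
  focalStart <- max(1L, m13 %/% 2L)
  focalEnd <- min(m13, focalStart + 3L)
  rows <- list()
  add <- function(id, chrom, s, e, cn)
    rows[[length(rows) + 1L]] <<- data.frame(sample_id = id,
      chromosome = chrom, start_bin = s, end_bin = e, copy_number = cn,
      stringsAsFactors = FALSE)
  g1 <- tumorIds[labels == 1L]
  nAmp <- min(20L, length(g1)); nDel <- min(10L, max(0L, length(g1) - nAmp))
  for (id in g1[seq_len(nAmp)])
    for (ch in paste0("chr", c(1, 4, 7, 9, 11))) add(id, ch, 1L, NA, 3L)
  if (nDel > 0)
    for (id in g1[nAmp + seq_len(nDel)])
      for (ch in paste0("chr", c(2, 6, 10, 16, 21))) add(id, ch, 1L, NA, 1L)
  if (length(g1) > nAmp + nDel)
    for (id in g1[(nAmp + nDel + 1L):length(g1)]) {
      add(id, "chr5", 1L, NA, 3L)
      add(id, "chr8", 1L, NA, 1L)
    }
  g2 <- tumorIds[labels == 2L]
  for (i in seq_along(g2)) {
    for (ch in paste0("chr", c(3, 6, 10, 18, 21))) add(g2[i], ch, 1L, NA, 1L)
    if (i %% 2L == 1L) add(g2[i], "chr13", focalStart, focalEnd, 1L)
  }
  do.call(rbind, rows)
}

#' Generate intensity channels and FISH counts from planted copy number
#'
#' Per probe p and sample s the total intensity is
#' `T = T0 * (CN(p, s) / 2) * exp(eta)` with lognormal noise
#' `eta ~ N(0, intensityLogSd)`; the methylated channel is `beta * T` and
#' the unmethylated channel `(1 - beta) * T`, so the channel ratio
#' reproduces beta exactly. Normal panel samples are copy-neutral blends of
#' the four cell types. The FISH table holds, per tumor and autosome, the
#' mean of `fishCells` Poisson draws around the true mean copy number of
#' that autosome (a per-cell centromere count averaged over counted
#' nuclei).
#'
#' @param cfg a [simConfig()].
#' @param tumors output of [generateTumorCohort()].
#' @return list with `meth`/`unmeth` (matrices over tumors + normals),
#'   `fish` (data.frame sample_id/autosome/mean_count), `normalIds`,
#'   `truth` (adds `trueSegments`, the per-sample planted CN segments, and
#'   `trueChromCN`, the per-sample per-autosome mean copy number).
#' @export
generateIntensityChannels <- function(cfg, tumors) {
  validateSimConfig(cfg)
  truth <- tumors$truth
  layout <- truth$layout
  tumorBeta <- betaValues(tumors$beta)
  tumorIds <- colnames(tumorBeta)
  plan <- cfg$cnaPlan
  win <- probeWindow(layout$position, cfg$binBp)
  maxWin <- tapply(win, layout$chrom, max)
  if (is.null(plan))
    plan <- defaultCnaPlan(cfg, tumorIds, unname(truth$labels), maxWin)
  ## per-probe copy number for tumors
  cn <- matrix(2, cfg$nProbes, length(tumorIds),
               dimnames = list(layout$probeIds, tumorIds))
  if (!is.null(plan) && nrow(plan)) {
    for (r in seq_len(nrow(plan))) {
      ch <- plan$chromosome[r]
      if (!ch %in% AUTOSOMES) stop("config error: unknown chromosome ", ch)
      e <- plan$end_bin[r]
      if (is.na(e)) e <- maxWin[[ch]]
      if (plan$start_bin[r] < 1 || e > maxWin[[ch]])
        stop("config error: CNA plan bins outside ", ch)
      sel <- layout$chrom == ch & win >= plan$start_bin[r] & win <= e
      cn[sel, plan$sample_id[r]] <- plan$copy_number[r]
    }
  }
  normalIds <- sprintf("N%02d", seq_len(cfg$nNormals))
  withSeed(deriveSeed(cfg$seed, "intensity"), {
    normalBeta <- matrix(rowMeans(truth$latent), cfg$nProbes, cfg$nNormals,
                         dimnames = list(layout$probeIds, normalIds))
    normalBeta <- addNoise(normalBeta, cfg$noiseSd)
    beta <- cbind(tumorBeta, normalBeta)
    cnAll <- cbind(cn, matrix(2, cfg$nProbes, cfg$nNormals,
                              dimnames = list(layout$probeIds, normalIds)))
    eta <- matrix(rnorm(length(beta), sd = cfg$intensityLogSd),
                  nrow(beta), ncol(beta))
    total <- cfg$intensityBaseline * (cnAll / 2) * exp(eta)
    meth <- beta * total
    unmeth <- (1 - beta) * total
    dimnames(meth) <- dimnames(unmeth) <- dimnames(beta)
    chromCN <- t(vapply(seq_along(tumorIds), function(j)
      tapply(cn[, j], layout$chrom, mean)[AUTOSOMES], numeric(22L)))
    dimnames(chromCN) <- list(tumorIds, AUTOSOMES)
    fish <- withSeed(deriveSeed(cfg$seed, "fish"), {
      do.call(rbind, lapply(seq_along(tumorIds), function(j) {
        data.frame(sample_id = tumorIds[j], autosome = AUTOSOMES,
                   mean_count = vapply(chromCN[j, ], function(mu)
                     mean(rpois(cfg$fishCells, mu)), 0),
                   stringsAsFactors = FALSE)
      }))
    })
    truth$trueSegments <- plan
    truth$trueChromCN <- chromCN
    list(meth = meth, unmeth = unmeth, fish = fish,
         normalIds = normalIds, truth = truth)
  })
}

#' Serialize the planted ground truth as JSON
#'
#' Writes labels, origins, purity, mixing proportions, planted probe sets,
#' marker table and copy-number segments (not the latent matrices) so that
#' recovery can be scored outside R.
#'
#' @param truth a `SyntheticTruth` list.
#' @param path output path.
#' @export
writeTruth <- function(truth, path) {
  out <- list(
    labels = as.list(truth$labels),
    groupNames = truth$groupNames,
    origins = as.list(truth$origins),
    lambda = as.list(truth$lambda),
    proportions = if (!is.null(truth$proportions))
      as.data.frame(truth$proportions) else NULL,
    specificSets = truth$specificSets,
    lineageSets = truth$lineageSets,
    dmpSets = truth$dmpSets,
    hescSets = truth$hescSets,
    markerTable = truth$markerTable,
    trueSegments = truth$trueSegments)
  jsonlite::write_json(out[!vapply(out, is.null, TRUE)], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
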