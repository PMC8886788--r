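## End-to-end orchestration: simulate -> cluster -> differential
## methylation -> deconvolution -> tree -> copy number -> report, from a
## single config with one master seed. Every stage output in the report is
## recomputed from the stage results; when ground truth is available the
## report adds recovery metrics (ARI, proportion MAE, clade checks).

#' Pipeline configuration
#'
#' Assembles per-stage parameter blocks around a [simConfig()]. Unknown
#' keys in `...` are rejected (silent typos being the main field-use
#' hazard).
#'
#' @param sim a [simConfig()] (default: the standard synthetic cohort).
#' @param seed master seed; overrides `sim$seed` so one integer drives all
#'   randomness.
#' @param outDir output directory, or `NULL` to skip writing files.
#' @param ... stage overrides: `topK`, `kmin`, `kmax`, `reps`, `pItem`,
#'   `cbsAlpha`, `cbsPerm`, `minSegBins`, `minProbesPerBin`,
#'   `writeIntermediate`.
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(sim = NULL, seed = 1, outDir = NULL, ...) {
  cfg <- list(topK = 10000, kmin = 2L, kmax = 5L, reps = 250, pItem = 0.8,
              cbsAlpha = 0.01, cbsPerm = 200, minSegBins = 3,
              minProbesPerBin = 15, writeIntermediate = FALSE)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (is.null(sim)) sim <- simConfig(seed = seed)
  sim$seed <- as.integer(seed)
  cfg$sim <- sim
  cfg$seed <- as.integer(seed)
  cfg$outDir <- outDir
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The file may contain a `seed`, an `outDir`, a `sim` block (arguments of
#' [simConfig()], including a `groups` list) and a `stages` block
#' (arguments of [pipelineConfig()]). Unknown keys at any level are
#' rejected.
#'
#' @param path YAML file path.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  known <- c("seed", "outDir", "sim", "stages")
  unknown <- setdiff(names(y), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  simArgs <- if (is.null(y$sim)) list() else y$sim
  badSim <- setdiff(names(simArgs), names(formals(simConfig)))
  if (length(badSim)) stop("unknown sim key(s): ",
                           paste(badSim, collapse = ", "))
  sim <- do.call(simConfig, simArgs)
  stageArgs <- if (is.null(y$stages)) list() else y$stages
  do.call(pipelineConfig,
          c(list(sim = sim,
                 seed = if (is.null(y$seed)) sim$seed else y$seed,
                 outDir = y$outDir),
            stageArgs))
}

#' Cohort characteristics table
#'
#' Counts and percentages (half-up rounding to one decimal) of tumor
#' samples per grade and per tumor/metastasis status.
#'
#' @param sheet a sample sheet (see [readSampleSheet()]).
#' @return data.frame(category, variable, count, percent).
#' @export
summarizeCohort <- function(sheet) {
  if (!nrow(sheet)) stop("empty sample sheet")
  tum <- sheet[sheet$role == "tumor", , drop = FALSE]
  n <- nrow(tum)
  if (!n) stop("no tumor rows")
  block <- function(category, values) {
    tab <- table(values)
    data.frame(category = category, variable = names(tab),
               count = as.integer(tab),
               percent = roundHalfUp(100 * as.integer(tab) / n, 1),
               stringsAsFactors = FALSE)
  }
  out <- block("grade", factor(tum$grade, levels = intersect(GRADES, tum$grade)))
  if (!is.null(tum$tumor_type) && any(nzchar(tum$tumor_type)))
    out <- rbind(out, block("tumor_type", tum$tumor_type))
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes, in dependency order: cohort simulation; consensus clustering
#' of the most variable probes over `kmin..kmax` with delta-area k
#' selection; differential methylation between the two largest clusters
#' with volcano classification, marker overlap, and island / stem-cell
#' probe-set scores; reference DMP calling, atlas construction, NNLS
#' deconvolution and group-proportion comparisons; the phylo-epigenetic
#' neighbor-joining tree with the exocrine clade check; copy-number
#' inference (log2 ratios, binning, CBS, chromosome calls, signatures,
#' focal recurrence, FISH regression); and the cohort summary. All
#' randomness derives from the master seed; the same config reproduces
#' identical results.
#'
#' @param cfg a [pipelineConfig()].
#' @return a `Report` list; also writes `report.json`, labels, the Newick
#'   tree, a SEG file and (optionally) the simulated tables when `outDir`
#'   is set.
#' @export
runPipeline <- function(cfg = pipelineConfig()) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  sim <- cfg$sim
  stage <- function(name) message("[pipeline] ", name)

  stage("simulate")
  refs <- generateReferenceProfiles(sim)
  ann <- generateAnnotationAndSets(sim)
  tumors <- generateTumorCohort(sim, refs)
  intens <- generateIntensityChannels(sim, tumors)
  truth <- intens$truth
  sheet <- rbind(refs$sheet, tumors$sheet)

  stage("clustering")
  topProbes <- selectVariableProbes(tumors$beta, cfg$topK)
  consensus <- lapply(cfg$kmin:cfg$kmax, function(k)
    consensusCluster(tumors$beta, topProbes, k, reps = cfg$reps,
                     pItem = cfg$pItem,
                     seed = deriveSeed(cfg$seed, paste0("consensus", k))))
  bestK <- chooseK(consensus)
  labels <- clusterLabels(consensus[[bestK - cfg$kmin + 1L]])
  ari <- mclust::adjustedRandIndex(labels, truth$labels[names(labels)])

  ## map discovered clusters onto the planted groups by majority overlap
  sizes <- sort(table(labels), decreasing = TRUE)
  majorityGroup <- function(cl)
    names(which.max(table(truth$groupNames[truth$labels[
      names(labels)[labels == cl]]])))
  clusterGroup <- vapply(names(sizes), majorityGroup, "")

  stage("differential methylation")
  g1 <- names(labels)[labels == as.integer(names(sizes)[1])]
  g2 <- names(labels)[labels == as.integer(names(sizes)[2])]
  dmp <- classifyTumorDmps(dmpTest(tumors$beta, g2, g1))
  overlap <- markerOverlap(dmp, ann$annotation, ann$markers)
  islandProbes <- names(ann$annotation)[ann$annotation$island_relation ==
                                        "Island"]
  islandScore <- probeSetScore(tumors$beta, islandProbes)
  hescHyperScore <- probeSetScore(tumors$beta, ann$hescSets$hyper)
  islandP <- wilcoxonRankSum(islandScore[g2], islandScore[g1])$p_value
  hescP <- wilcoxonRankSum(hescHyperScore[g2], hescHyperScore[g1])$p_value

  stage("deconvolution")
  atlasProbes <- callReferenceDmps(refs$beta, refs$sheet)
  atlas <- buildAtlas(refs$beta, refs$sheet, atlasProbes)
  props <- deconvolveCohort(atlas, tumors$beta)
  groupOf <- setNames(tumors$sheet$group_label, tumors$sheet$sample_id)
  propTests <- compareGroupProportions(props, groupOf)
  propMae <- mean(abs(as.matrix(props[, cellTypes(atlas)]) -
                      truth$proportions[props$sample_id, cellTypes(atlas)]))

  stage("phylo-epigenetic tree")
  joint <- BetaMatrix(cbind(betaValues(tumors$beta), betaValues(refs$beta)))
  dm <- methylDistance(joint, atlasProbes, metric = "pearson")
  tree <- neighborJoining(dm)
  exocrineRefs <- refs$sheet$sample_id[refs$sheet$cell_type %in%
                                       c("acinar", "ductal")]
  groupB <- tumors$sheet$sample_id[tumors$sheet$group_label == "B"]
  exocrineClade <- if (length(groupB))
    isCladeWith(tree, groupB, exocrineRefs) else NA

  stage("copy number")
  total <- totalIntensity(intens$meth, intens$unmeth)
  ratios <- log2Ratio(total, intens$normalIds)
  profile <- binProbes(ratios, ann$annotation, cfg$minProbesPerBin, sim$binBp)
  segments <- cbsSegment(profile, alpha = cfg$cbsAlpha, nPerm = cfg$cbsPerm,
                         minSegBins = cfg$minSegBins,
                         seed = deriveSeed(cfg$seed, "cbs"))
  calls <- chromosomeCalls(segments)
  signatures <- vapply(split(calls, calls$sample_id), cnaSignature, "")
  recurrence <- focalRecurrence(profile, segments, groupOf)
  fishFit <- fishRegression(intens$fish, calls)

  stage("report")
  report <- list(
    seed = cfg$seed,
    cohort = summarizeCohort(sheet),
    clustering = list(
      chosen_k = bestK, ari = ari,
      cluster_sizes = as.list(table(labels)),
      cluster_group = as.list(clusterGroup),
      consensus_areas = vapply(consensus, consensusCdfArea, 0)),
    dmp = list(class_counts = as.list(table(dmp$class)),
               island_wilcoxon_p = islandP,
               hesc_hyper_wilcoxon_p = hescP,
               marker_counts = overlap$counts),
    deconvolution = list(
      n_atlas_probes = length(atlasProbes),
      mean_proportions_by_group = lapply(
        split(props[, cellTypes(atlas)], groupOf[props$sample_id]),
        colMeans),
      comparisons = propTests,
      proportion_mae = propMae),
    tree = list(newick = writeNewick(tree),
                exocrine_clade = exocrineClade),
    cna = list(signature_counts = as.list(table(signatures)),
               chr13_focal_loss_freq = vapply(
                 split(recurrence[recurrence$chromosome == "chr13", ],
                       recurrence$group[recurrence$chromosome == "chr13"]),
                 function(d) max(d$loss_freq), 0),
               fish = fishFit))
  if (!is.null(cfg$outDir)) {
    dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
    op <- function(f) file.path(cfg$outDir, f)
    if (isTRUE(cfg$writeIntermediate)) {
      writeBetaMatrix(refs$beta, op("references.tsv"))
      writeBetaMatrix(tumors$beta, op("tumors.tsv"))
      writeProbeAnnotation(ann$annotation, op("annotation.tsv"))
      writeIntensityMatrix(intens$meth, op("methylated.tsv"))
      writeIntensityMatrix(intens$unmeth, op("unmethylated.tsv"))
      data.table::fwrite(intens$fish, op("fish.csv"))
    }
    writeSampleSheet(sheet, op("samples.csv"))
    writeTruth(truth, op("truth.json"))
    data.table::fwrite(data.frame(sample_id = names(labels),
                                  cluster = labels), op("labels.csv"))
    data.table::fwrite(props, op("proportions.tsv"), sep = "\t")
    writeLines(report$tree$newick, op("tree.nwk"))
    writeSegFile(segments, op("segments.seg"))
    data.table::fwrite(recurrence, op("recurrence.tsv"), sep = "\t")
    jsonlite::write_json(reportJson(report), op("report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

## report with data.frames flattened for JSON
reportJson <- function(report) {
  rapply(report, function(x) x, how = "replace")
}
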