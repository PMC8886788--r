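## Shared fixtures, generated in code and memoized per test run.

.fixtureCache <- new.env(parent = emptyenv())

memo <- function(key, make) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, make(), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

## a reduced three-group cohort with the same planted structure as the
## default study design (alpha/acinar/beta origins, island + hESC shifts)
smallSimConfig <- function(seed = 7) {
  simConfig(
    nProbes = 4400, nSpecificPerType = 100, nLineageShared = 100,
    groups = list(
      list(name = "A", origin = "alpha", nSamples = 16, nDmp = 80,
           dmpShift = 0.4, islandShift = 0, hescHyperShift = 0,
           hescHypoShift = 0, grades = c(NETG1 = 8, NETG2 = 5, NETG3 = 3)),
      list(name = "B", origin = "acinar", nSamples = 8, nDmp = 80,
           dmpShift = 0.4, islandShift = 0.15, hescHyperShift = 0.15,
           hescHypoShift = -0.15, grades = c(NEC = 8)),
      list(name = "C", origin = "beta", nSamples = 4, nDmp = 80,
           dmpShift = 0.4, islandShift = 0.15, hescHyperShift = 0,
           hescHypoShift = 0, grades = c(NETG3 = 4))),
    hescSetSize = 100, nNormals = 4, seed = seed)
}

smallCohort <- function() {
  memo("smallCohort", function() {
    cfg <- smallSimConfig()
    refs <- generateReferenceProfiles(cfg)
    tumors <- generateTumorCohort(cfg, refs)
    ann <- generateAnnotationAndSets(cfg)
    intens <- generateIntensityChannels(cfg, tumors)
    list(cfg = cfg, refs = refs, tumors = tumors, ann = ann,
         intens = intens, truth = intens$truth)
  })
}

## tiny hand-checkable beta matrix
toyBeta <- function() {
  m <- matrix(c(0.1, 0.2, 0.9, 0.8,
                0.5, 0.5, 0.5, 0.5,
                0.2, NA, 0.6, 0.7), nrow = 3, byrow = TRUE,
              dimnames = list(c("cg1", "cg2", "cg3"),
                              c("s1", "s2", "s3", "s4")))
  BetaMatrix(m)
}

## annotation GRanges for a handful of probes
toyAnnotation <- function(ids, regions = NULL, genes = NULL) {
  n <- length(ids)
  gr <- GenomicRanges::GRanges(rep("chr1", n),
                               IRanges::IRanges(seq_len(n) * 1000, width = 1))
  names(gr) <- ids
  gr$island_relation <- rep("OpenSea", n)
  gr$gene <- if (is.null(genes)) rep("", n) else genes
  gr$gene_region <- if (is.null(regions)) rep("", n) else regions
  gr
}
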