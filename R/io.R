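## Tabular IO for the formats every other stage consumes.
## Dialect: TSV, UTF-8, '.' decimal, no quoting of numeric fields,
## na_token default "NA"; sample sheets are CSV. All readers enforce the
## type invariants so downstream code never re-validates.

readNumericTsv <- function(path, naToken = "NA") {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = naToken, colClasses = list(character = 1L),
                          data.table = FALSE, showProgress = FALSE)
  if (ncol(dt) < 2) stop("expected a probe-id column plus sample columns: ", path)
  ids <- dt[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate probe id(s): ",
         paste(unique(ids[duplicated(ids)])[1:min(3, sum(duplicated(ids)))],
               collapse = ", "), " in ", path)
  m <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Read / write a beta-value matrix
#'
#' TSV with header `probe_id<TAB>sample1<TAB>...`, one probe per row.
#' Cells equal to `naToken` are masked; any numeric cell outside \[0, 1\]
#' is rejected with its probe/sample coordinates.
#'
#' @param path file path.
#' @param naToken string marking a masked cell (default `"NA"`).
#' @return [readBetaMatrix()]: a [BetaMatrix-class].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' b <- BetaMatrix(matrix(c(0.2, 0.8), 1, 2,
#'        dimnames = list("cg1", c("s1", "s2"))))
#' writeBetaMatrix(b, f)
#' identical(betaValues(readBetaMatrix(f)), betaValues(b))
#' @export
readBetaMatrix <- function(path, naToken = "NA") {
  m <- readNumericTsv(path, naToken)
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("beta value %g outside [0, 1] at probe %s, sample %s in %s",
                 m[bad[1, 1], bad[1, 2]], rownames(m)[bad[1, 1]],
                 colnames(m)[bad[1, 2]], path))
  }
  BetaMatrix(m)
}

writeMatrixTsv <- function(m, path, naToken = "NA") {
  dt <- data.table::data.table(probe_id = rownames(m), m)
  data.table::fwrite(dt, path, sep = "\t", na = naToken, quote = FALSE)
  invisible(path)
}

#' @rdname readBetaMatrix
#' @param b a [BetaMatrix-class] to serialize.
#' @export
writeBetaMatrix <- function(b, path, naToken = "NA") {
  stopifnot(is(b, "BetaMatrix"))
  writeMatrixTsv(betaValues(b), path, naToken)
}

#' Read / write an intensity matrix
#'
#' Same TSV layout as a beta matrix but values are nonnegative fluorescence
#' intensities (arbitrary units), used for the methylated and unmethylated
#' channels of the copy-number analysis.
#'
#' @inheritParams readBetaMatrix
#' @return a numeric matrix with probe rownames and sample colnames.
#' @export
readIntensityMatrix <- function(path, naToken = "NA") {
  m <- readNumericTsv(path, naToken)
  bad <- which(!is.na(m) & m < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("negative intensity at probe %s, sample %s in %s",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]], path))
  m
}

#' @rdname readIntensityMatrix
#' @param m numeric intensity matrix to serialize.
#' @export
writeIntensityMatrix <- function(m, path, naToken = "NA") {
  writeMatrixTsv(m, path, naToken)
}

#' Read / write a probe set
#'
#' Plain text, one probe id per line; `#` starts a comment. Repeated ids
#' are deduplicated (first occurrence kept, order preserved) with a
#' warning.
#'
#' @param path file path.
#' @return [readProbeSet()]: character vector of unique probe ids.
#' @export
readProbeSet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readLines(path, warn = FALSE)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  x <- x[nzchar(x)]
  if (!length(x)) stop("empty probe set: ", path)
  if (anyDuplicated(x)) {
    warning(sum(duplicated(x)), " duplicated probe id(s) in ", path,
            "; keeping first occurrences")
    x <- x[!duplicated(x)]
  }
  x
}

#' @rdname readProbeSet
#' @param probes character vector of probe ids.
#' @export
writeProbeSet <- function(probes, path) {
  stopifnot(is.character(probes), !anyDuplicated(probes))
  writeLines(probes, path)
  invisible(path)
}

#' Read / write a probe annotation table
#'
#' TSV with columns `probe_id`, `chromosome`, `position`,
#' `island_relation`, `gene`, `gene_region` (the last `';'`-joined when a
#' probe maps to several gene-region features). Coordinates are 1-based
#' positions with `chr`-prefixed chromosome labels; `island_relation` and
#' `gene_region` are closed vocabularies (Island/Shore/Shelf/OpenSea and
#' TSS200/TSS1500/5'UTR/1stExon/Body/3'UTR).
#'
#' @param path file path.
#' @return [readProbeAnnotation()]: a [GenomicRanges::GRanges], names =
#'   probe ids, with metadata columns `island_relation`, `gene`,
#'   `gene_region`.
#' @export
readProbeAnnotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character",
                          data.table = FALSE, showProgress = FALSE)
  need <- c("probe_id", "chromosome", "position", "island_relation",
            "gene", "gene_region")
  if (!all(need %in% colnames(dt)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(dt$probe_id)) stop("duplicate probe id in annotation: ", path)
  pos <- as.integer(dt$position)
  if (anyNA(pos) || any(pos < 1)) stop("positions must be integers >= 1")
  chrom <- ifelse(grepl("^chr", dt$chromosome), dt$chromosome,
                  paste0("chr", dt$chromosome))
  okChrom <- c(paste0("chr", 1:22), "chrX", "chrY")
  if (!all(chrom %in% okChrom)) stop("unknown chromosome label(s) in ", path)
  if (!all(dt$island_relation %in% ISLAND_RELATIONS))
    stop("island_relation outside {", paste(ISLAND_RELATIONS, collapse = ", "), "}")
  regions <- strsplit(dt$gene_region, ";", fixed = TRUE)
  flat <- unlist(regions)
  flat <- flat[nzchar(flat)]
  if (length(flat) && !all(flat %in% GENE_REGIONS))
    stop("gene_region outside {", paste(GENE_REGIONS, collapse = ", "), "}")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  names(gr) <- dt$probe_id
  gr$island_relation <- dt$island_relation
  gr$gene <- ifelse(is.na(dt$gene), "", dt$gene)
  gr$gene_region <- ifelse(is.na(dt$gene_region), "", dt$gene_region)
  gr
}

#' @rdname readProbeAnnotation
#' @param ann a probe-annotation `GRanges` as returned by
#'   [readProbeAnnotation()] or [generateAnnotationAndSets()].
#' @export
writeProbeAnnotation <- function(ann, path) {
  dt <- data.table::data.table(
    probe_id = names(ann),
    chromosome = as.character(GenomicRanges::seqnames(ann)),
    position = GenomicRanges::start(ann),
    island_relation = ann$island_relation,
    gene = ann$gene,
    gene_region = ann$gene_region)
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read / write a sample sheet
#'
#' CSV with header
#' `sample_id,role,grade,cell_type,group_label,mutations` and an optional
#' trailing `tumor_type` column (`primary|metastasis|unknown`). `role` is
#' one of tumor/normal/reference_cell; tumor rows must carry a grade
#' (NETG1/NETG2/NETG3/NEC/NA) and reference_cell rows a non-empty
#' `cell_type`; `mutations` is a `'|'`-joined set of gene symbols.
#'
#' @param path file path.
#' @return [readSampleSheet()]: a `data.frame` with those columns
#'   (`mutations` as a list column of character vectors).
#' @export
readSampleSheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = ",", header = TRUE,
                          colClasses = "character", na.strings = NULL,
                          data.table = FALSE, showProgress = FALSE)
  need <- c("sample_id", "role", "grade", "cell_type", "group_label", "mutations")
  if (!all(need %in% colnames(dt)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  if (!nrow(dt)) stop("empty sample sheet: ", path)
  if (anyDuplicated(dt$sample_id)) stop("duplicate sample id in ", path)
  if (!all(dt$role %in% SAMPLE_ROLES))
    stop("role outside {", paste(SAMPLE_ROLES, collapse = ", "), "}")
  grade <- ifelse(dt$grade == "", "NA", dt$grade)
  if (!all(grade %in% GRADES))
    stop("grade outside {", paste(GRADES, collapse = ", "), "}")
  isRef <- dt$role == "reference_cell"
  if (any(isRef & !nzchar(dt$cell_type)))
    stop("reference_cell rows must carry a cell_type")
  isTum <- dt$role == "tumor"
  if (any(isTum & dt$grade == ""))
    stop("tumor rows must carry a grade (use 'NA' when ungraded)")
  out <- data.frame(
    sample_id = dt$sample_id, role = dt$role, grade = grade,
    cell_type = dt$cell_type, group_label = dt$group_label,
    stringsAsFactors = FALSE)
  out$mutations <- lapply(strsplit(dt$mutations, "|", fixed = TRUE),
                          function(x) x[nzchar(x)])
  out$tumor_type <- if ("tumor_type" %in% colnames(dt)) dt$tumor_type else ""
  out
}

#' @rdname readSampleSheet
#' @param sheet a sample-sheet `data.frame`.
#' @export
writeSampleSheet <- function(sheet, path) {
  dt <- data.table::data.table(
    sample_id = sheet$sample_id, role = sheet$role, grade = sheet$grade,
    cell_type = sheet$cell_type, group_label = sheet$group_label,
    mutations = vapply(sheet$mutations, paste, "", collapse = "|"),
    tumor_type = if (is.null(sheet$tumor_type)) "" else sheet$tumor_type)
  data.table::fwrite(dt, path, sep = ",", quote = FALSE)
  invisible(path)
}

#' Beta-to-M logit transform
#'
#' Replaces each unmasked beta by `log2(b' / (1 - b'))` where
#' `b' = min(max(beta, clip), 1 - clip)`; clipping guarantees finite
#' M-values at beta = 0 or 1. Masked entries stay masked. The transform is
#' strictly increasing on `[clip, 1 - clip]` and odd around beta = 0.5.
#'
#' @param b a [BetaMatrix-class].
#' @param clip clipping bound in (0, 0.5); default 0.001.
#' @return an [MValueMatrix-class] with the same axes.
#' @examples
#' b <- BetaMatrix(matrix(c(0.5, 0.8), 1, 2,
#'        dimnames = list("cg1", c("s1", "s2"))))
#' mValues(betaToMValue(b))  # 0 and 2
#' @export
betaToMValue <- function(b, clip = 0.001) {
  stopifnot(is(b, "BetaMatrix"))
  if (!isSingleNumber(clip) || clip <= 0 || clip >= 0.5)
    stop("clip must lie in (0, 0.5)")
  v <- betaValues(b)
  v <- pmin(pmax(v, clip), 1 - clip)
  MValueMatrix(log2(v / (1 - v)))
}
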