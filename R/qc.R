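## NPX quality control: LOD-based detectability, assay inclusion filtering,
## PCA-based sample outlier exclusion.

#' Per-assay detectability
#'
#' Fraction of non-missing values strictly above the assay's limit of
#' detection. Missing values are excluded from the denominator; an assay with
#' no non-missing value is flagged with an `NA` fraction.
#'
#' @param npx an [NPXMatrix-class].
#' @return named numeric vector, one fraction in `[0, 1]` (or `NA`) per assay.
#' @examples
#' npx <- NPXMatrix(matrix(c(1, 3, 2, 0), 2, 2),
#'                  data.frame(protein_id = c("P1", "P2"), gene = "G",
#'                             chrom = "chr1", gene_start = 1, gene_end = 2,
#'                             panel = "ExploreI", lod = c(1.5, 1.5)))
#' detectability(npx)
#' @export
detectability <- function(npx) {
  stopifnot(is(npx, "NPXMatrix"))
  v <- npxValues(npx)
  above <- sweep(v, 1, lodValues(npx), FUN = ">")
  rowMeans(above, na.rm = TRUE)  # all-NA rows yield NaN
}

#' Filter assays on detectability
#'
#' Retains assays whose detectability is strictly greater than `minDetect`
#' (the default 0.25 keeps assays with more than 25% of values above LOD,
#' i.e. removes those with at least 75% of values below it). Below-LOD values
#' in retained assays are kept, never blanked. Idempotent.
#'
#' @param npx an [NPXMatrix-class].
#' @param minDetect detectability threshold in `[0, 1]`; strict inequality.
#' @return the filtered [NPXMatrix-class]; excluded assays (with their
#'   detectability) are recorded in `metadata(x)$excluded_assays`.
#' @export
filterAssays <- function(npx, minDetect = 0.25) {
  minDetect <- .checkFraction(minDetect, "minDetect")
  det <- detectability(npx)
  keep <- !is.na(det) & det > minDetect
  out <- npx[keep, ]
  excl <- data.frame(protein_id = assayAnnotation(npx)$protein_id[!keep],
                     detectability = det[!keep],
                     reason = ifelse(is.na(det[!keep]), "all values missing",
                                     paste0("detectability <= ", minDetect)),
                     stringsAsFactors = FALSE)
  S4Vectors::metadata(out)$excluded_assays <- excl
  out
}

#' PCA-based sample outlier detection
#'
#' Principal component analysis of the sample-by-assay matrix (missing values
#' mean-imputed per assay for the decomposition only); samples whose score on
#' any of the first `nComponents` components lies more than `zCut` standard
#' deviations from that component's mean are flagged.
#'
#' @param npx an [NPXMatrix-class] (after assay filtering).
#' @param nComponents number of leading components inspected.
#' @param zCut exclusion threshold in SD units (default 5; `Inf` disables).
#' @return data.frame with columns `sample_id`, `component`, `score`, `z`
#'   (one row per flagged sample/component pair; zero rows if none).
#' @export
pcaOutliers <- function(npx, nComponents = 2, zCut = 5) {
  nComponents <- .checkCount(nComponents, "nComponents")
  x <- t(npxValues(npx))  # samples x assays
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- mean(x[, j], na.rm = TRUE)
  }
  keep <- apply(x, 2, stats::var) > 0
  if (!any(keep))
    stop("decomposition error: NPX matrix is constant", call. = FALSE)
  x <- x[, keep, drop = FALSE]
  nComponents <- min(nComponents, ncol(x), nrow(x) - 1L)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(nComponents), drop = FALSE]
  z <- scale(scores)
  hits <- which(abs(z) > zCut, arr.ind = TRUE)
  data.frame(sample_id = colnames(npx)[hits[, 1]],
             component = colnames(scores)[hits[, 2]],
             score = scores[hits], z = z[hits],
             stringsAsFactors = FALSE)
}

#' Run the full NPX quality-control stage
#'
#' Computes per-assay detectability, drops assays at or below the
#' detectability threshold, then excludes PCA outlier samples.
#'
#' @inheritParams filterAssays
#' @inheritParams pcaOutliers
#' @return list with elements `npx` (the QC'd [NPXMatrix-class]) and `report`
#'   (list: `detectability` table, `excluded_assays`, `excluded_samples`).
#' @export
runQC <- function(npx, minDetect = 0.25, nComponents = 2, zCut = 5) {
  det <- detectability(npx)
  detTable <- data.frame(protein_id = assayAnnotation(npx)$protein_id,
                         detectability = det, stringsAsFactors = FALSE)
  kept <- filterAssays(npx, minDetect)
  outl <- pcaOutliers(kept, nComponents, zCut)
  exSamp <- unique(outl$sample_id)
  final <- kept[, !colnames(kept) %in% exSamp]
  report <- list(detectability = detTable,
                 excluded_assays = S4Vectors::metadata(kept)$excluded_assays,
                 excluded_samples = outl)
  list(npx = final, report = report)
}

#' Write a QC report to disk
#'
#' @param report the `report` element of [runQC()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (detectability TSV, exclusion TSVs,
#'   JSON summary).
#' @export
writeQCReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(detectability = file.path(dir, "detectability.tsv"),
             assays = file.path(dir, "excluded_assays.tsv"),
             samples = file.path(dir, "excluded_samples.tsv"),
             json = file.path(dir, "qc_report.json"))
  data.table::fwrite(report$detectability, paths["detectability"],
                     sep = "\t")
  data.table::fwrite(report$excluded_assays, paths["assays"], sep = "\t")
  data.table::fwrite(report$excluded_samples, paths["samples"], sep = "\t")
  jsonlite::write_json(
    list(n_assays = nrow(report$detectability),
         n_excluded_assays = nrow(report$excluded_assays),
         excluded_samples = unique(report$excluded_samples$sample_id)),
    paths["json"], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
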