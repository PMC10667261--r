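## Plain-text readers and writers for every exchanged table: dosage TSV,
## minimal VCF, NPX wide CSV with LOD sidecar, covariate TSV, outcome
## summary TSV. All tables round-trip through their readers.

utils::globalVariables(c("pos", "y", "r2"))

#' Write/read a genotype dosage TSV
#'
#' Layout: variant metadata columns (`id, chrom, pos, effect_allele,
#' other_allele, eaf`) followed by one column per sample.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param path file path.
#' @return `writeDosageTSV()` the path, invisibly; `readDosageTSV()` a
#'   [GenotypeMatrix-class].
#' @export
writeDosageTSV <- function(genotypes, path) {
  tab <- cbind(variantInfo(genotypes), as.data.frame(dosages(genotypes)))
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}

#' @rdname writeDosageTSV
#' @export
readDosageTSV <- function(path) {
  tab <- as.data.frame(data.table::fread(path, sep = "\t"))
  meta <- c("id", "chrom", "pos", "effect_allele", "other_allele", "eaf")
  GenotypeMatrix(as.matrix(tab[, setdiff(names(tab), meta)]), tab[, meta])
}

#' Write genotypes as a minimal VCF
#'
#' VCFv4.2 with GT fields only; requires integral dosages (0/1/2), written
#' with the effect allele as ALT so the ALT dosage equals the stored dosage.
#'
#' @param genotypes a [GenotypeMatrix-class] with integer dosages.
#' @param path output path (uncompressed `.vcf`).
#' @return the path, invisibly.
#' @export
writeVCF <- function(genotypes, path) {
  d <- dosages(genotypes)
  if (any(d != round(d)))
    stop("VCF output requires integral dosages", call. = FALSE)
  v <- variantInfo(genotypes)
  gt <- matrix(c("0/0", "0/1", "1/1")[d + 1], nrow(d), ncol(d))
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(d)), collapse = "\t"))
  body <- paste(v$chrom, v$pos, v$id, v$other_allele, v$effect_allele, ".",
                "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write/read an NPX matrix as wide CSV plus LOD sidecar
#'
#' The main CSV has one row per sample (`sample_id` first column, one column
#' per protein assay); the sidecar CSV holds the per-assay annotation
#' including the limit of detection.
#'
#' @param npx an [NPXMatrix-class].
#' @param path main CSV path; the sidecar is written next to it with suffix
#'   `"_assays.csv"`.
#' @return `writeNPXCSV()` the two paths, invisibly; `readNPXCSV()` an
#'   [NPXMatrix-class].
#' @export
writeNPXCSV <- function(npx, path) {
  side <- sub("\\.csv$", "", path)
  side <- paste0(side, "_assays.csv")
  wide <- data.frame(sample_id = colnames(npx), t(npxValues(npx)),
                     check.names = FALSE)
  data.table::fwrite(wide, path)
  data.table::fwrite(assayAnnotation(npx), side)
  invisible(c(path, side))
}

#' @rdname writeNPXCSV
#' @export
readNPXCSV <- function(path) {
  side <- paste0(sub("\\.csv$", "", path), "_assays.csv")
  wide <- as.data.frame(data.table::fread(path))
  anno <- as.data.frame(data.table::fread(side))
  vals <- t(as.matrix(wide[, anno$protein_id, drop = FALSE]))
  colnames(vals) <- wide$sample_id
  NPXMatrix(vals, anno)
}

#' Write/read an outcome summary-statistics TSV
#'
#' Header: `chrom pos id effect_allele other_allele eaf beta se p n_case
#' n_control`.
#'
#' @param outcome outcome summary data.frame.
#' @param path file path.
#' @return `writeOutcomeSummary()` the path, invisibly;
#'   `readOutcomeSummary()` the data.frame.
#' @export
writeOutcomeSummary <- function(outcome, path) {
  cols <- c("chrom", "pos", "id", "effect_allele", "other_allele", "eaf",
            "beta", "se", "p", "n_case", "n_control")
  data.table::fwrite(outcome[, cols], path, sep = "\t")
  invisible(path)
}

#' @rdname writeOutcomeSummary
#' @export
readOutcomeSummary <- function(path) {
  out <- as.data.frame(data.table::fread(path, sep = "\t"))
  if (any(out$se <= 0)) stop("invalid outcome summary: se must be > 0",
                             call. = FALSE)
  out
}

#' Write/read a covariate TSV
#'
#' @param covariates covariate data.frame ([simulateCovariates()] layout).
#' @param path file path.
#' @return `writeCovariates()` the path, invisibly; `readCovariates()` the
#'   data.frame with categorical levels restored.
#' @export
writeCovariates <- function(covariates, path) {
  data.table::fwrite(covariates, path, sep = "\t")
  invisible(path)
}

#' @rdname writeCovariates
#' @export
readCovariates <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  df$menopause <- factor(df$menopause, levels = c("pre", "peri", "post"))
  df$hrt_status <- factor(df$hrt_status,
                          levels = c("never_or_past", "current"))
  df$smoking_status <- factor(df$smoking_status,
                              levels = c("never_or_past", "current"))
  df$case_status <- factor(df$case_status, levels = c("control", "case"))
  df
}
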