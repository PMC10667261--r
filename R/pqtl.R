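## Cis-window pQTL scanning: region definition, covariate-adjusted additive
## association, independent-variant counting, the global significance
## threshold, and greedy clumping of significant hits.

#' Define the cis testing region for one protein assay
#'
#' The window is `[max(1, gene_start - window), gene_end + window]`, 1-based
#' inclusive; variants on the gene's chromosome with position inside the
#' window belong to the region.
#'
#' @param assay one-row data.frame (or list) with `protein_id`, `chrom`,
#'   `gene_start`, `gene_end` — one row of [assayAnnotation()].
#' @param variants variant metadata data.frame ([variantInfo()]), sorted by
#'   position within chromosome.
#' @param window flank size in bp on each side of the gene (default 1 Mbp).
#' @return a [CisRegion-class], or `NULL` (with a warning) when the assay
#'   lacks gene coordinates.
#' @export
defineCisRegion <- function(assay, variants, window = 1000000) {
  if (is.na(assay$gene_start) || is.na(assay$gene_end) ||
      is.na(assay$chrom)) {
    warning("assay ", assay$protein_id,
            " lacks gene coordinates; region skipped")
    return(NULL)
  }
  lo <- max(1, assay$gene_start - window)
  hi <- assay$gene_end + window
  inWin <- variants$chrom == assay$chrom &
    variants$pos >= lo & variants$pos <= hi
  ids <- variants$id[inWin][order(variants$pos[inWin])]
  new("CisRegion", proteinId = as.character(assay$protein_id),
      chrom = as.character(assay$chrom),
      windowStart = lo, windowEnd = hi,
      variantIds = ids, nVariants = length(ids),
      nIndependent = NA_integer_)
}

## residualise columns of M on covariate design X (with intercept)
.residualise <- function(M, X) {
  qrX <- qr(X)
  M - X %*% qr.coef(qrX, M)
}

#' Cis-window association scan for one protein
#'
#' Per variant in the region, an additive OLS model of NPX on dosage adjusted
#' for age, BMI and 10 genetic principal components. Computed by
#' Frisch-Waugh residualisation (NPX and each dosage regressed on the
#' covariates, then on each other), which is identical to the joint model.
#' Variants with minor allele frequency below `mafMin` are dropped before
#' testing; zero-variance dosages are skipped with a reason. NPX is
#' z-standardised per protein by default, so betas are in NPX SD units per
#' effect-allele copy; values below LOD participate like any other value.
#'
#' @param npxColumn one protein's NPX values aligned to genotype samples.
#' @param genotypes a [GenotypeMatrix-class].
#' @param covariates covariate data.frame with `age`, `bmi`, `PC1`..`PC10`.
#' @param region a [CisRegion-class] for this protein.
#' @param mafMin minor-allele-frequency filter (default 0.01, strict `<`
#'   drops).
#' @param standardize z-scale the NPX vector first (default `TRUE`).
#' @return data.frame of association results (`protein_id, id, chrom, pos,
#'   effect_allele, other_allele, eaf, beta, se, p, n`); skipped variants are
#'   recorded in `attr(, "skipped")`.
#' @export
cisScan <- function(npxColumn, genotypes, covariates, region,
                    mafMin = 0.01, standardize = TRUE) {
  stopifnot(is(region, "CisRegion"))
  vinfo <- variantInfo(genotypes)
  idx <- match(region@variantIds, vinfo$id)
  if (anyNA(idx)) stop("region variants missing from genotypes",
                       call. = FALSE)
  G <- t(dosages(genotypes)[idx, , drop = FALSE])  # samples x variants
  ok <- !is.na(npxColumn)
  G <- G[ok, , drop = FALSE]
  y <- npxColumn[ok]
  if (standardize) y <- as.numeric(scale(y))
  covs <- covariates[ok, , drop = FALSE]
  X <- as.matrix(cbind(1, covs[, c("age", "bmi", paste0("PC", 1:10))]))
  n <- nrow(G)

  af <- colMeans(G) / 2
  maf <- pmin(af, 1 - af)
  vr <- apply(G, 2, stats::var)
  drop <- maf < mafMin | vr == 0
  skipped <- data.frame(
    id = colnames(G)[drop],
    reason = ifelse(vr[drop] == 0, "zero-variance dosage",
                    paste0("MAF < ", mafMin)),
    stringsAsFactors = FALSE)
  keep <- which(!drop)
  if (!length(keep)) {
    out <- vinfo[integer(0), ]
    attr(out, "skipped") <- skipped
    return(out)
  }
  Gk <- G[, keep, drop = FALSE]
  ry <- .residualise(cbind(y), X)[, 1]
  rG <- .residualise(Gk, X)
  sxx <- colSums(rG^2)
  beta <- as.numeric(crossprod(rG, ry)) / sxx
  df <- n - ncol(X) - 1L
  rss <- sum(ry^2) - beta^2 * sxx
  se <- sqrt(pmax(rss, 0) / df / sxx)
  tv <- beta / se
  pv <- 2 * stats::pt(-abs(tv), df)
  v <- vinfo[idx[keep], ]
  out <- data.frame(protein_id = region@proteinId, id = v$id,
                    chrom = v$chrom, pos = v$pos,
                    effect_allele = v$effect_allele,
                    other_allele = v$other_allele,
                    eaf = af[keep], beta = beta, se = se, p = pv, n = n,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Count independent variants in a region
#'
#' Greedy pruning on squared Pearson correlation of dosages, iterating in
#' position order: a variant is kept iff its r-squared with every previously
#' kept variant is below `r2Max`. Position order (rather than p-value order)
#' makes the count independent of any association result, as it must be —
#' it defines the multiple-testing burden.
#'
#' @param regionDosages samples x variants dosage matrix in position order.
#' @param r2Max pruning threshold (default 0.1).
#' @return integer count of kept variants (1 for a single-variant region).
#' @export
countIndependent <- function(regionDosages, r2Max = 0.1) {
  m <- ncol(regionDosages)
  if (m == 0L) return(0L)
  kept <- 1L
  for (j in seq_len(m)[-1]) {
    r2 <- vapply(kept, function(k)
      .r2(regionDosages[, j], regionDosages[, k]), numeric(1))
    if (all(r2 < r2Max)) kept <- c(kept, j)
  }
  length(kept)
}

#' Global cis significance threshold
#'
#' Bonferroni-style alpha divided by the mean number of independent variants
#' per cis region (e.g. 0.05 / 180 = 2.77e-4), applied globally to all cis
#' tests.
#'
#' @param meanIndependent mean independent-variant count, at least 1.
#' @param alpha family-wise alpha (default 0.05).
#' @return the p-value threshold.
#' @examples
#' significanceThreshold(180)  # 2.77e-4
#' @export
significanceThreshold <- function(meanIndependent, alpha = 0.05) {
  if (!is.numeric(meanIndependent) || meanIndependent < 1)
    stop("'meanIndependent' must be >= 1", call. = FALSE)
  alpha / meanIndependent
}

## shared greedy clumping on ascending p with documented tie rule
## (lower p, then lower se, then position); returns row indices of results
.greedyClump <- function(results, regionDosages, r2Max) {
  ord <- order(results$p, results$se, results$pos)
  chosen <- integer(0)
  for (i in ord) {
    gi <- regionDosages[, results$id[i]]
    if (all(vapply(chosen, function(k)
      .r2(gi, regionDosages[, results$id[k]]), numeric(1)) < r2Max))
      chosen <- c(chosen, i)
  }
  chosen
}

#' Select independent significant cis-pQTL
#'
#' Greedy clumping by ascending p-value: the most significant variant below
#' the threshold is taken, every variant with r-squared at or above `r2Max`
#' against it is discarded, and the process repeats. Ties in p are broken by
#' lower standard error, then position. Returned hits are pairwise
#' r-squared `< r2Max` by construction.
#'
#' @param results association data.frame from [cisScan()] (one region).
#' @param threshold global significance threshold from
#'   [significanceThreshold()].
#' @param regionDosages samples x variants dosage matrix with variant ids as
#'   column names (LD reference).
#' @param r2Max clumping threshold (default 0.1).
#' @return the significant subset of `results` with a `rank` column in
#'   selection order; zero rows when nothing is significant.
#' @export
selectPqtl <- function(results, threshold, regionDosages, r2Max = 0.1) {
  sig <- results[!is.na(results$p) & results$p < threshold, , drop = FALSE]
  if (!nrow(sig)) {
    sig$rank <- integer(0)
    return(sig)
  }
  chosen <- .greedyClump(sig, regionDosages, r2Max)
  out <- sig[chosen, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Scan all proteins for cis-pQTL
#'
#' Runs [defineCisRegion()], [cisScan()], [countIndependent()] per protein,
#' derives the global threshold from the mean independent count (or a fixed
#' `alphaFixed`), then clumps significant hits per region.
#'
#' @param npx a QC'd [NPXMatrix-class].
#' @param genotypes a [GenotypeMatrix-class].
#' @param covariates covariate data.frame aligned to samples.
#' @param window cis window in bp (default 1 Mbp).
#' @param mafMin minor-allele-frequency filter.
#' @param r2Independent pruning threshold for counting and clumping.
#' @param alpha family-wise alpha for the threshold.
#' @param alphaFixed optional fixed p-value threshold overriding the
#'   mean-independent derivation.
#' @param perRegion if `TRUE`, each region is tested at
#'   `alpha / nIndependent(region)` instead of the global threshold.
#' @return list: `hits` (all clumped pQTL with ranks), `associations` (full
#'   scan results), `regions` (per-region summary with `n_variants`,
#'   `n_independent`), `threshold`, `meanIndependent`.
#' @export
pqtlScan <- function(npx, genotypes, covariates, window = 1000000,
                     mafMin = 0.01, r2Independent = 0.1, alpha = 0.05,
                     alphaFixed = NULL, perRegion = FALSE) {
  if (!identical(colnames(genotypes), colnames(npx)))
    stop("alignment error: genotype and NPX samples differ", call. = FALSE)
  if (!identical(colnames(genotypes), covariates$sample_id))
    stop("alignment error: genotype samples and covariate rows differ",
         call. = FALSE)
  anno <- assayAnnotation(npx)
  vinfo <- variantInfo(genotypes)
  v <- npxValues(npx)
  dosT <- t(dosages(genotypes))
  regions <- list(); assoc <- list(); nInd <- integer(0)
  for (i in seq_len(nrow(anno))) {
    reg <- defineCisRegion(anno[i, ], vinfo, window)
    if (is.null(reg) || reg@nVariants == 0L) next
    D <- dosT[, reg@variantIds, drop = FALSE]
    reg@nIndependent <- as.integer(countIndependent(D, r2Independent))
    regions[[reg@proteinId]] <- reg
    assoc[[reg@proteinId]] <- cisScan(v[i, ], genotypes, covariates, reg,
                                      mafMin)
    nInd[reg@proteinId] <- reg@nIndependent
  }
  meanInd <- mean(nInd)
  thr <- if (!is.null(alphaFixed)) alphaFixed
         else significanceThreshold(meanInd, alpha)
  hits <- list()
  for (pid in names(assoc)) {
    res <- assoc[[pid]]
    if (!nrow(res)) next
    thisThr <- if (perRegion) alpha / nInd[pid] else thr
    D <- dosT[, regions[[pid]]@variantIds, drop = FALSE]
    h <- selectPqtl(res, thisThr, D, r2Independent)
    if (nrow(h)) hits[[pid]] <- h
  }
  regionTable <- do.call(rbind, lapply(regions, function(r)
    data.frame(protein_id = r@proteinId, chrom = r@chrom,
               window_start = r@windowStart, window_end = r@windowEnd,
               n_variants = r@nVariants, n_independent = r@nIndependent,
               stringsAsFactors = FALSE)))
  rownames(regionTable) <- NULL
  list(hits = if (length(hits)) do.call(rbind, c(hits,
                                                 make.row.names = FALSE))
       else NULL,
       associations = do.call(rbind, c(assoc, make.row.names = FALSE)),
       regions = regionTable, threshold = thr, meanIndependent = meanInd)
}
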