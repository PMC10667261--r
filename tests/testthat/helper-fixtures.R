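# Small in-code fixture builders shared across test files.

# NPX container with minimal annotation; values is assays x samples
makeNPX <- function(values, lod, panel = "ExploreI") {
  k <- nrow(values)
  anno <- data.frame(protein_id = paste0("P", seq_len(k)),
                     gene = paste0("G", seq_len(k)),
                     chrom = "chr1",
                     gene_start = 2000000L, gene_end = 2010000L,
                     panel = panel, lod = lod,
                     stringsAsFactors = FALSE)
  colnames(values) <- sprintf("S%04d", seq_len(ncol(values)))
  NPXMatrix(values, anno)
}

# genotype container from a samples x variants dosage matrix
makeGenotypes <- function(dosage, pos = NULL, chrom = "chr1",
                          eaf = colMeans(dosage) / 2) {
  m <- ncol(dosage)
  if (is.null(pos)) pos <- seq(1000000L, by = 10000L, length.out = m)
  v <- data.frame(id = paste0("v", seq_len(m)), chrom = chrom, pos = pos,
                  effect_allele = "A", other_allele = "G", eaf = eaf,
                  stringsAsFactors = FALSE)
  d <- t(dosage)
  colnames(d) <- sprintf("S%04d", seq_len(nrow(dosage)))
  GenotypeMatrix(d, v)
}

# covariate table with exact layout but controlled values
makeCovariates <- function(n, seed = 1) {
  set.seed(seed)
  df <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    age = rnorm(n, 54, 9), bmi = rnorm(n, 25, 4),
    menopause = factor(sample(c("pre", "peri", "post"), n, TRUE),
                       levels = c("pre", "peri", "post")),
    birth_times = rpois(n, 2),
    hrt_status = factor(sample(c("never_or_past", "current"), n, TRUE),
                        levels = c("never_or_past", "current")),
    alcohol_gram_week = rgamma(n, 2, 0.05),
    smoking_status = factor(sample(c("never_or_past", "current"), n, TRUE),
                            levels = c("never_or_past", "current")),
    storage_time = runif(n, 100, 2000),
    case_status = factor(rep(c("control", "case"), length.out = n),
                         levels = c("control", "case")),
    stringsAsFactors = FALSE)
  cbind(df, matrix(rnorm(n * 10), n, 10,
                   dimnames = list(NULL, paste0("PC", 1:10))))
}

# AR(1)-correlated dosage panel for LD fixtures (samples x variants)
makeLDDosage <- function(n, m, rho, maf = rep(0.3, m), seed = 1) {
  set.seed(seed)
  hap <- function() {
    z <- matrix(rnorm(n * m), n, m)
    if (m > 1 && rho > 0)
      for (j in 2:m) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
    sweep(z, 2, qnorm(maf), "<") * 1
  }
  d <- hap() + hap()
  colnames(d) <- paste0("v", seq_len(m))
  d
}

# independent re-implementation of the greedy position-order pruning rule
oracleCountIndependent <- function(D, r2max = 0.1) {
  kept <- integer(0)
  for (j in seq_len(ncol(D))) {
    ok <- TRUE
    for (k in kept) {
      r <- suppressWarnings(cor(D[, j], D[, k]))
      r2 <- if (is.na(r)) 0 else r^2
      if (r2 >= r2max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, j)
  }
  length(kept)
}

# independent re-implementation of greedy p-ordered clumping; returns ids
oracleClump <- function(res, D, r2max) {
  res <- res[order(res$p, res$se, res$pos), ]
  chosen <- character(0)
  for (i in seq_len(nrow(res))) {
    ok <- TRUE
    for (id in chosen) {
      r <- suppressWarnings(cor(D[, res$id[i]], D[, id]))
      r2 <- if (is.na(r)) 0 else r^2
      if (r2 >= r2max) { ok <- FALSE; break }
    }
    if (ok) chosen <- c(chosen, res$id[i])
  }
  chosen
}

# brute-force Benjamini-Hochberg step-up from the definition
oracleBH <- function(p, m = length(p)) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (r in seq_len(n)) {
    cand <- p[o][r:n] * m / (r:n)
    q[o[r]] <- min(1, min(cand))
  }
  q
}
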