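# Cis-region definition, covariate-adjusted scanning, independent-variant
# counting, the significance threshold, and greedy hit clumping.

assayRow <- function(start = 2000000L, end = 2010000L)
  data.frame(protein_id = "P1", chrom = "chr1", gene_start = start,
             gene_end = end, stringsAsFactors = FALSE)

test_that("cis window boundaries are 1-based inclusive", {
  v <- data.frame(id = c("a", "b", "c"), chrom = "chr1",
                  pos = c(999999L, 1000000L, 3010000L),
                  effect_allele = "A", other_allele = "G", eaf = 0.3)
  reg <- defineCisRegion(assayRow(), v)
  expect_equal(reg@windowStart, 1000000)
  expect_equal(reg@windowEnd, 3010000)
  expect_setequal(reg@variantIds, c("b", "c"))  # 999999 excluded
  # window clipped at 1 for genes near the chromosome start
  regClip <- defineCisRegion(assayRow(start = 500L, end = 600L), v)
  expect_equal(regClip@windowStart, 1)
  # missing coordinates -> skipped with warning
  expect_warning(
    expect_null(defineCisRegion(assayRow(start = NA), v)), "skipped")
})

test_that("region membership matches a brute-force interval test", {
  set.seed(30)
  pos <- sort(sample(1:4000000, 20))
  v <- data.frame(id = paste0("v", 1:20), chrom = "chr1", pos = pos,
                  effect_allele = "A", other_allele = "G", eaf = 0.3)
  reg <- defineCisRegion(assayRow(), v)
  manual <- v$id[v$pos >= 1000000 & v$pos <= 3010000]
  expect_identical(reg@variantIds, manual)
  expect_equal(reg@nVariants, length(manual))
})

test_that("cisScan recovers a known dosage effect with covariates", {
  set.seed(31)
  n <- 598
  d <- makeLDDosage(n, 5, rho = 0.3, seed = 31)
  g <- makeGenotypes(d, pos = seq(2000000L, by = 1000L, length.out = 5))
  cov <- makeCovariates(n)
  npx <- 0.4 * d[, 3] + rnorm(n, 0, 0.05)
  reg <- defineCisRegion(assayRow(), variantInfo(g))
  res <- cisScan(npx, g, cov, reg, standardize = FALSE)
  hit <- res[res$id == "v3", ]
  expect_lt(abs(hit$beta - 0.4), 1.96 * hit$se)
  expect_equal(res$n, rep(n, nrow(res)))
})

test_that("null p-values are uniform across independent variants", {
  set.seed(32)
  n <- 400
  d <- makeLDDosage(n, 200, rho = 0, seed = 32)
  g <- makeGenotypes(d, pos = seq(2000000L, by = 1000L, length.out = 200))
  cov <- makeCovariates(n)
  reg <- defineCisRegion(assayRow(), variantInfo(g))
  res <- cisScan(rnorm(n), g, cov, reg)
  expect_gt(ks.test(res$p, "punif")$p.value, 0.01)
})

test_that("allele recoding negates beta and preserves p", {
  set.seed(33)
  n <- 300
  d <- makeLDDosage(n, 4, rho = 0, seed = 33)
  cov <- makeCovariates(n)
  npx <- 0.3 * d[, 2] + rnorm(n)
  pos <- seq(2000000L, by = 1000L, length.out = 4)
  g1 <- makeGenotypes(d, pos = pos)
  g2 <- makeGenotypes(2 - d, pos = pos)    # swap effect/other coding
  reg <- defineCisRegion(assayRow(), variantInfo(g1))
  r1 <- cisScan(npx, g1, cov, reg)
  r2 <- cisScan(npx, g2, cov, reg)
  expect_equal(r1$beta, -r2$beta, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
})

test_that("joint-model beta equals Frisch-Waugh residualised beta", {
  set.seed(34)
  n <- 250
  d <- makeLDDosage(n, 3, rho = 0.5, seed = 34)
  g <- makeGenotypes(d, pos = seq(2000000L, by = 1000L, length.out = 3))
  cov <- makeCovariates(n)
  npx <- 0.2 * d[, 1] + 0.02 * cov$age + rnorm(n)
  reg <- defineCisRegion(assayRow(), variantInfo(g))
  res <- cisScan(npx, g, cov, reg, standardize = FALSE)
  X <- as.matrix(cbind(cov$age, cov$bmi, cov[, paste0("PC", 1:10)]))
  for (j in 1:3) {
    joint <- coef(lm(npx ~ d[, j] + X))[2]
    expect_equal(res$beta[res$id == paste0("v", j)], unname(joint),
                 tolerance = 1e-8)
  }
})

test_that("MAF filtering and zero-variance skipping are reported", {
  set.seed(35)
  n <- 200
  d <- makeLDDosage(n, 4, rho = 0, seed = 35)
  d[, 2] <- 0                                   # monomorphic
  d[, 3] <- rbinom(n, 2, 0.003)                 # rare
  g <- makeGenotypes(d, pos = seq(2000000L, by = 1000L, length.out = 4),
                     eaf = c(0.3, 0.01, 0.005, 0.3))
  reg <- defineCisRegion(assayRow(), variantInfo(g))
  res <- cisScan(rnorm(n), g, makeCovariates(n), reg, mafMin = 0.01)
  expect_setequal(res$id, c("v1", "v4"))
  expect_setequal(attr(res, "skipped")$id, c("v2", "v3"))
  expect_true("zero-variance dosage" %in% attr(res, "skipped")$reason)
})

test_that("countIndependent follows the greedy position-order rule", {
  set.seed(36)
  ind <- makeLDDosage(100, 5, rho = 0, seed = 36)
  expect_equal(countIndependent(ind), 5L)

  dup <- cbind(ind[, 1], ind[, 1], ind[, 2])   # duplicated variant
  expect_equal(countIndependent(dup), 2L)

  # invariant to duplicating any kept variant
  d12 <- makeLDDosage(100, 12, rho = 0.8, seed = 37)
  base <- countIndependent(d12)
  expect_equal(countIndependent(cbind(d12, d12[, 1])), base)

  # block-LD fixtures match the independent oracle
  for (i in 1:30) {
    D <- makeLDDosage(150, 12, rho = runif(1, 0.3, 0.97), seed = 100 + i)
    expect_equal(countIndependent(D), oracleCountIndependent(D))
  }
})

test_that("the significance threshold divides alpha by the mean count", {
  # 0.05/180 = 2.7778e-4, printed as 2.77E-04 (truncated to 3 sig. figures)
  expect_equal(trunc(significanceThreshold(180) * 1e6) / 1e6, 2.77e-4)
  expect_equal(significanceThreshold(1), 0.05)
  expect_equal(trunc(significanceThreshold(511) * 1e7) / 1e7, 9.78e-5)
  expect_error(significanceThreshold(0.5), ">= 1")
})

test_that("selectPqtl clumps greedily by ascending p", {
  set.seed(38)
  D <- makeLDDosage(400, 6, rho = 0.9, seed = 38)
  res <- data.frame(protein_id = "P1", id = paste0("v", 1:6), chrom = "chr1",
                    pos = 1:6 * 1000L, effect_allele = "A",
                    other_allele = "G", eaf = 0.3,
                    beta = 0.3, se = 0.05,
                    p = c(1e-8, 2e-3, 5e-9, 0.2, 1e-4, 0.9), n = 400)
  hits <- selectPqtl(res, threshold = 2.77e-4, D)
  expect_equal(hits$id[1], "v3")            # smallest p leads
  expect_equal(hits$rank, seq_len(nrow(hits)))
  # pairwise r2 of hits below threshold, by post-hoc assertion
  if (nrow(hits) > 1) {
    cmb <- combn(hits$id, 2)
    r2s <- apply(cmb, 2, function(ij) cor(D[, ij[1]], D[, ij[2]])^2)
    expect_true(all(r2s < 0.1))
  }
  # adjacent high-LD pair: only the smaller-p one survives
  r2_13 <- cor(D[, "v1"], D[, "v3"])^2
  if (r2_13 >= 0.1) expect_false("v1" %in% hits$id)
  # nothing significant -> empty, not an error
  none <- selectPqtl(transform(res, p = p + 0.5), 2.77e-4, D)
  expect_equal(nrow(none), 0L)
})

test_that("a simulated causal region is led by the causal variant or a tight proxy", {
  found <- vapply(1:100, function(i) {
    cfg <- simulationConfig(nProteins = 1, nSamples = 598, cisH2 = 0.1,
                            scenario = "null", seed = 2000 + i)
    rep <- mrSimulationReplicate(cfg, protein = 1)
    if (is.na(rep$leadHitId)) return(NA)
    if (rep$leadHitId == rep$truth$lead_id) return(TRUE)
    g <- simulateGenotypes(cfg)
    D <- t(dosages(g))
    cor(D[, rep$leadHitId], D[, rep$truth$lead_id])^2 > 0.5
  }, logical(1))
  expect_gte(mean(found, na.rm = TRUE), 0.9)
})

test_that("pqtlScan is calibrated under the cis-null", {
  cfg <- simulationConfig(nProteins = 40, nSamples = 300, cisH2 = 0,
                          covariateEffects = numeric(0), seed = 40)
  g <- simulateGenotypes(cfg)
  cov <- simulateCovariates(cfg)
  npx <- simulateNPX(g, cov, cfg)
  # at the fixed 2.77e-4 threshold the per-region family-wise rate is well
  # below alpha (21 correlated tests x 2.77e-4)
  scan <- pqtlScan(npx, g, cov, alphaFixed = 2.77e-4)
  nWithHit <- if (is.null(scan$hits)) 0 else
    length(unique(scan$hits$protein_id))
  expect_lte(nWithHit / 40, 0.05 + 3 * sqrt(0.05 * 0.95 / 40))
})
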