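# Regional alignment, lead concordance, proxy lookup, effect-size
# concordance across studies.

mkAssoc <- function(ids, pos, p, beta = 0.3, chrom = "chr1", ea = "A",
                    oa = "G")
  data.frame(protein_id = "P1", id = ids, chrom = chrom, pos = pos,
             effect_allele = ea, other_allele = oa, eaf = 0.3, beta = beta,
             se = 0.05, p = p, n = 500, stringsAsFactors = FALSE)

mkOutcome <- function(ids, pos, p, beta = 0.1, ea = "A", oa = "G",
                      chrom = "chr1")
  data.frame(chrom = chrom, pos = pos, id = ids, effect_allele = ea,
             other_allele = oa, eaf = 0.3, beta = beta, se = 0.02, p = p,
             n_case = 5000, n_control = 5000, stringsAsFactors = FALSE)

mkRegion <- function(ids, lo = 1L, hi = 10000000L)
  new("CisRegion", proteinId = "P1", chrom = "chr1", windowStart = lo,
      windowEnd = hi, variantIds = ids, nVariants = length(ids),
      nIndependent = NA_integer_)

test_that("region alignment joins on the shared variant set", {
  ids <- paste0("v", 1:8)
  pos <- 1:8 * 1000L
  D <- makeLDDosage(200, 8, rho = 0.5, seed = 60)
  e <- mkAssoc(ids, pos, p = runif(8))
  o <- mkOutcome(ids, pos, p = runif(8))
  al <- regionAlignment(e, o, mkRegion(ids), D)
  expect_equal(nrow(al$data), 8L)           # identical sets: full join

  # outcome missing half: join is the brute-force intersection
  oHalf <- o[c(1, 3, 5, 7), ]
  alH <- regionAlignment(e, oHalf, mkRegion(ids), D)
  expect_setequal(alH$data$id, intersect(e$id, oHalf$id))
  # symmetric join size
  expect_equal(nrow(alH$data), length(intersect(oHalf$id, e$id)))

  # all outcome p = 1 -> outcome track flat at 0
  oFlat <- mkOutcome(ids, pos, p = rep(1, 8))
  alF <- regionAlignment(e, oFlat, mkRegion(ids), D)
  expect_equal(alF$data$mlog10p_outcome, rep(0, 8))

  expect_error(regionAlignment(e, mkOutcome("z9", 500L, 0.5, chrom = "chr9"),
                               mkRegion(ids), D), "empty region")
})

test_that("leads are the argmin-p variants of the shared set", {
  ids <- paste0("v", 1:5)
  pos <- 1:5 * 1000L
  D <- makeLDDosage(200, 5, rho = 0.3, seed = 61)
  e <- mkAssoc(ids, pos, p = c(0.5, 1e-9, 0.2, 0.8, 0.1))
  o <- mkOutcome(ids, pos, p = c(0.9, 0.3, 0.2, 1e-6, 0.7))
  al <- regionAlignment(e, o, mkRegion(ids), D)
  expect_equal(al$lead_exposure_id, "v2")
  expect_equal(al$lead_outcome_id, "v4")
  expect_true(all(al$data$mlog10p_exposure >= 0))
})

test_that("lead concordance verdicts follow the r2 tiers", {
  ids <- paste0("v", 1:5)
  pos <- 1:5 * 1000L
  D <- makeLDDosage(300, 5, rho = 0.2, seed = 62)
  e <- mkAssoc(ids, pos, p = c(1e-9, 0.5, 0.5, 0.5, 0.5))

  # identical leads -> concordant with r2 = 1
  o1 <- mkOutcome(ids, pos, p = c(1e-7, 0.5, 0.5, 0.5, 0.5))
  v1 <- leadConcordance(regionAlignment(e, o1, mkRegion(ids), D), D)
  expect_true(v1$same_lead)
  expect_equal(v1$r2_leads, 1)
  expect_equal(v1$verdict, "concordant_lead")

  # tight-LD leads (duplicated column, r2 = 1 but different id)
  D2 <- cbind(D, v6 = D[, "v1"])
  e2 <- mkAssoc(c(ids, "v6"), c(pos, 6000L), p = c(1e-9, rep(0.5, 4), 0.4))
  o2 <- mkOutcome(c(ids, "v6"), c(pos, 6000L),
                  p = c(0.4, rep(0.5, 4), 1e-7))
  v2 <- leadConcordance(regionAlignment(e2, o2, mkRegion(c(ids, "v6")), D2),
                        D2)
  expect_false(v2$same_lead)
  expect_equal(v2$verdict, "concordant_lead")

  # uncorrelated leads -> discordant
  o3 <- mkOutcome(ids, pos, p = c(0.5, 0.5, 0.5, 1e-7, 0.5))
  v3 <- leadConcordance(regionAlignment(e, o3, mkRegion(ids), D), D)
  expect_equal(v3$verdict, "discordant")
})

test_that("proxy lookup matches an exhaustive all-pairs scan", {
  D <- makeLDDosage(400, 10, rho = 0.97, seed = 63)
  px <- proxyLookup("v5", D, r2Min = 0.8)
  brute <- sapply(setdiff(colnames(D), "v5"),
                  function(id) cor(D[, id], D[, "v5"])^2)
  expect_setequal(px$id, names(brute)[brute > 0.8])
  expect_false("v5" %in% px$id)
  expect_true(all(diff(px$r2) <= 0))   # sorted by descending r2

  # duplicated variant returns r2 = 1
  D2 <- cbind(D, v11 = D[, "v5"])
  expect_equal(proxyLookup("v11", D2)$id[1], "v5")
  expect_equal(proxyLookup("v11", D2)$r2[1], 1)

  # independent panel -> empty; absent variant -> warning + empty
  Di <- makeLDDosage(400, 6, rho = 0, seed = 64)
  expect_equal(nrow(proxyLookup("v1", Di)), 0L)
  expect_warning(expect_equal(nrow(proxyLookup("zz", Di)), 0L), "absent")

  # symmetry: b in proxies(a) <=> a in proxies(b)
  for (a in colnames(D)) for (b in setdiff(colnames(D), a))
    expect_equal(b %in% proxyLookup(a, D)$id, a %in% proxyLookup(b, D)$id)
})

test_that("effect-size concordance is invariant to allele recoding", {
  set.seed(65)
  n <- 40
  betas <- rnorm(n, 0, 0.4)
  ids <- paste0("v", 1:n); pos <- 1:n * 1000L
  a <- mkAssoc(ids, pos, p = runif(n), beta = betas)
  b <- mkAssoc(ids, pos, p = runif(n), beta = betas)
  expect_equal(compareEffectSizes(a, b)$pearson_r, 1, tolerance = 1e-12)

  # recode half of study B's alleles: betas negate, r still 1 (never -1)
  flip <- 1:20
  b2 <- b
  b2$effect_allele[flip] <- "G"; b2$other_allele[flip] <- "A"
  b2$beta[flip] <- -b2$beta[flip]; b2$eaf[flip] <- 1 - b2$eaf[flip]
  cmp <- compareEffectSizes(a, b2)
  expect_equal(cmp$pearson_r, 1, tolerance = 1e-12)
  expect_equal(cmp$n_overlap, n)

  expect_error(compareEffectSizes(a[1:2, ], b[1:2, ]),
               "insufficient overlap")
})

test_that("noisy replicates attenuate the correlation as predicted", {
  # Monte-Carlo oracle for corr of two noisy copies: r = 1 / (1 + tau^2)
  # with tau = noise SD / beta SD on both sides
  set.seed(66)
  tau <- 0.3
  oracle <- mean(replicate(200, {
    tb <- rnorm(500); cor(tb + rnorm(500, 0, tau), tb + rnorm(500, 0, tau))
  }))
  n <- 500
  betas <- rnorm(n)
  ids <- paste0("v", 1:n); pos <- 1:n * 1000L
  a <- mkAssoc(ids, pos, p = runif(n), beta = betas + rnorm(n, 0, tau))
  b <- mkAssoc(ids, pos, p = runif(n), beta = betas + rnorm(n, 0, tau))
  expect_lt(abs(compareEffectSizes(a, b)$pearson_r - oracle), 0.05)
})

test_that("the LD-confounded scenario is detected as non-concordant", {
  verdicts <- vapply(1:25, function(i) {
    cfg <- simulationConfig(nProteins = 1, scenario = "ld_confounded",
                            nCases = 5000, nControls = 5000,
                            seed = 3000 + i)
    r <- mrSimulationReplicate(cfg, withConcordance = TRUE)
    if (is.null(r$concordance)) NA_character_ else r$concordance$verdict
  }, character(1))
  expect_gte(mean(verdicts != "concordant_lead", na.rm = TRUE), 0.9)
})
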