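# Instrument clumping, allele harmonisation, Wald ratio, IVW, discovery
# screening and replication logic.

hit <- function(id, p, pos, beta = 0.5, se = 0.05)
  data.frame(protein_id = "P1", id = id, chrom = "chr1", pos = pos,
             effect_allele = "A", other_allele = "G", eaf = 0.3,
             beta = beta, se = se, p = p, n = 500,
             stringsAsFactors = FALSE)

outRow <- function(id, pos, ea = "A", oa = "G", eaf = 0.3, beta = 0.1,
                   se = 0.02, chrom = "chr1")
  data.frame(chrom = chrom, pos = pos, id = id, effect_allele = ea,
             other_allele = oa, eaf = eaf, beta = beta, se = se,
             p = 2 * pnorm(-abs(beta / se)), n_case = 5000,
             n_control = 5000, stringsAsFactors = FALSE)

test_that("instrument clumping collapses correlated hits", {
  D <- makeLDDosage(500, 6, rho = 0.95, seed = 50)
  one <- hit("v1", 1e-8, 1000L)
  expect_equal(nrow(clumpInstruments(one, D)), 1L)

  # r2 = 0.05 >= 0.001 -> still one instrument
  set.seed(51)
  a <- rbinom(4000, 2, 0.3)
  b <- ifelse(runif(4000) < 0.14, a, rbinom(4000, 2, 0.3))
  D2 <- cbind(v1 = a, v2 = b)
  expect_gte(cor(a, b)^2, 0.001)
  two <- rbind(hit("v1", 1e-8, 1000L), hit("v2", 1e-6, 2000L))
  cl <- clumpInstruments(two, D2)
  expect_equal(cl$id, "v1")

  # 6-hit fixture with a known r2 matrix matches the brute-force oracle
  hits6 <- do.call(rbind, lapply(1:6, function(j)
    hit(paste0("v", j), c(1e-9, 5e-9, 1e-7, 2e-6, 3e-6, 1e-5)[j],
        j * 1000L)))
  expect_equal(clumpInstruments(hits6, D)$id, oracleClump(hits6, D, 0.001))
  expect_equal(nrow(clumpInstruments(hits6[0, ], D)), 0L)
})

test_that("harmonisation aligns, flips, and drops correctly", {
  ins <- data.frame(protein_id = "P1", id = "v1", chrom = "chr1",
                    pos = 1000L, effect_allele = "A", other_allele = "G",
                    eaf = 0.3, beta_exp = 0.5, se_exp = 0.05,
                    stringsAsFactors = FALSE)
  # identical alleles -> unchanged
  h <- harmoniseInstruments(ins, outRow("v1", 1000L, "A", "G", beta = 0.05))
  expect_equal(h$action, "unchanged")
  expect_equal(h$beta_out, 0.05)
  # swapped alleles -> beta negated, frequency complemented
  h <- harmoniseInstruments(ins, outRow("v1", 1000L, "G", "A", eaf = 0.7,
                                        beta = 0.05))
  expect_equal(h$action, "flipped")
  expect_equal(h$beta_out, -0.05)
  expect_equal(h$eaf_out, 0.3)
  # mismatched allele set -> dropped
  h <- harmoniseInstruments(ins, outRow("v1", 1000L, "A", "C"))
  expect_equal(h$action, "dropped_mismatch")
  # absent variant -> missing
  h <- harmoniseInstruments(ins, outRow("v9", 99999L))
  expect_equal(h$action, "missing")
})

test_that("palindromic variants are resolved by allele frequency", {
  pal <- data.frame(protein_id = "P1", id = "v1", chrom = "chr1",
                    pos = 1000L, effect_allele = "A", other_allele = "T",
                    eaf = 0.10, beta_exp = 0.5, se_exp = 0.05,
                    stringsAsFactors = FALSE)
  # both frequencies below the band -> aligned; cross-checked by the
  # strand-flip enumeration: flipping strand maps A/T to T/A, i.e. the same
  # unordered pair, so only frequency can orient it
  h <- harmoniseInstruments(pal, outRow("v1", 1000L, "A", "T", eaf = 0.12))
  expect_equal(h$action, "unchanged")
  # frequencies on opposite sides -> flipped
  h <- harmoniseInstruments(pal, outRow("v1", 1000L, "A", "T", eaf = 0.88))
  expect_equal(h$action, "flipped")
  expect_equal(h$eaf_out, 0.12)
  # mid-frequency -> ambiguous, dropped
  mid <- transform(pal, eaf = 0.5)
  h <- harmoniseInstruments(mid, outRow("v1", 1000L, "A", "T", eaf = 0.5))
  expect_equal(h$action, "dropped_palindromic")
})

test_that("the Wald ratio follows the stated formulas", {
  # beta = beta_out / beta_exp, se = se_out / |beta_exp|, two-sided normal p
  w <- waldRatio(data.frame(beta_exp = 0.5, beta_out = 0.1, se_out = 0.02))
  expect_equal(w$beta, 0.2, tolerance = 1e-12)
  expect_equal(w$se, 0.04, tolerance = 1e-12)
  expect_equal(w$p, 2 * pnorm(-5), tolerance = 1e-12)
  # null outcome effect -> estimate 0, p = 1
  w0 <- waldRatio(data.frame(beta_exp = 0.5, beta_out = 0, se_out = 0.02))
  expect_equal(w0$beta, 0)
  expect_equal(w0$p, 1)
  # negative exposure beta still yields a positive SE
  wn <- waldRatio(data.frame(beta_exp = -0.5, beta_out = 0.1, se_out = 0.02))
  expect_equal(wn$se, 0.04)
  expect_equal(wn$beta, -0.2)
  # simultaneous allele recode leaves everything unchanged
  wr <- waldRatio(data.frame(beta_exp = -0.5, beta_out = -0.1, se_out = 0.02))
  expect_equal(wr[, c("beta", "se", "p")], w[, c("beta", "se", "p")],
               tolerance = 1e-12)
  expect_error(waldRatio(data.frame(beta_exp = 0, beta_out = 1,
                                    se_out = 0.1)), "undefined ratio")
})

test_that("IVW is the se^-2-weighted mean and reduces to Wald", {
  mk <- function(be, bo, so) data.frame(beta_exp = be, beta_out = bo,
                                        se_out = so, action = "unchanged")
  # singleton: exact reduction
  single <- mk(0.5, 0.1, 0.02)
  expect_identical(ivw(single)[, c("beta", "se", "p")],
                   waldRatio(single)[, c("beta", "se", "p")])
  expect_equal(ivw(single)$method, "wald")

  # two ratios 0.2 and 0.4 with equal se 0.04 -> 0.3, 0.04/sqrt(2)
  two <- rbind(mk(0.5, 0.1, 0.02), mk(0.5, 0.2, 0.02))
  est <- ivw(two)
  expect_equal(est$beta, 0.3, tolerance = 1e-12)
  expect_equal(est$se, 0.04 / sqrt(2), tolerance = 1e-12)
  expect_equal(est$method, "ivw")
  expect_equal(est$nsnp, 2L)

  # duplicating a pair k times: beta unchanged, se shrinks by sqrt(k)
  k <- 4
  dup <- do.call(rbind, replicate(k, single, simplify = FALSE))
  expect_equal(ivw(dup)$beta, waldRatio(single)$beta)
  expect_equal(ivw(dup)$se, waldRatio(single)$se / sqrt(k))

  expect_error(ivw(transform(single, action = "dropped_mismatch")),
               "no usable instrument")
})

test_that("every MR output is invariant to allele recoding", {
  set.seed(52)
  for (i in 1:20) {
    be <- runif(1, -1, 1); bo <- runif(1, -0.2, 0.2); so <- runif(1, 0.01, 0.1)
    a <- data.frame(beta_exp = be, beta_out = bo, se_out = so,
                    action = "unchanged")
    b <- data.frame(beta_exp = -be, beta_out = -bo, se_out = so,
                    action = "unchanged")
    if (be == 0) next
    expect_equal(unlist(ivw(a)[, c("beta", "se", "p")]),
                 unlist(ivw(b)[, c("beta", "se", "p")]), tolerance = 1e-12)
  }
})

test_that("mrScreen books untested proteins separately", {
  ins <- rbind(
    data.frame(protein_id = "P1", id = "v1", chrom = "chr1", pos = 1000L,
               effect_allele = "A", other_allele = "G", eaf = 0.3,
               beta_exp = 0.5, se_exp = 0.05),
    data.frame(protein_id = "P2", id = "u1", chrom = "chr2", pos = 5000L,
               effect_allele = "A", other_allele = "G", eaf = 0.3,
               beta_exp = 0.4, se_exp = 0.05))
  outcome <- outRow("v1", 1000L, beta = 0.3, se = 0.02)  # P2's variant absent
  res <- mrScreen(ins, outcome)
  expect_equal(res$status[res$protein_id == "P1"], "tested")
  expect_equal(res$status[res$protein_id == "P2"], "untested")
  expect_true(res$significant[res$protein_id == "P1"])  # z = 15
  expect_false(res$significant[res$protein_id == "P2"])
  # works unchanged against a second outcome (subtype / risk-factor GWAS)
  res2 <- mrScreen(ins, outRow("v1", 1000L, beta = 0, se = 0.02),
                   outcomeId = "er_negative")
  expect_equal(res2$outcome_id[1], "er_negative")
  expect_false(res2$significant[res2$protein_id == "P1"])
})

test_that("replication requires nominal significance and sign agreement", {
  ins <- data.frame(protein_id = "P1", id = "v1", chrom = "chr1",
                    pos = 1000L, effect_allele = "A", other_allele = "G",
                    eaf = 0.3, beta_exp = 0.5, se_exp = 0.05)
  disc <- mrScreen(ins, outRow("v1", 1000L, beta = 0.3, se = 0.02))
  # same sign, p < 0.05 -> replicated
  repOut <- outRow("v1", 1000L, beta = 0.05, se = 0.02)   # z = 2.5
  expect_true(replicateMR(disc, ins, repOut)$replicated)
  # opposite sign, p < 0.05 -> not replicated
  repFlip <- outRow("v1", 1000L, beta = -0.05, se = 0.02)
  expect_false(replicateMR(disc, ins, repFlip)$replicated)
  # not significant -> not replicated
  repNull <- outRow("v1", 1000L, beta = 0.001, se = 0.02)
  expect_false(replicateMR(disc, ins, repNull)$replicated)
  # absent from replication -> unreplicable
  repMiss <- outRow("u9", 1000L, chrom = "chr9")
  expect_false(replicateMR(disc, ins, repMiss)$replicated)
})
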