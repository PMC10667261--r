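## Synthetic study generator: LD-structured genotypes, cis-regulated NPX with
## LOD censoring, covariates, and case-control outcome summary statistics.
##
## LD model: a latent Gaussian AR(1) process along each region is thresholded
## at the MAF quantile to give one haplotype; two independent haplotypes sum
## to the dosage. Adjacent-variant LD is therefore governed by the Gaussian
## copula with correlation ldRho and decays geometrically with distance.

## one haplotype set: n samples x m variants, values 0/1
.ar1Haplotype <- function(n, m, rho, maf) {
  z <- matrix(stats::rnorm(n * m), n, m)
  if (m > 1 && rho > 0) {
    s <- sqrt(1 - rho^2)
    for (j in 2:m) z[, j] <- rho * z[, j - 1] + s * z[, j]
  }
  (sweep(z, 2, stats::qnorm(maf), FUN = "<")) * 1
}

.regionDosage <- function(n, m, rho, maf)
  .ar1Haplotype(n, m, rho, maf) + .ar1Haplotype(n, m, rho, maf)

## deterministic per-protein variant metadata (identical for every stream
## drawn from the same config)
.regionVariants <- function(config, p) {
  m <- config@variantsPerRegion
  set.seed(subSeed(config@seed, "variants", p))
  maf <- stats::runif(m, config@mafRange[1], config@mafRange[2])
  pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                 c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
  idx <- sample.int(nrow(pairs), m, replace = TRUE)
  ea <- pairs[idx, 1]; oa <- pairs[idx, 2]
  if (config@palindromeFraction > 0) {
    pal <- stats::runif(m) < config@palindromeFraction
    palPairs <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
    pidx <- sample.int(4, m, replace = TRUE)
    ea[pal] <- palPairs[pidx[pal], 1]
    oa[pal] <- palPairs[pidx[pal], 2]
  }
  centre <- (m + 1L) %/% 2L
  data.frame(id = sprintf("rs%d_%03d", p, seq_len(m)),
             chrom = paste0("chr", p),
             pos = 1005000L + (seq_len(m) - centre) * 5000L,
             effect_allele = ea, other_allele = oa,
             eaf = maf, stringsAsFactors = FALSE)
}

## lead (and optional secondary) signal indices within a region
.signalIndices <- function(config) {
  m <- config@variantsPerRegion
  if (config@nSignals == 1L) (m + 1L) %/% 2L
  else unique(pmax(1L, c(round(m / 4), round(3 * m / 4))))
}

#' Simulate LD-structured genotype dosages
#'
#' One cis region per protein, each on its own chromosome, with AR(1)
#' latent-Gaussian LD between adjacent variants and minor allele frequencies
#' drawn uniformly from `mafRange`. Haplotypes are obtained by thresholding
#' the latent Gaussian at the MAF quantile; two independent haplotypes sum to
#' the dosage. Deterministic given `(config, stream)`.
#'
#' @param config a [SimulationConfig-class].
#' @param nSamples number of samples (defaults to `config`'s `nSamples`).
#' @param stream label separating independent draws that share variant
#'   metadata (e.g. `"exposure"` vs outcome studies).
#' @return a [GenotypeMatrix-class].
#' @examples
#' g <- simulateGenotypes(simulationConfig(nProteins = 2, nSamples = 50))
#' g
#' @export
simulateGenotypes <- function(config, nSamples = config@nSamples,
                              stream = "exposure") {
  validObject(config)
  pieces <- vector("list", config@nProteins)
  doses <- vector("list", config@nProteins)
  for (p in seq_len(config@nProteins)) {
    v <- .regionVariants(config, p)
    set.seed(subSeed(config@seed, stream, "geno", p))
    d <- .regionDosage(nSamples, config@variantsPerRegion, config@ldRho,
                       v$eaf)
    pieces[[p]] <- v
    doses[[p]] <- t(d)
  }
  variants <- do.call(rbind, pieces)
  dosage <- do.call(rbind, doses)
  colnames(dosage) <- sprintf("S%04d", seq_len(nSamples))
  gm <- GenotypeMatrix(dosage, variants)
  S4Vectors::metadata(gm)$stream <- stream
  gm
}

#' Simulate a sample covariate table
#'
#' Emulates the baseline characteristics of a middle-aged female screening
#' cohort: age, BMI, menopausal status, parity, hormone-replacement therapy,
#' alcohol intake, smoking, sample storage time, a balanced incident
#' case-control label, and 10 genetic principal components. Categorical
#' reference levels are pre-menopause, never-or-past HRT and never-or-past
#' smoking.
#'
#' @param config a [SimulationConfig-class].
#' @param nSamples number of rows (defaults to `config`'s `nSamples`).
#' @return a data.frame keyed by `sample_id`.
#' @export
simulateCovariates <- function(config, nSamples = config@nSamples) {
  set.seed(subSeed(config@seed, "covariates"))
  n <- nSamples
  df <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    age = pmin(pmax(stats::rnorm(n, 54, 9), 30), 75),
    bmi = pmin(pmax(stats::rnorm(n, 25.5, 4), 16), 45),
    menopause = factor(sample(c("pre", "peri", "post"), n, replace = TRUE,
                              prob = c(0.35, 0.10, 0.55)),
                       levels = c("pre", "peri", "post")),
    birth_times = stats::rpois(n, 1.8),
    hrt_status = factor(sample(c("never_or_past", "current"), n,
                               replace = TRUE, prob = c(0.9, 0.1)),
                        levels = c("never_or_past", "current")),
    alcohol_gram_week = round(stats::rgamma(n, shape = 1.5, scale = 35), 1),
    smoking_status = factor(sample(c("never_or_past", "current"), n,
                                   replace = TRUE, prob = c(0.85, 0.15)),
                            levels = c("never_or_past", "current")),
    storage_time = round(stats::runif(n, 100, 2500)),
    case_status = factor(rep(c("control", "case"), length.out = n),
                         levels = c("control", "case")),
    stringsAsFactors = FALSE)
  pcs <- matrix(stats::rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("PC", 1:10)))
  cbind(df, as.data.frame(pcs))
}

#' Simulate cis-regulated NPX protein levels
#'
#' Per protein, `NPX = beta_g * dosage(lead cis variant) + covariate effects +
#' Gaussian noise`, scaled so the total variance is 1 and the lead-variant
#' component explains `cisH2` of it; with `nSignals = 2` the heritability is
#' split equally between two well-separated cis variants. The per-assay limit
#' of detection is placed at the `lodQuantile` of the simulated values; values
#' below it are retained and flagged. Generating truth (lead variant ids and
#' per-allele effects) is stored in the metadata.
#'
#' @param genotypes a [GenotypeMatrix-class] from [simulateGenotypes()].
#' @param covariates data.frame from [simulateCovariates()]; sample ids must
#'   match the genotype columns.
#' @param config the [SimulationConfig-class] used for the genotypes.
#' @return an [NPXMatrix-class] with `metadata()` entries `truth` and
#'   `config`.
#' @export
simulateNPX <- function(genotypes, covariates, config) {
  validObject(config)
  if (!identical(colnames(genotypes), covariates$sample_id))
    stop("alignment error: genotype samples and covariate rows differ",
         call. = FALSE)
  n <- ncol(genotypes)
  eff <- config@covariateEffects
  covPart <- 0
  for (nm in names(eff)) {
    if (!nm %in% names(covariates) || !is.numeric(covariates[[nm]]))
      stop("invalid configuration: 'covariateEffects' names a covariate ",
           "not present or not numeric: ", nm, call. = FALSE)
    covPart <- covPart + eff[[nm]] * as.numeric(scale(covariates[[nm]]))
  }
  noiseSD <- sqrt(1 - config@cisH2 - sum(eff^2))
  sig <- .signalIndices(config)
  vinfo <- variantInfo(genotypes)
  dos <- dosages(genotypes)
  m <- config@variantsPerRegion
  vals <- matrix(NA_real_, config@nProteins, n)
  truth <- vector("list", config@nProteins)
  info <- vector("list", config@nProteins)
  for (p in seq_len(config@nProteins)) {
    rows <- (p - 1L) * m + seq_len(m)
    maf <- vinfo$eaf[rows][sig]
    betaG <- sqrt((config@cisH2 / length(sig)) / (2 * maf * (1 - maf)))
    set.seed(subSeed(config@seed, "npx", p))
    gpart <- 0
    for (k in seq_along(sig))
      gpart <- gpart + betaG[k] * (dos[rows[sig[k]], ] - 2 * maf[k])
    vals[p, ] <- gpart + covPart + stats::rnorm(n, 0, noiseSD)
    truth[[p]] <- data.frame(
      protein_id = paste0("P", p), chrom = paste0("chr", p),
      lead_id = vinfo$id[rows[sig[1]]],
      signal_ids = paste(vinfo$id[rows[sig]], collapse = ","),
      beta_per_allele = betaG[1],
      causal = config@scenario == "causal" && p == config@causalProtein,
      stringsAsFactors = FALSE)
    info[[p]] <- data.frame(
      protein_id = paste0("P", p), gene = paste0("GENE", p),
      chrom = paste0("chr", p), gene_start = 1000000L,
      gene_end = 1010000L,
      panel = if (p <= ceiling(config@nProteins / 2)) "ExploreI"
              else "ExploreII",
      lod = NA_real_, stringsAsFactors = FALSE)
  }
  assayInfo <- do.call(rbind, info)
  assayInfo$lod <- apply(vals, 1, stats::quantile,
                         probs = config@lodQuantile)
  colnames(vals) <- colnames(genotypes)
  npx <- NPXMatrix(vals, assayInfo)
  S4Vectors::metadata(npx)$truth <- do.call(rbind, truth)
  S4Vectors::metadata(npx)$config <- config
  npx
}

## fast per-variant case-control summary statistics: one-step logistic score
## test, beta = U/V, se = V^{-1/2} with U the score and V the null
## information. Equivalent to logistic regression for small effects.
.scoreStats <- function(G, y) {
  ybar <- mean(y)
  Gc <- sweep(G, 2, colMeans(G))
  U <- as.numeric(crossprod(Gc, y - ybar))
  V <- ybar * (1 - ybar) * colSums(Gc^2)
  keep <- V > 0
  beta <- U[keep] / V[keep]
  se <- 1 / sqrt(V[keep])
  z <- beta / se
  list(keep = keep, beta = beta, se = se,
       p = 2 * stats::pnorm(-abs(z)))
}

.glmStats <- function(G, y) {
  m <- ncol(G)
  beta <- se <- p <- rep(NA_real_, m)
  keep <- apply(G, 2, stats::var) > 0
  for (j in which(keep)) {
    fit <- suppressWarnings(stats::glm(y ~ G[, j], family = stats::binomial()))
    cf <- summary(fit)$coefficients
    beta[j] <- cf[2, 1]; se[j] <- cf[2, 2]; p[j] <- cf[2, 4]
  }
  list(keep = keep, beta = beta[keep], se = se[keep], p = p[keep])
}

#' Simulate case-control outcome GWAS summary statistics
#'
#' Draws a fresh genotype sample of `nCases + nControls` individuals with the
#' same variant metadata as the exposure study, assigns case status from a
#' logistic model on the causal protein's liability (`scenario = "causal"`),
#' on a direct variant effect in LD with the lead pQTL
#' (`scenario = "ld_confounded"`, protein path zero), or on the intercept
#' alone (`scenario = "null"`), then emits per-variant log-odds-ratio summary
#' statistics. The intercept is set so the expected case fraction matches
#' `nCases / (nCases + nControls)`. Discovery and replication use independent
#' random sub-streams.
#'
#' @param genotypes exposure-study [GenotypeMatrix-class] (supplies variant
#'   metadata; its dosages are not reused).
#' @param npx the [NPXMatrix-class] from [simulateNPX()] (supplies the
#'   generating truth).
#' @param config the shared [SimulationConfig-class].
#' @param which `"discovery"` or `"replication"` — independent outcome draws.
#' @param method `"score"` (vectorised one-step logistic score test, the
#'   default) or `"glm"` (per-variant logistic regression; slow, for
#'   cross-checks).
#' @return a data.frame with columns `chrom, pos, id, effect_allele,
#'   other_allele, eaf, beta, se, p, n_case, n_control` (monomorphic variants
#'   are omitted, as a GWAS would).
#' @export
simulateOutcomeSummary <- function(genotypes, npx, config,
                                   which = c("discovery", "replication"),
                                   method = c("score", "glm")) {
  which <- match.arg(which)
  method <- match.arg(method)
  validObject(config)
  if (config@scenario == "null" && config@theta != 0)
    stop("invalid configuration: 'theta' must be 0 under scenario = \"null\"",
         call. = FALSE)
  truth <- S4Vectors::metadata(npx)$truth
  if (is.null(truth))
    stop("npx lacks generating truth; use simulateNPX()", call. = FALSE)
  n <- config@nCases + config@nControls
  alpha <- stats::qlogis(config@nCases / n)
  m <- config@variantsPerRegion
  vinfo <- variantInfo(genotypes)
  cp <- config@causalProtein
  sig <- .signalIndices(config)

  ## causal-region dosages first: case status may depend on them
  Gcausal <- NULL
  eta <- rep(alpha, n)
  if (config@scenario != "null") {
    rows <- (cp - 1L) * m + seq_len(m)
    maf <- vinfo$eaf[rows]
    set.seed(subSeed(config@seed, which, "geno", cp))
    Gcausal <- .regionDosage(n, m, config@ldRho, maf)
    if (config@scenario == "causal") {
      betaG <- sqrt((config@cisH2 / length(sig)) / (2 * maf[sig] *
                                                      (1 - maf[sig])))
      set.seed(subSeed(config@seed, which, "liability"))
      L <- stats::rnorm(n, 0, sqrt(1 - config@cisH2))
      for (k in seq_along(sig))
        L <- L + betaG[k] * (Gcausal[, sig[k]] - 2 * maf[sig[k]])
      eta <- eta + config@theta * L
    } else {
      ## direct variant -> outcome effect on a variant in LD with the lead
      ## pQTL; the protein-mediated path carries nothing.
      off <- if (config@ldRho > 0)
        max(1L, as.integer(round(log(sqrt(config@confounderR2)) /
                                   log(config@ldRho)))) else 1L
      cidx <- min(m, sig[1] + off)
      eta <- eta + config@confounderLogOR *
        (Gcausal[, cidx] - 2 * maf[cidx])
    }
  }
  set.seed(subSeed(config@seed, which, "case"))
  y <- stats::rbinom(n, 1, stats::plogis(eta))

  out <- vector("list", config@nProteins)
  for (p in seq_len(config@nProteins)) {
    rows <- (p - 1L) * m + seq_len(m)
    if (!is.null(Gcausal) && p == cp) {
      G <- Gcausal
    } else {
      set.seed(subSeed(config@seed, which, "geno", p))
      G <- .regionDosage(n, m, config@ldRho, vinfo$eaf[rows])
    }
    st <- if (method == "score") .scoreStats(G, y) else .glmStats(G, y)
    v <- vinfo[rows, ][st$keep, ]
    out[[p]] <- data.frame(
      chrom = v$chrom, pos = v$pos, id = v$id,
      effect_allele = v$effect_allele, other_allele = v$other_allele,
      eaf = colMeans(G)[st$keep] / 2,
      beta = st$beta, se = st$se, p = st$p,
      n_case = sum(y), n_control = n - sum(y),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a complete two-sample MR study
#'
#' Convenience wrapper drawing genotypes, covariates, NPX and both outcome
#' summary-statistic sets from one configuration.
#'
#' @param config a [SimulationConfig-class].
#' @return a list with elements `genotypes`, `covariates`, `npx`,
#'   `discovery`, `replication`, `truth`.
#' @export
simulateStudy <- function(config) {
  genotypes <- simulateGenotypes(config)
  covariates <- simulateCovariates(config)
  npx <- simulateNPX(genotypes, covariates, config)
  list(genotypes = genotypes, covariates = covariates, npx = npx,
       discovery = simulateOutcomeSummary(genotypes, npx, config,
                                          "discovery"),
       replication = simulateOutcomeSummary(genotypes, npx, config,
                                            "replication"),
       truth = S4Vectors::metadata(npx)$truth)
}
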