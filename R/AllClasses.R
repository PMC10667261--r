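#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData assayNames
#' @importFrom S4Vectors metadata DataFrame
NULL

## ---------------------------------------------------------------------------
## SimulationConfig
## ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Parameters of the synthetic study generator: LD-structured genotypes,
#' cis-regulated NPX protein levels with limit-of-detection censoring, and
#' case-control outcome summary statistics under a null, causal or
#' LD-confounded scenario.
#'
#' @slot nSamples number of exposure-study samples.
#' @slot nProteins number of proteins (one cis region each, on its own
#'   chromosome).
#' @slot variantsPerRegion variants simulated per cis region.
#' @slot ldRho AR(1) correlation of the latent Gaussian between adjacent
#'   variants, in `[0, 1)`; squared-correlation LD decays geometrically.
#' @slot mafRange range of minor allele frequencies, within `(0, 0.5]`.
#' @slot cisH2 fraction of NPX variance explained by the lead cis variant(s),
#'   in `[0, 1)`.
#' @slot nSignals number of independent cis signals per protein (1 or 2); with
#'   2 the heritability is split equally between two well-separated variants.
#' @slot covariateEffects named numeric vector of covariate effects in NPX SD
#'   units, applied to the standardised covariate (names must be numeric
#'   columns of the covariate table, e.g. `age`, `bmi`).
#' @slot lodQuantile fraction of each protein's values flagged below the limit
#'   of detection, in `[0, 1)`.
#' @slot theta causal effect of the causal protein on outcome log-odds per NPX
#'   SD; must be 0 under `scenario = "null"` and the protein-mediated path is
#'   ignored under `"ld_confounded"`.
#' @slot causalProtein index of the causal protein (scenario `"causal"`) or
#'   the confounded protein (scenario `"ld_confounded"`).
#' @slot confounderR2 target LD (latent r-squared) between the lead pQTL and
#'   the variant carrying the direct outcome effect in the LD-confounded
#'   scenario.
#' @slot confounderLogOR per-allele direct log-odds effect of that variant.
#' @slot nCases,nControls case and control counts of each outcome study.
#' @slot palindromeFraction fraction of variants assigned complementary
#'   (A/T or C/G) allele pairs; 0 by default (strand-resolved simulation).
#' @slot scenario one of `"null"`, `"causal"`, `"ld_confounded"`.
#' @slot seed master integer seed; all sub-streams derive from it.
#'
#' @seealso [simulationConfig()] for the user-facing constructor with
#'   defaults, [simulateGenotypes()], [simulateNPX()],
#'   [simulateOutcomeSummary()].
#' @export
setClass("SimulationConfig", representation(
  nSamples = "integer",
  nProteins = "integer",
  variantsPerRegion = "integer",
  ldRho = "numeric",
  mafRange = "numeric",
  cisH2 = "numeric",
  nSignals = "integer",
  covariateEffects = "numeric",
  lodQuantile = "numeric",
  theta = "numeric",
  causalProtein = "integer",
  confounderR2 = "numeric",
  confounderLogOR = "numeric",
  nCases = "integer",
  nControls = "integer",
  palindromeFraction = "numeric",
  scenario = "character",
  seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  if (length(object@mafRange) != 2L ||
      any(object@mafRange <= 0) || any(object@mafRange > 0.5) ||
      object@mafRange[1] > object@mafRange[2])
    msg <- c(msg, "'mafRange' must be an increasing pair within (0, 0.5]")
  if (object@ldRho < 0 || object@ldRho >= 1)
    msg <- c(msg, "'ldRho' must lie in [0, 1)")
  if (object@cisH2 < 0 || object@cisH2 >= 1)
    msg <- c(msg, "'cisH2' must lie in [0, 1)")
  if (object@lodQuantile < 0 || object@lodQuantile >= 1)
    msg <- c(msg, "'lodQuantile' must lie in [0, 1)")
  if (!object@scenario %in% c("null", "causal", "ld_confounded"))
    msg <- c(msg, "'scenario' must be one of null, causal, ld_confounded")
  if (object@scenario == "null" && object@theta != 0)
    msg <- c(msg, "'theta' must be 0 under scenario = \"null\"")
  if (!object@nSignals %in% 1:2)
    msg <- c(msg, "'nSignals' must be 1 or 2")
  if (object@causalProtein > object@nProteins)
    msg <- c(msg, "'causalProtein' exceeds 'nProteins'")
  if (object@cisH2 + sum(object@covariateEffects^2) >= 1)
    msg <- c(msg, paste0("'cisH2' plus squared 'covariateEffects' must be ",
                         "< 1 (NPX total variance is 1)"))
  if (object@confounderR2 <= 0 || object@confounderR2 >= 1)
    msg <- c(msg, "'confounderR2' must lie in (0, 1)")
  if (object@palindromeFraction < 0 || object@palindromeFraction > 1)
    msg <- c(msg, "'palindromeFraction' must lie in [0, 1]")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Create a simulation configuration
#'
#' Defaults describe a study of 598 exposure samples (a matched case-control
#' proteomics cohort) with strong cis effects (`cisH2 = 0.2`) and two
#' independent outcome case-control studies of 10,000 cases and 10,000
#' controls each. Under `scenario = "causal"` the default causal effect is
#' `theta = 0.4` log-odds per NPX SD.
#'
#' @param nSamples,nProteins,variantsPerRegion,ldRho,mafRange,cisH2,nSignals
#'   see the class documentation.
#' @param covariateEffects,lodQuantile,theta,causalProtein see the class
#'   documentation.
#' @param confounderR2,confounderLogOR,nCases,nControls,palindromeFraction
#'   see the class documentation.
#' @param scenario,seed see the class documentation.
#' @return a validated [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(nProteins = 2, scenario = "causal")
#' cfg
#' @export
simulationConfig <- function(nSamples = 598, nProteins = 10,
                             variantsPerRegion = 21, ldRho = 0.9,
                             mafRange = c(0.05, 0.5), cisH2 = 0.2,
                             nSignals = 1,
                             covariateEffects = c(age = 0.1, bmi = 0.2),
                             lodQuantile = 0.25,
                             theta = if (scenario == "causal") 0.4 else 0,
                             causalProtein = 1, confounderR2 = 0.3,
                             confounderLogOR = 0.3,
                             nCases = 10000, nControls = 10000,
                             palindromeFraction = 0,
                             scenario = c("null", "causal", "ld_confounded"),
                             seed = 1) {
  scenario <- match.arg(scenario)
  cfg <- new("SimulationConfig",
             nSamples = .checkCount(nSamples, "nSamples"),
             nProteins = .checkCount(nProteins, "nProteins"),
             variantsPerRegion = .checkCount(variantsPerRegion,
                                             "variantsPerRegion"),
             ldRho = .checkFraction(ldRho, "ldRho", 0, 1, hi.open = TRUE),
             mafRange = as.numeric(mafRange),
             cisH2 = .checkFraction(cisH2, "cisH2", 0, 1, hi.open = TRUE),
             nSignals = .checkCount(nSignals, "nSignals"),
             covariateEffects = if (length(covariateEffects))
               covariateEffects else stats::setNames(numeric(0), character(0)),
             lodQuantile = .checkFraction(lodQuantile, "lodQuantile", 0, 1,
                                          hi.open = TRUE),
             theta = as.numeric(theta),
             causalProtein = .checkCount(causalProtein, "causalProtein"),
             confounderR2 = as.numeric(confounderR2),
             confounderLogOR = as.numeric(confounderLogOR),
             nCases = .checkCount(nCases, "nCases"),
             nControls = .checkCount(nControls, "nControls"),
             palindromeFraction = .checkFraction(palindromeFraction,
                                                 "palindromeFraction"),
             scenario = scenario,
             seed = .checkCount(seed, "seed"))
  cfg
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n",
      "  scenario: ", object@scenario,
      " (theta = ", object@theta, ")\n",
      "  samples: ", object@nSamples,
      ", proteins: ", object@nProteins,
      ", variants/region: ", object@variantsPerRegion, "\n",
      "  ldRho: ", object@ldRho,
      ", maf: [", object@mafRange[1], ", ", object@mafRange[2], "]",
      ", cisH2: ", object@cisH2, "\n",
      "  outcome: ", object@nCases, " cases / ", object@nControls,
      " controls; seed ", object@seed, "\n", sep = "")
})

## ---------------------------------------------------------------------------
## GenotypeMatrix / NPXMatrix containers
## ---------------------------------------------------------------------------

#' Genotype dosage container
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one `"dosage"` assay
#' (rows = variants, columns = samples) and variant metadata (`id`, `chrom`,
#' `pos`, `effect_allele`, `other_allele`, `eaf`) in `rowData`.
#'
#' @export
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  msg <- character(0)
  need <- c("id", "chrom", "pos", "effect_allele", "other_allele", "eaf")
  rd <- rowData(object)
  if (!all(need %in% colnames(rd)))
    return(paste("rowData must contain:", paste(need, collapse = ", ")))
  if (!"dosage" %in% assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- assay(object, "dosage")
    if (anyNA(d)) msg <- c(msg, "dosages must not contain missing values")
    else if (min(d) < 0 || max(d) > 2)
      msg <- c(msg, "dosages must lie in [0, 2]")
  }
  if (anyDuplicated(rd$id)) msg <- c(msg, "variant ids must be unique")
  if (any(rd$effect_allele == rd$other_allele))
    msg <- c(msg, "effect and other allele must differ")
  if (any(rd$pos < 1)) msg <- c(msg, "positions are 1-based (pos >= 1)")
  chrom <- as.character(rd$chrom)
  if (length(rle(chrom)$values) != length(unique(chrom)))
    msg <- c(msg, "variants of one chromosome must be contiguous")
  else if (any(tapply(rd$pos, factor(chrom, unique(chrom)), is.unsorted)))
    msg <- c(msg, "variants must be sorted by position within chromosome")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosage numeric matrix, variants x samples, values in `[0, 2]`.
#' @param variants data.frame with columns `id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, one row per dosage row, sorted by
#'   `(chrom, pos)`.
#' @return a [GenotypeMatrix-class].
#' @export
GenotypeMatrix <- function(dosage, variants) {
  dosage <- as.matrix(dosage)
  rownames(dosage) <- variants$id
  se <- SummarizedExperiment(assays = list(dosage = dosage),
                             rowData = variants)
  new("GenotypeMatrix", se)
}

#' NPX protein abundance container
#'
#' A [SummarizedExperiment::SummarizedExperiment] with an `"npx"` assay
#' (rows = protein assays, columns = samples), a logical `"belowLOD"` assay
#' flagging values below the per-assay limit of detection, and per-assay
#' annotation (`protein_id`, `gene`, `chrom`, `gene_start`, `gene_end`,
#' `panel`, `lod`) in `rowData`. Values below LOD are retained, never blanked.
#'
#' @export
setClass("NPXMatrix", contains = "SummarizedExperiment")

setValidity("NPXMatrix", function(object) {
  msg <- character(0)
  need <- c("protein_id", "gene", "chrom", "gene_start", "gene_end",
            "panel", "lod")
  rd <- rowData(object)
  if (!all(need %in% colnames(rd)))
    return(paste("rowData must contain:", paste(need, collapse = ", ")))
  if (!"npx" %in% assayNames(object))
    msg <- c(msg, "assay 'npx' is required")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  if (anyDuplicated(rd$protein_id))
    msg <- c(msg, "protein ids must be unique")
  if (any(rd$gene_start > rd$gene_end))
    msg <- c(msg, "gene_start must be <= gene_end")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct an NPXMatrix
#'
#' @param npx numeric matrix, assays x samples (missing values allowed).
#' @param assayInfo data.frame with columns `protein_id`, `gene`, `chrom`,
#'   `gene_start`, `gene_end`, `panel`, `lod`.
#' @return an [NPXMatrix-class]; the `belowLOD` assay is derived from `lod`.
#' @export
NPXMatrix <- function(npx, assayInfo) {
  npx <- as.matrix(npx)
  rownames(npx) <- assayInfo$protein_id
  below <- sweep(npx, 1, assayInfo$lod, FUN = "<=")
  se <- SummarizedExperiment(assays = list(npx = npx, belowLOD = below),
                             rowData = assayInfo)
  new("NPXMatrix", se)
}

## ---------------------------------------------------------------------------
## Accessors
## ---------------------------------------------------------------------------

#' @rdname GenotypeMatrix-class
#' @param x a `GenotypeMatrix`.
#' @return `dosages()`: the variants x samples dosage matrix.
#' @export
dosages <- function(x) assay(x, "dosage")

#' @rdname GenotypeMatrix-class
#' @return `variantInfo()`: variant metadata as a data.frame.
#' @export
variantInfo <- function(x) as.data.frame(rowData(x))

#' @rdname NPXMatrix-class
#' @param x an `NPXMatrix`.
#' @return `npxValues()`: the assays x samples NPX matrix.
#' @export
npxValues <- function(x) assay(x, "npx")

#' @rdname NPXMatrix-class
#' @return `assayAnnotation()`: per-assay annotation as a data.frame.
#' @export
assayAnnotation <- function(x) as.data.frame(rowData(x))

#' @rdname NPXMatrix-class
#' @return `lodValues()`: named per-assay limit of detection.
#' @export
lodValues <- function(x)
  stats::setNames(rowData(x)$lod, rowData(x)$protein_id)

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object), "variants x", ncol(object),
      "samples on", length(unique(rowData(object)$chrom)),
      "chromosome(s)\n")
})

setMethod("show", "NPXMatrix", function(object) {
  nb <- mean(assay(object, "belowLOD"), na.rm = TRUE)
  cat("NPXMatrix:", nrow(object), "assays x", ncol(object), "samples;",
      sprintf("%.1f%%", 100 * nb), "of values below LOD\n")
})

## ---------------------------------------------------------------------------
## CisRegion
## ---------------------------------------------------------------------------

#' Cis testing region around a protein-coding gene
#'
#' The window is `[max(1, gene_start - window), gene_end + window]`,
#' 1-based inclusive, on the gene's chromosome.
#'
#' @slot proteinId protein assay label.
#' @slot chrom chromosome label.
#' @slot windowStart,windowEnd window bounds (bp, 1-based inclusive).
#' @slot variantIds ids of variants falling in the window, in position order.
#' @slot nVariants number of such variants.
#' @slot nIndependent number of independent variants (pairwise r-squared
#'   below the pruning threshold), `NA` until computed.
#' @seealso [defineCisRegion()], [countIndependent()]
#' @export
setClass("CisRegion", representation(
  proteinId = "character", chrom = "character",
  windowStart = "numeric", windowEnd = "numeric",
  variantIds = "character", nVariants = "integer",
  nIndependent = "integer"))

setValidity("CisRegion", function(object) {
  msg <- character(0)
  if (object@windowStart < 1) msg <- c(msg, "windowStart must be >= 1")
  if (object@windowEnd < object@windowStart)
    msg <- c(msg, "windowEnd must be >= windowStart")
  if (object@nVariants != length(object@variantIds))
    msg <- c(msg, "nVariants must equal length(variantIds)")
  if (!is.na(object@nIndependent) &&
      (object@nIndependent > object@nVariants ||
       (object@nVariants >= 1L && object@nIndependent < 1L)))
    msg <- c(msg, "nIndependent must lie in [1, nVariants]")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

setMethod("show", "CisRegion", function(object) {
  cat("CisRegion ", object@proteinId, ": ", object@chrom, ":",
      object@windowStart, "-", object@windowEnd, ", ",
      object@nVariants, " variants",
      if (!is.na(object@nIndependent))
        paste0(" (", object@nIndependent, " independent)"), "\n", sep = "")
})
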