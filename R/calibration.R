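## One self-contained simulate -> scan -> instrument -> MR replicate, used
## for calibration studies (type-I error, parameter recovery, LD-confounding
## discordance) without the file-writing overhead of the full pipeline.

#' Run one simulated MR replicate for a single protein
#'
#' Simulates a study from `config`, scans the chosen protein's cis region,
#' clumps significant hits into instruments, simulates the requested outcome
#' summary set, harmonises and estimates the causal effect by Wald ratio or
#' IVW. For a single-protein study the cis threshold is alpha divided by the
#' region's own independent-variant count.
#'
#' @param config a [SimulationConfig-class]; vary its `seed` across
#'   replicates.
#' @param protein protein index to analyse (defaults to the causal protein).
#' @param whichOutcome `"discovery"` or `"replication"`.
#' @param alpha family-wise alpha for the cis threshold.
#' @param withConcordance also compute the regional lead-concordance verdict
#'   against the outcome.
#' @return a list: `mr` (one-row MRResult data.frame, or `NULL` when no
#'   instrument), `nInstruments`, `leadHitId`, `truth` (the generating
#'   truth row), and optionally `concordance`.
#' @export
mrSimulationReplicate <- function(config, protein = config@causalProtein,
                                  whichOutcome = "discovery", alpha = 0.05,
                                  withConcordance = FALSE) {
  geno <- simulateGenotypes(config)
  covs <- simulateCovariates(config)
  npx <- simulateNPX(geno, covs, config)
  anno <- assayAnnotation(npx)[protein, ]
  vinfo <- variantInfo(geno)
  reg <- defineCisRegion(anno, vinfo)
  dosT <- t(dosages(geno))[, reg@variantIds, drop = FALSE]
  res <- cisScan(npxValues(npx)[protein, ], geno, covs, reg)
  thr <- significanceThreshold(countIndependent(dosT), alpha)
  hits <- selectPqtl(res, thr, dosT)
  truth <- S4Vectors::metadata(npx)$truth[protein, ]
  out <- list(mr = NULL, nInstruments = 0L, leadHitId = NA_character_,
              truth = truth)
  if (!nrow(hits)) return(out)
  instr <- clumpInstruments(hits, dosT)
  outcome <- simulateOutcomeSummary(geno, npx, config, whichOutcome)
  h <- harmoniseInstruments(instr, outcome)
  if (!any(h$action %in% c("unchanged", "flipped"))) return(out)
  out$mr <- ivw(h)
  out$nInstruments <- nrow(instr)
  out$leadHitId <- hits$id[1]
  if (withConcordance) {
    al <- regionAlignment(res, outcome, reg, dosT)
    out$concordance <- leadConcordance(al, dosT)
  }
  out
}
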