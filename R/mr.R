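## Two-sample Mendelian randomisation: instrument selection, allele
## harmonisation, Wald-ratio and fixed-effect IVW estimation, discovery
## screening and replication.

#' Select independent instruments from pQTL hits
#'
#' Greedy p-ordered clumping of one protein's cis-pQTL hits at a stringent
#' r-squared threshold (default 0.001), collapsing near-duplicate signals to
#' one instrumental variable each.
#'
#' @param hits pQTL hit data.frame from [selectPqtl()] (one protein).
#' @param regionDosages samples x variants dosage reference with variant ids
#'   as column names.
#' @param r2Max clumping threshold (default 0.001).
#' @return data.frame of instruments: `protein_id, id, chrom, pos,
#'   effect_allele, other_allele, eaf, beta_exp, se_exp`; zero rows for empty
#'   input.
#' @export
clumpInstruments <- function(hits, regionDosages, r2Max = 0.001) {
  cols <- c("protein_id", "id", "chrom", "pos", "effect_allele",
            "other_allele", "eaf")
  if (is.null(hits) || !nrow(hits)) {
    out <- data.frame(matrix(nrow = 0, ncol = length(cols),
                             dimnames = list(NULL, cols)))
    out$beta_exp <- numeric(0); out$se_exp <- numeric(0)
    return(out)
  }
  chosen <- .greedyClump(hits, regionDosages, r2Max)
  out <- hits[chosen, cols]
  out$beta_exp <- hits$beta[chosen]
  out$se_exp <- hits$se[chosen]
  rownames(out) <- NULL
  out
}

#' Harmonise instruments against an outcome summary set
#'
#' Matches each instrument to the outcome by chromosome and position plus the
#' unordered allele pair (variant id as fallback), then aligns the outcome
#' effect to the exposure effect allele: swapped alleles negate the outcome
#' beta and complement its frequency (`action = "flipped"`); palindromic
#' (A/T, C/G) variants are aligned by effect-allele frequency when both
#' frequencies fall on the same side of the `palindromeEafBand` (both below
#' it, or both above its complement), flipped when they fall on opposite
#' sides, and dropped otherwise (`"dropped_palindromic"`); non-matching
#' allele sets are dropped (`"dropped_mismatch"`); instruments absent from
#' the outcome get `action = "missing"`.
#'
#' @param instruments data.frame from [clumpInstruments()].
#' @param outcome outcome summary-statistics data.frame (see
#'   [simulateOutcomeSummary()] for the layout).
#' @param palindromeEafBand ambiguity band (default 0.42): palindromic
#'   variants with frequency in `(band, 1 - band)` on either side are
#'   dropped.
#' @return `instruments` with appended `beta_out, se_out, eaf_out, action`.
#' @export
harmoniseInstruments <- function(instruments, outcome,
                                 palindromeEafBand = 0.42) {
  band <- .checkFraction(palindromeEafBand, "palindromeEafBand", 0, 0.5)
  n <- nrow(instruments)
  beta_out <- se_out <- eaf_out <- rep(NA_real_, n)
  action <- rep("missing", n)
  okey <- .variantKey(outcome$chrom, outcome$pos, outcome$effect_allele,
                      outcome$other_allele)
  for (i in seq_len(n)) {
    ik <- .variantKey(instruments$chrom[i], instruments$pos[i],
                      instruments$effect_allele[i],
                      instruments$other_allele[i])
    j <- match(ik, okey)
    if (is.na(j)) {
      ## same locus, different allele set?
      pos <- which(outcome$chrom == instruments$chrom[i] &
                     outcome$pos == instruments$pos[i])
      if (!length(pos)) pos <- which(outcome$id == instruments$id[i])
      if (length(pos)) {
        j <- pos[1]
        same <- outcome$effect_allele[j] %in%
          c(instruments$effect_allele[i], instruments$other_allele[i]) &&
          outcome$other_allele[j] %in%
          c(instruments$effect_allele[i], instruments$other_allele[i])
        if (!same) { action[i] <- "dropped_mismatch"; next }
      } else next  # truly missing
    }
    ea <- instruments$effect_allele[i]; oa <- instruments$other_allele[i]
    pal <- .isPalindromic(ea, oa)
    sameOrder <- outcome$effect_allele[j] == ea &&
      outcome$other_allele[j] == oa
    swapped <- outcome$effect_allele[j] == oa &&
      outcome$other_allele[j] == ea
    if (!sameOrder && !swapped) { action[i] <- "dropped_mismatch"; next }
    if (pal) {
      fe <- instruments$eaf[i]; fo <- outcome$eaf[j]
      low <- function(f) f < band
      high <- function(f) f > 1 - band
      if ((low(fe) && low(fo)) || (high(fe) && high(fo))) {
        beta_out[i] <- outcome$beta[j]; se_out[i] <- outcome$se[j]
        eaf_out[i] <- fo; action[i] <- "unchanged"
      } else if ((low(fe) && high(fo)) || (high(fe) && low(fo))) {
        beta_out[i] <- -outcome$beta[j]; se_out[i] <- outcome$se[j]
        eaf_out[i] <- 1 - fo; action[i] <- "flipped"
      } else action[i] <- "dropped_palindromic"
    } else if (sameOrder) {
      beta_out[i] <- outcome$beta[j]; se_out[i] <- outcome$se[j]
      eaf_out[i] <- outcome$eaf[j]; action[i] <- "unchanged"
    } else {
      beta_out[i] <- -outcome$beta[j]; se_out[i] <- outcome$se[j]
      eaf_out[i] <- 1 - outcome$eaf[j]; action[i] <- "flipped"
    }
  }
  cbind(instruments, data.frame(beta_out = beta_out, se_out = se_out,
                                eaf_out = eaf_out, action = action,
                                stringsAsFactors = FALSE))
}

#' Wald-ratio causal estimate for one instrument
#'
#' The causal estimate is the outcome (disease risk) beta divided by the
#' exposure (protein level) beta; its standard error is the outcome standard
#' error divided by the absolute exposure beta; the z-score is formed from
#' the two and the two-sided p-value is computed from both tails of the
#' standard normal distribution. (The absolute value keeps the SE positive
#' for negative exposure betas without changing |z|.)
#'
#' @param pair one harmonised row with `beta_exp, beta_out, se_out` (e.g.
#'   from [harmoniseInstruments()]).
#' @return one-row data.frame: `method = "wald", nsnp = 1, beta, se, p`.
#' @examples
#' waldRatio(data.frame(beta_exp = 0.5, beta_out = 0.1, se_out = 0.02))
#' @export
waldRatio <- function(pair) {
  if (pair$beta_exp == 0)
    stop("undefined ratio: exposure beta is 0", call. = FALSE)
  beta <- pair$beta_out / pair$beta_exp
  se <- pair$se_out / abs(pair$beta_exp)
  z <- beta / se
  data.frame(method = "wald", nsnp = 1L, beta = beta, se = se,
             p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
}

#' Fixed-effect inverse-variance-weighted causal estimate
#'
#' Per-instrument Wald ratios `b_i` with standard errors `s_i` are combined
#' with weights `w_i = s_i^-2`: `beta = sum(w b) / sum(w)`,
#' `se = sum(w)^-0.5`, p from the standard normal. A single usable
#' instrument reduces exactly to the Wald ratio (`method = "wald"`).
#' Cochran's Q over the ratios is attached as a heterogeneity diagnostic
#' (`attr(, "Q")`), not used for inference.
#'
#' @param pairs harmonised data.frame; only rows with `action` in
#'   `"unchanged"`/`"flipped"` are used.
#' @return one-row data.frame: `method, nsnp, beta, se, p`.
#' @export
ivw <- function(pairs) {
  use <- pairs[pairs$action %in% c("unchanged", "flipped"), , drop = FALSE]
  if (!nrow(use))
    stop("no usable instrument after harmonisation", call. = FALSE)
  b <- use$beta_out / use$beta_exp
  s <- use$se_out / abs(use$beta_exp)
  w <- 1 / s^2
  beta <- sum(w * b) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- beta / se
  out <- data.frame(method = if (nrow(use) == 1L) "wald" else "ivw",
                    nsnp = nrow(use), beta = beta, se = se,
                    p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  attr(out, "Q") <- sum(w * (b - beta)^2)
  out
}

#' Discovery MR screen across proteins
#'
#' Harmonises each protein's instruments against the outcome and computes the
#' Wald-ratio (one instrument) or IVW (several) causal estimate. Proteins
#' whose instruments are all absent from the outcome or dropped during
#' harmonisation are reported as untested — bookkept separately from
#' non-significant results.
#'
#' @param instruments instrument data.frame covering one or more proteins
#'   (column `protein_id`).
#' @param outcome outcome summary-statistics data.frame.
#' @param alphaDiscovery discovery significance threshold (default 7.5e-5).
#' @param outcomeId label recorded in the results (default `"outcome"`).
#' @param palindromeEafBand passed to [harmoniseInstruments()].
#' @return data.frame: `protein_id, outcome_id, method, nsnp, beta, se, p,
#'   significant, status` (`status` is `"tested"` or `"untested"`).
#' @export
mrScreen <- function(instruments, outcome, alphaDiscovery = 7.5e-5,
                     outcomeId = "outcome", palindromeEafBand = 0.42) {
  pids <- unique(instruments$protein_id)
  rows <- lapply(pids, function(pid) {
    ins <- instruments[instruments$protein_id == pid, , drop = FALSE]
    h <- harmoniseInstruments(ins, outcome, palindromeEafBand)
    usable <- h$action %in% c("unchanged", "flipped")
    if (!any(usable))
      return(data.frame(protein_id = pid, outcome_id = outcomeId,
                        method = NA_character_, nsnp = 0L, beta = NA_real_,
                        se = NA_real_, p = NA_real_, significant = FALSE,
                        status = "untested", stringsAsFactors = FALSE))
    est <- ivw(h)
    data.frame(protein_id = pid, outcome_id = outcomeId,
               method = est$method, nsnp = est$nsnp, beta = est$beta,
               se = est$se, p = est$p,
               significant = est$p < alphaDiscovery, status = "tested",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Replication of discovery-significant MR findings
#'
#' Re-estimates each discovery-significant protein against an independent
#' replication outcome at a nominal threshold; a finding replicates iff the
#' replication p-value is below `alphaRep` and the effect direction agrees
#' with discovery. Proteins whose instruments cannot be matched in the
#' replication outcome are reported unreplicable.
#'
#' @param discovery results from [mrScreen()]; only `significant` rows are
#'   followed up.
#' @param instruments the instrument data.frame used for discovery.
#' @param replicationOutcome independent outcome summary-statistics set.
#' @param alphaRep nominal replication threshold (default 0.05).
#' @param palindromeEafBand passed to [harmoniseInstruments()].
#' @return the discovery rows with appended `beta_rep, se_rep, p_rep,
#'   replicated`.
#' @export
replicateMR <- function(discovery, instruments, replicationOutcome,
                        alphaRep = 0.05, palindromeEafBand = 0.42) {
  hits <- discovery[discovery$significant %in% TRUE, , drop = FALSE]
  if (!nrow(hits)) {
    hits$beta_rep <- hits$se_rep <- hits$p_rep <- numeric(0)
    hits$replicated <- logical(0)
    return(hits)
  }
  rep <- mrScreen(instruments[instruments$protein_id %in% hits$protein_id, ,
                              drop = FALSE],
                  replicationOutcome, alphaDiscovery = alphaRep,
                  outcomeId = "replication",
                  palindromeEafBand = palindromeEafBand)
  j <- match(hits$protein_id, rep$protein_id)
  hits$beta_rep <- rep$beta[j]
  hits$se_rep <- rep$se[j]
  hits$p_rep <- rep$p[j]
  hits$replicated <- !is.na(hits$p_rep) & hits$p_rep < alphaRep &
    sign(hits$beta_rep) == sign(hits$beta)
  hits$replicated[rep$status[j] == "untested"] <- FALSE
  hits
}
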