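## Per-protein association with clinical characteristics, global FDR
## correction, and the incident case-control protein model.

.clinicalTerms <- c("age", "bmi", "menopause_preVSperi",
                    "menopause_preVSpost", "birth_times", "hrt_status",
                    "alcohol_gram_week", "smoking_status")

.clinicalDesign <- function(covariates) {
  needed <- c("age", "bmi", "menopause", "birth_times", "hrt_status",
              "alcohol_gram_week", "smoking_status")
  miss <- setdiff(needed, names(covariates))
  if (length(miss))
    stop("covariate table lacks: ", paste(miss, collapse = ", "),
         call. = FALSE)
  X <- cbind(`(Intercept)` = 1,
             age = covariates$age,
             bmi = covariates$bmi,
             menopause_preVSperi = as.numeric(covariates$menopause == "peri"),
             menopause_preVSpost = as.numeric(covariates$menopause == "post"),
             birth_times = covariates$birth_times,
             hrt_status = as.numeric(covariates$hrt_status == "current"),
             alcohol_gram_week = covariates$alcohol_gram_week,
             smoking_status = as.numeric(covariates$smoking_status ==
                                           "current"))
  X
}

## OLS with classical SEs and t-based two-sided p; shared by the clinical and
## case-control models
.olsTerms <- function(y, X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- nrow(X); df <- n - ncol(X)
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  s2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(s2 * diag(XtXinv))
  if (stats::var(y) == 0) {  # degenerate response: flag, don't report p = 0
    tv <- rep(NA_real_, length(beta))
    p <- rep(NA_real_, length(beta))
    beta[-1] <- 0
  } else {
    tv <- beta / se
    p <- 2 * stats::pt(-abs(tv), df)
  }
  data.frame(term = colnames(X), beta = as.numeric(beta), se = se, p = p,
             n = n, df = df, stringsAsFactors = FALSE)
}

#' Fit the per-protein clinical-characteristics model
#'
#' Multivariable OLS of one protein's NPX values on the seven baseline
#' characteristics: `NPX ~ age + bmi + menopause_preVSperi +
#' menopause_preVSpost + birth_times + hrt_status + alcohol_gram_week +
#' smoking_status`, with pre-menopause, never-or-past HRT and never-or-past
#' smoking as reference levels. Samples with any missing modelled covariate
#' or NPX value are dropped listwise; classical standard errors and
#' t-distribution two-sided p-values are reported for the eight
#' non-intercept terms (menopause contributes two contrasts of one
#' characteristic family).
#'
#' @param npxColumn numeric vector of one protein's NPX values, aligned to
#'   `covariates` rows.
#' @param covariates data.frame in the layout of [simulateCovariates()].
#' @param minComplete minimum number of complete cases (default 30).
#' @return data.frame with columns `term, beta, se, p, n, df, n_dropped`.
#' @export
fitClinicalModel <- function(npxColumn, covariates, minComplete = 30) {
  X <- .clinicalDesign(covariates)
  ok <- stats::complete.cases(X) & !is.na(npxColumn)
  if (sum(ok) < minComplete)
    stop("fewer than ", minComplete, " complete cases", call. = FALSE)
  fit <- .olsTerms(npxColumn[ok], X[ok, , drop = FALSE])
  fit <- fit[fit$term != "(Intercept)", ]
  fit$n_dropped <- sum(!ok)
  rownames(fit) <- NULL
  fit
}

#' Benjamini-Hochberg adjustment with an explicit test count
#'
#' Step-up false-discovery-rate adjustment with denominator `m`, supporting
#' correction of a sub-vector against a larger family of performed tests,
#' or — as in the proteins-times-7-characteristics convention, where the two
#' menopause contrasts count as one characteristic — a family counted in
#' contrast families rather than individual terms (`m` below `length(p)`).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param m number of tests counted in the family (default `length(p)`).
#' @return q-values in the input order, capped at 1; equal to
#'   `p.adjust(p, "BH")` when `m = length(p)`.
#' @examples
#' fdrAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
fdrAdjust <- function(p, m = length(p)) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (m < 1) stop("'m' must be at least 1", call. = FALSE)
  n <- length(p)
  if (n == 0L) return(numeric(0))
  o <- order(p)
  q <- (m / seq_len(n)) * p[o]
  q <- pmin(rev(cummin(rev(q))), 1)
  out <- numeric(n)
  out[o] <- q
  out
}

#' Clinical associations across all proteins
#'
#' Fits [fitClinicalModel()] per protein and adjusts all p-values jointly by
#' Benjamini-Hochberg over `m = nProteins * 7` tests — the two menopause
#' contrasts are counted as one characteristic family, matching the
#' "proteins times 7 characteristics" correction convention — unless
#' `mPerProtein` is changed (set it to 8 for the exact per-term count).
#'
#' @param npx an [NPXMatrix-class].
#' @param covariates covariate data.frame aligned to the NPX columns.
#' @param mPerProtein tests counted per protein in the FDR family (default
#'   7).
#' @return data.frame with columns `protein_id, term, beta, se, p, q, n,
#'   n_dropped`.
#' @export
clinicalAssociations <- function(npx, covariates, mPerProtein = 7) {
  v <- npxValues(npx)
  ids <- assayAnnotation(npx)$protein_id
  res <- vector("list", nrow(v))
  for (i in seq_len(nrow(v))) {
    fit <- fitClinicalModel(v[i, ], covariates)
    fit$protein_id <- ids[i]
    res[[i]] <- fit
  }
  out <- do.call(rbind, res)
  ok <- !is.na(out$p)
  out$q <- NA_real_
  out$q[ok] <- fdrAdjust(out$p[ok], m = nrow(v) * mPerProtein)
  out[, c("protein_id", "term", "beta", "se", "p", "q", "n", "n_dropped")]
}

#' Incident case-control association for one protein
#'
#' OLS of NPX on case status adjusted for age at blood draw, body mass index
#' and sample storage time.
#'
#' @inheritParams fitClinicalModel
#' @return one-row data.frame for the case-status term (`beta, se, p, n`).
#' @export
caseControlAssoc <- function(npxColumn, covariates) {
  if (length(unique(covariates$case_status[!is.na(npxColumn)])) < 2L)
    stop("both cases and controls are required", call. = FALSE)
  X <- cbind(`(Intercept)` = 1,
             case_status = as.numeric(covariates$case_status == "case"),
             age = covariates$age, bmi = covariates$bmi,
             storage_time = covariates$storage_time)
  ok <- stats::complete.cases(X) & !is.na(npxColumn)
  fit <- .olsTerms(npxColumn[ok], X[ok, , drop = FALSE])
  fit <- fit[fit$term == "case_status", c("term", "beta", "se", "p", "n")]
  rownames(fit) <- NULL
  fit
}

#' Case-control screen across proteins at 5% FDR
#'
#' @param npx an [NPXMatrix-class].
#' @param covariates covariate data.frame aligned to the NPX columns.
#' @param fdr false-discovery-rate level for the significance flag.
#' @return data.frame with columns `protein_id, beta, se, p, q, significant`.
#' @export
caseControlScreen <- function(npx, covariates, fdr = 0.05) {
  v <- npxValues(npx)
  ids <- assayAnnotation(npx)$protein_id
  rows <- lapply(seq_len(nrow(v)), function(i) {
    fit <- caseControlAssoc(v[i, ], covariates)
    data.frame(protein_id = ids[i], beta = fit$beta, se = fit$se, p = fit$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- fdrAdjust(out$p)
  out$significant <- out$q < fdr
  out
}
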