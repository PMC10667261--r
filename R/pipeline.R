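## End-to-end orchestration: simulate -> QC -> clinical association ->
## cis-pQTL scan -> MR discovery -> replication -> regional concordance,
## with a funnel summary and a checksummed run manifest.

#' Create a pipeline configuration
#'
#' Thresholds default to the analysis conventions of the pipeline: assays
#' kept above 25% detectability, variants above 1% MAF, independent-variant
#' pruning at r-squared 0.1, instrument clumping at r-squared 0.001, the
#' cis significance threshold derived from the mean independent count at
#' alpha 0.05, MR discovery at 7.5e-5, replication at nominal 0.05, and
#' LD proxies at r-squared 0.8.
#'
#' @param sim a [SimulationConfig-class] for self-contained runs, or `NULL`
#'   when `inputs` provides file paths.
#' @param inputs optional named list of file paths (`dosage`, `npx`,
#'   `covariates`, `discovery`, `replication`) read with the package's
#'   readers; exactly one of `sim`/`inputs` must be given.
#' @param minDetect,mafMin,r2Independent,r2Clump,alpha,alphaMR,alphaRep,r2Proxy
#'   stage thresholds (see description).
#' @param alphaPqtlFixed optional fixed cis threshold overriding the
#'   mean-independent derivation.
#' @param seed master seed; overrides `sim`'s seed when given.
#' @return a validated list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(sim = simulationConfig(), inputs = NULL,
                           minDetect = 0.25, mafMin = 0.01,
                           r2Independent = 0.1, r2Clump = 0.001,
                           alpha = 0.05, alphaPqtlFixed = NULL,
                           alphaMR = 7.5e-5, alphaRep = 0.05,
                           r2Proxy = 0.8, seed = NULL) {
  if (is.null(sim) == is.null(inputs))
    stop("exactly one of 'sim' or 'inputs' must be supplied", call. = FALSE)
  if (!is.null(sim)) {
    stopifnot(is(sim, "SimulationConfig"))
    if (!is.null(seed)) sim@seed <- .checkCount(seed, "seed")
    validObject(sim)
  }
  for (f in c("minDetect", "mafMin", "r2Independent", "r2Clump", "alpha",
              "alphaMR", "alphaRep", "r2Proxy"))
    .checkFraction(get(f), f)
  structure(list(sim = sim, inputs = inputs, minDetect = minDetect,
                 mafMin = mafMin, r2Independent = r2Independent,
                 r2Clump = r2Clump, alpha = alpha,
                 alphaPqtlFixed = alphaPqtlFixed, alphaMR = alphaMR,
                 alphaRep = alphaRep, r2Proxy = r2Proxy),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `sim` (fields of [simulationConfig()]) and `thresholds`
#' (arguments of [pipelineConfig()]); unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return a `"PipelineConfig"`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  bad <- setdiff(names(y), c("sim", "thresholds", "seed"))
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  simArgs <- y$sim
  if (!is.null(simArgs$mafRange)) simArgs$mafRange <- unlist(simArgs$mafRange)
  if (!is.null(simArgs$covariateEffects))
    simArgs$covariateEffects <- unlist(simArgs$covariateEffects)
  sim <- do.call(simulationConfig, simArgs)
  do.call(pipelineConfig, c(list(sim = sim, seed = y$seed), y$thresholds))
}

.loadInputs <- function(config) {
  if (!is.null(config$sim)) {
    study <- simulateStudy(config$sim)
  } else {
    inp <- config$inputs
    study <- list(genotypes = readDosageTSV(inp$dosage),
                  covariates = readCovariates(inp$covariates),
                  npx = readNPXCSV(inp$npx),
                  discovery = readOutcomeSummary(inp$discovery),
                  replication = if (!is.null(inp$replication))
                    readOutcomeSummary(inp$replication) else NULL,
                  truth = NULL)
  }
  study
}

#' Run the full proteome-to-disease pipeline
#'
#' Executes, in order: data simulation (or loading), NPX quality control,
#' clinical-characteristics association, incident case-control screen,
#' cis-pQTL scan with independent-variant correction, instrument clumping,
#' discovery MR, replication, and lead-variant concordance for the
#' replicated proteins. Each stage's outputs are written before the next
#' starts; per-stage counts are propagated into a funnel summary (proteins
#' in, post-QC, with cis-pQTL, MR-tested, significant, replicated), which is
#' non-increasing by construction.
#'
#' @param config a `"PipelineConfig"` from [pipelineConfig()].
#' @param outDir output directory (created; tables and manifest written
#'   there).
#' @return the run manifest (list): `seed`, `config_hash`, `funnel`,
#'   per-stage counts, output `files` with md5 checksums, and the result
#'   tables themselves in `$tables`.
#' @export
runPipeline <- function(config, outDir) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log <- list()

  ## stage 1: data
  study <- .loadInputs(config)
  writeDosageTSV(study$genotypes, file.path(outDir, "dosage.tsv"))
  writeCovariates(study$covariates, file.path(outDir, "covariates.tsv"))
  writeNPXCSV(study$npx, file.path(outDir, "npx.csv"))
  writeOutcomeSummary(study$discovery, file.path(outDir, "discovery.tsv"))
  if (!is.null(study$replication))
    writeOutcomeSummary(study$replication,
                        file.path(outDir, "replication.tsv"))
  if (!is.null(config$sim))
    jsonlite::write_json(
      c(list(scenario = config$sim@scenario, theta = config$sim@theta,
             cisH2 = config$sim@cisH2, seed = config$sim@seed),
        if (!is.null(study$truth)) list(truth = study$truth)),
      file.path(outDir, "truth.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  log$n_proteins_in <- nrow(study$npx)
  log$n_samples_in <- ncol(study$npx)

  ## stage 2: QC
  qc <- runQC(study$npx, minDetect = config$minDetect)
  writeQCReport(qc$report, outDir)
  npx <- qc$npx
  keepSamples <- colnames(npx)
  covs <- study$covariates[match(keepSamples, study$covariates$sample_id), ]
  geno <- study$genotypes[, keepSamples]
  log$n_proteins_qc <- nrow(npx)
  log$n_samples_qc <- ncol(npx)

  ## stage 3: clinical associations + case-control screen
  clin <- clinicalAssociations(npx, covs)
  data.table::fwrite(clin, file.path(outDir, "clinical_assoc.tsv"),
                     sep = "\t")
  cc <- caseControlScreen(npx, covs)
  data.table::fwrite(cc, file.path(outDir, "case_control.tsv"), sep = "\t")
  log$n_clinical_fdr_significant <- sum(clin$q < 0.05, na.rm = TRUE)
  log$n_case_control_significant <- sum(cc$significant)

  ## stage 4: cis-pQTL scan
  scan <- pqtlScan(npx, geno, covs, mafMin = config$mafMin,
                   r2Independent = config$r2Independent,
                   alpha = config$alpha,
                   alphaFixed = config$alphaPqtlFixed)
  data.table::fwrite(scan$associations,
                     file.path(outDir, "cis_associations.tsv"), sep = "\t")
  data.table::fwrite(scan$regions, file.path(outDir, "regions.tsv"),
                     sep = "\t")
  if (!is.null(scan$hits))
    data.table::fwrite(scan$hits, file.path(outDir, "pqtl_hits.tsv"),
                       sep = "\t")
  log$pqtl_threshold <- scan$threshold
  log$mean_independent <- scan$meanIndependent
  log$n_pqtl_hits <- if (is.null(scan$hits)) 0L else nrow(scan$hits)
  log$n_proteins_with_pqtl <- if (is.null(scan$hits)) 0L else
    length(unique(scan$hits$protein_id))

  ## stage 5: instruments + discovery MR
  dosT <- t(dosages(geno))
  instruments <- NULL
  if (!is.null(scan$hits)) {
    byProt <- split(scan$hits, scan$hits$protein_id)
    instruments <- do.call(rbind, lapply(byProt, function(h) {
      reg <- scan$regions[scan$regions$protein_id == h$protein_id[1], ]
      ids <- scan$associations$id[scan$associations$protein_id ==
                                    h$protein_id[1]]
      clumpInstruments(h, dosT[, ids, drop = FALSE], config$r2Clump)
    }))
    rownames(instruments) <- NULL
  }
  mr <- NULL; replication <- NULL
  if (!is.null(instruments) && nrow(instruments)) {
    data.table::fwrite(instruments, file.path(outDir, "instruments.tsv"),
                       sep = "\t")
    mr <- mrScreen(instruments, study$discovery,
                   alphaDiscovery = config$alphaMR,
                   outcomeId = "discovery")
    data.table::fwrite(mr, file.path(outDir, "mr_discovery.tsv"),
                       sep = "\t")
    log$n_mr_tested <- sum(mr$status == "tested")
    log$n_mr_untested <- sum(mr$status == "untested")
    log$n_mr_significant <- sum(mr$significant)

    ## stage 6: replication
    if (!is.null(study$replication)) {
      replication <- replicateMR(mr, instruments, study$replication,
                                 alphaRep = config$alphaRep)
      data.table::fwrite(replication,
                         file.path(outDir, "mr_replication.tsv"),
                         sep = "\t")
      log$n_replicated <- sum(replication$replicated)
    } else log$n_replicated <- NA_integer_
  } else {
    log$n_mr_tested <- 0L; log$n_mr_untested <- 0L
    log$n_mr_significant <- 0L; log$n_replicated <- 0L
  }

  ## stage 7: concordance for replicated proteins
  verdicts <- NULL
  followUp <- if (!is.null(replication) && nrow(replication))
    replication$protein_id[replication$replicated] else character(0)
  if (length(followUp)) {
    anno <- assayAnnotation(npx)
    vinfo <- variantInfo(geno)
    verdicts <- do.call(rbind, lapply(followUp, function(pid) {
      reg <- defineCisRegion(anno[anno$protein_id == pid, ], vinfo)
      al <- regionAlignment(
        scan$associations[scan$associations$protein_id == pid, ],
        study$discovery, reg, dosT)
      cbind(protein_id = pid,
            leadConcordance(al, dosT, r2Concordant = config$r2Proxy))
    }))
    data.table::fwrite(verdicts, file.path(outDir, "concordance.tsv"),
                       sep = "\t")
  }

  funnel <- data.frame(
    stage = c("proteins_in", "post_qc", "with_cis_pqtl", "mr_tested",
              "mr_significant", "replicated"),
    n = c(log$n_proteins_in, log$n_proteins_qc, log$n_proteins_with_pqtl,
          log$n_mr_tested, log$n_mr_significant, log$n_replicated))
  data.table::fwrite(funnel, file.path(outDir, "funnel.tsv"), sep = "\t")

  cfgFile <- tempfile(fileext = ".json")
  jsonlite::write_json(list(thresholds = unclass(config)[-(1:2)],
                            seed = if (!is.null(config$sim))
                              config$sim@seed else NA),
                       cfgFile, auto_unbox = TRUE, digits = NA)
  files <- list.files(outDir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("proteoMR")),
    seed = if (!is.null(config$sim)) config$sim@seed else NA,
    config_hash = unname(tools::md5sum(cfgFile)),
    timestamp = format(Sys.time(), tz = "UTC"),
    counts = log,
    funnel = funnel,
    files = data.frame(file = basename(files),
                       md5 = unname(tools::md5sum(files)),
                       stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  manifest$tables <- list(clinical = clin, case_control = cc,
                          pqtl = scan, instruments = instruments,
                          mr = mr, replication = replication,
                          concordance = verdicts)
  invisible(manifest)
}
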