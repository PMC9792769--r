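## End-to-end orchestration: stratify -> differential expression ->
## reversal scoring -> upstream regulators -> validation, per cohort, with
## per-cohort failure isolation, a cross-cohort intersection report and a
## JSON manifest. All randomness flows from a single root seed split
## deterministically per stage and cohort, so a rerun with the same config
## is bitwise identical.

#' Validate (and normalize) a pipeline run configuration
#'
#' @param config named list or path to a flat YAML document. Required keys:
#'   \code{expression}, \code{conditions}, \code{variants}, \code{pathways},
#'   \code{drugProfiles}, \code{network}, \code{gold} (input paths),
#'   \code{outDir} and \code{seed}. Optional keys with defaults:
#'   \code{cancerType} ("synthetic"), \code{applyLog2} (FALSE),
#'   \code{pseudocount} (1), \code{alphaQDe} (0.05), \code{minAbsLfc} (0),
#'   \code{alphaQDrugs} (0.05), \code{alphaRegulators} (0.05),
#'   \code{tail} ("inhibited"), \code{nPerm} (1000), \code{nControls}
#'   (1000), \code{cutoffs} (5, 10, 20, 50),
#'   \code{excludeClasses} ("Silent").
#' @return the completed config list.
#' @export
validateRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(cancerType = "synthetic", applyLog2 = FALSE,
                   pseudocount = 1, alphaQDe = 0.05, minAbsLfc = 0,
                   alphaQDrugs = 0.05, alphaRegulators = 0.05,
                   tail = "inhibited", nPerm = 1000, nControls = 1000,
                   cutoffs = c(5, 10, 20, 50), excludeClasses = "Silent")
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  config$cutoffs <- sort(unique(as.integer(unlist(config$cutoffs))))
  required <- c("expression", "conditions", "variants", "pathways",
                "drugProfiles", "network", "gold", "outDir", "seed")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    stop(sprintf("config is missing required key(s): %s",
                 paste(missing, collapse = ", ")))
  }
  for (nm in c("alphaQDe", "alphaQDrugs", "alphaRegulators")) {
    stopIfNotScalarProb(config[[nm]], nm)
  }
  inputs <- c("expression", "conditions", "variants", "pathways",
              "drugProfiles", "network", "gold")
  absent <- inputs[!file.exists(unlist(config[inputs]))]
  if (length(absent)) {
    stop(sprintf("input file(s) not found for: %s",
                 paste(absent, collapse = ", ")))
  }
  config
}

.stageLog <- function(stage, cohort, fmt, ...) {
  message(sprintf("[%s:%s] %s", stage, cohort, sprintf(fmt, ...)))
}

#' Run the full repurposing pipeline
#'
#' Executes, per DNA-repair cohort: tumor-vs-normal moderated-t
#' differential expression, signature construction, drug reversal scoring
#' and ranking, upstream-regulator scoring, and ranking validation against
#' the gold standard with random controls. A failing cohort is logged and
#' marked FAILED without aborting the others. Writes per-cohort TSVs, a
#' cross-cohort intersection report (drugs and CDTs significant in every
#' successful cohort) and \code{manifest.json}.
#'
#' @param config see [validateRunConfig()].
#' @return the manifest list, invisibly.
#' @export
runPipeline <- function(config) {
  config <- validateRunConfig(config)
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)

  se <- readExpressionMatrix(config$expression, config$conditions,
                             cancerType = config$cancerType)
  if (isTRUE(config$applyLog2)) {
    se <- log2Transform(se, pseudocount = config$pseudocount)
  }
  pathways <- readGmt(config$pathways)
  variants <- readVariants(config$variants)
  drugs <- readDrugProfiles(config$drugProfiles)
  network <- readNetwork(config$network)
  gold <- readGoldStandard(config$gold)
  goldDrugs <- unique(unlist(gold, use.names = FALSE))

  cohorts <- stratifyPatients(variants, pathways,
                              excludeClasses = config$excludeClasses)
  writeResultTable(cohortSummary(cohorts, config$cancerType),
                   file.path(config$outDir, "cohorts.tsv"),
                   provenance = sprintf("seed=%d", seed))

  tumorSamples <- colnames(se)[se$condition == "tumor"]
  normalSamples <- colnames(se)[se$condition == "normal"]
  cohortInfo <- list()
  rankingsByCohort <- list()
  regulatorsByCohort <- list()

  for (i in seq_along(cohorts)) {
    pw <- names(cohorts)[[i]]
    info <- list(pathway = pw, n_patients = length(cohorts[[i]]),
                 status = "OK")
    res <- tryCatch({
      members <- intersect(cohorts[[i]], tumorSamples)
      dropped <- setdiff(cohorts[[i]], tumorSamples)
      if (length(dropped)) {
        .stageLog("diffexpr", pw,
                  "%d cohort member(s) without expression data dropped",
                  length(dropped))
      }
      if (length(members) < 2L) {
        stop(sprintf("cohort has %d member(s) with expression data; need >= 2",
                     length(members)))
      }
      info$n_expression <- length(members)
      .stageLog("diffexpr", pw, "%d tumor vs %d normal samples",
                length(members), length(normalSamples))
      seCohort <- se[, c(members, normalSamples)]
      de <- moderatedTTest(seCohort)
      signature <- buildSignature(de, alphaQ = config$alphaQDe,
                                  minAbsLfc = config$minAbsLfc, cohort = pw)
      info$n_up <- length(upSet(signature))
      info$n_down <- length(downSet(signature))
      .stageLog("diffexpr", pw, "%d up / %d down DE genes",
                info$n_up, info$n_down)
      writeSignature(signature,
                     file.path(config$outDir,
                               sprintf("signature_%s.tsv", pw)),
                     provenance = sprintf("seed=%d", seed))

      scores <- scoreDrugs(signature, drugs, nPerm = config$nPerm,
                           seed = childSeed(seed, 100L + i))
      ranking <- suppressWarnings(rankDrugs(scores,
                                            alphaQ = config$alphaQDrugs))
      info$n_drugs_scored <- nrow(scores)
      info$n_drugs_retained <- nrow(ranking)
      .stageLog("reversal", pw, "%d drugs scored, %d retained at q < %g",
                nrow(scores), nrow(ranking), config$alphaQDrugs)
      writeResultTable(ranking,
                       file.path(config$outDir,
                                 sprintf("drug_ranking_%s.tsv", pw)),
                       provenance = sprintf("seed=%d nPerm=%d", seed,
                                            as.integer(config$nPerm)))

      regs <- scoreAllRegulators(network, signature,
                                 alpha = config$alphaRegulators,
                                 tail = config$tail)
      info$n_cdts_retained <- nrow(regs)
      .stageLog("regulators", pw, "%d CDT(s) retained at p < %g",
                nrow(regs), config$alphaRegulators)
      writeResultTable(regs,
                       file.path(config$outDir,
                                 sprintf("regulators_%s.tsv", pw)),
                       provenance = sprintf("seed=%d tail=%s", seed,
                                            config$tail))

      if (nrow(ranking)) {
        cut <- unique(pmin(config$cutoffs, nrow(ranking)))
        sens <- sensitivityAtCutoffs(ranking$drug_id, goldDrugs, cut)
        rel <- relevanceLabels(ranking$drug_id, goldDrugs)
        sens$ndcg <- vapply(cut, function(p) ndcg(rel, p), numeric(1))
        ctrl <- randomControlCurve(ranking$drug_id, goldDrugs, cut,
                                   nControls = config$nControls,
                                   seed = childSeed(seed, 200L + i))
        val <- cbind(sens, ctrl[, -1L])
        writeResultTable(val,
                         file.path(config$outDir,
                                   sprintf("validation_%s.tsv", pw)),
                         provenance = sprintf("seed=%d nControls=%d", seed,
                                              as.integer(config$nControls)))
      } else {
        .stageLog("validation", pw, "empty ranking; validation skipped")
      }
      list(ranking = ranking, regulators = regs, info = info)
    }, error = function(e) {
      .stageLog("pipeline", pw, "FAILED: %s", conditionMessage(e))
      writeLines(sprintf("FAILED: %s", conditionMessage(e)),
                 file.path(config$outDir, sprintf("FAILED_%s", pw)))
      info$status <- "FAILED"
      info$error <- conditionMessage(e)
      list(ranking = NULL, regulators = NULL, info = info)
    })
    cohortInfo[[pw]] <- res$info
    if (identical(res$info$status, "OK")) {
      rankingsByCohort[[pw]] <- res$ranking
      regulatorsByCohort[[pw]] <- res$regulators
    }
  }

  if (length(rankingsByCohort)) {
    commonDrugs <- sort(Reduce(intersect,
                               lapply(rankingsByCohort, `[[`, "drug_id")))
    commonCdts <- sort(Reduce(intersect,
                              lapply(regulatorsByCohort, `[[`, "cdt_id")))
    n <- max(length(commonDrugs), length(commonCdts), 1L)
    writeResultTable(
      data.frame(drug_id = c(commonDrugs, rep("", n - length(commonDrugs))),
                 cdt_id = c(commonCdts, rep("", n - length(commonCdts)))),
      file.path(config$outDir, "intersection.tsv"),
      provenance = sprintf("significant in all %d successful cohort(s)",
                           length(rankingsByCohort)))
  } else {
    commonDrugs <- character(0)
    commonCdts <- character(0)
  }

  manifest <- list(
    package = "repurposeDR",
    version = as.character(packageVersion("repurposeDR")),
    seed = seed,
    parameters = config[c("cancerType", "applyLog2", "pseudocount",
                          "alphaQDe", "minAbsLfc", "alphaQDrugs",
                          "alphaRegulators", "tail", "nPerm", "nControls",
                          "cutoffs", "excludeClasses")],
    cohorts = cohortInfo,
    intersection = list(drugs = commonDrugs, cdts = commonCdts))
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
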