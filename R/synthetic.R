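## Seeded synthetic-data generator. Emulates the statistical structure the
## analysis assumes -- tumor/normal expression with inverse-chi-square
## gene-wise variances and planted signed DE effects, mutation tables that
## place patients into overlapping pathway cohorts, drug rank profiles with
## planted reverters/mimickers/nulls, and a signed network with planted
## therapeutic regulators -- so every pipeline stage runs offline. The
## entire scenario is a pure function of (parameters, seed).

#' Define a synthetic study scenario
#'
#' Defaults describe the desk-scale study the package is exercised on:
#' 2,000 genes, 40 tumor + 40 adjacent-normal samples, five DNA-repair
#' pathways with KEGG-like set sizes, a 5% DE fraction with |log2FC| = 2
#' effects under a scaled inverse-chi-square variance prior (d0 = 4,
#' s0^2 = 0.05), 100 drugs of which 5 are perfect reverters (mimickers are
#' available as an explicit option), and 50 CDTs of which 2 are therapeutic
#' with 20 edges each (the scale of well-characterized drug regulators).
#'
#' @param nGenes number of genes.
#' @param nTumor,nNormal samples per condition (>= 2 each).
#' @param cancerType label used throughout the generated files.
#' @param pathwaySizes named integer vector of pathway gene-set sizes; the
#'   generator draws the sets disjointly so planted cohort membership is
#'   exactly recoverable.
#' @param mutationProb named per-pathway probability that a patient carries
#'   a deleterious variant in that pathway (independent across pathways, so
#'   cohorts overlap).
#' @param deFraction fraction of genes differentially expressed in tumors.
#' @param delta absolute log2 fold-change of planted DE genes.
#' @param d0,s0Sq variance-prior degrees of freedom and scale.
#' @param nDrugs,nReverters,nMimickers drug collection composition.
#' @param rho reversal strength in [0, 1]: 1 places signature genes at the
#'   profile extremes, 0 collapses to a uniformly random profile.
#' @param nCdts,nTherapeutic,edgesPerCdt network composition.
#' @param weightRange range of edge confidence weights (uniform draw);
#'   the default c(1, 1) gives unit weights.
#' @param seed root seed; every generator derives its own stream from it.
#' @return a \code{SyntheticScenario} (validated list).
#' @export
syntheticScenario <- function(
    nGenes = 2000L, nTumor = 40L, nNormal = 40L, cancerType = "synthetic",
    pathwaySizes = c(HR = 41L, BER = 33L, MMR = 23L, NER = 47L, NHEJ = 13L),
    mutationProb = c(HR = 0.35, BER = 0.20, MMR = 0.30, NER = 0.25,
                     NHEJ = 0.15),
    deFraction = 0.05, delta = 2, d0 = 4, s0Sq = 0.05,
    nDrugs = 100L, nReverters = 5L, nMimickers = 0L, rho = 1,
    nCdts = 50L, nTherapeutic = 2L, edgesPerCdt = 20L,
    weightRange = c(1, 1), seed = 1L) {
  sc <- list(nGenes = as.integer(nGenes), nTumor = as.integer(nTumor),
             nNormal = as.integer(nNormal), cancerType = cancerType,
             pathwaySizes = pathwaySizes, mutationProb = mutationProb,
             deFraction = deFraction, delta = delta, d0 = d0, s0Sq = s0Sq,
             nDrugs = as.integer(nDrugs), nReverters = as.integer(nReverters),
             nMimickers = as.integer(nMimickers), rho = rho,
             nCdts = as.integer(nCdts),
             nTherapeutic = as.integer(nTherapeutic),
             edgesPerCdt = as.integer(edgesPerCdt),
             weightRange = weightRange, seed = as.integer(seed))
  with(sc, {
    stopifnot(nGenes >= 10, nTumor >= 2, nNormal >= 2,
              all(pathwaySizes >= 1), sum(pathwaySizes) <= nGenes,
              identical(names(pathwaySizes), names(mutationProb)),
              all(mutationProb >= 0), all(mutationProb <= 1),
              deFraction >= 0, deFraction <= 1, delta >= 0,
              d0 > 0, s0Sq > 0,
              nDrugs >= 1, nReverters >= 0, nMimickers >= 0,
              nReverters + nMimickers <= nDrugs,
              rho >= 0, rho <= 1,
              nCdts >= 1, nTherapeutic >= 0, nTherapeutic <= nCdts,
              edgesPerCdt >= 1, length(weightRange) == 2,
              weightRange[1] > 0, weightRange[2] <= 1,
              weightRange[1] <= weightRange[2])
  })
  structure(sc, class = "SyntheticScenario")
}

.geneIds <- function(sc) sprintf("G%04d", seq_len(sc$nGenes))
.patientIds <- function(sc) sprintf("P%03d", seq_len(sc$nTumor))
.normalIds <- function(sc) sprintf("N%03d", seq_len(sc$nNormal))

#' Generate disjoint DNA-repair pathway gene sets
#'
#' @param scenario a [syntheticScenario()].
#' @return named list of gene-id vectors.
#' @export
generatePathways <- function(scenario) {
  withSeed(childSeed(scenario$seed, 1L), {
    genes <- sample(.geneIds(scenario), sum(scenario$pathwaySizes))
    split(genes, rep(names(scenario$pathwaySizes), scenario$pathwaySizes))[
      names(scenario$pathwaySizes)]
  })
}

#' Generate tumor/normal expression with planted DE genes
#'
#' Gene-wise variances are drawn from a scaled inverse-chi-square prior
#' (d0, s0^2); a \code{deFraction} of genes is shifted by +/- delta in
#' tumors; Gaussian noise throughout. Values are on the log2 scale.
#'
#' @param scenario a [syntheticScenario()].
#' @return list with \code{se} (SummarizedExperiment) and \code{truth}
#'   (DataFrame gene/sign/effect for planted DE genes, empty when
#'   delta = 0 or deFraction = 0).
#' @export
generateExpression <- function(scenario) {
  sc <- scenario
  withSeed(childSeed(sc$seed, 2L), {
    genes <- .geneIds(sc)
    sigma2 <- sc$d0 * sc$s0Sq / rchisq(sc$nGenes, df = sc$d0)
    baseline <- rnorm(sc$nGenes, mean = 7, sd = 1.5)
    nDe <- round(sc$deFraction * sc$nGenes)
    deGenes <- if (sc$delta > 0 && nDe > 0) sample(genes, nDe) else character(0)
    signs <- if (length(deGenes)) {
      sample(c(-1L, 1L), length(deGenes), replace = TRUE)
    } else integer(0)
    effect <- numeric(sc$nGenes)
    effect[match(deGenes, genes)] <- sc$delta * signs
    n <- sc$nTumor + sc$nNormal
    noise <- matrix(rnorm(sc$nGenes * n, sd = sqrt(sigma2)),
                    nrow = sc$nGenes, ncol = n)
    mat <- baseline + noise
    mat[, seq_len(sc$nTumor)] <- mat[, seq_len(sc$nTumor)] + effect
    dimnames(mat) <- list(genes, c(.patientIds(sc), .normalIds(sc)))
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(exprs = mat),
      colData = S4Vectors::DataFrame(
        condition = rep(c("tumor", "normal"), c(sc$nTumor, sc$nNormal)),
        row.names = colnames(mat)))
    S4Vectors::metadata(se)$cancerType <- sc$cancerType
    truth <- S4Vectors::DataFrame(gene = deGenes, sign = signs,
                                  effect = sc$delta * signs)
    list(se = se, truth = truth)
  })
}

.VARIANT_CLASSES <- c("Missense_Mutation", "Nonsense_Mutation",
                      "Frame_Shift_Del", "Splice_Site")

#' Generate a somatic-variant table with planted cohort membership
#'
#' Each patient is independently mutated in each pathway with the
#' scenario's per-pathway probability; a mutated patient gets one
#' deleterious variant in a uniformly chosen gene of that pathway.
#' Background noise adds Silent variants in pathway genes (excluded by the
#' default stratification) and deleterious variants in non-pathway genes
#' (in no cohort's gene set), so planted membership stays exact.
#'
#' @param scenario a [syntheticScenario()].
#' @param pathways gene sets from [generatePathways()].
#' @return list with \code{variants} (data.frame) and \code{truth} (named
#'   list pathway -> sorted planted patient ids).
#' @export
generateVariants <- function(scenario, pathways) {
  sc <- scenario
  withSeed(childSeed(sc$seed, 3L), {
    patients <- .patientIds(sc)
    rows <- list()
    truth <- list()
    for (pw in names(pathways)) {
      hit <- patients[runif(length(patients)) < sc$mutationProb[[pw]]]
      truth[[pw]] <- sort(hit)
      if (length(hit)) {
        rows[[pw]] <- data.frame(
          patient_id = hit,
          gene_symbol = sample(pathways[[pw]], length(hit), replace = TRUE),
          variant_class = sample(.VARIANT_CLASSES, length(hit),
                                 replace = TRUE))
      }
    }
    pwGenes <- unlist(pathways, use.names = FALSE)
    otherGenes <- setdiff(.geneIds(sc), pwGenes)
    silentIn <- patients[runif(length(patients)) < 0.2]
    if (length(silentIn)) {
      rows[["silent"]] <- data.frame(
        patient_id = silentIn,
        gene_symbol = sample(pwGenes, length(silentIn), replace = TRUE),
        variant_class = "Silent")
    }
    noiseIn <- patients[runif(length(patients)) < 0.5]
    if (length(noiseIn)) {
      rows[["noise"]] <- data.frame(
        patient_id = noiseIn,
        gene_symbol = sample(otherGenes, length(noiseIn), replace = TRUE),
        variant_class = sample(.VARIANT_CLASSES, length(noiseIn),
                               replace = TRUE))
    }
    variants <- if (length(rows)) do.call(rbind, rows) else
      data.frame(patient_id = character(0), gene_symbol = character(0),
                 variant_class = character(0))
    rownames(variants) <- NULL
    list(variants = variants, truth = truth)
  })
}

#' Generate drug rank profiles with planted reverters and mimickers
#'
#' A reverter places disease-up genes in the bottom (drug-down) extreme and
#' disease-down genes in the top extreme of its ranking; a mimicker is the
#' mirror image; null drugs are uniformly random permutations. The reversal
#' strength \code{rho} selects the fraction of signature genes placed at
#' the extremes (seeded choice), interpolating between perfect placement
#' (rho = 1) and a fully random profile (rho = 0).
#'
#' @param scenario a [syntheticScenario()].
#' @param upGenes,downGenes the planted disease signature (e.g. the truth
#'   from [generateExpression()] split by sign).
#' @return list with \code{drugs} (a [DrugRankSet-class]) and \code{labels}
#'   (data.frame drug_id/role with role in reverter/mimicker/null).
#' @export
generateDrugProfiles <- function(scenario, upGenes, downGenes) {
  sc <- scenario
  genes <- .geneIds(sc)
  if (!all(c(upGenes, downGenes) %in% genes)) {
    stop("signature genes must belong to the scenario gene universe")
  }
  if (length(upGenes) + length(downGenes) > sc$nGenes) {
    stop("signature too large to place at the profile extremes")
  }
  withSeed(childSeed(sc$seed, 4L), {
    ids <- sprintf("D%03d", seq_len(sc$nDrugs))
    roles <- rep("null", sc$nDrugs)
    special <- sample(seq_len(sc$nDrugs), sc$nReverters + sc$nMimickers)
    roles[special[seq_len(sc$nReverters)]] <- "reverter"
    if (sc$nMimickers > 0) {
      roles[special[sc$nReverters + seq_len(sc$nMimickers)]] <- "mimicker"
    }
    extremeProfile <- function(topGenes, bottomGenes) {
      # genes listed first get the smallest ranks (profile top)
      nTop <- round(sc$rho * length(topGenes))
      nBot <- round(sc$rho * length(bottomGenes))
      top <- if (nTop) sample(topGenes, nTop) else character(0)
      bottom <- if (nBot) sample(bottomGenes, nBot) else character(0)
      middle <- sample(setdiff(genes, c(top, bottom)))
      ordering <- c(sample(top), middle, sample(bottom))
      structure(seq_along(ordering)[match(genes, ordering)], names = genes)
    }
    ranks <- matrix(NA_integer_, nrow = sc$nGenes, ncol = sc$nDrugs,
                    dimnames = list(genes, ids))
    for (j in seq_len(sc$nDrugs)) {
      ranks[, j] <- switch(roles[j],
        reverter = extremeProfile(downGenes, upGenes),
        mimicker = extremeProfile(upGenes, downGenes),
        null = sample.int(sc$nGenes))
    }
    list(drugs = DrugRankSet(ranks),
         labels = data.frame(drug_id = ids, role = roles))
  })
}

#' Generate a signed CDT network with planted therapeutic regulators
#'
#' Therapeutic CDTs get edges to planted DE genes whose signs oppose the
#' disease direction (activation of down-regulated genes, inhibition of
#' up-regulated ones), so their regulator z-score is strongly negative
#' under the inhibited hypothesis. Null CDTs get random-sign edges to
#' random genes.
#'
#' @param scenario a [syntheticScenario()].
#' @param upGenes,downGenes the planted disease signature.
#' @return list with \code{network} (a [SignedNetwork-class]) and
#'   \code{labels} (data.frame cdt_id/role with role therapeutic/null).
#' @export
generateNetwork <- function(scenario, upGenes, downGenes) {
  sc <- scenario
  deGenes <- c(upGenes, downGenes)
  deSign <- c(rep(1L, length(upGenes)), rep(-1L, length(downGenes)))
  withSeed(childSeed(sc$seed, 5L), {
    ids <- sprintf("CDT%03d", seq_len(sc$nCdts))
    roles <- rep("null", sc$nCdts)
    if (sc$nTherapeutic > 0) {
      roles[sample(seq_len(sc$nCdts), sc$nTherapeutic)] <- "therapeutic"
    }
    rows <- vector("list", sc$nCdts)
    for (j in seq_len(sc$nCdts)) {
      k <- min(sc$edgesPerCdt,
               if (roles[j] == "therapeutic") length(deGenes) else sc$nGenes)
      if (roles[j] == "therapeutic") {
        pick <- sample(seq_along(deGenes), k)
        targets <- deGenes[pick]
        signs <- -deSign[pick]
      } else {
        targets <- sample(.geneIds(sc), k)
        signs <- sample(c(-1L, 1L), k, replace = TRUE)
      }
      rows[[j]] <- data.frame(
        source = ids[j], target = targets, sign = signs,
        weight = runif(k, sc$weightRange[1], sc$weightRange[2]))
    }
    edges <- do.call(rbind, rows)
    list(network = SignedNetwork(edges),
         labels = data.frame(cdt_id = ids, role = roles))
  })
}

#' Generate every synthetic input for a scenario
#'
#' Runs all generators and assembles the gold standard (the planted
#' reverter drugs for the scenario's indication). A pure function of the
#' scenario, including its seed.
#'
#' @param scenario a [syntheticScenario()].
#' @return list with pathways, expression (se + truth), variants
#'   (table + truth), drugs (rank set + labels), network (edges + labels)
#'   and gold (indication -> reverter drug ids).
#' @export
generateScenarioData <- function(scenario) {
  pathways <- generatePathways(scenario)
  expression <- generateExpression(scenario)
  variants <- generateVariants(scenario, pathways)
  up <- as.character(expression$truth$gene[expression$truth$sign == 1L])
  down <- as.character(expression$truth$gene[expression$truth$sign == -1L])
  drugs <- generateDrugProfiles(scenario, up, down)
  network <- generateNetwork(scenario, up, down)
  gold <- list(drugs$labels$drug_id[drugs$labels$role == "reverter"])
  names(gold) <- scenario$cancerType
  list(scenario = scenario, pathways = pathways, expression = expression,
       variants = variants, drugs = drugs, network = network, gold = gold)
}

#' Write a generated scenario to disk in every pipeline input format
#'
#' Also writes \code{truth_*.tsv} files recording the planted DE genes,
#' cohort membership, drug roles and CDT roles.
#'
#' @param data list from [generateScenarioData()].
#' @param dir output directory (created if absent).
#' @return named list of the written file paths, invisibly.
#' @export
writeScenarioData <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  writeExpressionMatrix(data$expression$se, p("expression.tsv"),
                        p("conditions.tsv"))
  writeGmt(data$pathways, p("pathways.gmt"))
  writeVariants(data$variants$variants, p("variants.tsv"))
  writeDrugProfiles(data$drugs$drugs, p("drug_profiles.tsv"))
  writeNetwork(data$network$network, p("network.tsv"))
  writeGoldStandard(data$gold, p("gold_standard.tsv"))
  write.table(as.data.frame(data$expression$truth), p("truth_de_genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cohortTruth <- data.frame(
    pathway = rep(names(data$variants$truth),
                  lengths(data$variants$truth)),
    patient_id = unlist(data$variants$truth, use.names = FALSE))
  write.table(cohortTruth, p("truth_cohorts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data$drugs$labels, p("truth_drugs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data$network$labels, p("truth_cdts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(
    expression = p("expression.tsv"), conditions = p("conditions.tsv"),
    pathways = p("pathways.gmt"), variants = p("variants.tsv"),
    drugProfiles = p("drug_profiles.tsv"), network = p("network.tsv"),
    gold = p("gold_standard.tsv")))
}
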