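test_that("the generated scenario is a pure function of parameters and seed", {
  sc <- syntheticScenario(nGenes = 300L, nTumor = 10L, nNormal = 10L,
                          pathwaySizes = c(HR = 10L, MMR = 8L),
                          mutationProb = c(HR = 0.4, MMR = 0.3),
                          nDrugs = 20L, nReverters = 2L, nMimickers = 2L,
                          nCdts = 10L, nTherapeutic = 1L, edgesPerCdt = 5L,
                          seed = 13L)
  a <- generateScenarioData(sc)
  b <- generateScenarioData(sc)
  expect_identical(SummarizedExperiment::assay(a$expression$se),
                   SummarizedExperiment::assay(b$expression$se))
  expect_identical(a$variants, b$variants)
  expect_identical(rankMatrix(a$drugs$drugs), rankMatrix(b$drugs$drugs))
  expect_identical(as.data.frame(networkEdges(a$network$network)),
                   as.data.frame(networkEdges(b$network$network)))

  d1 <- file.path(tempdir(), "sim1"); d2 <- file.path(tempdir(), "sim2")
  writeScenarioData(a, d1)
  writeScenarioData(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
})

test_that("generated files parse back through the readers without warnings", {
  sc <- syntheticScenario(nGenes = 200L, nTumor = 6L, nNormal = 6L,
                          pathwaySizes = c(HR = 8L, BER = 6L),
                          mutationProb = c(HR = 0.5, BER = 0.5),
                          nDrugs = 8L, nReverters = 1L, nMimickers = 1L,
                          nCdts = 5L, nTherapeutic = 1L, edgesPerCdt = 4L,
                          seed = 3L)
  dat <- generateScenarioData(sc)
  dir <- file.path(tempdir(), "sim_io")
  paths <- writeScenarioData(dat, dir)
  expect_no_warning({
    se <- readExpressionMatrix(paths$expression, paths$conditions)
    pw <- readGmt(paths$pathways)
    v <- readVariants(paths$variants)
    ds <- readDrugProfiles(paths$drugProfiles)
    net <- readNetwork(paths$network)
    gold <- readGoldStandard(paths$gold)
  })
  expect_identical(rankMatrix(ds), rankMatrix(dat$drugs$drugs))
  expect_equal(pw, dat$pathways)
  expect_equal(sum(se$condition == "tumor"), 6L)
})

test_that("planted cohort membership is recovered exactly by stratification", {
  for (seed in c(2L, 17L, 91L)) {
    sc <- syntheticScenario(seed = seed)
    pw <- generatePathways(sc)
    gv <- generateVariants(sc, pw)
    cohorts <- stratifyPatients(gv$variants, pw)
    expect_identical(lapply(cohorts, as.character),
                     lapply(gv$truth, as.character))
  }
  # degenerate probabilities
  sc0 <- syntheticScenario(mutationProb = c(HR = 0, BER = 0, MMR = 0,
                                            NER = 0, NHEJ = 0), seed = 1L)
  gv0 <- generateVariants(sc0, generatePathways(sc0))
  expect_true(all(lengths(gv0$truth) == 0))
  sc1 <- syntheticScenario(mutationProb = c(HR = 1, BER = 0, MMR = 0,
                                            NER = 0, NHEJ = 0), seed = 1L)
  gv1 <- generateVariants(sc1, generatePathways(sc1))
  expect_equal(gv1$truth$HR, sprintf("P%03d", 1:40))
})

test_that("a global-null scenario yields an empty truth table and few discoveries", {
  sc <- syntheticScenario(delta = 0, seed = 8L)
  gx <- generateExpression(sc)
  expect_equal(nrow(gx$truth), 0L)
  de <- moderatedTTest(gx$se)
  q <- bhAdjust(de$p)
  expect_lte(sum(q < 0.05), 3L)  # false positives only
})

test_that("planted drug roles shape the connectivity scores as designed", {
  sc <- syntheticScenario(nDrugs = 210L, nReverters = 5L, nMimickers = 5L,
                          seed = 21L)
  gx <- generateExpression(sc)
  up <- as.character(gx$truth$gene[gx$truth$sign == 1L])
  down <- as.character(gx$truth$gene[gx$truth$sign == -1L])
  gd <- generateDrugProfiles(sc, up, down)
  sig <- makeSignature(up, down)
  sc_tbl <- normalizeScores(connectivityScores(sig, gd$drugs))
  roles <- gd$labels$role[match(sc_tbl$drug_id, gd$labels$drug_id)]

  # rho = 1 reverters sit at the collection minimum and attain norm -1
  expect_equal(min(sc_tbl$raw_score), min(sc_tbl$raw_score[roles == "reverter"]))
  expect_equal(sort(sc_tbl$norm_score[roles == "reverter"])[1], -1)
  expect_true(all(sc_tbl$raw_score[roles == "reverter"] < -1.5))
  expect_true(all(sc_tbl$raw_score[roles == "mimicker"] > 1.5))

  # null drugs center near zero: |mean| < 0.1 over 200 nulls
  expect_lt(abs(mean(sc_tbl$norm_score[roles == "null"])), 0.1)

  # rho = 0 collapses a "reverter" to a random profile
  sc0 <- syntheticScenario(rho = 0, seed = 21L)
  gd0 <- generateDrugProfiles(sc0, up, down)
  tbl0 <- connectivityScores(sig, gd0$drugs)
  roles0 <- gd0$labels$role[match(tbl0$drug_id, gd0$labels$drug_id)]
  expect_true(all(abs(tbl0$raw_score[roles0 == "reverter"]) < 1))

  # a signature too large for the extremes errors out
  scTiny <- syntheticScenario(nGenes = 10L, pathwaySizes = c(HR = 2L),
                              mutationProb = c(HR = 0.5), seed = 1L)
  expect_error(
    generateDrugProfiles(scTiny, sprintf("G%04d", 1:6), sprintf("G%04d", 5:10)),
    "too large")
})

test_that("planted network roles drive the regulator z-scores", {
  sc <- syntheticScenario(nCdts = 500L, nTherapeutic = 4L, edgesPerCdt = 10L,
                          seed = 33L)
  gx <- generateExpression(sc)
  up <- as.character(gx$truth$gene[gx$truth$sign == 1L])
  down <- as.character(gx$truth$gene[gx$truth$sign == -1L])
  gn <- generateNetwork(sc, up, down)
  sig <- makeSignature(up, down)
  thera <- gn$labels$cdt_id[gn$labels$role == "therapeutic"]
  zThera <- vapply(thera, function(cdt) {
    regulatorZscore(cdt, gn$network, sig)
  }, numeric(1))
  # 10 unit-weight edges, all opposing the disease sign: z = -sqrt(10)
  expect_equal(unname(zThera), rep(-sqrt(10), 4))

  nulls <- gn$labels$cdt_id[gn$labels$role == "null"]
  zNull <- vapply(nulls, function(cdt) {
    regulatorZscore(cdt, gn$network, sig)
  }, numeric(1))
  zNull <- zNull[!is.na(zNull)]
  expect_gt(length(zNull), 100)
  expect_lt(abs(mean(zNull)), 0.2)

  # the gold standard passes through exactly the planted reverters
  dat <- generateScenarioData(syntheticScenario(seed = 5L))
  expect_identical(dat$gold[[dat$scenario$cancerType]],
                   dat$drugs$labels$drug_id[dat$drugs$labels$role == "reverter"])
})
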