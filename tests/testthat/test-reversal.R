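rankVec <- function(n) structure(seq_len(n), names = sprintf("g%d", seq_len(n)))

test_that("KS statistic matches hand-enumerated maxima and the brute-force oracle", {
  r10 <- rankVec(10)
  expect_equal(ksStatistic("g1", r10), 0.9)    # a = 1 - 0.1
  expect_equal(ksStatistic("g10", r10), -1.0)  # b = 1.0 wins
  expect_equal(ksStatistic(c("g1", "g2"), r10), 0.8)

  expect_error(ksStatistic(character(0), r10), "empty")
  expect_error(ksStatistic("gX", r10), "gX")

  set.seed(19)
  for (i in 1:300) {
    n <- sample(5:50, 1)
    t <- sample(seq_len(n - 1), 1)
    pos <- sample.int(n, t)
    r <- rankVec(n)
    expect_identical(ksStatistic(names(r)[pos], r), oracleKs(pos, n))
  }
})

test_that("connectivity scores compose the KS components with the same-sign rule", {
  # up gene at the bottom, down gene at the top: strong reverter, raw -1.9
  ds <- makeDrugSet(list(rev = sprintf("g%d", c(2, 3, 4, 5, 6, 7, 8, 9, 10, 1)),
                         mim = sprintf("g%d", c(10, 2, 3, 4, 5, 6, 7, 8, 9, 1))))
  # 'rev' ranks: g2..g10 at 1..9, g10 at rank 9, g1 at rank 10
  sig <- makeSignature(upGenes = "g1", downGenes = "g2")
  sc <- connectivityScores(sig, ds)
  i <- which(sc$drug_id == "rev")
  expect_equal(sc$ks_up[i], -1.0)
  expect_equal(sc$ks_down[i], 0.9)
  expect_equal(sc$raw_score[i], -1.9)

  # perfect mimicker: up gene on top, down gene at bottom -> raw > 0
  sigM <- makeSignature(upGenes = "g10", downGenes = "g1")
  scM <- connectivityScores(sigM, ds)
  expect_gt(scM$raw_score[scM$drug_id == "mim"], 0)

  # same-sign components zero out
  ds2 <- makeDrugSet(list(d = sprintf("g%d", c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10))))
  sig2 <- makeSignature(upGenes = "g1", downGenes = "g2")
  sc2 <- connectivityScores(sig2, ds2)  # both sets near the top: same sign
  expect_equal(sign(sc2$ks_up), sign(sc2$ks_down))
  expect_equal(sc2$raw_score, 0)

  # empty intersection with the universe: warned, nothing scored
  sigX <- makeSignature(upGenes = "zz", downGenes = "g2")
  expect_warning(scX <- connectivityScores(sigX, ds), "empty intersection")
  expect_equal(nrow(scX), 0L)
})

test_that("profile reversal maps reverters to mimickers antisymmetrically", {
  n <- 200
  genes <- sprintf("g%d", 1:n)
  # planted strong reverter: flipping its profile yields a strong mimicker
  up <- genes[1:8]; down <- genes[9:16]
  ord <- c(down, setdiff(genes, c(up, down)), up)
  ranks <- structure(match(genes, ord), names = genes)
  flipped <- structure(n + 1L - ranks, names = genes)
  rawRev <- ksStatistic(up, ranks) - ksStatistic(down, ranks)
  rawMim <- ksStatistic(up, flipped) - ksStatistic(down, flipped)
  expect_lt(rawRev, -1.5)
  expect_gt(rawMim, 1.5)
  expect_lt(abs(rawMim + rawRev), 4 / n)  # equal sizes: 1/n discretization

  # random profiles, away from the same-sign zero boundary
  set.seed(5)
  checked <- 0
  for (i in 1:60) {
    ord <- sample(genes)
    ranks <- structure(match(genes, ord), names = genes)
    flipped <- structure(n + 1L - ranks, names = genes)
    up <- sample(genes, 10)
    down <- sample(setdiff(genes, up), 10)
    ku <- ksStatistic(up, ranks); kd <- ksStatistic(down, ranks)
    kuF <- ksStatistic(up, flipped); kdF <- ksStatistic(down, flipped)
    raw <- if (sign(ku) == sign(kd)) 0 else ku - kd
    rawF <- if (sign(kuF) == sign(kdF)) 0 else kuF - kdF
    if (raw != 0 && rawF != 0) {
      expect_lt(abs(rawF + raw), 4 / n)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 10)
})

test_that("normalization lands scores on the [-1, +1] collection scale", {
  tbl <- S4Vectors::DataFrame(drug_id = c("a", "b", "c"),
                              ks_up = 0, ks_down = 0,
                              raw_score = c(-1.9, 0.95, 0))
  expect_equal(normalizeScores(tbl)$norm_score, c(-1, 0.5, 0))
  tbl$raw_score <- c(0, 0, 0)
  expect_equal(normalizeScores(tbl)$norm_score, c(0, 0, 0))
  tbl <- tbl[1, ]; tbl$raw_score <- -0.4
  expect_equal(normalizeScores(tbl)$norm_score, -1)
})

test_that("permutation p-values are deterministic, smoothed, and flag planted reverters", {
  set.seed(23)
  n <- 200
  genes <- sprintf("g%d", 1:n)
  up <- genes[1:10]; down <- genes[11:20]
  sig <- makeSignature(up, down)
  # planted: down genes at the very top, up genes at the very bottom
  orderings <- c(
    list(planted = c(down, setdiff(genes, c(up, down)), up)),
    lapply(1:50, function(i) sample(genes)))
  names(orderings) <- c("planted", sprintf("null%02d", 1:50))
  ds <- makeDrugSet(orderings)
  sc <- scoreDrugs(sig, ds, nPerm = 1000, seed = 77)
  expect_lte(sc$p[sc$drug_id == "planted"], 0.002)
  expect_equal(min(sc$p), 1 / 1001)  # add-one smoothing floor

  # raw score exactly 0 gives p = 1 by construction
  expect_true(all(sc$p[sc$raw_score == 0] == 1))

  sc2 <- scoreDrugs(sig, ds, nPerm = 1000, seed = 77)
  expect_identical(sc$p, sc2$p)

  expect_error(permutationPvalues(sc, ds, nPerm = 0), "positive")
})

test_that("compiled permutation null matches the R reference distribution", {
  set.seed(1)
  nullsCpp <- repurposeDR:::.ksNullRaw(8L, 6L, 100L, 2000L)
  set.seed(2)
  nullsR <- referenceNullRaw(8, 6, 100, 2000)
  expect_true(all(abs(nullsCpp) <= 2))
  expect_gt(suppressWarnings(ks.test(nullsCpp, nullsR)$p.value), 0.01)
  expect_equal(mean(nullsCpp == 0), mean(nullsR == 0), tolerance = 0.1)
})

test_that("drug ranking filters on q and orders ascending with lexicographic ties", {
  tbl <- S4Vectors::DataFrame(
    drug_id = c("A", "B", "C"),
    ks_up = 0, ks_down = 0, raw_score = c(-0.9, 0.2, -0.5),
    norm_score = c(-0.9, 0.2, -0.5),
    p = c(0.001, 0.001, 0.1), q = c(0.01, 0.01, 0.2))
  rk <- rankDrugs(tbl, alphaQ = 0.05)
  expect_equal(rk$drug_id, c("A", "B"))
  expect_equal(rk$rank, 1:2)

  tie <- tbl; tie$norm_score <- c(-0.5, -0.5, 0); tie$q <- 0.01
  expect_equal(rankDrugs(tie)$drug_id, c("A", "B", "C"))

  high <- tbl; high$q <- 0.5
  expect_warning(empty <- rankDrugs(high), "no drug")
  expect_equal(nrow(empty), 0L)
})
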