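test_that("log2 transform applies the declared pseudocount and rejects negatives", {
  mat <- matrix(c(0, 7, 3, 1), nrow = 2,
                dimnames = list(c("g1", "g2"), c("S1", "S2")))
  se <- makeSE(mat, c("tumor", "normal"))
  out <- SummarizedExperiment::assay(log2Transform(se, pseudocount = 1))
  expect_equal(out["g1", "S1"], 0)
  expect_equal(out["g2", "S1"], 3)   # log2(7 + 1)

  mat["g1", "S2"] <- -1
  expect_error(log2Transform(makeSE(mat, c("tumor", "normal"))),
               "gene 'g1', sample 'S2'")
})

test_that("variance prior fit takes the infinite-d0 branch for zero dispersion and drops zero variances", {
  fit <- fitVariancePrior(rep(0.25, 50), df = 10)
  expect_equal(fit$d0, Inf)
  expect_equal(fit$s0Sq, 0.25)

  expect_warning(fit2 <- fitVariancePrior(c(0, rexp(100) + 0.1), df = 10),
                 "excluded")
  expect_true(fit2$s0Sq > 0)

  expect_error(suppressWarnings(fitVariancePrior(c(0, 0.5), df = 10)),
               ">= 2")
})

test_that("variance prior fit recovers simulated hyperparameters and matches limma's fit", {
  d0 <- 4; s0 <- 0.05; df <- 78
  set.seed(42)
  sigma2 <- d0 * s0 / rchisq(1000, df = d0)
  s2 <- sigma2 * rchisq(1000, df = df) / df
  fit <- fitVariancePrior(s2, df = df)
  expect_lt(abs(fit$d0 - d0) / d0, 0.5)
  expect_lt(abs(fit$s0Sq - s0) / s0, 0.2)

  lf <- limma::fitFDist(s2, df1 = df)
  expect_equal(fit$d0, lf$df2, tolerance = 0.1)
  expect_equal(fit$s0Sq, lf$scale, tolerance = 0.05)
})

test_that("moderated t matches a direct formula transcription and its limit cases", {
  set.seed(7)
  mat <- matrix(rnorm(12), nrow = 2,
                dimnames = list(c("g1", "g2"), paste0("S", 1:6)))
  cond <- rep(c("tumor", "normal"), each = 3)
  se <- makeSE(mat, cond)

  # hand-supplied prior vs scalar oracle, to 1e-10
  de <- moderatedTTest(se, prior = list(d0 = 4, s0Sq = 0.05))
  for (g in c("g1", "g2")) {
    o <- oracleModT(mat[g, cond == "tumor"], mat[g, cond == "normal"],
                    d0 = 4, s0sq = 0.05)
    i <- which(de$gene == g)
    expect_equal(de$log2fc[i], o$lfc, tolerance = 1e-10)
    expect_equal(de$t[i], o$t, tolerance = 1e-10)
    expect_equal(de$p[i], o$p, tolerance = 1e-10)
  }

  # d0 = 0 reduces to the ordinary pooled two-sample t
  de0 <- moderatedTTest(se, prior = list(d0 = 0, s0Sq = 1))
  tt <- t.test(mat["g1", cond == "tumor"], mat["g1", cond == "normal"],
               var.equal = TRUE)
  expect_equal(de0$t[de0$gene == "g1"], unname(tt$statistic),
               tolerance = 1e-12)
  expect_equal(de0$p[de0$gene == "g1"], tt$p.value, tolerance = 1e-12)

  # d0 -> infinity: denominator variance tends to s0Sq
  deBig <- moderatedTTest(se, prior = list(d0 = 1e12, s0Sq = 0.05))
  deInf <- moderatedTTest(se, prior = list(d0 = Inf, s0Sq = 0.05))
  expect_equal(deBig$t, deInf$t, tolerance = 1e-6)

  # identical group means: t = 0, p = 1
  matEq <- matrix(c(1, 2, 3, 1, 2, 3), nrow = 1,
                  dimnames = list("g1", paste0("S", 1:6)))
  deEq <- moderatedTTest(makeSE(matEq, cond), prior = list(d0 = 4, s0Sq = 0.05))
  expect_equal(deEq$t, 0)
  expect_equal(deEq$p, 1)

  expect_error(moderatedTTest(makeSE(mat[, 1:3], c("tumor", "tumor", "normal"))),
               ">= 2 samples")
})

test_that("moderated t agrees with limma given the same prior", {
  set.seed(11)
  mat <- matrix(rnorm(100 * 12, sd = 0.5), nrow = 100,
                dimnames = list(sprintf("g%03d", 1:100), paste0("S", 1:12)))
  cond <- rep(c("tumor", "normal"), each = 6)
  mat[1:10, cond == "tumor"] <- mat[1:10, cond == "tumor"] + 2
  design <- cbind(Intercept = 1, tumor = as.integer(cond == "tumor"))
  eb <- limma::eBayes(limma::lmFit(mat, design))
  de <- moderatedTTest(makeSE(mat, cond),
                       prior = list(d0 = eb$df.prior, s0Sq = eb$s2.prior))
  expect_equal(de$t, unname(eb$t[, "tumor"]), tolerance = 1e-8)
  expect_equal(de$p, unname(eb$p.value[, "tumor"]), tolerance = 1e-8)
  expect_equal(de$log2fc, unname(eb$coefficients[, "tumor"]),
               tolerance = 1e-10)

  # the package's own prior estimate is close to limma's empirical Bayes fit
  fit <- fitVariancePrior(unname(eb$sigma)^2, df = 10)
  expect_equal(fit$d0, eb$df.prior, tolerance = 0.05)
  expect_equal(fit$s0Sq, eb$s2.prior, tolerance = 0.05)
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bhAdjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bhAdjust(0.37), 0.37)            # m = 1
  expect_equal(bhAdjust(rep(0.05, 10)), rep(0.05, 10))

  set.seed(3)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(bhAdjust(p), oracleBH(p))
  }

  # permutation invariance up to order restoration; q >= p always
  p <- runif(25)
  perm <- sample(25)
  expect_equal(bhAdjust(p)[perm], bhAdjust(p[perm]))
  expect_true(all(bhAdjust(p) >= p))

  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("signature construction applies the q and fold-change gates", {
  de <- S4Vectors::DataFrame(
    gene = c("a", "b", "c", "d"),
    log2fc = c(1.2, 0.4, -2.0, -1.5),
    t = c(8, 3, -2, -9),
    p = c(1e-6, 1e-6, 0.15, 1e-7))
  # q-values: BH of (1e-6, 1e-6, 0.15, 1e-7) keeps a,b,d significant
  sig <- buildSignature(de, alphaQ = 0.05, minAbsLfc = 0.6)
  dirs <- geneDirections(sig)
  expect_equal(unname(dirs[c("a", "b", "c", "d")]), c(1L, 0L, 0L, -1L))
  expect_length(intersect(upSet(sig), downSet(sig)), 0)

  sig2 <- buildSignature(de, alphaQ = 0.05, minAbsLfc = 0)
  expect_equal(unname(geneDirections(sig2)["c"]), 0L)  # fails the q gate

  deNull <- S4Vectors::DataFrame(gene = "a", log2fc = 0.1, t = 0.5, p = 0.8)
  expect_error(buildSignature(deNull), "empty signature")
})
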