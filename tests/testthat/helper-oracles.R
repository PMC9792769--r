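# Independent oracles: plain-loop transcriptions of the defining formulas,
# kept deliberately separate from the package implementation paths.

# KS enrichment: enumerate both maxima directly over the sorted positions.
oracleKs <- function(pos, n) {
  pos <- sort(pos)
  t <- length(pos)
  a <- -Inf
  b <- -Inf
  for (j in seq_len(t)) {
    a <- max(a, j / t - pos[j] / n)
    b <- max(b, pos[j] / n - (j - 1) / t)
  }
  if (a > b) a else -b
}

# Benjamini-Hochberg step-up, written as the literal procedure: sort
# ascending, multiply p_(i) by m/i, enforce monotonicity from the largest
# rank down, cap at 1, restore input order.
oracleBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) {
    if (m == 1) break
    adj[i] <- min(adj[i], adj[i + 1])
  }
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Moderated t per gene, scalar transcription of the posterior-variance and
# t formulas.
oracleModT <- function(tumor, normal, d0, s0sq) {
  nT <- length(tumor)
  nN <- length(normal)
  lfc <- mean(tumor) - mean(normal)
  df <- nT + nN - 2
  s2 <- (sum((tumor - mean(tumor))^2) + sum((normal - mean(normal))^2)) / df
  s2post <- if (is.infinite(d0)) s0sq else if (d0 == 0) s2 else
    (d0 * s0sq + df * s2) / (d0 + df)
  tstat <- lfc / sqrt(s2post * (1 / nT + 1 / nN))
  p <- if (is.infinite(d0)) 2 * pnorm(-abs(tstat)) else
    2 * pt(-abs(tstat), df = d0 + df)
  list(lfc = lfc, t = tstat, p = p)
}

# Regulator z-score: literal sum over edges.
oracleZ <- function(w, se, sg) {
  num <- 0
  den <- 0
  for (i in seq_along(w)) {
    num <- num + w[i] * se[i] * sg[i]
    den <- den + w[i]^2
  }
  num / sqrt(den)
}

# R-only reference for one permutation-null draw of the raw connectivity
# score (random disjoint up/down sets composed through ksStatistic).
referenceNullRaw <- function(tUp, tDown, n, nPerm) {
  genes <- sprintf("g%d", seq_len(n))
  vapply(seq_len(nPerm), function(b) {
    pick <- sample.int(n, tUp + tDown)
    ranks <- structure(seq_len(n), names = genes)
    ku <- ksStatistic(genes[pick[seq_len(tUp)]], ranks)
    kd <- ksStatistic(genes[pick[tUp + seq_len(tDown)]], ranks)
    if (sign(ku) == sign(kd)) 0 else ku - kd
  }, numeric(1))
}

childSeedForTest <- function(s) 10000L + s

readTsvFixture <- function(path) {
  read.delim(path, sep = "\t", comment.char = "#", check.names = FALSE,
             stringsAsFactors = FALSE)
}

# Small fixtures -------------------------------------------------------------

# expression SummarizedExperiment with explicit values
makeSE <- function(mat, condition) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = mat),
    colData = S4Vectors::DataFrame(condition = condition,
                                   row.names = colnames(mat)))
  se
}

# a signature with hand-set directions (q/lfc chosen to satisfy them)
makeSignature <- function(upGenes, downGenes, otherGenes = character(0)) {
  genes <- c(upGenes, downGenes, otherGenes)
  dirs <- c(rep(1L, length(upGenes)), rep(-1L, length(downGenes)),
            rep(0L, length(otherGenes)))
  GeneSignature(
    S4Vectors::DataFrame(
      gene = genes,
      log2fc = ifelse(dirs == 0L, 0, 2 * dirs),
      t = 5 * dirs, p = ifelse(dirs == 0L, 0.9, 1e-4),
      q = ifelse(dirs == 0L, 0.9, 1e-3),
      direction = dirs),
    alphaQ = 0.05, minAbsLfc = 0, cohort = "fixture")
}

# a DrugRankSet from a named list drug -> ordering of genes (first = rank 1)
makeDrugSet <- function(orderings) {
  genes <- sort(orderings[[1L]])
  ranks <- vapply(orderings, function(ord) {
    stopifnot(setequal(ord, genes))
    structure(match(genes, ord), names = genes)
  }, integer(length(genes)))
  rownames(ranks) <- genes
  DrugRankSet(ranks)
}

makeNetwork <- function(source, target, sign, weight = NULL) {
  if (is.null(weight)) weight <- rep(1, length(source))
  SignedNetwork(data.frame(source = source, target = target, sign = sign,
                           weight = weight))
}
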