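## Per-cohort differential expression: empirical-Bayes moderated t-statistic
## with Benjamini-Hochberg FDR, producing signed disease signatures.

#' Log2-transform a raw expression matrix
#'
#' Replaces every value x by log2(x + pseudocount). The caller declares
#' whether the input is raw: the transform is never applied implicitly and
#' idempotence is not assumed.
#'
#' @param se SummarizedExperiment with non-negative raw intensities.
#' @param pseudocount non-negative offset added before the log (default 1).
#' @return the SummarizedExperiment with its assay transformed.
#' @export
log2Transform <- function(se, pseudocount = 1) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      is.na(pseudocount) || pseudocount < 0) {
    stop("pseudocount must be a single non-negative value")
  }
  mat <- SummarizedExperiment::assay(se)
  if (any(mat < 0)) {
    bad <- which(mat < 0, arr.ind = TRUE)
    stop(sprintf("negative expression value at gene '%s', sample '%s'",
                 rownames(mat)[bad[1L, 1L]], colnames(mat)[bad[1L, 2L]]))
  }
  SummarizedExperiment::assay(se) <- log2(mat + pseudocount)
  se
}

# Invert the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf)); used by the method-of-moments prior fit.
trigammaInverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Fit the empirical-Bayes variance prior (d0, s0^2)
#'
#' Assumes gene-wise residual variances follow a scaled inverse-chi-square
#' prior with d0 degrees of freedom and scale s0^2, so that log sample
#' variances have moments expressible through digamma/trigamma functions.
#' Method-of-moments on the log variances: solve
#' trigamma(d0/2) = var(log s^2) - trigamma(df/2) for d0, then match the
#' mean. When the trigamma equation has no positive solution (observed
#' dispersion no larger than sampling noise), d0 is infinite and s0^2 is the
#' mean variance.
#'
#' @param variances per-gene residual variances (positive; zero-variance
#'   genes are excluded with a warning).
#' @param df residual degrees of freedom each variance was estimated with.
#' @return list with elements \code{d0} and \code{s0Sq}.
#' @export
fitVariancePrior <- function(variances, df) {
  if (!is.numeric(df) || length(df) != 1L || df <= 0) {
    stop("df must be a single positive number")
  }
  ok <- is.finite(variances) & variances > 0
  if (any(!ok)) {
    warning(sprintf("%d gene(s) with non-positive variance excluded from prior fit",
                    sum(!ok)))
  }
  v <- variances[ok]
  if (length(v) < 2L) {
    stop("need >= 2 positive variances to estimate the prior")
  }
  z <- log(v)
  vz <- var(z)
  target <- vz - trigamma(df / 2)
  if (!is.finite(target) || target <= 0) {
    return(list(d0 = Inf, s0Sq = mean(v)))
  }
  halfD0 <- trigammaInverse(target)
  d0 <- 2 * halfD0
  s0Sq <- exp(mean(z) - digamma(df / 2) + log(df / 2) +
                digamma(halfD0) - log(halfD0))
  list(d0 = d0, s0Sq = s0Sq)
}

#' Moderated two-sample t-test (tumor vs normal)
#'
#' For each gene: log2FC = mean(tumor) - mean(normal); pooled variance s_g^2
#' on d_g = n_T + n_N - 2 degrees of freedom; posterior variance
#' (d0*s0^2 + d_g*s_g^2) / (d0 + d_g); moderated t = log2FC /
#' (s_post * sqrt(1/n_T + 1/n_N)); two-sided p from a t distribution with
#' d0 + d_g degrees of freedom (standard normal when d0 is infinite).
#' With d0 = 0 the statistic is the ordinary pooled two-sample t.
#'
#' @param se SummarizedExperiment with log2 expression and a
#'   \code{condition} column in colData (\code{tumor}/\code{normal}, at
#'   least 2 samples each).
#' @param prior \code{"estimate"} (fit via [fitVariancePrior()]) or a list
#'   with elements \code{d0} and \code{s0Sq}.
#' @return \link[S4Vectors]{DataFrame} with columns gene, log2fc, t, p and
#'   metadata fields \code{prior}, \code{dfResidual}, \code{nTumor},
#'   \code{nNormal}.
#' @export
moderatedTTest <- function(se, prior = "estimate") {
  cond <- as.character(se$condition)
  nT <- sum(cond == "tumor")
  nN <- sum(cond == "normal")
  if (nT < 2L || nN < 2L) {
    stop(sprintf("need >= 2 samples per condition (got %d tumor, %d normal)",
                 nT, nN))
  }
  mat <- SummarizedExperiment::assay(se)
  tum <- mat[, cond == "tumor", drop = FALSE]
  nor <- mat[, cond == "normal", drop = FALSE]
  mT <- rowMeans(tum)
  mN <- rowMeans(nor)
  lfc <- mT - mN
  df <- nT + nN - 2
  s2 <- (rowSums((tum - mT)^2) + rowSums((nor - mN)^2)) / df

  if (identical(prior, "estimate")) {
    prior <- fitVariancePrior(s2, df)
  }
  d0 <- prior$d0
  s0Sq <- prior$s0Sq
  s2post <- if (is.infinite(d0)) {
    rep(s0Sq, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * s0Sq + df * s2) / (d0 + df)
  }
  tstat <- lfc / sqrt(s2post * (1 / nT + 1 / nN))
  bad <- !is.finite(tstat)
  if (any(bad)) {
    warning(sprintf("%d gene(s) with undefined statistic (zero variance and zero prior) reported as missing",
                    sum(bad)))
    tstat[bad] <- NA_real_
  }
  dfTotal <- d0 + df
  p <- if (is.infinite(dfTotal)) 2 * pnorm(-abs(tstat)) else
    2 * pt(-abs(tstat), df = dfTotal)
  out <- S4Vectors::DataFrame(gene = rownames(mat), log2fc = unname(lfc),
                              t = unname(tstat), p = unname(p))
  S4Vectors::metadata(out) <- list(prior = list(d0 = d0, s0Sq = s0Sq),
                                   dfResidual = df, nTumor = nT, nNormal = nN)
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values in the original input order (delegates to
#' \code{p.adjust(method = "BH")} after validating the domain).
#'
#' @param pValues numeric vector of p-values in [0, 1].
#' @return q-values, same length and order.
#' @export
bhAdjust <- function(pValues) {
  if (any(!is.finite(pValues)) || any(pValues < 0) || any(pValues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pValues, method = "BH")
}

#' Build a signed signature from a differential-expression result
#'
#' Applies FDR and fold-change gates: s(g) = +1 iff q < alphaQ and
#' log2FC >= +minAbsLfc; -1 iff q < alphaQ and log2FC <= -minAbsLfc;
#' 0 otherwise. Defaults (alphaQ = 0.05, minAbsLfc = 0) match the main
#' pipeline; minAbsLfc = 0.6 mirrors the stricter cell-line setting.
#'
#' @param deResult DataFrame from [moderatedTTest()] (columns gene, log2fc,
#'   t, p).
#' @param alphaQ FDR threshold.
#' @param minAbsLfc minimum absolute log2 fold-change.
#' @param cohort label stored on the signature.
#' @return a [GeneSignature-class] object.
#' @export
buildSignature <- function(deResult, alphaQ = 0.05, minAbsLfc = 0,
                           cohort = NA_character_) {
  stopIfNotScalarProb(alphaQ, "alphaQ", openUpper = FALSE)
  pFilled <- ifelse(is.na(deResult$p), 1, deResult$p)
  q <- bhAdjust(pFilled)
  q[is.na(deResult$p)] <- NA_real_
  direction <- callDirections(deResult$log2fc, q, alphaQ, minAbsLfc)
  if (!any(direction != 0L)) {
    stop("empty signature: no gene passes the q and fold-change thresholds")
  }
  GeneSignature(
    S4Vectors::DataFrame(gene = as.character(deResult$gene),
                         log2fc = deResult$log2fc, t = deResult$t,
                         p = deResult$p, q = q, direction = direction),
    alphaQ = alphaQ, minAbsLfc = minAbsLfc, cohort = cohort)
}
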