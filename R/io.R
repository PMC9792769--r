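## Readers and writers for every external file format the pipeline touches.
## All parsers validate strictly: a file violating a type invariant is an
## error, never silently coerced. Comment lines starting with '#' are
## provenance and are skipped on read.

#' Read a log2 expression matrix with a sample condition map
#'
#' The expression file is a TSV with a header row of sample identifiers and
#' gene symbols in the first column. The condition map is a two-column TSV
#' (\code{sample_id}, \code{condition}) with condition in
#' \{\code{tumor}, \code{normal}\}. Values are taken as already on the log2
#' scale; use [log2Transform()] if the input is raw intensities.
#'
#' @param path expression TSV path.
#' @param conditionPath condition-map TSV path.
#' @param cancerType free-text label stored in the object metadata.
#' @return a \link[SummarizedExperiment]{SummarizedExperiment} with assay
#'   \code{exprs}, per-sample \code{condition} in \code{colData}, and
#'   \code{cancerType} in \code{metadata}.
#' @export
readExpressionMatrix <- function(path, conditionPath,
                                 cancerType = NA_character_) {
  raw <- readTsv(path)
  if (ncol(raw) < 2L) stop("expression matrix needs >= 1 sample column")
  genes <- as.character(raw[[1L]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup)) {
    stop(sprintf("duplicate gene symbol(s) in expression matrix: %s",
                 paste(dup, collapse = ", ")))
  }
  sampleIds <- colnames(raw)[-1L]
  if (anyDuplicated(sampleIds)) {
    stop("duplicate sample identifiers in expression matrix header")
  }
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(raw[, -1L, drop = FALSE], 2L,
                                              as.numeric))) &
                 !is.na(as.matrix(raw[, -1L, drop = FALSE])),
                 arr.ind = TRUE)
    coord <- if (nrow(bad)) {
      sprintf(" (first at gene '%s', sample '%s')",
              genes[bad[1L, 1L]], sampleIds[bad[1L, 2L]])
    } else ""
    stop(sprintf("non-numeric expression value%s", coord))
  }
  if (any(!is.finite(mat))) {
    bad <- which(!is.finite(mat), arr.ind = TRUE)
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 genes[bad[1L, 1L]], sampleIds[bad[1L, 2L]]))
  }
  rownames(mat) <- genes
  colnames(mat) <- sampleIds

  cmap <- readTsv(conditionPath)
  if (ncol(cmap) < 2L) stop("condition map needs columns sample_id, condition")
  condLookup <- structure(as.character(cmap[[2L]]),
                          names = as.character(cmap[[1L]]))
  missing <- setdiff(sampleIds, names(condLookup))
  if (length(missing)) {
    stop(sprintf("sample(s) missing from condition map: %s",
                 paste(missing, collapse = ", ")))
  }
  condition <- unname(condLookup[sampleIds])
  bad <- setdiff(unique(condition), c("tumor", "normal"))
  if (length(bad)) {
    stop(sprintf("condition labels must be 'tumor' or 'normal'; found: %s",
                 paste(bad, collapse = ", ")))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = mat),
    colData = S4Vectors::DataFrame(condition = condition, row.names = sampleIds))
  S4Vectors::metadata(se)$cancerType <- cancerType
  se
}

#' Write an expression matrix and its condition map
#'
#' @param se SummarizedExperiment as returned by [readExpressionMatrix()].
#' @param path,conditionPath output TSV paths.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(se, path, conditionPath) {
  mat <- SummarizedExperiment::assay(se)
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cmap <- data.frame(sample_id = colnames(se),
                     condition = as.character(se$condition))
  write.table(cmap, conditionPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read pathway gene sets from a GMT file
#'
#' Standard GMT: each line is \code{name<TAB>description<TAB>gene1<TAB>...}.
#' The description field is discarded; repeated genes within a line are kept
#' once.
#'
#' @param path GMT file path.
#' @return named list of character vectors (one gene set per line).
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    genes <- unique(fields[-(1:2)][nzchar(fields[-(1:2)])])
    if (length(fields) < 3L || !length(genes)) {
      stop(sprintf("GMT line %d has no genes (need name, description, >=1 gene)",
                   i))
    }
    nm <- fields[[1L]]
    if (nm %in% names(out)) {
      stop(sprintf("duplicate pathway name '%s' at GMT line %d", nm, i))
    }
    out[[nm]] <- genes
  }
  out
}

#' Write pathway gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a MAF-lite somatic variant table
#'
#' TSV with columns \code{patient_id}, \code{gene_symbol},
#' \code{variant_class}. Duplicate (patient, gene) records are permitted.
#'
#' @param path variant TSV path.
#' @return data.frame with those three character columns.
#' @export
readVariants <- function(path) {
  df <- readTsv(path)
  need <- c("patient_id", "gene_symbol", "variant_class")
  if (!all(need %in% colnames(df))) {
    stop(sprintf("variant table must have columns: %s",
                 paste(need, collapse = ", ")))
  }
  df <- df[, need]
  for (col in need) df[[col]] <- as.character(df[[col]])
  if (nrow(df) && (any(!nzchar(df$patient_id)) || any(!nzchar(df$gene_symbol)))) {
    stop("variant table has empty patient_id or gene_symbol")
  }
  df
}

#' Write a MAF-lite variant table
#' @param variants data.frame as from [readVariants()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVariants <- function(variants, path) {
  write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read drug-exposure rank profiles (long form)
#'
#' Long-form TSV with columns \code{drug_id}, \code{gene_symbol},
#' \code{rank}. Every drug must rank the identical gene universe, and each
#' drug's ranks must be a permutation of 1..n.
#'
#' @param path long-form TSV path.
#' @return a [DrugRankSet-class] object.
#' @export
readDrugProfiles <- function(path) {
  df <- readTsv(path)
  need <- c("drug_id", "gene_symbol", "rank")
  if (!all(need %in% colnames(df))) {
    stop(sprintf("drug profile table must have columns: %s",
                 paste(need, collapse = ", ")))
  }
  drugs <- unique(as.character(df$drug_id))
  universe <- sort(unique(as.character(df$gene_symbol[df$drug_id == drugs[[1L]]])))
  n <- length(universe)
  ranks <- matrix(NA_integer_, nrow = n, ncol = length(drugs),
                  dimnames = list(universe, drugs))
  for (d in drugs) {
    sub <- df[df$drug_id == d, ]
    g <- as.character(sub$gene_symbol)
    if (!setequal(g, universe) || length(g) != n) {
      stop(sprintf("drug '%s' ranks a different gene universe", d))
    }
    r <- as.integer(sub$rank)
    srt <- sort(r)
    if (!identical(srt, seq_len(n))) {
      off <- srt[which(srt != seq_len(n))[1L]]
      stop(sprintf("ranks for drug '%s' are not a permutation of 1..%d (offending rank %d)",
                   d, n, off))
    }
    ranks[g, d] <- r
  }
  DrugRankSet(ranks)
}

#' Write drug rank profiles in long form
#' @param drugs a [DrugRankSet-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDrugProfiles <- function(drugs, path) {
  m <- rankMatrix(drugs)
  df <- data.frame(
    drug_id = rep(colnames(m), each = nrow(m)),
    gene_symbol = rep(rownames(m), times = ncol(m)),
    rank = as.integer(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.SIGN_TOKENS <- c("+" = 1L, "-" = -1L, "+1" = 1L, "-1" = -1L,
                  "activation" = 1L, "inhibition" = -1L)

#' Read a signed CDT-to-gene interaction network
#'
#' Edge-list TSV with columns \code{source}, \code{target}, \code{sign} and
#' optionally \code{weight} (default 1.0). Accepted sign tokens
#' (case-insensitive): \code{+}, \code{-}, \code{+1}, \code{-1},
#' \code{activation}, \code{inhibition}. Edges with weight below
#' \code{minConfidence} are dropped, mirroring a literature-confidence
#' filter.
#'
#' @param path edge-list TSV path.
#' @param minConfidence drop edges with weight strictly below this value.
#' @return a [SignedNetwork-class] object.
#' @export
readNetwork <- function(path, minConfidence = 0) {
  df <- readTsv(path)
  need <- c("source", "target", "sign")
  if (!all(need %in% colnames(df))) {
    stop("network table must have columns source, target, sign [, weight]")
  }
  tok <- tolower(trimws(as.character(df$sign)))
  unknown <- setdiff(unique(tok), names(.SIGN_TOKENS))
  if (length(unknown)) {
    stop(sprintf("unrecognized sign token(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  sign <- unname(.SIGN_TOKENS[tok])
  weight <- if ("weight" %in% colnames(df)) as.numeric(df$weight) else
    rep(1.0, nrow(df))
  if (any(!is.finite(weight)) || any(weight <= 0) || any(weight > 1)) {
    stop("edge weights must lie in (0, 1]")
  }
  keep <- weight >= minConfidence
  SignedNetwork(S4Vectors::DataFrame(
    source = as.character(df$source)[keep],
    target = as.character(df$target)[keep],
    sign = sign[keep], weight = weight[keep]))
}

#' Write a signed network as an edge-list TSV
#' @param network a [SignedNetwork-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(network, path) {
  e <- as.data.frame(networkEdges(network))
  e$sign <- ifelse(e$sign > 0, "+", "-")
  write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gold-standard drug-indication labels
#'
#' Two-column TSV (\code{indication}, \code{drug_id}); approved and
#' investigational drugs are both treated as relevant.
#'
#' @param path two-column TSV path.
#' @return named list: indication -> character vector of relevant drugs.
#' @export
readGoldStandard <- function(path) {
  df <- readTsv(path)
  if (ncol(df) < 2L) stop("gold standard needs columns indication, drug_id")
  split(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Write gold-standard drug-indication labels
#' @param gold named list: indication -> character vector of drugs.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGoldStandard <- function(gold, path) {
  df <- data.frame(
    indication = rep(names(gold), lengths(gold)),
    drug_id = unlist(gold, use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a GeneSignature as a TSV stage output
#'
#' Columns: gene, log2fc, t_mod, p, q, direction; thresholds and the cohort
#' label are stored on provenance comment lines so [readSignature()] can
#' reconstruct the object.
#'
#' @param signature a [GeneSignature-class] object.
#' @param path output path.
#' @param provenance extra comment lines (e.g. seed, parameters).
#' @return `path`, invisibly.
#' @export
writeSignature <- function(signature, path, provenance = character()) {
  th <- signatureThresholds(signature)
  st <- as.data.frame(signatureStats(signature))
  colnames(st) <- c("gene", "log2fc", "t_mod", "p", "q", "direction")
  writeResultTable(st, path, provenance = c(
    sprintf("signature alphaQ=%.17g minAbsLfc=%.17g cohort=%s",
            th$alphaQ, th$minAbsLfc, th$cohort),
    provenance))
}

#' Read a GeneSignature written by [writeSignature()]
#' @param path signature TSV path.
#' @return a [GeneSignature-class] object.
#' @export
readSignature <- function(path) {
  header <- grep("^# signature ", readLines(path, n = 10L), value = TRUE)
  if (!length(header)) stop("not a signature file: missing '# signature' header")
  fields <- strsplit(sub("^# signature ", "", header[[1L]]), " ")[[1L]]
  kv <- strsplit(fields, "=", fixed = TRUE)
  vals <- structure(vapply(kv, `[`, character(1), 2L),
                    names = vapply(kv, `[`, character(1), 1L))
  st <- readTsv(path)
  GeneSignature(
    S4Vectors::DataFrame(gene = as.character(st$gene), log2fc = st$log2fc,
                         t = st$t_mod, p = st$p, q = st$q,
                         direction = as.integer(st$direction)),
    alphaQ = as.numeric(vals[["alphaQ"]]),
    minAbsLfc = as.numeric(vals[["minAbsLfc"]]),
    cohort = vals[["cohort"]])
}
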