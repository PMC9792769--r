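#' Stratify patients into DNA-repair-deficiency cohorts
#'
#' A patient belongs to a pathway's cohort iff the variant table records at
#' least one non-excluded variant in a gene of that pathway's set. The same
#' patient may fall into multiple cohorts. Stratification is deterministic
#' and independent of record order.
#'
#' @param variants data.frame with columns patient_id, gene_symbol,
#'   variant_class (see [readVariants()]).
#' @param pathways named list of gene sets (see [readGmt()]).
#' @param excludeClasses variant classes that do not count as mutations;
#'   defaults to \code{"Silent"}.
#' @return named list: pathway -> sorted character vector of patient ids.
#' @export
stratifyPatients <- function(variants, pathways,
                             excludeClasses = c("Silent")) {
  if (!length(pathways) || any(!lengths(pathways))) {
    stop("pathway gene sets must be non-empty")
  }
  if (!nrow(variants)) {
    warning("empty variant table: all cohorts are empty")
    return(structure(rep(list(character(0)), length(pathways)),
                     names = names(pathways)))
  }
  keep <- !(variants$variant_class %in% excludeClasses)
  v <- variants[keep, , drop = FALSE]
  lapply(pathways, function(genes) {
    sort(unique(v$patient_id[v$gene_symbol %in% genes]))
  })
}

#' Summarize cohort sizes in a per-pathway table with a total row
#'
#' The total is a membership count: a patient in two cohorts counts twice,
#' so the total row equals the column sum of per-pathway counts.
#'
#' @param cohorts named list of patient-id vectors from [stratifyPatients()].
#' @param cancerType optional label repeated in the output.
#' @param expectedTotal optional externally reported total; a mismatch with
#'   the column sum is flagged with a warning rather than reproduced.
#' @return data.frame with columns pathway, cancer_type, n_patients; the
#'   last row is \code{"Total"}.
#' @export
cohortSummary <- function(cohorts, cancerType = NA_character_,
                          expectedTotal = NULL) {
  n <- vapply(cohorts, length, integer(1))
  if (!is.null(expectedTotal) && expectedTotal != sum(n)) {
    warning(sprintf(
      "supplied total (%d) does not match the membership column sum (%d)",
      as.integer(expectedTotal), sum(n)))
  }
  data.frame(
    pathway = c(names(cohorts), "Total"),
    cancer_type = cancerType,
    n_patients = c(unname(n), sum(n)),
    stringsAsFactors = FALSE)
}
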