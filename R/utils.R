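## Small internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so library code never perturbs a user's
# random stream.
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically derive a child seed (kept below 2^31) from a root seed
# and an integer index, so each pipeline stage/cohort gets its own stream.
childSeed <- function(seed, index) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(index)) %% 2147483629)
}

# Write a results table as TSV with provenance comment lines.
writeResultTable <- function(df, path, provenance = character()) {
  df <- as.data.frame(df)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# generated-by repurposeDR %s",
                     as.character(packageVersion("repurposeDR"))), con)
  for (line in provenance) writeLines(paste0("# ", line), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path, ...) {
  read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
             check.names = FALSE, stringsAsFactors = FALSE, ...)
}

stopIfNotScalarProb <- function(x, name, openUpper = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x > 0 &&
    (if (openUpper) x < 1 else x <= 1)
  if (!ok) {
    stop(sprintf("%s must be a single value in (0, 1%s)",
                 name, if (openUpper) "" else "]"), call. = FALSE)
  }
  invisible(TRUE)
}
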