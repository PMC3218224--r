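#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. `seed = NULL` leaves the stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage seed derived from a global seed and a stage name,
# kept inside 32-bit integer range so set.seed() accepts it anywhere.
stage_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% 1048573
  as.integer((abs(as.numeric(seed)) %% 2039 + 1) * 1048573 + h) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a data.frame as TSV without quoting or row names (the package's
# interchange format for all tabular outputs).
write_tsv <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(file, ...) {
  utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
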