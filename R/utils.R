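#' @importFrom methods as is
#' @importFrom stats median quantile rnbinom dnbinom qnbinom rlnorm uniroot setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_format <- function(...) {
  stop(errorCondition(sprintf(...), class = "commscore_error"))
}

# All tables the pipeline emits: header row, tab-separated, no quoting, LF endings.
write_tsv_file <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

read_tsv_file <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE)
}

# Open a text connection, auto-detecting gzip by magic bytes (not extension).
open_maybe_gz <- function(path, binary = FALSE) {
  magic <- readBin(path, "raw", n = 2L)
  gz <- length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
  mode <- if (binary) "rb" else "r"
  if (gz) gzfile(path, open = mode) else file(path, open = mode)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
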