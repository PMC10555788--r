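# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Emit a log message
#'
#' All readers and model fits report row counts and exclusions through this
#' hook. Silence with `options(sibmr.verbose = FALSE)`.
#' @noRd
sib_log <- function(...) {
  if (isTRUE(getOption("sibmr.verbose", TRUE))) message("[sibmr] ", ...)
  invisible(NULL)
}

# Derive a stream-specific 32-bit seed from a master seed.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1009 + 97 * as.numeric(stream)) %% 2147483587)
}

stop_sibmr <- function(...) stop(..., call. = FALSE)

# Numeric columns are written with 17 significant digits so that fixture
# round-trips are lossless to ~1e-15 relative error.
write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- formatC(out[[j]], digits = 17, format = "g")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_checked <- function(path, required = NULL, what = "table") {
  if (!file.exists(path)) stop_sibmr(what, " file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 1L) stop_sibmr(what, " file is empty: ", path)
  nfield <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- which(nfield != nfield[1L])
  if (length(bad)) {
    stop_sibmr("malformed row in ", what, " file ", basename(path), ": line ",
               bad[1L], " has ", nfield[bad[1L]], " fields, expected ", nfield[1L])
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(required)) {
    miss <- setdiff(required, names(df))
    if (length(miss)) {
      stop_sibmr(what, " file ", basename(path), " is missing required column(s): ",
                 paste(miss, collapse = ", "))
    }
  }
  df
}
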