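# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Append a structured line to a pipeline log
#'
#' Line-delimited records: ISO timestamp, stage, then `key=value` pairs.
#' Used by every filtering and pairing step so that in/out counts are
#' auditable. A `NULL` path is a no-op.
#'
#' @param path log file path or `NULL`
#' @param stage short stage label
#' @param ... named scalar values to record
#' @return invisibly, the formatted line (or `NULL`)
#' @export
log_line <- function(path, stage, ...) {
  fields <- list(...)
  kv <- if (length(fields)) {
    paste(names(fields), vapply(fields, function(x) paste(format(x), collapse = ";"),
                                character(1)),
          sep = "=", collapse = "\t")
  } else ""
  line <- paste(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, kv, sep = "\t")
  if (!is.null(path)) cat(line, "\n", sep = "", file = path, append = TRUE)
  invisible(line)
}

stop_if_missing_cols <- function(df, cols, what) {
  miss <- setdiff(cols, colnames(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# deterministic seed derivation: one base seed, named substreams
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}
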