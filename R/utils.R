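# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

msc_assert <- function(ok, msg, call. = FALSE) {
  if (!isTRUE(ok)) stop(msg, call. = call.)
}

# Polynomial rolling hash (mod 2^31 - 1) of a character scalar, returned as
# 8 hex digits. Used only to stamp output files with a configuration
# fingerprint; not cryptographic.
msc_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

# Write a data.frame as TSV preceded by '#'-prefixed provenance lines.
msc_write_tsv <- function(df, path, extra_header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(
    sprintf("# melanoscan %s", as.character(packageVersion("melanoscan"))),
    extra_header
  )
  writeLines(hdr, con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}

msc_read_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

msc_log <- function(..., level = "INFO") {
  message(sprintf("[%s] %s", level, sprintf(...)))
}
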