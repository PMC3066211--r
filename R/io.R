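# Shared delimited-text helpers. Files are TSV by default; a comma-separated
# file is accepted when its header contains commas and no tabs.

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) return("\t")
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else "\t"
}

read_delimited <- function(path, required = character()) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "", quote = "\"")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop_format("%s: missing required column(s): %s",
                basename(path), paste(miss, collapse = ", "))
  df
}

# Full-precision writer: doubles survive a write/read round trip bit-exactly
# (17 significant digits); everything else is written as-is.
write_tsv <- function(df, path, digits = NA) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      fmt <- if (is.na(digits)) "%.17g" else paste0("%.", digits, "g")
      v <- sprintf(fmt, out[[j]])
      v[is.na(out[[j]])] <- "NA"
      out[[j]] <- v
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
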