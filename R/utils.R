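# Shared small helpers.

# Write a tibble as TSV with optional '#'-prefixed provenance header lines.
# Readers in this package skip '#' comments.
write_tsv_with_header <- function(x, path, header_lines = character()) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) {
    writeLines(paste0("# ", header_lines), con)
  }
  writeLines(paste(names(x), collapse = "\t"), con)
  body <- do.call(paste, c(lapply(x, format_tsv_col), list(sep = "\t")))
  if (length(body)) writeLines(body, con)
  invisible(path)
}

format_tsv_col <- function(v) {
  if (is.double(v)) {
    out <- formatC(v, digits = 10, format = "g")
    out[is.na(v)] <- "NA"
    out
  } else {
    out <- as.character(v)
    out[is.na(v)] <- "NA"
    out
  }
}
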