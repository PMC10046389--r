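#' Write a TSV with a provenance header
#'
#' All tabular outputs share this format: `#`-prefixed header lines
#' recording the tool version and the parameters of the run, then a
#' tab-separated table with column names.  Reruns with identical
#' parameters produce byte-identical files (no timestamps).
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param params named list of parameters recorded in the header.
#' @return `path`, invisibly.
#' @export
write_tsv_provenance <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("pbtraj"))
  writeLines(sprintf("# pbtraj %s", ver), con)
  if (length(params)) {
    kv <- vapply(seq_along(params), function(i)
      paste0(names(params)[i], "=", paste(format(params[[i]]), collapse = ",")),
      character(1))
    writeLines(paste0("# ", kv), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a provenance TSV
#'
#' @param path file written by [write_tsv_provenance()].
#' @return data.frame; header parameter lines are attached as attribute
#'   `provenance`.
#' @export
read_tsv_provenance <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines)
  df <- utils::read.table(text = lines[-hdr], sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  attr(df, "provenance") <- sub("^# ?", "", lines[hdr])
  df
}
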