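#' Strip a trailing version suffix from an Ensembl-style identifier
#'
#' GENCODE/Ensembl transcript and gene ids carry version suffixes
#' (`ENST00000456328.2`) inconsistently across files, so all joins between
#' site tables, annotation and expression tables are performed on the
#' version-stripped id. Original ids are preserved for output.
#'
#' @param id Character vector of ids.
#' @return Character vector with a final `.<digits>` removed, if present.
#' @export
#' @examples
#' strip_tx_version(c("ENST00000456328.2", "tx1"))
strip_tx_version <- function(id) {
  sub("\\.[0-9]+$", "", as.character(id))
}

# Normalized chromosome name: UCSC "chr1" and Ensembl "1" compare equal.
norm_chrom <- function(x) sub("^chr", "", as.character(x), ignore.case = TRUE)

# Write a data frame as a headered, unquoted TSV (the canonical output format).
write_tsv_plain <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  tibble::as_tibble(read.table(path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE, check.names = FALSE))
}

# Resolve a canonical column name against a header, honouring a user-supplied
# column_map (canonical -> actual) before the built-in alias list.
resolve_column <- function(canonical, header, aliases, column_map = NULL) {
  if (!is.null(column_map) && canonical %in% names(column_map)) {
    actual <- unname(column_map[[canonical]])
    if (!actual %in% header) {
      stop(sprintf("column '%s' (mapped from '%s') not found in header",
                   actual, canonical), call. = FALSE)
    }
    return(actual)
  }
  hit <- intersect(aliases, header)
  if (length(hit) == 0L) return(NA_character_)
  hit[[1L]]
}
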