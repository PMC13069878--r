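#' Read an m6Anet site-probability table
#'
#' Loads a `data.site_proba.csv`-style table of per-site m6A predictions:
#' one row per candidate site with its transcript coordinate, sequencing
#' depth, predicted probability of modification, 5-mer context and
#' estimated modification ratio (fraction of reads carrying the mark).
#'
#' Column-name dialects differ between m6Anet versions; a built-in alias
#' map covers the common ones and `column_map` overrides it. Rows that
#' fail validation (probability or ratio outside \[0,1\], malformed k-mer,
#' negative position, unparseable numbers) are dropped with a warning
#' reporting the count; if more than half of the rows fail the load aborts,
#' on the assumption that the wrong file was supplied. Duplicate
#' (transcript, position) rows after the first are dropped and counted as
#' rejected.
#'
#' @param path Path to the CSV file.
#' @param sample_id Label stamped on every row (e.g. `"naive_rep1"`).
#' @param column_map Optional named character vector mapping canonical
#'   names (`transcript_id`, `transcript_position`, `n_reads`,
#'   `prob_modified`, `kmer`, `mod_ratio`) to the actual header names.
#' @param position_base Either 0 or 1: the coordinate convention of the
#'   `transcript_position` column. Positions are stored 0-based
#'   internally, so `position_base = 1` shifts the column down by one.
#' @return A tibble with columns `transcript_id`, `transcript_position`
#'   (0-based coordinate of the central adenosine), `n_reads`,
#'   `prob_modified`, `kmer`, `mod_ratio`, `sample_id`, plus attribute
#'   `n_rejected` (number of dropped rows).
#' @export
read_site_proba <- function(path, sample_id, column_map = NULL,
                            position_base = 0) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  stopifnot(position_base %in% c(0, 1))
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)

  aliases <- list(
    transcript_id       = c("transcript_id", "transcript", "tx_id"),
    transcript_position = c("transcript_position", "position", "pos"),
    n_reads             = c("n_reads", "num_reads", "coverage", "reads"),
    prob_modified       = c("probability_modified", "prob_modified",
                            "mod_prob", "probability", "prob_mod"),
    kmer                = c("kmer", "motif", "sequence"),
    mod_ratio           = c("mod_ratio", "modification_ratio", "ratio")
  )
  header <- names(raw)
  actual <- vapply(names(aliases), function(canon) {
    resolve_column(canon, header, aliases[[canon]], column_map)
  }, character(1))
  if (anyNA(actual)) {
    stop("missing required column(s): ",
         paste(names(actual)[is.na(actual)], collapse = ", "),
         call. = FALSE)
  }
  df <- raw[actual]
  names(df) <- names(aliases)

  n_in <- nrow(df)
  df$transcript_id <- as.character(df$transcript_id)
  df$kmer <- toupper(as.character(df$kmer))
  suppressWarnings({
    df$transcript_position <- as.numeric(df$transcript_position)
    df$n_reads <- as.numeric(df$n_reads)
    df$prob_modified <- as.numeric(df$prob_modified)
    df$mod_ratio <- as.numeric(df$mod_ratio)
  })
  if (position_base == 1) df$transcript_position <- df$transcript_position - 1

  ok <- !is.na(df$transcript_id) & nzchar(df$transcript_id) &
    !is.na(df$transcript_position) & df$transcript_position >= 0 &
    df$transcript_position == floor(df$transcript_position) &
    !is.na(df$n_reads) & df$n_reads > 0 &
    !is.na(df$prob_modified) & df$prob_modified >= 0 & df$prob_modified <= 1 &
    !is.na(df$mod_ratio) & df$mod_ratio >= 0 & df$mod_ratio <= 1 &
    nchar(df$kmer) == 5L & !grepl("[^ACGT]", df$kmer)
  if (n_in > 0 && mean(!ok) > 0.5) {
    stop(sprintf("%d/%d rows failed validation; is this an m6Anet site table?",
                 sum(!ok), n_in), call. = FALSE)
  }
  df <- df[ok, , drop = FALSE]

  dup <- duplicated(df[c("transcript_id", "transcript_position")])
  df <- df[!dup, , drop = FALSE]

  n_rejected <- n_in - nrow(df)
  if (n_rejected > 0) {
    warning(sprintf("dropped %d invalid/duplicate row(s) from %s",
                    n_rejected, basename(path)), call. = FALSE)
  }
  df$transcript_position <- as.integer(df$transcript_position)
  df$n_reads <- as.integer(df$n_reads)
  df$sample_id <- as.character(sample_id)
  out <- tibble::as_tibble(df)
  attr(out, "n_rejected") <- n_rejected
  out
}
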