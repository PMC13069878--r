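#' Read a BED3/BED6 file of genomic intervals
#'
#' BED coordinates are 0-based half-open. Missing optional columns are
#' filled in: auto-generated names (`feature_1`, ...), `NA` scores, `"."`
#' strand. Rows with `start >= end` or a non-numeric start/end are
#' rejected with a warning naming the offending line numbers.
#'
#' @param path Path to a tab- or space-separated BED file without header.
#' @return Tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.table(path, sep = "", header = FALSE, stringsAsFactors = FALSE,
                    fill = TRUE, colClasses = "character")
  if (ncol(raw) < 3) stop("BED file needs at least 3 columns", call. = FALSE)
  for (j in seq_len(6)) if (ncol(raw) < j) raw[[j]] <- ""
  names(raw)[1:6] <- paste0("V", 1:6)
  df <- tibble::tibble(
    chrom = raw$V1,
    start = suppressWarnings(as.integer(raw$V2)),
    end = suppressWarnings(as.integer(raw$V3)),
    name = ifelse(nzchar(raw$V4) & raw$V4 != ".", raw$V4, NA_character_),
    score = suppressWarnings(as.numeric(ifelse(raw$V5 %in% c("", "."), NA, raw$V5))),
    strand = ifelse(raw$V6 %in% c("+", "-"), raw$V6, ".")
  )
  bad <- is.na(df$start) | is.na(df$end) | df$start < 0 | df$start >= df$end
  if (any(bad)) {
    warning(sprintf("rejected %d malformed BED row(s) at line(s) %s",
                    sum(bad), paste(which(bad), collapse = ", ")),
            call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  auto <- is.na(df$name)
  if (any(auto)) df$name[auto] <- paste0("feature_", which(auto))
  df
}

#' Write genomic intervals as BED6
#'
#' Tab-separated, no header; missing scores are written as `0` and missing
#' strands as `"."` so that the first six columns round-trip through
#' [read_bed()].
#'
#' @param intervals Tibble/data frame with `chrom`, `start`, `end` and
#'   optionally `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$start >= intervals$end)) {
    stop("invalid interval: start >= end", call. = FALSE)
  }
  n <- nrow(intervals)
  name <- intervals$name %||% paste0("feature_", seq_len(n))
  score <- intervals$score %||% rep(0, n)
  strand <- intervals$strand %||% rep(".", n)
  score <- ifelse(is.na(score), 0, score)
  strand <- ifelse(strand %in% c("+", "-"), strand, ".")
  out <- data.frame(intervals$chrom, intervals$start, intervals$end,
                    name, score, strand)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
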