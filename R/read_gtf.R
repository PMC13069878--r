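#' Read transcript models from a GTF annotation
#'
#' Parses an Ensembl/GENCODE-dialect GTF (via [rtracklayer::import()]) and
#' assembles one transcript model per `transcript_id`: chromosome, strand,
#' biotype, the ordered exon structure and, when CDS features are present,
#' the lengths of the 5'UTR, CDS and 3'UTR measured in transcript
#' orientation (the 5'UTR is the exonic span upstream of the first CDS
#' base along the transcript).
#'
#' Exon features lacking a `transcript_id` attribute are skipped with a
#' warning. Transcripts whose exons overlap each other, or whose CDS does
#' not fit inside the exon structure, are excluded and reported; their ids
#' are available as `attr(x, "excluded")`.
#'
#' @param path Path to a GTF file (1-based inclusive coordinates on disk;
#'   models are stored 0-based half-open).
#' @return An object of class `tx_models`: a list with
#'   `transcripts` (tibble of per-transcript fields, including
#'   `length_total`, `length_utr5`, `length_cds`, `length_utr3` and the
#'   version-stripped join keys `tx_key`/`gene_key`) and `exons`/`cds`
#'   (named lists of 0-based half-open interval data frames, sorted by
#'   genomic start).
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  if (!"type" %in% names(df)) stop("GTF has no feature type column", call. = FALSE)

  get_attr <- function(d, candidates, default = NA_character_) {
    for (cand in candidates) if (cand %in% names(d)) return(as.character(d[[cand]]))
    rep(default, nrow(d))
  }

  ex <- df[df$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0) stop("GTF contains no exon features", call. = FALSE)
  ex_tx <- get_attr(ex, "transcript_id")
  no_tx <- is.na(ex_tx) | !nzchar(ex_tx)
  if (any(no_tx)) {
    warning(sprintf("skipping %d exon feature(s) without transcript_id",
                    sum(no_tx)), call. = FALSE)
    ex <- ex[!no_tx, , drop = FALSE]
    ex_tx <- ex_tx[!no_tx]
  }
  ex$transcript_id <- ex_tx
  ex$gene_id <- get_attr(ex, "gene_id", "unknown_gene")
  ex$gene_name <- get_attr(ex, "gene_name")
  ex$biotype <- {
    b <- get_attr(ex, c("transcript_biotype", "transcript_type"))
    g <- get_attr(ex, c("gene_biotype", "gene_type"))
    ifelse(is.na(b), ifelse(is.na(g), "unknown", g), b)
  }

  cds <- df[df$type == "CDS", , drop = FALSE]
  cds_tx <- if (nrow(cds)) get_attr(cds, "transcript_id") else character(0)
  cds_by_tx <- if (nrow(cds)) split(cds, cds_tx) else list()

  excluded <- character(0)
  rows <- list()
  exon_list <- list()
  cds_list <- list()

  for (tx in unique(ex$transcript_id)) {
    e <- ex[ex$transcript_id == tx, , drop = FALSE]
    chrom <- unique(as.character(e$seqnames))
    strand <- unique(as.character(e$strand))
    if (length(chrom) != 1L || length(strand) != 1L || !strand %in% c("+", "-")) {
      excluded <- c(excluded, tx)
      next
    }
    # GTF is 1-based inclusive; convert to 0-based half-open.
    e0 <- data.frame(start = e$start - 1L, end = e$end)
    e0 <- e0[order(e0$start), , drop = FALSE]
    rownames(e0) <- NULL
    if (nrow(e0) > 1 && any(e0$start[-1] < e0$end[-nrow(e0)])) {
      excluded <- c(excluded, tx)
      next
    }
    length_total <- sum(e0$end - e0$start)

    c_df <- cds_by_tx[[tx]]
    if (!is.null(c_df) && nrow(c_df) > 0) {
      c0 <- data.frame(start = c_df$start - 1L, end = c_df$end)
      c0 <- c0[order(c0$start), , drop = FALSE]
      rownames(c0) <- NULL
      length_cds <- sum(c0$end - c0$start)
      first_cds_g <- if (strand == "+") min(c0$start) else max(c0$end) - 1L
      utr5 <- tryCatch(
        genome_to_transcript(first_cds_g, list(strand = strand, exons = e0)),
        error = function(e) NA_integer_
      )
      if (is.na(utr5) || utr5 + length_cds > length_total) {
        excluded <- c(excluded, tx)
        next
      }
      length_utr5 <- utr5
      length_utr3 <- length_total - length_utr5 - length_cds
    } else {
      c0 <- data.frame(start = integer(0), end = integer(0))
      length_cds <- 0L
      length_utr5 <- 0L
      length_utr3 <- 0L
    }

    key <- strip_tx_version(tx)
    rows[[tx]] <- data.frame(
      transcript_id = tx, tx_key = key,
      gene_id = e$gene_id[1], gene_key = strip_tx_version(e$gene_id[1]),
      gene_name = ifelse(is.na(e$gene_name[1]), e$gene_id[1], e$gene_name[1]),
      chrom = chrom, strand = strand, biotype = e$biotype[1],
      n_exons = nrow(e0),
      length_total = as.integer(length_total),
      length_utr5 = as.integer(length_utr5),
      length_cds = as.integer(length_cds),
      length_utr3 = as.integer(length_utr3),
      stringsAsFactors = FALSE
    )
    exon_list[[key]] <- e0
    cds_list[[key]] <- c0
  }

  if (length(excluded)) {
    warning(sprintf("excluded %d malformed transcript(s): %s",
                    length(excluded),
                    paste(head(excluded, 5), collapse = ", ")),
            call. = FALSE)
  }
  if (length(rows) == 0) stop("no valid transcript models in GTF", call. = FALSE)

  out <- structure(
    list(transcripts = tibble::as_tibble(bind_rows(rows)),
         exons = exon_list, cds = cds_list),
    class = "tx_models"
  )
  attr(out, "excluded") <- excluded
  out
}

#' Extract one transcript model
#'
#' @param models A `tx_models` object from [read_gtf()].
#' @param transcript_id Transcript id; a version suffix is ignored.
#' @return A list with the per-transcript fields plus `exons` and `cds`
#'   interval data frames (0-based half-open, sorted by genomic start).
#' @export
tx_model <- function(models, transcript_id) {
  stopifnot(inherits(models, "tx_models"))
  key <- strip_tx_version(transcript_id)
  row <- models$transcripts[models$transcripts$tx_key == key, , drop = FALSE]
  if (nrow(row) == 0) stop("transcript not found: ", transcript_id, call. = FALSE)
  m <- as.list(row[1, ])
  m$exons <- models$exons[[key]]
  m$cds <- models$cds[[key]]
  m
}

#' @export
print.tx_models <- function(x, ...) {
  cat(sprintf("<tx_models> %d transcripts, %d genes on %d sequence(s)\n",
              nrow(x$transcripts),
              length(unique(x$transcripts$gene_key)),
              length(unique(x$transcripts$chrom))))
  invisible(x)
}
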