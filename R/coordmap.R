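# Transcript <-> genome coordinate projection.
#
# A transcript coordinate counts bases along the mature transcript in 5'->3'
# orientation. On '+' transcripts this walks exons in genomic order; on '-'
# transcripts it walks them in reverse genomic order, and offset o inside an
# exon [s, e) maps to genomic position e - 1 - o. All coordinates are 0-based.

# exons of `model` in transcript (5'->3') order
.tx_exons <- function(model) {
  e <- model$exons
  if (identical(model$strand, "-")) e[rev(seq_len(nrow(e))), , drop = FALSE] else e
}

#' Project transcript positions to genomic positions
#'
#' @param transcript_position Integer vector of 0-based transcript
#'   coordinates, each in `[0, length_total)`.
#' @param model A single transcript model (see [tx_model()]): a list with
#'   at least `strand` and `exons` (0-based half-open, sorted by genomic
#'   start); `transcript_id` is used in error messages when present.
#' @return Integer vector of 0-based genomic positions.
#' @export
project_to_genome <- function(transcript_position, model) {
  p <- as.integer(transcript_position)
  e <- .tx_exons(model)
  w <- e$end - e$start
  total <- sum(w)
  if (any(p < 0 | p >= total)) {
    stop(sprintf("transcript position out of range for %s (length %d)",
                 model$transcript_id %||% "<transcript>", total),
         call. = FALSE)
  }
  cum <- cumsum(w)
  idx <- findInterval(p, c(0L, cum), rightmost.closed = FALSE)
  offset <- p - c(0L, cum)[idx]
  if (identical(model$strand, "-")) {
    as.integer(e$end[idx] - 1L - offset)
  } else {
    as.integer(e$start[idx] + offset)
  }
}

#' Map genomic positions back to transcript coordinates
#'
#' Inverse of [project_to_genome()]; defined only for exonic positions.
#'
#' @param genomic_position Integer vector of 0-based genomic positions,
#'   each inside an exon of `model`.
#' @inheritParams project_to_genome
#' @return Integer vector of 0-based transcript coordinates, satisfying
#'   `project_to_genome(invert_projection(g, m), m) == g`.
#' @export
invert_projection <- function(genomic_position, model) {
  g <- as.integer(genomic_position)
  e <- .tx_exons(model)
  w <- e$end - e$start
  before <- c(0L, cumsum(w))[seq_len(nrow(e))]
  out <- rep(NA_integer_, length(g))
  for (i in seq_len(nrow(e))) {
    hit <- g >= e$start[i] & g < e$end[i]
    if (!any(hit)) next
    offset <- if (identical(model$strand, "-")) e$end[i] - 1L - g[hit] else g[hit] - e$start[i]
    out[hit] <- before[i] + offset
  }
  if (anyNA(out)) {
    stop(sprintf("genomic position(s) %s not exonic in %s",
                 paste(g[is.na(out)], collapse = ", "),
                 model$transcript_id %||% "<transcript>"),
         call. = FALSE)
  }
  as.integer(out)
}

# used by read_gtf before a full model exists
genome_to_transcript <- invert_projection

#' Project m6A sites to genomic BED-style intervals
#'
#' Converts each site's transcript coordinate to genomic coordinates
#' through its transcript's exon structure and strand. In `"base"` mode
#' the interval is the single central adenosine; in `"kmer"` mode it
#' covers the five k-mer positions, emitting multiple rows (sharing the
#' `name` field) when an exon junction falls inside the k-mer so that the
#' k-mer is not contiguous in genome space. K-mer positions that would
#' fall off a transcript end are trimmed.
#'
#' Sites on transcripts absent from `models` are skipped; the count is
#' reported in a warning and in `attr(x, "n_skipped")`.
#'
#' @param sites Site table from [read_site_proba()] (filtered or not).
#' @param models `tx_models` from [read_gtf()].
#' @param width_mode `"base"` (default) or `"kmer"`.
#' @return Tibble of BED6-compatible intervals: `chrom`, `start`, `end`
#'   (0-based half-open), `name` (`transcriptID|position|kmer`), `score`
#'   (the site's modification ratio), `strand`, plus carried-through
#'   columns `transcript_id`, `transcript_position`, `sample_id`, `kmer`.
#' @export
project_sites <- function(sites, models, width_mode = c("base", "kmer")) {
  width_mode <- match.arg(width_mode)
  stopifnot(inherits(models, "tx_models"))
  keys <- strip_tx_version(sites$transcript_id)
  known <- keys %in% models$transcripts$tx_key
  n_skipped <- sum(!known)
  if (n_skipped > 0) {
    warning(sprintf("%d site(s) on transcripts absent from the annotation were skipped",
                    n_skipped), call. = FALSE)
  }
  sites <- sites[known, , drop = FALSE]
  keys <- keys[known]

  out <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    m <- tx_model(models, keys[i])
    p <- sites$transcript_position[i]
    if (p < 0 || p >= m$length_total) {
      stop(sprintf("site position %d out of range for %s (length %d)",
                   p, sites$transcript_id[i], m$length_total), call. = FALSE)
    }
    pp <- if (width_mode == "base") p else {
      seq.int(max(0L, p - 2L), min(m$length_total - 1L, p + 2L))
    }
    g <- sort(project_to_genome(pp, m))
    run <- cumsum(c(1L, diff(g) != 1L))
    iv <- do.call(rbind, lapply(split(g, run), function(gs) {
      c(start = min(gs), end = max(gs) + 1L)
    }))
    out[[i]] <- tibble::tibble(
      chrom = m$chrom,
      start = as.integer(iv[, "start"]),
      end = as.integer(iv[, "end"]),
      name = paste(sites$transcript_id[i], p, sites$kmer[i], sep = "|"),
      score = sites$mod_ratio[i],
      strand = m$strand,
      transcript_id = sites$transcript_id[i],
      transcript_position = p,
      sample_id = sites$sample_id[i],
      kmer = sites$kmer[i]
    )
  }
  res <- if (length(out)) bind_rows(out) else tibble::tibble(
    chrom = character(0), start = integer(0), end = integer(0),
    name = character(0), score = numeric(0), strand = character(0),
    transcript_id = character(0), transcript_position = integer(0),
    sample_id = character(0), kmer = character(0)
  )
  attr(res, "n_skipped") <- n_skipped
  res
}
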