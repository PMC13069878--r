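# Metagene profiling: each coding transcript's 5'UTR, CDS and 3'UTR are
# rescaled to unit length and concatenated, so a site's position falls in
# [0,1) for the 5'UTR, [1,2) for the CDS and [2,3) for the 3'UTR.

#' Scale site positions onto the 3-region metagene axis
#'
#' Only coding transcripts (non-empty CDS) are profiled; sites on
#' non-coding transcripts are set aside (see
#' [noncoding_relative_positions()]) because the three-region scaling is
#' undefined without a CDS. A site position at or beyond the transcript
#' length is an error naming the transcript, since it indicates a
#' site/annotation mismatch.
#'
#' @param sites Filtered site table.
#' @param models `tx_models`.
#' @return Tibble `(transcript_id, transcript_position, scaled_position,
#'   region_label)` with `scaled_position` in `[0, 3)` and `region_label`
#'   in `{UTR5, CDS, UTR3}`. `attr(x, "n_noncoding")` counts the sites
#'   set aside on non-coding transcripts; `attr(x, "n_unannotated")` the
#'   sites on transcripts absent from the annotation.
#' @export
metagene_positions <- function(sites, models) {
  j <- .join_models(sites, models)
  n_unannotated <- sum(is.na(j$length_total))
  j <- j[!is.na(j$length_total), , drop = FALSE]
  bad <- j$transcript_position >= j$length_total
  if (any(bad)) {
    stop("site position beyond transcript length for: ",
         paste(unique(j$transcript_id[bad]), collapse = ", "), call. = FALSE)
  }
  coding <- j$length_cds > 0
  n_noncoding <- sum(!coding)
  j <- j[coding, , drop = FALSE]

  p <- j$transcript_position
  u5 <- j$length_utr5
  cd <- j$length_cds
  u3 <- j$length_utr3
  in_utr5 <- p < u5
  in_cds <- !in_utr5 & p < u5 + cd
  scaled <- as.numeric(ifelse(in_utr5, p / u5,
                              ifelse(in_cds, 1 + (p - u5) / cd,
                                     2 + (p - u5 - cd) / u3)))
  region <- as.character(ifelse(in_utr5, "UTR5",
                                ifelse(in_cds, "CDS", "UTR3")))
  out <- tibble::tibble(
    transcript_id = j$transcript_id,
    transcript_position = p,
    scaled_position = scaled,
    region_label = region
  )
  attr(out, "n_noncoding") <- n_noncoding
  attr(out, "n_unannotated") <- n_unannotated
  out
}

#' Whole-transcript relative positions for non-coding transcripts
#'
#' @param sites Filtered site table.
#' @param models `tx_models`.
#' @return Tibble `(transcript_id, transcript_position, rel_position)`
#'   with `rel_position = position / length_total` in `[0, 1)`, restricted
#'   to annotated transcripts without a CDS.
#' @export
noncoding_relative_positions <- function(sites, models) {
  j <- .join_models(sites, models)
  j <- j[!is.na(j$length_total) & j$length_cds == 0, , drop = FALSE]
  tibble::tibble(
    transcript_id = j$transcript_id,
    transcript_position = j$transcript_position,
    rel_position = j$transcript_position / j$length_total
  )
}

#' Kernel density of metagene positions
#'
#' Gaussian kernel density estimate of the scaled positions over the
#' concatenated `[0, 3]` metagene axis, evaluated on a fixed grid.
#' Bandwidth defaults to Silverman's rule of thumb (`stats::bw.nrd0`).
#'
#' @param positions Output of [metagene_positions()], or any numeric
#'   vector of scaled positions.
#' @param bandwidth Kernel bandwidth; `NULL` for Silverman's rule.
#' @param n_grid Number of grid points (default 512).
#' @return Tibble `(x, density)`; the curve integrates to 1 over its
#'   padded support.
#' @export
metagene_density <- function(positions, bandwidth = NULL, n_grid = 512) {
  x <- if (is.data.frame(positions)) positions$scaled_position else positions
  x <- x[!is.na(x)]
  if (length(x) < 2) {
    stop("need at least 2 positions for a density; report raw positions instead",
         call. = FALSE)
  }
  d <- density(x, bw = bandwidth %||% "nrd0", kernel = "gaussian", n = n_grid)
  tibble::tibble(x = d$x, density = d$y)
}
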