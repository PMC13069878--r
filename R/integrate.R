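# Methylation x expression integration: transcripts with a defined
# differential-methylation direction are crossed with their gene's
# differential-expression call into six functional categories
# (hyper/hypo-methylated x up/down/not-significantly regulated).

.category_levels <- c("hyper_up", "hyper_down", "hyper_ns",
                      "hypo_up", "hypo_down", "hypo_ns")

#' Classify transcripts into six methylation-by-expression categories
#'
#' Methylation direction comes from [diff_methylation()]: `hyper_a` reads
#' as hypermethylated (in condition A relative to B) and `hyper_b` as
#' hypomethylated; transcripts with direction `unchanged` are excluded
#' and counted. Expression direction comes from the gene-level DGE table:
#' `up` when `padj < alpha` and `log2fc >= lfc_min`, `down` when
#' `padj < alpha` and `log2fc <= -lfc_min`, otherwise `ns`; genes missing
#' from the DGE table (or with missing `padj`) are `ns` and flagged with
#' `in_dge = FALSE`.
#'
#' @param diff Differential-methylation table from [diff_methylation()].
#' @param dge DGE table from [read_dge()].
#' @param models `tx_models`, for gene identity, biotype and (optionally)
#'   region assignment.
#' @param alpha Significance threshold on `padj`.
#' @param lfc_min Minimum absolute log2 fold change for a call (default 0).
#' @param sites Optional filtered site table; when supplied, each
#'   transcript's `dominant_region` (the region holding the plurality of
#'   its modified sites; ties broken toward the 3'-most region;
#'   `noncoding` for transcripts without CDS) is added.
#' @return Tibble `(transcript_id, tx_key, gene_id, gene_key,
#'   meth_direction, expr_direction, category, biotype, in_dge,
#'   log2_wmr_ratio, median_diff, q_value, log2fc, padj[,
#'   dominant_region])`; `attr(x, "n_excluded")` counts transcripts with
#'   undefined methylation direction.
#' @export
classify_integration <- function(diff, dge, models, alpha = 0.05,
                                 lfc_min = 0, sites = NULL) {
  classified <- diff[diff$direction != "unchanged", , drop = FALSE]
  n_excluded <- nrow(diff) - nrow(classified)

  m <- models$transcripts
  idx <- match(classified$tx_key, m$tx_key)
  out <- tibble::tibble(
    transcript_id = classified$transcript_id,
    tx_key = classified$tx_key,
    gene_id = m$gene_id[idx],
    gene_key = m$gene_key[idx],
    biotype = ifelse(is.na(idx), "unannotated", m$biotype[idx]),
    meth_direction = ifelse(classified$direction == "hyper_a", "hyper", "hypo"),
    log2_wmr_ratio = classified$log2_wmr_ratio,
    median_diff = classified$median_diff,
    q_value = classified$q_value
  )

  di <- match(out$gene_key, dge$gene_key)
  out$in_dge <- !is.na(di)
  out$log2fc <- dge$log2fc[di]
  out$padj <- dge$padj[di]
  sig <- out$in_dge & !is.na(out$padj) & out$padj < alpha
  up <- sig & !is.na(out$log2fc) & out$log2fc >= lfc_min & out$log2fc > -lfc_min
  down <- sig & !is.na(out$log2fc) & out$log2fc <= -lfc_min & out$log2fc < lfc_min
  out$expr_direction <- ifelse(up, "up", ifelse(down, "down", "ns"))
  out$category <- factor(paste(out$meth_direction, out$expr_direction, sep = "_"),
                         levels = .category_levels)

  if (!is.null(sites)) {
    out$dominant_region <- vapply(out$tx_key, function(tx) {
      dominant_region_for(tx, sites, models)
    }, character(1))
  }
  out <- select(out, "transcript_id", "tx_key", "gene_id", "gene_key",
                "meth_direction", "expr_direction", "category", "biotype",
                "in_dge", "log2_wmr_ratio", "median_diff", "q_value",
                "log2fc", "padj", dplyr::any_of("dominant_region"))
  attr(out, "n_excluded") <- n_excluded
  out
}

# Region holding the plurality of a transcript's modified sites; ties go to
# the 3'-most region (UTR3 over CDS over UTR5).
dominant_region_for <- function(tx_key, sites, models) {
  m <- models$transcripts
  row <- m[m$tx_key == tx_key, , drop = FALSE]
  if (nrow(row) == 0) return(NA_character_)
  if (row$length_cds == 0) return("noncoding")
  s <- sites[strip_tx_version(sites$transcript_id) == tx_key, , drop = FALSE]
  if (nrow(s) == 0) return(NA_character_)
  mp <- metagene_positions(s, models)
  counts <- table(factor(mp$region_label, levels = c("UTR3", "CDS", "UTR5")))
  names(counts)[which.max(counts)]  # which.max takes the first max: 3'-most
}

#' Biotype composition within each integration category
#'
#' @param records Output of [classify_integration()].
#' @return Tibble `(category, biotype, n, fraction)`; fractions sum to 1
#'   within each category.
#' @export
category_biotype_summary <- function(records) {
  records %>%
    count(.data$category, .data$biotype, name = "n") %>%
    group_by(.data$category) %>%
    mutate(fraction = .data$n / sum(.data$n)) %>%
    ungroup() %>%
    arrange(.data$category, dplyr::desc(.data$n))
}

#' Transcript-region composition within each integration category
#'
#' Counts each classified transcript's modified sites by metagene region
#' (5'UTR/CDS/3'UTR; sites on non-coding transcripts under `noncoding`).
#'
#' @param records Output of [classify_integration()].
#' @param sites Filtered site table (the same one the comparison used).
#' @param models `tx_models`.
#' @return Tibble `(category, region, n_sites, fraction)`; fractions sum
#'   to 1 within each category.
#' @export
category_region_summary <- function(records, sites, models) {
  sites$tx_key <- strip_tx_version(sites$transcript_id)
  s <- sites[sites$tx_key %in% records$tx_key, , drop = FALSE]
  mp <- metagene_positions(s, models)
  mp$tx_key <- strip_tx_version(mp$transcript_id)
  nc <- noncoding_relative_positions(s, models)
  per_site <- bind_rows(
    tibble::tibble(tx_key = mp$tx_key, region = mp$region_label),
    tibble::tibble(tx_key = strip_tx_version(nc$transcript_id),
                   region = "noncoding")
  )
  per_site %>%
    left_join(distinct(records, .data$tx_key, .data$category), by = "tx_key") %>%
    count(.data$category, .data$region, name = "n_sites") %>%
    group_by(.data$category) %>%
    mutate(fraction = .data$n_sites / sum(.data$n_sites)) %>%
    ungroup() %>%
    arrange(.data$category, dplyr::desc(.data$n_sites))
}
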