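# Descriptive summaries of high-confidence m6A sites ("part 1" analytics).
# All per-transcript/per-gene summaries count distinct transcripts or genes,
# not sites, so fractions read as "% of modified transcripts/genes".

#' Filter sites by modification probability
#'
#' Retains sites whose predicted probability of modification is *strictly*
#' greater than `threshold` (default 0.9, the conventional cut-off for
#' high-confidence m6Anet sites).
#'
#' @param sites Site table from [read_site_proba()].
#' @param threshold Probability cut-off in \[0, 1\].
#' @return The filtered site table.
#' @export
filter_sites <- function(sites, threshold = 0.9) {
  stopifnot(threshold >= 0, threshold <= 1)
  out <- sites[sites$prob_modified > threshold, , drop = FALSE]
  attr(out, "threshold_used") <- threshold
  out
}

# join helper: sites annotated with model fields (NA where unannotated)
.join_models <- function(sites, models) {
  stopifnot(inherits(models, "tx_models"))
  sites$tx_key <- strip_tx_version(sites$transcript_id)
  left_join(sites, models$transcripts, by = "tx_key",
            suffix = c("", ".model"))
}

#' Count modified sites, transcripts and genes
#'
#' @param sites Filtered site table.
#' @param models `tx_models` from [read_gtf()].
#' @return A list with `n_sites`, `n_transcripts`, `n_genes`,
#'   `n_unmatched_transcripts` (modified transcripts absent from the
#'   annotation; these do not contribute to the gene count) and
#'   `threshold_used` when the input carries one.
#' @export
count_summary <- function(sites, models) {
  j <- .join_models(sites, models)
  tx <- distinct(j, .data$tx_key, .data$gene_key)
  list(
    n_sites = nrow(j),
    n_transcripts = nrow(tx),
    n_genes = length(unique(tx$gene_key[!is.na(tx$gene_key)])),
    n_unmatched_transcripts = sum(is.na(tx$gene_key)),
    threshold_used = attr(sites, "threshold_used") %||% NA_real_
  )
}

#' Frequency of modified sites per transcript
#'
#' @param sites Filtered site table.
#' @return Tibble `(n_sites, n_transcripts)`: how many transcripts carry
#'   exactly `n_sites` modified sites; `attr(x, "max_sites")` holds the
#'   maximum.
#' @export
sites_per_transcript <- function(sites) {
  per_tx <- count(sites, .data$transcript_id, name = "k")
  out <- count(per_tx, n_sites = .data$k, name = "n_transcripts") %>%
    arrange(.data$n_sites)
  attr(out, "max_sites") <- if (nrow(out)) max(out$n_sites) else 0L
  out
}

#' Frequency of modified transcripts per gene
#'
#' @param sites Filtered site table.
#' @param models `tx_models`.
#' @return Tibble `(n_transcripts, n_genes)`; unannotated transcripts are
#'   excluded. `attr(x, "max_transcripts")` holds the maximum.
#' @export
transcripts_per_gene <- function(sites, models) {
  j <- .join_models(sites, models)
  per_gene <- j %>%
    filter(!is.na(.data$gene_key)) %>%
    distinct(.data$gene_key, .data$tx_key) %>%
    count(.data$gene_key, name = "k")
  out <- count(per_gene, n_transcripts = .data$k, name = "n_genes") %>%
    arrange(.data$n_transcripts)
  attr(out, "max_transcripts") <- if (nrow(out)) max(out$n_transcripts) else 0L
  out
}

#' The 18 concrete DRACH 5-mers
#'
#' D = A/G/T, R = A/G, then the methylated A, C, and H = A/C/T.
#'
#' @return Character vector of the 18 DRACH 5-mers, sorted.
#' @export
drach_kmers <- function() {
  g <- expand.grid(D = c("A", "G", "T"), R = c("A", "G"),
                   A = "A", C = "C", H = c("A", "C", "T"),
                   stringsAsFactors = FALSE)
  sort(apply(g, 1, paste0, collapse = ""))
}

#' Test 5-mers against the DRACH consensus
#'
#' @param kmer Character vector of 5-mers.
#' @return Logical vector.
#' @export
is_drach <- function(kmer) {
  grepl("^[AGT][AG]AC[ACT]$", toupper(kmer))
}

#' K-mer usage among modified sites
#'
#' @param sites Filtered site table.
#' @return Tibble `(kmer, count, fraction, is_DRACH)` sorted by
#'   decreasing count; fractions sum to 1.
#' @export
kmer_frequency <- function(sites) {
  out <- count(sites, .data$kmer, name = "count") %>%
    mutate(fraction = .data$count / sum(.data$count),
           is_DRACH = is_drach(.data$kmer)) %>%
    arrange(dplyr::desc(.data$count), .data$kmer)
  out
}

#' Biotype composition of modified transcripts
#'
#' Counts distinct modified transcripts per transcript biotype;
#' transcripts absent from the annotation are grouped as `"unannotated"`.
#'
#' @param sites Filtered site table.
#' @param models `tx_models`.
#' @return Tibble `(biotype, n_transcripts, fraction)`.
#' @export
biotype_summary <- function(sites, models) {
  j <- .join_models(sites, models)
  j %>%
    mutate(biotype = ifelse(is.na(.data$biotype), "unannotated", .data$biotype)) %>%
    distinct(.data$tx_key, .data$biotype) %>%
    count(.data$biotype, name = "n_transcripts") %>%
    mutate(fraction = .data$n_transcripts / sum(.data$n_transcripts)) %>%
    arrange(dplyr::desc(.data$n_transcripts))
}

#' Length distribution of modified transcripts
#'
#' Bins each modified transcript's total (mature) length once, with
#' closed right edges: the defaults give <=1000, 1001-5000, 5001-10000
#' and >10000 nucleotides.
#'
#' @param sites Filtered site table.
#' @param models `tx_models`.
#' @param bin_edges Increasing numeric vector of edges (first usually 0,
#'   last `Inf`).
#' @return Tibble `(bin, n_transcripts)` with one row per bin (zero-count
#'   bins included); unannotated transcripts are excluded.
#' @export
transcript_length_bins <- function(sites, models,
                                   bin_edges = c(0, 1000, 5000, 10000, Inf)) {
  stopifnot(length(bin_edges) >= 2, !is.unsorted(bin_edges, strictly = TRUE))
  j <- .join_models(sites, models) %>%
    filter(!is.na(.data$length_total)) %>%
    distinct(.data$tx_key, .data$length_total)
  lo <- bin_edges[-length(bin_edges)]
  hi <- bin_edges[-1]
  labels <- ifelse(is.infinite(hi), paste0(">", lo),
                   ifelse(lo == 0, paste0("<=", hi),
                          paste0(lo + 1, "-", hi)))
  b <- cut(j$length_total, breaks = bin_edges, labels = labels,
           right = TRUE, include.lowest = TRUE)
  tibble::tibble(bin = labels,
                 n_transcripts = as.integer(table(factor(b, levels = labels))))
}

#' Chromosome distribution of modified genes
#'
#' Each modified gene is counted once on its chromosome (taken from the
#' GTF-derived transcript models).
#'
#' @param sites Filtered site table.
#' @param models `tx_models`.
#' @return Tibble `(chrom, n_genes, fraction)`; fractions sum to 1.
#' @export
chromosome_distribution <- function(sites, models) {
  j <- .join_models(sites, models)
  j %>%
    filter(!is.na(.data$gene_key)) %>%
    distinct(.data$gene_key, .data$chrom) %>%
    count(.data$chrom, name = "n_genes") %>%
    mutate(fraction = .data$n_genes / sum(.data$n_genes)) %>%
    arrange(dplyr::desc(.data$n_genes))
}
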