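# Comparative ("part 2") analytics: group overlaps, the per-transcript
# weighted modification ratio (WMR), and differential methylation with or
# without replicates.
#
# WMR = sum of site modification ratios on a transcript / transcript length,
# a per-base methylation burden. Without replicates, conditions are compared
# by log2(WMR_A/WMR_B) with a pseudocount; with >=2 replicates per condition
# the per-replicate WMR distributions are compared by Wilcoxon rank-sum and
# the per-transcript median difference.

#' Common and unique elements across sample groups
#'
#' For any number of user-defined groups of filtered sites, counts the
#' elements exclusive to every non-empty subset of groups, at three
#' levels of identity: site (`transcript + position`), transcript, and
#' gene (requires `models`). Subset counts sum to the size of the union
#' at each level.
#'
#' @param groups Named list (>= 2 entries) of filtered site tables, one
#'   per group; replicates of a group should be row-bound first.
#' @param models Optional `tx_models`, required for the gene level.
#' @return Tibble `(level, groups, n)` where `groups` is the
#'   `&`-separated set of group names an element occurs in.
#' @export
group_overlap <- function(groups, models = NULL) {
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("groups must be a named list", call. = FALSE)
  }
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)

  keys_of <- function(sites, level) {
    tx <- strip_tx_version(sites$transcript_id)
    switch(level,
      site = unique(paste(tx, sites$transcript_position, sep = ":")),
      transcript = unique(tx),
      gene = {
        m <- models$transcripts
        g <- m$gene_key[match(unique(tx), m$tx_key)]
        unique(g[!is.na(g)])
      }
    )
  }
  levels <- c("site", "transcript", if (!is.null(models)) "gene")
  out <- lapply(levels, function(level) {
    sets <- lapply(groups, keys_of, level = level)
    universe <- unique(unlist(sets))
    member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
    if (length(universe) == 1L) member <- matrix(member, nrow = 1)
    combo <- apply(member, 1, function(row) paste(names(groups)[row], collapse = "&"))
    tb <- table(combo)
    tibble::tibble(level = level, groups = names(tb), n = as.integer(tb))
  })
  bind_rows(out)
}

#' Weighted modification ratio per transcript and sample
#'
#' `WMR = sum(mod_ratio over the transcript's filtered sites) /
#' length_total` for every (sample, transcript) pair present in `sites`.
#' Transcripts absent from the annotation have no defined length, so they
#' are excluded and reported via a warning and `attr(x, "excluded")`.
#'
#' @param sites Filtered site table (any number of samples).
#' @param models `tx_models`.
#' @return Tibble `(transcript_id, tx_key, gene_key, sample_id, wmr,
#'   n_sites_used, length_total)`.
#' @export
compute_wmr <- function(sites, models) {
  j <- .join_models(sites, models)
  missing_tx <- unique(j$transcript_id[is.na(j$length_total)])
  if (length(missing_tx)) {
    warning(sprintf("WMR undefined for %d transcript(s) absent from the annotation",
                    length(missing_tx)), call. = FALSE)
  }
  out <- j %>%
    filter(!is.na(.data$length_total)) %>%
    group_by(.data$tx_key, .data$sample_id) %>%
    summarise(
      transcript_id = .data$transcript_id[1],
      gene_key = .data$gene_key[1],
      wmr = sum(.data$mod_ratio) / .data$length_total[1],
      n_sites_used = n(),
      length_total = .data$length_total[1],
      .groups = "drop"
    ) %>%
    select("transcript_id", "tx_key", "gene_key", "sample_id",
           "wmr", "n_sites_used", "length_total")
  attr(out, "excluded") <- missing_tx
  out
}

#' Log2 ratio of two weighted modification ratios
#'
#' `log2((wmr_a + pseudo) / (wmr_b + pseudo))`; positive values indicate
#' hypermethylation in the first condition. The pseudocount keeps the
#' ratio finite when one side is zero.
#'
#' @param wmr_a,wmr_b Non-negative WMR values (vectorized).
#' @param pseudo Pseudocount, default `1e-6`.
#' @return Numeric vector.
#' @export
log2_wmr_ratio <- function(wmr_a, wmr_b, pseudo = 1e-6) {
  stopifnot(pseudo > 0)
  # difference of logs rather than log of the quotient: exactly antisymmetric
  # in (wmr_a, wmr_b), so a group swap negates the ratio bit-for-bit
  log2(wmr_a + pseudo) - log2(wmr_b + pseudo)
}

#' Wilcoxon rank-sum comparison of replicate WMR values
#'
#' Two-sided rank-sum test between the two replicate vectors: exact
#' enumeration when `n_a + n_b <= 10` with no ties, normal approximation
#' (with tie correction and continuity correction) otherwise. Degenerate
#' input with all values identical across both groups returns `p = 1`.
#'
#' @param wmr_a,wmr_b Numeric vectors of per-replicate WMR values
#'   (>= 2 each for a meaningful test).
#' @return List with `p_value` and `median_diff = median(wmr_a) -
#'   median(wmr_b)`.
#' @export
wilcoxon_diffmeth <- function(wmr_a, wmr_b) {
  stopifnot(length(wmr_a) >= 1, length(wmr_b) >= 1)
  md <- median(wmr_a) - median(wmr_b)
  all_vals <- c(wmr_a, wmr_b)
  if (length(unique(all_vals)) == 1L) {
    return(list(p_value = 1, median_diff = 0))
  }
  ties <- any(duplicated(all_vals))
  exact <- (length(all_vals) <= 10) && !ties
  p <- suppressWarnings(
    wilcox.test(wmr_a, wmr_b, alternative = "two.sided", exact = exact,
                correct = TRUE)$p.value
  )
  list(p_value = unname(p), median_diff = md)
}

#' Benjamini-Hochberg adjusted P values
#'
#' @param p_values Numeric vector in \[0, 1\] (`NA` allowed and preserved).
#' @return Step-up BH q-values.
#' @export
adjust_pvalues <- function(p_values) {
  p.adjust(p_values, method = "BH")
}

#' Differential methylation between two conditions
#'
#' Compares per-transcript WMR between two groups of samples. With >= 2
#' replicates in each group, every transcript detected in both groups is
#' tested by [wilcoxon_diffmeth()] on its per-replicate WMR values
#' (replicates where the transcript has no retained site contribute WMR
#' 0), P values are BH-adjusted, and the direction is called at
#' `q < alpha` by the sign of the median difference. With a single sample
#' per group (e.g. replicates pooled upstream) the test is skipped and
#' the direction is the sign of the pooled log2 WMR ratio.
#'
#' Transcripts detected in only one group are not forced into a ratio;
#' they are reported separately in `attr(x, "exclusive")`.
#'
#' @param wmr WMR table from [compute_wmr()] covering all samples.
#' @param groups Named list of exactly two character vectors of
#'   `sample_id`s, e.g. `list(naive = c("n1","n2"), kd = c("k1","k2"))`.
#'   The first entry is condition A (the log2 ratio numerator).
#' @param alpha FDR threshold for direction calls in replicate mode.
#' @param pseudo Pseudocount for log2 ratios.
#' @return Tibble `(transcript_id, tx_key, gene_key, wmr_a, wmr_b,
#'   log2_wmr_ratio, median_diff, p_value, q_value, direction)` with
#'   `direction` in `{hyper_a, hyper_b, unchanged}`. Attributes: `mode`
#'   (`"replicate"` or `"pooled"`), `group_names`, `exclusive` (tibble of
#'   group-exclusive transcripts with their group and pooled WMR).
#' @export
diff_methylation <- function(wmr, groups, alpha = 0.05, pseudo = 1e-6) {
  if (length(groups) != 2 || is.null(names(groups))) {
    stop("groups must be a named list of exactly 2 sample-id vectors",
         call. = FALSE)
  }
  sa <- groups[[1]]
  sb <- groups[[2]]
  known <- unique(wmr$sample_id)
  missing_samples <- setdiff(c(sa, sb), known)
  if (length(missing_samples)) {
    stop("sample(s) not present in the WMR table: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  }
  replicate_mode <- length(sa) >= 2 && length(sb) >= 2
  if (!replicate_mode && (length(sa) > 1 || length(sb) > 1)) {
    warning("one group has a single sample; falling back to pooled log2-ratio mode",
            call. = FALSE)
    replicate_mode <- FALSE
  }

  wa <- wmr[wmr$sample_id %in% sa, , drop = FALSE]
  wb <- wmr[wmr$sample_id %in% sb, , drop = FALSE]
  tx_a <- unique(wa$tx_key)
  tx_b <- unique(wb$tx_key)
  common <- intersect(tx_a, tx_b)

  excl <- bind_rows(
    wa %>% filter(!.data$tx_key %in% common) %>%
      group_by(.data$tx_key) %>%
      summarise(transcript_id = .data$transcript_id[1],
                group = names(groups)[1],
                mean_wmr = mean(.data$wmr), .groups = "drop"),
    wb %>% filter(!.data$tx_key %in% common) %>%
      group_by(.data$tx_key) %>%
      summarise(transcript_id = .data$transcript_id[1],
                group = names(groups)[2],
                mean_wmr = mean(.data$wmr), .groups = "drop")
  )

  # per-replicate WMR vectors, absent replicates as 0
  vec_for <- function(w, samples, tx) {
    v <- setNames(rep(0, length(samples)), samples)
    rows <- w[w$tx_key == tx, , drop = FALSE]
    v[rows$sample_id] <- rows$wmr
    unname(v)
  }

  res <- lapply(common, function(tx) {
    a <- vec_for(wa, sa, tx)
    b <- vec_for(wb, sb, tx)
    ma <- mean(a)
    mb <- mean(b)
    row <- list(
      tx_key = tx,
      transcript_id = c(wa$transcript_id[wa$tx_key == tx],
                        wb$transcript_id[wb$tx_key == tx])[1],
      gene_key = c(wa$gene_key[wa$tx_key == tx],
                   wb$gene_key[wb$tx_key == tx])[1],
      wmr_a = ma, wmr_b = mb,
      log2_wmr_ratio = log2_wmr_ratio(ma, mb, pseudo)
    )
    if (replicate_mode) {
      t <- wilcoxon_diffmeth(a, b)
      row$median_diff <- t$median_diff
      row$p_value <- t$p_value
    } else {
      row$median_diff <- NA_real_
      row$p_value <- NA_real_
    }
    tibble::as_tibble(row)
  })
  out <- if (length(res)) bind_rows(res) else tibble::tibble(
    tx_key = character(0), transcript_id = character(0),
    gene_key = character(0), wmr_a = numeric(0), wmr_b = numeric(0),
    log2_wmr_ratio = numeric(0), median_diff = numeric(0),
    p_value = numeric(0)
  )

  if (replicate_mode) {
    out$q_value <- adjust_pvalues(out$p_value)
    out$direction <- ifelse(
      !is.na(out$q_value) & out$q_value < alpha & out$median_diff > 0, "hyper_a",
      ifelse(!is.na(out$q_value) & out$q_value < alpha & out$median_diff < 0,
             "hyper_b", "unchanged"))
  } else {
    out$q_value <- NA_real_
    out$direction <- ifelse(out$log2_wmr_ratio > 0, "hyper_a",
                            ifelse(out$log2_wmr_ratio < 0, "hyper_b",
                                   "unchanged"))
  }
  out <- select(out, "transcript_id", "tx_key", "gene_key", "wmr_a", "wmr_b",
                "log2_wmr_ratio", "median_diff", "p_value", "q_value",
                "direction")
  attr(out, "mode") <- if (replicate_mode) "replicate" else "pooled"
  attr(out, "group_names") <- names(groups)
  attr(out, "exclusive") <- excl
  out
}
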