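# Automated entry points: part 1 (per-sample descriptive statistics),
# part 2 (two-group comparison + expression integration), and genomic
# annotation. TSVs are the canonical outputs; the HTML report is a plain
# view assembled from the very tables that were written, never a
# recomputation.

# format a table exactly as it is written to TSV, for the HTML view
.fmt_df <- function(df) {
  out <- as.data.frame(df)
  for (j in seq_along(out)) out[[j]] <- as.character(out[[j]])
  out
}

.html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# minimal static HTML report: one section per table
render_html_report <- function(sections, path, title = "m6apost report") {
  esc <- .html_escape
  lines <- c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
             sprintf("<title>%s</title>", esc(title)),
             "<style>table{border-collapse:collapse}td,th{border:1px solid #999;padding:2px 6px;font:13px monospace}</style>",
             "</head><body>", sprintf("<h1>%s</h1>", esc(title)))
  for (nm in names(sections)) {
    df <- .fmt_df(sections[[nm]])
    lines <- c(lines, sprintf("<h2>%s</h2>", esc(nm)), "<table>",
               paste0("<tr>", paste0("<th>", esc(names(df)), "</th>",
                                     collapse = ""), "</tr>"))
    for (i in seq_len(nrow(df))) {
      lines <- c(lines, paste0("<tr>", paste0("<td>", esc(unlist(df[i, ])),
                                              "</td>", collapse = ""), "</tr>"))
    }
    lines <- c(lines, "</table>")
  }
  lines <- c(lines, "</body></html>")
  writeLines(lines, path)
  invisible(path)
}

.write_section <- function(df, out_dir, name) {
  write_tsv_plain(.fmt_df(df), file.path(out_dir, paste0(name, ".tsv")))
  df
}

#' Part 1: descriptive statistics report
#'
#' For every input sample: loads and filters the site table, then runs
#' the full set of descriptive summaries (counts, sites per transcript,
#' transcripts per gene, k-mer/DRACH usage, biotype frequencies,
#' transcript length bins, chromosome distribution of modified genes,
#' metagene positions and their kernel density). Each table is written as
#' a TSV under `out_dir` and collected into `report_part1.html`.
#'
#' @param sites_files Named character vector: sample label -> site CSV
#'   path.
#' @param gtf_file Path to the GTF annotation.
#' @param out_dir Output directory (created if needed).
#' @param threshold Probability threshold for [filter_sites()].
#' @param position_base Coordinate convention of the input positions.
#' @param column_map Passed to [read_site_proba()].
#' @param plots Also render per-sample metagene density PNGs? The TSVs
#'   remain the canonical output either way.
#' @return Invisibly, a nested list of the per-sample tables.
#' @export
run_part1 <- function(sites_files, gtf_file, out_dir, threshold = 0.9,
                      position_base = 0, column_map = NULL, plots = FALSE) {
  if (is.null(names(sites_files)) || any(!nzchar(names(sites_files)))) {
    stop("sites_files must be a named vector (sample label = path)", call. = FALSE)
  }
  if (missing(gtf_file) || is.null(gtf_file) || !file.exists(gtf_file)) {
    stop("a GTF annotation file is required", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  models <- read_gtf(gtf_file)

  sections <- list()
  results <- list()
  for (label in names(sites_files)) {
    sites <- read_site_proba(sites_files[[label]], sample_id = label,
                             column_map = column_map,
                             position_base = position_base)
    kept <- filter_sites(sites, threshold)
    if (nrow(kept) == 0) {
      warning(sprintf("sample %s: no sites pass probability > %g",
                      label, threshold), call. = FALSE)
    }
    cs <- count_summary(kept, models)
    tabs <- list(
      summary_counts = tibble::as_tibble(cs[c("n_sites", "n_transcripts",
                                              "n_genes",
                                              "n_unmatched_transcripts")]),
      sites_per_transcript = sites_per_transcript(kept),
      transcripts_per_gene = transcripts_per_gene(kept, models),
      kmer_frequency = kmer_frequency(kept),
      biotype_summary = biotype_summary(kept, models),
      transcript_length_bins = transcript_length_bins(kept, models),
      chromosome_distribution = chromosome_distribution(kept, models)
    )
    mp <- metagene_positions(kept, models)
    tabs$metagene_positions <- mp
    if (nrow(mp) >= 2) {
      tabs$metagene_density <- metagene_density(mp)
      if (plots) {
        grDevices::png(file.path(out_dir, paste0(label, "_metagene.png")),
                       width = 900, height = 500)
        d <- tabs$metagene_density
        plot(d$x, d$density, type = "l", xlab = "scaled position (5'UTR|CDS|3'UTR)",
             ylab = "density", main = paste("metagene profile:", label))
        graphics::abline(v = c(1, 2), lty = 2, col = "grey50")
        grDevices::dev.off()
      }
    }

    for (nm in names(tabs)) {
      .write_section(tabs[[nm]], out_dir, paste0(label, "_", nm))
      sections[[paste(label, nm, sep = ": ")]] <- tabs[[nm]]
    }
    results[[label]] <- tabs
  }
  render_html_report(sections, file.path(out_dir, "report_part1.html"),
                     title = "m6A descriptive statistics (part 1)")
  invisible(results)
}

#' Part 2: two-group comparative report
#'
#' Loads the per-replicate site tables of exactly two groups, reports
#' common/unique sites, transcripts and genes, computes the WMR matrix,
#' runs differential methylation (replicate mode is auto-detected from
#' >= 2 files per group) and, when a DGE table is given, the six-category
#' methylation-by-expression integration with biotype summaries (and
#' region summaries in pooled mode, or always with
#' `region_summary = TRUE`). Tables go to TSVs under `out_dir` plus
#' `report_part2.html`; the scatter-plot data (log2 WMR ratio vs log2
#' fold change) is written as `scatter_data.tsv`.
#'
#' @param groups Named list of exactly two character vectors of site CSV
#'   paths (one per replicate).
#' @param gtf_file Path to the GTF annotation.
#' @param dge_file Optional DGE table path (integration skipped without
#'   it, with a warning).
#' @param out_dir Output directory.
#' @param threshold,alpha,lfc_min,pseudo,position_base,column_map
#'   Analysis parameters (see the underlying functions).
#' @param region_summary Force the per-category region summary even in
#'   replicate mode.
#' @return Invisibly, a list of the computed tables.
#' @export
run_part2 <- function(groups, gtf_file, dge_file = NULL, out_dir,
                      threshold = 0.9, alpha = 0.05, lfc_min = 0,
                      pseudo = 1e-6, position_base = 0, column_map = NULL,
                      region_summary = FALSE) {
  if (length(groups) != 2 || is.null(names(groups))) {
    stop("exactly 2 named groups are required", call. = FALSE)
  }
  if (missing(gtf_file) || is.null(gtf_file) || !file.exists(gtf_file)) {
    stop("a GTF annotation file is required", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  models <- read_gtf(gtf_file)

  all_sites <- list()
  sample_groups <- list()
  for (g in names(groups)) {
    paths <- groups[[g]]
    labels <- sprintf("%s_rep%d", g, seq_along(paths))
    for (i in seq_along(paths)) {
      all_sites[[labels[i]]] <- read_site_proba(paths[i], sample_id = labels[i],
                                                column_map = column_map,
                                                position_base = position_base)
    }
    sample_groups[[g]] <- labels
  }
  sites <- filter_sites(bind_rows(all_sites), threshold)

  by_group <- lapply(names(groups), function(g) {
    sites[sites$sample_id %in% sample_groups[[g]], , drop = FALSE]
  })
  names(by_group) <- names(groups)
  overlap <- group_overlap(by_group, models)

  wmr <- compute_wmr(sites, models)
  wmr_matrix <- tidyr::pivot_wider(
    select(wmr, "transcript_id", "sample_id", "wmr"),
    names_from = "sample_id", values_from = "wmr")
  diff <- diff_methylation(wmr, sample_groups, alpha = alpha, pseudo = pseudo)

  tabs <- list(group_overlap = overlap, wmr_matrix = wmr_matrix,
               diffmeth = diff,
               group_exclusive = attr(diff, "exclusive"))

  if (!is.null(dge_file)) {
    dge <- read_dge(dge_file)
    records <- classify_integration(diff, dge, models, alpha = alpha,
                                    lfc_min = lfc_min, sites = sites)
    tabs$integration <- records
    tabs$category_biotype_summary <- category_biotype_summary(records)
    if (attr(diff, "mode") == "pooled" || region_summary) {
      tabs$category_region_summary <-
        category_region_summary(records, sites, models)
    }
    tabs$scatter_data <- records %>%
      select("transcript_id", "gene_id", "log2_wmr_ratio", "log2fc",
             "category") %>%
      filter(!is.na(.data$log2fc))
  } else {
    warning("no DGE table supplied; methylation-expression integration skipped",
            call. = FALSE)
  }

  for (nm in names(tabs)) .write_section(tabs[[nm]], out_dir, nm)
  render_html_report(tabs, file.path(out_dir, "report_part2.html"),
                     title = "m6A comparative analysis (part 2)")
  invisible(tabs)
}

#' Genomic projection and BED annotation
#'
#' Projects high-confidence sites to genomic coordinates, writes them as
#' a BED6 track, and (when feature BEDs are supplied) intersects them
#' with each feature file, writing per-source overlap TSVs and a summary.
#'
#' @param sites_file Site CSV path.
#' @param gtf_file Path to the GTF annotation.
#' @param bed_files Optional named character vector: feature label ->
#'   BED path.
#' @param out_dir Output directory.
#' @param sample_id Label for the sites.
#' @param threshold Probability threshold.
#' @param width_mode `"base"` or `"kmer"` (see [project_sites()]).
#' @param stranded Passed to [intersect_features()].
#' @param position_base,column_map Passed to [read_site_proba()].
#' @return Invisibly, a list with `projected`, `overlaps` and `summary`.
#' @export
run_annotate <- function(sites_file, gtf_file, bed_files = NULL, out_dir,
                         sample_id = "sample", threshold = 0.9,
                         width_mode = "base", stranded = FALSE,
                         position_base = 0, column_map = NULL) {
  if (missing(gtf_file) || is.null(gtf_file) || !file.exists(gtf_file)) {
    stop("a GTF annotation file is required", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  models <- read_gtf(gtf_file)
  sites <- filter_sites(read_site_proba(sites_file, sample_id = sample_id,
                                        column_map = column_map,
                                        position_base = position_base),
                        threshold)
  projected <- project_sites(sites, models, width_mode = width_mode)
  write_bed(projected, file.path(out_dir, paste0(sample_id, "_sites.bed")))

  overlaps <- NULL
  summary <- NULL
  if (!is.null(bed_files) && length(bed_files)) {
    if (is.null(names(bed_files))) names(bed_files) <- basename(bed_files)
    ov <- lapply(names(bed_files), function(lab) {
      intersect_features(projected, read_bed(bed_files[[lab]]),
                         stranded = stranded, label = lab)
    })
    overlaps <- bind_rows(ov)
    for (lab in names(bed_files)) {
      .write_section(overlaps[overlaps$feature_source == lab, , drop = FALSE],
                     out_dir, paste0("overlaps_", lab))
    }
    summary <- annotation_summary(overlaps)
    .write_section(summary, out_dir, "annotation_summary")
  }
  invisible(list(projected = projected, overlaps = overlaps,
                 summary = summary))
}
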