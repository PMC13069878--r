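# Interval intersection of projected m6A sites with genomic feature BEDs
# (RBP binding sites, SNPs, miRNA target sites, ...). Half-open semantics
# throughout: touching intervals do not overlap.

#' Intersect projected m6A sites with genomic features
#'
#' Reports every (site, feature) pair sharing at least 1 bp on the same
#' chromosome. Intersection is unstranded by default (SNP BEDs usually
#' carry no strand); with `stranded = TRUE` pairs on opposite defined
#' strands are dropped, while `"."` on either side still matches both
#' strands. Chromosome names are compared after normalizing a `chr`
#' prefix, with a warning when the two inputs use different conventions.
#'
#' @param sites Projected site intervals from [project_sites()] (any
#'   tibble with `chrom`, `start`, `end`, `name`, `strand`).
#' @param features Feature intervals from [read_bed()].
#' @param stranded Require strand agreement (see above)?
#' @param label Feature-source label recorded on every overlap row.
#' @return Tibble of overlap records: `site_name`, `site_chrom`,
#'   `site_start`, `site_end`, `site_strand`, `feature_name`,
#'   `feature_start`, `feature_end`, `feature_strand`, `feature_source`,
#'   `overlap_bp`.
#' @export
intersect_features <- function(sites, features, stranded = FALSE,
                               label = "features") {
  empty <- tibble::tibble(
    site_name = character(0), site_chrom = character(0),
    site_start = integer(0), site_end = integer(0),
    site_strand = character(0),
    feature_name = character(0), feature_start = integer(0),
    feature_end = integer(0), feature_strand = character(0),
    feature_source = character(0), overlap_bp = integer(0)
  )
  if (nrow(sites) == 0 || nrow(features) == 0) return(empty)

  if (length(intersect(unique(sites$chrom), unique(features$chrom))) == 0 &&
      length(intersect(norm_chrom(sites$chrom), norm_chrom(features$chrom))) > 0) {
    warning("site and feature chromosome names differ only by a 'chr' prefix; ",
            "normalizing for the intersection", call. = FALSE)
  }

  q <- GenomicRanges::GRanges(
    seqnames = norm_chrom(sites$chrom),
    ranges = IRanges::IRanges(start = sites$start + 1L, end = sites$end)
  )
  s <- GenomicRanges::GRanges(
    seqnames = norm_chrom(features$chrom),
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end)
  )
  suppressWarnings(
    hits <- GenomicRanges::findOverlaps(q, s, minoverlap = 1L,
                                        ignore.strand = TRUE)
  )
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  if (stranded) {
    ss <- sites$strand[qi]
    fs <- features$strand[si]
    keep <- ss == "." | fs == "." | ss == fs
    qi <- qi[keep]
    si <- si[keep]
  }
  if (length(qi) == 0) return(empty)
  tibble::tibble(
    site_name = sites$name[qi],
    site_chrom = sites$chrom[qi],
    site_start = sites$start[qi],
    site_end = sites$end[qi],
    site_strand = sites$strand[qi],
    feature_name = features$name[si],
    feature_start = features$start[si],
    feature_end = features$end[si],
    feature_strand = features$strand[si],
    feature_source = label,
    overlap_bp = as.integer(pmin(sites$end[qi], features$end[si]) -
                              pmax(sites$start[qi], features$start[si]))
  )
}

#' Summarise overlaps per feature source
#'
#' @param overlaps Tibble of overlap records from [intersect_features()]
#'   (rows from several sources may be concatenated).
#' @return Tibble `(feature_source, n_overlaps, n_sites_overlapping,
#'   n_features_hit)`; distinct sites are identified by name and
#'   coordinates, distinct features by name and coordinates.
#' @export
annotation_summary <- function(overlaps) {
  if (nrow(overlaps) == 0) {
    return(tibble::tibble(feature_source = character(0),
                          n_overlaps = integer(0),
                          n_sites_overlapping = integer(0),
                          n_features_hit = integer(0)))
  }
  overlaps %>%
    group_by(.data$feature_source) %>%
    summarise(
      n_overlaps = n(),
      n_sites_overlapping = dplyr::n_distinct(
        paste(.data$site_name, .data$site_chrom, .data$site_start, .data$site_end)),
      n_features_hit = dplyr::n_distinct(
        paste(.data$feature_name, .data$feature_start, .data$feature_end)),
      .groups = "drop"
    )
}
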