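# Deterministic synthetic-data generator: a toy annotated genome, m6Anet-style
# site tables for two conditions with replicates, a DGE table and feature BEDs,
# together with a machine-readable truth record of everything that was planted.
# The generator keeps its own per-base coordinate bookkeeping (independent of
# the projection code under test) and tallies its truth values with base R.

#' Specification for the synthetic dataset
#'
#' Defaults emulate a two-condition m6Anet comparison with three technical
#' replicates per condition: mostly protein-coding modified transcripts,
#' predominantly single-site transcripts, DRACH-dominated k-mer usage, a
#' 3'UTR-biased site distribution, and hypermethylation planted in a
#' subset of transcripts as a shift of the site modification ratios.
#'
#' @param n_genes Number of genes.
#' @param transcripts_per_gene Transcripts per gene.
#' @param exons_per_transcript Length-2 integer range for the number of
#'   exons per transcript.
#' @param biotype_mix Named probabilities over transcript biotypes
#'   (must sum to 1); `protein_coding` and `nonsense_mediated_decay`
#'   transcripts receive a CDS.
#' @param chroms Chromosome names of the toy genome.
#' @param sites_per_transcript_probs Named probabilities: number of m6A
#'   sites per modified transcript.
#' @param drach_fraction Fraction of sites drawn from the 18 DRACH 5-mers.
#' @param modified_fraction Fraction of transcripts carrying any site.
#' @param highconf_fraction Fraction of sites with modification
#'   probability above `threshold` (the rest are low-confidence decoys).
#' @param threshold High-confidence probability cut-off used for the
#'   truth tallies.
#' @param groups Two condition labels.
#' @param n_replicates Replicates per condition.
#' @param planted_fraction Fraction of the common coding transcripts
#'   planted as hypermethylated, per direction.
#' @param delta Modification-ratio shift of planted transcripts.
#' @param noise_sd Per-replicate Gaussian noise on modification ratios.
#' @param utr3_peak_fraction Fraction of coding-transcript sites placed
#'   just past the stop codon (start of the 3'UTR).
#' @param seed RNG seed; one pseudo-random stream drives the whole
#'   dataset, so a given spec is fully reproducible.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_genes = 30,
                         transcripts_per_gene = 2,
                         exons_per_transcript = c(1, 4),
                         biotype_mix = c(protein_coding = 0.70,
                                         retained_intron = 0.11,
                                         nonsense_mediated_decay = 0.11,
                                         lncRNA = 0.08),
                         chroms = c("chr1", "chr2", "chr11", "chr17", "chr19"),
                         sites_per_transcript_probs = c("1" = 0.45, "2" = 0.25,
                                                        "3" = 0.12, "4" = 0.08,
                                                        "5" = 0.06, "6" = 0.04),
                         drach_fraction = 0.9,
                         modified_fraction = 0.85,
                         highconf_fraction = 0.85,
                         threshold = 0.9,
                         groups = c("groupA", "groupB"),
                         n_replicates = 3,
                         planted_fraction = 0.2,
                         delta = 0.3,
                         noise_sd = 0.04,
                         utr3_peak_fraction = 0.6,
                         seed = 1) {
  spec <- list(n_genes = n_genes, transcripts_per_gene = transcripts_per_gene,
               exons_per_transcript = exons_per_transcript,
               biotype_mix = biotype_mix, chroms = chroms,
               sites_per_transcript_probs = sites_per_transcript_probs,
               drach_fraction = drach_fraction,
               modified_fraction = modified_fraction,
               highconf_fraction = highconf_fraction,
               threshold = threshold, groups = groups,
               n_replicates = n_replicates,
               planted_fraction = planted_fraction, delta = delta,
               noise_sd = noise_sd, utr3_peak_fraction = utr3_peak_fraction,
               seed = seed)
  if (abs(sum(biotype_mix) - 1) > 1e-9) stop("biotype_mix must sum to 1", call. = FALSE)
  if (abs(sum(sites_per_transcript_probs) - 1) > 1e-9) {
    stop("sites_per_transcript_probs must sum to 1", call. = FALSE)
  }
  if (length(groups) != 2) stop("exactly two groups are generated", call. = FALSE)
  if (delta < 0 || delta > 0.8) stop("delta must keep ratios clippable to [0,1]", call. = FALSE)
  class(spec) <- "fixture_spec"
  spec
}

# genomic positions of a transcript's bases in 5'->3' transcript order
.tx_base_map <- function(exons, strand) {
  bases <- unlist(mapply(function(s, e) seq.int(s, e - 1L), exons$start,
                         exons$end, SIMPLIFY = FALSE))
  if (strand == "-") rev(bases) else bases
}

# consecutive genomic positions -> 0-based half-open intervals
.runs_to_intervals <- function(g) {
  g <- sort(unique(as.integer(g)))
  run <- cumsum(c(1L, diff(g) != 1L))
  do.call(rbind, lapply(split(g, run), function(gs) {
    data.frame(start = min(gs), end = max(gs) + 1L)
  }))
}

#' Generate the toy annotated genome
#'
#' Lays out non-overlapping gene loci (toy chromosomes stay under 100 kb),
#' draws exon/intron structures and biotypes, assigns CDS spans to coding
#' biotypes, writes a GENCODE-dialect GTF and returns the matching
#' `tx_models` built directly from the generator's own bookkeeping.
#'
#' @param spec A [fixture_spec()]. The caller is responsible for seeding
#'   the RNG ([simulate_dataset()] does).
#' @param path Output GTF path.
#' @return A `tx_models` object (identical in content to
#'   `read_gtf(path)`).
#' @export
generate_genome <- function(spec, path) {
  coding_biotypes <- c("protein_coding", "nonsense_mediated_decay")
  min_exon <- 80L
  if (min_exon < 5) stop("exons must be at least as long as the 5-mer", call. = FALSE)
  cursor <- setNames(rep(1000L, length(spec$chroms)), spec$chroms)
  rows <- list()
  exon_list <- list()
  cds_list <- list()
  gtf_lines <- character(0)

  for (gi in seq_len(spec$n_genes)) {
    chrom <- sample(spec$chroms, 1)
    strand <- sample(c("+", "-"), 1)
    gene_id <- sprintf("G%03d.1", gi)
    gene_name <- sprintf("GENE%03d", gi)
    gene_start <- cursor[[chrom]]
    gene_end <- gene_start

    for (ti in seq_len(spec$transcripts_per_gene)) {
      tx_id <- sprintf("TX%03d%s.1", gi, letters[ti])
      key <- strip_tx_version(tx_id)
      biotype <- sample(names(spec$biotype_mix), 1, prob = spec$biotype_mix)
      n_ex <- sample(seq(spec$exons_per_transcript[1],
                         spec$exons_per_transcript[2]), 1)
      ex_len <- sample(min_exon:300, n_ex, replace = TRUE)
      gaps <- if (n_ex > 1) sample(50:400, n_ex - 1, replace = TRUE) else integer(0)
      s0 <- gene_start + sample(0:80, 1)
      starts <- s0 + c(0L, cumsum(ex_len[-n_ex] + gaps))
      exons <- data.frame(start = as.integer(starts),
                          end = as.integer(starts + ex_len))
      total <- sum(ex_len)
      gene_end <- max(gene_end, max(exons$end))

      if (biotype %in% coding_biotypes && total >= 120) {
        utr5 <- sample(20:min(80, total - 100), 1)
        utr3 <- sample(20:min(120, total - utr5 - 60), 1)
        cds_len <- total - utr5 - utr3
        bases <- .tx_base_map(exons, strand)
        cds_iv <- .runs_to_intervals(bases[(utr5 + 1):(utr5 + cds_len)])
      } else {
        utr5 <- 0L; utr3 <- 0L; cds_len <- 0L
        cds_iv <- data.frame(start = integer(0), end = integer(0))
        if (biotype %in% coding_biotypes) biotype <- "retained_intron"
      }

      rows[[tx_id]] <- data.frame(
        transcript_id = tx_id, tx_key = key,
        gene_id = gene_id, gene_key = strip_tx_version(gene_id),
        gene_name = gene_name, chrom = chrom, strand = strand,
        biotype = biotype, n_exons = n_ex,
        length_total = as.integer(total),
        length_utr5 = as.integer(utr5),
        length_cds = as.integer(cds_len),
        length_utr3 = as.integer(utr3),
        stringsAsFactors = FALSE
      )
      exon_list[[key]] <- exons
      cds_list[[key]] <- cds_iv

      attrs <- sprintf(
        'gene_id "%s"; transcript_id "%s"; gene_name "%s"; transcript_biotype "%s";',
        gene_id, tx_id, gene_name, biotype)
      feat <- function(type, iv) {
        sprintf("%s\ttoygen\t%s\t%d\t%d\t.\t%s\t.\t%s",
                chrom, type, iv$start + 1L, iv$end, strand, attrs)
      }
      gtf_lines <- c(gtf_lines, feat("exon", exons),
                     if (nrow(cds_iv)) feat("CDS", cds_iv))
    }
    cursor[[chrom]] <- gene_end + 800L
  }
  if (any(cursor > 100000L)) stop("toy chromosome exceeded 100 kb", call. = FALSE)
  writeLines(gtf_lines, path)

  structure(list(transcripts = tibble::as_tibble(bind_rows(rows)),
                 exons = exon_list, cds = cds_list),
            class = "tx_models")
}

# a random non-DRACH 5-mer
.non_drach_kmer <- function() {
  repeat {
    k <- paste(sample(c("A", "C", "G", "T"), 5, replace = TRUE), collapse = "")
    if (!is_drach(k)) return(k)
  }
}

#' Generate m6Anet-style site tables for every group and replicate
#'
#' Chooses which transcripts are modified and in which condition(s),
#' plants hypermethylation (a `delta` shift of all site modification
#' ratios) in disjoint gene sets for each direction, draws site
#' positions (3'UTR-biased on coding transcripts), k-mers and
#' probabilities, and writes one `data.site_proba.csv`-dialect file per
#' group x replicate. Site identities and probabilities are shared across
#' replicates; modification ratios get independent per-replicate noise.
#'
#' @param spec A [fixture_spec()].
#' @param models Output of [generate_genome()].
#' @param dir Output directory for the CSVs.
#' @return A list: `files` (named group -> vector of CSV paths), `sites`
#'   (the generator's internal site table including group means), and
#'   `planted` (`hyper_a`, `hyper_b`, `null` transcript keys).
#' @export
generate_sites <- function(spec, models, dir) {
  tr <- models$transcripts
  modified <- tr$tx_key[runif(nrow(tr)) < spec$modified_fraction]
  membership <- sample(c("both", "a_only", "b_only"), length(modified),
                       replace = TRUE, prob = c(0.7, 0.15, 0.15))
  names(membership) <- modified

  coding <- tr$tx_key[tr$length_cds > 0]
  candidates <- modified[membership == "both" & modified %in% coding]
  cand_genes <- unique(tr$gene_key[match(candidates, tr$tx_key)])
  cand_genes <- sample(cand_genes)
  n_target <- max(1L, round(spec$planted_fraction * length(candidates)))
  pool <- setNames(rep("null", length(candidates)), candidates)
  counts <- c(hyper_a = 0L, hyper_b = 0L)
  for (g in cand_genes) {
    gtx <- candidates[tr$gene_key[match(candidates, tr$tx_key)] == g]
    side <- if (counts[["hyper_a"]] <= counts[["hyper_b"]]) "hyper_a" else "hyper_b"
    if (counts[[side]] >= n_target) side <- setdiff(c("hyper_a", "hyper_b"), side)
    if (counts[[side]] >= n_target) break
    pool[gtx] <- side
    counts[[side]] <- counts[[side]] + length(gtx)
  }

  drach <- drach_kmers()
  site_rows <- list()
  for (tx in modified) {
    m <- tr[tr$tx_key == tx, ]
    len <- m$length_total
    if (len < 10) next
    k <- as.integer(sample(names(spec$sites_per_transcript_probs), 1,
                           prob = spec$sites_per_transcript_probs))
    valid <- 2:(len - 3)
    pos <- integer(0)
    for (i in seq_len(k)) {
      cand <- setdiff(valid, pos)
      if (!length(cand)) break
      if (m$length_cds > 0 && runif(1) < spec$utr3_peak_fraction) {
        u3_start <- m$length_utr5 + m$length_cds
        win <- intersect(u3_start + 0:min(30, m$length_utr3 - 1), cand)
        pos <- c(pos, if (length(win)) sample(win, 1) else sample(cand, 1))
      } else {
        pos <- c(pos, if (length(cand) == 1) cand else sample(cand, 1))
      }
    }
    for (p in pos) {
      kmer <- if (runif(1) < spec$drach_fraction) sample(drach, 1) else .non_drach_kmer()
      prob <- if (runif(1) < spec$highconf_fraction) {
        runif(1, spec$threshold + 0.005, 0.999)
      } else {
        runif(1, 0.4, spec$threshold - 0.005)
      }
      base <- runif(1, 0.15, 0.55)
      eff <- pool[tx]
      if (is.na(eff)) eff <- "null"
      mean_a <- min(base + if (eff == "hyper_a") spec$delta else 0, 0.99)
      mean_b <- min(base + if (eff == "hyper_b") spec$delta else 0, 0.99)
      site_rows[[length(site_rows) + 1]] <- data.frame(
        tx_key = tx,
        transcript_id = tx,  # site tables carry unversioned ids
        transcript_position = p, kmer = kmer, prob_modified = prob,
        n_reads = sample(20:200, 1),
        membership = membership[[tx]],
        mean_a = mean_a, mean_b = mean_b,
        stringsAsFactors = FALSE
      )
    }
  }
  site_tab <- bind_rows(site_rows)

  files <- list()
  clip <- function(x) pmin(pmax(x, 0.01), 0.99)
  for (g_idx in 1:2) {
    group <- spec$groups[g_idx]
    keep <- site_tab$membership %in% c("both", if (g_idx == 1) "a_only" else "b_only")
    sub <- site_tab[keep, , drop = FALSE]
    mean_col <- if (g_idx == 1) sub$mean_a else sub$mean_b
    paths <- character(spec$n_replicates)
    for (r in seq_len(spec$n_replicates)) {
      ratio <- clip(mean_col + stats::rnorm(nrow(sub), 0, spec$noise_sd))
      out <- data.frame(
        transcript_id = sub$transcript_id,
        transcript_position = sub$transcript_position,
        n_reads = sub$n_reads,
        probability_modified = round(sub$prob_modified, 6),
        kmer = sub$kmer,
        mod_ratio = round(ratio, 6)
      )
      paths[r] <- file.path(dir, sprintf("sites_%s_rep%d.csv", group, r))
      write.table(out, paths[r], sep = ",", quote = FALSE, row.names = FALSE)
    }
    files[[group]] <- paths
  }

  list(files = files, sites = tibble::as_tibble(site_tab),
       planted = list(hyper_a = names(pool)[pool == "hyper_a"],
                      hyper_b = names(pool)[pool == "hyper_b"],
                      null = names(pool)[pool == "null"]))
}

#' Generate a DESeq2-shaped differential-expression table
#'
#' Planted hypermethylated transcripts' genes receive expression calls
#' cycling through up / down / not-significant, fixing each planted
#' transcript's expected integration category; all other genes get null
#' statistics.
#'
#' @param spec A [fixture_spec()].
#' @param models `tx_models` from [generate_genome()].
#' @param planted Planted sets from [generate_sites()].
#' @param path Output TSV path (`gene_id`, `log2FoldChange`, `padj`).
#' @return A list: `dge` (tibble as written) and `categories` (named
#'   character vector: planted transcript key -> expected six-way
#'   category).
#' @export
generate_dge <- function(spec, models, planted, path) {
  tr <- models$transcripts
  genes <- unique(tr$gene_key)
  lfc <- stats::rnorm(length(genes), 0, 0.5)
  padj <- runif(length(genes), 0.2, 0.95)
  names(lfc) <- names(padj) <- genes

  categories <- character(0)
  assign_expr <- function(tx_keys, meth_label) {
    gk <- unique(tr$gene_key[match(tx_keys, tr$tx_key)])
    classes <- rep(c("up", "down", "ns"), length.out = length(gk))
    for (i in seq_along(gk)) {
      g <- gk[i]
      if (classes[i] == "up") {
        lfc[[g]] <<- runif(1, 1, 3)
        padj[[g]] <<- runif(1, 1e-5, 0.01)
      } else if (classes[i] == "down") {
        lfc[[g]] <<- -runif(1, 1, 3)
        padj[[g]] <<- runif(1, 1e-5, 0.01)
      } else {
        lfc[[g]] <<- stats::rnorm(1, 0, 0.3)
        padj[[g]] <<- runif(1, 0.3, 0.95)
      }
      gtx <- tx_keys[tr$gene_key[match(tx_keys, tr$tx_key)] == g]
      categories[gtx] <<- paste(meth_label, classes[i], sep = "_")
    }
  }
  assign_expr(planted$hyper_a, "hyper")
  assign_expr(planted$hyper_b, "hypo")

  dge <- tibble::tibble(gene_id = genes,
                        log2FoldChange = round(unname(lfc), 5),
                        padj = round(unname(padj), 6))
  write.table(dge, path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(dge = dge, categories = categories)
}

#' Generate feature BEDs with planted overlaps
#'
#' Builds an RBP-like BED (25 bp windows around a subset of
#' high-confidence group-A site positions, UCSC-style `chr` names) and a
#' SNP-like BED (1 bp features, Ensembl-style names without the `chr`
#' prefix, strand `"."`), plus non-overlapping decoy features placed
#' beyond the gene loci. Overlap truth is tallied by an all-pairs scan of
#' the generator's own site coordinates.
#'
#' @param spec A [fixture_spec()].
#' @param models `tx_models` from [generate_genome()].
#' @param sites Generator site table from [generate_sites()].
#' @param dir Output directory.
#' @return A list: `files` (named `rbp`/`snp`) and `truth` (per label:
#'   `n_sites_overlapping`, `n_features_hit`), relative to the
#'   high-confidence group-A sites in single-base mode.
#' @export
generate_features <- function(spec, models, sites, dir) {
  tr <- models$transcripts
  kept <- sites[sites$prob_modified > spec$threshold &
                  sites$membership %in% c("both", "a_only"), , drop = FALSE]
  gpos <- vapply(seq_len(nrow(kept)), function(i) {
    key <- kept$tx_key[i]
    bases <- .tx_base_map(models$exons[[key]],
                          tr$strand[match(key, tr$tx_key)])
    bases[kept$transcript_position[i] + 1L]
  }, numeric(1))
  site_df <- data.frame(chrom = tr$chrom[match(kept$tx_key, tr$tx_key)],
                        start = as.integer(gpos), end = as.integer(gpos) + 1L,
                        strand = tr$strand[match(kept$tx_key, tr$tx_key)])

  max_end <- max(unlist(lapply(models$exons, function(e) e$end)))
  decoy_start <- max_end + 5000L

  make_bed <- function(n_hit, width_lo, width_hi, n_decoy, prefix, chr_style,
                       use_strand) {
    hit_idx <- sample(seq_len(nrow(site_df)), min(n_hit, nrow(site_df)))
    f_start <- pmax(0L, site_df$start[hit_idx] - sample(0:width_lo, length(hit_idx), TRUE))
    f_end <- site_df$end[hit_idx] + sample(0:width_hi, length(hit_idx), TRUE)
    hits <- data.frame(chrom = site_df$chrom[hit_idx], start = f_start, end = f_end,
                       strand = if (use_strand) site_df$strand[hit_idx] else ".")
    decoys <- data.frame(
      chrom = sample(spec$chroms, n_decoy, replace = TRUE),
      start = decoy_start + sample(seq(0, 4000, by = 40), n_decoy),
      strand = "."
    )
    decoys$end <- decoys$start + sample(10:30, n_decoy, replace = TRUE)
    bed <- rbind(hits, decoys[, c("chrom", "start", "end", "strand")])
    bed$name <- paste0(prefix, seq_len(nrow(bed)))
    bed$score <- 0
    if (chr_style == "ensembl") bed$chrom <- norm_chrom(bed$chrom)
    bed[, c("chrom", "start", "end", "name", "score", "strand")]
  }

  rbp <- make_bed(25, 10, 15, 15, "RBP_", "ucsc", use_strand = TRUE)
  snp <- make_bed(10, 0, 0, 10, "SNP_", "ensembl", use_strand = FALSE)

  truth_for <- function(bed) {
    ov_feat <- logical(nrow(bed))
    ov_site <- logical(nrow(site_df))
    for (i in seq_len(nrow(bed))) {
      same <- norm_chrom(site_df$chrom) == norm_chrom(bed$chrom[i])
      hit <- same & site_df$start < bed$end[i] & bed$start[i] < site_df$end
      ov_feat[i] <- any(hit)
      ov_site <- ov_site | hit
    }
    list(n_sites_overlapping = sum(ov_site), n_features_hit = sum(ov_feat))
  }
  truth <- list(rbp = truth_for(rbp), snp = truth_for(snp))

  rbp_path <- file.path(dir, "features_rbp.bed")
  snp_path <- file.path(dir, "features_snp.bed")
  write_bed(rbp, rbp_path)
  write_bed(snp, snp_path)
  list(files = c(rbp = rbp_path, snp = snp_path), truth = truth)
}

#' Generate the full synthetic dataset with its truth record
#'
#' Runs the genome, site, DGE and feature generators under a single
#' seeded random stream, writes everything to `dir` (GTF, per-replicate
#' site CSVs, DGE TSV, feature BEDs, `spec.json`, `truth.json`) and
#' tallies ground truth for the downstream summaries with independent
#' base-R brute force over the planted site table.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return A list with `spec`, `paths`, `models`, `sites` (generator site
#'   table) and `truth`.
#' @export
simulate_dataset <- function(spec = fixture_spec(), dir = tempfile("m6afix")) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed, kind = "Mersenne-Twister")

  gtf_path <- file.path(dir, "genome.gtf")
  models <- generate_genome(spec, gtf_path)
  gs <- generate_sites(spec, models, dir)
  dge_path <- file.path(dir, "dge.tsv")
  dg <- generate_dge(spec, models, gs$planted, dge_path)
  fx <- generate_features(spec, models, gs$sites, dir)

  tr <- models$transcripts
  per_group_truth <- function(memberships) {
    kept <- gs$sites[gs$sites$prob_modified > spec$threshold &
                       gs$sites$membership %in% memberships, , drop = FALSE]
    tx <- unique(kept$tx_key)
    gk <- unique(tr$gene_key[match(tx, tr$tx_key)])
    bt <- table(tr$biotype[match(tx, tr$tx_key)])
    ch <- table(tr$chrom[match(gk, tr$gene_key)])
    len <- tr$length_total[match(tx, tr$tx_key)]
    bins <- c("<=1000" = sum(len <= 1000),
              "1001-5000" = sum(len > 1000 & len <= 5000),
              "5001-10000" = sum(len > 5000 & len <= 10000),
              ">10000" = sum(len > 10000))
    spt <- table(table(kept$tx_key))
    list(n_sites = nrow(kept), n_transcripts = length(tx), n_genes = length(gk),
         biotype_fractions = as.list(setNames(as.numeric(bt) / length(tx), names(bt))),
         chrom_fractions = as.list(setNames(as.numeric(ch) / length(gk), names(ch))),
         length_bins = as.list(bins),
         sites_per_transcript = as.list(setNames(as.integer(spt), names(spt))),
         max_sites_per_transcript = max(as.integer(names(spt))))
  }

  kept_all <- gs$sites[gs$sites$prob_modified > spec$threshold, , drop = FALSE]
  key_a <- with(kept_all[kept_all$membership %in% c("both", "a_only"), ],
                paste(tx_key, transcript_position, sep = ":"))
  key_b <- with(kept_all[kept_all$membership %in% c("both", "b_only"), ],
                paste(tx_key, transcript_position, sep = ":"))
  overlap_truth <- list(
    site = list(common = length(intersect(key_a, key_b)),
                a_only = length(setdiff(key_a, key_b)),
                b_only = length(setdiff(key_b, key_a)))
  )
  tx_of <- function(keys) unique(sub(":.*$", "", keys))
  overlap_truth$transcript <- list(
    common = length(intersect(tx_of(key_a), tx_of(key_b))),
    a_only = length(setdiff(tx_of(key_a), tx_of(key_b))),
    b_only = length(setdiff(tx_of(key_b), tx_of(key_a)))
  )

  truth <- list(
    per_group = setNames(list(per_group_truth(c("both", "a_only")),
                              per_group_truth(c("both", "b_only"))),
                         spec$groups),
    overlap = overlap_truth,
    planted = list(hyper_a = gs$planted$hyper_a,
                   hyper_b = gs$planted$hyper_b,
                   null = gs$planted$null,
                   delta = spec$delta,
                   categories = as.list(dg$categories)),
    features = fx$truth
  )

  spec_path <- file.path(dir, "spec.json")
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(unclass(spec), spec_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  list(spec = spec,
       paths = list(gtf = gtf_path, sites = gs$files, dge = dge_path,
                    features = fx$files, truth = truth_path,
                    spec = spec_path, dir = dir),
       models = models, sites = gs$sites, truth = truth)
}
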