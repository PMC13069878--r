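# Shared test helpers: a cached synthetic dataset, hand-built transcript
# models, small site-table constructors and independent brute-force oracles.

.fixture_cache <- new.env(parent = emptyenv())

# one simulated dataset per test session (deterministic seed)
get_fixture <- function(seed = 101) {
  key <- paste0("fx", seed)
  if (is.null(.fixture_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("m6apost_fixture_", seed))
    .fixture_cache[[key]] <- simulate_dataset(fixture_spec(seed = seed), dir)
  }
  .fixture_cache[[key]]
}

# genomic positions of a transcript's bases in transcript (5'->3') order:
# the exhaustive per-base oracle for coordinate projection
oracle_base_map <- function(exons, strand) {
  bases <- unlist(mapply(function(s, e) seq.int(s, e - 1L),
                         exons$start, exons$end, SIMPLIFY = FALSE))
  if (strand == "-") rev(bases) else bases
}

# build a tx_models object by hand; lengths derived by base enumeration,
# independent of the package's GTF/projection arithmetic
mk_models <- function(defs) {
  rows <- list()
  exon_list <- list()
  cds_list <- list()
  for (tx in names(defs)) {
    d <- defs[[tx]]
    exons <- d$exons[order(d$exons$start), , drop = FALSE]
    cds <- d$cds %||% data.frame(start = integer(0), end = integer(0))
    bases <- oracle_base_map(exons, d$strand)
    total <- length(bases)
    if (nrow(cds)) {
      cds_bases <- unlist(mapply(function(s, e) seq.int(s, e - 1L),
                                 cds$start, cds$end, SIMPLIFY = FALSE))
      in_cds <- bases %in% cds_bases
      utr5 <- which(in_cds)[1] - 1L
      cds_len <- sum(in_cds)
    } else {
      utr5 <- 0L
      cds_len <- 0L
    }
    rows[[tx]] <- data.frame(
      transcript_id = tx, tx_key = strip_tx_version(tx),
      gene_id = d$gene_id %||% paste0("g_", tx),
      gene_key = strip_tx_version(d$gene_id %||% paste0("g_", tx)),
      gene_name = d$gene_name %||% (d$gene_id %||% paste0("g_", tx)),
      chrom = d$chrom %||% "chr1", strand = d$strand,
      biotype = d$biotype %||% "protein_coding",
      n_exons = nrow(exons),
      length_total = total, length_utr5 = utr5, length_cds = cds_len,
      length_utr3 = total - utr5 - cds_len,
      stringsAsFactors = FALSE
    )
    exon_list[[strip_tx_version(tx)]] <- exons
    cds_list[[strip_tx_version(tx)]] <- cds
  }
  structure(list(transcripts = tibble::as_tibble(dplyr::bind_rows(rows)),
                 exons = exon_list, cds = cds_list),
            class = "tx_models")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# quick site-table constructor
mk_sites <- function(transcript_id, transcript_position,
                     prob_modified = 0.95, mod_ratio = 0.5,
                     kmer = "GGACT", n_reads = 50L, sample_id = "s1") {
  tibble::tibble(
    transcript_id = transcript_id,
    transcript_position = as.integer(transcript_position),
    n_reads = as.integer(n_reads),
    prob_modified = prob_modified,
    kmer = kmer,
    mod_ratio = mod_ratio,
    sample_id = sample_id
  )
}

# random multi-exon transcript model (for property tests)
random_model <- function(id = "rtx", n_exons = sample(2:5, 1),
                         strand = sample(c("+", "-"), 1)) {
  len <- sample(5:60, n_exons, replace = TRUE)
  gap <- sample(1:100, n_exons, replace = TRUE)
  starts <- cumsum(gap + c(0, len[-n_exons]))
  list(transcript_id = id, strand = strand,
       exons = data.frame(start = starts, end = starts + len))
}

# O(n*m) all-pairs half-open interval intersection oracle (vectorized over
# the full index cross product; no sweep, no tree)
oracle_intersect <- function(a, b, stranded = FALSE) {
  i <- rep(seq_len(nrow(a)), times = nrow(b))
  j <- rep(seq_len(nrow(b)), each = nrow(a))
  lo <- pmax(a$start[i], b$start[j])
  hi <- pmin(a$end[i], b$end[j])
  ok <- sub("^chr", "", a$chrom[i]) == sub("^chr", "", b$chrom[j]) & hi > lo
  if (stranded) {
    ok <- ok & (a$strand[i] == "." | b$strand[j] == "." |
                  a$strand[i] == b$strand[j])
  }
  data.frame(i = i[ok], j = j[ok], bp = (hi - lo)[ok])
}

# full-enumeration two-sided rank-sum p-value (no ties assumed)
oracle_wilcoxon_p <- function(a, b) {
  n <- length(a)
  vals <- c(a, b)
  ranks <- rank(vals)
  w_obs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2  # Mann-Whitney U of group a
  combos <- utils::combn(length(vals), n)
  u_all <- apply(combos, 2, function(idx) sum(ranks[idx]) - n * (n + 1) / 2)
  mu <- n * length(b) / 2
  mean(abs(u_all - mu) >= abs(w_obs - mu))
}

# write a minimal GENCODE-dialect GTF (1-based inclusive) from 0-based specs
write_toy_gtf <- function(path, features) {
  # features: data.frame chrom,type,start,end,strand,gene_id,transcript_id,biotype
  lines <- sprintf(
    "%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\"; transcript_biotype \"%s\";",
    features$chrom, features$type, features$start + 1L, features$end,
    features$strand, features$gene_id, features$transcript_id,
    features$biotype)
  writeLines(lines, path)
  path
}
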