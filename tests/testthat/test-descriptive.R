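# Descriptive ("part 1") summaries of filtered high-confidence sites.

test_that("probability filtering is strictly greater-than and idempotent", {
  s <- mk_sites("tx1", c(1, 2, 3), prob_modified = c(0.95, 0.90, 0.89))
  kept <- filter_sites(s, 0.9)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$prob_modified, 0.95)
  expect_equal(as.data.frame(filter_sites(kept, 0.9)), as.data.frame(kept))
  expect_equal(nrow(filter_sites(s, 1)), 0)
  expect_equal(nrow(filter_sites(s, 0)), 3)
})

test_that("site/transcript/gene counts and per-unit frequencies agree", {
  models <- mk_models(list(
    a = list(strand = "+", exons = data.frame(start = 0, end = 1000),
             gene_id = "g1"),
    b = list(strand = "+", exons = data.frame(start = 2000, end = 3000),
             gene_id = "g1"),
    c = list(strand = "-", exons = data.frame(start = 5000, end = 6000),
             gene_id = "g2")))
  s <- mk_sites(c("a", "a", "a", "b", "b"), c(10, 20, 30, 10, 20))
  cs <- count_summary(s, models)
  expect_equal(cs[c("n_sites", "n_transcripts", "n_genes")],
               list(n_sites = 5L, n_transcripts = 2L, n_genes = 1L))

  spt <- sites_per_transcript(s)
  expect_equal(as.data.frame(spt),
               data.frame(n_sites = c(2L, 3L), n_transcripts = c(1L, 1L)),
               ignore_attr = TRUE)
  expect_equal(attr(spt, "max_sites"), 3L)
  # n_sites identity: sum over the frequency table of k * count
  expect_equal(sum(spt$n_sites * spt$n_transcripts), cs$n_sites)
  expect_equal(sum(spt$n_transcripts), cs$n_transcripts)

  tpg <- transcripts_per_gene(s, models)
  expect_equal(as.data.frame(tpg),
               data.frame(n_transcripts = 2L, n_genes = 1L),
               ignore_attr = TRUE)

  empty <- count_summary(s[0, ], models)
  expect_equal(empty[c("n_sites", "n_transcripts", "n_genes")],
               list(n_sites = 0L, n_transcripts = 0L, n_genes = 0L))
})

test_that("fixture counts match the generator truth and brute-force tallies", {
  fx <- get_fixture()
  models <- read_gtf(fx$paths$gtf)
  s <- filter_sites(read_site_proba(fx$paths$sites$groupA[1], "a1"),
                    fx$spec$threshold)
  truth <- fx$truth$per_group$groupA
  cs <- count_summary(s, models)
  expect_equal(cs$n_sites, truth$n_sites)
  expect_equal(cs$n_transcripts, truth$n_transcripts)
  expect_equal(cs$n_genes, truth$n_genes)
  # sites-per-transcript equals an independent group-by tally
  spt <- sites_per_transcript(s)
  brute <- table(table(s$transcript_id))
  expect_equal(setNames(spt$n_transcripts, spt$n_sites),
               setNames(as.integer(brute), names(brute)))
  expect_equal(sum(spt$n_sites * spt$n_transcripts), cs$n_sites)
})

test_that("the DRACH predicate equals explicit enumeration of the 18 5-mers", {
  dk <- drach_kmers()
  expect_length(dk, 18)
  expect_true(all(substr(dk, 3, 3) == "A"))
  all5 <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), 5)), 1,
                paste0, collapse = "")
  expect_equal(sort(all5[is_drach(all5)]), dk)
  expect_true(is_drach("GGACT"))
  expect_true(is_drach("GAACA"))
  expect_false(is_drach("TTTTT"))
  expect_false(is_drach("CGACT"))  # C not in D
})

test_that("k-mer frequencies sum to one and flag DRACH membership", {
  s <- mk_sites("t", 1:3, kmer = c("GGACT", "GGACT", "CAACA"))
  kf <- kmer_frequency(s)
  expect_equal(kf$kmer, c("GGACT", "CAACA"))
  expect_equal(kf$fraction, c(2 / 3, 1 / 3))
  expect_equal(kf$is_DRACH, c(TRUE, FALSE))
  expect_equal(sum(kf$fraction), 1, tolerance = 1e-9)
})

test_that("biotype composition counts distinct transcripts, not sites", {
  models <- mk_models(list(
    a = list(strand = "+", exons = data.frame(start = 0, end = 100),
             biotype = "protein_coding"),
    b = list(strand = "+", exons = data.frame(start = 0, end = 100),
             biotype = "protein_coding"),
    c = list(strand = "+", exons = data.frame(start = 0, end = 100),
             biotype = "protein_coding"),
    d = list(strand = "+", exons = data.frame(start = 0, end = 100),
             biotype = "retained_intron")))
  # many sites on 'a' must not inflate protein_coding
  s <- mk_sites(c("a", "a", "a", "b", "c", "d"), c(1, 2, 3, 1, 1, 1))
  bs <- biotype_summary(s, models)
  expect_equal(bs$fraction[bs$biotype == "protein_coding"], 0.75)
  expect_equal(bs$fraction[bs$biotype == "retained_intron"], 0.25)
  expect_equal(sum(bs$fraction), 1, tolerance = 1e-9)

  s2 <- mk_sites("absent", 5)
  bs2 <- biotype_summary(s2, models)
  expect_equal(as.data.frame(bs2),
               data.frame(biotype = "unannotated", n_transcripts = 1L,
                          fraction = 1))
})

test_that("length bins use closed right edges and cover every transcript once", {
  models <- mk_models(list(
    a = list(strand = "+", exons = data.frame(start = 0, end = 800)),
    b = list(strand = "+", exons = data.frame(start = 0, end = 3000)),
    c = list(strand = "+", exons = data.frame(start = 0, end = 7000)),
    d = list(strand = "+", exons = data.frame(start = 0, end = 5000))))
  s <- mk_sites(c("a", "b", "c", "d"), c(1, 1, 1, 1))
  tb <- transcript_length_bins(s, models)
  expect_equal(tb$bin, c("<=1000", "1001-5000", "5001-10000", ">10000"))
  # 5000 lands in 1001-5000 (closed right edge)
  expect_equal(tb$n_transcripts, c(1L, 2L, 1L, 0L))
  expect_equal(sum(tb$n_transcripts), 4L)
})

test_that("fixture biotype/length/chromosome summaries equal generator truth", {
  fx <- get_fixture()
  models <- read_gtf(fx$paths$gtf)
  for (g in names(fx$paths$sites)) {
    s <- filter_sites(read_site_proba(fx$paths$sites[[g]][1], g),
                      fx$spec$threshold)
    truth <- fx$truth$per_group[[g]]

    bs <- biotype_summary(s, models)
    expect_equal(setNames(bs$fraction, bs$biotype)[names(truth$biotype_fractions)],
                 unlist(truth$biotype_fractions), tolerance = 1e-12)
    expect_equal(sum(bs$fraction), 1, tolerance = 1e-9)

    cd <- chromosome_distribution(s, models)
    expect_equal(setNames(cd$fraction, cd$chrom)[names(truth$chrom_fractions)],
                 unlist(truth$chrom_fractions), tolerance = 1e-12)
    expect_equal(sum(cd$fraction), 1, tolerance = 1e-9)

    tb <- transcript_length_bins(s, models)
    expect_equal(setNames(tb$n_transcripts, tb$bin),
                 unlist(truth$length_bins)[tb$bin])

    spt <- sites_per_transcript(s)
    expect_equal(setNames(spt$n_transcripts, spt$n_sites),
                 unlist(truth$sites_per_transcript)[as.character(spt$n_sites)])
    expect_equal(attr(spt, "max_sites"), truth$max_sites_per_transcript)

    kf <- kmer_frequency(s)
    expect_equal(kf$is_DRACH, is_drach(kf$kmer))
    expect_equal(sum(kf$fraction), 1, tolerance = 1e-9)
  }
})

test_that("chromosome distribution counts each modified gene once", {
  models <- mk_models(list(
    a = list(strand = "+", exons = data.frame(start = 0, end = 100),
             gene_id = "g1", chrom = "chr1"),
    b = list(strand = "+", exons = data.frame(start = 0, end = 100),
             gene_id = "g2", chrom = "chr1"),
    c = list(strand = "+", exons = data.frame(start = 0, end = 100),
             gene_id = "g3", chrom = "chr17")))
  s <- mk_sites(c("a", "a", "b", "c"), c(1, 2, 1, 1))
  cd <- chromosome_distribution(s, models)
  expect_equal(setNames(cd$fraction, cd$chrom),
               c(chr1 = 2 / 3, chr17 = 1 / 3))
})
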