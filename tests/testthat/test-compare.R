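# WMR arithmetic, group overlaps, rank-sum testing, BH adjustment,
# differential methylation and the six-category integration.

test_that("WMR is the sum of site ratios over the transcript length", {
  models <- mk_models(list(
    t1 = list(strand = "+", exons = data.frame(start = 0, end = 500)),
    t2 = list(strand = "+", exons = data.frame(start = 0, end = 1000))))
  s <- dplyr::bind_rows(
    mk_sites("t1", c(10, 20), mod_ratio = c(0.2, 0.3)),
    mk_sites("t2", 5, mod_ratio = 1.0))
  w <- compute_wmr(s, models)
  expect_equal(w$wmr[w$tx_key == "t1"], 0.001)
  expect_equal(w$wmr[w$tx_key == "t2"], 0.001)
  expect_equal(w$n_sites_used, c(2L, 1L))

  # unknown transcripts are excluded and reported
  expect_warning(w2 <- compute_wmr(mk_sites(c("t1", "ghost"), c(1, 1)), models),
                 "absent")
  expect_equal(attr(w2, "excluded"), "ghost")
})

test_that("WMR matches brute-force re-summation and scales linearly", {
  fx <- get_fixture()
  models <- read_gtf(fx$paths$gtf)
  s <- filter_sites(read_site_proba(fx$paths$sites$groupB[2], "b2"),
                    fx$spec$threshold)
  w <- compute_wmr(s, models)
  tr <- models$transcripts
  for (i in seq_len(nrow(w))) {
    manual <- sum(s$mod_ratio[strip_tx_version(s$transcript_id) == w$tx_key[i]]) /
      tr$length_total[tr$tx_key == w$tx_key[i]]
    expect_equal(w$wmr[i], manual)
  }
  # permutation invariance and linear scaling in the ratios
  s_shuf <- s[sample(nrow(s)), ]
  w_shuf <- compute_wmr(s_shuf, models)
  expect_equal(dplyr::arrange(w, tx_key)$wmr,
               dplyr::arrange(w_shuf, tx_key)$wmr)
  s_scaled <- dplyr::mutate(s, mod_ratio = mod_ratio / 2)
  expect_equal(compute_wmr(s_scaled, models)$wmr, w$wmr / 2)
})

test_that("log2 WMR ratios behave at equality, doubling and zero", {
  expect_equal(log2_wmr_ratio(0.3, 0.3), 0)
  expect_equal(log2_wmr_ratio(0.02, 0.01), 1, tolerance = 1e-3)
  expect_equal(log2_wmr_ratio(1e-3, 0, pseudo = 1e-6), log2(1001))
  expect_equal(log2_wmr_ratio(0, 1e-3, pseudo = 1e-6), -log2(1001))
})

test_that("group overlap counts equal explicit set algebra", {
  a <- mk_sites(c("t1", "t1", "t2"), c(1, 2, 1), sample_id = "a")
  b <- mk_sites(c("t1", "t3"), c(1, 9), sample_id = "b")
  models <- mk_models(list(
    t1 = list(strand = "+", exons = data.frame(start = 0, end = 100),
              gene_id = "g1"),
    t2 = list(strand = "+", exons = data.frame(start = 0, end = 100),
              gene_id = "g1"),
    t3 = list(strand = "+", exons = data.frame(start = 0, end = 100),
              gene_id = "g2")))
  ov <- group_overlap(list(A = a, B = b), models)
  get <- function(level, combo) {
    n <- ov$n[ov$level == level & ov$groups == combo]
    if (length(n)) n else 0L
  }
  expect_equal(get("site", "A&B"), 1L)    # t1:1
  expect_equal(get("site", "A"), 2L)      # t1:2, t2:1
  expect_equal(get("site", "B"), 1L)      # t3:9
  expect_equal(get("transcript", "A&B"), 1L)
  expect_equal(get("gene", "A&B"), 1L)    # g1
  expect_equal(get("gene", "B"), 1L)      # g2
  # counts over subsets sum to the union size per level
  expect_equal(sum(ov$n[ov$level == "site"]), 4L)
  expect_equal(sum(ov$n[ov$level == "transcript"]), 3L)
  expect_equal(sum(ov$n[ov$level == "gene"]), 2L)

  identical_groups <- group_overlap(list(A = a, B = a))
  expect_true(all(identical_groups$groups == "A&B"))
  disjoint <- group_overlap(list(A = a, B = mk_sites("t9", 1)))
  expect_false(any(disjoint$groups == "A&B"))
  expect_error(group_overlap(list(A = a)), "at least 2")
})

test_that("three-group overlaps match brute-force subset enumeration", {
  set.seed(31)
  mk <- function(n) mk_sites(paste0("t", sample(1:12, n, replace = TRUE)),
                             sample(1:5, n, replace = TRUE))
  groups <- list(X = mk(15), Y = mk(15), Z = mk(15))
  ov <- group_overlap(groups)
  keys <- lapply(groups, function(s)
    unique(paste(s$transcript_id, s$transcript_position, sep = ":")))
  universe <- unique(unlist(keys))
  combo <- vapply(universe, function(k) {
    paste(names(groups)[vapply(keys, function(s) k %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  want <- table(combo)
  got <- ov[ov$level == "site", ]
  expect_equal(setNames(got$n, got$groups)[names(want)],
               setNames(as.integer(want), names(want)))
  expect_equal(sum(got$n), length(universe))
})

test_that("rank-sum p-values equal full-permutation enumeration", {
  r <- wilcoxon_diffmeth(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)  # 2 of the 20 rank assignments are as extreme
  expect_equal(r$median_diff, -3)

  same <- wilcoxon_diffmeth(c(2, 4, 6), c(2, 4, 6))
  expect_equal(same$p_value, 1)
  expect_equal(same$median_diff, 0)

  set.seed(12)
  for (i in 1:25) {
    na <- sample(2:4, 1)
    nb <- sample(2:4, 1)
    repeat {
      a <- round(runif(na), 4)
      b <- round(runif(nb), 4)
      if (!any(duplicated(c(a, b)))) break
    }
    expect_equal(wilcoxon_diffmeth(a, b)$p_value, oracle_wilcoxon_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(0.2), 0.2)
  expect_equal(adjust_pvalues(c(1, 1, 1)), c(1, 1, 1))
  p <- runif(20)
  q <- adjust_pvalues(p)
  expect_true(all(q >= p - 1e-12))
})

test_that("differential methylation is antisymmetric under group swap", {
  fx <- get_fixture()
  models <- read_gtf(fx$paths$gtf)
  sites <- dplyr::bind_rows(lapply(names(fx$paths$sites), function(g) {
    dplyr::bind_rows(lapply(seq_along(fx$paths$sites[[g]]), function(r) {
      read_site_proba(fx$paths$sites[[g]][r], sprintf("%s_rep%d", g, r))
    }))
  }))
  sites <- filter_sites(sites, fx$spec$threshold)
  wmr <- compute_wmr(sites, models)
  ga <- paste0("groupA_rep", 1:3)
  gb <- paste0("groupB_rep", 1:3)
  d_ab <- diff_methylation(wmr, list(A = ga, B = gb))
  d_ba <- diff_methylation(wmr, list(B = gb, A = ga))
  m <- match(d_ab$tx_key, d_ba$tx_key)
  expect_equal(d_ab$log2_wmr_ratio, -d_ba$log2_wmr_ratio[m])
  expect_equal(d_ab$median_diff, -d_ba$median_diff[m])
  expect_equal(d_ab$p_value, d_ba$p_value[m])
  swap <- c(hyper_a = "hyper_b", hyper_b = "hyper_a", unchanged = "unchanged")
  expect_equal(unname(swap[d_ab$direction]), d_ba$direction[m])
  expect_equal(attr(d_ab, "mode"), "replicate")
})

test_that("planted hypermethylation separates the replicate WMR distributions", {
  fx <- get_fixture()
  models <- read_gtf(fx$paths$gtf)
  sites <- filter_sites(dplyr::bind_rows(lapply(names(fx$paths$sites), function(g) {
    dplyr::bind_rows(lapply(seq_along(fx$paths$sites[[g]]), function(r) {
      read_site_proba(fx$paths$sites[[g]][r], sprintf("%s_rep%d", g, r))
    }))
  })), fx$spec$threshold)
  wmr <- compute_wmr(sites, models)
  d <- diff_methylation(wmr, list(A = paste0("groupA_rep", 1:3),
                                  B = paste0("groupB_rep", 1:3)))
  planted <- fx$truth$planted
  da <- d[d$tx_key %in% planted$hyper_a, ]
  db <- d[d$tx_key %in% planted$hyper_b, ]
  expect_gte(mean(da$median_diff > 0), 0.9)
  expect_gte(mean(db$median_diff < 0), 0.9)
  expect_gte(mean(da$log2_wmr_ratio > 0), 0.9)
  # a delta = 0.3 shift fully separates 3-vs-3 replicates: the exact
  # rank-sum p sits at its 2/20 floor for the planted transcripts
  expect_true(all(abs(da$p_value - 0.1) < 1e-12))
})

test_that("pooled mode calls direction by the sign of the log2 ratio", {
  models <- mk_models(list(
    t1 = list(strand = "+", exons = data.frame(start = 0, end = 100)),
    t2 = list(strand = "+", exons = data.frame(start = 0, end = 100))))
  s <- dplyr::bind_rows(
    mk_sites(c("t1", "t2"), c(1, 1), mod_ratio = c(0.8, 0.2), sample_id = "a1"),
    mk_sites(c("t1", "t2"), c(1, 1), mod_ratio = c(0.2, 0.8), sample_id = "b1"))
  w <- compute_wmr(s, models)
  d <- diff_methylation(w, list(A = "a1", B = "b1"))
  expect_equal(attr(d, "mode"), "pooled")
  expect_equal(setNames(d$direction, d$tx_key),
               c(t1 = "hyper_a", t2 = "hyper_b"))
  expect_true(all(is.na(d$p_value)))
})

test_that("group-exclusive transcripts are set aside, not forced into ratios", {
  models <- mk_models(list(
    t1 = list(strand = "+", exons = data.frame(start = 0, end = 100)),
    t2 = list(strand = "+", exons = data.frame(start = 0, end = 100))))
  s <- dplyr::bind_rows(
    mk_sites("t1", 1, sample_id = "a1"),
    mk_sites(c("t1", "t2"), c(1, 2), sample_id = "b1"))
  d <- diff_methylation(compute_wmr(s, models), list(A = "a1", B = "b1"))
  expect_equal(d$tx_key, "t1")
  excl <- attr(d, "exclusive")
  expect_equal(excl$tx_key, "t2")
  expect_equal(excl$group, "B")
})

test_that("integration categories follow the 2x3 definition", {
  diff <- tibble::tibble(
    transcript_id = c("t1", "t2", "t3"), tx_key = c("t1", "t2", "t3"),
    gene_key = c("g1", "g2", "g3"),
    wmr_a = 1, wmr_b = 1,
    log2_wmr_ratio = c(1, -1, 1), median_diff = NA_real_,
    p_value = NA_real_, q_value = NA_real_,
    direction = c("hyper_a", "hyper_b", "unchanged"))
  dge <- tibble::tibble(gene_id = c("g1", "g2"), gene_key = c("g1", "g2"),
                        log2fc = c(2, 2), padj = c(0.01, 0.8))
  models <- mk_models(list(
    t1 = list(strand = "+", exons = data.frame(start = 0, end = 100),
              gene_id = "g1"),
    t2 = list(strand = "+", exons = data.frame(start = 0, end = 100),
              gene_id = "g2"),
    t3 = list(strand = "+", exons = data.frame(start = 0, end = 100),
              gene_id = "g3")))
  rec <- classify_integration(diff, dge, models)
  expect_equal(nrow(rec), 2)  # 'unchanged' excluded
  expect_equal(attr(rec, "n_excluded"), 1)
  expect_equal(as.character(rec$category), c("hyper_up", "hypo_ns"))
  # gene missing from the DGE table -> ns with a flag
  diff2 <- diff[3, ]
  diff2$direction <- "hyper_a"  # g3 has no DGE row
  rec2 <- classify_integration(diff2, dge, models)
  expect_equal(as.character(rec2$category), "hyper_ns")
  expect_false(rec2$in_dge)
})

test_that("fixture integration recovers every planted category label", {
  fx <- get_fixture()
  models <- read_gtf(fx$paths$gtf)
  # pooled comparison: first replicate of each condition
  sites <- filter_sites(dplyr::bind_rows(
    read_site_proba(fx$paths$sites$groupA[1], "a1"),
    read_site_proba(fx$paths$sites$groupB[1], "b1")), fx$spec$threshold)
  wmr <- compute_wmr(sites, models)
  d <- diff_methylation(wmr, list(A = "a1", B = "b1"))
  dge <- read_dge(fx$paths$dge)
  rec <- classify_integration(d, dge, models, sites = sites)
  planted <- unlist(fx$truth$planted$categories)
  hit <- rec$tx_key %in% names(planted)
  expect_equal(setNames(as.character(rec$category[hit]), rec$tx_key[hit]),
               planted[rec$tx_key[hit]])
  # six categories partition the classified set
  expect_true(all(!is.na(rec$category)))
  expect_equal(nrow(rec) + attr(rec, "n_excluded"), nrow(d))
})

test_that("per-category biotype and region fractions sum to one", {
  fx <- get_fixture()
  models <- read_gtf(fx$paths$gtf)
  sites <- filter_sites(dplyr::bind_rows(
    read_site_proba(fx$paths$sites$groupA[1], "a1"),
    read_site_proba(fx$paths$sites$groupB[1], "b1")), fx$spec$threshold)
  wmr <- compute_wmr(sites, models)
  d <- diff_methylation(wmr, list(A = "a1", B = "b1"))
  rec <- classify_integration(d, read_dge(fx$paths$dge), models, sites = sites)

  bt <- category_biotype_summary(rec)
  sums <- tapply(bt$fraction, as.character(bt$category), sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  rg <- category_region_summary(rec, sites, models)
  sums_r <- tapply(rg$fraction, as.character(rg$category), sum)
  expect_true(all(abs(sums_r - 1) < 1e-9))
  expect_true(all(rg$region %in% c("UTR5", "CDS", "UTR3", "noncoding")))

  expect_true(all(rec$dominant_region %in%
                    c("UTR5", "CDS", "UTR3", "noncoding")))
})

test_that("dominant region ties break toward the 3'-most region", {
  models <- mk_models(list(
    t1 = list(strand = "+", exons = data.frame(start = 0, end = 400),
              cds = data.frame(start = 100, end = 300))))
  # one CDS site, one 3'UTR site -> tie -> UTR3
  s <- mk_sites("t1", c(150, 350))
  expect_equal(m6apost:::dominant_region_for("t1", s, models), "UTR3")
  # two CDS sites, one UTR3 -> CDS
  s2 <- mk_sites("t1", c(150, 200, 350))
  expect_equal(m6apost:::dominant_region_for("t1", s2, models), "CDS")
})
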