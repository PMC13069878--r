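---
title: "Methods: post-processing site-level m6A predictions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-processing site-level m6A predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6apost)
```

## The problem

Nanopore direct RNA sequencing, run through m6Anet, yields a per-site
table of candidate N6-methyladenosine (m6A) positions: a transcript id,
a transcript coordinate, the 5-mer sequence context, a predicted
probability that the site is modified, and an estimated modification
ratio — the fraction of reads at the site carrying the mark. `m6apost`
turns that table into biological summaries (what is modified, where, in
what kind of transcript) and into a transcript-level comparison between
experimental conditions, optionally joined with differential
gene-expression (DGE) results.

Everything downstream of the site table needs a transcript annotation.
We parse an Ensembl/GENCODE GTF with `rtracklayer` and assemble one
model per transcript: ordered exons, optional CDS, strand, biotype, and
the lengths of the 5'UTR, CDS and 3'UTR measured along the mature
transcript (the 5'UTR is the exonic span upstream of the first CDS base
in transcript orientation — on the minus strand that is the
high-coordinate end). Identifier version suffixes (`ENST…​.2`) are
stripped for all joins between site tables, annotation and DGE tables,
because the suffixes appear inconsistently across files; original ids
are preserved in outputs.

## Coordinate conventions

m6Anet's documentation does not state whether `transcript_position` is
0- or 1-based. We treat positions as **0-based indices of the central
adenosine** of the 5-mer, and expose `position_base = 1` on every reader
for users whose upstream produced 1-based coordinates; guessing silently
would shift every projected site by one base. Internally all intervals
are 0-based half-open (BED semantics); the GTF's 1-based inclusive
coordinates are converted on read and write.

Transcript-to-genome projection walks exons in transcript (5'→3')
order: on `+` transcripts in genomic order, on `-` transcripts in
reverse genomic order with offset *o* inside an exon `[s, e)` mapping to
`e − 1 − o`. The inverse map is defined on exonic bases only and
round-trips exactly; both directions are validated in the tests against
an exhaustive per-base lookup table built by enumerating every base of
randomly generated multi-exon transcripts. Projected sites are written
as BED6 with name `transcriptID|position|kmer` and the modification
ratio in the score column, so genome browsers can shade sites by
modification level. In `kmer` mode the five k-mer positions are
projected individually and merged only where contiguous in genome
space; a k-mer interrupted by an exon junction therefore yields several
rows sharing one name, rather than a blocked BED12 line — simpler, and
safe for downstream interval intersection.

## Descriptive statistics

Sites are first filtered by predicted probability with a **strict**
`> 0.9` default, the conventional high-confidence cut-off for m6Anet
output. All per-transcript and per-gene summaries (biotype frequencies,
length bins, chromosome distribution) count **distinct transcripts or
genes, not sites**, so fractions read as "% of modified transcripts";
the per-site alternative would let one heavily modified transcript
dominate every composition estimate. Transcript length bins follow the
conventional ≤1000 / 1001–5000 / 5001–10000 / >10000 nucleotide ranges
with closed right edges (a 5000 nt transcript falls in 1001–5000).
Chromosomes are taken from the user's GTF rather than an organism
annotation database, which keeps the toolkit organism-agnostic.

The metagene profile rescales each coding transcript's 5'UTR, CDS and
3'UTR to unit length and concatenates them on `[0, 3]`: a site at
transcript position *p* maps to `p/U5` in the 5'UTR, `1 + (p−U5)/CDS`
in the CDS, `2 + (p−U5−CDS)/U3` in the 3'UTR. The three-region scaling
is undefined without a CDS, so non-coding transcripts are excluded from
it and summarized separately on a whole-transcript `[0, 1)` axis rather
than silently mixed in. Densities use a Gaussian kernel with Silverman's
rule-of-thumb bandwidth (`stats::density`, 512 grid points), both
user-overridable; the choice only smooths the display and never feeds a
test statistic.

## The weighted modification ratio

Transcript-level methylation burden is quantified as

$$\mathrm{WMR} = \frac{\sum_i \mathrm{mod\ ratio}_i}{\text{transcript length}}$$

summing over the transcript's retained sites in one sample. Dividing by
the mature transcript length makes burdens comparable between short and
long transcripts; units are "expected modified-read fraction per base".
WMR is linear in the modification ratios and invariant to site order,
both of which are asserted as properties in the tests.

Two comparison modes exist because practice produces both kinds of
input:

* **No replicates** (e.g. replicates pooled upstream in m6Anet): the
  log2 ratio `log2(WMR_A + ε) − log2(WMR_B + ε)` with pseudocount
  ε = 10⁻⁶ ranks transcripts as hyper- (positive) or hypomethylated
  (negative). The pseudocount keeps zero WMRs finite; it is far below
  any realistic WMR (a single fully modified site on a 10 kb transcript
  gives 10⁻⁴), so it only matters at exact zeros. Writing the ratio as
  a difference of logs makes a group swap negate it bit-for-bit.
* **Replicates** (≥ 2 per condition): each transcript's per-replicate
  WMR vectors are compared by the two-sided Wilcoxon rank-sum test —
  exact enumeration when `n_A + n_B ≤ 10` with no ties, the normal
  approximation with tie and continuity correction otherwise — together
  with the median difference `median(WMR_A) − median(WMR_B)`. P-values
  are adjusted across the tested transcript family by
  Benjamini–Hochberg (the raw p is also reported), and a direction is
  called at `q < alpha` (default 0.05) by the sign of the median
  difference. A replicate in which a transcript retains no site
  contributes WMR 0 — absence of confident sites is evidence of low
  methylation, not missingness. Transcripts detected in only one group
  are reported in a separate group-exclusive table instead of being
  forced into a ratio against zero, whose magnitude would be an
  artifact of the pseudocount.

**A statistical floor worth knowing.** With triplicates the exact
rank-sum test has only `C(6,3) = 20` rank arrangements, so the smallest
achievable two-sided p-value is `2/20 = 0.1` — and consequently no BH
q-value below 0.1 is possible, regardless of effect size. With three
replicates per condition the test can rank and orient transcripts but
cannot clear an FDR < 0.05 bar by itself; at least four replicates per
group (p-floor `2/70 ≈ 0.029`) are needed for that. The package applies
the test honestly rather than switching to the anti-conservative
unadjusted normal approximation to manufacture significance; with
triplicate designs the directional signal is carried by the
median-difference sign and the pooled log2 WMR ratio.

## Expression integration

When a DGE table (gene id, log2 fold change, adjusted P) is provided,
transcripts with a defined methylation direction are classified into
six categories: {hyper, hypo} × {up, down, ns}. We read the "six
functional categories" as this 2 × 3 product — methylation direction is
always defined for classified transcripts while expression has a
natural "no significant change" state; the alternative 3 × 2 reading
(adding an "unchanged methylation" row) would simply re-admit the
transcripts we deliberately exclude as unclassified. Expression is
"up" when `padj < alpha` and `log2fc ≥ lfc_min` (default `lfc_min = 0`;
a log2fc of exactly 0 is never called), "down" symmetrically, "ns"
otherwise; genes absent from the DGE table are "ns" with an explicit
`in_dge = FALSE` flag rather than dropped, so the classified set stays a
partition. Each category is summarized by transcript biotype, and — in
pooled mode, or on request in replicate mode — by transcript region,
counting each classified transcript's modified sites in the metagene
regions. A transcript's `dominant_region` is the region holding the
plurality of its sites, ties broken toward the 3'-most region because
m6A is canonically 3'UTR-enriched and a 3'-ward tie-break is the
conservative choice for this mark.

## Annotation

Projected sites are intersected with user-supplied BED features
(RBP/CLIP peaks, SNPs, miRNA sites) under half-open semantics — touching
intervals do not overlap, minimum overlap is 1 bp since sites are 1–5 bp
wide. Intersection is **unstranded by default** because common SNP BEDs
carry no strand; in stranded mode a `"."` on either side still matches
both strands. UCSC (`chr1`) and Ensembl (`1`) chromosome names are
reconciled by normalizing the `chr` prefix, with a warning so users
notice mixed conventions. The `GenomicRanges::findOverlaps` machinery
does the sweep; tests compare it against a vectorized all-pairs brute
force on random instances up to 1000 × 1000 intervals.

## The synthetic dataset

`simulate_dataset()` exists so that the whole toolchain — readers,
projection, summaries, comparison, integration, annotation — runs and
is testable without any external download, and so that every summary
has a planted, machine-readable expected value. The defaults emulate a
two-condition comparison with three technical replicates per condition,
the design the toolkit is aimed at: ~30 genes × 2 transcripts on five
toy chromosomes (≤ 100 kb so everything runs in seconds), a biotype mix
of 70% protein-coding with the remainder split between retained-intron,
nonsense-mediated-decay and lncRNA transcripts (mirroring the
composition commonly reported for modified transcripts in DRS
datasets), mostly single-site transcripts, 90% DRACH k-mers, 60% of
coding-transcript sites placed just past the stop codon to reproduce
the canonical 3'UTR-start density peak, site probabilities with 85%
above the 0.9 cut-off (the rest are decoys that must be filtered), and
base modification ratios uniform on [0.15, 0.55] with per-replicate
Gaussian noise (sd 0.04). Hypermethylation is planted in ~20% of the
commonly modified coding transcripts per direction as a +0.3 shift of
all site modification ratios, on disjoint gene sets, and the DGE
generator assigns those genes up/down/ns calls in rotation so each
planted transcript has a known six-way category. One seeded
Mersenne-Twister stream drives the entire dataset; outputs are
byte-identical across reruns and the spec and truth are serialized as
JSON next to the data.

What the generator does **not** emulate: read-level signal and
coverage-dependent uncertainty in the modification ratio, correlated
sites within a transcript, overdispersed replicate noise, annotation
errors, multi-isoform ambiguity of site assignment, and genome-scale
transcript counts. Passing tests therefore demonstrate the correctness
of the arithmetic, the coordinate handling and the statistical
machinery under the stated model — not the biological error rates to
expect on real nanopore data.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: identical values across both
replicate groups give p = 1; fewer than two positions refuse a density
estimate; empty post-filter tables propagate as zero-count tables
rather than errors. Fractions are validated to sum to 1 within 1e-9;
the metagene density integrates to 1 ± 0.05 over its padded support.
Test problem sizes — 100 random multi-exon transcripts for the
projection oracle, 50 random instances up to 1000 × 1000 for the
intersection oracle, full-permutation Wilcoxon enumeration up to
`n_A + n_B = 8`, and the default simulator dimensions above — were
chosen so the complete suite runs in about a minute on one core while
still exercising every code path.

## Known limitations

* Transcript-level WMR ignores coverage: a site seen in 10 reads and
  one seen in 500 contribute their ratios equally. A read-weighted
  variant would need read counts to be comparable across sites, which
  m6Anet does not guarantee.
* Differential methylation is transcript-level only; site-level testing
  across conditions is out of scope.
* Projection assumes the site's transcript is the annotated one;
  multi-mapping of sites across isoforms sharing exons is not resolved.
* The rank-sum p-value floor with ≤ 3 replicates (above) is a property
  of the design, not of the implementation; plan for ≥ 4 replicates if
  FDR-controlled per-transcript calls are required.
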