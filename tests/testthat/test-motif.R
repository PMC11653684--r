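# lay out n cassette events on one synthetic chromosome; introns 300 nt
motif_events <- function(n, exon_len = 150L, spacing = 2000L, shift = 0L) {
  off <- seq_len(n) * spacing + shift
  splice_events(
    event_id = sprintf("m%03d", seq_len(n)), gene_id = sprintf("g%03d", seq_len(n)),
    event_type = "SE", chrom = "chrM", strand = "+",
    exon_start = off + 400L, exon_end = off + 400L + exon_len,
    upstream_exon_start = off, upstream_exon_end = off + 100L,
    downstream_exon_start = off + 400L + exon_len + 300L,
    downstream_exon_end = off + 400L + exon_len + 400L
  )
}

motif_genome <- function(n, spacing = 2000L) {
  stats::setNames(rand_dna((n + 1L) * spacing + 1000L), "chrM")
}

test_that("scan_motif handles exact, overlapping and degenerate patterns", {
  expect_identical(scan_motif("AAGTGTGAA", "GTGTG"), 2L)
  expect_identical(scan_motif("GTGTGTG", "GTGTG"), c(0L, 2L))
  expect_identical(scan_motif("ATGACG", "A[CU]GAC[AG]"), 0L)
  expect_identical(scan_motif("AUGACG", "A[CU]GAC[AG]"), 0L)  # U == T
  expect_identical(scan_motif("AAAA", "GTGTG"), integer(0))
  expect_error(scan_motif("ACGT", "AXC"), "IUPAC")
})

test_that("scan_motif agrees with the brute-force IUPAC oracle", {
  set.seed(71)
  patterns <- c("GTGTG", "A[CU]GAC[AG]", "RYN", "TGW", "ACGT", "SS")
  for (i in 1:200) {
    s <- rand_dna(sample(20:200, 1))
    p <- sample(patterns, 1)
    expect_identical(scan_motif(s, p), oracle_scan(s, p))
  }
})

test_that("extract_flanks returns the documented regions and truncation", {
  ev <- motif_events(1)
  genome <- motif_genome(1)
  fl <- extract_flanks(ev, genome, window = 250)
  chr <- genome[["chrM"]]
  # downstream-intron region starts at exon_end, length 250
  expect_equal(fl$sequences[["downstream_intron"]],
               substr(chr, ev$exon_end + 1, ev$exon_end + 250))
  expect_equal(fl$sequences[["cassette_exon"]],
               substr(chr, ev$exon_start + 1, ev$exon_end))
  expect_equal(nchar(fl$sequences[["upstream_intron"]]), 250)
  expect_false(any(fl$truncated))  # introns (300) cover the 250 window
  # intron 300 < window 400: regions truncate to the intron length
  fl2 <- extract_flanks(ev, genome, window = 400)
  expect_equal(nchar(fl2$sequences[["upstream_intron"]]), 300)
  expect_true(fl2$truncated[["upstream_intron"]])
  expect_error(extract_flanks(ev, stats::setNames("ACGT", "chrM")), "outside")
})

test_that("minus-strand flanks reproduce the plus-strand sequences", {
  ev <- motif_events(1)
  genome <- motif_genome(1)
  chrom_len <- nchar(genome[["chrM"]])
  ev_m <- splice_events(
    "m001", "g001", "SE", "chrM", "-",
    exon_start = chrom_len - ev$exon_end, exon_end = chrom_len - ev$exon_start,
    upstream_exon_start = chrom_len - ev$upstream_exon_end,
    upstream_exon_end = chrom_len - ev$upstream_exon_start,
    downstream_exon_start = chrom_len - ev$downstream_exon_end,
    downstream_exon_end = chrom_len - ev$downstream_exon_start)
  genome_m <- stats::setNames(reverse_complement(genome[["chrM"]]), "chrM")
  fl_p <- extract_flanks(ev, genome, 250)
  fl_m <- extract_flanks(ev_m, genome_m, 250)
  expect_identical(fl_m$sequences, fl_p$sequences)
  # strand round-trip: motif offsets identical
  for (r in fl_p$region_names)
    expect_identical(scan_motif(fl_m$sequences[[r]], "GTG"),
                     scan_motif(fl_p$sequences[[r]], "GTG"))
})

test_that("region coverage totals match an independent per-event count", {
  set.seed(72)
  ev <- motif_events(10)
  genome <- motif_genome(10)
  cov <- splicedyn:::region_coverage(ev, genome, "GTG", "downstream_intron", 250)
  manual <- 0
  for (i in 1:10) {
    s <- extract_flanks(ev[i, ], genome, 250)$sequences[["downstream_intron"]]
    covered <- logical(250)
    for (o in scan_motif(s, "GTG")) covered[(o + 1):min(o + 3, 250)] <- TRUE
    manual <- manual + sum(covered)
  }
  expect_equal(sum(cov[, "covered"]), manual)
  expect_true(all(cov[, "informative"] == 10))
})

test_that("positional enrichment recovers a planted intronic motif", {
  set.seed(73)
  n <- 50
  ev_t <- motif_events(n)
  # background events occupy the gaps between target loci on the same
  # chromosome, so they share composition but not the planted positions
  ev_b <- motif_events(n, shift = 1000L)
  ev_b$event_id <- sprintf("b%03d", 1:n)
  genome_t <- motif_genome(n)
  genome_b <- motif_genome(n)
  # plant GTGTG at downstream-intron offset 100 of every target
  chr <- genome_t[["chrM"]]
  for (i in 1:n) {
    pos <- ev_t$exon_end[i] + 100L
    substr(chr, pos + 1L, pos + 5L) <- "GTGTG"
  }
  genome_t[["chrM"]] <- chr
  prof <- positional_enrichment(ev_t, ev_b, "GTGTG", genome_t, flank = 250)
  peak <- attr(prof, "peak")
  expect_equal(peak$region, "downstream_intron")
  expect_true(abs(peak$position - 100) <= 25)
  dn <- prof[prof$region == "downstream_intron", ]
  expect_lt(dn$pvalue[dn$position == 100], 1e-4)
  # mirrored planting: enrichment sign reverses
  prof_rev <- positional_enrichment(ev_b, ev_t, "GTGTG", genome_t, flank = 250)
  dn_rev <- prof_rev[prof_rev$region == "downstream_intron", ]
  at_peak <- dn_rev[dn_rev$position == 100, ]
  expect_gt(at_peak$background_score, at_peak$target_score)
  # null identity: a set against itself shows nothing after BH
  prof_null <- positional_enrichment(ev_b, ev_b, "GTGTG", genome_b, flank = 250)
  expect_gt(min(prof_null$fdr), 0.05)
  expect_error(positional_enrichment(ev_t[1:5, ], ev_b, "GTGTG", genome_t),
               "at least 20")
})

test_that("correlate_profiles is plain Pearson correlation", {
  x <- c(1, 2, 3, 4)
  expect_equal(correlate_profiles(x, x), 1)
  expect_equal(correlate_profiles(x, -x), -1)
  set.seed(74)
  expect_lt(abs(correlate_profiles(rnorm(5000), rnorm(5000))), 0.05)
})
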