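test_that("microexon bounds are inclusive at 3 and 27 nt", {
  expect_true(classify_microexon(15))
  expect_true(classify_microexon(3))
  expect_true(classify_microexon(27))
  expect_false(classify_microexon(28))
  expect_false(classify_microexon(2))
  expect_error(classify_microexon(0), ">= 1")
})

test_that("gc_content counts G+C over ACGT, ignoring N", {
  expect_equal(gc_content("GCGC"), 1)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("ACGT"), 0.5)
  expect_equal(gc_content("ACGTNNNN"), 0.5)
  expect_error(gc_content("NNN"), "all-N")
  set.seed(61)
  for (i in 1:10) {
    s <- rand_dna(200)
    expect_equal(gc_content(s), gc_content(reverse_complement(s)))
  }
})

nmd_fixture <- function(cassette_len, cds_span = c(30, 480), seed = 3) {
  simulate_gene_model(c(150, 100, cassette_len, 130, 200), cassette_index = 3,
                      cds_span = cds_span, seed = seed)
}

test_that("NMD classifier handles frameshift, in-frame and UTR cassettes", {
  # 122-nt cassette inside the CDS: skipping shifts the frame, PTC upstream
  # of the last junction -> the exclusion isoform is the decay target
  g1 <- nmd_fixture(122)
  r1 <- predict_nmd(g1$model, g1$event, g1$genome)
  expect_equal(r1$nmd_isoform, "exclusion")
  expect_false(r1$frame_preserving)
  expect_gt(r1$ptc_distance_to_last_junction[["exclusion"]], 50)
  # 120-nt cassette: frame preserved, no PTC on either isoform
  g2 <- nmd_fixture(120)
  r2 <- predict_nmd(g2$model, g2$event, g2$genome)
  expect_equal(r2$nmd_isoform, "none")
  expect_true(r2$frame_preserving)
  # cassette entirely in the 3'UTR: rule does not apply
  g3 <- nmd_fixture(90, cds_span = c(30, 90))
  r3 <- predict_nmd(g3$model, g3$event, g3$genome)
  expect_equal(r3$nmd_isoform, "none")
  # CDS lengths of the two isoforms differ by the cassette length
  inc <- g1$model$transcripts$inc; exc <- g1$model$transcripts$exc
  expect_equal(sum(inc$exons[, 2] - inc$exons[, 1]) -
                 sum(exc$exons[, 2] - exc$exons[, 1]), 122)
})

test_that("NMD prediction is strand-invariant", {
  g <- nmd_fixture(122)
  chrom_len <- nchar(g$genome[[1]])
  mirror <- function(v) chrom_len - rev(v)
  tx_mirror <- function(t) list(
    exons = cbind(start = chrom_len - rev(t$exons[, 2]),
                  end = chrom_len - rev(t$exons[, 1])),
    cds_start = chrom_len - t$cds_end, cds_end = chrom_len - t$cds_start)
  model_m <- gene_model("simGene", "chrSim", "-",
                        lapply(g$model$transcripts, tx_mirror))
  ev <- g$event
  ev_m <- splice_events(
    "simSE", "simGene", "SE", "chrSim", "-",
    exon_start = chrom_len - ev$exon_end, exon_end = chrom_len - ev$exon_start,
    upstream_exon_start = chrom_len - ev$upstream_exon_end,
    upstream_exon_end = chrom_len - ev$upstream_exon_start,
    downstream_exon_start = chrom_len - ev$downstream_exon_end,
    downstream_exon_end = chrom_len - ev$downstream_exon_start)
  genome_m <- stats::setNames(reverse_complement(g$genome[[1]]), "chrSim")
  r_plus <- predict_nmd(g$model, ev, g$genome)
  r_minus <- predict_nmd(model_m, ev_m, genome_m)
  expect_equal(r_minus$nmd_isoform, r_plus$nmd_isoform)
  expect_equal(r_minus$ptc_distance_to_last_junction,
               r_plus$ptc_distance_to_last_junction)
})

test_that("annotate_events combines length, frame, GC and NMD columns", {
  g <- nmd_fixture(122)
  models <- list(simGene = g$model)
  ann <- annotate_events(g$event, g$genome, models)
  expect_equal(ann$length, 122)
  expect_false(ann$is_microexon)
  expect_false(ann$frame_preserving)
  expect_equal(ann$nmd_isoform, "exclusion")
  expect_true(ann$gc > 0 && ann$gc < 1)
})

test_that("compare_distributions matches brute-force U and detects shifts", {
  a <- c(3.1, 4.5, 2.2, 5.0, 3.3)
  b <- c(1.0, 2.0, 6.1, 0.5, 1.7)
  r <- compare_distributions(a, b)
  # U by its definition: pairs where a > b (+ half ties)
  U_oracle <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  expect_equal(r$statistic, U_oracle)
  expect_equal(r$median_a, median(a))
  # p agrees with the stats::wilcox.test normal approximation
  w <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(r$pvalue, w$p.value, tolerance = 1e-9)
  # identical samples: no shift
  expect_gt(compare_distributions(a, a)$pvalue, 0.99)
  # all-tied degenerate input
  expect_equal(compare_distributions(rep(1, 5), rep(1, 5))$pvalue, 1)
  # a planted median shift at n = 200 is significant
  set.seed(62)
  x <- rnorm(200, 104, 10); y <- rnorm(200, 111, 10)
  expect_lt(compare_distributions(x, y)$pvalue, 0.01)
  expect_error(compare_distributions(1:2, 1:5), "at least 3")
})
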