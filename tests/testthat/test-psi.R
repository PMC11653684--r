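make_counts <- function(L, S, n_samples = ncol(L)) {
  md <- sample_metadata(sprintf("s%02d", seq_len(n_samples)))
  n <- nrow(L)
  off <- seq_len(n) * 10000L
  ev <- splice_events(sprintf("e%d", seq_len(n)), sprintf("g%d", seq_len(n)),
                      "SE", "chr1", "+",
                      exon_start = off, exon_end = off + 150L,
                      upstream_exon_start = off - 1000L,
                      upstream_exon_end = off - 800L,
                      downstream_exon_start = off + 1000L,
                      downstream_exon_end = off + 1200L)
  junction_counts(ev, L, S, md)
}

test_that("compute_psi is the plain inclusion ratio with a missing convention", {
  jc <- make_counts(L = rbind(c(25, 5, 0)), S = rbind(c(75, 0, 0)))
  p <- compute_psi(jc)
  expect_equal(unname(p$psi[1, ]), c(0.25, 1, NA_real_))
  expect_identical(unname(p$missing_mask[1, ]), c(FALSE, FALSE, TRUE))
  # reconstruction: L = psi * (L + S) exactly on integer fixtures
  set.seed(3)
  L <- matrix(rpois(60, 40), 6); S <- matrix(rpois(60, 60), 6)
  p2 <- compute_psi(make_counts(L, S))
  expect_equal(unname(p2$psi * (L + S)), L)
})

test_that("imputation preserves observed cells and stays in [0,1]", {
  # two clusters of co-spliced events: rows 1-10 around PSI 0.7, 11-20
  # around 0.3; nearest neighbours of row 5 are its own cluster
  set.seed(11)
  base <- rbind(matrix(runif(100, 0.65, 0.75), 10, 10),
                matrix(runif(100, 0.25, 0.35), 10, 10))
  L <- round(base * 100); S <- 100 - L
  p <- compute_psi(make_counts(L, S))
  expect_identical(impute_missing(p), p)  # nothing missing: identity
  L2 <- L; S2 <- S
  L2[5, ] <- 70; S2[5, ] <- 30
  L2[5, 4] <- NA; S2[5, 4] <- NA
  p2 <- compute_psi(make_counts(L2, S2))
  for (method in c("knn", "iterative")) {
    imp <- impute_missing(p2, method = method, seed = 2)
    expect_true(all(imp$psi >= 0 & imp$psi <= 1))
    obs <- !p2$missing_mask
    expect_identical(imp$psi[obs], p2$psi[obs])  # bit-exact
    expect_true(imp$missing_mask[5, 4])          # mask preserved
  }
  # knn oracle: imputed value equals the mean of the k nearest rows at s4,
  # which sit in the 0.7 cluster
  imp <- impute_missing(p2, method = "knn", k = 10, seed = 2)
  x <- p2$psi
  d <- apply(x[-5, ], 1, function(r) sqrt(mean((r[-4] - x[5, -4])^2)))
  nb <- order(d)[1:10]
  oracle <- mean(x[-5, ][nb, 4])
  expect_equal(unname(imp$psi[5, 4]), oracle, tolerance = 1e-12)
  expect_gt(imp$psi[5, 4], 0.6); expect_lt(imp$psi[5, 4], 0.8)
})

test_that("imputation refuses rows without information", {
  L <- matrix(c(NA, NA, NA, 10, 20, 30), 2, 3, byrow = TRUE)
  S <- matrix(c(NA, NA, NA, 10, 20, 30), 2, 3, byrow = TRUE)
  p <- compute_psi(make_counts(L, S))
  expect_error(impute_missing(p), "e1")
})

test_that("each filter rule removes exactly its designed violator", {
  n_samp <- 10L
  good <- function() { L <- round(runif(n_samp, 30, 70)); list(L = L, S = 100 - L) }
  set.seed(8)
  rows <- list(
    clean = good(),
    mean_band = list(L = rep(97, n_samp) + rpois(n_samp, 1), S = rep(2, n_samp)),
    low_total = list(L = rep(2, n_samp), S = rep(3, n_samp)),
    missing = local({ g <- good(); g$L[1:5] <- NA; g$S[1:5] <- NA; g }),
    flat = list(L = rep(500, n_samp) + c(0, rep(1, n_samp - 1)),
                S = rep(500, n_samp))
  )
  L <- do.call(rbind, lapply(rows, `[[`, "L"))
  S <- do.call(rbind, lapply(rows, `[[`, "S"))
  p <- impute_missing(compute_psi(make_counts(L, S)), seed = 1)
  f <- filter_events(p)
  expect_equal(sum(f$report$pass), 1L)
  expect_equal(f$psi$events$event_id, "e1")
  rep <- f$report
  expect_match(rep$failed_rules[2], "mean_psi_band")
  expect_match(rep$failed_rules[3], "mean_total_count")
  expect_match(rep$failed_rules[4], "missing_samples")
  expect_match(rep$failed_rules[5], "psi_range")
})

test_that("filter boundaries follow the printed thresholds", {
  n_samp <- 10L
  # mean PSI 0.97 -> removed by rule 1; range 0.04 -> removed by rule 4
  L <- rbind(rep(97, n_samp), round(seq(48, 52, length.out = n_samp)))
  S <- rbind(rep(3, n_samp), 100 - L[2, ])
  p <- impute_missing(compute_psi(make_counts(L, S)), seed = 1)
  f <- filter_events(p)
  expect_false(f$report$pass_mean_psi_band[1])
  expect_lt(max(p$psi[2, ]) - min(p$psi[2, ]), 0.05)
  expect_false(f$report$pass_psi_range[2])
  # missing rule is strict: 4 missing passes, 5 missing fails
  L2 <- matrix(50, 2, n_samp); S2 <- matrix(50, 2, n_samp)
  L2[1, 1:4] <- NA; S2[1, 1:4] <- NA
  L2[2, 1:5] <- NA; S2[2, 1:5] <- NA
  L2[, n_samp] <- c(40, 40)  # give the rows some range
  p2 <- impute_missing(compute_psi(make_counts(L2, S2)), seed = 1)
  f2 <- filter_events(p2)
  expect_true(f2$report$pass_missing_samples[1])
  expect_false(f2$report$pass_missing_samples[2])
})

test_that("filtering is order-independent (rules are conjunctive)", {
  set.seed(14)
  L <- matrix(rbinom(200, 100, runif(20, 0.02, 0.98)), 20, 10)
  S <- 100 - L
  p <- impute_missing(compute_psi(make_counts(L, S)), seed = 1)
  f <- filter_events(p)
  with_rep <- f$report
  survivors <- with_rep$event_id[with_rep$pass_mean_psi_band &
                                 with_rep$pass_mean_total_count &
                                 with_rep$pass_missing_samples &
                                 with_rep$pass_psi_range]
  expect_identical(f$psi$events$event_id, survivors)
})
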