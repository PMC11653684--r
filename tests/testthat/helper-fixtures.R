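# shared fixtures and independent oracles

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# brute-force IUPAC scanner: position-by-position set membership
IUPAC_TABLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_scan <- function(sequence, pattern) {
  # expand [..] groups and U by hand
  p <- toupper(chartr("U", "T", pattern))
  classes <- list()
  i <- 1L
  while (i <= nchar(p)) {
    ch <- substr(p, i, i)
    if (ch == "[") {
      j <- i + 1L
      grp <- character(0)
      while (substr(p, j, j) != "]") { grp <- c(grp, substr(p, j, j)); j <- j + 1L }
      classes[[length(classes) + 1L]] <- unique(unlist(IUPAC_TABLE[grp]))
      i <- j + 1L
    } else {
      classes[[length(classes) + 1L]] <- IUPAC_TABLE[[ch]]
      i <- i + 1L
    }
  }
  s <- strsplit(toupper(chartr("U", "T", sequence)), "")[[1L]]
  m <- length(classes)
  hits <- integer(0)
  for (start in seq_len(length(s) - m + 1L)) {
    ok <- TRUE
    for (k in seq_len(m))
      if (!s[start + k - 1L] %in% classes[[k]]) { ok <- FALSE; break }
    if (ok) hits <- c(hits, start - 1L)
  }
  hits
}

# literal step-up BH definition: adj_i = min over j with p_j >= p_i of p_(j)*m/j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj_sorted <- vapply(seq_len(m), function(i)
    min(1, min(ps[i:m] * m / seq(i, m))), numeric(1L))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# two-group simulated PSI fixture
sim_two_group <- function(n_const, n_shift, seed, reps = 5L, base = 0.3,
                          delta = 0.3, noise = noise_params(missing_rate = 0)) {
  md <- sample_metadata(sprintf("s%02d", seq_len(2L * reps)),
                        group = rep(c("GM", "DM"), each = reps))
  models <- c(replicate(n_const, psi_model("constant", base_psi = base),
                        simplify = FALSE),
              replicate(n_shift, psi_model("group_shift", base_psi = base,
                                           delta = delta), simplify = FALSE))
  sim <- simulate_junction_counts(models, md, noise, seed = seed)
  sim$psi <- impute_missing(compute_psi(sim$counts), seed = seed)
  sim
}

# tissue panel emulating 57 datasets over ten tissues (7 x 6 + 3 x 5)
tissue_metadata_57 <- function() {
  reps <- c(rep(6L, 7L), rep(5L, 3L))
  tissues <- paste0("tissue", 1:10)
  sample_metadata(sprintf("t%03d", seq_len(sum(reps))),
                  tissue = rep(tissues, times = reps),
                  replicate = unlist(lapply(reps, seq_len)))
}
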