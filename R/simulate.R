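#' Describe the true PSI pattern of a simulated event
#'
#' The four kinds mirror the splicing patterns the pipeline is designed to
#' detect: a flat baseline, a condition shift (proliferation vs
#' differentiation), a smooth logistic trajectory over ordered developmental
#' stages, and a single-tissue outlier.
#'
#' @param kind `"constant"`, `"group_shift"`, `"logistic_trajectory"` or
#'   `"tissue_outlier"`.
#' @param base_psi baseline inclusion level in (0,1).
#' @param delta shift magnitude (`group_shift`) or trajectory amplitude
#'   (`logistic_trajectory`); the shifted group is `group == "DM"`.
#' @param midpoint,slope logistic parameters over stage rank.
#' @param outlier_tissue,outlier_psi tissue whose mean PSI is replaced, and
#'   the replacement value (`tissue_outlier`).
#' @return list of class `psi_model`.
#' @export
psi_model <- function(kind = c("constant", "group_shift", "logistic_trajectory",
                               "tissue_outlier"),
                      base_psi = 0.5, delta = 0, midpoint = 14, slope = 0.5,
                      outlier_tissue = NULL, outlier_psi = NULL) {
  kind <- match.arg(kind)
  if (base_psi <= 0 || base_psi >= 1) stop("base_psi must lie in (0,1)")
  structure(list(kind = kind, base_psi = base_psi, delta = delta,
                 midpoint = midpoint, slope = slope,
                 outlier_tissue = outlier_tissue, outlier_psi = outlier_psi),
            class = "psi_model")
}

#' Noise model for simulated junction counts
#'
#' @param total_count_mean mean of the negative-binomial total junction count
#'   per event and sample (L + S).
#' @param total_count_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); must be > 0.
#' @param rho beta-binomial intra-class correlation in `[0,1)`; `rho = 0`
#'   reduces to binomial sampling.
#' @param missing_rate probability that a cell is masked missing, default
#'   0.006 (the missingness level of real stage-series PSI matrices).
#' @return list of class `noise_params`.
#' @export
noise_params <- function(total_count_mean = 100, total_count_dispersion = 0.1,
                         rho = 0.02, missing_rate = 0.006) {
  if (total_count_mean <= 0 || total_count_dispersion <= 0)
    stop("total_count_mean and total_count_dispersion must be > 0")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0,1)")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must lie in [0,1)")
  structure(list(total_count_mean = total_count_mean,
                 total_count_dispersion = total_count_dispersion,
                 rho = rho, missing_rate = missing_rate),
            class = "noise_params")
}

# true PSI for one model over the metadata, clamped to [0.001, 0.999]
true_psi_vector <- function(model, metadata) {
  n <- nrow(metadata)
  psi <- switch(model$kind,
    constant = rep(model$base_psi, n),
    group_shift = model$base_psi + model$delta * (metadata$group == "DM"),
    logistic_trajectory = {
      rank <- match(metadata$stage, sort(unique(metadata$stage)))
      model$base_psi + model$delta /
        (1 + exp(-model$slope * (rank - model$midpoint)))
    },
    tissue_outlier = {
      if (is.null(model$outlier_tissue) || is.null(model$outlier_psi))
        stop("tissue_outlier model needs outlier_tissue and outlier_psi")
      ifelse(metadata$tissue == model$outlier_tissue,
             model$outlier_psi, model$base_psi)
    })
  if (any(psi < 0 | psi > 1))
    stop("model implies PSI outside [0,1]; adjust base_psi/delta")
  pmin(pmax(psi, 0.001), 0.999)
}

rbetabinom <- function(n, size, prob, rho) {
  if (rho == 0) return(stats::rbinom(n, size, prob))
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  p <- stats::rbeta(n, a, b)
  stats::rbinom(n, size, p)
}

#' Simulate inclusion/skipping junction counts with known ground truth
#'
#' Per event and sample, the total junction count is negative-binomial and
#' the inclusion count is beta-binomial around the model's true PSI with
#' intra-class correlation `rho`. Cells are masked missing at
#' `missing_rate`. Identical seeds give identical output.
#'
#' @param psi_models list of [psi_model()] objects, one per event.
#' @param metadata a [sample_metadata()] table (>= 2 samples).
#' @param noise a [noise_params()] object.
#' @param seed integer seed (required).
#' @param chrom,event_spacing layout of the synthetic genomic coordinates
#'   assigned to the events.
#' @return list with `counts` (a [junction_counts()]), `true_psi`
#'   (events x samples matrix, pre-clamp model values clamped to
#'   `[0.001, 0.999]`) and `model_kind` (character per event).
#' @export
simulate_junction_counts <- function(psi_models, metadata, noise = noise_params(),
                                     seed, chrom = "chrSim",
                                     event_spacing = 10000L) {
  if (missing(seed)) stop("seed is required")
  if (length(psi_models) < 1L) stop("need at least one event")
  if (nrow(metadata) < 2L) stop("need at least two samples")
  if (inherits(psi_models, "psi_model")) psi_models <- list(psi_models)
  n_ev <- length(psi_models); n_sm <- nrow(metadata)
  withr_seed(seed)
  true_psi <- t(vapply(psi_models, true_psi_vector, numeric(n_sm),
                       metadata = metadata))
  if (n_sm == 1L) true_psi <- matrix(true_psi, ncol = 1L)
  size <- 1 / noise$total_count_dispersion
  totals <- matrix(stats::rnbinom(n_ev * n_sm, mu = noise$total_count_mean,
                                  size = size), n_ev, n_sm)
  L <- matrix(rbetabinom(n_ev * n_sm, as.vector(totals), as.vector(true_psi),
                         noise$rho), n_ev, n_sm)
  S <- totals - L
  if (noise$missing_rate > 0) {
    mask <- matrix(stats::runif(n_ev * n_sm) < noise$missing_rate, n_ev, n_sm)
    L[mask] <- NA; S[mask] <- NA
  }
  off <- seq_len(n_ev) * event_spacing
  ev <- splice_events(
    event_id = sprintf("ev%04d", seq_len(n_ev)),
    gene_id = sprintf("gene%04d", seq_len(n_ev)),
    event_type = "SE", chrom = chrom, strand = "+",
    exon_start = off + 1000L, exon_end = off + 1150L,
    upstream_exon_start = off, upstream_exon_end = off + 200L,
    downstream_exon_start = off + 2000L, downstream_exon_end = off + 2200L
  )
  counts <- junction_counts(ev, L, S, metadata)
  rownames(true_psi) <- ev$event_id; colnames(true_psi) <- metadata$sample_id
  list(counts = counts, true_psi = true_psi,
       model_kind = vapply(psi_models, `[[`, character(1L), "kind"))
}

withr_seed <- function(seed) set.seed(as.integer(seed))

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# replace in-frame stop codons deterministically (middle base -> T or C)
scrub_stops <- function(codons) {
  fix <- c(TAA = "TTA", TAG = "TTG", TGA = "TCA")
  ifelse(codons %in% names(fix), fix[codons], codons)
}

split_codons <- function(s) {
  substring(s, seq(1L, nchar(s), 3L), pmin(seq(3L, nchar(s) + 2L, 3L), nchar(s)))
}

#' Simulate a cassette-exon gene model with sequence
#'
#' Builds a single synthetic gene: a chain of exons separated by GT..AG
#' introns, with a cassette exon at `cassette_index`, an inclusion transcript
#' (all exons) and an exclusion transcript (cassette removed) sharing the
#' annotated start codon. The CDS of the inclusion mRNA is stop-free except
#' for its terminal stop codon. When skipping the cassette shifts the reading
#' frame, a premature stop in the shifted frame is guaranteed a few codons
#' after the cassette junction (a Leu/Ile/Asn stretch that reads as a stop in
#' both shifted frames), emulating decay-inducing exon skipping.
#'
#' @param exon_lengths integer exon lengths, 5' to 3'.
#' @param cassette_index which exon is the cassette (needs >= 1 flanking exon
#'   on each side).
#' @param cds_span length-2 integer vector: 0-based half-open CDS interval in
#'   inclusion-mRNA coordinates; its length must be a multiple of 3.
#' @param gc_target target GC fraction; the realized genomic GC is within
#'   +/- 0.05 (generator acceptance loop).
#' @param seed integer seed.
#' @param intron_length intron size between consecutive exons.
#' @param chrom chromosome name of the synthetic sequence.
#' @return list with `model` (a [gene_model()] with transcripts `"inc"` and
#'   `"exc"`), `genome` (named character vector of the chromosome sequence),
#'   and `event` (a [splice_events()] row for the cassette).
#' @export
simulate_gene_model <- function(exon_lengths, cassette_index, cds_span,
                                gc_target = 0.5, seed = 1L,
                                intron_length = 300L, chrom = "chrSim") {
  if (any(exon_lengths < 1L)) stop("exon lengths must be >= 1")
  n_ex <- length(exon_lengths)
  if (cassette_index < 2L || cassette_index > n_ex - 1L)
    stop("cassette must be flanked by at least one exon on each side")
  if (cds_span[1L] < 0 || cds_span[2L] > sum(exon_lengths) ||
      cds_span[1L] >= cds_span[2L])
    stop("CDS must lie inside the (inclusion) transcript")
  if ((cds_span[2L] - cds_span[1L]) %% 3L != 0L)
    stop("CDS length must be a multiple of 3")
  withr_seed(seed)
  tx_len <- sum(exon_lengths)
  ex_end_tx <- cumsum(exon_lengths)
  ex_start_tx <- ex_end_tx - exon_lengths
  cas_tx <- c(ex_start_tx[cassette_index], ex_end_tx[cassette_index])

  build_mrna <- function() {
    m <- random_dna(tx_len, gc_target)
    # impose start codon, stop-free internal codons, terminal stop
    cds <- substr(m, cds_span[1L] + 1L, cds_span[2L])
    codons <- split_codons(cds)
    codons[1L] <- "ATG"
    codons <- c(scrub_stops(codons[-length(codons)]), "TAA")
    shift <- (cas_tx[2L] - cas_tx[1L]) %% 3L
    cassette_in_cds <- cas_tx[1L] >= cds_span[1L] && cas_tx[2L] <= cds_span[2L]
    if (shift != 0L && cassette_in_cds) {
      # guarantee a shifted-frame PTC just after the cassette junction:
      # TTA ATT AAT is stop-free in frame 0 but reads TAA in both +1/+2 frames
      jc <- ceiling((cas_tx[2L] - cds_span[1L]) / 3) + 2L  # codon index
      if (jc + 2L < length(codons))
        codons[jc:(jc + 2L)] <- c("TTA", "ATT", "AAT")
    }
    paste0(substr(m, 1L, cds_span[1L]),
           paste(codons, collapse = ""),
           substr(m, cds_span[2L] + 1L, tx_len))
  }

  assemble <- function(mrna) {
    introns <- vapply(seq_len(n_ex - 1L), function(i)
      paste0("GT", random_dna(intron_length - 4L, gc_target), "AG"),
      character(1L))
    pieces <- character(2L * n_ex - 1L)
    pieces[seq(1L, by = 2L, length.out = n_ex)] <-
      substring(mrna, ex_start_tx + 1L, ex_end_tx)
    pieces[seq(2L, by = 2L, length.out = n_ex - 1L)] <- introns
    paste(pieces, collapse = "")
  }

  for (try in 1:50) {
    mrna <- build_mrna()
    genome_seq <- assemble(mrna)
    gc <- gc_content(genome_seq)
    if (abs(gc - gc_target) <= 0.05) break
  }
  if (abs(gc - gc_target) > 0.05)
    stop("could not reach GC target within +/-0.05")

  g_start <- (seq_len(n_ex) - 1L) * intron_length + ex_start_tx
  g_end <- g_start + exon_lengths
  tx2g <- function(pos_tx) {  # 0-based transcript offset -> genomic offset
    i <- findInterval(pos_tx, ex_start_tx)
    g_start[i] + (pos_tx - ex_start_tx[i])
  }
  cds_g <- c(tx2g(cds_span[1L]), tx2g(cds_span[2L] - 1L) + 1L)
  exons_inc <- cbind(start = g_start, end = g_end)
  exons_exc <- exons_inc[-cassette_index, , drop = FALSE]
  model <- gene_model(
    gene_id = "simGene", chrom = chrom, strand = "+",
    transcripts = list(
      inc = list(exons = exons_inc, cds_start = cds_g[1L], cds_end = cds_g[2L]),
      exc = list(exons = exons_exc, cds_start = cds_g[1L], cds_end = cds_g[2L])
    ))
  event <- splice_events(
    event_id = "simSE", gene_id = "simGene", event_type = "SE",
    chrom = chrom, strand = "+",
    exon_start = g_start[cassette_index], exon_end = g_end[cassette_index],
    upstream_exon_start = g_start[cassette_index - 1L],
    upstream_exon_end = g_end[cassette_index - 1L],
    downstream_exon_start = g_start[cassette_index + 1L],
    downstream_exon_end = g_end[cassette_index + 1L]
  )
  genome <- stats::setNames(genome_seq, chrom)
  list(model = model, genome = genome, event = event)
}

#' Plant IUPAC motif instances in a scrubbed background
#'
#' First removes every accidental match of `motif` from `sequence` by
#' deterministically mutating the middle base of each match to a base
#' outside that position's IUPAC class (repeated until clean, preserving
#' the rest of the background), then writes a concrete expansion of the
#' motif at each requested offset and re-scrubs any incidental match
#' created at the plant boundaries. The returned sequence matches the motif
#' at exactly the planted offsets.
#'
#' @param sequence background nucleotide string (ACGT).
#' @param motif IUPAC pattern (U allowed, treated as T).
#' @param offsets 0-based, non-overlapping plant positions.
#' @return the modified sequence.
#' @export
plant_motifs <- function(sequence, motif, offsets) {
  classes <- iupac_classes(motif)
  m <- length(classes)  # motif length in positions, not pattern characters
  n <- nchar(sequence)
  offsets <- sort(as.integer(offsets))
  if (any(offsets < 0L) || any(offsets + m > n))
    stop("offset out of range for the sequence")
  if (length(offsets) > 1L && any(diff(offsets) < m))
    stop("overlapping planted offsets")
  seqv <- strsplit(toupper(chartr("U", "T", sequence)), "")[[1L]]
  concrete <- vapply(classes, `[[`, character(1L), 1L)  # first allowed base
  protected <- unlist(lapply(offsets, function(o) (o + 1L):(o + m)))
  # deterministic replacement: first base outside the position's allowed class
  off_class <- function(allowed) setdiff(c("A", "C", "G", "T"), allowed)[1L]
  for (pass in 1:100) {
    for (o in offsets) seqv[(o + 1L):(o + m)] <- concrete
    hits <- scan_motif(paste(seqv, collapse = ""), motif)
    stray <- setdiff(hits, offsets)
    if (length(stray) == 0L) break
    for (s in stray) {
      span <- (s + 1L):(s + m)
      editable <- setdiff(span, protected)
      if (length(editable) == 0L)
        stop("cannot scrub a match overlapping only planted bases at offset ", s)
      pos <- editable[ceiling(length(editable) / 2)]
      seqv[pos] <- off_class(classes[[pos - s]])
    }
  }
  out <- paste(seqv, collapse = "")
  if (!identical(scan_motif(out, motif), offsets))
    stop("scrubbing failed to converge")
  out
}
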