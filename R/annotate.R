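#' Is an exon a microexon?
#'
#' Microexons are very short cassette exons of 3 to 27 nt (inclusive
#' bounds), a class that is predominantly frame-preserving.
#'
#' @param length exon length in nt (>= 1).
#' @return logical.
#' @export
classify_microexon <- function(length) {
  if (any(length < 1L)) stop("length must be >= 1")
  length >= 3L & length <= 27L
}

#' GC content of a nucleotide sequence
#'
#' `(G + C) / (A + C + G + T)`; `N` bases are excluded from the denominator.
#'
#' @param sequence non-empty string over ACGTN (case-insensitive).
#' @return fraction in `[0,1]`.
#' @export
gc_content <- function(sequence) {
  s <- toupper(sequence)
  counts <- vapply(c("A", "C", "G", "T"), function(b)
    lengths(regmatches(s, gregexpr(b, s, fixed = TRUE))), numeric(1L))
  denom <- sum(counts)
  if (nchar(s) == 0L || denom == 0) stop("empty or all-N sequence")
  (counts[["G"]] + counts[["C"]]) / denom
}

# assemble the mature mRNA of an exon chain (0-based half-open genomic
# intervals, ascending) in transcript orientation
splice_mrna <- function(exons, chrom, strand, genome) {
  pieces <- vapply(seq_len(nrow(exons)), function(i)
    fetch_seq(genome, chrom, exons[i, 1L], exons[i, 2L]), character(1L))
  mrna <- paste(pieces, collapse = "")
  if (strand == "-") mrna <- reverse_complement(mrna)
  mrna
}

# transcript offset of a genomic position for either strand (0-based; for
# '-' strand the transcript starts at the genomically rightmost base)
tx_offset <- function(pos, exons, strand) {
  lens <- exons[, 2L] - exons[, 1L]
  i <- which(pos >= exons[, 1L] & pos < exons[, 2L])
  if (length(i) != 1L) return(NA_integer_)
  if (strand == "+") {
    as.integer(sum(lens[seq_len(i - 1L)]) + (pos - exons[i, 1L]))
  } else {
    n <- nrow(exons)
    after <- if (i < n) sum(lens[(i + 1L):n]) else 0L
    as.integer(after + (exons[i, 2L] - 1L - pos))
  }
}

# first stop codon scanning in-frame from offset `from` (0-based); returns
# 0-based offset of the stop codon start, or NA
first_stop <- function(mrna, from) {
  n <- nchar(mrna)
  pos <- from
  while (pos + 3L <= n) {
    if (substr(mrna, pos + 1L, pos + 3L) %in% STOP_CODONS) return(pos)
    pos <- pos + 3L
  }
  NA_integer_
}

#' Predict NMD-triggering potential of a cassette exon
#'
#' Builds the inclusion and exclusion isoforms of the cassette from the
#' backbone transcript (the coding transcript containing the cassette with
#' the longest CDS), translates each from the shared annotated start codon,
#' and applies the exon-junction rule: an isoform is NMD-targeted iff its
#' first stop codon ends more than `rule_distance` nt upstream of its last
#' exon-exon junction. Cassette exons lying entirely in the UTR are `"none"`;
#' cassettes straddling a CDS boundary are flagged ambiguous and not called.
#'
#' @param model a [gene_model()].
#' @param event one-row [splice_events()] table locating the cassette.
#' @param genome chromosome sequences (named character or `DNAStringSet`).
#' @param rule_distance junction-rule distance in nt (default 50).
#' @return list: `nmd_isoform` (`"none"`, `"inclusion"`, `"exclusion"`,
#'   `"both"`, or `NA` when ambiguous), `ambiguous`,
#'   `ptc_distance_to_last_junction` (named, per isoform; `NA` when no PTC),
#'   `frame_preserving`.
#' @export
predict_nmd <- function(model, event, genome, rule_distance = 50L) {
  if (!model$coding) stop("gene model has no CDS; NMD prediction needs a coding gene")
  ev <- as.list(event[1L, ])
  # backbone: coding transcript containing the cassette, longest CDS
  cands <- Filter(function(t) !is.null(t$cds_start) &&
                    any(t$exons[, 1L] == ev$exon_start &
                        t$exons[, 2L] == ev$exon_end),
                  model$transcripts)
  if (length(cands) == 0L) stop("cassette exon not found in any coding transcript")
  cds_len <- vapply(cands, function(t) t$cds_end - t$cds_start, numeric(1L))
  bb <- cands[[which.max(cds_len)]]
  strand <- model$strand
  ex_inc <- bb$exons
  cas_row <- which(ex_inc[, 1L] == ev$exon_start & ex_inc[, 2L] == ev$exon_end)
  ex_exc <- ex_inc[-cas_row, , drop = FALSE]
  if (nrow(ex_exc) < 2L) stop("exclusion isoform needs at least 2 exons")

  mrna_inc <- splice_mrna(ex_inc, model$chrom, strand, genome)
  # start codon offset in the inclusion transcript
  start_g <- if (strand == "+") bb$cds_start else bb$cds_end - 1L
  cds_start_tx <- tx_offset(start_g, ex_inc, strand)
  if (is.na(cds_start_tx)) stop("CDS start is not exonic in the backbone")
  if (substr(mrna_inc, cds_start_tx + 1L, cds_start_tx + 3L) != "ATG")
    stop("start codon absent at the annotated CDS start")
  end_g <- if (strand == "+") bb$cds_end - 1L else bb$cds_start
  cds_end_tx <- tx_offset(end_g, ex_inc, strand) + 1L

  # cassette span in inclusion-transcript coordinates
  cas_tx_lo <- tx_offset(if (strand == "+") ev$exon_start else ev$exon_end - 1L,
                         ex_inc, strand)
  cas_tx_hi <- cas_tx_lo + (ev$exon_end - ev$exon_start)
  in_utr <- cas_tx_hi <= cds_start_tx || cas_tx_lo >= cds_end_tx
  straddles <- !in_utr &&
    (cas_tx_lo < cds_start_tx || cas_tx_hi > cds_end_tx)
  frame_preserving <- (ev$exon_end - ev$exon_start) %% 3L == 0L
  if (straddles)
    return(list(nmd_isoform = NA_character_, ambiguous = TRUE,
                ptc_distance_to_last_junction = c(inclusion = NA_integer_,
                                                  exclusion = NA_integer_),
                frame_preserving = frame_preserving))
  judge <- function(exons) {
    mrna <- splice_mrna(exons, model$chrom, strand, genome)
    st <- tx_offset(start_g, exons, strand)
    lens <- exons[, 2L] - exons[, 1L]
    last_junction <- sum(lens) - lens[if (strand == "+") nrow(exons) else 1L]
    stop_at <- first_stop(mrna, st)
    if (is.na(stop_at)) return(list(nmd = FALSE, dist = NA_integer_))
    dist <- as.integer(last_junction - (stop_at + 3L))
    list(nmd = dist > rule_distance, dist = dist)
  }
  if (in_utr) {
    j_inc <- judge(ex_inc); j_exc <- judge(ex_exc)
    return(list(nmd_isoform = "none", ambiguous = FALSE,
                ptc_distance_to_last_junction = c(inclusion = j_inc$dist,
                                                  exclusion = j_exc$dist),
                frame_preserving = frame_preserving))
  }
  j_inc <- judge(ex_inc)
  j_exc <- judge(ex_exc)
  nmd <- c(inclusion = j_inc$nmd, exclusion = j_exc$nmd)
  label <- if (all(nmd)) "both" else if (nmd[["inclusion"]]) "inclusion"
           else if (nmd[["exclusion"]]) "exclusion" else "none"
  list(nmd_isoform = label, ambiguous = FALSE,
       ptc_distance_to_last_junction = c(inclusion = j_inc$dist,
                                         exclusion = j_exc$dist),
       frame_preserving = frame_preserving)
}

#' Annotate cassette exons
#'
#' Length, microexon status, frame preservation, GC content of the exon
#' body, and (when a coding gene model is supplied) NMD-triggering
#' potential.
#'
#' @param events [splice_events()] table.
#' @param genome chromosome sequences.
#' @param models optional named list of [gene_model()] keyed by `gene_id`.
#' @param rule_distance NMD junction-rule distance.
#' @return data.frame of per-event annotations.
#' @export
annotate_events <- function(events, genome, models = NULL, rule_distance = 50L) {
  n <- nrow(events)
  gc <- vapply(seq_len(n), function(i)
    gc_content(fetch_seq(genome, events$chrom[i], events$exon_start[i],
                         events$exon_end[i])), numeric(1L))
  nmd <- rep(NA_character_, n)
  if (!is.null(models)) {
    for (i in seq_len(n)) {
      m <- models[[events$gene_id[i]]]
      if (!is.null(m) && m$coding)
        nmd[i] <- predict_nmd(m, events[i, ], genome, rule_distance)$nmd_isoform
    }
  }
  data.frame(event_id = events$event_id,
             length = events$exon_length,
             is_microexon = classify_microexon(events$exon_length),
             frame_preserving = events$exon_length %% 3L == 0L,
             gc = gc, nmd_isoform = nmd, stringsAsFactors = FALSE)
}

#' Compare two distributions with a Mann-Whitney U test
#'
#' Two-sided test using the normal approximation with tie correction and
#' continuity correction; also reports both medians. Degenerate all-tied
#' inputs give p = 1.
#'
#' @param a,b numeric vectors (length >= 3 each).
#' @return list: `statistic` (U for sample `a`), `pvalue`, `median_a`,
#'   `median_b`.
#' @export
compare_distributions <- function(a, b) {
  if (length(a) < 3L || length(b) < 3L) stop("need at least 3 values per sample")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) {
    p <- 1
  } else {
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    p <- 2 * stats::pnorm(z, lower.tail = FALSE)
    p <- min(p, 1)
  }
  list(statistic = U, pvalue = p,
       median_a = stats::median(a), median_b = stats::median(b))
}
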