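IUPAC_DNA <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# expand an IUPAC pattern (possibly with [..] groups and U) into a list of
# allowed-base character vectors, one per position
iupac_classes <- function(pattern) {
  p <- toupper(chartr("U", "T", pattern))
  out <- list()
  i <- 1L
  while (i <= nchar(p)) {
    ch <- substr(p, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(p, i, nchar(p)), fixed = TRUE)
      if (j < 0) stop("unbalanced '[' in pattern")
      grp <- strsplit(substr(p, i + 1L, i + j - 2L), "")[[1L]]
      bases <- sort(unique(unlist(IUPAC_DNA[grp])))
      if (any(!grp %in% names(IUPAC_DNA))) stop("invalid IUPAC code in group")
      out[[length(out) + 1L]] <- bases
      i <- i + j
    } else {
      if (!ch %in% names(IUPAC_DNA)) stop("invalid IUPAC code: ", ch)
      out[[length(out) + 1L]] <- IUPAC_DNA[[ch]]
      i <- i + 1L
    }
  }
  out
}

#' Scan a sequence for all (overlapping) matches of an IUPAC motif
#'
#' RNA-style patterns are accepted (U is treated as T), and `[..]` groups of
#' IUPAC codes are allowed, e.g. `"A[CU]GAC[AG]"`. Matches may overlap.
#'
#' @param sequence nucleotide string (ACGTN...; U treated as T).
#' @param pattern IUPAC pattern.
#' @return sorted integer vector of 0-based match offsets.
#' @export
#' @examples
#' scan_motif("GTGTGTG", "GTGTG")        # 0 2
#' scan_motif("ATGACG", "A[CU]GAC[AG]")  # 0
scan_motif <- function(sequence, pattern) {
  classes <- iupac_classes(pattern)
  s <- toupper(chartr("U", "T", sequence))
  rx <- paste0("(?=", paste(vapply(classes, function(b)
    if (length(b) == 1L) b else paste0("[", paste(b, collapse = ""), "]"),
    character(1L)), collapse = ""), ")")
  m <- gregexpr(rx, s, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(integer(0))
  as.integer(m) - 1L
}

#' Complement/reverse-complement a nucleotide string
#' @param sequence DNA string.
#' @return reverse complement string.
#' @export
reverse_complement <- function(sequence) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(sequence, function(s)
           paste(rev(strsplit(s, "")[[1L]]), collapse = ""), character(1L),
           USE.NAMES = FALSE))
}

# fetch [start, end) (0-based half-open) from a named genome vector,
# genome may be a named character vector or a Biostrings::DNAStringSet
fetch_seq <- function(genome, chrom, start, end) {
  if (methods::is(genome, "DNAStringSet")) {
    chr <- as.character(genome[[chrom]])
  } else {
    chr <- genome[[chrom]]
  }
  if (start < 0L || end > nchar(chr))
    stop("coordinates [", start, ",", end, ") outside ", chrom,
         " (length ", nchar(chr), ")")
  substr(chr, start + 1L, end)
}

#' Extract the five meta-regions around a cassette exon
#'
#' Returns, in transcript (pre-mRNA sense) orientation, the intronic windows
#' and exon bodies conventionally scanned for RBP motifs around a cassette
#' exon: the intron stretch downstream of the upstream exon
#' (`upstream_exon_flank`), the intron stretch immediately upstream of the
#' cassette (`upstream_intron`), the cassette exon itself, the intron
#' immediately downstream of the cassette (`downstream_intron`), and the
#' intron stretch upstream of the downstream exon (`downstream_exon_flank`).
#' Minus-strand events are reverse-complemented. When an intron is shorter
#' than `window` the region is truncated to the intron and flagged.
#'
#' @param event one row of a [splice_events()] table.
#' @param genome named character vector or `DNAStringSet` of chromosome
#'   sequences.
#' @param window flank width in nt (default 250).
#' @return list of class `flank_regions` with elements `sequences` (named
#'   character), `truncated` (named logical) and `region_names`.
#' @export
extract_flanks <- function(event, genome, window = 250L) {
  ev <- as.list(event[1L, ])
  plus <- ev$strand == "+"
  # genomic intron bounds, 0-based half-open
  if (plus) {
    int_up <- c(ev$upstream_exon_end, ev$exon_start)       # 5' intron
    int_dn <- c(ev$exon_end, ev$downstream_exon_start)     # 3' intron
  } else {
    int_up <- c(ev$exon_end, ev$upstream_exon_start)       # 5' intron (genomic right)
    int_dn <- c(ev$downstream_exon_end, ev$exon_start)     # 3' intron (genomic left)
  }
  len_up <- int_up[2L] - int_up[1L]
  len_dn <- int_dn[2L] - int_dn[1L]
  if (len_up < 1L || len_dn < 1L) stop("event has empty flanking introns")
  w_up <- min(window, len_up); w_dn <- min(window, len_dn)
  grab <- function(start, end) fetch_seq(genome, ev$chrom, start, end)
  if (plus) {
    seqs <- c(
      upstream_exon_flank  = grab(int_up[1L], int_up[1L] + w_up),
      upstream_intron      = grab(int_up[2L] - w_up, int_up[2L]),
      cassette_exon        = grab(ev$exon_start, ev$exon_end),
      downstream_intron    = grab(int_dn[1L], int_dn[1L] + w_dn),
      downstream_exon_flank = grab(int_dn[2L] - w_dn, int_dn[2L])
    )
  } else {
    seqs <- c(
      upstream_exon_flank  = reverse_complement(grab(int_up[2L] - w_up, int_up[2L])),
      upstream_intron      = reverse_complement(grab(int_up[1L], int_up[1L] + w_up)),
      cassette_exon        = reverse_complement(grab(ev$exon_start, ev$exon_end)),
      downstream_intron    = reverse_complement(grab(int_dn[2L] - w_dn, int_dn[2L])),
      downstream_exon_flank = reverse_complement(grab(int_dn[1L], int_dn[1L] + w_dn))
    )
  }
  truncated <- c(upstream_exon_flank = len_up < window,
                 upstream_intron = len_up < window,
                 cassette_exon = FALSE,
                 downstream_intron = len_dn < window,
                 downstream_exon_flank = len_dn < window)
  structure(list(sequences = seqs, truncated = truncated,
                 region_names = names(seqs)),
            class = "flank_regions")
}

#' Scan a motif over the flanking regions of many events
#'
#' @param events [splice_events()] table.
#' @param genome sequence source as in [extract_flanks()].
#' @param pattern IUPAC motif.
#' @param window flank width.
#' @return data.frame of motif hits: `event_id`, `region`, `offset`
#'   (0-based from the region's 5' end in transcript orientation) and
#'   `offset_1based`.
#' @export
scan_events <- function(events, genome, pattern, window = 250L) {
  res <- lapply(seq_len(nrow(events)), function(i) {
    fl <- extract_flanks(events[i, ], genome, window)
    hits <- lapply(fl$region_names, function(r) {
      off <- scan_motif(fl$sequences[[r]], pattern)
      if (length(off) == 0L) return(NULL)
      data.frame(event_id = events$event_id[i], region = r, offset = off,
                 offset_1based = off + 1L, stringsAsFactors = FALSE)
    })
    do.call(rbind, hits)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(event_id = character(0), region = character(0),
                      offset = integer(0), offset_1based = integer(0))
  out
}

# per-position motif coverage fraction for one region across events;
# returns matrix positions x 2 (covered count, events informative)
region_coverage <- function(events, genome, pattern, region, window) {
  m <- nchar(pattern)
  cov <- numeric(window); informative <- numeric(window)
  for (i in seq_len(nrow(events))) {
    fl <- extract_flanks(events[i, ], genome, window)
    s <- fl$sequences[[region]]
    len <- min(nchar(s), window)
    if (len < 1L) next
    covered <- logical(len)
    for (o in scan_motif(s, pattern)) {
      span <- (o + 1L):min(o + m, len)
      covered[span] <- TRUE
    }
    cov[seq_len(len)] <- cov[seq_len(len)] + covered
    informative[seq_len(len)] <- informative[seq_len(len)] + 1
  }
  cbind(covered = cov, informative = informative)
}

smooth_centered <- function(x, window) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - window %/% 2L); hi <- min(n, i + window %/% 2L)
    mean(x[lo:hi])
  }, numeric(1L))
}

#' Positional motif-enrichment profile of a target vs background exon set
#'
#' For each position of each meta-region (see [extract_flanks()]), computes
#' the fraction of events whose motif hits cover that position, smooths the
#' fractions with a centered window, and compares target vs background with
#' a one-sided two-proportion z-test per position (BH-adjusted across
#' positions). This is the motif-map style profile used to ask whether an
#' RBP's binding motif is enriched in the introns flanking regulated exons.
#'
#' @param target_events,background_events [splice_events()] tables
#'   (>= `min_events` rows each).
#' @param pattern IUPAC motif.
#' @param genome sequence source.
#' @param flank intron window in nt (default 250).
#' @param window smoothing window in nt (default 50).
#' @param min_events minimum events per set (default 20).
#' @return data.frame with `region`, `position` (0-based within region),
#'   `target_score`, `background_score`, `pvalue`, `fdr`; attribute `peak`
#'   holds the most enriched position.
#' @export
positional_enrichment <- function(target_events, background_events, pattern,
                                  genome, flank = 250L, window = 50L,
                                  min_events = 20L) {
  if (nrow(target_events) < min_events || nrow(background_events) < min_events)
    stop("need at least ", min_events, " events per set")
  regions <- c("upstream_exon_flank", "upstream_intron", "cassette_exon",
               "downstream_intron", "downstream_exon_flank")
  out <- lapply(regions, function(r) {
    w <- if (r == "cassette_exon")
      max(max(target_events$exon_length), max(background_events$exon_length))
    else flank
    tc <- region_coverage(target_events, genome, pattern, r, w)
    bc <- region_coverage(background_events, genome, pattern, r, w)
    keep <- tc[, "informative"] > 0 & bc[, "informative"] > 0
    if (!any(keep)) return(NULL)
    pt <- tc[keep, "covered"] / tc[keep, "informative"]
    pb <- bc[keep, "covered"] / bc[keep, "informative"]
    nt <- tc[keep, "informative"]; nb <- bc[keep, "informative"]
    # one-sided two-proportion z (target > background), pooled variance
    pool <- (tc[keep, "covered"] + bc[keep, "covered"]) / (nt + nb)
    se <- sqrt(pmax(pool * (1 - pool) * (1 / nt + 1 / nb), 1e-12))
    z <- (pt - pb) / se
    p <- stats::pnorm(z, lower.tail = FALSE)
    p[pool %in% c(0, 1)] <- 1
    data.frame(region = r, position = which(keep) - 1L,
               target_score = smooth_centered(pt, window),
               background_score = smooth_centered(pb, window),
               pvalue = p, stringsAsFactors = FALSE)
  })
  prof <- do.call(rbind, out)
  prof$fdr <- benjamini_hochberg(prof$pvalue)
  peak <- prof[which.max(prof$target_score - prof$background_score), ]
  attr(prof, "peak") <- peak
  prof
}

#' Pearson correlation of two numeric profiles
#'
#' Plumbing for expression/splicing correlation reports.
#' @param x,y numeric vectors of equal length.
#' @return Pearson correlation coefficient.
#' @export
correlate_profiles <- function(x, y) stats::cor(x, y, method = "pearson")
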