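#' Read an exon-level event/count table
#'
#' Reads a TSV in the junction-count dialect produced by exon-centric event
#' callers (rMATS JC/JCEC style): one row per event with genomic coordinates
#' and comma-separated per-sample inclusion (`IJC_SAMPLE`) and skipping
#' (`SJC_SAMPLE`) counts. Coordinates are normalized to the internal 0-based,
#' half-open convention (the rMATS `exonStart_0base` column already is).
#'
#' @param path path to the TSV file.
#' @param metadata a [sample_metadata()] table naming the samples in the
#'   order the count lists are written.
#' @param dialect `"rmats_jc"` or `"rmats_jcec"`. Both share the column
#'   layout; `"rmats_jcec"` additionally divides counts by the
#'   `IncFormLen`/`SkipFormLen` effective lengths when those columns are
#'   present (length normalization before the PSI ratio).
#' @return a [junction_counts()] object.
#' @export
read_event_table <- function(path, metadata, dialect = c("rmats_jc", "rmats_jcec")) {
  dialect <- match.arg(dialect)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("event_id", "GeneID", "chr", "strand", "exonStart_0base", "exonEnd",
           "upstreamES", "upstreamEE", "downstreamES", "downstreamEE",
           "IJC_SAMPLE", "SJC_SAMPLE")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  n_samp <- nrow(metadata)
  parse_counts <- function(txt, row, what) {
    v <- strsplit(txt, ",", fixed = TRUE)[[1L]]
    x <- suppressWarnings(as.numeric(v))
    if (length(x) != n_samp)
      stop("line ", row + 1L, ": ", what, " has ", length(x),
           " counts for ", n_samp, " samples")
    if (any(is.finite(x) & x < 0))
      stop("line ", row + 1L, ": negative count in ", what)
    x
  }
  L <- t(vapply(seq_len(nrow(tab)),
                function(i) parse_counts(tab$IJC_SAMPLE[i], i, "IJC_SAMPLE"),
                numeric(n_samp)))
  S <- t(vapply(seq_len(nrow(tab)),
                function(i) parse_counts(tab$SJC_SAMPLE[i], i, "SJC_SAMPLE"),
                numeric(n_samp)))
  if (n_samp == 1L) { L <- matrix(L, ncol = 1L); S <- matrix(S, ncol = 1L) }
  if (dialect == "rmats_jcec" &&
      all(c("IncFormLen", "SkipFormLen") %in% names(tab))) {
    L <- L / tab$IncFormLen
    S <- S / tab$SkipFormLen
  }
  ev <- splice_events(
    event_id = tab$event_id, gene_id = tab$GeneID,
    event_type = if ("event_type" %in% names(tab)) tab$event_type else "SE",
    chrom = tab$chr, strand = tab$strand,
    exon_start = tab$exonStart_0base, exon_end = tab$exonEnd,
    upstream_exon_start = tab$upstreamES, upstream_exon_end = tab$upstreamEE,
    downstream_exon_start = tab$downstreamES,
    downstream_exon_end = tab$downstreamEE
  )
  junction_counts(ev, L, S, metadata)
}

#' Write an event/count table in the rMATS-style dialect
#'
#' Inverse of [read_event_table()]; integer counts round-trip bit-exactly.
#'
#' @param counts a [junction_counts()] object.
#' @param path output TSV path.
#' @export
write_event_table <- function(counts, path) {
  ev <- counts$events
  fmt <- function(m) apply(m, 1L, function(r)
    paste(ifelse(is.na(r), "NA", format(r, digits = 15, scientific = FALSE,
                                        trim = TRUE)), collapse = ","))
  out <- data.frame(
    event_id = ev$event_id, GeneID = ev$gene_id, event_type = ev$event_type,
    chr = ev$chrom, strand = ev$strand,
    exonStart_0base = ev$exon_start, exonEnd = ev$exon_end,
    upstreamES = ev$upstream_exon_start, upstreamEE = ev$upstream_exon_end,
    downstreamES = ev$downstream_exon_start,
    downstreamEE = ev$downstream_exon_end,
    IJC_SAMPLE = fmt(counts$L), SJC_SAMPLE = fmt(counts$S),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Expects columns `sample_id`, and optionally `group`, `stage`, `tissue`,
#' `replicate`.
#' @param path TSV path.
#' @return [sample_metadata()] table.
#' @export
read_sample_metadata <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(tab)) stop("metadata needs a sample_id column")
  sample_metadata(
    sample_id = tab$sample_id,
    group = if ("group" %in% names(tab)) tab$group else "other",
    stage = if ("stage" %in% names(tab)) tab$stage else NA_real_,
    tissue = if ("tissue" %in% names(tab)) tab$tissue else NA_character_,
    replicate = if ("replicate" %in% names(tab)) tab$replicate else 1L
  )
}

#' Read gene models from a GTF file
#'
#' Parses `exon` and `CDS` features (1-based inclusive coordinates in the
#' file) into [gene_model()] objects with internal 0-based half-open
#' coordinates, grouped by gene.
#'
#' @param path GTF file path.
#' @return named list of [gene_model()] objects, one per gene.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type %in% c("exon", "CDS")]
  if (length(gr) == 0L) stop("no exon/CDS features in ", path)
  if (any(gr$type == "exon" & (is.na(gr$transcript_id) | gr$transcript_id == "")))
    stop("exon feature without transcript_id")
  grdf <- as.data.frame(gr)
  df <- data.frame(
    chrom = as.character(grdf$seqnames),
    start = grdf$start - 1L,  # GTF 1-based closed -> 0-based half-open
    end = grdf$end,
    strand = as.character(grdf$strand),
    type = as.character(grdf$type),
    gene_id = grdf$gene_id, transcript_id = grdf$transcript_id,
    stringsAsFactors = FALSE
  )
  out <- lapply(split(df, df$gene_id), function(g) {
    txs <- lapply(split(g, g$transcript_id), function(t) {
      ex <- t[t$type == "exon", c("start", "end")]
      ex <- ex[order(ex$start), , drop = FALSE]
      cds <- t[t$type == "CDS", , drop = FALSE]
      cds_span <- NULL
      if (nrow(cds)) {
        cds <- cds[order(cds$start), ]
        # contradictory CDS: overlapping segments on one transcript
        if (nrow(cds) > 1L && any(cds$start[-1L] < cds$end[-nrow(cds)]))
          stop("overlapping CDS segments on transcript ", t$transcript_id[1L])
        cds_span <- c(min(cds$start), max(cds$end))
      }
      list(exons = as.matrix(ex), cds_start = cds_span[1L], cds_end = cds_span[2L])
    })
    gene_model(gene_id = g$gene_id[1L], chrom = g$chrom[1L],
               strand = g$strand[1L], transcripts = txs)
  })
  out
}

#' Construct a gene model
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param transcripts named list; each element has `exons` (two-column matrix
#'   of 0-based half-open `start`,`end`, ascending) and optional genomic
#'   `cds_start`/`cds_end` (`NULL` for non-coding transcripts).
#' @return list of class `gene_model`; `$coding` flags whether any
#'   transcript has a CDS.
#' @export
gene_model <- function(gene_id, chrom, strand, transcripts) {
  for (nm in names(transcripts)) {
    t <- transcripts[[nm]]
    ex <- t$exons
    if (any(ex[, 1L] >= ex[, 2L])) stop("empty exon in transcript ", nm)
    if (nrow(ex) > 1L && any(ex[-1L, 1L] < ex[-nrow(ex), 2L]))
      stop("overlapping/unsorted exons in transcript ", nm)
    if (!is.null(t$cds_start) &&
        (t$cds_start < min(ex[, 1L]) || t$cds_end > max(ex[, 2L])))
      stop("CDS outside transcript bounds in ", nm)
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 transcripts = transcripts,
                 coding = any(vapply(transcripts,
                                     function(t) !is.null(t$cds_start),
                                     logical(1L)))),
            class = "gene_model")
}

#' Percentage of a set covered by an intersection
#'
#' Plain summary arithmetic used for overlap reporting, e.g. the fraction of
#' tissue-discovered exons also alternatively spliced during development.
#' Returns the unrounded percentage; round only at presentation time.
#'
#' @param n_intersection,n_total non-negative counts, `n_intersection <= n_total`,
#'   `n_total > 0`.
#' @return `100 * n_intersection / n_total`.
#' @export
#' @examples
#' summarize_overlap(5857, 7861)  # 74.51 (2 dp)
summarize_overlap <- function(n_intersection, n_total) {
  if (any(n_total <= 0)) stop("n_total must be > 0")
  if (any(n_intersection < 0) || any(n_intersection > n_total))
    stop("need 0 <= n_intersection <= n_total")
  100 * n_intersection / n_total
}

#' Consistency summary of up/down-regulated feature counts
#'
#' Checks and summarizes the arithmetic of a differential-expression style
#' report: total changed features must equal up + down.
#'
#' @param n_up,n_down non-negative counts.
#' @param n_total optional stated total; if given it is checked against
#'   `n_up + n_down`.
#' @return list with `total`, `up`, `down`, `pct_up`, `pct_down`, and
#'   `consistent` (`TRUE` iff a supplied total matches).
#' @export
summarize_updown <- function(n_up, n_down, n_total = NULL) {
  tot <- n_up + n_down
  consistent <- is.null(n_total) || identical(as.integer(n_total), as.integer(tot))
  list(total = tot, up = n_up, down = n_down,
       pct_up = summarize_overlap(n_up, tot),
       pct_down = summarize_overlap(n_down, tot),
       consistent = consistent)
}

#' Export cassette exons as BED6
#'
#' Writes one BED6 line (0-based half-open; strand in column 6) per event's
#' target exon. An empty event list yields an empty file.
#'
#' @param events a [splice_events()] table.
#' @param path output path.
#' @export
write_bed <- function(events, path) {
  if (nrow(events) == 0L) { file.create(path); return(invisible(path)) }
  lines <- paste(events$chrom, events$exon_start, events$exon_end,
                 events$event_id, 0L, events$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write a result table as TSV
#' @param x data.frame.
#' @param path output path.
#' @export
write_result_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
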