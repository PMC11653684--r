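#' Construct a table of splice events
#'
#' A splice-event table is a plain `data.frame` (class `splice_events`) with
#' one row per alternative-splicing event. All coordinates are 0-based,
#' half-open genomic intervals; conversion to other conventions happens only
#' at file boundaries.
#'
#' @param event_id character, unique event identifiers.
#' @param gene_id character, gene identifiers.
#' @param event_type one of `"SE"`, `"MXE"`, `"A5SS"`, `"A3SS"`, `"RI"`.
#' @param chrom character chromosome names.
#' @param strand `"+"` or `"-"`.
#' @param exon_start,exon_end integer bounds of the target (cassette) exon.
#' @param upstream_exon_start,upstream_exon_end,downstream_exon_start,downstream_exon_end
#'   integer bounds of the flanking exons. "Upstream"/"downstream" are in
#'   transcript orientation: for minus-strand events the upstream exon lies
#'   3' of the cassette in genomic coordinates.
#' @return a `data.frame` of class `splice_events` with an `exon_length`
#'   column (`exon_end - exon_start`).
#' @export
splice_events <- function(event_id, gene_id, event_type = "SE", chrom, strand,
                          exon_start, exon_end,
                          upstream_exon_start, upstream_exon_end,
                          downstream_exon_start, downstream_exon_end) {
  ev <- data.frame(
    event_id = as.character(event_id),
    gene_id = as.character(gene_id),
    event_type = as.character(event_type),
    chrom = as.character(chrom),
    strand = as.character(strand),
    exon_start = as.integer(exon_start),
    exon_end = as.integer(exon_end),
    upstream_exon_start = as.integer(upstream_exon_start),
    upstream_exon_end = as.integer(upstream_exon_end),
    downstream_exon_start = as.integer(downstream_exon_start),
    downstream_exon_end = as.integer(downstream_exon_end),
    stringsAsFactors = FALSE
  )
  ev$exon_length <- ev$exon_end - ev$exon_start
  validate_splice_events(ev)
}

validate_splice_events <- function(ev) {
  stopifnot(is.data.frame(ev))
  if (anyDuplicated(ev$event_id))
    stop("duplicate event_id: ", ev$event_id[duplicated(ev$event_id)][1L])
  if (!all(ev$event_type %in% c("SE", "MXE", "A5SS", "A3SS", "RI")))
    stop("unknown event_type")
  if (!all(ev$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(ev$exon_start >= ev$exon_end))
    stop("exon_start must be < exon_end")
  if (any(ev$exon_length < 1L))
    stop("exon_length must be >= 1")
  # flanking exons: upstream 5' of target in transcript orientation
  plus <- ev$strand == "+"
  bad_up <- ifelse(plus,
                   ev$upstream_exon_end > ev$exon_start,
                   ev$upstream_exon_start < ev$exon_end)
  bad_dn <- ifelse(plus,
                   ev$downstream_exon_start < ev$exon_end,
                   ev$downstream_exon_end > ev$exon_start)
  if (any(bad_up | bad_dn))
    stop("flanking exons must not overlap the cassette exon and must respect ",
         "transcript orientation (event ",
         ev$event_id[which(bad_up | bad_dn)[1L]], ")")
  class(ev) <- c("splice_events", "data.frame")
  ev
}

#' Construct sample metadata
#'
#' @param sample_id unique character sample names.
#' @param group condition label, e.g. `"GM"` / `"DM"` (default `"other"`).
#' @param stage ordered numeric developmental stage rank (`NA` if unused).
#' @param tissue tissue label (`NA` if unused).
#' @param replicate integer replicate index.
#' @return `data.frame` of class `sample_metadata`.
#' @export
sample_metadata <- function(sample_id, group = "other", stage = NA_real_,
                            tissue = NA_character_, replicate = 1L) {
  md <- data.frame(
    sample_id = as.character(sample_id),
    group = as.character(group),
    stage = as.numeric(stage),
    tissue = as.character(tissue),
    replicate = as.integer(replicate),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(md$sample_id)) stop("sample_ids must be unique")
  class(md) <- c("sample_metadata", "data.frame")
  md
}

#' Bundle inclusion/skipping junction counts with their events and samples
#'
#' @param events a [splice_events()] table.
#' @param L,S integer matrices (events x samples) of inclusion-junction (long
#'   form) and skipping-junction (short form) read counts. `NA` marks cells
#'   reported missing upstream.
#' @param metadata a [sample_metadata()] table; rows must match the columns
#'   of `L`/`S`.
#' @return list of class `junction_counts`.
#' @export
junction_counts <- function(events, L, S, metadata) {
  L <- as.matrix(L); S <- as.matrix(S)
  if (!identical(dim(L), dim(S))) stop("L and S must have identical dimensions")
  if (nrow(L) != nrow(events)) stop("count rows must match events")
  if (ncol(L) != nrow(metadata)) stop("count columns must match metadata rows")
  if (any(L < 0, na.rm = TRUE) || any(S < 0, na.rm = TRUE))
    stop("negative junction counts are not allowed")
  dimnames(L) <- dimnames(S) <- list(events$event_id, metadata$sample_id)
  structure(list(events = events, L = L, S = S, metadata = metadata),
            class = "junction_counts")
}

#' @export
print.junction_counts <- function(x, ...) {
  cat("junction_counts: ", nrow(x$L), " events x ", ncol(x$L), " samples\n",
      sep = "")
  invisible(x)
}

#' @export
print.psi_matrix <- function(x, ...) {
  cat("psi_matrix: ", nrow(x$psi), " events x ", ncol(x$psi), " samples; ",
      sum(x$missing_mask), " missing cells\n", sep = "")
  invisible(x)
}
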