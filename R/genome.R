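#' Genome builds
#'
#' A genome build is an ordered table of chromosomes with their lengths in
#' base pairs.  It defines the coordinate system used by the simulator, the
#' array emulator and the event-calling stage.  All internal coordinates are
#' 0-based half-open; TSV files on disk use 1-based inclusive coordinates
#' (SNP-array convention) and the readers/writers are the only place the
#' shift happens.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length integer vector of chromosome lengths in bp (all > 0).
#' @return A `genome_build` object (a data.frame with columns `chrom` and
#'   `length`).
#' @examples
#' gb <- genome_build(c("1", "2"), c(200e6, 150e6))
#' genome_size(gb)
#' @export
genome_build <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (length(chrom) != length(length) || length(chrom) == 0L)
    stop("chrom and length must be non-empty and of equal length")
  if (any(!is.finite(length)) || any(length <= 0))
    stop("chromosome lengths must be positive")
  structure(data.frame(chrom = chrom, length = length,
                       stringsAsFactors = FALSE),
            class = c("genome_build", "data.frame"))
}

#' Default human-like genome build
#'
#' 24 chromosomes with approximate human chromosome lengths (rounded to the
#' nearest Mbp).  Fully overridable: any [genome_build()] can be passed
#' wherever a genome is required, and a build can be loaded from a
#' two-column TSV with [read_genome_build()].
#'
#' @return A `genome_build` with chromosomes 1-22, X and Y.
#' @export
default_genome <- function() {
  genome_build(
    chrom  = c(as.character(1:22), "X", "Y"),
    length = c(249, 242, 198, 190, 182, 171, 159, 145, 138, 134,
               135, 133, 114, 107, 102, 90, 83, 80, 59, 64,
               47, 51, 156, 57) * 1e6
  )
}

#' Read a genome build from a two-column TSV
#'
#' @param path TSV file with columns `chrom` and `length` (header required,
#'   case-insensitive).
#' @return A [genome_build()].
#' @export
read_genome_build <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("chrom", "length") %in% names(df)))
    stop("genome build TSV needs columns 'chrom' and 'length'")
  genome_build(df$chrom, df$length)
}

#' Total genome size in bp
#' @param genome a [genome_build()].
#' @return Numeric, sum of chromosome lengths.
#' @export
genome_size <- function(genome) sum(genome$length)

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chrom)
  if (anyNA(i)) stop("unknown chromosome: ", paste(chrom[is.na(i)], collapse = ", "))
  genome$length[i]
}

#' Copy-number alteration events
#'
#' Build a validated table of CNA events.  Each event is a genomic segment
#' plus a kind and per-haplotype copy change; whole-genome duplication (wgd)
#' events are genome-wide and carry no segment.  "complex" events carry a
#' segment but are excluded from phylogeny placement (regions whose BAF/logR
#' structure cannot be decomposed into a single evolutionary step are merely
#' annotated, never interpreted).
#'
#' @param event_id character ids (unique).
#' @param chrom chromosome name per event (`NA` for wgd).
#' @param start,end 0-based half-open coordinates (`NA` for wgd).
#' @param kind one of `"gain"`, `"loss"`, `"cnloh"`, `"wgd"`, `"complex"`.
#' @param copy_delta integer per-haplotype copy change: >= 1 for gain,
#'   <= -1 for loss, 0 for cnloh; ignored for wgd (genome doubling).
#' @param haplotype optional haplotype index (1 or 2) the event sits on;
#'   used by the simulator/emulator, `NA` otherwise.
#' @param genome optional [genome_build()] used to validate coordinates.
#' @return A `cna_events` data.frame.
#' @export
cna_events <- function(event_id, chrom = NA_character_, start = NA_real_,
                       end = NA_real_, kind, copy_delta = NA_integer_,
                       haplotype = NA_integer_, genome = NULL) {
  n <- length(event_id)
  df <- data.frame(event_id = as.character(event_id),
                   chrom = rep_len(as.character(chrom), n),
                   start = rep_len(as.numeric(start), n),
                   end = rep_len(as.numeric(end), n),
                   kind = rep_len(as.character(kind), n),
                   copy_delta = rep_len(as.integer(copy_delta), n),
                   haplotype = rep_len(as.integer(haplotype), n),
                   stringsAsFactors = FALSE)
  validate_cna_events(df, genome)
  structure(df, class = c("cna_events", "data.frame"))
}

validate_cna_events <- function(df, genome = NULL) {
  if (anyDuplicated(df$event_id)) stop("event ids must be unique")
  bad_kind <- setdiff(df$kind, c("gain", "loss", "cnloh", "wgd", "complex"))
  if (length(bad_kind)) stop("unknown event kind: ", paste(bad_kind, collapse = ", "))
  wgd <- df$kind == "wgd"
  if (any(wgd & (!is.na(df$chrom) | !is.na(df$start))))
    stop("wgd events are genome-wide and carry no segment")
  seg <- !wgd
  if (any(seg & (is.na(df$chrom) | is.na(df$start) | is.na(df$end))))
    stop("non-wgd events require a segment")
  if (any(seg & !(df$start >= 0 & df$start < df$end)))
    stop("segments need 0 <= start < end")
  if (any(df$kind == "gain" & df$copy_delta < 1))
    stop("gain events need copy_delta >= 1")
  if (any(df$kind == "loss" & df$copy_delta > -1))
    stop("loss events need copy_delta <= -1")
  if (any(df$kind == "cnloh" & df$copy_delta != 0))
    stop("cnloh events need copy_delta 0")
  if (!is.null(genome)) {
    len <- chrom_length(genome, df$chrom[seg])
    if (any(df$end[seg] > len)) stop("segment end beyond chromosome length")
  }
  invisible(df)
}

#' Event length in bp
#'
#' @param events a `cna_events` table (or data.frame with `start`/`end`).
#' @return Numeric vector of `end - start` per event.  Genome-wide events
#'   (wgd) have no segment and raise an error.
#' @export
event_length <- function(events) {
  if (any(events$kind == "wgd") || anyNA(events$start))
    stop("no segment: wgd events are genome-wide and have no length")
  events$end - events$start
}

#' Filter events by minimum size
#'
#' Keeps events whose segment length is at least `min_len` bp.  Whole-genome
#' duplications are genome-scale and always kept.  The study's headline
#' filter is 1 Mbp ("events larger than 1 Mbp"), read as inclusive
#' >= 1,000,000 bp; the threshold is an argument, not a constant.  Order is
#' preserved and the operation is idempotent and monotone in `min_len`.
#'
#' @param events a `cna_events` table.
#' @param min_len minimum length in bp (>= 0).
#' @return The filtered `cna_events` table.
#' @export
size_filter <- function(events, min_len) {
  stopifnot(is.numeric(min_len), length(min_len) == 1L, min_len >= 0)
  if (nrow(events) == 0L) return(events)
  keep <- events$kind == "wgd" |
    (!is.na(events$start) & (events$end - events$start) >= min_len)
  events[keep, , drop = FALSE]
}

#' Reciprocal overlap of two genomic segments
#'
#' Fraction `min(overlap/len(a), overlap/len(b))`; 0 when the segments sit
#' on different chromosomes or do not intersect.  Symmetric and bounded by
#' 1.  Used to decide whether calls from different samples represent the
#' same alteration.
#'
#' @param a,b lists or one-row data.frames with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return A fraction in \[0, 1\].
#' @export
reciprocal_overlap <- function(a, b) {
  if (as.character(a$chrom) != as.character(b$chrom)) return(0)
  ov <- min(a$end, b$end) - max(a$start, b$start)
  if (ov <= 0) return(0)
  min(ov / (a$end - a$start), ov / (b$end - b$start))
}

seg_intersection <- function(a, b) {
  s <- max(a$start, b$start); e <- min(a$end, b$end)
  if (s >= e || as.character(a$chrom) != as.character(b$chrom))
    stop("segments do not intersect")
  list(chrom = as.character(a$chrom), start = s, end = e)
}

# order index of events by genome position (wgd first, then chrom order as in
# `chroms`, then start); used for deterministic tie-breaking
genome_order <- function(events, chroms) {
  ci <- match(events$chrom, chroms)
  ci[is.na(ci)] <- 0L  # wgd / unknown chrom sort first
  order(ci, ifelse(is.na(events$start), -1, events$start),
        ifelse(is.na(events$end), -1, events$end))
}
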