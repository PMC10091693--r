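# Files on disk use 1-based inclusive coordinates (SNP-array convention);
# everything internal is 0-based half-open.  The readers and writers in
# this file are the only place the shift happens.

config_error <- function(...) {
  stop(structure(class = c("clonecna_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Read a segment file
#'
#' Reads a TSV of called segments, one row per (sample, segment), in the
#' dialect of supplementary segment tables: columns `sample`, `chrom`,
#' `start`, `end` (1-based inclusive), `call`, and optionally `mean_logr`,
#' `mcf`, `n_probes`, `n_het`, `band_lower`, `band_upper`.  Headers are
#' matched case-insensitively; unknown columns are preserved.  Rows with
#' call `complex` are loaded and flagged (they stay out of tree building
#' downstream).
#'
#' @param path TSV file with a header.
#' @return Named list sample -> `called_segments` data.frame (coordinates
#'   converted to 0-based half-open).
#' @export
read_segment_file <- function(path) {
  if (!file.exists(path)) config_error("segment file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  names(df) <- tolower(names(df))
  req <- c("sample", "chrom", "start", "end", "call")
  miss <- setdiff(req, names(df))
  if (length(miss))
    config_error("segment file missing required columns: ",
                 paste(miss, collapse = ", "))
  if (!nrow(df)) {
    warning("segment file has a header but no rows: ", path)
    return(list())
  }
  df$chrom <- as.character(df$chrom)
  df$chrom[df$chrom %in% c("", "NA")] <- NA_character_
  genome_wide <- tolower(df$call) == "wgd"   # wgd rows carry no segment
  for (col in c("start", "end")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(v) & !genome_wide))
      config_error("non-numeric ", col, " in segment file row ",
                   which(is.na(v) & !genome_wide)[1])
    df[[col]] <- v
  }
  bad <- which(!is.na(df$start) & !is.na(df$end) & df$start > df$end)
  if (length(bad))
    config_error("start > end in segment file row ", bad[1])
  df$start <- df$start - 1  # to 0-based half-open
  for (col in c("mean_logr", "mcf", "band_lower", "band_upper", "sem_logr"))
    if (!col %in% names(df)) df[[col]] <- NA_real_
  if (!"n_probes" %in% names(df)) df$n_probes <- NA_integer_
  if (!"n_het" %in% names(df)) df$n_het <- NA_integer_
  if (!"baf_fold" %in% names(df))
    df$baf_fold <- ifelse(is.na(df$band_lower), NA_real_,
                          0.5 - df$band_lower)
  lapply(split(df, df$sample), function(s) {
    rownames(s) <- NULL
    structure(s, class = c("called_segments", "data.frame"),
              sample_id = s$sample[1])
  })
}

#' Convert loaded segments to events
#'
#' Turns the non-neutral rows of a [read_segment_file()] sample into a
#' [cna_events()] table, trusting the file's calls and MCFs (no floor or
#' threshold re-applied).  A row with call `wgd` becomes a genome-wide
#' event.
#'
#' @param segments one element of a [read_segment_file()] result.
#' @param sample_id id used in event ids.
#' @return A [cna_events()] table with `mcf` column.
#' @export
segments_to_events <- function(segments,
                               sample_id = attr(segments, "sample_id") %||% "S") {
  s <- segments[!segments$call %in% "neutral", , drop = FALSE]
  if (!nrow(s)) {
    ev <- cna_events(character(0), kind = character(0))
    ev$mcf <- numeric(0)
    return(ev)
  }
  wgd <- s$call == "wgd"
  ev <- cna_events(sprintf("%s_ev%02d", sample_id, seq_len(nrow(s))),
                   chrom = ifelse(wgd, NA_character_, s$chrom),
                   start = ifelse(wgd, NA_real_, s$start),
                   end = ifelse(wgd, NA_real_, s$end),
                   kind = s$call,
                   copy_delta = ifelse(s$call == "gain", 1L,
                                       ifelse(s$call == "loss", -1L, 0L)))
  ev$mcf <- s$mcf
  ev
}

#' Write / read an event-by-sample MCF matrix as TSV
#'
#' Columns: `event_id`, `chrom`, `start` (1-based inclusive), `end`,
#' `kind`, then one numeric column per sample.  Empty cells encode `NA`
#' ("not assessed"); 0 means confidently absent.
#'
#' @param matrix an [event_matrix()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_event_matrix <- function(matrix, path) {
  ev <- matrix$events
  df <- data.frame(event_id = ev$event_id,
                   chrom = ifelse(is.na(ev$chrom), "", ev$chrom),
                   start = ifelse(is.na(ev$start), "", ev$start + 1),
                   end = ifelse(is.na(ev$end), "", ev$end),
                   kind = ev$kind, stringsAsFactors = FALSE,
                   check.names = FALSE)
  m <- matrix$mcf
  for (s in matrix$samples)
    df[[s]] <- ifelse(is.na(m[, s]), "", format(m[, s], digits = 10,
                                                scientific = FALSE,
                                                trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_matrix
#' @param passages optional passage numbers stored on the read matrix.
#' @export
read_event_matrix <- function(path, passages = NULL) {
  if (!file.exists(path)) config_error("event matrix not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  names(df)[1:5] <- tolower(names(df)[1:5])
  req <- c("event_id", "chrom", "start", "end", "kind")
  if (!all(req %in% names(df)))
    config_error("event matrix needs columns ", paste(req, collapse = ", "))
  samples <- setdiff(names(df), req)
  if (!length(samples)) config_error("event matrix has no sample columns")
  num <- function(v) suppressWarnings(as.numeric(v))
  wgd <- df$kind == "wgd" | df$chrom == ""
  ev <- cna_events(df$event_id,
                   chrom = ifelse(wgd, NA_character_, df$chrom),
                   start = ifelse(wgd, NA_real_, num(df$start) - 1),
                   end = ifelse(wgd, NA_real_, num(df$end)),
                   kind = df$kind,
                   copy_delta = ifelse(df$kind == "gain", 1L,
                                       ifelse(df$kind == "loss", -1L, 0L)))
  m <- sapply(samples, function(s) {
    v <- num(ifelse(df[[s]] == "", NA, df[[s]]))
    v
  })
  m <- matrix(m, nrow = nrow(df), dimnames = list(df$event_id, samples))
  event_matrix(ev, m, samples, passages)
}

#' Write the full output set of a pipeline run
#'
#' Emits, under `dir`: per-regime event-matrix TSV, tree newick + JSON and
#' fishplot JSON; a combined segment TSV and per-sample event-count TSV;
#' group comparisons TSV; per-chromosome gain/loss summary TSV; the
#' effective configuration as JSON; and a run log recording the seed and
#' package/R versions.  All TSV output is deterministic given config and
#' seed.
#'
#' @param results a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(results, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2) != 0)
    stop("output directory not writable: ", dir)
  seg_rows <- list()
  for (rg in names(results$per_regime)) {
    r <- results$per_regime[[rg]]
    write_event_matrix(r$matrix, file.path(dir, paste0(rg, "_event_matrix.tsv")))
    writeLines(tree_newick(r$tree), file.path(dir, paste0(rg, "_tree.nwk")))
    jsonlite::write_json(tree_json(r$tree),
                         file.path(dir, paste0(rg, "_tree.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    fp <- r$fishplot
    jsonlite::write_json(
      list(timepoints = fp$timepoints, nodes = fp$nodes,
           cumulative = as.data.frame(fp$cumulative),
           own = as.data.frame(fp$own)),
      file.path(dir, paste0(rg, "_fishplot.json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(summarize_gain_loss(r$matrix),
                       file.path(dir, paste0(rg, "_gain_loss_summary.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (s in names(r$segments)) {
      seg <- r$segments[[s]]
      seg_rows[[paste(rg, s)]] <- data.frame(
        sample = s, regime = rg, chrom = seg$chrom, start = seg$start + 1,
        end = seg$end, call = seg$call, mean_logr = seg$mean_logr,
        n_probes = seg$n_probes, n_het = seg$n_het,
        band_lower = seg$band_lower, band_upper = seg$band_upper,
        stringsAsFactors = FALSE)
    }
  }
  utils::write.table(do.call(rbind, seg_rows), file.path(dir, "segments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(results$counts, file.path(dir, "event_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(results$comparisons))
    utils::write.table(results$comparisons, file.path(dir, "comparisons.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(serialize_config(results$config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(
    paste("clonecna version:",
          as.character(utils::packageVersion("clonecna"))),
    paste("R version:", R.version.string),
    paste("seed:", results$config$seed)),
    file.path(dir, "log.txt"))
  invisible(dir)
}
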