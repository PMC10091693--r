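#' Event-calling thresholds
#'
#' Bundle of the tunable parameters of the calling stage.  The logR
#' classification thresholds are deliberately lenient: classification must
#' not be the binding constraint on sensitivity — the clone-size
#' detectability floor (`clone_size_floor`, default 10% of cells, the
#' practical detection limit of clonal array analysis) is.
#'
#' @param t_gain segment called gain when (ploidy-adjusted) mean logR
#'   exceeds this (default 0.04).
#' @param t_loss segment called loss when mean logR is below `-t_loss`
#'   (default 0.04).
#' @param t_neutral |mean logR| at or below this counts as copy-neutral,
#'   enabling a cn-LOH call (default 0.02).
#' @param b_split minimum mirrored BAF band half-split for a cn-LOH call
#'   (default 0.06).
#' @param clone_size_floor events whose estimated MCF falls below this are
#'   not emitted (default 0.10).
#' @param complex_tol flag a segment complex when BAF- and logR-based MCF
#'   estimates disagree by more than this (default 0.35) — imbalances that
#'   cannot be a single one-copy step from the baseline.
#' @param min_het_probes het probes required before the BAF-based MCF
#'   estimate is trusted over the logR-based one (default 10).
#' @param reference_ploidy baseline total copy number (default 2).
#' @param stitch_gap,stitch_mcf_tol adjacent same-kind calls separated by
#'   at most `stitch_gap` bp whose MCFs differ by at most
#'   `stitch_mcf_tol` are stitched into one event (segmentation sometimes
#'   fractures one alteration into contiguous pieces).
#' @return A named list of thresholds.
#' @export
calling_thresholds <- function(t_gain = 0.04, t_loss = 0.04,
                               t_neutral = 0.02, b_split = 0.06,
                               clone_size_floor = 0.10, complex_tol = 0.35,
                               min_het_probes = 10L, reference_ploidy = 2,
                               stitch_gap = 1e5, stitch_mcf_tol = 0.15) {
  list(t_gain = t_gain, t_loss = t_loss, t_neutral = t_neutral,
       b_split = b_split, clone_size_floor = clone_size_floor,
       complex_tol = complex_tol, min_het_probes = min_het_probes,
       reference_ploidy = reference_ploidy, stitch_gap = stitch_gap,
       stitch_mcf_tol = stitch_mcf_tol)
}

# mixture identities, generalized to a baseline ploidy psi (= 2 for a
# diploid background): a single one-copy step carried by a fraction f of
# cells leaves these fingerprints in mean logR (L, relative to the psi
# baseline) and in the mirrored het BAF bands (b = lower, bu = upper):
#   loss : L = log2((psi - f)/psi)    b  = (psi/2 - f)/(psi - f)
#   gain : L = log2((psi + f)/psi)    bu = (psi/2 + f)/(psi + f)
#   cnloh: L = 0                      b  = (psi/2 - f)/psi
mcf_from_logr <- function(kind, L, psi = 2) {
  switch(kind,
         loss = psi * (1 - 2^L),
         gain = psi * (2^L - 1),
         cnloh = NA_real_)
}

mcf_from_baf <- function(kind, lower, upper, psi = 2) {
  switch(kind,
         loss = if (lower >= 1 - 1e-12) NA_real_
                else psi * (1 - 2 * lower) / (2 * (1 - lower)),
         gain = if (upper >= 1 - 1e-12) Inf
                else psi * (2 * upper - 1) / (2 * (1 - upper)),
         cnloh = psi / 2 * (1 - 2 * lower))
}

#' Estimate the mutated cell fraction of a called segment
#'
#' Inverts the single-step mixture identities for the segment's call.  The
#' BAF-based estimate is used when the segment holds at least
#' `min_het_probes` heterozygous probes (BAF is free of the logR baseline),
#' otherwise the logR-based one; the result is clipped to \[0, 1\].
#' With `L` the segment mean logR and `b` the lower het band, on a diploid
#' baseline: loss `f = (1-2b)/(1-b)` or `f = 2(1-2^L)`; gain
#' `f = (2bu-1)/(1-bu)` (upper band) or `f = 2(2^L-1)`; cn-LOH
#' `f = 1-2b`.
#'
#' @param call one row of a classified `called_segments` table (call must
#'   be gain, loss or cnloh).
#' @param reference_ploidy baseline total copy number (default 2); the
#'   segment mean logR is interpreted relative to
#'   `log2(reference_ploidy/2)`.
#' @param min_het_probes het-probe count needed for the BAF route
#'   (default 10).
#' @return MCF in \[0, 1\].
#' @export
estimate_mcf <- function(call, reference_ploidy = 2, min_het_probes = 10L) {
  kind <- call$call
  if (!kind %in% c("gain", "loss", "cnloh"))
    stop("MCF undefined for call '", kind, "'")
  psi <- reference_ploidy
  L <- call$mean_logr - log2(psi / 2)
  f_baf <- if (!is.na(call$baf_fold) && call$n_het >= min_het_probes)
    mcf_from_baf(kind, call$band_lower, call$band_upper, psi)
  else NA_real_
  f <- if (!is.na(f_baf) && is.finite(f_baf)) f_baf
       else mcf_from_logr(kind, L, psi)
  if (is.na(f)) stop("MCF inestimable: cn-LOH needs het BAF bands")
  min(1, max(0, f))
}

#' Classify segments as gain / loss / cn-LOH / neutral / complex
#'
#' Fills the `call` column of a [segment_signal()] result.  Relative to the
#' ploidy baseline: mean logR above `t_gain` is a gain, below `-t_loss` a
#' loss; a copy-neutral segment (|logR| <= `t_neutral`) whose mirrored BAF
#' bands split by more than `b_split` is cn-LOH; anything else is neutral.
#' A gain/loss/cnloh segment whose BAF- and logR-implied MCFs contradict
#' each other by more than `complex_tol` is re-labelled `complex`: its
#' allelic structure is not a single one-copy step and its evolutionary
#' trajectory is not decipherable, so it is annotated and excluded from
#' tree building.
#'
#' @param segments a `called_segments` table.
#' @param thresholds a [calling_thresholds()] list.
#' @param ploidy optional [detect_wgd()] result; when given (and flagged),
#'   logR is re-baselined to the detected ploidy before classification.
#' @return The segments table with `call` filled in.
#' @export
classify_segments <- function(segments, thresholds = calling_thresholds(),
                              ploidy = NULL) {
  th <- thresholds
  psi <- th$reference_ploidy
  if (!is.null(ploidy) && isTRUE(ploidy$wgd_flag)) psi <- ploidy$psi_hat
  base <- log2(psi / 2)
  for (i in seq_len(nrow(segments))) {
    L <- segments$mean_logr[i] - base
    has_bands <- !is.na(segments$baf_fold[i]) &&
      segments$n_het[i] >= th$min_het_probes
    split <- has_bands && segments$baf_fold[i] > th$b_split
    # the copy-neutrality test widens with the segment-mean noise: a short
    # segment's mean logR wobbles well past a fixed cutoff
    sem <- segments$sem_logr[i]
    t_neu <- if (!is.null(sem) && is.finite(sem))
      max(th$t_neutral, 3 * sem) else th$t_neutral
    call <-
      if (abs(L) <= t_neu && split) "cnloh"
      else if (L > th$t_gain) "gain"
      else if (L < -th$t_loss) "loss"
      else "neutral"
    if (call != "neutral" && has_bands) {
      f_b <- mcf_from_baf(call, segments$band_lower[i],
                          segments$band_upper[i], psi)
      f_l <- mcf_from_logr(call, L, psi)
      if (!is.na(f_b) && !is.na(f_l) &&
          abs(min(f_b, psi) - min(f_l, psi)) > th$complex_tol)
        call <- "complex"
      if (is.infinite(f_b)) call <- "complex"  # band at 1: total allelic loss
    }
    segments$call[i] <- call
  }
  attr(segments, "psi") <- psi
  segments
}

#' Call copy-number alteration events from classified segments
#'
#' Classifies segments (see [classify_segments()]), estimates each
#' non-neutral segment's MCF, and emits one event per gain/loss/cn-LOH
#' segment whose MCF clears the clone-size detectability floor; clonal
#' array analysis cannot resolve clones below ~10% of cells, so
#' sub-floor calls are suppressed rather than reported as uncertain.
#' Complex segments are emitted as `complex` events (annotation only; they
#' are never placed on the subclone tree and have `NA` MCF).  When a
#' [detect_wgd()] result with `wgd_flag` is supplied, a genome-wide `wgd`
#' event is appended with MCF `(psi_hat - 2)/2` (the genome-doubled cell
#' fraction implied by average ploidy) and segment logR is re-baselined
#' before classification.
#'
#' @param segments a `called_segments` table from one sample.
#' @param thresholds a [calling_thresholds()] list.
#' @param ploidy optional [detect_wgd()] result for this sample.
#' @param sample_id id used in event ids (default from segments).
#' @return A [cna_events()] table with an extra `mcf` column.
#' @export
call_events <- function(segments, thresholds = calling_thresholds(),
                        ploidy = NULL, sample_id = NULL) {
  if (is.null(sample_id))
    sample_id <- attr(segments, "sample_id") %||% "S"
  th <- thresholds
  segments <- classify_segments(segments, th, ploidy)
  psi <- attr(segments, "psi")
  rows <- list()
  for (i in seq_len(nrow(segments))) {
    call <- segments$call[i]
    if (call == "neutral") next
    if (call == "complex") {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = segments$chrom[i], start = segments$start[i],
        end = segments$end[i], kind = "complex", copy_delta = 0L,
        mcf = NA_real_, stringsAsFactors = FALSE)
      next
    }
    f <- estimate_mcf(segments[i, ], reference_ploidy = psi,
                      min_het_probes = th$min_het_probes)
    if (f < th$clone_size_floor) next
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = segments$chrom[i], start = segments$start[i],
      end = segments$end[i], kind = call,
      copy_delta = switch(call, gain = 1L, loss = -1L, 0L),
      mcf = f, stringsAsFactors = FALSE)
  }
  # stitch contiguous fragments of one alteration back together
  if (length(rows) >= 2L) {
    df <- do.call(rbind, rows)
    df <- df[order(df$chrom, df$start), ]
    keep <- rep(TRUE, nrow(df))
    for (i in 2:nrow(df)) {
      j <- max(which(keep[1:(i - 1L)]))
      len_i <- df$end[i] - df$start[i]; len_j <- df$end[j] - df$start[j]
      # a sliver (< 20% of its neighbour) is absorbed regardless of its
      # MCF: interior micro-fragments carry unreliable estimates
      sliver <- min(len_i, len_j) < 0.2 * max(len_i, len_j)
      same <- df$chrom[i] == df$chrom[j] && df$kind[i] == df$kind[j] &&
        df$kind[i] != "complex" &&
        df$start[i] - df$end[j] <= (th$stitch_gap %||% 1e5) &&
        (sliver ||
           abs(df$mcf[i] - df$mcf[j]) <= (th$stitch_mcf_tol %||% 0.15))
      if (same) {
        w <- c(df$end[j] - df$start[j], df$end[i] - df$start[i])
        df$mcf[j] <- sum(w * df$mcf[c(j, i)]) / sum(w)
        df$end[j] <- df$end[i]
        keep[i] <- FALSE
      }
    }
    rows <- lapply(which(keep), function(i) df[i, , drop = FALSE])
  }
  if (!is.null(ploidy) && isTRUE(ploidy$wgd_flag)) {
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = NA_character_, start = NA_real_, end = NA_real_,
      kind = "wgd", copy_delta = NA_integer_,
      mcf = min(1, max(0, (ploidy$psi_hat - 2) / 2)),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    ev <- cna_events(character(0), kind = character(0))
    ev$mcf <- numeric(0)
    return(ev)
  }
  df <- do.call(rbind, rows)
  ev <- cna_events(sprintf("%s_ev%02d", sample_id, seq_len(nrow(df))),
                   chrom = df$chrom, start = df$start, end = df$end,
                   kind = df$kind, copy_delta = df$copy_delta)
  ev$mcf <- df$mcf
  ev
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect whole genome duplication by ploidy grid search
#'
#' Converts every segment's (logR, BAF band) pair to implied allele-specific
#' copy numbers and scores how close they come to non-negative integers,
#' over a grid of candidate average ploidies psi.  Under median-centered
#' logR the implied total is `psi * 2^logR` and the grid is searched for
#' the best integer fit (smaller psi preferred at near-ties, the
#' conventional resolution of the ploidy ambiguity); under diploid-centered
#' logR the total `2 * 2^logR` is absolute, so psi is read directly as the
#' length-weighted mean total snapped to the grid.  The sample is flagged
#' genome-doubled when the fitted ploidy reaches `wgd_threshold`.
#'
#' @param segments a `called_segments` table covering at least half the
#'   genome.
#' @param psi_grid `c(lo, hi, step)` grid of candidate ploidies (default
#'   1.5-5.0 by 0.05).
#' @param centering `"diploid"` or `"median"` — how the logR baseline was
#'   set (default taken from the segments' source signal if recorded,
#'   otherwise diploid).
#' @param genome a [genome_build()] used for the coverage check.
#' @param wgd_threshold flag WGD at `psi_hat >=` this (default 3.0).
#' @param min_het_probes het probes needed to use a segment's BAF band for
#'   the allelic split (default 10; balanced split assumed otherwise).
#' @return A `ploidy_call` list: `psi_hat`, `wgd_flag`, `fit_score`.
#' @export
detect_wgd <- function(segments, psi_grid = c(1.5, 5.0, 0.05),
                       centering = NULL, genome = default_genome(),
                       wgd_threshold = 3.0, min_het_probes = 10L) {
  if (is.null(centering))
    centering <- attr(segments, "centering") %||% "diploid"
  centering <- match.arg(centering, c("diploid", "median"))
  len <- segments$end - segments$start
  if (sum(len) < 0.5 * genome_size(genome))
    stop("segments must cover at least 50% of the genome")
  w <- len / sum(len)
  bu <- ifelse(!is.na(segments$baf_fold) & segments$n_het >= min_het_probes,
               segments$band_upper, 0.5)
  psis <- seq(psi_grid[1], psi_grid[2], by = psi_grid[3])
  score <- function(total) {
    major <- total * bu; minor <- total * (1 - bu)
    sum(w * ((major - round(major))^2 + (minor - round(minor))^2))
  }
  if (centering == "median") {
    scores <- vapply(psis, function(p) score(p * 2^segments$mean_logr),
                     numeric(1))
    psi_hat <- psis[which(scores <= min(scores) + 1e-6)[1]]
    fit <- scores[match(psi_hat, psis)]
  } else {
    total <- 2 * 2^segments$mean_logr
    mean_total <- sum(w * total)
    psi_hat <- psis[which.min(abs(psis - mean_total))]
    fit <- score(total)
  }
  structure(list(psi_hat = psi_hat, wgd_flag = psi_hat >= wgd_threshold,
                 fit_score = fit),
            class = "ploidy_call")
}

#' Assemble the cross-sample event matrix
#'
#' Unifies events called independently in each sample into matrix rows:
#' two events represent the same alteration when they have the same kind
#' and reciprocal overlap at least `match_overlap` (wgd events match by
#' kind alone).  The unified segment is the running intersection of the
#' matched segments.  The MCF of an event in a sample where it was not
#' called is 0.  Rows are ordered by genome position.
#'
#' After assembly a consolidation pass runs: two rows of the same kind
#' whose segments still overlap reciprocally by at least
#' `consolidate_overlap` and whose sample supports are disjoint (they
#' never co-occur in any sample) are folded into one row.  Such pairs are
#' one alteration whose boundaries were drawn differently in different
#' samples — two genuinely distinct co-located same-kind alterations
#' would have to avoid every shared sample, which the events-never-revert
#' model makes implausible.
#'
#' @param per_sample_events named list (sample id -> [call_events()]
#'   result with `mcf` column).  Complex events are carried through with
#'   `NA` MCF where absent.
#' @param match_overlap reciprocal-overlap threshold (default 0.8).
#' @param genome a [genome_build()] (row ordering).
#' @param passages optional numeric passage per sample.
#' @param consolidate_overlap overlap at which non-co-occurring same-kind
#'   rows are folded together (default 0.5; NULL disables).
#' @return An [event_matrix()].
#' @export
build_event_matrix <- function(per_sample_events, match_overlap = 0.8,
                               genome = default_genome(), passages = NULL,
                               consolidate_overlap = 0.5) {
  samples <- names(per_sample_events)
  if (is.null(samples) || !length(samples)) stop("need at least one named sample")
  # the overlap test is taken against the best-matching member call, not
  # the running intersection: boundary jitter would otherwise shrink the
  # intersection and make later samples progressively harder to match
  uni <- list()   # each: chrom,start,end (intersection), kind, members
  mcf <- list()   # each: named numeric over samples
  for (s in samples) {
    ev <- per_sample_events[[s]]
    for (i in seq_len(nrow(ev))) {
      hit <- 0L; best_ov <- -1
      for (j in seq_along(uni)) {
        if (uni[[j]]$kind != ev$kind[i]) next
        if (ev$kind[i] == "wgd") { hit <- j; break }
        ov <- max(vapply(uni[[j]]$members, function(mb)
          reciprocal_overlap(mb, ev[i, ]), numeric(1)))
        if (ov >= match_overlap && ov > best_ov) { hit <- j; best_ov <- ov }
      }
      memb <- list(chrom = ev$chrom[i], start = ev$start[i],
                   end = ev$end[i])
      if (hit == 0L) {
        uni[[length(uni) + 1L]] <- list(chrom = ev$chrom[i],
                                        start = ev$start[i],
                                        end = ev$end[i], kind = ev$kind[i],
                                        members = list(memb))
        v <- stats::setNames(rep(0, length(samples)), samples)
        v[s] <- ev$mcf[i]
        mcf[[length(mcf) + 1L]] <- v
      } else {
        if (ev$kind[i] != "wgd") {
          uni[[hit]]$start <- max(uni[[hit]]$start, ev$start[i])
          uni[[hit]]$end <- min(uni[[hit]]$end, ev$end[i])
          uni[[hit]]$members <- c(uni[[hit]]$members, list(memb))
        }
        mcf[[hit]][s] <- ev$mcf[i]
      }
    }
  }
  # consolidation: same-kind overlapping rows that never co-occur
  if (!is.null(consolidate_overlap) && length(uni) >= 2L) {
    repeat {
      merged <- FALSE
      for (i in seq_along(uni)) {
        for (j in seq_along(uni)) {
          if (j <= i) next
          if (uni[[i]]$kind != uni[[j]]$kind ||
              uni[[i]]$kind == "wgd") next
          sup_i <- !is.na(mcf[[i]]) & mcf[[i]] > 0
          sup_j <- !is.na(mcf[[j]]) & mcf[[j]] > 0
          if (any(sup_i & sup_j)) next
          ov <- max(vapply(uni[[i]]$members, function(a)
            max(vapply(uni[[j]]$members, function(b)
              reciprocal_overlap(a, b), numeric(1))), numeric(1)))
          if (ov < consolidate_overlap) next
          uni[[i]]$start <- max(uni[[i]]$start, uni[[j]]$start)
          uni[[i]]$end <- min(uni[[i]]$end, uni[[j]]$end)
          uni[[i]]$members <- c(uni[[i]]$members, uni[[j]]$members)
          mcf[[i]][sup_j] <- mcf[[j]][sup_j]
          uni[[j]] <- NULL
          mcf[[j]] <- NULL
          merged <- TRUE
          break
        }
        if (merged) break
      }
      if (!merged) break
    }
  }
  if (!length(uni)) {
    ev <- cna_events(character(0), kind = character(0))
    return(event_matrix(ev, matrix(0, 0, length(samples)), samples, passages))
  }
  df <- data.frame(chrom = vapply(uni, `[[`, "", "chrom"),
                   start = vapply(uni, `[[`, 0, "start"),
                   end = vapply(uni, `[[`, 0, "end"),
                   kind = vapply(uni, `[[`, "", "kind"),
                   stringsAsFactors = FALSE)
  ord <- genome_order(df, genome$chrom)
  df <- df[ord, , drop = FALSE]
  m <- do.call(rbind, mcf)[ord, , drop = FALSE]
  # complex events: NA where never called in that sample
  cx <- df$kind == "complex"
  ev <- cna_events(sprintf("%s:%s-%s:%s",
                           ifelse(is.na(df$chrom), "genome", df$chrom),
                           ifelse(is.na(df$start), 0, df$start + 1),
                           ifelse(is.na(df$end), 0, df$end), df$kind),
                   chrom = df$chrom, start = df$start, end = df$end,
                   kind = df$kind,
                   copy_delta = ifelse(df$kind == "gain", 1L,
                                       ifelse(df$kind == "loss", -1L, 0L)))
  ev$event_id[ev$kind == "wgd"] <- "wgd"
  rownames(ev) <- NULL
  event_matrix(ev, m, samples, passages)
}
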