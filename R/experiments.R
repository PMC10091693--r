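# Reusable simulation experiments: detectability, tree recovery and WGD
# calling, each built from the package's own simulator/emulator/caller
# stack.  Tests and the acceptance script drive these functions rather
# than re-implementing the loops.

# compact genome used by the experiment helpers: enough chromosomes for
# realistic scan lengths, small enough for many replicates
experiment_genome <- function() {
  genome_build(as.character(1:6),
               c(180e6, 160e6, 150e6, 140e6, 120e6, 100e6))
}

#' Empirical detectability of a focal loss across clone fractions
#'
#' Simulates, for each clone fraction on the grid, a mixture in which one
#' subclone carries a single 5 Mbp one-copy loss, emulates an array sample
#' under default noise, runs segmentation and event calling with default
#' parameters, and records whether a loss event overlapping the true
#' segment (reciprocal overlap > 0.5) was emitted.  The detection rate per
#' fraction estimates the method's clone-size detectability curve, whose
#' rise pinpoints the practical detection floor of clonal array analysis.
#'
#' @param fractions grid of clone fractions (default 0.05-0.50 by 0.05).
#' @param n_rep replicates per fraction (default 50).
#' @param seed master seed.
#' @param event_size loss size in bp (default 5 Mbp).
#' @param thresholds a [calling_thresholds()] list.
#' @return data.frame with `fraction` and `detection_rate`.
#' @export
detection_experiment <- function(fractions = seq(0.05, 0.50, by = 0.05),
                                 n_rep = 50L, seed = 1L,
                                 event_size = 5e6,
                                 thresholds = calling_thresholds()) {
  genome <- experiment_genome()
  pm <- probe_map(genome, seed = seed)
  start <- 100e6; end <- start + event_size
  target <- list(chrom = "1", start = start, end = end)
  rate <- vapply(fractions, function(f) {
    clones <- data.frame(clone_id = c(1L, 2L), parent_id = c(NA, 1L),
                         fitness = 1, born = c(0L, 1L))
    ev <- cna_events("sub_loss", chrom = "1", start = start, end = end,
                     kind = "loss", copy_delta = -1L, haplotype = 2L)
    ev$clone_id <- 2L
    fr <- matrix(c(1 - f, f), 1, 2, dimnames = list("1", c("1", "2")))
    truth <- clone_truth(clones, ev, fr, 1, genome = genome)
    hits <- vapply(seq_len(n_rep), function(r) {
      sig <- emulate_sample(truth, 1, pm,
                            seed = stage_seed(seed, round(f * 100), r))
      called <- call_events(segment_signal(sig), thresholds)
      any(called$kind == "loss" & !is.na(called$chrom) &
            called$chrom == "1" &
            mapply(function(s, e)
              reciprocal_overlap(list(chrom = "1", start = s, end = e),
                                 target),
              called$start, called$end) > 0.5)
    }, logical(1))
    mean(hits)
  }, numeric(1))
  data.frame(fraction = fractions, detection_rate = rate)
}

#' Detection threshold from a detectability curve
#'
#' Two operationalizations of "smallest detectable clone size":
#' `level = 0.5` (default) interpolates the fraction at which the
#' monotonized detection curve crosses the given rate and snaps it to the
#' nearest grid point — the switch-on point of detection; `grid_rule`
#' instead returns the smallest grid fraction whose rate reaches `level`
#' (no interpolation), the conventional "reliably detected" reading.
#'
#' @param curve result of [detection_experiment()].
#' @param level detection rate defining the threshold.
#' @param grid_rule if TRUE return the smallest grid fraction with rate
#'   >= level; if FALSE (default) the interpolated crossing snapped to
#'   the grid.
#' @return Threshold fraction (NA if the curve never reaches `level`).
#' @export
detection_threshold <- function(curve, level = 0.5, grid_rule = FALSE) {
  f <- curve$fraction
  r <- cummax(curve$detection_rate)  # monotonize: rates rise with fraction
  if (all(r < level)) return(NA_real_)
  if (grid_rule) return(f[which(curve$detection_rate >= level)[1]])
  i <- which(r >= level)[1]
  if (i == 1L) return(f[1])
  cross <- f[i - 1L] + (level - r[i - 1L]) / (r[i] - r[i - 1L]) *
    (f[i] - f[i - 1L])
  f[which.min(abs(f - cross))]
}

# ---- random ground truths for recovery experiments --------------------------

#' Random clonal ground truth with distinguishable clones
#'
#' Draws a random clone tree (random parent among existing clones), gives
#' every non-founder clone 1-3 segmental events of 3-20 Mbp (non-
#' overlapping per haplotype within a lineage), and draws per-sample clone
#' fractions by a stick-breaking allocation down the tree.  Draws are
#' rejected until every non-founder clone reaches MCF >= `min_mcf` in at
#' least one sample and all clone MCF profiles are mutually separated by
#' more than `min_sep` in Chebyshev distance — the regime in which
#' ancestor-descendant relations are identifiable at clustering tolerance
#' `min_sep / 2`.
#'
#' @param n_clones clones including the founder (2-8).
#' @param n_samples number of samples.
#' @param seed RNG seed.
#' @param min_mcf detectability requirement per clone (default 0.2).
#' @param min_sep pairwise Chebyshev separation of clone profiles
#'   (default 0.25).
#' @param genome a [genome_build()].
#' @return A [clone_truth()] with samples recorded as passages
#'   `1..n_samples`.
#' @export
random_clone_truth <- function(n_clones, n_samples, seed,
                               min_mcf = 0.2, min_sep = 0.25,
                               genome = experiment_genome()) {
  stopifnot(n_clones >= 2, n_clones <= 8)
  set.seed(seed)
  for (try in 1:20000) {
    parent <- c(NA_integer_,
                vapply(2:n_clones, function(i)
                  sample.int(i - 1L, 1L), integer(1)))
    # per-sample stick-breaking: each clone keeps part of its share and
    # passes the rest to its children
    frac <- matrix(0, n_samples, n_clones,
                   dimnames = list(as.character(seq_len(n_samples)),
                                   as.character(seq_len(n_clones))))
    mcf <- matrix(0, n_samples, n_clones)
    for (s in seq_len(n_samples)) {
      cum <- numeric(n_clones)
      cum[1] <- 1
      for (i in 2:n_clones) {
        avail <- cum[parent[i]]
        kids_before <- which(parent[2:n_clones] == parent[i]) + 1L
        kids_before <- kids_before[kids_before < i]
        avail <- avail - sum(cum[kids_before])
        # children take most of what is available: large cumulative
        # fractions are what make nesting identifiable from MCFs alone
        cum[i] <- stats::runif(1, 0.5, 0.95) * max(0, avail)
        if (stats::runif(1) < 0.25) cum[i] <- 0  # clone absent here
      }
      own <- cum
      for (i in seq_len(n_clones)) {
        kids <- which(parent == i)
        own[i] <- cum[i] - sum(cum[kids])
      }
      frac[s, ] <- own
      mcf[s, ] <- cum
    }
    ok_detect <- all(apply(mcf[, -1, drop = FALSE], 2, max) >= min_mcf)
    seps <- TRUE
    for (i in 2:n_clones) for (j in seq_len(i - 1L))
      if (max(abs(mcf[, i] - mcf[, j])) <= min_sep) seps <- FALSE
    if (!ok_detect || !seps || any(frac < -1e-9)) next
    # identifiability: the true tree must be the unique member of the
    # exhaustively enumerated constraint-satisfying set, with margin
    # (tolerance 0.15 > the reconstruction tau of 0.10) so that noise
    # cannot open up alternative topologies.  A cheap necessary screen
    # first: no single cluster may be re-attachable to a different parent
    # without violating containment or pigeonhole.
    tau_chk <- 0.15
    true_parent <- vapply(2:n_clones, function(i)
      if (parent[i] == 1L) 0L else parent[i] - 1L, integer(1))
    k <- n_clones - 1L
    cumk <- mcf[, -1, drop = FALSE]           # samples x clusters
    lim <- function(q) if (q == 0L) rep(1, n_samples) else cumk[, q]
    ambiguous <- FALSE
    for (ci in seq_len(k)) {
      # clusters in ci's own subtree cannot serve as its parent
      sub <- ci
      repeat {
        more <- setdiff(which(true_parent %in% sub), sub)
        if (!length(more)) break
        sub <- c(sub, more)
      }
      for (q in setdiff(0:k, c(sub, true_parent[ci]))) {
        if (any(lim(q) < cumk[, ci] - tau_chk)) next    # containment fails
        kids <- setdiff(which(true_parent == q), ci)
        ssum <- cumk[, ci] + if (length(kids))
          rowSums(cumk[, kids, drop = FALSE]) else 0
        if (all(ssum <= lim(q) + tau_chk)) { ambiguous <- TRUE; break }
      }
      if (ambiguous) break
    }
    if (ambiguous) next
    fake_clusters <- lapply(2:n_clones, function(i)
      list(events = as.character(i),
           profile = stats::setNames(mcf[, i],
                                     as.character(seq_len(n_samples)))))
    sols <- enumerate_trees(fake_clusters, tau = tau_chk)
    if (length(sols) != 1L || !identical(sols[[1]], true_parent)) next
    frac[frac < 0] <- 0
    frac <- frac / rowSums(frac)

    # events: 1-3 per non-founder clone, 3-20 Mbp, globally disjoint —
    # overlapping events from unrelated clones create compound copy
    # states the single-step caller rightly refuses to decompose, which
    # is not what this experiment measures
    ev_rows <- list()
    carried <- data.frame(chrom = character(), start = numeric(),
                          end = numeric(), haplotype = integer())
    ok_place <- TRUE
    for (i in 2:n_clones) {
      k <- sample(1:3, 1)
      rows <- list()
      for (e in seq_len(k)) {
        done <- FALSE
        for (tr in 1:40) {
          size <- stats::runif(1, 3e6, 20e6)
          ci <- sample.int(nrow(genome), 1, prob = genome$length)
          if (size >= genome$length[ci]) next
          st <- floor(stats::runif(1, 0, genome$length[ci] - size))
          en <- floor(st + size)
          hap <- sample.int(2L, 1L)
          clash <- nrow(carried) > 0 &&
            any(carried$chrom == genome$chrom[ci] &
                  carried$start < en & st < carried$end)
          if (!clash) {
            kind <- sample(c("gain", "loss", "cnloh"), 1,
                           prob = c(0.4, 0.4, 0.2))
            rows[[e]] <- data.frame(chrom = genome$chrom[ci], start = st,
                                    end = en, kind = kind,
                                    copy_delta = switch(kind, gain = 1L,
                                                        loss = -1L, 0L),
                                    haplotype = hap,
                                    stringsAsFactors = FALSE)
            carried <- rbind(carried,
                             rows[[e]][, c("chrom", "start", "end",
                                           "haplotype")])
            done <- TRUE
            break
          }
        }
        if (!done) ok_place <- FALSE
      }
      if (!ok_place) break
      df <- do.call(rbind, rows)
      df$clone_id <- i
      ev_rows[[i]] <- df
    }
    if (!ok_place) next
    evdf <- do.call(rbind, ev_rows)
    ev <- cna_events(sprintf("e%03d", seq_len(nrow(evdf))), evdf$chrom,
                     evdf$start, evdf$end, evdf$kind, evdf$copy_delta,
                     evdf$haplotype, genome = genome)
    ev$clone_id <- evdf$clone_id
    clones <- data.frame(clone_id = seq_len(n_clones), parent_id = parent,
                         fitness = 1, born = c(0L, rep(1L, n_clones - 1L)))
    return(clone_truth(clones, ev, frac, seq_len(n_samples),
                       genome = genome))
  }
  stop("could not generate an admissible truth")
}

# ordered ancestor-descendant event-id pairs implied by a clone truth
truth_ad_pairs <- function(truth) {
  ev <- truth$events
  pairs <- character(0)
  for (i in seq_len(nrow(ev))) {
    desc <- setdiff(clone_descendants(truth$clones, ev$clone_id[i]),
                    ev$clone_id[i])
    below <- ev$event_id[ev$clone_id %in% desc]
    if (length(below))
      pairs <- c(pairs, paste(ev$event_id[i], below, sep = "<"))
  }
  pairs
}

# ordered ancestor-descendant pairs (in true-event-id terms) implied by a
# reconstructed tree, given a mapping called event id -> true event id
tree_ad_pairs <- function(tree, id_map) {
  pairs <- character(0)
  for (id in tree$nodes$node_id) {
    if (id == "root") next
    anc <- setdiff(ancestor_path(tree, id), c("root", id))
    ev_here <- id_map[tree$events[[id]]]
    ev_up <- id_map[unlist(tree$events[anc])]
    ev_here <- ev_here[!is.na(ev_here)]
    ev_up <- ev_up[!is.na(ev_up)]
    # same-branch events are unordered; only cross-branch pairs count
    for (a in ev_up) for (b in ev_here)
      pairs <- c(pairs, paste(a, b, sep = "<"))
  }
  pairs
}

#' One tree-recovery replicate
#'
#' Generates a [random_clone_truth()], emulates every sample with the
#' given noise, runs segmentation, event calling, event-matrix assembly
#' and tree reconstruction, then scores the result against the truth:
#' called events are matched to true events by kind and reciprocal
#' overlap > 0.5, ancestor-descendant event pairs are compared
#' (cross-branch pairs only, since ordering within one branch is not
#' identifiable), and the MCF RMSE over matched event/sample cells is
#' computed.
#'
#' @param seed replicate seed.
#' @param n_clones,n_samples truth dimensions (see
#'   [random_clone_truth()]).
#' @param sigma_logr,sigma_baf emulation noise.
#' @param tau tree tolerance.
#' @param thresholds a [calling_thresholds()] list.
#' @return List: `precision`, `recall` (NA when the truth implies no
#'   ancestor-descendant pair), `rmse`, `n_true_pairs`, `n_called`.
#' @export
recovery_replicate <- function(seed, n_clones = 6L, n_samples = 5L,
                               sigma_logr = 0.15, sigma_baf = 0.03,
                               tau = 0.10,
                               thresholds = calling_thresholds()) {
  truth <- random_clone_truth(n_clones, n_samples, seed)
  genome <- truth$genome
  pm <- probe_map(genome, seed = stage_seed(seed, 1L))
  events <- list()
  for (s in seq_len(n_samples)) {
    sid <- sprintf("S%02d", s)
    sig <- emulate_sample(truth, s, pm, sigma_logr, sigma_baf,
                          seed = stage_seed(seed, 2L, s), sample_id = sid)
    events[[sid]] <- call_events(segment_signal(sig), thresholds,
                                 sample_id = sid)
  }
  m <- build_event_matrix(events, genome = genome,
                          passages = seq_len(n_samples))
  true_m <- true_mcf_matrix(truth)
  # match called matrix rows to true events
  id_map <- stats::setNames(rep(NA_character_, nrow(m$events)),
                            m$events$event_id)
  for (i in seq_len(nrow(m$events))) {
    if (m$events$kind[i] %in% c("wgd", "complex")) next
    best <- 0.5; hit <- NA_character_
    for (j in seq_len(nrow(truth$events))) {
      if (truth$events$kind[j] != m$events$kind[i]) next
      ov <- reciprocal_overlap(m$events[i, ], truth$events[j, ])
      if (ov > best) { best <- ov; hit <- truth$events$event_id[j] }
    }
    id_map[i] <- hit
  }
  tree <- build_tree(cluster_events(matrix_for_tree(m), tau, genome), tau,
                     samples = m$samples)
  truth_pairs <- truth_ad_pairs(truth)
  called_pairs <- tree_ad_pairs(tree, id_map)
  tp <- sum(called_pairs %in% truth_pairs)
  precision <- if (length(called_pairs)) tp / length(called_pairs) else NA
  recall <- if (length(truth_pairs))
    sum(truth_pairs %in% called_pairs) / length(truth_pairs) else NA
  # MCF error over matched cells
  err <- numeric(0)
  for (i in seq_len(nrow(m$events))) {
    ti <- id_map[i]
    if (is.na(ti)) next
    err <- c(err, m$mcf[i, ] - true_m$mcf[ti, ])
  }
  list(precision = precision, recall = recall,
       rmse = if (length(err)) sqrt(mean(err^2)) else NA_real_,
       n_true_pairs = length(truth_pairs), n_called = nrow(m$events))
}

#' Whole-genome-duplication calling experiment
#'
#' Replicates of two constructed sample types: "wgd" mixtures (clonal
#' genome doubling plus 5 clonal segmental events, mimicking a
#' TP53-deficient sample) and "diploid" mixtures (no events).  Each
#' replicate is emulated under default noise, segmented, and run through
#' [detect_wgd()]; the fraction of replicates flagged genome-doubled is
#' returned per type.
#'
#' @param n_rep replicates per type (default 100).
#' @param seed master seed.
#' @param centering logR centering mode passed to the emulator/detector.
#' @return data.frame with `type` and `wgd_rate`.
#' @export
wgd_experiment <- function(n_rep = 100L, seed = 1L,
                           centering = "diploid") {
  genome <- experiment_genome()
  pm <- probe_map(genome, seed = seed)
  run_one <- function(type, r) {
    if (type == "wgd") {
      clones <- data.frame(clone_id = 1L, parent_id = NA_integer_,
                           fitness = 1, born = 0L)
      set.seed(stage_seed(seed, 5L, r))
      k <- 5L
      ci <- sample.int(nrow(genome), k, replace = TRUE)
      st <- vapply(ci, function(i)
        floor(stats::runif(1, 0, genome$length[i] - 21e6)), numeric(1))
      en <- st + floor(stats::runif(k, 5e6, 20e6))
      kind <- sample(c("gain", "loss"), k, replace = TRUE)
      ev <- cna_events(sprintf("e%02d", seq_len(k + 1)),
                       chrom = c(NA, genome$chrom[ci]),
                       start = c(NA, st), end = c(NA, en),
                       kind = c("wgd", kind),
                       copy_delta = c(NA, ifelse(kind == "gain", 1L, -1L)),
                       haplotype = c(NA, sample(1:2, k, replace = TRUE)))
      ev$clone_id <- 1L
      fr <- matrix(1, 1, 1, dimnames = list("1", "1"))
      truth <- clone_truth(clones, ev, fr, 1, genome = genome)
    } else {
      clones <- data.frame(clone_id = 1L, parent_id = NA_integer_,
                           fitness = 1, born = 0L)
      ev <- cna_events(character(0), kind = character(0))
      ev$clone_id <- integer(0)
      fr <- matrix(1, 1, 1, dimnames = list("1", "1"))
      truth <- clone_truth(clones, ev, fr, 1, genome = genome)
    }
    sig <- emulate_sample(truth, 1, pm, seed = stage_seed(seed, 6L, r),
                          centering = centering)
    seg <- segment_signal(sig)
    detect_wgd(seg, centering = centering, genome = genome)$wgd_flag
  }
  data.frame(
    type = c("wgd", "diploid"),
    wgd_rate = c(mean(vapply(seq_len(n_rep), function(r)
      run_one("wgd", r), logical(1))),
      mean(vapply(seq_len(n_rep), function(r)
        run_one("diploid", r), logical(1))))
  )
}

#' Programmed dominant-clone sweep
#'
#' Builds a deterministic clone truth in which a founder-derived clone A
#' dominates early passages and an unrelated sibling clone B sweeps to
#' dominance at a programmed passage — the classic clonal-replacement
#' pattern.  Used to verify that tree reconstruction plus
#' [detect_replacement()] recover the programmed switch exactly.
#'
#' @param switch_passage sampled passage at which B first dominates.
#' @param passages sampled passages (must contain `switch_passage`).
#' @param genome a [genome_build()].
#' @return A [clone_truth()].
#' @export
programmed_sweep_truth <- function(switch_passage = 20,
                                   passages = c(1, 8, 15, 20, 28, 36, 45),
                                   genome = experiment_genome()) {
  stopifnot(switch_passage %in% passages)
  clones <- data.frame(clone_id = 1:3,
                       parent_id = c(NA_integer_, 1L, 1L),
                       fitness = c(1, 1, 1.2), born = c(0L, 1L, 5L))
  ev <- cna_events(c("a1", "a2", "b1", "b2", "b3"),
                   chrom = c("1", "2", "3", "4", "5"),
                   start = c(20e6, 40e6, 10e6, 30e6, 50e6),
                   end = c(50e6, 60e6, 40e6, 60e6, 70e6),
                   kind = c("loss", "gain", "gain", "loss", "cnloh"),
                   copy_delta = c(-1L, 1L, 1L, -1L, 0L),
                   haplotype = c(1L, 2L, 1L, 2L, 1L), genome = genome)
  ev$clone_id <- c(2L, 2L, 3L, 3L, 3L)
  # B's fraction rises logistically, crossing A exactly at switch_passage
  fb <- 0.95 / (1 + exp(-0.35 * (passages - switch_passage + 0.5)))
  fa <- pmin(0.95 - fb, 0.9)
  fr <- cbind(1 - fa - fb, fa, fb)
  dimnames(fr) <- list(as.character(passages), c("1", "2", "3"))
  clone_truth(clones, ev, fr, passages, genome = genome)
}
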