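#' CIN regime configuration
#'
#' A regime bundles the per-passage dynamics of chromosomal instability for
#' one genetic background: how often clones acquire new copy-number events,
#' how likely a whole genome duplication is, the mix of event kinds, the
#' fitness consequences of events, and how well cells tolerate aneuploidy.
#' Presets encode the qualitative contrast observed between backgrounds:
#' TP53-deficient cells tolerate aneuploidy and can sweep through genome
#' doubling, while RB1/CDKN2A-deficient cells fail to establish new
#' detectable aneuploid clones.
#'
#' @param name regime label.
#' @param event_rate mean new segmental events per clone per passage
#'   (Poisson).
#' @param wgd_prob probability per clone per passage of spawning a
#'   genome-doubled child.
#' @param kind_weights named probabilities over `gain`, `loss`, `cnloh`
#'   (must sum to 1).
#' @param fitness_mean,fitness_sd mean/sd of the multiplicative fitness
#'   factor drawn per acquired event (1 = neutral).
#' @param aneuploidy_tolerance survival multiplier applied to clones
#'   carrying at least one event >= 1 Mbp; values well below 1 purge
#'   aneuploid clones before they become detectable.
#' @param wgd_fitness fitness multiplier of a genome-doubled clone.
#' @param complex_rate mean "complex" events (unresolvable overlapping
#'   gain+loss stacks) per clone per passage.
#' @return A `regime_config` list.
#' @seealso [regime_preset()]
#' @export
regime_config <- function(name, event_rate, wgd_prob, kind_weights,
                          fitness_mean = 1, fitness_sd = 0,
                          aneuploidy_tolerance = 1, wgd_fitness = 1,
                          complex_rate = 0) {
  stopifnot(event_rate >= 0, wgd_prob >= 0, wgd_prob <= 1,
            complex_rate >= 0, fitness_sd >= 0, aneuploidy_tolerance >= 0)
  kw <- kind_weights[c("gain", "loss", "cnloh")]
  if (anyNA(kw) || abs(sum(kw) - 1) > 1e-9)
    stop("kind_weights must be named over gain/loss/cnloh and sum to 1")
  structure(list(name = name, event_rate = event_rate, wgd_prob = wgd_prob,
                 kind_weights = kw, fitness_mean = fitness_mean,
                 fitness_sd = fitness_sd,
                 aneuploidy_tolerance = aneuploidy_tolerance,
                 wgd_fitness = wgd_fitness, complex_rate = complex_rate),
            class = "regime_config")
}

#' Preset CIN regimes
#'
#' Four presets mirroring the experimental backgrounds of a passaging study
#' of knocked-out immortalized fibroblasts:
#' \describe{
#'   \item{WT}{rare events, mild selection, full aneuploidy tolerance —
#'     retains the capacity for occasional clonal replacement.}
#'   \item{RB1, CDKN2A}{rare events whose carriers are strongly
#'     counter-selected (`aneuploidy_tolerance` well below 1): no new
#'     surviving detectable clones are expected.}
#'   \item{TP53}{frequent events, positive-probability whole genome
#'     duplication with a fitness advantage, and tolerance of aneuploidy,
#'     producing saltatory evolution through WGD.}
#' }
#' Event rates per background are free parameters chosen to reproduce the
#' qualitative contrast between regimes.
#'
#' @param name one of `"WT"`, `"RB1"`, `"CDKN2A"`, `"TP53"`.
#' @return A [regime_config()].
#' @export
regime_preset <- function(name = c("WT", "RB1", "CDKN2A", "TP53")) {
  name <- match.arg(name)
  kw <- c(gain = 0.4, loss = 0.4, cnloh = 0.2)
  switch(name,
    WT = regime_config("WT", event_rate = 0.08, wgd_prob = 0,
                       kind_weights = kw, fitness_mean = 1.05,
                       fitness_sd = 0.1, aneuploidy_tolerance = 1),
    RB1 = regime_config("RB1", event_rate = 0.08, wgd_prob = 0,
                        kind_weights = kw, fitness_mean = 0.9,
                        fitness_sd = 0.1, aneuploidy_tolerance = 0.1),
    CDKN2A = regime_config("CDKN2A", event_rate = 0.08, wgd_prob = 0,
                           kind_weights = kw, fitness_mean = 0.9,
                           fitness_sd = 0.1, aneuploidy_tolerance = 0.1),
    TP53 = regime_config("TP53", event_rate = 0.5, wgd_prob = 0.02,
                         kind_weights = kw, fitness_mean = 1.02,
                         fitness_sd = 0.15, aneuploidy_tolerance = 1.2,
                         wgd_fitness = 1.3, complex_rate = 0.02)
  )
}

#' Simulation configuration
#'
#' Parameters of one longitudinal passaging simulation.  The default layout
#' follows the study design: wild-type series cultured for 45 passages with
#' SNP-array samples at 7 time points; knockout series sampled at 3
#' passages (use `sampled_passages = c(15, 30, 45)` for those).
#'
#' @param genome a [genome_build()].
#' @param regime a [regime_config()].
#' @param n_passages number of passages to simulate (default 45).
#' @param bottleneck_size cells resampled at each passage bottleneck
#'   (default 10000).
#' @param sampled_passages passages at which array samples are taken
#'   (default 7 near-evenly spaced time points ending at `n_passages`).
#' @param event_size_range bp range of the log-uniform segmental event size
#'   distribution (default 0.5-50 Mbp).
#' @param seed integer RNG seed; the simulation is deterministic given the
#'   seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(genome = default_genome(),
                              regime = regime_preset("WT"),
                              n_passages = 45,
                              bottleneck_size = 10000,
                              sampled_passages = NULL,
                              event_size_range = c(5e5, 5e7),
                              seed = 1L) {
  if (is.null(sampled_passages))
    sampled_passages <- unique(round(seq(5, n_passages, length.out = 7)))
  stopifnot(nrow(genome) > 0, bottleneck_size >= 1, n_passages >= 1,
            length(event_size_range) == 2, event_size_range[1] > 0,
            event_size_range[2] >= event_size_range[1])
  if (any(sampled_passages < 1 | sampled_passages > n_passages))
    stop("sampled_passages must lie in [1, n_passages]")
  structure(list(genome = genome, regime = regime, n_passages = n_passages,
                 bottleneck_size = bottleneck_size,
                 sampled_passages = sort(unique(sampled_passages)),
                 event_size_range = event_size_range,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Construct a clone truth object
#'
#' Ground truth of a (simulated or programmed) clonal history: the clone
#' tree, the events acquired on each branch, and the clone fractions at
#' every recorded passage.  Events are never lost along a lineage (perfect
#' phylogeny), so a clone's event set is the union of branch events along
#' its ancestry.
#'
#' @param clones data.frame with columns `clone_id`, `parent_id` (`NA` for
#'   the founder), `fitness`, `born` (passage of origin).
#' @param events a [cna_events()] table with an extra `clone_id` column
#'   naming the branch each event was acquired on (may have zero rows).
#' @param fractions numeric matrix (passages x clones); rownames are
#'   passage numbers, colnames clone ids; each row sums to 1.
#' @param sampled_passages passages at which samples are taken (must be a
#'   subset of the recorded passages).
#' @param config optional originating [simulation_config()].
#' @param genome optional [genome_build()] (taken from `config` when
#'   absent); required downstream by the array emulator.
#' @return A `clone_truth` object.
#' @export
clone_truth <- function(clones, events, fractions, sampled_passages,
                        config = NULL, genome = NULL) {
  stopifnot(all(c("clone_id", "parent_id", "fitness") %in% names(clones)))
  if (!all(colnames(fractions) == as.character(clones$clone_id)))
    stop("fraction columns must match clone ids")
  if (any(abs(rowSums(fractions) - 1) > 1e-9))
    stop("clone fractions must sum to 1 at every passage")
  if (!all(as.character(sampled_passages) %in% rownames(fractions)))
    stop("sampled_passages must be recorded in fractions")
  if (nrow(events) > 0 && !all(events$clone_id %in% clones$clone_id))
    stop("events refer to unknown clones")
  if (is.null(genome) && !is.null(config)) genome <- config$genome
  structure(list(clones = clones, events = events, fractions = fractions,
                 sampled_passages = sampled_passages, config = config,
                 genome = genome),
            class = "clone_truth")
}

#' @export
print.clone_truth <- function(x, ...) {
  cat(sprintf("clone_truth: %d clones, %d events, %d passages (%d sampled)\n",
              nrow(x$clones), nrow(x$events), nrow(x$fractions),
              length(x$sampled_passages)))
  invisible(x)
}

# clone ids of `clone_id` and all its descendants
clone_descendants <- function(clones, clone_id) {
  out <- clone_id
  frontier <- clone_id
  repeat {
    kids <- clones$clone_id[!is.na(clones$parent_id) &
                              clones$parent_id %in% frontier]
    if (!length(kids)) break
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

# ancestry (founder .. clone) of one clone
clone_ancestry <- function(clones, clone_id) {
  path <- clone_id
  repeat {
    p <- clones$parent_id[match(path[1], clones$clone_id)]
    if (is.na(p)) break
    path <- c(p, path)
  }
  path
}

# event ids carried by a clone (accumulated along ancestry, in acquisition
# order)
clone_event_ids <- function(truth, clone_id) {
  anc <- clone_ancestry(truth$clones, clone_id)
  truth$events$event_id[truth$events$clone_id %in% anc][
    order(match(truth$events$clone_id[truth$events$clone_id %in% anc], anc))]
}

#' Simulate branching clonal evolution over serial passages
#'
#' Discrete per-passage dynamics, applied in order at every passage:
#' \enumerate{
#'   \item \strong{Mutation} — every existing clone spawns a child carrying
#'     `k ~ Poisson(event_rate)` new segmental events (child created only if
#'     `k >= 1`); event kinds follow `kind_weights`, sizes are log-uniform
#'     over `event_size_range`, positions uniform without overlapping the
#'     clone's existing events on the same haplotype.  With probability
#'     `wgd_prob` the clone additionally spawns a genome-doubled child.
#'   \item \strong{Selection} — discrete replicator update
#'     `x_i <- x_i w_i / sum_j x_j w_j`, where `w_i` is the clone's
#'     multiplicative fitness times the `aneuploidy_tolerance` factor if it
#'     carries any event >= 1 Mbp.
#'   \item \strong{Drift} — multinomial resampling of `bottleneck_size`
#'     cells; clones drawn at 0 cells go extinct.
#' }
#' Newborn clones start at one cell (`1/bottleneck_size`), taken from the
#' parent.  The run is deterministic given `config$seed` (single RNG
#' stream).
#'
#' @param config a [simulation_config()].
#' @return A [clone_truth()] with fractions recorded at passages
#'   `0..n_passages` (passage 0 = pure founder).
#' @export
simulate_lineage <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  reg <- config$regime
  genome <- config$genome
  set.seed(config$seed)

  clones <- data.frame(clone_id = 1L, parent_id = NA_integer_,
                       fitness = 1, born = 0L)
  has_large <- FALSE          # per clone: carries any event >= 1 Mbp
  ev <- list()                # list of per-event rows
  ev_n <- 0L
  frac <- 1                   # current fractions, aligned with clones
  hist <- list(`0` = frac)

  draw_events <- function(k, kinds, carried) {
    # carried: data.frame of this clone's existing segmental events
    rows <- vector("list", k)
    for (i in seq_len(k)) {
      kind <- kinds[i]
      placed <- FALSE
      for (try in 1:30) {
        size <- exp(stats::runif(1, log(config$event_size_range[1]),
                                 log(config$event_size_range[2])))
        ci <- sample.int(nrow(genome), 1, prob = genome$length)
        clen <- genome$length[ci]
        if (size >= clen) next
        start <- floor(stats::runif(1, 0, clen - size))
        end <- floor(start + size)
        hap <- sample.int(2L, 1L)
        clash <- nrow(carried) > 0 &&
          any(carried$chrom == genome$chrom[ci] & carried$haplotype == hap &
                carried$start < end & start < carried$end)
        if (!clash) {
          rows[[i]] <- data.frame(chrom = genome$chrom[ci], start = start,
                                  end = end, kind = kind,
                                  copy_delta = switch(kind, gain = 1L,
                                                      loss = -1L, 0L),
                                  haplotype = hap, stringsAsFactors = FALSE)
          carried <- rbind(carried,
                           rows[[i]][, c("chrom", "start", "end", "haplotype")])
          placed <- TRUE
          break
        }
      }
      if (!placed) rows[[i]] <- NULL
    }
    do.call(rbind, rows)
  }

  for (p in seq_len(config$n_passages)) {
    # --- mutation: iterate over the clones existing at passage start
    n0 <- nrow(clones)
    for (ci in seq_len(n0)) {
      if (frac[ci] <= 0) next
      k_seg <- stats::rpois(1, reg$event_rate)
      k_cplx <- if (reg$complex_rate > 0) stats::rpois(1, reg$complex_rate) else 0L
      if (k_seg + k_cplx >= 1 && frac[ci] > 1 / config$bottleneck_size) {
        kinds <- c(if (k_seg) sample(names(reg$kind_weights), k_seg,
                                     replace = TRUE, prob = reg$kind_weights),
                   rep("complex", k_cplx))
        anc <- clone_ancestry(clones, clones$clone_id[ci])
        carried_idx <- vapply(ev, function(e) e$clone_id %in% anc &&
                                !is.na(e$start), logical(1))
        carried <- if (any(carried_idx))
          do.call(rbind, lapply(ev[carried_idx], function(e)
            data.frame(chrom = e$chrom, start = e$start, end = e$end,
                       haplotype = e$haplotype, stringsAsFactors = FALSE)))
        else data.frame(chrom = character(), start = numeric(),
                        end = numeric(), haplotype = integer())
        new_ev <- draw_events(length(kinds), kinds, carried)
        if (!is.null(new_ev) && nrow(new_ev) > 0) {
          child_id <- nrow(clones) + 1L
          fit_mult <- prod(pmax(0.01, stats::rnorm(nrow(new_ev),
                                                   reg$fitness_mean,
                                                   reg$fitness_sd)))
          clones <- rbind(clones, data.frame(
            clone_id = child_id, parent_id = clones$clone_id[ci],
            fitness = clones$fitness[ci] * fit_mult, born = p))
          for (r in seq_len(nrow(new_ev))) {
            ev_n <- ev_n + 1L
            ev[[ev_n]] <- cbind(data.frame(event_id = sprintf("e%03d", ev_n),
                                           clone_id = child_id,
                                           stringsAsFactors = FALSE),
                                new_ev[r, , drop = FALSE])
          }
          has_large <- c(has_large, has_large[ci] ||
                           any(new_ev$end - new_ev$start >= 1e6))
          take <- 1 / config$bottleneck_size
          frac <- c(frac, take)
          frac[ci] <- frac[ci] - take
        }
      }
      # whole genome duplication child
      if (reg$wgd_prob > 0 && stats::runif(1) < reg$wgd_prob &&
          frac[ci] > 1 / config$bottleneck_size) {
        child_id <- nrow(clones) + 1L
        clones <- rbind(clones, data.frame(
          clone_id = child_id, parent_id = clones$clone_id[ci],
          fitness = clones$fitness[ci] * reg$wgd_fitness, born = p))
        ev_n <- ev_n + 1L
        ev[[ev_n]] <- data.frame(event_id = sprintf("e%03d", ev_n),
                                 clone_id = child_id, chrom = NA_character_,
                                 start = NA_real_, end = NA_real_,
                                 kind = "wgd", copy_delta = NA_integer_,
                                 haplotype = NA_integer_,
                                 stringsAsFactors = FALSE)
        has_large <- c(has_large, TRUE)
        take <- 1 / config$bottleneck_size
        frac <- c(frac, take)
        frac[ci] <- frac[ci] - take
      }
    }
    # --- selection (replicator with aneuploidy-tolerance survival factor)
    w <- clones$fitness * ifelse(has_large, reg$aneuploidy_tolerance, 1)
    x <- frac * w
    x <- x / sum(x)
    # --- drift (bottleneck resampling)
    counts <- stats::rmultinom(1, config$bottleneck_size, x)[, 1]
    frac <- counts / config$bottleneck_size
    hist[[as.character(p)]] <- frac
  }

  fr <- matrix(0, nrow = length(hist), ncol = nrow(clones),
               dimnames = list(names(hist), as.character(clones$clone_id)))
  for (i in seq_along(hist)) fr[i, seq_along(hist[[i]])] <- hist[[i]]

  events <- if (ev_n > 0) do.call(rbind, ev) else
    data.frame(event_id = character(), clone_id = integer(),
               chrom = character(), start = numeric(), end = numeric(),
               kind = character(), copy_delta = integer(),
               haplotype = integer(), stringsAsFactors = FALSE)
  clone_truth(clones, events, fr, config$sampled_passages, config)
}

#' True MCF matrix of a simulated history
#'
#' The mutated cell fraction of event `e` in the sample taken at passage
#' `s` is the summed fraction of all clones whose event set contains `e`
#' (the acquiring clone and its descendants).  Founder-branch events
#' therefore have MCF 1 in every sample.
#'
#' @param truth a [clone_truth()].
#' @param sampled_passages passages to tabulate (default: the truth's
#'   sampled passages); all must have been simulated.
#' @return An [event_matrix()] with one column per sampled passage (sample
#'   ids `P<passage>`).
#' @export
true_mcf_matrix <- function(truth, sampled_passages = truth$sampled_passages) {
  keys <- as.character(sampled_passages)
  if (!all(keys %in% rownames(truth$fractions)))
    stop("unknown passage: ",
         paste(setdiff(keys, rownames(truth$fractions)), collapse = ", "))
  ev <- truth$events
  mcf <- matrix(0, nrow = nrow(ev), ncol = length(keys),
                dimnames = list(ev$event_id, sprintf("P%02d", sampled_passages)))
  for (i in seq_len(nrow(ev))) {
    carriers <- as.character(clone_descendants(truth$clones, ev$clone_id[i]))
    mcf[i, ] <- rowSums(truth$fractions[keys, carriers, drop = FALSE])
  }
  event_matrix(ev, mcf, colnames(mcf), passages = sampled_passages)
}

#' Construct an event-by-sample MCF matrix
#'
#' The central intermediate of the analysis: rows are copy-number
#' alteration events (matched across samples), columns are samples, and
#' each element is the mutated cell fraction of that alteration in that
#' sample.  `NA` encodes "not assessed"; 0 means confidently absent.
#'
#' @param events a [cna_events()] table (row order defines matrix rows).
#' @param mcf numeric matrix events x samples with values in \[0, 1\] or
#'   `NA`.
#' @param samples sample ids (column order).
#' @param passages optional numeric passage per sample.
#' @return An `event_matrix` object.
#' @export
event_matrix <- function(events, mcf, samples, passages = NULL) {
  mcf <- as.matrix(mcf)
  if (nrow(mcf) != nrow(events) || ncol(mcf) != length(samples))
    stop("mcf dimensions must be events x samples")
  if (any(mcf < -1e-9 | mcf > 1 + 1e-9, na.rm = TRUE))
    stop("MCF values must lie in [0, 1]")
  mcf[] <- pmin(1, pmax(0, mcf))
  dimnames(mcf) <- list(events$event_id, samples)
  structure(list(events = events, mcf = mcf, samples = samples,
                 passages = passages),
            class = "event_matrix")
}

#' @export
print.event_matrix <- function(x, ...) {
  cat(sprintf("event_matrix: %d events x %d samples\n",
              nrow(x$mcf), ncol(x$mcf)))
  invisible(x)
}
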