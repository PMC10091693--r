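#' Pipeline run configuration
#'
#' All parameters of a full run, each with a recorded default.  The
#' default design mirrors a longitudinal passaging study: a wild-type-like
#' series followed for 45 passages with 7 array samples, and knockout-like
#' series sampled at 3 passages.
#'
#' @param genome a [genome_build()].
#' @param regimes character vector of [regime_preset()] names to run.
#' @param n_passages passages per series (default 45).
#' @param bottleneck_size cells kept at each passage (default 10000).
#' @param sampled_passages named list regime -> passages; defaults: 7
#'   near-even time points for WT, `c(15, 30, 45)` for knockouts.
#' @param spacing,het_frac probe map parameters (see [probe_map()]).
#' @param sigma_logr,sigma_baf array noise (see [emulate_sample()]).
#' @param centering logR centering mode (see [emulate_sample()]).
#' @param min_probes,alpha,merge_tol,merge_tol_baf segmentation parameters
#'   (see [segment_signal()]).
#' @param thresholds a [calling_thresholds()] list.
#' @param tau tree-building tolerance (see [build_tree()]).
#' @param min_len headline event-size filter in bp (default 1e6, the
#'   ">= 1 Mbp" rule).
#' @param match_overlap cross-sample event matching (see
#'   [build_event_matrix()]).
#' @param seed master seed; all stage seeds are derived from it.
#' @return A `run_config` list.
#' @export
run_config <- function(genome = default_genome(),
                       regimes = c("WT", "RB1", "CDKN2A", "TP53"),
                       n_passages = 45, bottleneck_size = 10000,
                       sampled_passages = NULL,
                       spacing = 5e4, het_frac = 0.3,
                       sigma_logr = 0.15, sigma_baf = 0.03,
                       centering = "diploid",
                       min_probes = 10L, alpha = 0.01,
                       merge_tol = 0.04, merge_tol_baf = 0.02,
                       thresholds = calling_thresholds(),
                       tau = 0.10, min_len = 1e6, match_overlap = 0.8,
                       seed = 1L) {
  if (is.null(sampled_passages))
    sampled_passages <- stats::setNames(lapply(regimes, function(r)
      if (r == "WT") unique(round(seq(5, n_passages, length.out = 7)))
      else unique(round(seq(n_passages / 3, n_passages, length.out = 3)))),
      regimes)
  structure(list(genome = genome, regimes = regimes,
                 n_passages = n_passages,
                 bottleneck_size = bottleneck_size,
                 sampled_passages = sampled_passages,
                 spacing = spacing, het_frac = het_frac,
                 sigma_logr = sigma_logr, sigma_baf = sigma_baf,
                 centering = centering, min_probes = as.integer(min_probes),
                 alpha = alpha, merge_tol = merge_tol,
                 merge_tol_baf = merge_tol_baf, thresholds = thresholds,
                 tau = tau, min_len = min_len,
                 match_overlap = match_overlap, seed = as.integer(seed)),
            class = "run_config")
}

serialize_config <- function(config) {
  out <- unclass(config)
  out$genome <- as.data.frame(config$genome)
  out
}

#' Read a run configuration from JSON
#'
#' Any subset of [run_config()] fields may appear in the file; missing
#' fields take the package defaults.  The genome may be given inline as
#' `{"chrom": [...], "length": [...]}` records or as a path to a
#' two-column TSV under `genome_tsv`.
#'
#' @param path JSON file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) config_error("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  if (!is.null(raw$genome_tsv)) args$genome <- read_genome_build(raw$genome_tsv)
  else if (!is.null(raw$genome))
    args$genome <- genome_build(raw$genome$chrom, raw$genome$length)
  if (!is.null(raw$thresholds))
    args$thresholds <- do.call(calling_thresholds, as.list(raw$thresholds))
  if (!is.null(raw$sampled_passages))
    args$sampled_passages <- lapply(raw$sampled_passages, as.numeric)
  scalars <- c("regimes", "n_passages", "bottleneck_size", "spacing",
               "het_frac", "sigma_logr", "sigma_baf", "centering",
               "min_probes", "alpha", "merge_tol", "merge_tol_baf", "tau",
               "min_len", "match_overlap", "seed")
  for (s in intersect(scalars, names(raw))) args[[s]] <- raw[[s]]
  bad <- setdiff(names(raw), c(scalars, "genome", "genome_tsv",
                               "thresholds", "sampled_passages"))
  if (length(bad))
    config_error("unknown config fields: ", paste(bad, collapse = ", "))
  do.call(run_config, args)
}

# stage seeds derived from the master seed, kept below 2^31
stage_seed <- function(seed, regime_index, offset = 0L) {
  (as.integer(seed) * 97L + regime_index * 1013L + as.integer(offset)) %%
    2000000000L
}

#' Restrict an event matrix to tree-placeable events
#'
#' Drops `complex` rows: regions whose allelic structure cannot be read
#' as a single evolutionary step are annotated but never placed on the
#' subclone tree.
#'
#' @param matrix an [event_matrix()].
#' @return The filtered [event_matrix()].
#' @export
matrix_for_tree <- function(matrix) {
  keep <- matrix$events$kind != "complex"
  event_matrix(matrix$events[keep, , drop = FALSE],
               matrix$mcf[keep, , drop = FALSE],
               matrix$samples, matrix$passages)
}

#' Run the full analysis pipeline on simulated series
#'
#' For every regime in the configuration: simulate the clonal history,
#' emulate one array sample per sampled passage, segment, detect whole
#' genome duplication, call events with MCFs, assemble the event matrix,
#' reconstruct the subclone tree, lay out the fishplot, and test for
#' dominant-clone replacement.  Per-sample event counts (total and
#' >= `min_len`) are tabulated across regimes and compared pairwise with
#' exact rank-sum tests when more than one regime is run.
#'
#' @param config a [run_config()].
#' @return A list with `per_regime` (each: `truth`, `segments`, `ploidy`,
#'   `events`, `matrix`, `tree`, `fishplot`, `replacement`), `counts`
#'   (data.frame), `comparisons` (data.frame or NULL) and the effective
#'   `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  th <- config$thresholds
  per_regime <- list()
  count_rows <- list()
  for (ri in seq_along(config$regimes)) {
    rg <- config$regimes[ri]
    sim_cfg <- simulation_config(
      genome = config$genome, regime = regime_preset(rg),
      n_passages = config$n_passages,
      bottleneck_size = config$bottleneck_size,
      sampled_passages = config$sampled_passages[[rg]],
      seed = stage_seed(config$seed, ri))
    truth <- simulate_lineage(sim_cfg)
    pm <- probe_map(config$genome, config$spacing, config$het_frac,
                    seed = stage_seed(config$seed, ri, 7L))
    segments <- list(); events <- list(); ploidy <- list()
    for (p in sim_cfg$sampled_passages) {
      sid <- sprintf("P%02d", p)
      sig <- emulate_sample(truth, p, pm, config$sigma_logr,
                            config$sigma_baf,
                            seed = stage_seed(config$seed, ri, 13L + p),
                            centering = config$centering, sample_id = sid)
      seg <- segment_signal(sig, config$min_probes, config$alpha,
                            config$merge_tol, config$merge_tol_baf)
      pl <- detect_wgd(seg, centering = config$centering,
                       genome = config$genome,
                       min_het_probes = th$min_het_probes)
      segments[[sid]] <- seg
      ploidy[[sid]] <- pl
      events[[sid]] <- call_events(seg, th,
                                   ploidy = if (pl$wgd_flag) pl else NULL,
                                   sample_id = sid)
    }
    m <- build_event_matrix(events, config$match_overlap, config$genome,
                            passages = sim_cfg$sampled_passages)
    tree <- build_tree(cluster_events(matrix_for_tree(m), config$tau,
                                      config$genome), config$tau,
                       samples = m$samples)
    tree$unplaced <- c(tree$unplaced,
                       m$events$event_id[m$events$kind == "complex"])
    fish <- fishplot_layout(tree, sim_cfg$sampled_passages)
    repl <- if (length(sim_cfg$sampled_passages) >= 2L)
      detect_replacement(tree, sim_cfg$sampled_passages) else NA_real_
    per_regime[[rg]] <- list(truth = truth, segments = segments,
                             ploidy = ploidy, events = events, matrix = m,
                             tree = tree, fishplot = fish,
                             replacement = repl)
    count_rows[[rg]] <- data.frame(
      sample = names(events), regime = rg,
      n_events = as.integer(count_events(events)),
      n_events_min_len = as.integer(count_events(events, config$min_len)),
      stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, count_rows)
  rownames(counts) <- NULL
  comparisons <- NULL
  if (length(config$regimes) >= 2L) {
    cmp <- function(col, metric) {
      by_g <- split(counts[[col]], counts$regime)
      out <- compare_groups(by_g)
      cbind(metric = metric, out, stringsAsFactors = FALSE)
    }
    comparisons <- rbind(cmp("n_events", "all_events"),
                         cmp("n_events_min_len", "events_ge_min_len"))
  }
  list(per_regime = per_regime, counts = counts,
       comparisons = comparisons, config = config)
}
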