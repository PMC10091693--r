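test_that("a mutation-free regime keeps the founder alone at fraction 1", {
  cfg <- simulation_config(
    genome = test_genome(),
    regime = regime_config("null", 0, 0, c(gain = 0.5, loss = 0.5,
                                           cnloh = 0)),
    n_passages = 10, sampled_passages = 10, seed = 1)
  tr <- simulate_lineage(cfg)
  expect_equal(nrow(tr$clones), 1L)
  expect_true(all(tr$fractions == 1))
  expect_equal(nrow(tr$events), 0L)
})

test_that("simulations are deterministic given the seed", {
  cfg <- simulation_config(genome = test_genome(),
                           regime = regime_preset("TP53"),
                           n_passages = 12, bottleneck_size = 1000,
                           sampled_passages = c(6, 12), seed = 42)
  a <- simulate_lineage(cfg)
  b <- simulate_lineage(cfg)
  expect_identical(a$fractions, b$fractions)
  expect_identical(a$events, b$events)
})

test_that("simulated histories obey perfect-phylogeny and pigeonhole", {
  for (seed in 1:3) {
    cfg <- simulation_config(genome = test_genome(),
                             regime = regime_preset("TP53"),
                             n_passages = 15, bottleneck_size = 1500,
                             sampled_passages = c(5, 10, 15), seed = seed)
    tr <- simulate_lineage(cfg)
    expect_true(all(abs(rowSums(tr$fractions) - 1) < 1e-9))
    m <- true_mcf_matrix(tr)
    expect_true(all(m$mcf >= -1e-9 & m$mcf <= 1 + 1e-9))
    # containment: an event on a parent branch has MCF >= any event on a
    # child branch, per sample
    for (i in seq_len(nrow(tr$clones))) {
      p <- tr$clones$parent_id[i]
      if (is.na(p)) next
      ev_c <- tr$events$event_id[tr$events$clone_id ==
                                   tr$clones$clone_id[i]]
      ev_p <- tr$events$event_id[tr$events$clone_id == p]
      if (!length(ev_c) || !length(ev_p)) next
      expect_true(all(m$mcf[ev_p[1], ] >= m$mcf[ev_c[1], ] - 1e-9))
    }
    # pigeonhole: sibling branches cannot sum past their parent
    for (p in tr$clones$clone_id) {
      kids <- tr$clones$clone_id[!is.na(tr$clones$parent_id) &
                                   tr$clones$parent_id == p]
      if (length(kids) < 2L) next
      kid_ev <- vapply(kids, function(k) {
        ids <- tr$events$event_id[tr$events$clone_id == k]
        if (length(ids)) ids[1] else NA_character_
      }, character(1))
      kid_ev <- kid_ev[!is.na(kid_ev)]
      if (length(kid_ev) < 2L) next
      p_ev <- tr$events$event_id[tr$events$clone_id == p]
      lim <- if (length(p_ev)) m$mcf[p_ev[1], ] else rep(1, ncol(m$mcf))
      expect_true(all(colSums(m$mcf[kid_ev, , drop = FALSE]) <=
                        lim + 1e-9))
    }
  }
})

test_that("true MCFs follow the carrying-clone definition", {
  # nested clones: founder(0.2) -> A(0.6 incl. child) -> B(0.2)
  clones <- data.frame(clone_id = 1:3, parent_id = c(NA, 1L, 2L),
                       fitness = 1, born = 0:2)
  ev <- cna_events(c("root_ev", "a_ev", "b_ev"), chrom = "1",
                   start = c(0, 20e6, 50e6), end = c(10e6, 30e6, 60e6),
                   kind = "gain", copy_delta = 1L)
  ev$clone_id <- 1:3
  fr <- matrix(c(0.4, 0.4, 0.2), 1, 3,
               dimnames = list("5", c("1", "2", "3")))
  tr <- clone_truth(clones, ev, fr, 5, genome = test_genome())
  m <- true_mcf_matrix(tr)
  expect_equal(unname(m$mcf["root_ev", 1]), 1.0)   # founder event
  expect_equal(unname(m$mcf["a_ev", 1]), 0.6)      # 0.4 + 0.2 carriers
  expect_equal(unname(m$mcf["b_ev", 1]), 0.2)      # private to B
  expect_error(true_mcf_matrix(tr, 99), "unknown passage")
})

test_that("mean surviving clone count matches an independent re-simulation", {
  # independent oracle: the same mutation/selection/drift update rules,
  # re-implemented directly on clone fractions (neutral fitness, so event
  # placement is irrelevant to the dynamics)
  oracle_one <- function(rate, bottleneck, n_pass) {
    frac <- 1
    p_child <- 1 - exp(-rate)
    for (p in seq_len(n_pass)) {
      n0 <- length(frac)
      for (i in seq_len(n0)) {
        if (frac[i] > 1 / bottleneck && stats::runif(1) < p_child) {
          frac <- c(frac, 1 / bottleneck)
          frac[i] <- frac[i] - 1 / bottleneck
        }
      }
      counts <- stats::rmultinom(1, bottleneck, frac)[, 1]
      frac <- counts / bottleneck
    }
    sum(frac > 0)
  }
  n_rep <- 40L
  reg <- regime_config("neutral", event_rate = 0.2, wgd_prob = 0,
                       kind_weights = c(gain = .4, loss = .4, cnloh = .2),
                       fitness_mean = 1, fitness_sd = 0)
  sim_counts <- vapply(seq_len(n_rep), function(r) {
    cfg <- simulation_config(genome = test_genome(), regime = reg,
                             n_passages = 15, bottleneck_size = 500,
                             sampled_passages = 15, seed = 5000 + r)
    tr <- simulate_lineage(cfg)
    sum(tr$fractions[nrow(tr$fractions), ] > 0)
  }, numeric(1))
  set.seed(77)
  ora_counts <- vapply(seq_len(n_rep), function(r)
    oracle_one(0.2, 500, 15), numeric(1))
  se <- sqrt(stats::var(sim_counts) / n_rep + stats::var(ora_counts) / n_rep)
  expect_lt(abs(mean(sim_counts) - mean(ora_counts)), 2 * se + 1e-9)
})

test_that("knockout regimes reproduce the detectable-aneuploidy contrast", {
  large_detectable <- function(regime, seed) {
    cfg <- simulation_config(genome = test_genome(), regime = regime,
                             n_passages = 20, bottleneck_size = 1500,
                             sampled_passages = c(10, 20), seed = seed)
    tr <- simulate_lineage(cfg)
    if (!nrow(tr$events)) return(0L)
    m <- true_mcf_matrix(tr)
    seg <- !is.na(tr$events$start)
    big <- seg & (tr$events$end - tr$events$start >= 1e6)
    sum(apply(m$mcf[big, , drop = FALSE], 1, max) > 0.1)
  }
  rb1 <- vapply(1:5, function(s) large_detectable(regime_preset("RB1"), s),
                integer(1))
  tp53 <- vapply(1:5, function(s) large_detectable(regime_preset("TP53"), s),
                 integer(1))
  expect_lte(mean(rb1), 1)       # essentially no surviving detectable CNAs
  expect_gt(mean(tp53), mean(rb1))  # TP53-like accumulates far more
})
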