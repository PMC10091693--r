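mk_seg <- function(call, mean_logr, band_lower = NA, band_upper = NA,
                   n_het = 30L, n_probes = 100L) {
  data.frame(chrom = "1", start = 0, end = 5e6, n_probes = n_probes,
             mean_logr = mean_logr, sem_logr = 0.015, n_het = n_het,
             baf_fold = if (is.na(band_lower)) NA_real_ else
               0.5 - band_lower,
             band_lower = band_lower, band_upper = band_upper,
             call = call, stringsAsFactors = FALSE)
}

test_that("MCF closed forms invert the mixture identities", {
  # clonal loss: logR -1 and lower band 0 both give f = 1
  expect_equal(estimate_mcf(mk_seg("loss", -1, 0, 1)), 1)
  expect_equal(estimate_mcf(mk_seg("loss", -1, n_het = 0L)), 1)
  # half-clonal loss from logR: L = log2(0.75) -> f = 0.5
  expect_equal(estimate_mcf(mk_seg("loss", log2(0.75), n_het = 0L)), 0.5)
  # half-clonal loss from BAF: b = 1/3 -> f = 0.5
  expect_equal(estimate_mcf(mk_seg("loss", log2(0.75), 1 / 3, 2 / 3)), 0.5)
  # gains: f = 0.5 -> logR log2(2.5/2), bands {0.4, 0.6}
  expect_equal(estimate_mcf(mk_seg("gain", log2(2.5 / 2), n_het = 0L)), 0.5)
  expect_equal(estimate_mcf(mk_seg("gain", log2(2.5 / 2), 0.4, 0.6)), 0.5)
  # cn-LOH from the lower band
  expect_equal(estimate_mcf(mk_seg("cnloh", 0, 0.25, 0.75)), 0.5)
  expect_error(estimate_mcf(mk_seg("neutral", 0)), "MCF undefined")
  expect_error(estimate_mcf(mk_seg("complex", 0.3)), "MCF undefined")
})

test_that("MCF estimates increase with |logR| for a fixed kind", {
  loss <- vapply(seq(-0.1, -0.9, by = -0.1), function(L)
    estimate_mcf(mk_seg("loss", L, n_het = 0L)), numeric(1))
  expect_true(all(diff(loss) > 0))
  gain <- vapply(seq(0.05, 0.55, by = 0.1), function(L)
    estimate_mcf(mk_seg("gain", L, n_het = 0L)), numeric(1))
  expect_true(all(diff(gain) > 0))   # below the clip to 1
})

test_that("segments classify by logR sign and BAF structure", {
  cls <- function(s) classify_segments(s)$call
  expect_equal(cls(mk_seg(NA, -0.9, 0.02, 0.98)), "loss")
  expect_equal(cls(mk_seg(NA, 0.0, 0.5, 0.5)), "neutral")
  expect_equal(cls(mk_seg(NA, 0.0, 0.25, 0.75)), "cnloh")
  # clonal two-copy state dressed as one segment: logR says total 4 but
  # BAF is balanced - contradictory, so complex
  expect_equal(cls(mk_seg(NA, 1.0, 0.5, 0.5)), "complex")
})

test_that("sub-floor clones yield no event under default noise", {
  pm <- probe_map(test_genome(), seed = 1)
  tr <- two_clone_truth(0.05)
  for (seed in 1:5) {
    sig <- emulate_sample(tr, 10, pm, seed = seed)
    called <- call_events(segment_signal(sig))
    hit <- called$kind == "loss" & !is.na(called$chrom) &
      called$chrom == "1" & called$start < 105e6 & called$end > 100e6
    expect_false(any(hit))
  }
})

test_that("MCF errors stay small across the detectable range", {
  pm <- probe_map(test_genome(), seed = 2)
  errs <- c()
  for (f in seq(0.2, 1.0, by = 0.2)) {
    tr <- two_clone_truth(f)
    for (seed in 1:5) {
      sig <- emulate_sample(tr, 10, pm, seed = 100 * f + seed)
      called <- call_events(segment_signal(sig))
      for (i in seq_len(nrow(tr$events))) {
        true_mcf <- if (tr$events$clone_id[i] == 1L) 1 else f
        hit <- which(called$kind == tr$events$kind[i] &
                       !is.na(called$chrom) &
                       called$chrom == tr$events$chrom[i])
        ovs <- vapply(hit, function(j)
          reciprocal_overlap(called[j, ], tr$events[i, ]), numeric(1))
        if (any(ovs > 0.5))
          errs <- c(errs, called$mcf[hit[which.max(ovs)]] - true_mcf)
      }
    }
  }
  expect_gt(length(errs), 50)
  expect_lte(sqrt(mean(errs^2)), 0.05)
})

test_that("ploidy grid search flags genome doubling and spares diploids", {
  pm <- probe_map(test_genome(), seed = 1)
  seg_dip <- segment_signal(emulate_sample(diploid_truth(), 10, pm,
                                           seed = 5))
  pl <- detect_wgd(seg_dip, genome = test_genome())
  expect_equal(pl$psi_hat, 2.0)
  expect_false(pl$wgd_flag)
  # clonal wgd, diploid-centered: logR ~ 1 genome-wide forces psi 4
  clones <- data.frame(clone_id = 1L, parent_id = NA_integer_,
                       fitness = 1, born = 0L)
  ev <- cna_events("w", kind = "wgd"); ev$clone_id <- 1L
  tw <- clone_truth(clones, ev, matrix(1, 1, 1,
                                       dimnames = list("1", "1")),
                    1, genome = test_genome())
  seg_wgd <- segment_signal(emulate_sample(tw, 1, pm, seed = 6))
  pw <- detect_wgd(seg_wgd, genome = test_genome())
  expect_equal(pw$psi_hat, 4.0, tolerance = 0.03)
  expect_true(pw$wgd_flag)
  # median-centered wgd + clonal loss: the loss's odd copy number breaks
  # the psi = 2 / psi = 4 ambiguity in favour of 4
  ev2 <- cna_events(c("w", "l"), chrom = c(NA, "1"),
                    start = c(NA, 20e6), end = c(NA, 60e6),
                    kind = c("wgd", "loss"), copy_delta = c(NA, -1L),
                    haplotype = c(NA, 1L))
  ev2$clone_id <- 1L
  tw2 <- clone_truth(clones, ev2, matrix(1, 1, 1,
                                         dimnames = list("1", "1")),
                     1, genome = test_genome())
  sigm <- emulate_sample(tw2, 1, pm, seed = 7, centering = "median")
  pm2 <- detect_wgd(segment_signal(sigm), centering = "median",
                    genome = test_genome())
  expect_true(pm2$wgd_flag)
  expect_equal(pm2$psi_hat, 4.0, tolerance = 0.03)
  # coverage precondition
  expect_error(detect_wgd(seg_dip[1, ], genome = default_genome()),
               "50%")
})

test_that("event matrices unify same-kind overlapping calls", {
  ev1 <- cna_events("a", chrom = "1", start = 0, end = 10e6,
                    kind = "loss", copy_delta = -1L)
  ev1$mcf <- 1
  per <- list(s1 = ev1, s2 = ev1, s3 = ev1)
  m <- build_event_matrix(per, genome = test_genome())
  expect_equal(nrow(m$events), 1L)
  expect_equal(unname(m$mcf[1, ]), c(1, 1, 1))
  # reciprocal overlap 0.5 < 0.8: two rows (and co-occurrence in s1/s2
  # keeps consolidation away)
  ev2 <- cna_events("b", chrom = "1", start = 5e6, end = 15e6,
                    kind = "loss", copy_delta = -1L)
  ev2$mcf <- 0.5
  m2 <- build_event_matrix(list(s1 = rbind(ev1, ev2), s2 = rbind(ev1, ev2)),
                           genome = test_genome())
  expect_equal(nrow(m2$events), 2L)
  # same segment, different kind: never unified
  ev3 <- cna_events("c", chrom = "1", start = 0, end = 10e6,
                    kind = "gain", copy_delta = 1L)
  ev3$mcf <- 0.4
  m3 <- build_event_matrix(list(s1 = ev1, s2 = ev3),
                           genome = test_genome())
  expect_equal(nrow(m3$events), 2L)
})
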