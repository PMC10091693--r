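test_that("mixture copy numbers average clone states by fraction", {
  expect_equal(mixture_copy_numbers(diploid_truth(), 10, "1", 50e6),
               c(h1 = 1, h2 = 1))
  # clonal wgd
  clones <- data.frame(clone_id = 1L, parent_id = NA_integer_,
                       fitness = 1, born = 0L)
  ev <- cna_events("w", kind = "wgd")
  ev$clone_id <- 1L
  tw <- clone_truth(clones, ev, matrix(1, 1, 1,
                                       dimnames = list("1", "1")),
                    1, genome = test_genome())
  expect_equal(mixture_copy_numbers(tw, 1, "1", 50e6), c(h1 = 2, h2 = 2))
  # one-copy loss in half the cells: lost haplotype averages 0.5
  tr <- two_clone_truth(0.5)
  expect_equal(mixture_copy_numbers(tr, 10, "1", 102e6),
               c(h1 = 1, h2 = 0.5))
})

test_that("expected logR and BAF follow the mixture identities", {
  expect_equal(expected_logr(1, 1), 0)
  expect_equal(expected_logr(1, 0), -1)
  expect_equal(expected_logr(1.5, 1), log2(2.5 / 2))
  expect_equal(expected_logr(0, 0), -5)   # floor for total loss
  expect_equal(expected_baf(1, 1, 1L), 0.5)
  expect_equal(expected_baf(1, 0, 2L), 0) # B haplotype lost
  expect_equal(expected_baf(1.5, 1, 1L), 0.6)
  expect_equal(expected_baf(0, 0, 1L), 0.5)
  # mirrored-BAF symmetry: swapping the B haplotype reflects around 0.5
  for (h in list(c(1, 1), c(1.5, 1), c(2, 0.3), c(0.2, 1.7)))
    expect_equal(expected_baf(h[1], h[2], 1L),
                 1 - expected_baf(h[1], h[2], 2L))
})

test_that("emulation is exact without noise and deterministic with it", {
  pm <- probe_map(test_genome(), seed = 1)
  sig0 <- emulate_sample(diploid_truth(), 10, pm, sigma_logr = 0,
                         sigma_baf = 0, seed = 1)
  expect_true(all(sig0$logr == 0))
  expect_true(all(sig0$baf[sig0$het] == 0.5))
  expect_true(all(sig0$baf[!sig0$het] %in% c(0, 1)))
  a <- emulate_sample(two_clone_truth(0.5), 10, pm, seed = 9)
  b <- emulate_sample(two_clone_truth(0.5), 10, pm, seed = 9)
  expect_identical(a, b)
})

test_that("emitted noise has the configured spread", {
  pm <- probe_map(genome_build("1", 500e6), spacing = 5e4, seed = 2)
  gb <- genome_build("1", 500e6)
  tr <- diploid_truth(gb)
  sig <- emulate_sample(tr, 10, pm, sigma_logr = 0.15, seed = 3)
  expect_equal(stats::sd(sig$logr), 0.15, tolerance = 0.01 / 0.15)
})

test_that("noiseless emulation round-trips through event calling", {
  pm <- probe_map(test_genome(), seed = 1)
  for (f in c(0.2, 0.5, 1.0)) {
    tr <- two_clone_truth(f)
    sig <- emulate_sample(tr, 10, pm, sigma_logr = 0, sigma_baf = 0,
                          seed = 1)
    called <- call_events(segment_signal(sig))
    truth_ev <- tr$events
    for (i in seq_len(nrow(truth_ev))) {
      true_mcf <- if (truth_ev$clone_id[i] == 1L) 1 else f
      if (true_mcf < 0.2) next
      hit <- which(called$kind == truth_ev$kind[i] &
                     !is.na(called$chrom) &
                     called$chrom == truth_ev$chrom[i])
      ovs <- vapply(hit, function(j)
        reciprocal_overlap(called[j, ], truth_ev[i, ]), numeric(1))
      expect_true(any(ovs >= 0.95),
                  info = sprintf("event %s at f=%.2f recovered",
                                 truth_ev$event_id[i], f))
      j <- hit[which.max(ovs)]
      expect_equal(called$mcf[j], true_mcf, tolerance = 1e-6)
    }
  }
})
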