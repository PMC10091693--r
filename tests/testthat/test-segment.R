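test_that("constant signal yields one neutral segment per chromosome", {
  pm <- probe_map(test_genome(), seed = 1)
  sig <- emulate_sample(diploid_truth(), 10, pm, seed = 4)
  seg <- classify_segments(segment_signal(sig))
  expect_equal(nrow(seg), 2L)
  expect_true(all(seg$call == "neutral"))
})

test_that("a strong step is localized to within two probes", {
  # 200-probe chromosome with a -1.0 step at probe 120, sigma = 0.1
  for (seed in 1:5) {
    set.seed(seed)
    n <- 200L
    pos <- seq(25e3, by = 5e4, length.out = n)
    truth_step <- 120L
    x <- c(rep(0, truth_step), rep(-1, n - truth_step)) +
      stats::rnorm(n, 0, 0.1)
    sig <- data.frame(chrom = "1", pos = pos, logr = x,
                      baf = stats::runif(n), het = FALSE)
    seg <- segment_signal(sig)
    expect_equal(nrow(seg), 2L)
    bk_bp <- seg$end[1]
    bk_probe <- findInterval(bk_bp, pos)
    expect_lte(abs(bk_probe - truth_step), 2L)
  }
})

test_that("degenerate chromosomes come back as a single segment", {
  sig <- data.frame(chrom = "1", pos = c(1e4, 2e4),
                    logr = c(0.5, -0.5), baf = c(0.5, 0.5),
                    het = c(TRUE, TRUE))
  seg <- segment_signal(sig, min_probes = 10)
  expect_equal(nrow(seg), 1L)
})

test_that("focal events inside a long chromosome are found and delimited", {
  pm <- probe_map(test_genome(), seed = 1)
  tr <- two_clone_truth(0.5)
  hits <- 0L
  for (seed in 1:5) {
    sig <- emulate_sample(tr, 10, pm, seed = seed)
    seg <- segment_signal(sig)
    hit <- seg$chrom == "1" & seg$start < 105e6 & seg$end > 100e6 &
      (seg$end - seg$start) < 10e6
    if (any(hit)) {
      hits <- hits + 1L
      s <- seg[hit, ][1, ]
      expect_lt(abs(s$start - 100e6), 5e5)
      expect_lt(abs(s$end - 105e6), 5e5)
    }
  }
  expect_equal(hits, 5L)
})
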