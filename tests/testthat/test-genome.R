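test_that("event lengths follow the segment definition and wgd has none", {
  ev <- cna_events(c("a", "b"), chrom = c("1", "7"),
                   start = c(0, 10000), end = c(1e6, 10500),
                   kind = "loss", copy_delta = -1L)
  expect_equal(event_length(ev), c(1e6, 500))
  wgd <- cna_events("w", kind = "wgd")
  expect_error(event_length(wgd), "no segment")
})

test_that("size filter is inclusive, keeps wgd, and is idempotent/monotone", {
  ev <- cna_events(c("a", "b", "c", "w"),
                   chrom = c("1", "1", "2", NA),
                   start = c(0, 10e6, 0, NA),
                   end = c(0.5e6, 11e6, 3e6, NA),
                   kind = c("loss", "loss", "gain", "wgd"),
                   copy_delta = c(-1L, -1L, 1L, NA))
  kept <- size_filter(ev, 1e6)
  expect_setequal(kept$event_id, c("b", "c", "w"))  # 1.0 Mbp kept: inclusive
  expect_identical(size_filter(ev, 0)$event_id, ev$event_id)
  expect_identical(size_filter(kept, 1e6), kept)    # idempotent
  for (ml in c(0, 5e5, 2e6, 5e6))
    expect_true(all(size_filter(ev, ml + 1e6)$event_id %in%
                      size_filter(ev, ml)$event_id))  # monotone
})

test_that("reciprocal overlap matches hand-computed fractions", {
  seg <- function(chrom, s, e) list(chrom = chrom, start = s, end = e)
  expect_equal(reciprocal_overlap(seg("1", 0, 100), seg("1", 0, 100)), 1)
  expect_equal(reciprocal_overlap(seg("1", 0, 100), seg("1", 200, 300)), 0)
  expect_equal(reciprocal_overlap(seg("1", 0, 100), seg("2", 0, 100)), 0)
  expect_equal(reciprocal_overlap(seg("1", 0, 100), seg("1", 50, 150)), 0.5)
  set.seed(1)
  for (i in 1:20) {
    a <- sort(sample(0:1000, 2)); b <- sort(sample(0:1000, 2))
    if (a[1] == a[2] || b[1] == b[2]) next
    x <- seg("1", a[1], a[2]); y <- seg("1", b[1], b[2])
    expect_equal(reciprocal_overlap(x, y), reciprocal_overlap(y, x))
    expect_lte(reciprocal_overlap(x, y), 1)
  }
})

test_that("genome builds validate input and load from TSV", {
  expect_error(genome_build(c("1", "1"), c(1e6, 2e6)), "unique")
  expect_error(genome_build("1", -5), "positive")
  gb <- default_genome()
  expect_equal(nrow(gb), 24L)
  expect_true(all(gb$length > 0))
  f <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(chrom = c("1", "2"),
                                length = c(2e8, 1e8)),
                     f, sep = "\t", row.names = FALSE, quote = FALSE)
  gb2 <- read_genome_build(f)
  expect_equal(genome_size(gb2), 3e8)
})

test_that("event tables enforce kind-specific invariants", {
  expect_error(cna_events("a", chrom = "1", start = 0, end = 1e6,
                          kind = "gain", copy_delta = 0L), "gain")
  expect_error(cna_events("a", chrom = "1", start = 0, end = 1e6,
                          kind = "loss", copy_delta = 1L), "loss")
  expect_error(cna_events("a", chrom = "1", start = 0, end = 1e6,
                          kind = "cnloh", copy_delta = 1L), "cnloh")
  expect_error(cna_events("a", chrom = "1", start = 5, end = 5,
                          kind = "loss", copy_delta = -1L), "start")
  expect_error(cna_events("w", chrom = "1", start = 0, end = 1e6,
                          kind = "wgd"), "genome-wide")
})
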