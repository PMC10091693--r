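test_that("exact rank-sum enumeration reproduces hand counts", {
  r <- ranksum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$W, 6)
  expect_equal(r$p_two_sided, 0.1)   # 2 * 1/20 over all 20 assignments
  expect_true(r$exact_flag)
  r2 <- ranksum_test(1, 2)
  expect_equal(r2$W, 1)
  expect_equal(r2$p_two_sided, 1)    # both assignments equally extreme
  r3 <- ranksum_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(r3$p_two_sided, 1)    # midranks make the tails symmetric
  expect_error(ranksum_test(numeric(0), 1), "non-empty")
})

test_that("exact p agrees with wilcox.test and the normal approximation", {
  set.seed(42)
  for (i in 1:50) {
    xs <- round(stats::rnorm(6), 6); ys <- round(stats::rnorm(6, 0.5), 6)
    mine <- ranksum_test(xs, ys)
    ref <- suppressWarnings(stats::wilcox.test(xs, ys, exact = TRUE))
    # wilcox.test reports U = W - n1(n1+1)/2
    expect_equal(mine$W - 6 * 7 / 2, unname(ref$statistic))
    expect_equal(mine$p_two_sided, ref$p.value, tolerance = 1e-9)
    appr <- ranksum_test(xs, ys, exact = FALSE)
    expect_lt(abs(mine$p_two_sided - appr$p_two_sided), 0.02)
  }
})

test_that("large samples fall back to the tie-corrected normal approximation", {
  set.seed(7)
  xs <- stats::rpois(10, 4); ys <- stats::rpois(10, 8)
  r <- ranksum_test(xs, ys)
  expect_false(r$exact_flag)
  ref <- suppressWarnings(stats::wilcox.test(xs, ys, exact = FALSE,
                                             correct = TRUE))
  expect_equal(r$p_two_sided, ref$p.value, tolerance = 1e-6)
})

test_that("group comparisons adjust with Holm across pairs", {
  counts <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(2, 3, 4))
  res <- compare_groups(counts)
  expect_equal(nrow(res), 3L)
  expect_equal(res$p_holm, stats::p.adjust(res$p_raw, "holm"))
  one <- compare_groups(counts, pairs = list(c("a", "b")))
  expect_equal(one$p_raw, one$p_holm)
  expect_error(compare_groups(list(a = 1)), "2 groups")
})

test_that("event counting respects the size filter and counts wgd once", {
  ev <- cna_events(c("a", "b", "c", "w"),
                   chrom = c("1", "1", "1", NA),
                   start = c(0, 10e6, 30e6, NA),
                   end = c(0.5e6, 12e6, 35e6, NA),
                   kind = c("loss", "loss", "gain", "wgd"),
                   copy_delta = c(-1L, -1L, 1L, NA))
  empty <- cna_events(character(0), kind = character(0))
  counts <- count_events(list(s1 = ev, s2 = empty))
  expect_equal(unname(counts), c(4L, 0L))
  counts1m <- count_events(list(s1 = ev), min_len = 1e6)
  expect_equal(unname(counts1m), 3L)   # 0.5 Mbp dropped, wgd kept
  for (ml in c(0, 1e6, 3e6, 10e6)) {
    expect_gte(count_events(list(s = ev), ml),
               count_events(list(s = ev), ml + 1e6))
  }
})

test_that("fishplot layout keeps nested bands summing to one", {
  m <- profile_matrix(rbind(c(1, 1, 1), c(0.6, 0.4, 0.2), c(0.2, 0.3, 0.1)))
  tree <- build_tree(cluster_events(m, 0.1, test_genome()), 0.1)
  fp <- fishplot_layout(tree, passages = c(5, 20, 45))
  expect_true(all(abs(colSums(fp$own) - 1) < 1e-6))
  for (i in seq_len(nrow(fp$nodes))) {
    p <- fp$nodes$parent_id[i]
    if (is.na(p)) next
    expect_true(all(fp$cumulative[p, ] >=
                      fp$cumulative[fp$nodes$node_id[i], ] - 1e-6))
  }
  expect_true(all(abs(fp$interp$cumulative[, 1] - fp$cumulative[, 1]) <
                    1e-9))
  # emergence is the first passage with positive cumulative fraction
  m2 <- profile_matrix(rbind(c(1, 1, 1), c(0, 0, 0.4)))
  tree2 <- build_tree(cluster_events(m2, 0.1, test_genome()), 0.1)
  fp2 <- fishplot_layout(tree2, passages = c(5, 20, 45))
  expect_equal(fp2$nodes$emergence[fp2$nodes$node_id == "N2"], 45)
  # stem-only: one band at 1 throughout
  m3 <- profile_matrix(matrix(c(1, 1, 1), 1))
  fp3 <- fishplot_layout(build_tree(cluster_events(m3, 0.1,
                                                   test_genome()), 0.1),
                         passages = c(5, 20, 45))
  expect_true(all(fp3$cumulative["N1", ] == 1))
  expect_true(all(fp3$own["root", ] == 0))
})

test_that("fishplot bands equal clone proportions from the tree", {
  tr <- programmed_sweep_truth(20)
  mt <- true_mcf_matrix(tr)
  tree <- build_tree(cluster_events(mt, 0.1, tr$genome), 0.1)
  fp <- fishplot_layout(tree, tr$sampled_passages)
  for (s in seq_along(tr$sampled_passages)) {
    own <- clone_proportions(tree, colnames(tree$profiles)[s])
    expect_equal(unname(fp$own[names(own), s]), unname(own),
                 tolerance = 1e-9)
  }
})

test_that("gain/loss summaries tabulate per chromosome and kind", {
  ev <- cna_events(c("a", "b", "c"), chrom = c("1", "1", "2"),
                   start = c(0, 20e6, 0), end = c(10e6, 30e6, 5e6),
                   kind = c("loss", "loss", "gain"),
                   copy_delta = c(-1L, -1L, 1L))
  m <- event_matrix(ev, rbind(c(0.5, 1), c(0.2, 0.3), c(0, 0.8)),
                    c("s1", "s2"))
  s <- summarize_gain_loss(m)
  loss1 <- s[s$chrom == "1" & s$kind == "loss", ]
  expect_equal(loss1$n_events, 2L)
  expect_equal(loss1$mbp, 20)
  expect_equal(loss1$max_mcf, 1)
})
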