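test_that("events cluster by MCF profile at the tau cut", {
  m <- profile_matrix(rbind(c(1, 1), c(1, 1)))
  expect_length(cluster_events(m, 0.1, test_genome()), 1L)
  m2 <- profile_matrix(rbind(c(1, 1), c(0.2, 0.9)))
  expect_length(cluster_events(m2, 0.1, test_genome()), 2L)
  # pairwise Chebyshev distances 0.05 / 0.20 / 0.18 -> {1,2} {3}
  m3 <- profile_matrix(rbind(c(0.50, 0.50), c(0.55, 0.52), c(0.70, 0.70)))
  cl <- cluster_events(m3, 0.1, test_genome())
  expect_length(cl, 2L)
  expect_setequal(cl[[1]]$events, c("ev01", "ev02"))
  # raising tau never increases the cluster count
  for (seed in 1:10) {
    rm <- random_tree_matrix(5, 3, seed)$matrix
    sizes <- vapply(c(0.05, 0.1, 0.2, 0.3),
                    function(tau) length(cluster_events(rm, tau,
                                                        test_genome())),
                    numeric(1))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("stem alterations chain under the root", {
  m <- profile_matrix(rbind(c(1, 1, 1)))
  tree <- build_tree(cluster_events(m, 0.1, test_genome()), 0.1)
  expect_equal(tree$nodes$parent_id, c(NA, "root"))
  own <- clone_proportions(tree, "s1")
  expect_equal(unname(own["N1"]), 1)
  expect_equal(unname(own["root"]), 0)
})

test_that("containment decides chain versus siblings as worked by hand", {
  # B >= C everywhere and the closest-ancestor rule gives A -> B -> C
  m <- profile_matrix(rbind(c(1, 1), c(0.6, 0.2), c(0.3, 0.1)))
  chain <- build_tree(cluster_events(m, 0.1, test_genome()), 0.1)
  expect_equal(chain$nodes$parent_id, c(NA, "root", "N1", "N2"))
  # containment fails both ways between B and C -> siblings under A
  m2 <- profile_matrix(rbind(c(1, 1), c(0.6, 0.2), c(0.3, 0.5)))
  sib <- build_tree(cluster_events(m2, 0.1, test_genome()), 0.1)
  expect_equal(sib$nodes$parent_id, c(NA, "root", "N1", "N1"))
})

test_that("constructed trees always satisfy both constraint families", {
  for (seed in 1:25) {
    rm <- random_tree_matrix(sample(2:6, 1), sample(2:5, 1), seed)
    tree <- build_tree(cluster_events(rm$matrix, 0.1, test_genome()), 0.1)
    expect_silent(validate_subclone_tree(tree))
  }
})

test_that("greedy trees are members of the exhaustive oracle set", {
  n_checked <- 0L
  for (seed in 1:40) {
    rm <- random_tree_matrix(sample(2:5, 1), 3, seed)
    cl <- cluster_events(rm$matrix, 0.1, test_genome())
    if (length(cl) > 6L) next
    tree <- build_tree(cl, 0.1)
    pv <- clonecna:::tree_parent_vector(tree, cl)
    if (is.null(pv)) next
    sols <- enumerate_trees(cl, 0.1)
    expect_true(any(vapply(sols, identical, logical(1), pv)))
    n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 30L)
  expect_length(enumerate_trees(list(list(events = "a",
                                          profile = c(s1 = 0.5))), 0.1)[[1]],
                1L)
  expect_error(enumerate_trees(vector("list", 8), 0.1), "7")
})

test_that("clone proportions subtract children and renormalize overshoot", {
  m <- profile_matrix(rbind(c(0.6, 0.6), c(0.2, 0.2)))
  tree <- build_tree(cluster_events(m, 0.1, test_genome()), 0.1)
  own <- clone_proportions(tree, "s1")
  expect_equal(unname(own[c("root", "N1", "N2")]), c(0.4, 0.4, 0.2))
  # sibling overshoot from noise: children sum past the parent, the
  # overshoot is clipped and the vector renormalized with a warning
  nodes <- data.frame(node_id = c("root", "A", "B", "C"),
                      parent_id = c(NA, "root", "A", "A"),
                      stringsAsFactors = FALSE)
  prof <- matrix(c(1, 1.0, 0.55, 0.5), 4, 1,
                 dimnames = list(c("root", "A", "B", "C"), "s1"))
  tr <- subclone_tree(nodes, prof, list(root = character(0), A = "a",
                                        B = "b", C = "c"), tau = 0.1)
  expect_warning(own2 <- clone_proportions(tr, "s1"), "clipped")
  expect_equal(sum(own2), 1)
  expect_equal(unname(own2["A"]), 0)
})

test_that("replacement is a lineage switch, not clonal succession", {
  # identical proportions across passages: no replacement
  m <- profile_matrix(matrix(c(0.8, 0.8, 0.8), 1))
  tree <- build_tree(cluster_events(m, 0.1, test_genome()), 0.1)
  expect_true(is.na(detect_replacement(tree, c(1, 10, 20))))
  # parent-dominant -> child-dominant on one lineage: succession, not
  # replacement
  m2 <- profile_matrix(rbind(c(0.9, 0.9), c(0.1, 0.8)))
  tree2 <- build_tree(cluster_events(m2, 0.1, test_genome()), 0.1)
  expect_true(is.na(detect_replacement(tree2, c(5, 25))))
  # a sibling sweeping at passage 22 is a replacement at 22
  tr <- programmed_sweep_truth(22, passages = c(1, 8, 15, 22, 30, 45))
  mt <- true_mcf_matrix(tr)
  tree3 <- build_tree(cluster_events(mt, 0.1, tr$genome), 0.1)
  expect_equal(detect_replacement(tree3, tr$sampled_passages), 22)
})

test_that("newick export parses and keeps stem chains", {
  skip_if_not_installed("ape")
  m <- profile_matrix(rbind(c(1, 1), c(0.6, 0.2), c(0.3, 0.1)))
  tree <- build_tree(cluster_events(m, 0.1, test_genome()), 0.1)
  nwk <- tree_newick(tree, annotate = FALSE)
  expect_match(nwk, ";$")
  parsed <- ape::read.tree(text = nwk)
  expect_s3_class(parsed, "phylo")
  j <- tree_json(tree)
  expect_length(j$nodes, 4L)
  expect_equal(j$samples, c("s1", "s2"))
})
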