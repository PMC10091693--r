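# Shared fixture builders.  Everything is generated in code; no binary
# data ships with the package.

# compact two-chromosome genome for focused tests
test_genome <- function() genome_build(c("1", "2"), c(200e6, 100e6))

# founder + one subclone at fraction f carrying a stem gain, a stem
# cn-LOH and a subclonal 5 Mbp loss
two_clone_truth <- function(f, genome = test_genome(),
                            loss_span = c(100e6, 105e6)) {
  clones <- data.frame(clone_id = c(1L, 2L),
                       parent_id = c(NA_integer_, 1L),
                       fitness = 1, born = c(0L, 1L))
  ev <- cna_events(c("stem_gain", "stem_cnloh", "sub_loss"),
                   chrom = c("2", "2", "1"),
                   start = c(10e6, 60e6, loss_span[1]),
                   end = c(30e6, 80e6, loss_span[2]),
                   kind = c("gain", "cnloh", "loss"),
                   copy_delta = c(1L, 0L, -1L),
                   haplotype = c(1L, 1L, 2L))
  ev$clone_id <- c(1L, 1L, 2L)
  fr <- matrix(c(1 - f, f), 1, 2, dimnames = list("10", c("1", "2")))
  clone_truth(clones, ev, fr, 10, genome = genome)
}

# pure diploid founder-only truth
diploid_truth <- function(genome = test_genome()) {
  clones <- data.frame(clone_id = 1L, parent_id = NA_integer_,
                       fitness = 1, born = 0L)
  ev <- cna_events(character(0), kind = character(0))
  ev$clone_id <- integer(0)
  fr <- matrix(1, 1, 1, dimnames = list("10", "1"))
  clone_truth(clones, ev, fr, 10, genome = genome)
}

# event matrix from a plain profile matrix (one loss event per row, laid
# out along chromosome 1 so genome order equals row order)
profile_matrix <- function(profiles, samples = NULL) {
  profiles <- as.matrix(profiles)
  if (is.null(samples)) samples <- colnames(profiles)
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(profiles)))
  n <- nrow(profiles)
  ev <- cna_events(sprintf("ev%02d", seq_len(n)), chrom = "1",
                   start = seq_len(n) * 10e6,
                   end = seq_len(n) * 10e6 + 5e6,
                   kind = "loss", copy_delta = -1L)
  event_matrix(ev, profiles, samples)
}

# random MCF matrix drawn from a random valid clone tree with one event
# per clone and small jitter; returns the matrix and the true parent
# vector (0 = root) for oracle tests
random_tree_matrix <- function(n_clusters, n_samples, seed, jitter = 0.02) {
  set.seed(seed)
  repeat {
    parent <- c(0L, vapply(seq_len(n_clusters - 1L), function(i)
      sample.int(i + 1L, 1L) - 1L, integer(1)))
    if (n_clusters == 1L) parent <- 0L
    prof <- matrix(0, n_clusters, n_samples)
    for (s in seq_len(n_samples)) {
      cum <- numeric(n_clusters)
      for (i in seq_len(n_clusters)) {
        avail <- if (parent[i] == 0L) 1 else cum[parent[i]]
        sibs <- which(parent == parent[i] & seq_len(n_clusters) < i)
        avail <- avail - sum(cum[sibs])
        cum[i] <- stats::runif(1, 0, max(0, avail))
      }
      prof[, s] <- cum
    }
    if (all(apply(prof, 1, max) >= 0.15)) break
  }
  prof[] <- pmin(1, pmax(0, prof + stats::runif(length(prof),
                                                -jitter, jitter)))
  colnames(prof) <- sprintf("s%d", seq_len(n_samples))
  list(matrix = profile_matrix(prof), parent = parent)
}
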