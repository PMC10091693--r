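#' Probe map of a genotyping-array-like design
#'
#' Places probes at (approximately) uniform spacing along every chromosome
#' and assigns each one a germline genotype: heterozygous probes carry the
#' B allele on one of the two homologs; homozygous probes are AA or BB.
#' Real array manifests are irrelevant to the method, so only density and
#' heterozygosity are modelled.
#'
#' @param genome a [genome_build()].
#' @param spacing probe spacing in bp (default 50 kb, i.e. one probe per
#'   50 kb).
#' @param het_frac fraction of heterozygous probes (default 0.3).
#' @param seed RNG seed for genotype assignment.
#' @return A `probe_map` data.frame with columns `chrom`, `pos` (0-based),
#'   `het` (logical), `b_hap` (1 or 2; haplotype carrying B, het probes
#'   only), `hom_b` (logical; BB homozygote).
#' @export
probe_map <- function(genome, spacing = 5e4, het_frac = 0.3, seed = 1L) {
  stopifnot(spacing > 0, het_frac >= 0, het_frac <= 1)
  set.seed(seed)
  per_chrom <- lapply(seq_len(nrow(genome)), function(i) {
    pos <- seq(spacing / 2, genome$length[i] - 1, by = spacing)
    data.frame(chrom = genome$chrom[i], pos = floor(pos),
               stringsAsFactors = FALSE)
  })
  pm <- do.call(rbind, per_chrom)
  n <- nrow(pm)
  pm$het <- stats::runif(n) < het_frac
  pm$b_hap <- sample(c(1L, 2L), n, replace = TRUE)
  pm$hom_b <- stats::runif(n) < 0.5
  structure(pm, class = c("probe_map", "data.frame"))
}

# per-clone haplotype copy numbers at one position: start diploid (1,1) and
# apply branch events in acquisition order
clone_copies_at <- function(truth, clone_id, chrom, pos) {
  ids <- clone_event_ids(truth, clone_id)
  h <- c(1, 1)
  if (!length(ids)) return(h)
  ev <- truth$events[match(ids, truth$events$event_id), ]
  for (i in seq_len(nrow(ev))) {
    if (ev$kind[i] == "wgd") { h <- 2 * h; next }
    if (ev$chrom[i] != chrom || pos < ev$start[i] || pos >= ev$end[i]) next
    a <- ev$haplotype[i]; b <- 3L - a
    switch(ev$kind[i],
           gain = { h[a] <- h[a] + ev$copy_delta[i] },
           loss = { h[a] <- max(0, h[a] + ev$copy_delta[i]) },
           cnloh = { h[b] <- h[b] + h[a]; h[a] <- 0 },
           complex = { h[a] <- h[a] + 2; h[b] <- max(0, h[b] - 1) })
  }
  h
}

#' Mixture-averaged haplotype copy numbers at a position
#'
#' For every clone alive at the given passage, applies its events (gains
#' and losses adjust the affected haplotype, cn-LOH zeroes one haplotype
#' and doubles the other, whole genome duplication doubles both), weights
#' by the clone's fraction and sums.  A pure diploid mixture returns
#' `(1, 1)`.
#'
#' @param truth a [clone_truth()].
#' @param passage recorded passage number.
#' @param chrom,pos genomic position (0-based).
#' @return Named numeric vector `c(h1 = , h2 = )` of mixture-averaged
#'   per-haplotype copy numbers.
#' @export
mixture_copy_numbers <- function(truth, passage, chrom, pos) {
  key <- as.character(passage)
  if (!key %in% rownames(truth$fractions)) stop("unknown passage: ", passage)
  fr <- truth$fractions[key, ]
  alive <- which(fr > 0)
  out <- c(h1 = 0, h2 = 0)
  for (i in alive) {
    cid <- truth$clones$clone_id[i]
    out <- out + fr[i] * clone_copies_at(truth, cid, chrom, pos)
  }
  out
}

# piecewise-constant mixture copy profile for every chromosome at one
# passage: list per chrom with breakpoints `bks` (0 .. chrom length) and
# per-interval mixture copies `h1`, `h2`
mixture_profiles <- function(truth, passage, genome = truth$genome) {
  if (is.null(genome)) genome <- truth$config$genome
  if (is.null(genome)) stop("a genome build is required")
  key <- as.character(passage)
  if (!key %in% rownames(truth$fractions)) stop("unknown passage: ", passage)
  fr <- truth$fractions[key, ]
  alive <- which(fr > 0)
  clone_ids <- truth$clones$clone_id[alive]
  clone_ev <- lapply(clone_ids, function(cid) {
    ids <- clone_event_ids(truth, cid)
    truth$events[match(ids, truth$events$event_id), , drop = FALSE]
  })
  out <- vector("list", nrow(genome))
  names(out) <- genome$chrom
  for (g in seq_len(nrow(genome))) {
    chrom <- genome$chrom[g]; clen <- genome$length[g]
    cuts <- unlist(lapply(clone_ev, function(e) {
      e <- e[!is.na(e$chrom) & e$chrom == chrom, ]
      c(e$start, e$end)
    }))
    bks <- sort(unique(c(0, pmin(cuts, clen), clen)))
    k <- length(bks) - 1L
    h1 <- numeric(k); h2 <- numeric(k)
    for (ci in seq_along(clone_ids)) {
      c1 <- rep(1, k); c2 <- rep(1, k)
      e <- clone_ev[[ci]]
      for (i in seq_len(nrow(e))) {
        if (e$kind[i] == "wgd") { c1 <- 2 * c1; c2 <- 2 * c2; next }
        if (e$chrom[i] != chrom) next
        idx <- which(bks[-length(bks)] >= e$start[i] & bks[-1] <= e$end[i])
        if (!length(idx)) next
        a <- e$haplotype[i]
        cc <- list(c1, c2)
        b <- 3L - a
        switch(e$kind[i],
               gain = { cc[[a]][idx] <- cc[[a]][idx] + e$copy_delta[i] },
               loss = { cc[[a]][idx] <- pmax(0, cc[[a]][idx] + e$copy_delta[i]) },
               cnloh = { cc[[b]][idx] <- cc[[b]][idx] + cc[[a]][idx]
                         cc[[a]][idx] <- 0 },
               complex = { cc[[a]][idx] <- cc[[a]][idx] + 2
                           cc[[b]][idx] <- pmax(0, cc[[b]][idx] - 1) })
        c1 <- cc[[1]]; c2 <- cc[[2]]
      }
      h1 <- h1 + fr[alive[ci]] * c1
      h2 <- h2 + fr[alive[ci]] * c2
    }
    if (!length(clone_ids)) { h1 <- rep(1, k); h2 <- rep(1, k) }
    out[[g]] <- list(bks = bks, h1 = h1, h2 = h2)
  }
  out
}

#' Expected logR of a copy-number mixture
#'
#' `log2((h1 + h2) / reference_ploidy)`.  The default reference ploidy of 2
#' centers logR on a diploid genome; pipelines that median-center instead
#' are emulated by re-centering the emitted signal (see
#' [emulate_sample()]).
#'
#' @param h1,h2 per-haplotype (mixture-averaged) copy numbers.
#' @param reference_ploidy positive reference (default 2).
#' @param floor value returned where total copy number is 0 (default -5).
#' @return Numeric logR values.
#' @export
expected_logr <- function(h1, h2, reference_ploidy = 2, floor = -5) {
  stopifnot(reference_ploidy > 0)
  total <- h1 + h2
  if (any(total < 0)) stop("copy numbers must be non-negative")
  out <- rep(floor, length(total))
  pos <- total > 0
  out[pos] <- log2(total[pos] / reference_ploidy)
  pmax(out, floor)
}

#' Expected B-allele frequency at a heterozygous probe
#'
#' B copies over total copies, where the B allele sits on the haplotype
#' given by `b_hap`.  Zero total copies returns 0.5 by convention.
#' Swapping the B-haplotype assignment mirrors the value around 0.5
#' (`baf -> 1 - baf`).
#'
#' @param h1,h2 per-haplotype copy numbers.
#' @param b_hap 1 or 2: which haplotype carries the B allele.
#' @return BAF values in \[0, 1\].
#' @export
expected_baf <- function(h1, h2, b_hap) {
  total <- h1 + h2
  b <- ifelse(b_hap == 1L, h1, h2)
  ifelse(total > 0, b / total, 0.5)
}

#' Emulate one array sample from a clone mixture
#'
#' Computes expected logR and BAF per probe from the mixture copy-number
#' profile at the given passage and adds independent Gaussian noise.
#' Homozygous probes emit BAF near 0 (AA) or 1 (BB).  Deterministic given
#' `seed`.
#'
#' @param truth a [clone_truth()].
#' @param passage recorded passage to sample.
#' @param probemap a [probe_map()].
#' @param sigma_logr Gaussian sd of logR noise (default 0.15).
#' @param sigma_baf Gaussian sd of BAF noise (default 0.03).
#' @param seed RNG seed.
#' @param centering `"diploid"` (logR centered on a diploid genome, the
#'   default) or `"median"` (signal re-centered on its median, as many
#'   array pipelines do; a clonal WGD then shows logR near 0).
#' @param sample_id id stored with the signal (default `P<passage>`).
#' @param genome genome build (default: the truth's).
#' @return A `probe_signal` data.frame with columns `chrom`, `pos`, `logr`,
#'   `baf`, `het` and attributes `sample_id` and `passage`.
#' @export
emulate_sample <- function(truth, passage, probemap, sigma_logr = 0.15,
                           sigma_baf = 0.03, seed = 1L,
                           centering = c("diploid", "median"),
                           sample_id = sprintf("P%02d", passage),
                           genome = truth$genome) {
  centering <- match.arg(centering)
  prof <- mixture_profiles(truth, passage, genome)
  set.seed(seed)
  n <- nrow(probemap)
  h1 <- numeric(n); h2 <- numeric(n)
  for (chrom in names(prof)) {
    idx <- which(probemap$chrom == chrom)
    if (!length(idx)) next
    p <- prof[[chrom]]
    iv <- findInterval(probemap$pos[idx], p$bks,
                       rightmost.closed = TRUE, all.inside = TRUE)
    h1[idx] <- p$h1[iv]
    h2[idx] <- p$h2[iv]
  }
  logr <- expected_logr(h1, h2) + stats::rnorm(n, 0, sigma_logr)
  if (centering == "median") logr <- logr - stats::median(logr)
  baf_true <- ifelse(probemap$het,
                     expected_baf(h1, h2, probemap$b_hap),
                     ifelse(probemap$hom_b, 1, 0))
  baf <- pmin(1, pmax(0, baf_true + stats::rnorm(n, 0, sigma_baf)))
  out <- data.frame(chrom = probemap$chrom, pos = probemap$pos,
                    logr = logr, baf = baf, het = probemap$het,
                    stringsAsFactors = FALSE)
  structure(out, class = c("probe_signal", "data.frame"),
            sample_id = sample_id, passage = passage, centering = centering)
}
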