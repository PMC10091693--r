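# ---- noise estimation -------------------------------------------------------

# robust per-probe logR noise sd from successive differences
estimate_noise_sd <- function(x) {
  d <- diff(x)
  if (!length(d)) return(0)
  stats::median(abs(d)) / (sqrt(2) * stats::qnorm(0.75))
}

# ---- multiscale binary segmentation -----------------------------------------

# best candidate split of x[lo..hi]: the maximum over
#  * edge splits — every position, two-sample z of left vs right means;
#  * interior windows — a geometric ladder of widths at stride w/6, z of
#    window vs remainder (this is what catches focal events embedded in a
#    long chromosome, which a plain left/right split dilutes away).
# Noise sd is re-estimated locally on every interval: tracks like folded
# BAF are heteroscedastic (allelic imbalance widens the folded noise), and
# a global sd overstates significance inside imbalanced regions.
scan_best <- function(x, cs, lo, hi, min_probes) {
  n <- hi - lo + 1L
  sigma <- max(estimate_noise_sd(x[lo:hi]), 1e-6)
  total <- cs[hi + 1L] - cs[lo]
  best_z <- -Inf; best <- NULL

  k <- seq.int(lo + min_probes - 1L, hi - min_probes)
  if (length(k)) {
    nl <- k - lo + 1L; nr <- hi - k
    ml <- (cs[k + 1L] - cs[lo]) / nl
    mr <- (cs[hi + 1L] - cs[k + 1L]) / nr
    z <- abs(ml - mr) / (sigma * sqrt(1 / nl + 1 / nr))
    i <- which.max(z)
    best_z <- z[i]; best <- list(type = "edge", k = k[i])
  }

  w <- min_probes
  widths <- integer(0)
  while (w <= n - min_probes) { widths <- c(widths, w); w <- ceiling(w * 1.25) }
  for (w in widths) {
    stride <- max(1L, w %/% 6L)
    s <- seq.int(lo, hi - w + 1L, by = stride)
    mean_in <- (cs[s + w] - cs[s]) / w
    mean_out <- (total - (cs[s + w] - cs[s])) / (n - w)
    z <- abs(mean_in - mean_out) / (sigma * sqrt(1 / w + 1 / (n - w)))
    i <- which.max(z)
    if (z[i] > best_z) {
      best_z <- z[i]
      best <- list(type = "window", s = s[i], w = w, stride = stride)
    }
  }
  list(z = best_z, best = best, sigma = sigma)
}

# Critical value for the max scan statistic under the null, by Monte Carlo
# (the same calibration role permutation p-values play in circular binary
# segmentation).  Null tracks are simulated (Gaussian for logR, folded
# Gaussian for |BAF - 0.5|), the max scan statistic collected, and the
# upper alpha quantile read off a fitted Gumbel (max-domain) law.  Values
# are cached per (length bucket, min_probes, alpha, track) for the session;
# lengths are bucketed geometrically since the max statistic grows only
# logarithmically with n.
.crit_cache <- new.env(parent = emptyenv())

null_crit <- function(n, min_probes, alpha, track = c("normal", "folded"),
                      nsim = 60L) {
  track <- match.arg(track)
  if (n < 2L * min_probes) return(Inf)
  bucket <- as.integer(ceiling(1.4^ceiling(log(n) / log(1.4))))
  key <- paste(bucket, min_probes, alpha, track, sep = "_")
  hit <- get0(key, envir = .crit_cache)
  if (!is.null(hit)) return(hit)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(bucket + min_probes)  # cache is deterministic, independent of caller
  zmax <- vapply(seq_len(nsim), function(i) {
    x <- stats::rnorm(bucket)
    if (track == "folded") x <- abs(x)
    scan_best(x, c(0, cumsum(x)), 1L, bucket, min_probes)$z
  }, numeric(1))
  beta <- stats::sd(zmax) * sqrt(6) / pi
  mu <- mean(zmax) - 0.5772157 * beta
  crit <- mu - beta * log(-log(1 - alpha))
  assign(key, crit, envir = .crit_cache)
  crit
}

# breakpoints (probe indices ending a segment) within x[lo..hi], recursive
scan_interval <- function(x, cs, lo, hi, min_probes, alpha, track = "normal") {
  n <- hi - lo + 1L
  if (n < 2L * min_probes) return(integer(0))
  sc <- scan_best(x, cs, lo, hi, min_probes)
  best_z <- sc$z; best <- sc$best; sigma <- sc$sigma
  total <- cs[hi + 1L] - cs[lo]
  crit <- null_crit(n, min_probes, alpha, track)
  if (!is.finite(best_z) || best_z <= crit) return(integer(0))

  if (best$type == "edge") {
    k <- best$k
    return(sort(unique(c(k,
                         scan_interval(x, cs, lo, k, min_probes, alpha, track),
                         scan_interval(x, cs, k + 1L, hi, min_probes, alpha,
                                       track)))))
  }

  # refine window boundaries by coordinate-wise exact search (placement
  # only; acceptance was decided on the scanned statistic above)
  a <- best$s; b <- best$s + best$w - 1L; st <- best$stride
  zfun <- function(a, b) {
    w1 <- b - a + 1L
    if (w1 < 1L || n - w1 < 1L) return(-Inf)
    mi <- (cs[b + 1L] - cs[a]) / w1
    mo <- (total - (cs[b + 1L] - cs[a])) / (n - w1)
    abs(mi - mo) / (sigma * sqrt(1 / w1 + 1 / (n - w1)))
  }
  for (pass in 1:3) {
    reach <- max(st, (b - a + 1L) %/% 2L)
    cand_a <- max(lo, a - reach):min(b - 1L, a + reach)
    a <- cand_a[which.max(vapply(cand_a, zfun, numeric(1), b = b))]
    cand_b <- max(a + 1L, b - reach):min(hi, b + reach)
    b <- cand_b[which.max(vapply(cand_b, function(bb) zfun(a, bb), numeric(1)))]
  }
  bks <- c(if (a > lo) a - 1L, if (b < hi) b)
  sub <- c(if (a > lo) scan_interval(x, cs, lo, a - 1L, min_probes, alpha,
                                     track),
           scan_interval(x, cs, a, b, min_probes, alpha, track),
           if (b < hi) scan_interval(x, cs, b + 1L, hi, min_probes, alpha,
                                     track))
  sort(unique(c(bks, sub)))
}

# coalesce segments shorter than min_probes into the neighbour with the
# closest mean logR (boundary jitter from pooling the logR and BAF tracks
# can leave slivers below the minimum)
absorb_short_segments <- function(seg, x, min_probes) {
  repeat {
    n_probes <- seg$i1 - seg$i0 + 1L
    j <- which(n_probes < min_probes)
    if (!length(j) || nrow(seg) < 2L) break
    j <- j[1L]
    means <- mapply(function(i0, i1) mean(x[i0:i1]), seg$i0, seg$i1)
    left <- if (j > 1L) abs(means[j] - means[j - 1L]) else Inf
    right <- if (j < nrow(seg)) abs(means[j] - means[j + 1L]) else Inf
    if (left <= right) {
      seg$i1[j - 1L] <- seg$i1[j]
      seg <- seg[-j, , drop = FALSE]
    } else {
      seg$i0[j + 1L] <- seg$i0[j]
      seg <- seg[-j, , drop = FALSE]
    }
  }
  seg
}

# merge adjacent segments indistinguishable on BOTH tracks.  A pair is
# mergeable on a track when the mean difference is below the tolerance OR
# not statistically separable (z < 3 against the within-segment sems) —
# short noisy fragments of one true state must fold back even though their
# noisy means differ by more than the tolerance.  seg has i0/i1 probe index
# bounds; x is logR, d folded BAF (NA for hom probes).
merge_close_segments <- function(seg, x, d, merge_tol, merge_tol_baf) {
  seg_stats <- function(i0, i1) {
    idx <- i0:i1
    dd <- d[idx][!is.na(d[idx])]
    c(mean(x[idx]), sum((x[idx] - mean(x[idx]))^2), length(idx),
      if (length(dd)) mean(dd) else NA_real_,
      if (length(dd)) sum((dd - mean(dd))^2) else NA_real_,
      length(dd))
  }
  # pooled-variance two-sample z; pooling keeps the test stable when one
  # fragment is tiny (its own variance estimate would be worthless)
  pair_ok <- function(m1, ss1, n1, m2, ss2, n2, tol) {
    if (is.na(m1) || is.na(m2) || n1 == 0 || n2 == 0) return(NA)
    diff <- abs(m1 - m2)
    if (diff < tol) return(TRUE)
    df <- n1 + n2 - 2
    if (df < 2) return(TRUE)
    sp <- sqrt(max((ss1 + ss2) / df, 1e-12))
    diff < 3 * sp * sqrt(1 / n1 + 1 / n2)
  }
  repeat {
    if (nrow(seg) < 2L) break
    st <- mapply(seg_stats, seg$i0, seg$i1)
    k <- ncol(st) - 1L
    dl <- abs(diff(st[1, ]))
    db <- abs(diff(st[4, ]))
    mergeable <- vapply(seq_len(k), function(j) {
      ok_l <- pair_ok(st[1, j], st[2, j], st[3, j],
                      st[1, j + 1], st[2, j + 1], st[3, j + 1], merge_tol)
      ok_b <- pair_ok(st[4, j], st[5, j], st[6, j],
                      st[4, j + 1], st[5, j + 1], st[6, j + 1],
                      merge_tol_baf)
      isTRUE(ok_l) && !isFALSE(ok_b)
    }, logical(1))
    if (!any(mergeable)) break
    score <- dl / merge_tol + ifelse(is.na(db), 0, db / merge_tol_baf)
    score[!mergeable] <- Inf
    j <- which.min(score)
    seg$i1[j] <- seg$i1[j + 1L]
    seg <- seg[-(j + 1L), , drop = FALSE]
  }
  seg
}

# re-optimize each internal boundary by the local two-segment contrast
# (exact CUSUM between the two adjacent segments): the global window scan
# locates events, but its statistic is a blunt instrument for boundary
# placement, and matching events across samples needs tight boundaries.
# Each boundary is polished on the track that actually separates the two
# segments — logR, or folded BAF for copy-neutral (cn-LOH) boundaries,
# which leave no logR step at all.
polish_boundaries <- function(seg, x, d, passes = 2L) {
  sd_x <- max(estimate_noise_sd(x), 1e-6)
  dd <- d[!is.na(d)]
  sd_d <- max(estimate_noise_sd(dd), 1e-6)
  for (pass in seq_len(passes)) {
    if (nrow(seg) < 2L) break
    for (j in seq_len(nrow(seg) - 1L)) {
      lo <- seg$i0[j]; hi <- seg$i1[j + 1L]
      span <- max(2L, min(seg$i1[j] - seg$i0[j] + 1L,
                          seg$i1[j + 1L] - seg$i0[j + 1L] + 1L) %/% 2L)
      klo <- max(lo, seg$i1[j] - span); khi <- min(hi - 1L, seg$i1[j] + span)
      if (khi - klo < 1L) next
      ks <- klo:khi
      n <- hi - lo + 1L
      # logR contrast at every candidate
      cs <- c(0, cumsum(x[lo:hi]))
      kk <- ks - lo + 1L
      ml <- cs[kk + 1L] / kk
      mr <- (cs[n + 1L] - cs[kk + 1L]) / (n - kk)
      z_x <- (ml - mr) / (sd_x * sqrt(1 / kk + 1 / (n - kk)))
      # folded-BAF contrast at the same candidates (over het probes)
      het <- which(!is.na(d))
      het <- het[het >= lo & het <= hi]
      z_d <- rep(0, length(ks))
      if (length(het) >= 6L) {
        hc <- c(0, cumsum(d[het]))
        nl <- findInterval(ks, het)
        nh <- length(het)
        okd <- nl >= 3L & (nh - nl) >= 3L
        if (any(okd)) {
          mdl <- hc[nl[okd] + 1L] / nl[okd]
          mdr <- (hc[nh + 1L] - hc[nl[okd] + 1L]) / (nh - nl[okd])
          z_d[okd] <- (mdl - mdr) /
            (sd_d * sqrt(1 / nl[okd] + 1 / (nh - nl[okd])))
        }
      }
      k <- ks[which.max(z_x^2 + z_d^2)]
      seg$i1[j] <- k
      seg$i0[j + 1L] <- k + 1L
    }
  }
  seg
}

# mirrored BAF band estimate from het probes of one segment: bands are
# 0.5 +- mean(|baf - 0.5|) (single pair of mirrored bands; the folded mean
# is slightly biased upward near 0, which errs on the side of calling weak
# imbalance -- see the methods vignette)
baf_bands <- function(baf) {
  n <- length(baf)
  if (!n) return(list(fold = NA_real_, lower = NA_real_, upper = NA_real_,
                      n_het = 0L))
  m <- mean(abs(baf - 0.5))
  list(fold = m, lower = 0.5 - m, upper = 0.5 + m, n_het = n)
}

#' Segment a probe signal into constant copy-number stretches
#'
#' Recursive mean-shift segmentation of logR per chromosome.  At every step
#' both single split positions (maximizing the two-sample z statistic) and
#' interior windows over a geometric ladder of widths (window vs remainder
#' z statistic; required to detect focal events inside long chromosomes)
#' are scanned; the best candidate is accepted if it exceeds the
#' Bonferroni-corrected critical value for level `alpha`, and both
#' resulting sides must hold at least `min_probes` probes.  Adjacent
#' segments whose means differ by less than `merge_tol` are merged back.
#' Heterozygous-probe BAF is summarized per segment as a mirrored band pair
#' centered on 0.5.  Chromosomes with fewer than `2 * min_probes` probes
#' are returned as a single segment.
#'
#' Segment boundaries in bp are placed halfway between the boundary probes
#' of adjacent segments (extended half a spacing beyond terminal probes),
#' so a k-probe segment at spacing d has length ~ k*d.
#'
#' Segmentation runs on two tracks: mean shifts in logR over all probes,
#' and mean shifts in folded BAF (`|BAF - 0.5|`) over heterozygous probes —
#' the latter is what delimits copy-neutral LOH, which is invisible in
#' logR.  Breakpoints from both tracks are pooled.
#'
#' @param signal a `probe_signal` from [emulate_sample()] or any data.frame
#'   with columns `chrom`, `pos`, `logr`, `baf`, `het`.
#' @param min_probes minimum probes per segment (default 10; also the
#'   minimum het probes per segment on the BAF track).
#' @param alpha per-step split significance level (default 0.01,
#'   Bonferroni-corrected over candidates).
#' @param merge_tol merge adjacent segments closer than this in mean logR
#'   (default 0.04) ...
#' @param merge_tol_baf ... and closer than this in folded-BAF mean
#'   (default 0.02); both must hold for a merge.
#' @return A `called_segments` data.frame: `chrom`, `start`, `end` (0-based
#'   half-open), `n_probes`, `mean_logr`, `n_het`, `baf_fold`,
#'   `band_lower`, `band_upper`, `call` (`NA`, filled by [call_events()]).
#' @export
segment_signal <- function(signal, min_probes = 10L, alpha = 0.01,
                           merge_tol = 0.04, merge_tol_baf = 0.02) {
  stopifnot(min_probes >= 2L, alpha > 0, alpha < 1)
  out <- list()
  for (chrom in unique(signal$chrom)) {
    s <- signal[signal$chrom == chrom, ]
    s <- s[order(s$pos), ]
    x <- s$logr
    n <- length(x)
    bks <- if (n >= 2L * min_probes)
      scan_interval(x, c(0, cumsum(x)), 1L, n, min_probes, alpha, "normal")
    else integer(0)
    # BAF track: folded het BAF, breakpoints mapped back to probe indices
    het_idx <- which(s$het)
    d_full <- rep(NA_real_, n)
    d_full[het_idx] <- abs(s$baf[het_idx] - 0.5)
    if (length(het_idx) >= 2L * min_probes) {
      d <- d_full[het_idx]
      bks_d <- scan_interval(d, c(0, cumsum(d)), 1L, length(d),
                             min_probes, alpha, "folded")
      bks <- sort(unique(c(bks, het_idx[bks_d])))
    }
    i0 <- c(1L, bks + 1L); i1 <- c(bks, n)
    seg <- absorb_short_segments(data.frame(i0 = i0, i1 = i1), x, min_probes)
    seg <- merge_close_segments(seg, x, d_full, merge_tol, merge_tol_baf)
    # polish can pull a diluted boundary back onto the true step, after
    # which fragments of one state become mergeable — so merge again
    seg <- polish_boundaries(seg, x, d_full)
    seg <- merge_close_segments(seg, x, d_full, merge_tol, merge_tol_baf)
    seg <- polish_boundaries(seg, x, d_full)
    # bp boundaries: midpoints between neighbouring boundary probes
    half <- if (n > 1) stats::median(diff(s$pos)) / 2 else 1
    bp0 <- ifelse(seg$i0 == 1L, pmax(0, s$pos[1] - half),
                  (s$pos[seg$i0] + s$pos[pmax(1L, seg$i0 - 1L)]) / 2)
    bp1 <- ifelse(seg$i1 == n, s$pos[n] + half,
                  (s$pos[seg$i1] + s$pos[pmin(n, seg$i1 + 1L)]) / 2)
    for (j in seq_len(nrow(seg))) {
      idx <- seg$i0[j]:seg$i1[j]
      bb <- baf_bands(s$baf[idx][s$het[idx]])
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = floor(bp0[j]), end = ceiling(bp1[j]),
        n_probes = length(idx), mean_logr = mean(x[idx]),
        sem_logr = stats::sd(x[idx]) / sqrt(length(idx)),
        n_het = bb$n_het, baf_fold = bb$fold,
        band_lower = bb$lower, band_upper = bb$upper,
        call = NA_character_, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("called_segments", "data.frame"),
            sample_id = attr(signal, "sample_id"),
            passage = attr(signal, "passage"))
}
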