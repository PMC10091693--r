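#' Fishplot layout data for clonal dynamics
#'
#' Converts a subclone tree with per-sample MCF profiles into the nested
#' band structure of a fishplot: per timepoint, each node's cumulative
#' fraction (its MCF) and own fraction (cells in the node but none of its
#' children).  Own fractions are taken from [clone_proportions()] (clipped
#' and renormalized to sum to 1) and cumulative fractions are rebuilt
#' bottom-up from them, so the layout invariants hold exactly: own
#' fractions sum to 1 and a child band never exceeds its parent.  Linear
#' interpolation between sampled passages is included for plotting, and
#' each node's emergence is recorded as the first sampled passage with
#' positive cumulative fraction.
#'
#' @param tree a [subclone_tree()].
#' @param passages numeric passage number per sample column of the tree.
#' @param n_interp interpolation points per curve (default 101).
#' @return A `fishplot_data` list: `timepoints`, `nodes` (data.frame
#'   node_id, parent_id, emergence), `cumulative` and `own` (node x
#'   timepoint matrices), `interp` (grid + interpolated cumulative).
#' @export
fishplot_layout <- function(tree, passages = NULL, n_interp = 101L) {
  samples <- colnames(tree$profiles)
  if (is.null(passages)) passages <- seq_along(samples)
  stopifnot(length(passages) == length(samples))
  ord <- order(passages)
  samples <- samples[ord]; passages <- passages[ord]
  ids <- tree$nodes$node_id
  own <- vapply(samples, function(s) clone_proportions(tree, s)[ids],
                numeric(length(ids)))
  own <- matrix(own, nrow = length(ids),
                dimnames = list(ids, as.character(passages)))
  # rebuild cumulative bottom-up so that cum(node) = own + sum(cum(children))
  cum <- own
  depth <- vapply(ids, function(id) length(ancestor_path(tree, id)),
                  integer(1))
  for (id in ids[order(-depth)]) {
    kids <- ids[!is.na(tree$nodes$parent_id) & tree$nodes$parent_id == id]
    if (length(kids))
      cum[id, ] <- own[id, ] + colSums(cum[kids, , drop = FALSE])
  }
  emergence <- apply(cum, 1, function(v) {
    i <- which(v > 0)
    if (length(i)) passages[i[1]] else NA_real_
  })
  if (length(passages) > 1L) {
    grid <- seq(min(passages), max(passages), length.out = n_interp)
    interp <- t(apply(cum, 1, function(v)
      stats::approx(passages, v, xout = grid)$y))
  } else {
    grid <- passages
    interp <- cum
  }
  structure(list(timepoints = passages,
                 nodes = data.frame(node_id = ids,
                                    parent_id = tree$nodes$parent_id,
                                    emergence = emergence,
                                    stringsAsFactors = FALSE),
                 cumulative = cum, own = own,
                 interp = list(grid = grid, cumulative = interp)),
            class = "fishplot_data")
}

#' Render a fishplot
#'
#' Minimal base-graphics rendering of [fishplot_layout()] data: nested
#' polygons, children drawn inside their parent's band.
#'
#' @param x a `fishplot_data` object.
#' @param palette colors per node (recycled).
#' @param ... passed to [graphics::plot()].
#' @export
plot.fishplot_data <- function(x, palette = grDevices::hcl.colors(
                                 nrow(x$nodes), "Zissou 1"), ...) {
  g <- x$interp$grid
  cum <- x$interp$cumulative
  ids <- x$nodes$node_id
  col <- stats::setNames(rep_len(palette, length(ids)), ids)
  graphics::plot(range(g), c(0, 1), type = "n", xlab = "passage",
                 ylab = "fraction of cells", ...)
  draw <- function(id, y0) {
    h <- cum[match(id, ids), ]
    graphics::polygon(c(g, rev(g)), c(y0, rev(y0 + h)),
                      col = col[id], border = NA)
    kids <- ids[!is.na(x$nodes$parent_id) & x$nodes$parent_id == id]
    yk <- y0
    for (k in kids) {
      draw(k, yk)
      yk <- yk + cum[match(k, ids), ]
    }
  }
  root <- ids[is.na(x$nodes$parent_id)]
  draw(root, rep(0, length(g)))
  invisible(x)
}

#' Count events per sample
#'
#' @param per_sample_events named list sample -> [cna_events()] table.
#' @param min_len optional minimum event size in bp ([size_filter()] is
#'   applied first; wgd events always count, as single events).
#' @return Named integer vector of event counts.
#' @export
count_events <- function(per_sample_events, min_len = NULL) {
  vapply(per_sample_events, function(ev) {
    if (!is.null(min_len)) ev <- size_filter(ev, min_len)
    nrow(ev)
  }, integer(1))
}

#' Wilcoxon rank-sum test with exact small-sample enumeration
#'
#' `W` is the sum of the (mid)ranks of `xs` in the pooled sample.  For
#' `n1 + n2 <= 12` the two-sided p-value is computed exactly by complete
#' enumeration of all `choose(n1+n2, n1)` rank assignments
#' (`p = min(1, 2 * min(P(W <= w), P(W >= w)))`), which remains valid
#' under ties since midranks are enumerated as observed.  For larger
#' samples the normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param xs,ys numeric vectors (both non-empty).
#' @param group_labels labels stored with the result.
#' @param exact force (`TRUE`) or suppress (`FALSE`) exact enumeration;
#'   default `NULL` enumerates exactly when `n1 + n2 <= 12`.
#' @return A `group_comparison` list: `W`, `p_two_sided`, `exact_flag`,
#'   `n1`, `n2`, `labels`.
#' @export
ranksum_test <- function(xs, ys, group_labels = c("x", "y"),
                         exact = NULL) {
  n1 <- length(xs); n2 <- length(ys)
  if (!n1 || !n2) stop("both groups must be non-empty")
  r <- rank(c(xs, ys))
  W <- sum(r[seq_len(n1)])
  N <- n1 + n2
  if (is.null(exact)) exact <- N <= 12L
  if (exact) {
    if (N > 16L) stop("exact enumeration is limited to n1 + n2 <= 16")
    combos <- utils::combn(N, n1)
    Ws <- colSums(matrix(r[combos], nrow = n1))
    p <- min(1, 2 * min(mean(Ws <= W + 1e-9), mean(Ws >= W - 1e-9)))
  } else {
    mu <- n1 * (N + 1) / 2
    ties <- table(r)
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    cc <- if (W == mu) 0 else 0.5 * sign(W - mu)
    z <- (W - mu - cc) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  structure(list(W = W, p_two_sided = p, exact_flag = exact,
                 n1 = n1, n2 = n2, labels = group_labels),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: W = %g, p = %.4g (%s)\n", x$labels[1], x$labels[2],
              x$W, x$p_two_sided, if (x$exact_flag) "exact" else "normal approx."))
  invisible(x)
}

#' Pairwise group comparisons of event counts with Holm adjustment
#'
#' Runs [ranksum_test()] for every requested pair of groups and adjusts
#' the two-sided p-values across pairs with Holm's step-down procedure.
#'
#' @param counts_by_group named list group -> numeric vector of per-sample
#'   event counts.
#' @param pairs list of 2-element character vectors (default: all pairs).
#' @return data.frame with columns `group1`, `group2`, `W`, `p_raw`,
#'   `p_holm`, `exact_flag`.
#' @export
compare_groups <- function(counts_by_group, pairs = NULL) {
  groups <- names(counts_by_group)
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (is.null(pairs)) {
    cb <- utils::combn(groups, 2)
    pairs <- lapply(seq_len(ncol(cb)), function(i) cb[, i])
  }
  res <- lapply(pairs, function(p) {
    t <- ranksum_test(counts_by_group[[p[1]]], counts_by_group[[p[2]]], p)
    data.frame(group1 = p[1], group2 = p[2], W = t$W,
               p_raw = t$p_two_sided, exact_flag = t$exact_flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_holm <- stats::p.adjust(out$p_raw, method = "holm")
  out[, c("group1", "group2", "W", "p_raw", "p_holm", "exact_flag")]
}

#' Per-chromosome gain/loss summary
#'
#' Tabulates, per chromosome and event kind, the number of matrix rows,
#' total affected length and maximum MCF seen in any sample — a tabular
#' stand-in for a circos-style overview of where the genome gained and
#' lost material.
#'
#' @param matrix an [event_matrix()].
#' @return data.frame with `chrom`, `kind`, `n_events`, `mbp`, `max_mcf`.
#' @export
summarize_gain_loss <- function(matrix) {
  ev <- matrix$events
  if (!nrow(ev))
    return(data.frame(chrom = character(), kind = character(),
                      n_events = integer(), mbp = numeric(),
                      max_mcf = numeric(), stringsAsFactors = FALSE))
  key <- paste(ifelse(is.na(ev$chrom), "genome", ev$chrom), ev$kind)
  rows <- lapply(split(seq_len(nrow(ev)), key), function(idx) {
    data.frame(chrom = ifelse(is.na(ev$chrom[idx[1]]), "genome",
                              ev$chrom[idx[1]]),
               kind = ev$kind[idx[1]], n_events = length(idx),
               mbp = sum((ev$end[idx] - ev$start[idx]) / 1e6, na.rm = TRUE),
               max_mcf = suppressWarnings(
                 max(matrix$mcf[idx, ], na.rm = TRUE)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(match(out$chrom, c(unique(ev$chrom), "genome")), out$kind), ]
}
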