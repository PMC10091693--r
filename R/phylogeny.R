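#' Cluster events by their MCF profiles
#'
#' Events acquired on the same branch of the clonal tree share a mutated
#' cell fraction profile across samples (up to noise), so events are
#' grouped by complete-linkage agglomeration under Chebyshev distance
#' (maximum over samples of |delta MCF|), cutting at `tau`.  A reported
#' MCF of 0 is censored rather than exact — the detectability floor
#' suppresses sub-floor calls — so the per-sample distance between a 0
#' and a positive value is taken as the amount by which the positive
#' value exceeds `floor` (two co-branch events straddling the floor in
#' one sample would otherwise be pushed apart artificially).  Complex and
#' otherwise unplaceable events must be excluded before clustering (see
#' [build_tree()]).  Input rows are put in genome order first, making
#' tie-breaks deterministic.
#'
#' @param matrix an [event_matrix()].
#' @param tau clustering tolerance in MCF units, in (0, 0.5) (default 0.1,
#'   matching the ~10% clone-size resolution of the data).
#' @param genome a [genome_build()] for the deterministic ordering.
#' @param floor the detectability floor below which reported zeros are
#'   censored (default 0.10; 0 gives the plain Chebyshev distance).
#' @return List of clusters, each a list with `events` (event ids),
#'   `profile` (per-sample consensus = median over member events).
#' @export
cluster_events <- function(matrix, tau = 0.10, genome = default_genome(),
                           floor = 0.10) {
  stopifnot(tau > 0, tau < 0.5)
  m <- matrix$mcf
  if (nrow(m) == 0L) return(list())
  ord <- genome_order(matrix$events, genome$chrom)
  m <- m[ord, , drop = FALSE]
  ids <- matrix$events$event_id[ord]
  if (nrow(m) == 1L) {
    cl <- 1L
  } else {
    n <- nrow(m)
    dm <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      a <- m[i, ]; b <- m[j, ]
      cell <- abs(a - b)
      cens <- (a == 0) != (b == 0)   # one censored, one observed
      cell[cens] <- pmax(0, pmax(a, b)[cens] - floor)
      dm[i, j] <- dm[j, i] <- max(cell)
    }
    cl <- stats::cutree(stats::hclust(stats::as.dist(dm),
                                      method = "complete"), h = tau)
  }
  lapply(unique(cl), function(k) {
    idx <- which(cl == k)
    prof <- apply(m[idx, , drop = FALSE], 2, stats::median)
    list(events = ids[idx], profile = prof)
  })
}

#' Construct a subclone tree object
#'
#' @param nodes data.frame with `node_id`, `parent_id` (`NA` for root).
#' @param profiles matrix nodes x samples of per-sample MCF consensus
#'   (rownames = node ids; root row all 1).
#' @param events named list node_id -> character vector of event ids
#'   acquired on the branch into that node.
#' @param unplaced character vector of event ids not placed on the tree.
#' @param tau tolerance used during construction.
#' @return A `subclone_tree` object.  Containment (parent profile >= child
#'   profile - tau in every sample) and the pigeonhole constraint (sibling
#'   profiles sum to at most the parent profile + tau per sample) are
#'   asserted.
#' @export
subclone_tree <- function(nodes, profiles, events, unplaced = character(0),
                          tau = 0.10) {
  stopifnot(sum(is.na(nodes$parent_id)) == 1L)
  tr <- structure(list(nodes = nodes, profiles = profiles, events = events,
                       unplaced = unplaced, tau = tau),
                  class = "subclone_tree")
  validate_subclone_tree(tr)
  tr
}

validate_subclone_tree <- function(tree) {
  nodes <- tree$nodes; prof <- tree$profiles; tau <- tree$tau
  root <- nodes$node_id[is.na(nodes$parent_id)]
  if (any(abs(prof[root, ] - 1) > 1e-9)) stop("root profile must be 1")
  for (i in seq_len(nrow(nodes))) {
    p <- nodes$parent_id[i]
    if (is.na(p)) next
    if (any(prof[p, ] < prof[nodes$node_id[i], ] - tau - 1e-9))
      stop("containment violated on edge ", p, " -> ", nodes$node_id[i])
  }
  for (p in nodes$node_id) {
    kids <- nodes$node_id[!is.na(nodes$parent_id) & nodes$parent_id == p]
    if (length(kids) < 2L) next
    s <- colSums(prof[kids, , drop = FALSE])
    if (any(s > prof[p, ] + tau + 1e-9))
      stop("pigeonhole violated under node ", p)
  }
  invisible(tree)
}

#' @export
print.subclone_tree <- function(x, ...) {
  cat(sprintf("subclone_tree: %d nodes (+root), %d samples, %d unplaced events\n",
              nrow(x$nodes) - 1L, ncol(x$profiles), length(x$unplaced)))
  invisible(x)
}

# first event id of a cluster in genome order is its tie-break key; the
# clusters arrive already genome-ordered from cluster_events
cluster_key <- function(cl) cl$events[1]

#' Greedy subclone-tree reconstruction under MCF constraints
#'
#' Builds a rooted tree of event clusters obeying, at tolerance `tau` in
#' every sample, (i) containment — a descendant's MCF cannot exceed its
#' ancestor's, and (ii) the pigeonhole constraint — sibling MCFs cannot sum
#' beyond their parent's.  Stem clusters (profile >= 1 - tau in all
#' samples, i.e. alterations carried by every cell) are chained directly
#' under the root in descending-mean order.  Remaining clusters are sorted
#' by descending mean MCF and attached greedily: among all nodes satisfying
#' both constraint families if chosen as parent, the one minimizing the
#' summed per-sample MCF gap to the cluster (the closest feasible
#' ancestor) is picked, ties broken by earliest first event in genome
#' order.  A cluster with no feasible parent is reported in `unplaced`
#' rather than forced onto the tree.
#'
#' @param clusters result of [cluster_events()].
#' @param tau constraint tolerance (default 0.1).
#' @param samples sample ids (needed when `clusters` is empty; otherwise
#'   taken from the cluster profiles).
#' @return A [subclone_tree()]; the root is the normal (event-free)
#'   ancestor with profile 1 everywhere.
#' @export
build_tree <- function(clusters, tau = 0.10, samples = NULL) {
  if (length(clusters)) samples <- names(clusters[[1]]$profile)
  if (is.null(samples)) samples <- character(0)
  prof <- matrix(1, 1, length(samples),
                 dimnames = list("root", samples))
  nodes <- data.frame(node_id = "root", parent_id = NA_character_,
                      stringsAsFactors = FALSE)
  events <- list(root = character(0))
  unplaced <- character(0)
  if (!length(clusters))
    return(subclone_tree(nodes, prof, events, unplaced, tau))

  means <- vapply(clusters, function(cl) mean(cl$profile), numeric(1))
  is_stem <- vapply(clusters, function(cl) all(cl$profile >= 1 - tau),
                    logical(1))
  ord <- order(-means, vapply(clusters, cluster_key, character(1)))
  node_n <- 0L
  add_node <- function(parent, cl) {
    node_n <<- node_n + 1L
    id <- sprintf("N%d", node_n)
    nodes <<- rbind(nodes, data.frame(node_id = id, parent_id = parent,
                                      stringsAsFactors = FALSE))
    prof <<- rbind(prof, matrix(cl$profile, 1,
                                dimnames = list(id, samples)))
    events[[id]] <<- cl$events
    id
  }

  # stem chain under root, descending mean
  tip <- "root"
  for (i in ord[is_stem[ord]]) tip <- add_node(tip, clusters[[i]])

  for (i in ord[!is_stem[ord]]) {
    cl <- clusters[[i]]
    cand <- character(0); gap <- numeric(0)
    for (p in nodes$node_id) {
      if (any(prof[p, ] < cl$profile - tau)) next
      kids <- nodes$node_id[!is.na(nodes$parent_id) & nodes$parent_id == p]
      s <- if (length(kids)) colSums(prof[kids, , drop = FALSE]) else
        rep(0, length(samples))
      if (any(s + cl$profile > prof[p, ] + tau)) next
      cand <- c(cand, p)
      gap <- c(gap, sum(prof[p, ] - cl$profile))
    }
    if (!length(cand)) { unplaced <- c(unplaced, cl$events); next }
    best <- cand[gap == min(gap)]
    if (length(best) > 1L) {
      keys <- vapply(best, function(p)
        if (p == "root") "" else events[[p]][1], character(1))
      best <- best[order(keys)][1]
    } else best <- best[1]
    add_node(best, cl)
  }
  subclone_tree(nodes, prof, events, unplaced, tau)
}

#' Exhaustively enumerate constraint-satisfying trees (testing oracle)
#'
#' Enumerates every way of attaching each cluster to either the root or
#' another cluster (all rooted forests hung from the common root), keeping
#' those that are acyclic and satisfy containment and pigeonhole at
#' tolerance `tau` in every sample.  Combinatorial guard: at most 7
#' clusters.  [build_tree()]'s output (when it places every cluster) must
#' be a member of this set.
#'
#' @param clusters result of [cluster_events()] (length <= 7).
#' @param tau constraint tolerance.
#' @return List of parent assignments; each is an integer vector `p` where
#'   `p[i]` is the parent cluster index of cluster i (0 = root).
#' @export
enumerate_trees <- function(clusters, tau = 0.10) {
  k <- length(clusters)
  if (k > 7L) stop("refusing to enumerate more than 7 clusters")
  if (k == 0L) return(list(integer(0)))
  profs <- do.call(rbind, lapply(clusters, `[[`, "profile"))
  ns <- ncol(profs)
  ok_edge <- function(p, c) all(profs[p, ] >= profs[c, ] - tau)
  out <- list()
  parent <- integer(k)
  recurse <- function(i) {
    if (i > k) {
      # acyclicity: follow parents from each node
      for (s in seq_len(k)) {
        seen <- 0L; v <- s
        while (v != 0L) {
          v <- parent[v]
          seen <- seen + 1L
          if (seen > k) return(invisible())
        }
      }
      # pigeonhole per parent (root = 0)
      for (p in 0:k) {
        kids <- which(parent == p)
        if (length(kids) < 2L) next
        s <- colSums(profs[kids, , drop = FALSE])
        lim <- if (p == 0L) rep(1, ns) else profs[p, ]
        if (any(s > lim + tau)) return(invisible())
      }
      out[[length(out) + 1L]] <<- parent + 0L
      return(invisible())
    }
    for (p in 0:k) {
      if (p == i) next
      if (p != 0L && !ok_edge(p, i)) next
      parent[i] <<- p
      recurse(i + 1L)
    }
  }
  recurse(1L)
  out
}

# parent assignment of a built tree in cluster-index terms, for comparison
# with enumerate_trees output; returns NULL if any cluster is unplaced
tree_parent_vector <- function(tree, clusters) {
  k <- length(clusters)
  first_ev <- vapply(clusters, cluster_key, character(1))
  node_of <- rep(NA_character_, k)
  for (id in names(tree$events)) {
    if (id == "root") next
    hit <- match(tree$events[[id]][1], first_ev)
    if (!is.na(hit)) node_of[hit] <- id
  }
  if (anyNA(node_of)) return(NULL)
  vapply(seq_len(k), function(i) {
    p <- tree$nodes$parent_id[match(node_of[i], tree$nodes$node_id)]
    # stem chains pass through intermediate stem nodes; map to cluster index
    while (!is.na(p) && p != "root" && !(p %in% node_of))
      p <- tree$nodes$parent_id[match(p, tree$nodes$node_id)]
    if (is.na(p) || p == "root") 0L else match(p, node_of)
  }, integer(1))
}

#' Per-sample clone proportions from a subclone tree
#'
#' The "own" fraction of a node in a sample is its MCF minus the summed
#' MCFs of its children (cells carrying the node's events but none of its
#' descendants'); the root's own fraction is whatever is left of 1.  Noise
#' can push sums slightly past the parent; negative own fractions are
#' clipped to 0 and the vector renormalized (with a warning) when clipping
#' changed the total materially.
#'
#' @param tree a [subclone_tree()].
#' @param sample sample id (column of the tree profiles).
#' @return Named numeric vector node -> own fraction, summing to 1.
#' @export
clone_proportions <- function(tree, sample) {
  prof <- stats::setNames(tree$profiles[, sample], rownames(tree$profiles))
  nodes <- tree$nodes
  own <- stats::setNames(numeric(nrow(nodes)), nodes$node_id)
  clipped <- FALSE
  for (id in nodes$node_id) {
    kids <- nodes$node_id[!is.na(nodes$parent_id) & nodes$parent_id == id]
    raw <- prof[id] - sum(prof[kids])
    if (raw < -1e-9) clipped <- TRUE
    own[id] <- max(0, raw)
  }
  if (abs(sum(own) - 1) > 1e-9) {
    if (clipped)
      warning("clone proportions clipped (children exceeded parent); renormalized")
    own <- own / sum(own)
  }
  own
}

#' Detect replacement of the dominant lineage across passages
#'
#' The dominant node of each sampled passage is the one with the largest
#' own fraction (ties to the shallower node).  A replacement is flagged at
#' the first sampled passage whose dominant node is on a different lineage
#' than the previous passage's dominant — i.e. neither its ancestor, nor
#' its descendant, nor itself.  A parent giving way to its own descendant
#' is ordinary clonal succession, not replacement.
#'
#' @param tree a [subclone_tree()].
#' @param passages numeric passage number per sample column (default: the
#'   tree profile column order with the matrix's recorded passages).
#' @return The earliest passage at which a replacement is seen, or `NA` if
#'   none.
#' @export
detect_replacement <- function(tree, passages = NULL) {
  samples <- colnames(tree$profiles)
  if (is.null(passages)) passages <- seq_along(samples)
  if (length(samples) < 2L) stop("need at least 2 sampled passages")
  ord <- order(passages)
  depth <- function(id) length(ancestor_path(tree, id))
  dominant <- vapply(samples[ord], function(s) {
    own <- clone_proportions(tree, s)
    top <- names(own)[own == max(own)]
    if (length(top) > 1L) top <- top[order(vapply(top, depth, integer(1)))][1]
    top
  }, character(1))
  for (i in 2:length(dominant)) {
    a <- dominant[i - 1L]; b <- dominant[i]
    if (a == b) next
    pa <- ancestor_path(tree, a); pb <- ancestor_path(tree, b)
    if (!(a %in% pb) && !(b %in% pa))
      return(passages[ord][i])
  }
  NA_real_
}

ancestor_path <- function(tree, id) {
  path <- id
  repeat {
    p <- tree$nodes$parent_id[match(path[1], tree$nodes$node_id)]
    if (is.na(p)) break
    path <- c(p, path)
  }
  path
}

#' Export a subclone tree as a newick string
#'
#' Node labels are node ids; branch annotations (the events acquired on
#' the branch) are attached as newick comments in square brackets after
#' each label.  Chained (single-child) internal nodes are kept — the stem
#' of a clonal phylogeny is a chain by construction.
#'
#' @param tree a [subclone_tree()].
#' @param annotate include `[event,event,...]` comments (default TRUE).
#' @return A single newick string terminated by `;`.
#' @export
tree_newick <- function(tree, annotate = TRUE) {
  nodes <- tree$nodes
  lab <- function(id) {
    if (!annotate || !length(tree$events[[id]])) return(id)
    paste0(id, "[", paste(tree$events[[id]], collapse = ","), "]")
  }
  rec <- function(id) {
    kids <- nodes$node_id[!is.na(nodes$parent_id) & nodes$parent_id == id]
    if (!length(kids)) return(lab(id))
    paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","), ")",
           lab(id))
  }
  root <- nodes$node_id[is.na(nodes$parent_id)]
  paste0(rec(root), ";")
}

#' Export a subclone tree as a JSON-ready list
#'
#' @param tree a [subclone_tree()].
#' @return A list with `nodes` (id, parent, events), `profiles`
#'   (per-sample MCF per node) and `unplaced`, suitable for
#'   `jsonlite::write_json()`.
#' @export
tree_json <- function(tree) {
  list(
    nodes = lapply(seq_len(nrow(tree$nodes)), function(i) {
      id <- tree$nodes$node_id[i]
      list(node_id = id,
           parent_id = tree$nodes$parent_id[i],
           events = tree$events[[id]],
           profile = as.list(tree$profiles[id, ]))
    }),
    samples = colnames(tree$profiles),
    unplaced = tree$unplaced,
    tau = tree$tau
  )
}
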