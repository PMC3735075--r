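#' Delineate MOTUs by tree-guided threshold clustering
#'
#' Realizes the "least inclusive terminal groups" rule: traverse the rooted
#' ingroup tree from the root; at each node, if the mean pairwise K2P
#' divergence among all leaves under that node is at most the threshold,
#' emit those leaves as one MOTU and stop descending; otherwise recurse
#' into the children. Single leaves reached this way become singleton
#' MOTUs. Every MOTU is therefore the full leaf set of some tree node
#' whose mean internal divergence respects the threshold.
#'
#' @param tree An `ape::phylo` tree over (a superset of) the matrix ids.
#'   If `outgroup` is supplied the tree is first rooted there and the
#'   outgroup tips are excluded from delineation.
#' @param m K2P distance matrix (proportions) covering all ingroup tips.
#' @param threshold Mean-divergence threshold in percent (e.g. 2).
#' @param outgroup Optional character vector of outgroup tip labels.
#' @return A `motu_result` list: `partition` (named vector id -> MOTU
#'   label, labels `MOTU_001`... in traversal order), `threshold`,
#'   `per_cluster_within` (mean within divergence per MOTU, `NA` for
#'   singletons), `mean_within`, `mean_between`, `ratio`, `singletons`,
#'   `n_motus`.
#' @export
tree_guided_motus <- function(tree, m, threshold, outgroup = NULL) {
  stopifnot(threshold > 0)
  if (!is.null(outgroup) && length(outgroup) > 0L) {
    tree <- root_at_outgroup(tree, outgroup)
    tree <- ape::drop.tip(tree, outgroup)
  } else if (!ape::is.rooted(tree)) {
    # without an outgroup the NJ trifurcation is an arbitrary start point
    # that can fall inside a cluster; midpoint rooting puts the root on
    # the longest path, i.e. between clusters
    tree <- phangorn::midpoint(tree)
  }
  tips <- tree$tip.label
  missing_ids <- setdiff(tips, rownames(m))
  if (length(missing_ids) > 0L) {
    stop(sprintf("tips absent from distance matrix: %s", toString(missing_ids)))
  }
  thr <- threshold / 100
  ntip <- length(tips)
  root <- ntip + 1L
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  clade_tips <- function(node) {
    if (node <= ntip) return(node)
    unlist(lapply(kids[[as.character(node)]], clade_tips), use.names = FALSE)
  }
  clusters <- list()
  emit <- function(node) {
    lv <- clade_tips(node)
    if (length(lv) == 1L) {
      clusters[[length(clusters) + 1L]] <<- tips[lv]
      return(invisible())
    }
    sm <- m[tips[lv], tips[lv]]
    if (mean(sm[upper.tri(sm)]) <= thr) {
      clusters[[length(clusters) + 1L]] <<- tips[lv]
    } else {
      for (ch in kids[[as.character(node)]]) emit(ch)
    }
  }
  emit(root)
  partition <- stats::setNames(
    rep(sprintf("MOTU_%03d", seq_along(clusters)), lengths(clusters)),
    unlist(clusters)
  )
  partition <- partition[tips] # tree tip order
  .motu_result(partition, m, threshold)
}

.motu_result <- function(partition, m, threshold) {
  wb <- within_between(m[names(partition), names(partition)], partition)
  sizes <- table(partition)
  res <- list(
    partition = partition,
    threshold = threshold,
    per_cluster_within = wb$per_cluster_within,
    mean_within = wb$mean_within,
    mean_between = wb$mean_between,
    ratio = wb$ratio,
    singletons = names(sizes)[sizes == 1L],
    n_motus = length(sizes)
  )
  class(res) <- "motu_result"
  res
}

#' @export
print.motu_result <- function(x, ...) {
  cat(sprintf(
    "motu_result: %d MOTUs at %.3g%% threshold (%d singletons)\n",
    x$n_motus, x$threshold, length(x$singletons)
  ))
  cat(sprintf(
    "  mean within %.2f%%, mean between %.2f%%, ratio %.1f\n",
    100 * x$mean_within, 100 * x$mean_between, x$ratio
  ))
  invisible(x)
}

#' Tree-free threshold clustering of a distance matrix
#'
#' Hierarchical agglomerative clustering on the K2P distances cut at the
#' threshold; the cross-check variant of [tree_guided_motus()]. In the
#' well-separated regime (max within < threshold < min between) both
#' produce identical partitions.
#'
#' @param m Distance matrix (proportions).
#' @param threshold Percent threshold at which the dendrogram is cut.
#' @param linkage `"average"` (default) or `"single"`.
#' @return Named character vector (id -> `MOTU_001`... in order of first
#'   appearance in the matrix row order).
#' @export
threshold_clusters <- function(m, threshold, linkage = c("average", "single")) {
  linkage <- match.arg(linkage)
  stopifnot(threshold > 0)
  hc <- stats::hclust(stats::as.dist(m), method = linkage)
  grp <- stats::cutree(hc, h = threshold / 100)
  relabel <- stats::setNames(
    sprintf("MOTU_%03d", seq_along(unique(grp))), unique(grp)
  )
  stats::setNames(unname(relabel[as.character(grp)]), names(grp))
}

#' Mean divergence within and between clusters
#'
#' @param m Distance matrix (proportions) covering all partition ids.
#' @param partition Named character vector (id -> cluster label).
#' @return List with `mean_within` (mean over all intra-cluster pairs;
#'   clusters of size 1 contribute none; `NA` if no cluster has size >= 2),
#'   `mean_between` (mean over inter-cluster pairs; `NA` for a single
#'   cluster), `ratio` (`between/within`; `Inf` when within is 0),
#'   `per_cluster_within`, and the pair counts.
#' @export
within_between <- function(m, partition) {
  ids <- names(partition)
  miss <- setdiff(ids, rownames(m))
  if (length(miss) > 0L) {
    stop(sprintf("partition ids absent from matrix: %s", toString(miss)))
  }
  mm <- m[ids, ids]
  same <- outer(partition, partition, "==")
  ut <- upper.tri(mm)
  within_vals <- mm[ut & same]
  between_vals <- mm[ut & !same]
  per_cluster <- vapply(unique(partition), function(cl) {
    members <- ids[partition == cl]
    if (length(members) < 2L) return(NA_real_)
    sm <- mm[members, members]
    mean(sm[upper.tri(sm)])
  }, numeric(1))
  mean_within <- if (length(within_vals)) mean(within_vals) else NA_real_
  mean_between <- if (length(between_vals)) mean(between_vals) else NA_real_
  ratio <- if (is.na(mean_within) || is.na(mean_between)) {
    NA_real_
  } else if (mean_within == 0) {
    Inf
  } else {
    mean_between / mean_within
  }
  list(
    mean_within = mean_within, mean_between = mean_between, ratio = ratio,
    per_cluster_within = per_cluster,
    n_within_pairs = length(within_vals),
    n_between_pairs = length(between_vals)
  )
}
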