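#' Neighbor-Joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: at each step join the pair `(i, j)` minimizing
#' `Q(i,j) = (r - 2) d(i,j) - R_i - R_j` where `R` are row sums over the
#' `r` active nodes. Exact ties on `Q` are broken by the lexicographically
#' smallest `(i, j)` in current node-index order, so the result is
#' deterministic across runs and platforms. Negative branch lengths are
#' clamped to zero (the deficit is not redistributed); the number of clamps
#' is attached as attribute `clamped`.
#'
#' @param m Symmetric distance matrix with ids as dimnames, no `NA`
#'   entries, at least 3 taxa.
#' @return An unrooted `ape::phylo` tree (trifurcating root) over all ids,
#'   additive-exact: for an additive input matrix the leaf-to-leaf path
#'   lengths reproduce the input.
#' @export
nj_tree <- function(m) {
  if (anyNA(m)) {
    stop("distance matrix has undefined entries; resolve saturation first")
  }
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 taxa")
  ids <- rownames(m)
  if (is.null(ids)) stop("distance matrix must carry ids as dimnames")
  if (any(grepl("[():,;[:space:]]", ids))) {
    stop("ids may not contain Newick metacharacters or whitespace")
  }
  D <- unname(m)
  # each active node carries a growing newick fragment
  sub <- ids
  clamped <- 0L
  while (nrow(D) > 3L) {
    r <- nrow(D)
    R <- rowSums(D)
    Qm <- (r - 2) * D - outer(R, R, "+")
    diag(Qm) <- Inf
    qmin <- min(Qm)
    cand <- which(Qm == qmin, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    i <- cand[1L, 1L]
    j <- cand[1L, 2L]
    li <- 0.5 * D[i, j] + (R[i] - R[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    if (li < 0) { li <- 0; clamped <- clamped + 1L }
    if (lj < 0) { lj <- 0; clamped <- clamped + 1L }
    new_sub <- sprintf("(%s:%.15g,%s:%.15g)", sub[i], li, sub[j], lj)
    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]), c(dnew[keep], 0))
    D <- D2
    sub <- c(sub[keep], new_sub)
  }
  d12 <- D[1L, 2L]; d13 <- D[1L, 3L]; d23 <- D[2L, 3L]
  a <- 0.5 * (d12 + d13 - d23)
  b <- 0.5 * (d12 + d23 - d13)
  c3 <- 0.5 * (d13 + d23 - d12)
  for (v in c(a, b, c3)) if (v < 0) clamped <- clamped + 1L
  a <- max(a, 0); b <- max(b, 0); c3 <- max(c3, 0)
  txt <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);", sub[1L], a, sub[2L], b,
                 sub[3L], c3)
  tr <- ape::read.tree(text = txt)
  attr(tr, "clamped") <- clamped
  tr
}

#' Bootstrap support for an NJ tree
#'
#' Resamples alignment columns with replacement, recomputes the K2P
#' distance matrix and NJ tree per replicate, and scores each internal
#' bipartition of the original tree by the percentage of retained
#' replicates containing it. Replicates with undefined distances
#' (saturation or no comparable sites under the resampling) are discarded
#' with a message; more than 50% discarded is an error.
#'
#' @param aln A [barcode_alignment()].
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; the same seed reproduces the supports exactly.
#' @return The NJ tree of the full alignment with `node.label` set to
#'   support percentages (root label empty) and the numeric supports in
#'   attribute `support`.
#' @export
bootstrap_support <- function(aln, B = 1000, seed = 1) {
  stopifnot(B >= 1)
  m <- distance_matrix(aln)
  tr <- nj_tree(m)
  set.seed(seed)
  ncols <- ncol(aln)
  reps <- vector("list", B)
  kept <- 0L
  for (b in seq_len(B)) {
    cols <- sample.int(ncols, ncols, replace = TRUE)
    mb <- tryCatch(
      suppressWarnings(distance_matrix(aln[, cols, drop = FALSE],
                                       on_saturation = "undefined")),
      error = function(e) NULL
    )
    if (is.null(mb) || anyNA(mb)) next
    kept <- kept + 1L
    reps[[kept]] <- nj_tree(mb)
  }
  if (kept < B) {
    message(sprintf("discarded %d of %d bootstrap replicates", B - kept, B))
  }
  if (kept * 2L < B) stop("more than 50% of bootstrap replicates undefined")
  reps <- reps[seq_len(kept)]
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(tr, reps, rooted = FALSE)
  pct <- 100 * counts / kept
  tr$node.label <- ifelse(is.na(pct), "", as.character(round(pct, 1)))
  attr(tr, "support") <- pct
  attr(tr, "replicates_used") <- kept
  tr
}

#' Root a tree at an outgroup
#'
#' Roots on the pendant edge of a single outgroup, or on the edge
#' subtending the outgroup clade. If the outgroup is not monophyletic in
#' the unrooted tree, the tree is rooted at the node of the outgroup's most
#' recent common ancestor.
#'
#' @param tree An `ape::phylo` tree.
#' @param outgroup_ids Character vector of tip labels.
#' @return A rooted `ape::phylo` tree; ingroup topology is unchanged.
#' @export
root_at_outgroup <- function(tree, outgroup_ids) {
  unknown <- setdiff(outgroup_ids, tree$tip.label)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown outgroup id(s): %s", toString(unknown)))
  }
  if (length(outgroup_ids) == 1L ||
      ape::is.monophyletic(tree, outgroup_ids)) {
    ape::root(tree, outgroup = outgroup_ids, resolve.root = TRUE)
  } else {
    # non-monophyletic outgroup: root on the edge subtending its MRCA's
    # clade when that is a proper subset of the tips, otherwise on the
    # first outgroup tip's pendant edge
    node <- ape::getMRCA(tree, outgroup_ids)
    under <- tryCatch(ape::extract.clade(tree, node)$tip.label,
                      error = function(e) tree$tip.label)
    if (length(under) < length(tree$tip.label)) {
      ape::root(tree, outgroup = under, resolve.root = TRUE)
    } else {
      ape::root(tree, outgroup = outgroup_ids[1L], resolve.root = TRUE)
    }
  }
}
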