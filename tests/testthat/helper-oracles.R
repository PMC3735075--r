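# Independent oracles and small fixture builders, kept deliberately naive.

# Per-site loop K2P oracle: no vectorization, no shared code with the
# package implementation.
naive_k2p <- function(a, b) {
  if (is.character(a) && length(a) == 1L) a <- strsplit(a, "")[[1L]]
  if (is.character(b) && length(b) == 1L) b <- strsplit(b, "")[[1L]]
  acgt <- c("A", "C", "G", "T")
  ts_pairs <- list(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  L <- 0L; ts <- 0L; tv <- 0L
  for (s in seq_along(a)) {
    x <- a[s]; y <- b[s]
    if (!(x %in% acgt) || !(y %in% acgt)) next
    L <- L + 1L
    if (x == y) next
    is_ts <- FALSE
    for (tp in ts_pairs) if (x == tp[1L] && y == tp[2L]) is_ts <- TRUE
    if (is_ts) ts <- ts + 1L else tv <- tv + 1L
  }
  P <- ts / L; Q <- tv / L
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

random_alignment <- function(n, L, seed,
                             freqs = c(A = 0.32, C = 0.16, G = 0.14, T = 0.38)) {
  set.seed(seed)
  m <- matrix(sample(names(freqs), n * L, replace = TRUE, prob = freqs), n, L)
  rownames(m) <- sprintf("t%02d", seq_len(n))
  barcode_alignment(m)
}

# Pair of sequences at controlled divergence: start identical, then mutate
# a known number of sites of b.
mutated_pair <- function(L, n_ts, n_tv, seed) {
  set.seed(seed)
  a <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  b <- a
  pos <- sample.int(L, n_ts + n_tv)
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map <- c(A = "C", G = "T", C = "G", T = "A")
  for (i in seq_len(n_ts)) b[pos[i]] <- ts_map[[b[pos[i]]]]
  for (i in seq_len(n_tv)) {
    p <- pos[n_ts + i]
    b[p] <- tv_map[[b[p]]]
  }
  list(a = a, b = b)
}

# Random unrooted binary tree with positive branch lengths and its exact
# path-length (additive) distance matrix, via ape.
random_additive_case <- function(n, seed) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n, br = function(k) stats::runif(k, 0.05, 1)))
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

# Two-cluster alignment: cluster members near-identical, clusters far
# apart; returns alignment and the true partition.
two_cluster_alignment <- function(per_cluster = 3, L = 300, seed = 1) {
  sim <- simulate_alignment(sim_config(
    n_species = 2, seqs_per_species = per_cluster, seq_length = L,
    within_divergence = 1, between_divergence = 20, seed = seed
  ))
  sim
}
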