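test_that("three taxa resolve to the closed-form star", {
  D <- matrix(c(0, 0.3, 0.5, 0.3, 0, 0.6, 0.5, 0.6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  # a = (dAB + dAC - dBC)/2 etc.
  lens <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(lens[["A"]], 0.1)
  expect_equal(lens[["B"]], 0.2)
  expect_equal(lens[["C"]], 0.4)
})

test_that("a four-taxon additive matrix is recovered exactly", {
  # tree: A,B joined (1, 2) to an internal edge of length 1, then C,D (3, 4)
  D <- matrix(c(
    0, 3, 5, 6,
    3, 0, 6, 7,
    5, 6, 0, 7,
    6, 7, 7, 0
  ), 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(D)
  expect_equal(ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]], D,
               tolerance = 1e-12)
  lens <- setNames(tr$edge.length[match(1:4, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(lens[LETTERS[1:4]]), c(1, 2, 3, 4))
})

test_that("NJ is consistent on random additive matrices (5-8 taxa)", {
  for (seed in 1:25) {
    case <- random_additive_case(sample(5:8, 1), seed)
    out <- nj_tree(case$D)
    expect_equal(
      ape::cophenetic.phylo(out)[rownames(case$D), colnames(case$D)],
      case$D, tolerance = 1e-9
    )
  }
})

test_that("NJ agrees with an independent implementation on noisy matrices", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 10
    base <- ape::cophenetic.phylo(ape::rtree(n))
    noise <- matrix(runif(n * n, 0, 0.02), n, n)
    D <- base + noise + t(noise)
    diag(D) <- 0
    expect_equal(
      phangorn::RF.dist(ape::unroot(nj_tree(D)), ape::unroot(ape::nj(D))),
      0
    )
  }
})

test_that("undefined entries are refused with guidance", {
  D <- matrix(0.1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D) <- 0
  D[1, 2] <- D[2, 1] <- NA
  expect_error(nj_tree(D), "saturation")
})

test_that("negative branch lengths are clamped and counted", {
  # a non-additive matrix known to produce a negative NJ branch
  D <- matrix(c(
    0, 0.1, 0.4, 0.4,
    0.1, 0, 0.4, 0.4,
    0.4, 0.4, 0, 0.01,
    0.4, 0.4, 0.01, 0
  ), 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(D)
  expect_true(all(tr$edge.length >= 0))
  expect_true(is.numeric(attr(tr, "clamped")))
})

test_that("bootstrap supports are deterministic and correct in clear cases", {
  sim <- two_cluster_alignment(per_cluster = 2, L = 400, seed = 11)
  aln <- sim$alignment
  bt1 <- bootstrap_support(aln, B = 100, seed = 5)
  bt2 <- bootstrap_support(aln, B = 100, seed = 5)
  expect_identical(attr(bt1, "support"), attr(bt2, "support"))
  # the bipartition separating two maximally divergent clusters: support 100
  sup <- attr(bt1, "support")
  expect_true(100 %in% round(sup[!is.na(sup)]))
  # single replicate gives only 0 or 100
  bt3 <- bootstrap_support(aln, B = 1, seed = 2)
  s3 <- attr(bt3, "support")
  expect_true(all(s3[!is.na(s3)] %in% c(0, 100)))
})

test_that("bootstrap supports are invariant to leaf-order permutation", {
  sim <- simulate_alignment(sim_config(n_species = 3, seqs_per_species = 2,
                                       seq_length = 300, seed = 8))
  aln <- sim$alignment
  perm <- unclass(aln)[c(3, 1, 5, 2, 6, 4), ]
  aln2 <- barcode_alignment(perm)
  b1 <- bootstrap_support(aln, B = 50, seed = 3)
  b2 <- bootstrap_support(aln2, B = 50, seed = 3)
  key <- function(tr) {
    sup <- attr(tr, "support")
    parts <- ape::prop.part(tr)
    labs <- attr(parts, "labels")
    sets <- vapply(parts, function(p) paste(sort(labs[p]), collapse = ","),
                   character(1))
    setNames(sup, sets)[order(sets)]
  }
  k1 <- key(b1); k2 <- key(b2)
  shared <- intersect(names(k1), names(k2))
  expect_gt(length(shared), 0)
  expect_equal(k1[shared], k2[shared])
})

test_that("outgroup rooting covers single tips, cherries and fallback", {
  tr <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,(O1:1,O2:1):3,D:4);")
  r1 <- root_at_outgroup(tr, "O1")
  expect_true(ape::is.rooted(r1))
  r2 <- root_at_outgroup(tr, c("O1", "O2"))
  expect_true(ape::is.rooted(r2))
  expect_true(ape::is.monophyletic(r2, c("O1", "O2")))
  # rooting then unrooting preserves the bipartition set
  expect_equal(phangorn::RF.dist(ape::unroot(r2), tr), 0)
  expect_error(root_at_outgroup(tr, "nope"), "unknown")
  # non-monophyletic outgroup falls back to the MRCA node
  r3 <- root_at_outgroup(tr, c("O1", "D"))
  expect_true(ape::is.rooted(r3))
})
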