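test_that("site-pattern counting distinguishes transitions, transversions and excluded sites", {
  cmp <- count_site_patterns("ACGT", "ACGT")
  expect_equal(c(cmp$L, cmp$transitions, cmp$transversions), c(4, 0, 0))
  cmp <- count_site_patterns("AAAA", "GAAA")
  expect_equal(c(cmp$L, cmp$transitions, cmp$transversions), c(4, 1, 0))
  # N site excluded by pairwise deletion; remaining sites: A/A, C/T, T/T
  cmp <- count_site_patterns("ACNT", "ATGT")
  expect_equal(cmp$L, 3)
  expect_equal(cmp$transitions, 1)
  expect_equal(cmp$transversions, 0)
  # gaps excluded the same way
  cmp <- count_site_patterns("A-CT", "AGCA")
  expect_equal(cmp$L, 3)
  expect_equal(cmp$transversions, 1)
  expect_error(count_site_patterns("NNN", "ACG"), "no comparable sites")
  expect_error(count_site_patterns("ACG", "ACGT"), "equal")
})

test_that("K2P closed form matches its high-precision evaluation and flags saturation", {
  expect_identical(k2p_distance(0, 0), 0)
  # frozen from -0.5*log(0.75) - 0.25*log(0.9)
  expect_equal(k2p_distance(0.1, 0.05), 0.1701811651403470, tolerance = 1e-14)
  expect_error(k2p_distance(0.5, 0), "saturation")
  expect_warning(d <- k2p_distance(0.5, 0, on_saturation = "undefined"),
                 "undefined")
  expect_true(is.na(d))
  # monotone in P and in Q across the valid domain
  grid <- seq(0, 0.2, by = 0.02)
  dP <- k2p_distance(grid, 0.05)
  dQ <- k2p_distance(0.05, grid)
  expect_true(all(diff(dP) > 0))
  expect_true(all(diff(dQ) > 0))
  expect_true(all(dP >= 0) && all(dQ >= 0))
})

test_that("distance matrix equals the naive per-pair oracle and ape's K80", {
  # related sequences (so K2P is defined for every pair) with N/gap noise
  sim <- simulate_alignment(sim_config(
    n_species = 5, seqs_per_species = 2, seq_length = 636,
    within_divergence = 2, between_divergence = 20, seed = 42
  ))
  m <- unclass(sim$alignment)
  set.seed(9)
  m[sample(length(m), 200)] <- "N"
  m[sample(length(m), 50)] <- "-"
  aln <- barcode_alignment(m)
  dm <- distance_matrix(aln)
  expect_equal(dm, t(dm))
  expect_equal(unname(diag(dm)), rep(0, 10))
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(dm[i, j], naive_k2p(m[i, ], m[j, ]), tolerance = 1e-12)
  }
  seqs <- lapply(seq_len(nrow(m)), function(i) tolower(m[i, ]))
  names(seqs) <- rownames(m)
  db <- as.matrix(ape::dist.dna(ape::as.DNAbin(seqs), model = "K80",
                                pairwise.deletion = TRUE))
  expect_equal(dm, db[rownames(dm), colnames(dm)], tolerance = 1e-9)
})

test_that("pairwise deletion: N columns never change distances", {
  aln <- simulate_alignment(sim_config(
    n_species = 3, seqs_per_species = 2, seq_length = 200,
    within_divergence = 2, between_divergence = 15, seed = 7
  ))$alignment
  d0 <- distance_matrix(aln)
  m <- unclass(aln)
  m2 <- cbind(m, matrix("N", nrow(m), 5))
  d1 <- distance_matrix(barcode_alignment(m2))
  expect_equal(d0, d1)
})

test_that("identical records give a zero matrix", {
  m <- rbind(a = strsplit("ACGTACGT", "")[[1]],
             b = strsplit("ACGTACGT", "")[[1]])
  expect_equal(unname(distance_matrix(barcode_alignment(m))),
               matrix(0, 2, 2))
})

test_that("composition stats respect codon position and the frame offset", {
  m <- matrix("A", 2, 9, dimnames = list(c("x", "y"), NULL))
  cs <- composition_stats(barcode_alignment(m))
  expect_equal(unname(cs$overall["A"]), 1)
  expect_equal(unname(cs$by_position[, "A"]), rep(1, 3))
  # periodic ACGTACGT... every base 0.25 overall
  per <- matrix(rep(c("A", "C", "G", "T"), 30), 1, 120,
                dimnames = list("z", NULL))
  cs2 <- composition_stats(barcode_alignment(per))
  expect_equal(unname(cs2$overall), rep(0.25, 4))
  # period-3 pattern: offset shifts which column is position 1
  p3 <- matrix(rep(c("A", "C", "G"), 30), 1, 90, dimnames = list("z", NULL))
  cs3 <- composition_stats(barcode_alignment(p3), reading_frame_offset = 0)
  expect_equal(unname(cs3$by_position["pos1", "A"]), 1)
  cs4 <- composition_stats(barcode_alignment(p3), reading_frame_offset = 1)
  expect_equal(unname(cs4$by_position["pos1", "C"]), 1)
  # generator frequencies are recovered within sampling error
  big <- random_alignment(20, 1000, seed = 3,
                          freqs = c(A = 0.35, C = 0.15, G = 0.15, T = 0.35))
  expect_equal(composition_stats(big)$at_overall, 0.70, tolerance = 0.02)
})

test_that("distance histogram conserves pair counts and shows the barcoding gap", {
  m <- rbind(a = rep("A", 20), b = rep("A", 20), c = rep("A", 20))
  rownames(m) <- c("a", "b", "c")
  h <- distance_histogram(distance_matrix(barcode_alignment(m)))
  expect_equal(sum(h$count), 3)
  expect_equal(h$count[1], 3)
  sim <- two_cluster_alignment(per_cluster = 4, L = 600, seed = 5)
  dm <- distance_matrix(sim$alignment)
  h2 <- distance_histogram(dm, bin_width = 0.01)
  expect_equal(sum(h2$count), choose(8, 2))
  mid <- h2$lower >= 0.05 & h2$upper <= 0.15
  expect_equal(sum(h2$count[mid]), 0)
  expect_gt(h2$count[1] + h2$count[2], 0)
})
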