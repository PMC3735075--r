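test_that("configs are validated", {
  expect_error(sim_config(base_freqs = c(A = 1, C = 1, G = 1, T = 1)),
               "sum to 1")
  expect_error(sim_config(within_divergence = 5, between_divergence = 4),
               "exceed")
  expect_error(sim_config(n_species = 2, seqs_per_species = c(1, 2, 3)),
               "each species")
  # the expected-K2P curve plateaus near 3.4 subs/site for these
  # frequencies; targets beyond it are unreachable
  expect_error(calibrate_tau(4, 4, c(A = 0.32, C = 0.16, G = 0.14, T = 0.38)),
               "saturation")
})

test_that("zero within-divergence yields identical conspecific sequences", {
  sim <- simulate_alignment(sim_config(
    n_species = 2, seqs_per_species = 3, seq_length = 200,
    within_divergence = 0, between_divergence = 15, seed = 2
  ))
  dm <- distance_matrix(sim$alignment)
  wb <- within_between(dm, sim$truth$partition)
  expect_equal(wb$mean_within, 0)
  expect_gt(wb$mean_between, 0.1)
})

test_that("the same seed reproduces the dataset byte-identically", {
  cfg <- sim_config(n_species = 4, seqs_per_species = 2, seed = 77)
  s1 <- simulate_alignment(cfg)
  s2 <- simulate_alignment(cfg)
  expect_identical(unclass(s1$alignment)[, ], unclass(s2$alignment)[, ])
  expect_identical(simulate_morphometrics(s1$truth, cfg),
                   simulate_morphometrics(s2$truth, cfg))
  s3 <- simulate_alignment(sim_config(n_species = 4, seqs_per_species = 2,
                                      seed = 78))
  expect_false(identical(unclass(s1$alignment)[, ],
                         unclass(s3$alignment)[, ]))
})

test_that("realized divergences track the calibrated targets", {
  # many small replicates: mean realized between-K2P near the 20% target
  vals <- vapply(1:30, function(seed) {
    sim <- simulate_alignment(sim_config(
      n_species = 2, seqs_per_species = 1, seq_length = 636,
      between_divergence = 20, seed = seed
    ))
    100 * distance_matrix(sim$alignment)[1, 2]
  }, numeric(1))
  expect_equal(mean(vals), 20, tolerance = 0.05)
  # convergence with sequence length: the long alignment sits closer
  err_at <- function(L, seed) {
    sim <- simulate_alignment(sim_config(
      n_species = 3, seqs_per_species = 2, seq_length = L,
      within_divergence = 1.8, between_divergence = 20, seed = seed
    ))
    wb <- within_between(distance_matrix(sim$alignment),
                         sim$truth$partition)
    abs(100 * wb$mean_between - 20)
  }
  e_short <- mean(vapply(1:8, function(s) err_at(636, s), numeric(1)))
  e_long <- mean(vapply(1:8, function(s) err_at(6360, s), numeric(1)))
  expect_lt(e_long, e_short + 0.05)
})

test_that("composition is AT-biased as configured", {
  sim <- simulate_alignment(sim_config(
    n_species = 5, seqs_per_species = 2, seq_length = 1200,
    base_freqs = c(A = 0.35, C = 0.15, G = 0.15, T = 0.35),
    within_divergence = 1, between_divergence = 12, seed = 4
  ))
  cs <- composition_stats(sim$alignment)
  expect_equal(cs$at_overall, 0.70, tolerance = 0.03)
})

test_that("well-separated scenarios show an empty mid-band (barcoding gap)", {
  scen <- paper_scale_scenario(seed = 29)
  h <- distance_histogram(distance_matrix(scen$alignment), bin_width = 0.01)
  mid <- h$lower >= 0.05 & h$upper <= 0.15
  expect_equal(sum(h$count[mid]), 0)
  expect_gt(sum(h$count[h$lower < 0.03]), 0)
  expect_gt(sum(h$count[h$lower >= 0.15]), 0)
})

test_that("the study-scale scenario has the documented shape", {
  scen <- paper_scale_scenario(seed = 101)
  expect_equal(nrow(scen$alignment), 47L)
  expect_equal(ncol(scen$alignment), 636L)
  sizes <- table(scen$truth$partition)
  expect_length(sizes, 20L)
  expect_equal(sum(sizes == 1), 5L)
  expect_equal(dim(scen$morphometrics), c(47L, 16L))
  # specimen ids parse back to the true species
  parsed <- parse_label(specimen_ids(scen$alignment))
  expect_identical(parsed$label, unname(scen$truth$partition))
})

test_that("discordance injection produces the designed split and merge", {
  scen <- discordant_scenario(seed = 41)
  dm <- distance_matrix(scen$alignment)
  truth <- scen$truth$partition
  sp1 <- names(truth)[truth == "JHB01"]
  sub <- dm[sp1, sp1]
  # the odd specimen out sits ~12.6% from its two conspecifics
  expect_equal(100 * max(sub), 12.6, tolerance = 1 / 12.6)
  expect_lt(100 * min(sub[sub > 0]), 3)
  # merged species pair is nearly identical across species
  m13 <- names(truth)[truth == "JHB13"]
  m14 <- names(truth)[truth == "JHB14"]
  expect_lt(100 * mean(dm[m13, m14]), 2)
  # all downstream stages run without format errors (smoke property)
  tr <- nj_tree(dm)
  res <- tree_guided_motus(tr, dm, 2)
  expect_s3_class(res, "motu_result")
})
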