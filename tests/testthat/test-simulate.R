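test_that("simulation is reproducible and emits the full category set", {
  cfg <- sim_preset("paper_like", seed = 11)
  s1 <- simulate_pc_dataset(cfg)
  s2 <- simulate_pc_dataset(cfg)
  expect_identical(unclass(s1$matrices$whole_genome),
                   unclass(s2$matrices$whole_genome))
  expect_equal(write_newick(s1$tree), write_newick(s2$tree))

  # 1 whole genome + 4 family categories + 10 subcellular categories
  expect_length(s1$matrices, 15L)
  expect_setequal(
    names(s1$matrices),
    c("whole_genome", "proteases", "CAZy", "ribosomal", "DUF_UPF",
      "cell_wall", "nuclear", "mitochondrial", "cytoplasmic",
      "plasma_membrane", "endoplasmic_reticulum", "golgi", "extracellular",
      "vacuolar", "lysosomal"))
  # category partition conserves the whole-genome family set
  expect_setequal(
    unlist(lapply(s1$matrices[-1], rownames)),
    rownames(s1$matrices$whole_genome))
  # matrices' species codes match the true tree's leaves
  expect_setequal(colnames(s1$matrices$whole_genome), s1$tree$tip.label)
  expect_false(identical(
    unclass(simulate_pc_dataset(sim_preset("paper_like", seed = 12))$matrices$whole_genome),
    unclass(s1$matrices$whole_genome)))
})

test_that("injected rare families are exactly the curation filter's removals", {
  sim <- simulate_pc_dataset(sim_preset("paper_like", seed = 21))
  m <- sim$matrices$whole_genome
  removed <- setdiff(rownames(m),
                     rownames(suppressMessages(filter_rare_families(m))))
  expect_setequal(removed, sim$rare_ids)
  expect_length(sim$rare_ids, sim$config$n_rare)
  presence <- rowSums(unclass(m)[sim$rare_ids, ] > 0)
  expect_true(all(presence %in% 1:2))
})

test_that("per-branch copy dynamics have the closed-form expected scaling", {
  # height-1 ultrametric tree, no loss: E[leaf count] = E[c0] * exp(dup)
  cfg <- sim_config(n_species = 4, species = c("AA", "BB", "CC", "DD"),
                    n_families = 10000, ancestral_mean = 5,
                    dup_rate = 0.2, loss_rate = 0.1, n_rare = 0,
                    lifestyle_groups = list(), f_conv = 0, conv_factor = 1,
                    category_sizes = c(all = 10000L), seed = 31)
  sim <- simulate_pc_dataset(cfg)
  x <- unclass(sim$matrices$whole_genome)
  expected <- 6 * exp(0.2 - 0.1)
  for (sp in colnames(x)) {
    se <- stats::sd(x[, sp]) / sqrt(nrow(x))
    expect_lt(abs(mean(x[, sp]) - expected), 3 * se)
  }
})

test_that("a degenerate configuration warns and carries no distance signal", {
  cfg <- sim_config(dup_rate = 0, loss_rate = 0, f_conv = 0, conv_factor = 1,
                    n_rare = 0,
                    category_sizes = c(all = 2000L), seed = 3)
  expect_warning(sim <- simulate_pc_dataset(cfg), "degenerate")
  # every species inherits the ancestral counts unchanged: all columns are
  # identical, so all between-species distances collapse to zero
  d <- as.matrix(correlation_distance(sim$matrices$whole_genome))
  expect_true(all(d == 0))
  # a species with constant counts across families is rejected by name
  flat <- pc_matrix(matrix(c(2L, 2L, 1L, 5L), 2, 2,
                           dimnames = list(c("F1", "F2"), c("AA", "BB"))))
  expect_error(correlation_distance(flat), "zero-variance.*AA")
})

test_that("tree pairs with prescribed MAST size verify against the oracle", {
  # k = n gives identical trees
  p <- make_tree_pair_with_mast(10, 10, seed = 1)
  expect_true(same_topology(p$t1, p$t2))
  # small n: certified by brute force
  for (k in c(3, 5, 6, 7)) {
    p <- make_tree_pair_with_mast(8, k, seed = k + 40)
    expect_equal(brute_force_mast(p$t1, p$t2)$size, k)
    expect_length(p$witness, k)
    expect_true(same_topology(restrict_to_leaves(p$t1, p$witness),
                              restrict_to_leaves(p$t2, p$witness)))
  }
  # full scale used by the congruence-grid reproduction
  for (k in c(8, 12, 16)) {
    p <- make_tree_pair_with_mast(27, k, seed = k)
    expect_equal(mast_rooted(p$t1, p$t2)$size, k)
  }
  expect_error(make_tree_pair_with_mast(8, 1, seed = 1), "2 <= k")
})

test_that("single-replicate recovery returns binary outcomes", {
  rec <- recovery_experiment(sim_preset("low_noise", seed = 5),
                             replicates = 1, seed = 9)
  expect_true(rec$recovery_fraction %in% c(0, 1))
  expect_true(all(unlist(rec$monophyly_fraction) %in% c(0, 1)))
  expect_equal(nrow(rec$details), 1L)
})
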