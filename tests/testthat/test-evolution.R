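test_that("mutation regimes have the documented rate structure", {
  r <- mutation_regime("constant", 7)
  expect_equal(r$rates, rep(1e-5, 7))
  set.seed(1)
  rates <- replicate(2000, mutation_regime("variable", 7)$rates)
  expect_true(all(rates >= 1e-5 / 5 & rates <= 5e-5))
  expect_true(all(apply(rates, 2, max) / apply(rates, 2, min) <= 25))
  # arithmetic mean (b-a)/log(b/a) ~ 1.49e-5; geometric mean exactly 1e-5
  expect_lt(abs(mean(rates) - 4.8e-5 / log(25)) / 1.5e-5, 0.03)
  expect_lt(abs(exp(mean(log(rates))) - 1e-5) / 1e-5, 0.03)
})

test_that("a one-gene landscape fixates at its only maximum", {
  dag <- new_poset(1)
  set.seed(5)
  l <- assign_birth_rates(fitness_graph_from_dag(dag))
  tr <- simulate_to_fixation(l, quick_config())
  expect_equal(tr$fixated, 1L)
  lod <- extract_lod(tr)
  expect_equal(lod$genotypes, c(0L, 1L))
  expect_equal(lod$path, "G1")
})

test_that("representable landscapes fixate at the fully mutated genotype with K-step LODs", {
  set.seed(8)
  l <- generate_landscape("representable", 4)
  b <- batch_simulate(l, quick_config(), n_runs = 20)
  for (lod in b$lods) {
    expect_equal(lod$genotypes[1], 0L)
    expect_equal(lod$genotypes[length(lod$genotypes)], 2L^4 - 1L)
    # each step adds exactly one mutation
    steps <- popcount(bitwXor(lod$genotypes[-1],
                              lod$genotypes[-length(lod$genotypes)]))
    expect_true(all(steps == 1L))
    expect_equal(length(lod$path), 4L)
  }
  expect_true(b$all_genes_covered)
})

test_that("LODs in representable landscapes follow monotonically fitness-increasing accessible paths", {
  set.seed(9)
  for (i in 1:3) {
    l <- generate_landscape("representable", sample(3:5, 1))
    b <- batch_simulate(l, quick_config(), n_runs = 10,
                        keep_trajectories = FALSE)
    for (lod in b$lods) {
      rates <- l$birth_rate[lod$genotypes + 1L]
      expect_true(all(diff(rates) > 0))
      expect_true(all(rates > 0))
    }
  }
})

test_that("pruned landscapes fixate only at their fitness-graph sinks", {
  set.seed(10)
  l <- generate_landscape("local_maxima", 5, n_tries = 10)
  sinks <- landscape_local_maxima(l)
  b <- batch_simulate(l, quick_config(), n_runs = 15,
                      keep_trajectories = FALSE)
  fix <- vapply(b$lods, function(x) x$genotypes[length(x$genotypes)],
                integer(1))
  expect_true(all(fix %in% sinks))
})

test_that("the same seed reproduces the identical LOD sequence", {
  l <- withr::with_seed(2, generate_landscape("representable", 5))
  set.seed(123)
  b1 <- batch_simulate(l, quick_config(), n_runs = 5,
                       keep_trajectories = FALSE)
  set.seed(123)
  b2 <- batch_simulate(l, quick_config(), n_runs = 5,
                       keep_trajectories = FALSE)
  expect_identical(b1$paths, b2$paths)
})

test_that("exact Gillespie and tau-leap give consistent LOD distributions", {
  # cross-check of the two integrators on a tiny landscape where the path
  # probabilities are far from degenerate
  set.seed(33)
  l <- assign_birth_rates(fitness_graph_from_dag(new_poset(3)))
  n <- 60
  pg <- batch_simulate(l, quick_config(method = "gillespie"), n_runs = n,
                       keep_trajectories = FALSE)$paths
  pt <- batch_simulate(l, quick_config(method = "tauleap"), n_runs = n,
                       keep_trajectories = FALSE)$paths
  # both explore several paths and agree on support breadth
  expect_gt(length(unique(pg)), 1)
  expect_gt(length(unique(pt)), 1)
  js <- js_divergence(lod_path_distribution(pg), lod_path_distribution(pt))
  expect_lt(js, 0.5)
})

test_that("snapshot populations are positive and fixation frequency is honored", {
  set.seed(12)
  l <- generate_landscape("representable", 4)
  tr <- simulate_to_fixation(l, quick_config(fixation_threshold = 0.95))
  expect_true(all(tr$snapshots$size > 0))
  expect_true(all(tr$snapshots$top_n <= tr$snapshots$size))
  last <- nrow(tr$snapshots)
  expect_gte(tr$snapshots$top_n[last] / tr$snapshots$size[last], 0.95)
  expect_equal(tr$snapshots$top_geno[last], tr$fixated)
})

test_that("smaller initial populations sweep harder (less clonal interference)", {
  set.seed(14)
  l <- generate_landscape("representable", 5)
  top_freq <- function(N0) {
    b <- batch_simulate(l, sim_config(init_size = N0), n_runs = 8)
    mean(vapply(b$trajectories, function(s) {
      mid <- s[which.min(abs(s$time - max(s$time) / 2)), ]
      mid$top_n / mid$size
    }, numeric(1)))
  }
  expect_gt(top_freq(2000), top_freq(50000))
})
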