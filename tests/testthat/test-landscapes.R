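test_that("random DAGs satisfy the structural invariants and are reproducible", {
  expect_error(generate_random_dag(0), "n_genes")
  d1 <- generate_random_dag(1, density = 0.9)
  expect_equal(d1$n_genes, 1L)
  expect_equal(nrow(d1$edges), 0L)  # a single gene can only hang off Root

  set.seed(42)
  d <- generate_random_dag(7, density = 0.3)
  expect_true(is_acyclic(7, d$edges))
  set.seed(42)
  d2 <- generate_random_dag(7, density = 0.3)
  expect_identical(d, d2)

  # density 0 yields the empty poset: 4! source-to-sink paths on 4 genes
  d0 <- generate_random_dag(4, density = 0)
  expect_equal(nrow(d0$edges), 0L)
  expect_equal(length(paths_from_model(d0)), factorial(4))
})

test_that("fitness graph of the conjunctive DAG matches the brute-force AND rule", {
  fg <- fitness_graph_from_dag(fig_dag())
  expect_equal(length(fg$nodes), 10L)
  expect_false(geno_mask("1001") %in% fg$nodes)
  expect_setequal(fg$nodes, oracle_accessible(fig_dag()))
  # every edge adds exactly one mutation
  expect_true(all(popcount(bitwXor(fg$edges[, 1], fg$edges[, 2])) == 1L))

  # empty poset on 7 genes: full hypercube, 7! paths
  fg7 <- fitness_graph_from_dag(new_poset(7))
  expect_equal(length(fg7$nodes), 2L^7)
  expect_equal(length(paths_from_model(new_poset(7))), factorial(7))

  # agreement with the oracle on random DAGs with K <= 6
  set.seed(7)
  for (i in 1:25) {
    K <- sample(2:6, 1)
    dag <- generate_random_dag(K, stats::runif(1, 0, 0.6))
    expect_setequal(fitness_graph_from_dag(dag)$nodes, oracle_accessible(dag))
  }
})

test_that("birth rates start at 1, increase along edges, and zero out inaccessible genotypes", {
  set.seed(1)
  fg <- fitness_graph_from_dag(fig_dag())
  l <- assign_birth_rates(fg)
  expect_equal(l$birth_rate[1], 1)
  expect_equal(l$birth_rate[geno_mask("1001") + 1], 0)
  # strict increase along every fitness-graph edge, within the multiplier band
  ratio <- l$birth_rate[fg$edges[, 2] + 1] / l$birth_rate[fg$edges[, 1] + 1]
  expect_true(all(ratio > 1))
  # the child/max-parent ratio lies in [1.01, 1.19]
  for (g in fg$nodes[fg$nodes != 0]) {
    par <- fg$edges[fg$edges[, 2] == g, 1]
    r <- l$birth_rate[g + 1] / max(l$birth_rate[par + 1])
    expect_gte(r, 1.01); expect_lte(r, 1.19)
  }
})

test_that("pruning keeps all nodes reachable and does not lose accessibility", {
  set.seed(3)
  for (i in 1:40) {
    K <- sample(3:5, 1)
    fg <- fitness_graph_from_dag(generate_random_dag(K, stats::runif(1, 0, 0.4)))
    pr <- prune_to_local_maxima(fg, removal_fraction = 0.6, n_tries = 2)
    expect_identical(pr$nodes, fg$nodes)
    # reachability from wild type
    reached <- 0L
    repeat {
      new <- setdiff(pr$edges[pr$edges[, 1] %in% reached, 2], reached)
      if (!length(new)) break
      reached <- c(reached, new)
    }
    expect_setequal(reached, fg$nodes)
    # sinks never decrease
    sinks0 <- sum(!(fg$nodes %in% fg$edges[, 1]))
    sinks1 <- sum(!(pr$nodes %in% pr$edges[, 1]))
    expect_gte(sinks1, sinks0)
  }
  fg <- fitness_graph_from_dag(fig_dag())
  expect_identical(prune_to_local_maxima(fg, 0), fg)
})

test_that("representable landscapes have a single maximum at the fully mutated genotype", {
  set.seed(11)
  for (i in 1:10) {
    K <- sample(3:7, 1)
    l <- generate_landscape("representable", K)
    st <- landscape_stats(l)
    expect_equal(st$n_local_maxima, 1L)
    expect_equal(st$max_genotype_sizes, K)
  }
})

test_that("pruned landscapes report their local maxima", {
  # prune the Fig-1-style graph down to specific sinks: removing all outgoing
  # edges of 1100 and 1010 yields three maxima
  fg <- fitness_graph_from_dag(fig_dag())
  drop <- fg$edges[, 1] %in% geno_mask(c("1100", "1010"))
  pr <- fg; pr$edges <- fg$edges[!drop, , drop = FALSE]; pr$pruned <- TRUE
  set.seed(5)
  l <- assign_birth_rates(pr)
  st <- landscape_stats(l)
  expect_equal(st$n_local_maxima, 3L)
  expect_setequal(st$max_genotype_sizes, c(2L, 2L, 4L))
})

test_that("RMF landscapes are positive, reference-peaked, and HoC maxima match theory", {
  set.seed(21)
  for (i in 1:10) {
    l <- rmf_landscape(5, slope_c = 0.08, hoc_sd = 0.04)
    expect_true(all(l$birth_rate > 0))
    expect_equal(l$birth_rate[1], 1)
    expect_equal(which.max(l$birth_rate) - 1L, l$provenance$reference)
  }
  # purely additive: a single local maximum (the reference), rate strictly
  # decreasing in Hamming distance from it
  l <- rmf_landscape(4, slope_c = 0.1, hoc_sd = 0)
  expect_equal(landscape_stats(l)$n_local_maxima, 1L)
  d <- popcount(bitwXor(0:15, l$provenance$reference))
  by_d <- tapply(l$birth_rate, d, unique)
  expect_true(all(lengths(by_d) == 1L))
  expect_true(all(diff(unlist(by_d)) < 0))

  # pure House of Cards: expected fraction of local maxima (no-back-mutation
  # neighborhoods) is the mean of 1/(k_free + 1) over the hypercube levels;
  # Monte-Carlo over many landscapes, exhaustive neighbor comparison
  set.seed(22)
  K <- 6
  nm <- replicate(400, landscape_stats(rmf_landscape(K, 0, 1))$n_local_maxima)
  # each genotype is a maximum among itself and its K neighbors w.p. 1/(K+1)
  expected <- 2^K / (K + 1)
  expect_lt(abs(mean(nm) - expected) / expected, 0.05)
})

test_that("landscape serialization is seed-stable and round-trips", {
  # same seed -> byte-identical serialization
  f <- withr::local_tempfile(fileext = ".json")
  fb <- withr::local_tempfile(fileext = ".json")
  set.seed(31)
  write_landscape(generate_landscape("local_maxima", 5, n_tries = 5), f)
  set.seed(31)
  write_landscape(generate_landscape("local_maxima", 5, n_tries = 5), fb)
  expect_identical(readLines(f), readLines(fb))

  set.seed(31)
  l <- generate_landscape("local_maxima", 5, n_tries = 5)
  l2 <- read_landscape(f)
  expect_equal(l2$birth_rate, l$birth_rate, tolerance = 1e-12)
  expect_identical(sort(l2$graph$edges[, 1] * 64 + l2$graph$edges[, 2]),
                   sort(l$graph$edges[, 1] * 64 + l$graph$edges[, 2]))
  expect_equal(landscape_stats(l2)$n_local_maxima,
               landscape_stats(l)$n_local_maxima)

  r <- rmf_landscape(4)
  f2 <- withr::local_tempfile(fileext = ".json")
  write_landscape(r, f2)
  r2 <- read_landscape(f2)
  expect_equal(r2$birth_rate, r$birth_rate, tolerance = 1e-12)
  expect_identical(r2$provenance$reference, r$provenance$reference)
})
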