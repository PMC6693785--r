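test_that("path entropy matches closed forms", {
  expect_equal(path_entropy(uniform_path_distribution("A>B")), 0)
  expect_equal(path_entropy(rand_dist("A")), 0)
  d <- structure(c(`A>B` = 0.5, `A>C` = 0.5), class = "path_distribution")
  expect_equal(path_entropy(d), log(2), tolerance = 1e-12)
  # uniform over n has entropy ln n
  set.seed(30)
  for (n in c(1, 2, 7, 100, 10000)) {
    u <- structure(stats::setNames(rep(1 / n, n), paste0("p", 1:n)),
                   class = "path_distribution")
    expect_equal(path_entropy(u), log(n), tolerance = 1e-9)
  }
  # the study's equiprobable-path equivalents: 25 paths ~ 3.2 nats,
  # 400 paths ~ 6.0 nats
  expect_equal(round(log(25), 1), 3.2)
  expect_equal(round(log(400), 1), 6.0)
})

test_that("JS divergence is a scaled symmetric divergence on the union support", {
  d1 <- structure(c(`A>B` = 0.5, `A>C` = 0.5), class = "path_distribution")
  d2 <- structure(c(`A>B` = 0.5, `C>A` = 0.5), class = "path_distribution")
  d3 <- structure(c(`B>A` = 0.7, `C>B` = 0.3), class = "path_distribution")
  expect_equal(js_divergence(d1, d1), 0)
  expect_equal(js_divergence(d1, d3), 1)  # disjoint supports
  expect_equal(js_divergence(d1, d2), 0.5, tolerance = 1e-12)
  set.seed(31)
  for (i in 1:200) {
    labels <- paste0("F", 1:5)
    P <- rand_dist(rand_paths(sample(2:10, 1), 3, labels))
    Q <- rand_dist(rand_paths(sample(2:10, 1), 3, labels))
    v <- js_divergence(P, Q)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(v, js_divergence(Q, P), tolerance = 1e-12)
    expect_equal(js_divergence(P, P), 0, tolerance = 1e-12)
    expect_equal(v, oracle_js(P, Q), tolerance = 1e-12)
  }
})

test_that("the unequal-length comparison reproduces its worked example", {
  lod <- structure(c(`A>B>C` = 1), class = "path_distribution")
  cpm <- structure(c(`A>B` = 1), class = "path_distribution")
  cmp <- compare_path_distributions(lod, cpm)
  expect_equal(cmp$one_minus_recall, 1 / 3, tolerance = 1e-12)
  expect_equal(cmp$one_minus_precision, 0)
  # JS of P = [2/3, 1/3] vs Q = [1, 0], base 2
  P <- c(2 / 3, 1 / 3); Q <- c(1, 0); M <- (P + Q) / 2
  js_direct <- 0.5 * sum(P * log2(P / M)) +
    0.5 * sum(Q[1] * log2(Q[1] / M[1]))
  expect_equal(cmp$js, js_direct, tolerance = 1e-12)
  expect_equal(cmp$js, 0.1909, tolerance = 1e-3)
})

test_that("equal-length comparisons collapse to the plain statistics", {
  set.seed(32)
  labels <- paste0("F", 1:6)
  for (i in 1:60) {
    k <- sample(2:5, 1)
    P <- rand_dist(rand_paths(sample(2:8, 1), k, labels))
    Q <- rand_dist(rand_paths(sample(2:8, 1), k, labels))
    cmp <- compare_path_distributions(P, Q)
    expect_equal(cmp$js, js_divergence(P, Q), tolerance = 1e-12)
    expect_equal(cmp$one_minus_recall,
                 sum(P[!(names(P) %in% names(Q))]), tolerance = 1e-12)
    expect_equal(cmp$one_minus_precision,
                 sum(Q[!(names(Q) %in% names(P))]), tolerance = 1e-12)
  }
})

test_that("mixed-length comparisons agree with the literal-transcription oracle", {
  set.seed(33)
  for (i in 1:200) {
    inst <- rand_instance()
    for (renorm in c(TRUE, FALSE)) {
      got <- compare_path_distributions(inst$lod, inst$cpm,
                                        renormalize = renorm)
      want <- oracle_compare(inst$lod, inst$cpm, renormalize = renorm)
      expect_equal(got$js, min(1, want$js), tolerance = 1e-9)
      expect_equal(got$one_minus_recall, want$one_minus_recall,
                   tolerance = 1e-9)
      expect_equal(got$one_minus_precision, want$one_minus_precision,
                   tolerance = 1e-9)
    }
    # probability-flow conservation and ranges
    got <- compare_path_distributions(inst$lod, inst$cpm)
    expect_gte(got$js, 0); expect_lte(got$js, 1)
    expect_gte(got$one_minus_recall, 0); expect_lte(got$one_minus_recall, 1)
    expect_equal(sum(got$w_k), 1, tolerance = 1e-12)
  }
})

test_that("disjoint prefix structure drives all three statistics to 1", {
  lod <- structure(c(`A>B` = 0.6, `A>C>D` = 0.4),
                   class = "path_distribution")
  cpm <- structure(c(`B>A>D` = 0.5, `C>D>A` = 0.5),
                   class = "path_distribution")
  cmp <- compare_path_distributions(lod, cpm)
  expect_equal(cmp$js, 1)
  expect_equal(cmp$one_minus_recall, 1)
  expect_equal(cmp$one_minus_precision, 1)
})

test_that("recall and precision can both be 0 while JS stays large", {
  # every LOD path is a CPM path and vice versa, but with very different
  # masses: both misses are 0 yet JS is substantial
  lod <- structure(c(`A>B>C` = 0.98, `B>A>C` = 0.01, `C>A>B` = 0.01),
                   class = "path_distribution")
  cpm <- structure(c(`A>B>C` = 0.01, `B>A>C` = 0.01, `C>A>B` = 0.98),
                   class = "path_distribution")
  cmp <- compare_path_distributions(lod, cpm)
  expect_equal(cmp$one_minus_recall, 0)
  expect_equal(cmp$one_minus_precision, 0)
  expect_gt(cmp$js, 0.7)
})

test_that("most common LOD recovery honors the prefix-matching rule", {
  lod <- structure(c(`A>B` = 0.6, `C>A` = 0.4), class = "path_distribution")
  expect_equal(most_common_lod_recovered(lod, c("A>B>C", "B>C>A")), 1L)
  expect_equal(most_common_lod_recovered(lod, c("B>A>C")), 0L)
  # longer modal LOD matched through its prefix
  lod2 <- structure(c(`A>B>C>D` = 0.7, `B>A` = 0.3),
                    class = "path_distribution")
  expect_equal(most_common_lod_recovered(lod2, c("A>B>C")), 1L)
  # ties: recovered if any modal path matches
  lod3 <- structure(c(`A>B` = 0.5, `B>A` = 0.5), class = "path_distribution")
  expect_equal(most_common_lod_recovered(lod3, "B>A>C"), 1L)
})
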