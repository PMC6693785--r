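test_that("OT recovers chains from noiseless chain data and stars from independence", {
  # noiseless chain A -> B -> C: genotypes 000, 100, 110, 111
  x <- rbind(matrix(rep(c(0, 0, 0), 500), ncol = 3, byrow = TRUE),
             matrix(rep(c(1, 0, 0), 500), ncol = 3, byrow = TRUE),
             matrix(rep(c(1, 1, 0), 500), ncol = 3, byrow = TRUE),
             matrix(rep(c(1, 1, 1), 500), ncol = 3, byrow = TRUE))
  ds <- build_dataset(as.integer(x %*% c(1, 2, 4)), 3)
  m <- fit_ot(ds)
  expect_equal(m$parent, c(0L, 1L, 2L))

  # independent features with equal marginals: star tree
  set.seed(40)
  xi <- matrix(rbinom(4000 * 3, 1, 0.4), ncol = 3)
  dsi <- build_dataset(as.integer(xi %*% c(1, 2, 4)), 3)
  mi <- fit_ot(dsi)
  expect_equal(mi$parent, c(0L, 0L, 0L))

  # determinism
  expect_identical(fit_ot(ds), fit_ot(ds))
  # output is always a spanning arborescence rooted at Root
  set.seed(41)
  for (i in 1:10) {
    K <- sample(2:6, 1)
    d <- build_dataset(sample(0:(2^K - 1), 300, replace = TRUE), K)
    mm <- fit_ot(d)
    # every feature reaches Root by following parents
    for (j in seq_len(K)) {
      seen <- integer(0); cur <- j
      while (cur != 0L) {
        expect_false(cur %in% seen)
        seen <- c(seen, cur); cur <- mm$parent[cur]
      }
    }
    expect_true(all(mm$weight > 0 & mm$weight <= 1))
  }
})

test_that("OT warns on degenerate columns and still returns a tree", {
  x <- cbind(a = rep(1L, 20), b = rbinom(20, 1, 0.5), c = rep(0L, 20))
  x[1, 2] <- 1L; x[2, 2] <- 0L
  ds <- structure(list(x = x, labels = colnames(x), provenance = list()),
                  class = "cpm_dataset")
  expect_warning(m <- fit_ot(ds), "degenerate")
  expect_length(m$parent, 3L)
})

test_that("CBN single-feature occupancy matches the exponential-race closed form", {
  p1 <- new_poset(1)
  for (lam in c(0.3, 1, 4)) {
    m <- cbn_model(p1, lam)
    pr <- cbn_genotype_probs(m)
    # P(mutated at Exp(1) observation) = lambda / (1 + lambda)
    expect_equal(pr$prob[pr$mask == 1], lam / (1 + lam), tolerance = 1e-12)
    expect_equal(sum(pr$prob), 1, tolerance = 1e-12)
    # exact loglik of a dataset of k mutated out of n
    ds <- build_dataset(c(rep(1L, 3), rep(0L, 2)), 1)
    ll <- cbn_loglik(cbn_model(p1, lam), ds)
    expect_equal(ll, 3 * log(lam / (1 + lam)) + 2 * log(1 / (1 + lam)),
                 tolerance = 1e-10)
  }
})

test_that("CBN occupancy probabilities match Monte-Carlo forward sampling", {
  set.seed(42)
  for (rep in 1:3) {
    dag <- generate_random_dag(3, 0.5)
    lam <- stats::rgamma(3, 2) + 0.2
    m <- cbn_model(dag, lam)
    pr <- cbn_genotype_probs(m)
    sim <- generate_from_cbn(m, 40000)
    emp <- tabulate(as.integer(sim$x %*% c(1L, 2L, 4L)) + 1L, 8) / 40000
    for (i in seq_len(nrow(pr))) {
      p <- pr$prob[i]
      se <- sqrt(p * (1 - p) / 40000)
      expect_lt(abs(emp[pr$mask[i] + 1] - p), max(3.5 * se, 1e-3))
    }
  }
})

test_that("generate_from_cbn respects poset compatibility and error rates", {
  dag <- fig_dag()
  m <- cbn_model(dag, rep(1, 4), eps = 0)
  set.seed(43)
  ds <- generate_from_cbn(m, 500)
  masks <- as.integer(ds$x %*% bitwShiftL(1L, 0:3))
  fg <- fitness_graph_from_dag(dag)
  expect_true(all(masks %in% fg$nodes))
  # single parentless feature with lambda = 1 has marginal ~ 0.5
  m1 <- cbn_model(new_poset(1), 1)
  set.seed(44)
  d1 <- generate_from_cbn(m1, 20000)
  expect_lt(abs(mean(d1$x) - 0.5), 0.02)
  # lambda -> Inf: all-ones rows
  mbig <- cbn_model(new_poset(2), c(1e9, 1e9))
  expect_true(all(generate_from_cbn(mbig, 50)$x == 1L))
})

test_that("the nested CBN parameter fit never decreases the log-likelihood", {
  set.seed(45)
  m <- cbn_model(fig_dag(), c(2, 1, 1, 3), eps = 0.05)
  ds <- generate_from_cbn(m, 800)
  fit <- fit_cbn(ds, cbn_control(proposals = 0))
  expect_true(all(diff(fit$trace) >= -1e-8))
  # annealed fit scores at least the empty-poset fit on the same data
  fit2 <- fit_cbn(ds, cbn_control(restarts = 1, proposals = 60))
  expect_gte(fit2$loglik, fit$loglik - 1e-6)
})

test_that("the true generating model outscores a perturbed poset on large data", {
  set.seed(46)
  truth <- cbn_model(fig_dag(), c(1, 1.5, 0.7, 2), eps = 0.05)
  ds <- generate_from_cbn(truth, 3000)
  ll_true <- cbn_loglik(truth, ds)
  wrong <- cbn_model(new_poset(4, rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L))),
                     truth$lambda, truth$eps)
  expect_gt(ll_true, cbn_loglik(wrong, ds))
})

test_that("CBN structure recovery improves with sample size", {
  set.seed(47)
  truth <- cbn_model(fig_dag(), rep(1, 4), eps = 0.05)
  ctl <- cbn_control(restarts = 1, proposals = 120)
  hit <- function(n, reps = 3) {
    mean(replicate(reps, {
      ds <- generate_from_cbn(truth, n)
      fit <- fit_cbn(ds, ctl)
      identical(sort(fit$poset$edges[, 1] * 10 + fit$poset$edges[, 2]),
                sort(truth$poset$edges[, 1] * 10 + truth$poset$edges[, 2]))
    }))
  }
  h100 <- hit(100); h2000 <- hit(2000)
  expect_gte(h2000, h100)
  expect_gte(h2000, 2 / 3)
})

test_that("degenerate features are clamped and re-attached with a warning", {
  set.seed(48)
  m <- cbn_model(new_poset(2), c(1, 1), eps = 0)
  ds <- generate_from_cbn(m, 200)
  ds$x <- cbind(ds$x, dead = 0L, hot = 1L)
  ds$labels <- colnames(ds$x)
  expect_warning(fit <- fit_cbn(ds, cbn_control(proposals = 0)),
                 "degenerate")
  expect_equal(fit$n_genes, 4L)
  expect_lt(fit$lambda[3], 1e-3)   # never-mutated feature
  expect_gt(fit$lambda[4], 1e3)    # always-mutated feature
})

test_that("models serialize to JSON and back", {
  set.seed(49)
  m <- cbn_model(fig_dag(), c(1, 2, 3, 4), eps = 0.1)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(m, f)
  m2 <- read_model(f)
  expect_equal(m2$lambda, m$lambda)
  expect_equal(m2$poset$edges, m$poset$edges, ignore_attr = TRUE)
  ds <- toy_dataset()
  ot <- fit_ot(ds)
  f2 <- withr::local_tempfile(fileext = ".json")
  write_model(ot, f2)
  ot2 <- read_model(f2)
  expect_equal(ot2$parent, ot$parent)
  expect_equal(ot2$weight, ot$weight)
})
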