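# UPGMA, branching schedules, the mixed-model likelihood engine, null
# fits and the likelihood-ratio test.

test_that("UPGMA halves merge distances and reproduces ultrametric input", {
  v <- matrix(c(0, 0.2, 0.2, 0), 2, 2, dimnames = list(c("a", "b"),
                                                       c("a", "b")))
  tr <- upgma_tree(as_divergence_matrix(v))
  expect_identical(sort(tr$tip.label), c("a", "b"))
  expect_equal(unname(tr$edge.length), c(0.1, 0.1))
  # cophenetic consistency on an ultrametric matrix
  src <- ape::read.tree(text = "((a:1,b:1):2,(c:2.5,d:2.5):0.5);")
  cm <- ape::cophenetic.phylo(src)
  tr2 <- upgma_tree(as_divergence_matrix(cm))
  expect_equal(ape::cophenetic.phylo(tr2)[rownames(cm), colnames(cm)], cm,
               tolerance = 1e-12)
  expect_error(upgma_tree(as_divergence_matrix(matrix(0, 1, 1,
    dimnames = list("a", "a")))), ">= 2")
})

test_that("UPGMA cophenetic matrices equal the naive average-linkage oracle", {
  set.seed(131)
  for (rep in 1:8) {
    n <- sample(5:8, 1)
    v <- rand_distance_matrix(n)
    tr <- upgma_tree(as_divergence_matrix(v))
    got <- ape::cophenetic.phylo(tr)[rownames(v), colnames(v)]
    want <- oracle_upgma_cophenetic(v)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("branching schedules enumerate intervals and entities by hand", {
  tre <- toy_tree(paste0("((a:0.6,b:0.6):2.4,((c:0.2,d:0.2):0.3,",
                         "e:0.5):2.5);"))
  # T above the root: the whole tree is one coalescent set
  sch <- branching_schedule(tre, T = 10)
  expect_identical(sch$n_clusters, 1L)
  expect_identical(sch$n_entities, 1L)
  expect_equal(sch$intervals$n_coalescent, c(2, 3, 4))
  # T = 0: every node diversification, every tip its own entity
  sch0 <- branching_schedule(tre, T = 0)
  expect_identical(sch0$n_entities, 5L)
  expect_identical(sch0$n_clusters, 0L)
  expect_equal(sch0$intervals$n_yule, c(2, 3, 4))
  expect_equal(sch0$intervals$duration, c(2.4, 0.1, 0.3))
  # intermediate threshold: hand bookkeeping of the four segments
  sch1 <- branching_schedule(tre, T = 1)
  expect_identical(sch1$n_clusters, 2L)
  expect_identical(sch1$n_entities, 2L)
  expect_equal(sch1$intervals$duration, c(2, 0.4, 0.1, 0.3))
  expect_equal(sch1$intervals$n_yule, c(2, 2, 2, 2))
  expect_equal(sch1$intervals$n_coalescent, c(0, 0, 2, 4))
  expect_identical(sch1$intervals$ends_at_event, c(FALSE, TRUE, TRUE, TRUE))
})

test_that("the likelihood engine matches a hand computation on a small tree", {
  tre <- toy_tree("((a:1,b:1):2,(c:2.5,d:2.5):0.5);")
  # one-process likelihood: segments (3,2.5) n=2 and (2.5,1) n=3, factors
  # at both terminating events
  lam <- 0.4; p <- 1
  hand <- (log(lam * 2^p) - lam * 2^p * 0.5) +
    (log(lam * 3^p) - lam * 3^p * 1.5)
  expect_equal(gmyc_loglik(tre, 0, lam, p), hand, tolerance = 1e-10)
  # mixed likelihood with active coalescent sets, hand-summed segment rates
  tre2 <- toy_tree(paste0("((a:0.6,b:0.6):2.4,((c:0.2,d:0.2):0.3,",
                          "e:0.5):2.5);"))
  l1 <- 0.5; p1 <- 1; l2 <- 3; p2 <- 1.5
  b_above <- l1 * 2^p1
  b3 <- l1 * 2^p1 + l2 * 2^p2
  b4 <- l1 * 2^p1 + l2 * 2 * 2^p2
  hand2 <- (-b_above * 2) +
    (log(b_above) - b_above * 0.4) +
    (log(b3) - b3 * 0.1) +
    (log(b4) - b4 * 0.3)
  expect_equal(gmyc_loglik(tre2, 1, l1, p1, l2, p2), hand2, tolerance = 1e-10)
})

test_that("the null fit satisfies its stationarity and scaling identities", {
  set.seed(139)
  tre <- ape::rphylo(20, birth = 1, death = 0)
  fit <- fit_null(tre)
  # closed-form rate at the fitted exponent: lambda = E / sum(n^p x)
  th <- bathydelim:::.node_heights(tre)
  idx <- bathydelim:::.tree_index(th)
  st <- bathydelim:::.gmyc_structure(th, idx, 0)
  expect_equal(fit$lambda,
               st$n_events / sum(st$nY^fit$p * st$x), tolerance = 1e-4)
  # doubling all branch lengths halves the rate and shifts lnL by -E*log(2)
  tre2 <- tre
  tre2$edge.length <- tre2$edge.length * 2
  fit2 <- fit_null(tre2)
  expect_equal(fit2$lambda, fit$lambda / 2, tolerance = 1e-3)
  expect_equal(fit2$logLik, fit$logLik - st$n_events * log(2),
               tolerance = 1e-4)
  expect_equal(fit2$p, fit$p, tolerance = 1e-2)
})

test_that("the null exponent is recovered on pure-birth simulations", {
  set.seed(149)
  p_hat <- replicate(50, fit_null(ape::rphylo(15, birth = 1, death = 0))$p)
  # mean exponent close to 1 within 3 standard errors
  se <- stats::sd(p_hat) / sqrt(length(p_hat))
  expect_lt(abs(mean(p_hat) - 1), 3 * se + 0.05)
})

test_that("the threshold fit recovers clean cluster structure and nests the null", {
  tre <- toy_tree(paste0("((a1:0.01,a2:0.01):0.99,((b1:0.02,b2:0.02):0.78,",
                         "(c1:0.015,c2:0.015):0.785):0.2);"))
  fit <- fit_gmyc(tre)
  expect_identical(fit$n_entities, 3L)
  expect_identical(fit$n_clusters, 3L)
  expect_gt(fit$threshold, 0.02)
  expect_lt(fit$threshold, 0.8)
  truth <- as_partition(c(a1 = "A", a2 = "A", b1 = "B", b2 = "B",
                          c1 = "C", c2 = "C"))
  expect_identical(compare_partitions(fit$partition, truth)$relation, "equal")
  null <- fit_null(tre)
  expect_gte(fit$logLik, null$logLik - 1e-8)
  # the T = 0 profile point reproduces the null model exactly
  expect_equal(fit$profile$logLik[fit$profile$T == 0], null$logLik,
               tolerance = 1e-6)
  # entities decrease monotonically along the threshold profile
  expect_true(all(diff(fit$profile$n_entities[order(fit$profile$T)]) <= 0))
  # support interval contains the ML threshold
  expect_gte(fit$threshold, fit$support_interval[1])
  expect_lte(fit$threshold, fit$support_interval[2])
  expect_error(fit_gmyc(toy_tree("((a:1,b:1):1,c:2);")), ">= 4")
})

test_that("the mixed fit dominates the null on random trees", {
  set.seed(151)
  for (rep in 1:5) {
    tre <- if (rep %% 2) ape::rphylo(12, birth = 1, death = 0) else
      ape::rcoal(12)
    expect_gte(fit_gmyc(tre)$logLik, fit_null(tre)$logLik - 1e-8)
  }
})

test_that("non-ultrametric trees are rejected at the stated tolerance", {
  tre <- toy_tree("((a:1,b:1.4):2,(c:2.5,d:2.5):0.9);")
  expect_error(fit_null(tre), "not ultrametric")
  expect_error(fit_gmyc(tre), "not ultrametric")
  expect_silent(fit_null(toy_tree("((a:1,b:1):2,(c:2.5,d:2.5):0.5);"),
                         ultra_tol = 1e-6))
})

test_that("likelihood-ratio arithmetic and chi-square reference behave", {
  lrt <- gmyc_lrt(10, 16.18670)
  expect_equal(lrt$statistic, 2 * 6.18670, tolerance = 1e-12)
  expect_equal(lrt$p_value,
               stats::pchisq(12.3734, df = 3, lower.tail = FALSE))
  same <- gmyc_lrt(42.5, 42.5)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(gmyc_lrt(10, 9.5), "negative")
  expect_equal(gmyc_lrt(10, 12, df = 1)$df, 1)
})
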