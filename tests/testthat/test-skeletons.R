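test_that("Fisher-z test is calibrated under the null and detects dependence", {
  # rejection rate under independence ~ alpha
  set.seed(1)
  alpha <- 0.05
  rej <- mean(vapply(1:500, function(s) {
    x <- matrix(stats::rnorm(2000), 1000, 2)
    !fisher_z_ci_test(x, 1, 2, integer(0), alpha)$independent
  }, logical(1)))
  expect_lt(abs(rej - alpha), 3 * sqrt(alpha * (1 - alpha) / 500))

  # perfect correlation
  x <- cbind(stats::rnorm(200))
  tst <- fisher_z_ci_test(cbind(x, x), 1, 2, integer(0), 0.01)
  expect_false(tst$independent)
  expect_lt(tst$p_value, 1e-10)

  # chain: X1 indep X3 given X2
  sem <- gaussian_sem(chain3(), rbind(c(0, .8, 0), c(0, 0, .8), c(0, 0, 0)), rep(1, 3))
  d <- sample_observational(sem, 5000, seed = 1)
  expect_true(fisher_z_ci_test(d, 1, 3, 2L, 0.01)$independent)
  expect_false(fisher_z_ci_test(d, 1, 3, integer(0), 0.01)$independent)
})

test_that("PC recovers canonical structures and the true essential graph", {
  # collider: both edges oriented into node 3
  semc <- gaussian_sem(collider3(), rbind(c(0, 0, .8), c(0, 0, .8), c(0, 0, 0)), rep(1, 3))
  dc <- sample_observational(semc, 5000, seed = 3)
  pcc <- pc_estimate(dc, alpha = 0.01)
  expect_equal(unname(pcc$directed), unname(collider3()$adjacency))

  # chain: fully undirected 1--2--3
  semh <- gaussian_sem(chain3(), rbind(c(0, .8, 0), c(0, 0, .8), c(0, 0, 0)), rep(1, 3))
  dh <- sample_observational(semh, 5000, seed = 4)
  pch <- pc_estimate(dh, alpha = 0.01)
  expect_equal(sum(pch$directed), 0)
  expect_equal(unname(pch$undirected), unname(skeleton_of(chain3())$undirected))

  # independent columns: (almost) no edges, alpha-controlled
  set.seed(5)
  x <- matrix(stats::rnorm(500 * 6), 500, 6)
  expect_lte(sum(spgies:::any_adjacency(pc_estimate(x, alpha = 0.01))) / 2, 2)

  # consistency sweep: exact essential-graph recovery on a fixed 6-node
  # DAG under comfortably faithful SEMs.  The fixture is triangle-free
  # (no edge's endpoints share a child) with same-sign weights bounded
  # away from zero: random-sign or shielded configurations routinely
  # violate strong faithfulness (a collider child induces a negative
  # partial correlation that cancels a positive direct edge), which no
  # constraint-based learner can survive at finite n.
  a6 <- matrix(0L, 6, 6)
  a6[1, 2] <- a6[2, 3] <- a6[4, 3] <- a6[3, 5] <- a6[5, 6] <- a6[1, 4] <- 1L
  g6 <- directed_graph(a6)
  truth_eg <- essential_graph(g6)
  hits <- 0
  for (s in 1:50) {
    set.seed(1000 + s)
    w <- matrix(0, 6, 6)
    w[a6 == 1L] <- stats::runif(sum(a6), 0.6, 1)
    sem <- gaussian_sem(g6, w, rep(1, 6))
    d <- sample_observational(sem, 1e4, seed = 2000 + s)
    est <- pc_estimate(d, alpha = 0.01)
    if (identical(unname(est$directed), unname(truth_eg$directed)) &&
        identical(unname(est$undirected), unname(truth_eg$undirected))) hits <- hits + 1
  }
  expect_gte(hits, 45)
})

test_that("mutual information estimates are symmetric and consistent", {
  set.seed(6)
  x <- matrix(stats::rnorm(1e4 * 4), 1e4, 4)
  mi <- mutual_information_matrix(x)
  expect_true(all(mi == t(mi)))
  expect_lt(max(mi), 0.02)  # independent columns

  y <- cbind(x[, 1], x[, 1] + 0.01 * stats::rnorm(1e4), x[, 3:4])
  mih <- mutual_information_matrix(y, estimator = "histogram")
  expect_true(all(mih == t(mih)))
  expect_equal(which.max(mih), which(row(mih) == 2 & col(mih) == 1) , ignore_attr = TRUE)

  expect_warning(mutual_information_matrix(cbind(x[, 1:2], 0)), "zero-variance")
})

test_that("CLR standardizes against gene backgrounds", {
  cm <- matrix(0.3, 5, 5); diag(cm) <- 0
  expect_true(all(clr_scores(cm) == 0))

  mi <- matrix(0.1, 4, 4) + stats::runif(16, 0, 0.01)
  mi <- (mi + t(mi)) / 2; diag(mi) <- 0
  mi[1, 2] <- mi[2, 1] <- 2
  sc <- clr_scores(mi)
  expect_true(all(sc == t(sc)))
  expect_equal(which.max(sc), which(row(sc) == 2 & col(sc) == 1), ignore_attr = TRUE)
})

test_that("top-fraction thresholding keeps the exact edge count with stable ties", {
  set.seed(7)
  sc <- matrix(stats::runif(100), 10, 10); sc <- (sc + t(sc)) / 2; diag(sc) <- 0
  full <- threshold_top_fraction(sc, 1)
  expect_equal(sum(full$undirected) / 2, 45)
  ten <- threshold_top_fraction(sc, 0.10)
  expect_equal(sum(ten$undirected) / 2, 5)  # ceiling(0.1 * 45)
  # all-zero scores: deterministic lowest-index pairs
  z <- matrix(0, 4, 4)
  tz <- threshold_top_fraction(z, 0.5)   # ceiling(0.5 * 6) = 3 pairs
  expect_equal(sum(tz$undirected) / 2, 3)
  expect_equal(unname(tz$undirected[1, 2:4]), c(1L, 1L, 1L))
})

test_that("ARACNE applies the MI threshold and the DPI triangle rule", {
  mi <- matrix(0, 3, 3)
  mi[1, 2] <- mi[2, 1] <- 0.9
  mi[2, 3] <- mi[3, 2] <- 0.8
  mi[1, 3] <- mi[3, 1] <- 0.2   # weakest edge of the triangle: indirect
  pruned <- aracne_prune(mi, mi_threshold = 0.05)
  expect_equal(unname(pruned$undirected[1, 3]), 0L)
  expect_equal(unname(pruned$undirected[1, 2]), 1L)
  expect_equal(unname(pruned$undirected[2, 3]), 1L)

  # triangle-free scores survive DPI untouched
  mi2 <- matrix(0, 4, 4)
  mi2[1, 2] <- mi2[2, 1] <- 0.5; mi2[3, 4] <- mi2[4, 3] <- 0.4
  expect_equal(sum(aracne_prune(mi2, 0.1)$undirected) / 2, 2)

  # threshold above the maximum empties the graph
  expect_equal(sum(aracne_prune(mi, 1.0)$undirected), 0)
})

test_that("permutation-null MI threshold is monotone, calibrated and reproducible", {
  set.seed(8)
  x <- matrix(stats::rnorm(200 * 5), 200, 5)
  t5 <- mi_null_threshold(x, p_value = 0.05, n_permutations = 100, seed = 1)
  t1 <- mi_null_threshold(x, p_value = 0.01, n_permutations = 100, seed = 1)
  t8 <- mi_null_threshold(x, p_value = 1e-8, n_permutations = 100, seed = 1)
  expect_lt(t5, t1)
  expect_lt(t1, t8)
  expect_identical(t5, mi_null_threshold(x, p_value = 0.05, n_permutations = 100, seed = 1))

  # self-consistency: ~5% of fresh null MI values exceed the 5% cutoff
  null_mi <- mutual_information_matrix(apply(x, 2, sample))
  frac <- mean(null_mi[upper.tri(null_mi)] > t5)
  expect_lt(abs(frac - 0.05), 0.12)  # only 10 pairs; loose binomial bound
})

test_that("deviation matrix flags descendants of a knockout, scale-free", {
  sem <- gaussian_sem(chain3(), rbind(c(0, .9, 0), c(0, 0, .9), c(0, 0, 0)), rep(1, 3))
  d <- sem_benchmark_samples(sem, 2000, seed = 11)
  dev <- deviation_matrix(d)
  expect_true(all(diag(dev) == 0))
  # knocking out 3 cannot move its ancestors 1, 2 far
  expect_lt(max(dev[3, 1:2]), 3)
  # column scaling leaves scores unchanged
  d2 <- d; d2$data[, 3] <- d2$data[, 3] * 10
  expect_equal(deviation_matrix(d2), deviation_matrix(d), tolerance = 1e-12)
  # missing knockout raises
  obs_only <- sample_observational(sem, 50, seed = 12)
  expect_error(deviation_matrix(obs_only), "missing knockout")
})
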