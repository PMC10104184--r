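test_that("local BIC score is decomposable and consistent", {
  g <- chain3()
  sem <- gaussian_sem(g, rbind(c(0, .8, 0), c(0, 0, .8), c(0, 0, 0)), rep(1, 3))
  d <- sample_observational(sem, 1e4, seed = 1)

  # adding the true parent helps, adding a spurious one hurts
  expect_gt(local_score(2, 1L, d), local_score(2, integer(0), d))
  expect_lt(local_score(3, c(1L, 2L), d), local_score(3, 2L, d))

  # zero-variance node hits the degenerate sentinel
  dz <- sample_set(cbind(d$data[1:50, 1:2], 0))
  expect_identical(local_score(3, 1L, dz), -Inf)

  # decomposability: the DAG score is the sum of local scores in any order
  a <- g$adjacency
  s_fwd <- sum(vapply(1:3, function(v) local_score(v, which(a[, v] == 1), d), numeric(1)))
  s_rev <- sum(vapply(3:1, function(v) local_score(v, which(a[, v] == 1), d), numeric(1)))
  expect_identical(s_fwd, s_rev)
  expect_equal(score_dag(d, a), s_fwd)
})

test_that("two-model score comparison orients a 2-node interventional design", {
  g <- directed_graph(rbind(c(0, 1), c(0, 0)), labels = c("X", "Y"))
  sem <- gaussian_sem(g, rbind(c(0, 0.9), c(0, 0)), c(1, 1))
  d <- bind_samples(sample_observational(sem, 100, seed = 2),
                    sample_intervention(sem, 1, n = 1, seed = 3),
                    sample_intervention(sem, 2, n = 1, seed = 4))
  fit <- fit_gies(d)
  # the greedy result always agrees with the exhaustive two-model oracle
  s_fwd <- local_score(1, integer(0), d) + local_score(2, 1L, d)
  s_rev <- local_score(2, integer(0), d) + local_score(1, 2L, d)
  oracle <- if (s_fwd > s_rev) rbind(c(0L, 1L), c(0L, 0L)) else rbind(c(0L, 0L), c(1L, 0L))
  expect_equal(unname(fit$member_dag$adjacency), oracle)
  expect_equal(fit$score, max(s_fwd, s_rev), tolerance = 1e-9)
})

test_that("observational chain data yields the undirected essential graph", {
  sem <- gaussian_sem(chain3(), rbind(c(0, .8, 0), c(0, 0, .8), c(0, 0, 0)), rep(1, 3))
  d <- sample_observational(sem, 5000, seed = 5)
  fit <- fit_gies(d)
  expect_equal(sum(fit$graph$directed), 0)
  expect_equal(unname(fit$graph$undirected), unname(skeleton_of(chain3())$undirected))
})

test_that("the allowed-set restriction is a hard constraint", {
  bm <- make_benchmark("small_world", 10, list(k = 2, p = 0.5), seed = 6)
  # empty allowed set: no edges, regardless of data
  empty <- fit_gies(bm$samples, allowed = matrix(0, 10, 10))
  expect_equal(sum(empty$member_dag$adjacency), 0)
  # oracle skeleton: estimated edges are a subset of the true skeleton
  fit <- fit_gies(bm$samples, allowed = skeleton_of(bm$graph))
  sk <- spgies:::any_adjacency(bm$graph)
  expect_true(all(sk[fit$member_dag$adjacency == 1L] == 1L))
})

test_that("every accepted move strictly increases the score", {
  for (s in 1:3) {
    bm <- make_benchmark("erdos_renyi", 8, list(p = 0.4), seed = s)
    fit <- fit_gies(bm$samples)
    expect_true(all(fit$trace$gain > 0))
    # total score equals the base empty-graph score plus the gains
    cache <- spgies:::score_cache(spgies:::as_sample_set(bm$samples))
    base <- sum(vapply(1:8, function(v) spgies:::local_score_cached(cache, v, integer(0)),
                       numeric(1)))
    expect_equal(fit$score, base + sum(fit$trace$gain), tolerance = 1e-6)
  }
})

test_that("DAGs in the same interventional MEC receive equal scores", {
  set.seed(7)
  for (rep in 1:6) {
    u <- random_topology("erdos_renyi", 4, list(p = 0.6), seed = rep)
    g <- orient_random(u, seed = rep + 50)
    sem <- random_sem(g, seed = rep + 100)
    fam <- if (rep %% 2 == 0) list(sample.int(4, 1)) else list()
    d <- sample_observational(sem, 100, seed = rep + 150)
    for (I in fam) d <- bind_samples(d, sample_intervention(sem, I, n = 5, seed = rep + 200))
    mec <- enumerate_mec(g, fam)
    scores <- vapply(mec, function(m) score_dag(d, m$adjacency), numeric(1))
    expect_lt(diff(range(scores)), 1e-8)
  }
})

test_that("GIES recovers faithful 5-node SEMs with ample interventional data", {
  # triangle-free fixture with same-sign weights: keeps the SEM inside the
  # strong-faithfulness region (see the PC consistency test for why).
  a5 <- matrix(0L, 5, 5)
  a5[1, 2] <- a5[2, 3] <- a5[1, 4] <- a5[4, 5] <- 1L
  g <- directed_graph(a5)
  hits <- 0
  n_rep <- 50
  for (s in seq_len(n_rep)) {
    set.seed(300 + s)
    w <- matrix(0, 5, 5)
    w[a5 == 1L] <- stats::runif(sum(a5), 0.6, 1)
    sem <- gaussian_sem(g, w, rep(1, 5))
    d <- sample_observational(sem, 1e4, seed = 400 + s)
    for (v in 1:5) d <- bind_samples(d, sample_intervention(sem, v, n = 100,
                                                            seed = 500 + 10 * s + v))
    fit <- fit_gies(d)
    if (identical(unname(fit$member_dag$adjacency), unname(g$adjacency))) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("SP-GIES restricts to its estimated skeleton and degenerates cleanly", {
  bm <- make_benchmark("small_world", 15, list(k = 2, p = 0.5), seed = 10)
  fit <- sp_gies(bm$samples, skeleton_method = "pc")
  allow <- spgies:::any_adjacency(fit$skeleton)
  expect_true(all(allow[fit$member_dag$adjacency == 1L] == 1L))
  expect_equal(fit$method, "sp-gies")
  expect_equal(fit$params$skeleton$method, "pc")

  # skeleton_method = "none" reproduces unrestricted GIES exactly
  plain <- fit_gies(bm$samples)
  none <- sp_gies(bm$samples, skeleton_method = "none")
  expect_equal(none$member_dag$adjacency, plain$member_dag$adjacency)
  expect_equal(none$score, plain$score)

  # CLR and ARACNE skeletons drive the same contract
  fit_clr <- sp_gies(bm$samples, skeleton_method = "clr")
  expect_true(all(spgies:::any_adjacency(fit_clr$skeleton)[
    fit_clr$member_dag$adjacency == 1L] == 1L))
})

test_that("the NULL baseline is edgeless with the expected metric behaviour", {
  nr <- null_result(10)
  expect_equal(sum(nr$member_dag$adjacency), 0)
  bm <- make_benchmark("scale_free", 10, list(k = 2), seed = 11)
  expect_equal(shd(bm$graph, nr), sum(bm$graph$adjacency))
  prev <- sum(bm$graph$adjacency) / 90
  expect_equal(aucpr(bm$graph, nr), (1 + prev) / 2, tolerance = 1e-9)
})
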