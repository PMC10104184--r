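test_that("bootstrap posterior is reproducible and degenerates as expected", {
  bm <- make_benchmark("erdos_renyi", 6, list(p = 0.4), n_obs = 60, seed = 1)
  learner <- function(s) fit_gies(s)
  # B = 1 without resampling: the point estimate itself
  p1 <- bootstrap_posterior(bm$samples, learner, B = 1, seed = 2, resample = FALSE)
  expect_equal(p1$graphs[[1]]$adjacency, learner(bm$samples)$member_dag$adjacency)
  expect_equal(p1$weights, 1)
  # fixed seed reproducibility of the full graph list
  pa <- bootstrap_posterior(bm$samples, learner, B = 5, seed = 3)
  pb <- bootstrap_posterior(bm$samples, learner, B = 5, seed = 3)
  expect_identical(lapply(pa$graphs, `[[`, "adjacency"),
                   lapply(pb$graphs, `[[`, "adjacency"))
  expect_equal(sum(pa$weights), 1)

  # strong signal: all replicates agree on the true skeleton
  g2 <- directed_graph(rbind(c(0, 1), c(0, 0)))
  sem2 <- gaussian_sem(g2, rbind(c(0, 0.9), c(0, 0)), c(1, 1))
  d2 <- bind_samples(sample_observational(sem2, 2000, seed = 4),
                     sample_intervention(sem2, 1, n = 20, seed = 5),
                     sample_intervention(sem2, 2, n = 20, seed = 6))
  ps <- bootstrap_posterior(d2, learner, B = 10, seed = 7)
  for (g in ps$graphs) expect_equal(sum(spgies:::any_adjacency(g)) / 2, 1)
})

test_that("edge-orientation utility matches the enumeration oracle on the chain", {
  post <- structure(list(graphs = list(chain3()), weights = 1),
                    class = "spg_posterior")
  # oracle values by brute-force class enumeration
  oracle <- vapply(1:3, function(v) {
    mec0 <- enumerate_mec(chain3(), list())
    before <- sum(Reduce(`*`, lapply(mec0, `[[`, "adjacency")))
    mec1 <- enumerate_mec(chain3(), list(v))
    after <- sum(Reduce(`*`, lapply(mec1, `[[`, "adjacency")))
    after - before
  }, numeric(1))
  vals <- vapply(1:3, function(v) utility_edge_orientation(post, list(), v), numeric(1))
  expect_equal(vals, oracle)
  expect_equal(vals[2], 2)  # middle knockout orients both chain edges

  # weight linearity: duplicating a graph with split weights changes nothing
  post2 <- structure(list(graphs = list(chain3(), chain3()), weights = c(0.5, 0.5)),
                     class = "spg_posterior")
  expect_equal(utility_edge_orientation(post2, list(), 2), vals[2])
})

test_that("information gain resolves the two-graph posterior and vanishes when settled", {
  g12 <- directed_graph(rbind(c(0, 1), c(0, 0)))
  g21 <- directed_graph(rbind(c(0, 0), c(1, 0)))
  post <- structure(list(graphs = list(g12, g21), weights = c(0.5, 0.5)),
                    class = "spg_posterior")
  # intervening on node 1 distinguishes the two members: one uniform bit
  expect_equal(utility_information_gain(post, 1), log(2))
  # concentrated posterior: zero entropy, zero utility
  point <- structure(list(graphs = list(chain3()), weights = 1),
                     class = "spg_posterior")
  expect_equal(utility_information_gain(point, 2), 0)
  # node-relabeling invariance
  perm <- c(2, 1)
  g12p <- directed_graph(g12$adjacency[perm, perm])
  g21p <- directed_graph(g21$adjacency[perm, perm])
  postp <- structure(list(graphs = list(g12p, g21p), weights = c(0.5, 0.5)),
                     class = "spg_posterior")
  expect_equal(utility_information_gain(postp, 2), utility_information_gain(post, 1))
})

test_that("both utilities vanish on posteriors fully oriented by existing targets", {
  set.seed(8)
  graphs <- lapply(1:4, function(s) orient_random(
    random_topology("erdos_renyi", 5, list(p = 0.5), seed = s), seed = s + 20))
  post <- structure(list(graphs = graphs, weights = rep(0.25, 4)),
                    class = "spg_posterior")
  all_single <- as.list(1:5)
  for (v in 1:5) {
    expect_equal(utility_edge_orientation(post, all_single, v), 0)
    expect_equal(utility_information_gain(post, v, all_single), 0)
  }
})

test_that("intervention selection follows the utilities with deterministic ties", {
  bm <- make_benchmark("erdos_renyi", 5, list(p = 0.4), n_obs = 40, seed = 9)
  st <- oed_state(bm$samples, candidate_targets = 3L)
  post <- structure(list(graphs = list(bm$graph), weights = 1),
                    class = "spg_posterior")
  expect_equal(select_intervention(st, post, "edge_orient"), 3L)
  expect_equal(select_intervention(st, post, "random", seed = 1), 3L)

  # selected index equals the argmax of the utility vector
  st_all <- oed_state(bm$samples)
  existing <- spgies:::distinct_targets(bm$samples)
  u <- vapply(1:5, function(v) utility_edge_orientation(post, existing, v), numeric(1))
  expect_equal(select_intervention(st_all, post, "edge_orient"),
               which.max(u))

  # random strategy: reproducible and approximately uniform
  draws <- vapply(1:1000, function(s) select_intervention(st_all, post, "random",
                                                          seed = s), integer(1))
  expect_identical(draws, vapply(1:1000, function(s)
    select_intervention(st_all, post, "random", seed = s), integer(1)))
  tab <- tabulate(draws, 5)
  expect_gt(stats::chisq.test(tab)$p.value, 1e-4)
})

test_that("the acquisition loop records history and respects its fixed points", {
  bm <- make_benchmark("small_world", 8, list(k = 2, p = 0.5), n_obs = 60, seed = 10)
  # zero rounds: history holds only the initial fit
  st0 <- run_oed_loop(bm$sem, function(s) fit_gies(s), rounds = 0, B = 2, seed = 11,
                      init_samples = bm$samples)
  expect_equal(nrow(st0$history), 1)
  expect_equal(nrow(st0$samples$data), nrow(bm$samples$data))

  # oracle learner: metrics flat at the optimum across rounds
  oracle <- function(s) {
    new_fit <- spgies:::new_learner_result(
      graph = i_essential_graph(bm$graph, s$targets),
      member_dag = bm$graph, score = 0, method = "oracle", params = list())
    new_fit
  }
  sto <- run_oed_loop(bm$sem, oracle, strategy = "edge_orient", rounds = 3, B = 2,
                      seed = 12, init_samples = bm$samples)
  expect_true(all(sto$history$shd == 0))
  expect_true(all(sto$history$aucpr == 1))
  expect_equal(nrow(sto$history), 4)
  expect_equal(nrow(sto$samples$data), nrow(bm$samples$data) + 3)

  # reproducibility under the master seed
  a <- run_oed_loop(bm$sem, function(s) fit_gies(s), strategy = "random", rounds = 2,
                    B = 2, seed = 13, init_samples = bm$samples)
  b <- run_oed_loop(bm$sem, function(s) fit_gies(s), strategy = "random", rounds = 2,
                    B = 2, seed = 13, init_samples = bm$samples)
  expect_identical(a$history, b$history)
})
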