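# Optimal experimental design: bootstrap posterior over graphs,
# intervention utilities (expected newly oriented edges; information gain
# over edge states), target selection, and the round-by-round acquisition
# loop that grows the dataset one knockout sample at a time.

#' Bootstrap posterior over causal graphs
#'
#' Approximates the graph posterior by refitting a learner on bootstrap
#' resamples of the data.  Rows are resampled with replacement within
#' intervention strata (all rows sharing a target set form a stratum), so
#' every replicate keeps the design of the original experiment.  Weights
#' are uniform; replicates whose fit fails are dropped with a warning and
#' the weights renormalized.
#'
#' @param samples an `spg_samples`.
#' @param learner function mapping an `spg_samples` to an
#'   `spg_learner_result` (e.g. `fit_gies` or a [sp_gies()] closure).
#' @param B number of bootstrap replicates.
#' @param seed integer seed.
#' @param resample set `FALSE` to refit on the original data (degenerate
#'   single-point posterior, useful with `B = 1`).
#' @return object of class `spg_posterior`: `graphs` (member DAGs) and
#'   `weights` summing to 1.
#' @export
bootstrap_posterior <- function(samples, learner, B = 20L, seed = NULL,
                                resample = TRUE) {
  stopifnot(inherits(samples, "spg_samples"), B >= 1L)
  keys <- vapply(samples$targets, function(t) paste(t, collapse = ","), character(1))
  strata <- split(seq_along(keys), keys)
  graphs <- with_seed(seed, {
    out <- list()
    for (b in seq_len(B)) {
      rows <- if (resample) {
        sort(unlist(lapply(strata, function(ix) ix[sample.int(length(ix),
                                                              length(ix),
                                                              replace = TRUE)])))
      } else {
        seq_along(keys)
      }
      boot <- sample_set(samples$data[rows, , drop = FALSE],
                         targets = samples$targets[rows],
                         labels = samples$node_labels)
      fit <- tryCatch(learner(boot), error = function(e) {
        warning("bootstrap replicate dropped: ", conditionMessage(e))
        NULL
      })
      if (!is.null(fit)) out[[length(out) + 1L]] <- fit$member_dag
    }
    out
  })
  if (length(graphs) == 0L) stop("all bootstrap replicates failed")
  structure(list(graphs = graphs,
                 weights = rep(1 / length(graphs), length(graphs))),
            class = "spg_posterior")
}

#' Expected number of newly oriented edges from an intervention
#'
#' For each posterior DAG, counts how many additional edges its
#' interventional essential graph orients once `candidate` is added to the
#' existing target family, and averages under the posterior weights.
#'
#' @param posterior an `spg_posterior`.
#' @param existing_targets list of existing intervention target sets (the
#'   empty observational set is implied).
#' @param candidate node index of the candidate intervention.
#' @return nonnegative expected count.
#' @export
utility_edge_orientation <- function(posterior, existing_targets = list(),
                                     candidate) {
  stopifnot(inherits(posterior, "spg_posterior"))
  fam0 <- distinct_targets(existing_targets)
  fam1 <- c(fam0, list(as.integer(candidate)))
  val <- 0
  for (b in seq_along(posterior$graphs)) {
    g <- posterior$graphs[[b]]
    before <- count_oriented(i_essential_graph(g, fam0))
    after <- count_oriented(i_essential_graph(g, fam1))
    val <- val + posterior$weights[b] * (after - before)
  }
  val
}

# Per-pair edge-state codes of a DAG adjacency: 0 absent, 1 i->j, 2 j->i
# for the unordered pairs i < j.
edge_state_codes <- function(a) {
  up <- upper.tri(a)
  a[up] + 2L * t(a)[up]
}

# entropy (nats) of a weighted discrete distribution
weighted_entropy <- function(states, w) {
  tot <- tapply(w, states, sum)
  tot <- tot / sum(tot)
  -sum(tot * log(tot))
}

#' Expected information gain of an intervention over edge states
#'
#' Uncertainty surrogate: the entropy `H` of a target family is the
#' posterior-weighted sum, over node pairs, of the Shannon entropy of the
#' bootstrap edge-state frequencies (absent / `i->j` / `j->i`) *within*
#' groups of graphs that the family cannot distinguish — graphs sharing the
#' same interventional essential graph.  Adding a target refines this
#' grouping, so the utility `H(current) - H(current + candidate)` is
#' nonnegative; it vanishes when the posterior is concentrated or already
#' fully oriented.  Entropies are in nats.
#'
#' @param posterior an `spg_posterior` (at least 2 graphs for a
#'   nondegenerate entropy).
#' @param candidate node index of the candidate intervention.
#' @param existing_targets list of existing target sets.
#' @return nonnegative expected entropy decrease.
#' @export
utility_information_gain <- function(posterior, candidate,
                                     existing_targets = list()) {
  stopifnot(inherits(posterior, "spg_posterior"))
  fam0 <- distinct_targets(existing_targets)
  fam1 <- c(fam0, list(as.integer(candidate)))
  family_entropy(posterior, fam0) - family_entropy(posterior, fam1)
}

# H(family): conditional entropy of DAG edge states given the I-essential
# graph the family would identify.
family_entropy <- function(posterior, fam) {
  B <- length(posterior$graphs)
  states <- lapply(posterior$graphs, function(g) edge_state_codes(g$adjacency))
  group <- vapply(posterior$graphs, function(g) {
    e <- i_essential_graph(g, fam)
    paste(c(e$directed, e$undirected), collapse = "")
  }, character(1))
  H <- 0
  for (grp in unique(group)) {
    ix <- which(group == grp)
    w <- posterior$weights[ix]
    wg <- sum(w)
    st <- do.call(rbind, states[ix])  # replicate x pair
    for (pair in seq_len(ncol(st))) {
      H <- H + wg * weighted_entropy(st[, pair], w / wg)
    }
  }
  H
}

#' Select the next intervention target
#'
#' Maximizes the chosen utility over the candidate targets; ties break to
#' the lowest node index.  The `random` strategy draws uniformly.
#'
#' @param state an `spg_oed_state` (see [oed_state()]).
#' @param posterior an `spg_posterior`.
#' @param strategy `"random"`, `"info_gain"` or `"edge_orient"`.
#' @param seed integer seed (used by the random strategy).
#' @return selected node index.
#' @export
select_intervention <- function(state, posterior,
                                strategy = c("random", "info_gain", "edge_orient"),
                                seed = NULL) {
  strategy <- match.arg(strategy)
  cand <- state$candidate_targets
  if (length(cand) == 0L) stop("no candidate targets")
  if (strategy == "random") {
    return(with_seed(seed, cand[sample.int(length(cand), 1L)]))
  }
  existing <- distinct_targets(state$samples)
  util <- vapply(cand, function(v) {
    if (strategy == "edge_orient") {
      utility_edge_orientation(posterior, existing, v)
    } else {
      utility_information_gain(posterior, v, existing)
    }
  }, numeric(1))
  cand[which.max(util)]  # which.max takes the first (lowest-index) maximum
}

#' Construct an experimental-design state
#'
#' @param samples current `spg_samples`.
#' @param candidate_targets node indices available for intervention
#'   (defaults to all nodes; repeat selections are allowed).
#' @return object of class `spg_oed_state` with an empty history.
#' @export
oed_state <- function(samples, candidate_targets = NULL) {
  stopifnot(inherits(samples, "spg_samples"))
  if (is.null(candidate_targets)) {
    candidate_targets <- seq_len(ncol(samples$data))
  }
  structure(list(samples = samples,
                 candidate_targets = as.integer(candidate_targets),
                 history = data.frame(round = integer(0), target = integer(0),
                                      shd = integer(0), aucpr = numeric(0))),
            class = "spg_oed_state")
}

#' Run the experimental-design acquisition loop
#'
#' Per round: sample the bootstrap posterior, pick the next knockout target
#' by the chosen strategy, draw one new interventional sample from the true
#' SEM at that target, append it, refit the point estimate on the grown
#' dataset and record SHD and AUC-PR against the truth.  Round 0 records
#' the fit on the initial data.
#'
#' @param sem the ground-truth `spg_sem` (plays the role of the lab).
#' @param learner function `spg_samples -> spg_learner_result`.
#' @param strategy acquisition strategy, see [select_intervention()].
#' @param rounds number of acquisition rounds.
#' @param B bootstrap replicates per round.
#' @param seed master integer seed; per-round substreams are derived.
#' @param init_samples starting dataset; defaults to the benchmark design
#'   of `n_obs` observational rows plus one knockout row per node.
#' @param n_obs observational rows for the default starting dataset.
#' @param knockout_value clamp value of acquired knockouts.
#' @return an `spg_oed_state` whose `history` has one row per round
#'   (including round 0) with columns `round`, `target`, `shd`, `aucpr`.
#' @export
run_oed_loop <- function(sem, learner, strategy = "edge_orient", rounds = 10L,
                         B = 20L, seed = NULL, init_samples = NULL,
                         n_obs = 100L, knockout_value = 0) {
  stopifnot(inherits(sem, "spg_sem"), rounds >= 0L)
  if (is.null(seed)) seed <- sample.int(2^31 - 1, 1)
  p <- sem$graph$n_nodes
  if (is.null(init_samples)) {
    init_samples <- sample_observational(sem, n_obs,
                                         seed = substream_seed(seed, "oed_obs"))
    for (v in seq_len(p)) {
      init_samples <- rbind_samples(
        init_samples,
        sample_intervention(sem, v, value = knockout_value, n = 1,
                            seed = substream_seed(seed, "oed_init_int", v)))
    }
  }
  state <- oed_state(init_samples)
  fit <- learner(state$samples)
  state$history <- data.frame(round = 0L, target = NA_integer_,
                              shd = shd(sem$graph, fit),
                              aucpr = aucpr(sem$graph, fit))
  for (r in seq_len(rounds)) {
    post <- bootstrap_posterior(state$samples, learner, B = B,
                                seed = substream_seed(seed, "oed_boot", r))
    tgt <- select_intervention(state, post, strategy = strategy,
                               seed = substream_seed(seed, "oed_pick", r))
    newrow <- sample_intervention(sem, tgt, value = knockout_value, n = 1,
                                  seed = substream_seed(seed, "oed_draw", r))
    state$samples <- rbind_samples(state$samples, newrow)
    fit <- learner(state$samples)
    state$history <- rbind(state$history,
                           data.frame(round = r, target = tgt,
                                      shd = shd(sem$graph, fit),
                                      aucpr = aucpr(sem$graph, fit)))
  }
  state
}
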