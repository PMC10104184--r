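# Shared builders and brute-force oracles for the test suite.  Everything
# is generated in code; no stored fixtures.

chain3 <- function() {
  directed_graph(rbind(c(0, 1, 0), c(0, 0, 1), c(0, 0, 0)),
                 labels = c("G1", "G2", "G3"))
}

collider3 <- function() {
  directed_graph(rbind(c(0, 0, 1), c(0, 0, 1), c(0, 0, 0)),
                 labels = c("G1", "G2", "G3"))
}

# stack sample sets (internal helper re-exposed for tests)
bind_samples <- function(...) {
  out <- NULL
  for (s in list(...)) out <- if (is.null(out)) s else spgies:::rbind_samples(out, s)
  out
}

# benchmark-style dataset from a SEM: n_obs observational + one knockout
# per node
sem_benchmark_samples <- function(sem, n_obs, seed) {
  d <- sample_observational(sem, n_obs, seed = seed)
  for (v in seq_len(sem$graph$n_nodes)) {
    d <- spgies:::rbind_samples(
      d, sample_intervention(sem, v, n = 1, seed = seed + 7919 * v))
  }
  d
}

# every DAG on n nodes (used for exhaustive oracle sweeps, n <= 4)
all_dags <- function(n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  m <- nrow(pairs)
  out <- list()
  for (code in seq_len(3^m) - 1L) {
    a <- matrix(0L, n, n)
    c0 <- code
    for (e in seq_len(m)) {
      st <- c0 %% 3L; c0 <- c0 %/% 3L
      i <- pairs[e, 1L]; j <- pairs[e, 2L]
      if (st == 1L) a[i, j] <- 1L else if (st == 2L) a[j, i] <- 1L
    }
    if (is_acyclic(a)) out[[length(out) + 1L]] <- a
  }
  out
}

# total interventional BIC of a DAG adjacency on a sample set
score_dag <- function(samples, a) {
  cache <- spgies:::score_cache(spgies:::as_sample_set(samples))
  sum(vapply(seq_len(ncol(a)),
             function(v) spgies:::local_score_cached(cache, v, which(a[, v] == 1L)),
             numeric(1)))
}

# Numeric linear-SEM oracle for the structural intervention distance:
# draws generic weights on the true DAG, computes each pair's true total
# causal effect and the effect inferred by parent adjustment in the
# estimated graph from the observational covariance, and counts mismatches.
# A pair is a mistake if it mismatches under any weight draw.
sid_oracle <- function(truth_adj, est_adj, n_draws = 3, tol = 1e-7) {
  n <- nrow(truth_adj)
  mistakes <- matrix(FALSE, n, n)
  for (d in seq_len(n_draws)) {
    w <- matrix(0, n, n)
    nz <- which(truth_adj == 1L)
    w[nz] <- stats::runif(length(nz), 0.5, 1.5) * sample(c(-1, 1), length(nz), TRUE)
    M <- solve(diag(n) - w)          # M[i, j] = total effect of i on j
    Sig <- t(M) %*% M                 # unit noise variances
    for (i in seq_len(n)) {
      Z <- which(est_adj[, i] == 1L)
      for (j in seq_len(n)) {
        if (i == j) next
        true_eff <- M[i, j]
        est_eff <- if (j %in% Z) {
          0  # claimed null effect
        } else {
          S <- c(i, Z)
          beta <- solve(Sig[S, S, drop = FALSE], Sig[S, j])
          beta[1L]
        }
        if (abs(est_eff - true_eff) > tol) mistakes[i, j] <- TRUE
      }
    }
  }
  sum(mistakes)
}
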