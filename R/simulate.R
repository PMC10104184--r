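# Linear-Gaussian simulation benchmark: random topologies, random DAG
# orientation, structural equation models, observational sampling and hard
# knockout interventions.

# Run code under a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Derive a deterministic 31-bit substream seed from a master seed, a stage
# name and an index, so that independent pipeline stages never share a
# stream.
substream_seed <- function(seed, stage, index = 0L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  val <- (as.double(seed) * 48271 + h * 1299721 + as.double(index) * 69621)
  as.integer(val %% 2147483629)
}

#' Random undirected network topology
#'
#' Generates the benchmark's three topology families: Erdős–Rényi
#' G(n, p), Barabási–Albert scale-free graphs (each arriving node attaches
#' to `k` existing nodes preferentially by degree, so the edge count is
#' exactly `k * (n - k)`), and Watts–Strogatz small-world graphs (ring
#' lattice of degree `k` with rewiring probability `p`; rewiring preserves
#' the edge count `n * k / 2`).
#'
#' @param kind one of `"erdos_renyi"`, `"scale_free"`, `"small_world"`.
#' @param n_nodes number of nodes.
#' @param params named list: `p` (edge probability) for Erdős–Rényi;
#'   `k` (attachment count) for scale-free; `k` (even lattice degree) and
#'   `p` (rewiring probability) for small-world.  Benchmark defaults are
#'   `p = 0.5` and `k = 2`.
#' @param seed integer seed.
#' @return an `spg_pdgraph` with only undirected edges and labels `G1..Gn`.
#' @export
random_topology <- function(kind = c("erdos_renyi", "scale_free", "small_world"),
                            n_nodes, params = list(), seed = NULL) {
  kind <- match.arg(kind)
  n <- as.integer(n_nodes)
  if (n < 1L) stop("n_nodes must be positive")
  labels <- paste0("G", seq_len(n))
  sk <- with_seed(seed, {
    switch(kind,
      erdos_renyi = {
        p <- params$p
        if (is.null(p)) p <- 0.5
        if (p < 0 || p > 1) stop("edge probability p must lie in [0, 1]")
        ig <- igraph::sample_gnp(n, p)
        as.matrix(igraph::as_adjacency_matrix(ig))
      },
      scale_free = {
        k <- params$k
        if (is.null(k)) k <- 2L
        k <- as.integer(k)
        if (k < 1L || k >= n) stop("attachment count k must satisfy 1 <= k < n_nodes")
        barabasi_albert_edges(n, k)
      },
      small_world = {
        k <- params$k
        if (is.null(k)) k <- 2L
        k <- as.integer(k)
        p <- params$p
        if (is.null(p)) p <- 0.5
        if (p < 0 || p > 1) stop("rewiring probability p must lie in [0, 1]")
        if (k < 2L || k %% 2L != 0L || k >= n) {
          stop("lattice degree k must be even with 2 <= k < n_nodes")
        }
        ig <- igraph::sample_smallworld(1, n, k %/% 2L, p)
        ig <- igraph::simplify(ig)
        as.matrix(igraph::as_adjacency_matrix(ig))
      }
    )
  })
  sk <- (sk + t(sk)) > 0
  diag(sk) <- FALSE
  storage.mode(sk) <- "integer"
  partially_directed_graph(undirected = sk, labels = labels)
}

# Barabási–Albert preferential attachment with k initially unconnected
# nodes and k distinct preferential targets per arriving node (the
# convention under which |E| = k * (n - k) exactly).
barabasi_albert_edges <- function(n, k) {
  a <- matrix(0L, n, n)
  targets <- seq_len(k)
  repeated <- integer(0)
  for (src in (k + 1L):n) {
    a[src, targets] <- 1L
    a[targets, src] <- 1L
    repeated <- c(repeated, targets, rep.int(src, k))
    # distinct preferential targets for the next arrival
    nxt <- integer(0)
    while (length(nxt) < k) {
      pick <- repeated[sample.int(length(repeated), 1L)]
      if (!(pick %in% nxt)) nxt <- c(nxt, pick)
    }
    targets <- nxt
  }
  a
}

#' Orient an undirected graph into a random DAG
#'
#' Draws a uniformly random node permutation and orients every edge from the
#' earlier to the later node, which guarantees acyclicity.
#'
#' @param u an `spg_pdgraph` with only undirected edges.
#' @param seed integer seed.
#' @return an `spg_dgraph` DAG with the same skeleton.
#' @export
orient_random <- function(u, seed = NULL) {
  stopifnot(inherits(u, "spg_pdgraph"))
  if (any(u$directed != 0L)) stop("input must be fully undirected")
  n <- u$n_nodes
  perm <- with_seed(seed, sample.int(n))
  rank <- order(perm)  # rank[i] = position of node i in the permutation
  a <- matrix(0L, n, n)
  idx <- which(u$undirected == 1L & upper.tri(u$undirected), arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1L]; j <- idx[r, 2L]
    if (rank[i] < rank[j]) a[i, j] <- 1L else a[j, i] <- 1L
  }
  directed_graph(a, labels = u$node_labels, check_dag = TRUE)
}

#' Linear-Gaussian structural equation model
#'
#' @param graph an `spg_dgraph` DAG.
#' @param weights numeric matrix; `weights[i, j]` is the coefficient of node
#'   `i` in node `j`'s structural equation, nonzero only where the adjacency
#'   has an edge.
#' @param noise_vars positive noise variances, one per node.
#' @return an object of class `spg_sem`.
#' @export
gaussian_sem <- function(graph, weights, noise_vars) {
  stopifnot(inherits(graph, "spg_dgraph"))
  if (!is_acyclic(graph)) stop("SEM graph must be a DAG")
  weights <- as.matrix(weights)
  if (any(dim(weights) != graph$n_nodes)) stop("weights dimension mismatch")
  if (any(weights[graph$adjacency == 0L] != 0)) {
    stop("weights must be zero off the adjacency support")
  }
  noise_vars <- as.numeric(noise_vars)
  if (length(noise_vars) != graph$n_nodes || any(noise_vars <= 0)) {
    stop("noise_vars must be positive, one per node")
  }
  structure(list(graph = graph, weights = weights, noise_vars = noise_vars),
            class = "spg_sem")
}

#' Draw a random SEM on a given DAG
#'
#' Edge weights have magnitude uniform in `[0.25, 1]` with random sign
#' (bounded away from zero to avoid near-unfaithful effects) and unit noise
#' variance on every node.
#'
#' @param g an `spg_dgraph` DAG.
#' @param seed integer seed.
#' @param w_range magnitude range of the nonzero weights.
#' @return an `spg_sem`.
#' @export
random_sem <- function(g, seed = NULL, w_range = c(0.25, 1)) {
  stopifnot(inherits(g, "spg_dgraph"))
  if (!is_acyclic(g)) stop("random_sem requires a DAG")
  n <- g$n_nodes
  w <- with_seed(seed, {
    nz <- which(g$adjacency == 1L)
    mag <- stats::runif(length(nz), w_range[1], w_range[2])
    sgn <- sample(c(-1, 1), length(nz), replace = TRUE)
    w <- matrix(0, n, n)
    w[nz] <- mag * sgn
    w
  })
  gaussian_sem(g, w, rep(1, n))
}

#' Sample set: expression matrix plus intervention annotation
#'
#' @param data numeric samples-by-nodes matrix.
#' @param targets list of per-row intervention target sets (empty integer
#'   vector = observational row); defaults to all-observational.
#' @param labels node labels (defaults to `data`'s column names).
#' @return an object of class `spg_samples` with fields `data`, `targets`,
#'   `node_labels`.
#' @export
sample_set <- function(data, targets = NULL, labels = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || any(!is.finite(data))) stop("data must be finite numeric")
  if (is.null(labels)) labels <- colnames(data)
  if (is.null(labels)) labels <- paste0("G", seq_len(ncol(data)))
  colnames(data) <- labels
  if (is.null(targets)) targets <- rep(list(integer(0)), nrow(data))
  if (length(targets) != nrow(data)) {
    stop("targets must have one entry per data row")
  }
  targets <- unclass(intervention_family(targets, ncol(data)))
  structure(list(data = data, targets = targets, node_labels = as.character(labels)),
            class = "spg_samples")
}

#' @export
print.spg_samples <- function(x, ...) {
  n_int <- sum(vapply(x$targets, length, integer(1)) > 0)
  cat(sprintf("Sample set: %d rows (%d interventional) x %d nodes\n",
              nrow(x$data), n_int, ncol(x$data)))
  invisible(x)
}

# coerce plain matrices to all-observational sample sets
as_sample_set <- function(x) {
  if (inherits(x, "spg_samples")) x else sample_set(x)
}

# indices of observational rows
observational_rows <- function(s) {
  which(vapply(s$targets, length, integer(1)) == 0L)
}

#' Closed-form covariance of a linear-Gaussian SEM
#'
#' For `X = W' X + e` the covariance is `M' diag(noise) M` with
#' `M = (I - W)^{-1}`; used in tests and as the basis of the symbolic
#' intervention-distance oracle.
#'
#' @param sem an `spg_sem`.
#' @return the `n x n` covariance matrix.
#' @export
sem_covariance <- function(sem) {
  n <- sem$graph$n_nodes
  M <- solve(diag(n) - sem$weights)
  t(M) %*% diag(sem$noise_vars, n) %*% M
}

#' Sample observational data from a linear-Gaussian SEM
#'
#' Nodes are generated in topological order: each node is the weighted sum
#' of its parents plus independent Gaussian noise.
#'
#' @param sem an `spg_sem`.
#' @param n number of samples.
#' @param seed integer seed.
#' @return an `spg_samples` with all-observational rows.
#' @export
sample_observational <- function(sem, n, seed = NULL) {
  stopifnot(inherits(sem, "spg_sem"), n >= 1)
  x <- with_seed(seed, sem_draw(sem, n, target = NULL, value = 0))
  sample_set(x, labels = sem$graph$node_labels)
}

# draw n rows; when target is non-NULL that column is clamped to value and
# its structural equation is skipped (hard intervention).
sem_draw <- function(sem, n, target = NULL, value = 0) {
  p <- sem$graph$n_nodes
  a <- sem$graph$adjacency
  x <- matrix(stats::rnorm(n * p, sd = rep(sqrt(sem$noise_vars), each = n)), n, p)
  for (j in topological_order(a)) {
    if (!is.null(target) && j == target) {
      x[, j] <- value
      next
    }
    pa <- which(a[, j] == 1L)
    if (length(pa) > 0L) {
      x[, j] <- x[, j] + x[, pa, drop = FALSE] %*% sem$weights[pa, j]
    }
  }
  colnames(x) <- sem$graph$node_labels
  x
}

#' Sample under a hard intervention (knockout)
#'
#' Clamps the target node to a constant and samples every other node from
#' its structural equation: descendants respond, non-descendants keep their
#' observational law.
#'
#' @param sem an `spg_sem`.
#' @param target node index to clamp.
#' @param value clamp value (0 emulates a gene knockout).
#' @param n number of samples.
#' @param seed integer seed.
#' @return an `spg_samples` whose rows all carry target set `{target}`.
#' @export
sample_intervention <- function(sem, target, value = 0, n = 1, seed = NULL) {
  stopifnot(inherits(sem, "spg_sem"))
  target <- as.integer(target)
  if (length(target) != 1L || target < 1L || target > sem$graph$n_nodes) {
    stop("invalid intervention target index")
  }
  x <- with_seed(seed, sem_draw(sem, n, target = target, value = value))
  sample_set(x, targets = rep(list(target), n), labels = sem$graph$node_labels)
}

# stack two sample sets over the same nodes
rbind_samples <- function(s1, s2) {
  stopifnot(identical(s1$node_labels, s2$node_labels))
  sample_set(rbind(s1$data, s2$data), targets = c(s1$targets, s2$targets),
             labels = s1$node_labels)
}

#' Generate a full benchmark instance
#'
#' The benchmark protocol: draw a random topology, orient it into a DAG,
#' equip it with a random linear-Gaussian SEM, then sample `n_obs`
#' observational rows followed by one knockout (clamp to 0) row per node.
#'
#' @param kind,n_nodes,params topology arguments, see [random_topology()].
#' @param n_obs number of observational samples (benchmark default 100).
#' @param seed master integer seed; stage substreams are derived from it.
#' @param knockout_value clamp value for the interventional rows.
#' @return list with elements `graph` (true DAG), `sem`, and `samples`
#'   (`n_obs + n_nodes` rows).
#' @export
make_benchmark <- function(kind, n_nodes, params = list(), n_obs = 100,
                           seed = NULL, knockout_value = 0) {
  if (is.null(seed)) seed <- sample.int(2^31 - 1, 1)
  topo <- random_topology(kind, n_nodes, params, seed = substream_seed(seed, "topology"))
  dag <- orient_random(topo, seed = substream_seed(seed, "orient"))
  sem <- random_sem(dag, seed = substream_seed(seed, "sem"))
  s <- sample_observational(sem, n_obs, seed = substream_seed(seed, "obs"))
  for (v in seq_len(n_nodes)) {
    s <- rbind_samples(
      s, sample_intervention(sem, v, value = knockout_value, n = 1,
                             seed = substream_seed(seed, "intervention", v)))
  }
  list(graph = dag, sem = sem, samples = s)
}
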