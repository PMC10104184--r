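# Greedy interventional equivalence search (GIES) with an interventional
# Gaussian BIC score, and the two-step SP-GIES variant in which an
# observational skeleton estimate restricts the candidate edge set.
#
# The search walks DAG space with single-edge insertions, deletions and
# turnings, each accepted only on a strict score increase, and reports the
# interventional essential graph of the local optimum.  The score is
# decomposable: node v's local score is a Gaussian BIC computed over the
# rows that do not intervene on v (a knockout severs v's structural
# equation, so clamped rows carry no information about v's parents).

# Sufficient statistics for the interventional BIC: per node, the usable
# rows (target set excludes the node), their count and their cross-product
# matrix, plus a memo of local scores and insertion-gain vectors.
score_cache <- function(samples) {
  samples <- as_sample_set(samples)
  x <- samples$data
  p <- ncol(x)
  usable <- lapply(seq_len(p), function(v) {
    which(!vapply(samples$targets, function(t) v %in% t, logical(1)))
  })
  grams <- lapply(usable, function(rows) crossprod(x[rows, , drop = FALSE]))
  list(p = p, m = lengths(usable), grams = grams, usable = usable,
       labels = samples$node_labels, memo = new.env(parent = emptyenv()))
}

# BIC local score from a gram matrix: -(m/2) (1 + log(2 pi s2))
# - (log m / 2) (k + 1), with s2 the ML residual variance of v on pa.
bic_from_rss <- function(rss, m, k) {
  s2 <- rss / m
  if (!is.finite(s2) || s2 < 1e-12) return(-Inf)
  -(m / 2) * (1 + log(2 * pi * s2)) - (log(m) / 2) * (k + 1)
}

local_score_cached <- function(cache, v, pa) {
  pa <- sort(pa)
  key <- paste0("s", v, "|", paste(pa, collapse = ","))
  hit <- cache$memo[[key]]
  if (!is.null(hit)) return(hit)
  m <- cache$m[v]
  val <- if (m < length(pa) + 2) {
    -Inf
  } else {
    S <- cache$grams[[v]]
    rss <- if (length(pa) == 0L) {
      S[v, v]
    } else {
      beta <- tryCatch(solve(S[pa, pa, drop = FALSE], S[pa, v]),
                       error = function(e) NULL)
      if (is.null(beta)) NA else S[v, v] - sum(S[v, pa] * beta)
    }
    if (is.na(rss)) -Inf else bic_from_rss(rss, m, length(pa))
  }
  cache$memo[[key]] <- val
  val
}

# Gains of inserting u -> v for every candidate u at once, given v's
# current parent set (vector indexed by node; NA for v itself and parents).
# Uses the block-inverse update of the regression RSS so one solve serves
# all candidates.
insertion_gains <- function(cache, v, pa) {
  pa <- sort(pa)
  key <- paste0("g", v, "|", paste(pa, collapse = ","))
  hit <- cache$memo[[key]]
  if (!is.null(hit)) return(hit)
  p <- cache$p
  m <- cache$m[v]
  gains <- rep(NA_real_, p)
  base <- local_score_cached(cache, v, pa)
  cand <- setdiff(seq_len(p), c(v, pa))
  if (length(cand) > 0L) {
    if (m < length(pa) + 3 || !is.finite(base)) {
      gains[cand] <- -Inf
    } else {
      S <- cache$grams[[v]]
      if (length(pa) == 0L) {
        rssP <- S[v, v]
        cu <- S[cand, v]
        du <- diag(S)[cand]
      } else {
        A <- tryCatch(solve(S[pa, pa, drop = FALSE]), error = function(e) NULL)
        if (is.null(A)) {
          gains[cand] <- -Inf
          cache$memo[[key]] <- gains
          return(gains)
        }
        av <- A %*% S[pa, v]
        rssP <- S[v, v] - sum(S[v, pa] * av)
        B <- S[cand, pa, drop = FALSE]
        cu <- S[cand, v] - as.numeric(B %*% av)
        du <- diag(S)[cand] - rowSums((B %*% A) * B)
      }
      ok <- du > 1e-10
      rss_u <- rssP - ifelse(ok, cu^2 / du, NA)
      sc <- rep(-Inf, length(cand))
      fin <- ok & is.finite(rss_u)
      sc[fin] <- vapply(rss_u[fin], bic_from_rss, numeric(1),
                        m = m, k = length(pa) + 1L)
      gains[cand] <- sc - base
    }
  }
  cache$memo[[key]] <- gains
  gains
}

# lexicographic comparison of moves on (gain desc, source, target)
better_move <- function(cand, best, tol = 1e-9) {
  if (is.null(cand) || !is.finite(cand$gain) || cand$gain <= tol) return(FALSE)
  if (is.null(best)) return(TRUE)
  if (cand$gain > best$gain + 1e-12) return(TRUE)
  if (cand$gain < best$gain - 1e-12) return(FALSE)
  if (cand$u != best$u) return(cand$u < best$u)
  cand$v < best$v
}

#' Fit a network by greedy interventional equivalence search
#'
#' Score-based structure learning from mixed observational/interventional
#' data.  Starting from the empty graph, the forward phase repeatedly adds
#' the single edge with the largest score gain, the backward phase removes
#' edges, and the turning phase reverses them; each phase runs to a local
#' optimum and the outer loop cycles through the phases until no move
#' improves the interventional BIC.  Every accepted move strictly increases
#' the score, which guarantees termination.
#'
#' @param samples an `spg_samples` (rows annotated with their intervention
#'   targets) or a plain matrix (treated as observational).
#' @param allowed optional `spg_pdgraph` (or logical/binary matrix): only
#'   node pairs joined in `allowed` may be connected.  This is the hook by
#'   which SP-GIES restricts the search space.
#' @param phases character subset of `c("forward", "backward", "turning")`.
#' @param tol minimal score improvement for a move to be accepted.
#' @return an `spg_learner_result`: `graph` (the I-essential graph of the
#'   optimum), `member_dag`, `score`, `method`, `params`, and a `trace`
#'   data frame of accepted moves with their gains.
#' @export
fit_gies <- function(samples, allowed = NULL,
                     phases = c("forward", "backward", "turning"),
                     tol = 1e-9) {
  samples <- as_sample_set(samples)
  cache <- score_cache(samples)
  p <- cache$p
  allow <- if (is.null(allowed)) {
    matrix(TRUE, p, p)
  } else if (inherits(allowed, "spg_pdgraph") || inherits(allowed, "spg_dgraph")) {
    any_adjacency(allowed) > 0
  } else {
    as.matrix(allowed) > 0
  }
  allow <- allow | t(allow)
  diag(allow) <- FALSE
  A <- matrix(0L, p, p)
  pa <- rep(list(integer(0)), p)
  locsc <- vapply(seq_len(p), function(v) local_score_cached(cache, v, integer(0)),
                  numeric(1))
  trace <- list()

  forward_best <- function() {
    best <- NULL
    for (v in seq_len(p)) {
      cand <- which(allow[, v] & A[, v] == 0L & A[v, ] == 0L)
      if (length(cand) == 0L) next
      desc <- descendants_of(A, v)
      cand <- setdiff(cand, desc)
      if (length(cand) == 0L) next
      g <- insertion_gains(cache, v, pa[[v]])[cand]
      i <- which.max(ifelse(is.finite(g), g, -Inf))
      if (length(i) == 0L) next
      mv <- list(u = cand[i], v = v, gain = g[i], type = "forward")
      if (better_move(mv, best, tol)) best <- mv
    }
    best
  }
  backward_best <- function() {
    best <- NULL
    edges <- which(A == 1L, arr.ind = TRUE)
    for (r in seq_len(nrow(edges))) {
      u <- edges[r, 1L]; v <- edges[r, 2L]
      gain <- local_score_cached(cache, v, setdiff(pa[[v]], u)) - locsc[v]
      mv <- list(u = u, v = v, gain = gain, type = "backward")
      if (better_move(mv, best, tol)) best <- mv
    }
    best
  }
  turning_best <- function() {
    best <- NULL
    edges <- which(A == 1L, arr.ind = TRUE)
    for (r in seq_len(nrow(edges))) {
      u <- edges[r, 1L]; v <- edges[r, 2L]
      A2 <- A; A2[u, v] <- 0L
      if (v %in% descendants_of(A2, u)) next  # reversal would create a cycle
      gain <- (local_score_cached(cache, v, setdiff(pa[[v]], u)) - locsc[v]) +
        (local_score_cached(cache, u, c(pa[[u]], v)) - locsc[u])
      mv <- list(u = u, v = v, gain = gain, type = "turning")
      if (better_move(mv, best, tol)) best <- mv
    }
    best
  }

  apply_move <- function(mv) {
    u <- mv$u; v <- mv$v
    if (mv$type == "forward") {
      A[u, v] <<- 1L
      pa[[v]] <<- sort(c(pa[[v]], u))
      locsc[v] <<- local_score_cached(cache, v, pa[[v]])
    } else if (mv$type == "backward") {
      A[u, v] <<- 0L
      pa[[v]] <<- setdiff(pa[[v]], u)
      locsc[v] <<- local_score_cached(cache, v, pa[[v]])
    } else {
      A[u, v] <<- 0L; A[v, u] <<- 1L
      pa[[v]] <<- setdiff(pa[[v]], u)
      pa[[u]] <<- sort(c(pa[[u]], v))
      locsc[v] <<- local_score_cached(cache, v, pa[[v]])
      locsc[u] <<- local_score_cached(cache, u, pa[[u]])
    }
    trace[[length(trace) + 1L]] <<- data.frame(
      phase = mv$type, source = u, target = v, gain = mv$gain)
  }

  finders <- list(forward = forward_best, backward = backward_best,
                  turning = turning_best)[phases]
  guard <- 0L
  repeat {
    moved_any <- FALSE
    for (fnd in finders) {
      repeat {
        mv <- fnd()
        if (is.null(mv)) break
        apply_move(mv)
        moved_any <- TRUE
        guard <- guard + 1L
        if (guard > 100000L) stop("move guard exceeded; search failed to terminate")
      }
    }
    if (!moved_any) break
  }

  dag <- directed_graph(A, labels = cache$labels, check_dag = TRUE)
  new_learner_result(
    graph = i_essential_graph(dag, samples$targets),
    member_dag = dag,
    score = sum(locsc),
    method = "gies",
    params = list(phases = phases, tol = tol,
                  restricted = !is.null(allowed)),
    trace = if (length(trace)) do.call(rbind, trace) else
      data.frame(phase = character(0), source = integer(0),
                 target = integer(0), gain = numeric(0))
  )
}

#' Interventional BIC local score of a node given a parent set
#'
#' Gaussian BIC of regressing `node` on `parents` (without intercept) over
#' the usable rows — the rows whose intervention targets exclude `node`:
#' `-(m/2) (1 + log(2 pi s2)) - (log(m)/2) (|parents| + 1)` with `s2` the
#' maximum-likelihood residual variance.  Rank-deficient designs and
#' zero-variance nodes score `-Inf`.
#'
#' @param node node index.
#' @param parents integer vector of parent indices.
#' @param samples `spg_samples` or numeric matrix.
#' @return the local score (possibly `-Inf`).
#' @export
local_score <- function(node, parents, samples) {
  cache <- score_cache(as_sample_set(samples))
  local_score_cached(cache, as.integer(node), as.integer(parents))
}

new_learner_result <- function(graph, member_dag, score, method, params,
                               seed = NULL, trace = NULL, scores = NULL) {
  structure(list(graph = graph, member_dag = member_dag, score = score,
                 method = method, params = params, seed = seed,
                 trace = trace, scores = scores),
            class = "spg_learner_result")
}

#' @export
print.spg_learner_result <- function(x, ...) {
  cat(sprintf("<%s> score %.3f; estimated graph: %d directed + %d undirected edges\n",
              x$method, x$score, sum(x$graph$directed),
              sum(x$graph$undirected) / 2L))
  invisible(x)
}

#' Skeleton-primed GIES (SP-GIES)
#'
#' Two-step hybrid learner: (1) estimate an undirected skeleton from the
#' observational rows only, with PC, CLR or ARACNE; (2) run [fit_gies()] on
#' all rows with the candidate edge set restricted to the skeleton's node
#' pairs.  Only the adjacencies of the skeleton estimate are used — PC's
#' edge orientations are not forced on the search.
#'
#' @param samples an `spg_samples` with mixed observational/interventional
#'   rows.
#' @param skeleton_method `"pc"`, `"clr"`, `"aracne"` or `"none"` (the last
#'   reduces to unrestricted GIES).
#' @param skeleton_params named list of per-method parameters:
#'   `alpha` (PC, default 0.01); `estimator` and `fraction` (CLR, defaults
#'   `"gaussian"` and 0.1); `estimator`, `p_value` (default 1e-8),
#'   `n_permutations`, `dpi_tolerance`, `mi_threshold`, `seed` (ARACNE).
#' @param ... passed to [fit_gies()].
#' @return an `spg_learner_result`; `$params$skeleton` records the first
#'   stage and `$skeleton` holds its estimated graph.
#' @export
sp_gies <- function(samples, skeleton_method = c("pc", "clr", "aracne", "none"),
                    skeleton_params = list(), ...) {
  skeleton_method <- match.arg(skeleton_method)
  samples <- as_sample_set(samples)
  obs <- sample_set(samples$data[observational_rows(samples), , drop = FALSE],
                    labels = samples$node_labels)
  sk <- NULL
  sp <- skeleton_params
  if (skeleton_method == "pc") {
    if (is.null(sp$alpha)) sp$alpha <- 0.01
    sk <- pc_estimate(obs, alpha = sp$alpha)
  } else if (skeleton_method == "clr") {
    if (is.null(sp$estimator)) sp$estimator <- "gaussian"
    if (is.null(sp$fraction)) sp$fraction <- 0.1
    mi <- mutual_information_matrix(obs, estimator = sp$estimator)
    sk <- threshold_top_fraction(clr_scores(mi), fraction = sp$fraction)
  } else if (skeleton_method == "aracne") {
    if (is.null(sp$estimator)) sp$estimator <- "gaussian"
    if (is.null(sp$p_value)) sp$p_value <- 1e-8
    if (is.null(sp$n_permutations)) sp$n_permutations <- 50L
    if (is.null(sp$dpi_tolerance)) sp$dpi_tolerance <- 0
    mi <- mutual_information_matrix(obs, estimator = sp$estimator)
    if (is.null(sp$mi_threshold)) {
      sp$mi_threshold <- mi_null_threshold(obs, p_value = sp$p_value,
                                           n_permutations = sp$n_permutations,
                                           seed = sp$seed,
                                           estimator = sp$estimator)
    }
    sk <- aracne_prune(mi, mi_threshold = sp$mi_threshold,
                       dpi_tolerance = sp$dpi_tolerance)
  }
  fit <- fit_gies(samples, allowed = sk, ...)
  fit$method <- "sp-gies"
  fit$params$skeleton <- c(list(method = skeleton_method), sp)
  fit$skeleton <- sk
  fit
}

#' Empty-graph baseline (NULL learner)
#'
#' The no-dependency reference network: useful because sparse true networks
#' sit close to the empty graph, so SHD and AUC-PR flatter it.
#'
#' @param n_nodes number of nodes.
#' @param labels optional node labels.
#' @return an `spg_learner_result` with an edgeless graph and `NA` score.
#' @export
null_result <- function(n_nodes, labels = NULL) {
  if (is.null(labels)) labels <- paste0("G", seq_len(n_nodes))
  dag <- directed_graph(matrix(0L, n_nodes, n_nodes), labels = labels)
  new_learner_result(
    graph = partially_directed_graph(n_nodes = n_nodes, labels = labels),
    member_dag = dag, score = NA_real_, method = "null", params = list())
}
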