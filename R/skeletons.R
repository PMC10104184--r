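# Observational skeleton estimators used as step (1) of SP-GIES: the
# order-independent PC algorithm with Fisher-z conditional-independence
# tests, mutual-information based CLR and ARACNE, and the knockout
# deviation-matrix baseline.

#' Fisher-z conditional independence test
#'
#' Tests `X_i` independent of `X_j` given `X_cond` via the Fisher
#' z-transform of the sample partial correlation; the null distribution of
#' `sqrt(n - |cond| - 3) * z` is standard normal.
#'
#' @param data numeric samples-by-nodes matrix (or `spg_samples`, whose
#'   observational rows are used).
#' @param i,j node indices.
#' @param cond integer vector of conditioning node indices (possibly empty).
#' @param alpha significance level; independence is declared when
#'   `p >= alpha`.
#' @return list with `statistic`, `p_value`, `independent`.
#' @export
fisher_z_ci_test <- function(data, i, j, cond = integer(0), alpha = 0.01) {
  if (inherits(data, "spg_samples")) {
    data <- data$data[observational_rows(data), , drop = FALSE]
  }
  n <- nrow(data)
  if (n - length(cond) - 3 <= 0) stop("too few samples for this conditioning size")
  C <- stats::cor(data[, c(i, j, cond), drop = FALSE])
  r <- tryCatch(partial_cor_from_cor(C), error = function(e) NA_real_)
  if (is.na(r)) {
    # singular conditioning covariance: flag as dependent
    return(list(statistic = Inf, p_value = 0, independent = FALSE))
  }
  r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
  z <- 0.5 * log((1 + r) / (1 - r))
  stat <- sqrt(n - length(cond) - 3) * abs(z)
  p <- 2 * stats::pnorm(-stat)
  list(statistic = stat, p_value = p, independent = p >= alpha)
}

# partial correlation of variables 1 and 2 given the rest, from their joint
# correlation matrix
partial_cor_from_cor <- function(C) {
  if (ncol(C) == 2L) return(C[1L, 2L])
  P <- solve(C)
  -P[1L, 2L] / sqrt(P[1L, 1L] * P[2L, 2L])
}

#' PC algorithm (stable variant)
#'
#' Constraint-based estimate of the essential graph from observational
#' rows: the adjacency search removes edges between conditionally
#' independent pairs with growing conditioning-set sizes, using the
#' order-independent ("stable") neighbour sets frozen per level, then
#' v-structures are oriented from the recorded separating sets and the Meek
#' rules are applied.
#'
#' @param samples an `spg_samples` (interventional rows are ignored) or a
#'   numeric matrix.
#' @param alpha Fisher-z significance level (default 0.01).
#' @param max_cond largest conditioning-set size to attempt; tests whose
#'   conditioning sets the sample size cannot support are skipped with a
#'   warning.
#' @return an `spg_pdgraph` (a CPDAG on faithful data).
#' @export
pc_estimate <- function(samples, alpha = 0.01, max_cond = Inf) {
  samples <- as_sample_set(samples)
  x <- samples$data[observational_rows(samples), , drop = FALSE]
  p <- ncol(x)
  n <- nrow(x)
  C <- stats::cor(x)
  adj <- matrix(TRUE, p, p); diag(adj) <- FALSE
  sepset <- vector("list", p * p)
  dim(sepset) <- c(p, p)
  n_max <- n - 4  # largest |cond| the Fisher-z test supports
  warned <- FALSE
  l <- 0L
  repeat {
    if (l > max_cond) break
    if (l > n_max) {
      if (!warned && any(adj)) {
        warning("sample size too small for conditioning sets of size ", l,
                "; remaining tests skipped")
      }
      break
    }
    frozen <- adj  # stable variant: neighbour sets fixed within the level
    done <- TRUE
    for (i in seq_len(p)) {
      nb_i <- which(frozen[i, ])
      for (j in nb_i) {
        if (!adj[i, j]) next
        others <- setdiff(nb_i, j)
        if (length(others) < l) next
        done <- FALSE
        subsets <- if (l == 0L) list(integer(0)) else
          utils::combn(others, l, simplify = FALSE)
        for (S in subsets) {
          tst <- fisher_z_test_cor(C, n, i, j, S, alpha)
          if (tst$independent) {
            adj[i, j] <- adj[j, i] <- FALSE
            sepset[[i, j]] <- sepset[[j, i]] <- S
            break
          }
        }
      }
    }
    if (done) break
    l <- l + 1L
  }
  # v-structure orientation from separating sets; conflicting orientations
  # cancel out and the edge is left undirected
  D <- matrix(0L, p, p)
  for (k in seq_len(p)) {
    nb <- which(adj[k, ])
    if (length(nb) < 2L) next
    cmb <- utils::combn(nb, 2L)
    for (c in seq_len(ncol(cmb))) {
      i <- cmb[1L, c]; j <- cmb[2L, c]
      if (adj[i, j]) next
      S <- sepset[[i, j]]
      if (!(k %in% S)) {
        D[i, k] <- 1L
        D[j, k] <- 1L
      }
    }
  }
  both <- D == 1L & t(D) == 1L
  D[both] <- 0L
  U <- adj * 1L
  U[D == 1L | t(D) == 1L] <- 0L
  storage.mode(U) <- "integer"
  res <- meek_apply(D, U)
  partially_directed_graph(res$directed, res$undirected,
                           labels = samples$node_labels)
}

# Fisher-z test evaluated from a precomputed correlation matrix (PC's fast
# path; shares the statistic with fisher_z_ci_test).
fisher_z_test_cor <- function(C, n, i, j, S, alpha) {
  sub <- C[c(i, j, S), c(i, j, S), drop = FALSE]
  r <- tryCatch(partial_cor_from_cor(sub), error = function(e) NA_real_)
  if (is.na(r) || !is.finite(r)) {
    return(list(statistic = Inf, p_value = 0, independent = FALSE))
  }
  r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
  z <- 0.5 * log((1 + r) / (1 - r))
  stat <- sqrt(n - length(S) - 3) * abs(z)
  p <- 2 * stats::pnorm(-stat)
  list(statistic = stat, p_value = p, independent = p >= alpha)
}

#' Pairwise mutual-information matrix
#'
#' Symmetric matrix of pairwise mutual-information estimates between node
#' columns, from observational rows.  The default Gaussian closed form is
#' `-log(1 - rho^2) / 2`; the `histogram` estimator is an equal-width-bin
#' plug-in estimate (in nats) standing in for spline/adaptive-partition
#' estimators.
#'
#' @param samples `spg_samples` or numeric matrix (at least 3 rows).
#' @param estimator `"gaussian"` or `"histogram"`.
#' @param bins bin count for the histogram estimator.
#' @return an `n x n` score matrix with zero diagonal.
#' @export
mutual_information_matrix <- function(samples, estimator = c("gaussian", "histogram"),
                                      bins = 8L) {
  estimator <- match.arg(estimator)
  samples <- as_sample_set(samples)
  x <- samples$data[observational_rows(samples), , drop = FALSE]
  if (nrow(x) < 3L) stop("at least 3 observational samples are required")
  p <- ncol(x)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) warning("zero-variance column(s); their MI is set to 0")
  if (estimator == "gaussian") {
    ok <- sds > 0
    C <- matrix(0, p, p)
    if (any(ok)) C[ok, ok] <- stats::cor(x[, ok, drop = FALSE])
    diag(C) <- 0
    mi <- -0.5 * log(pmax(1 - C^2, 1e-12))
  } else {
    disc <- apply(x, 2L, function(col) {
      if (stats::sd(col) == 0) return(rep(1L, length(col)))
      br <- seq(min(col), max(col), length.out = bins + 1L)
      br[1L] <- br[1L] - 1e-9
      cut(col, breaks = br, labels = FALSE)
    })
    mi <- matrix(0, p, p)
    for (i in seq_len(p - 1L)) {
      for (j in (i + 1L):p) {
        mi[i, j] <- mi[j, i] <- histogram_mi(disc[, i], disc[, j])
      }
    }
  }
  diag(mi) <- 0
  dimnames(mi) <- list(samples$node_labels, samples$node_labels)
  mi
}

# plug-in MI (nats) of two integer-coded columns
histogram_mi <- function(a, b) {
  tab <- table(a, b)
  pj <- tab / sum(tab)
  pa <- rowSums(pj); pb <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / outer(pa, pb)[nz]))
}

#' Context-likelihood-of-relatedness (CLR) scores
#'
#' Standardizes each mutual-information value against the background
#' distributions of its two genes: `z_i` is `MI(i, j)` standardized by row
#' `i`'s mean and standard deviation (negatives clipped to 0) and the score
#' is `sqrt(z_i^2 + z_j^2)`.
#'
#' @param mi symmetric mutual-information matrix.
#' @return symmetric score matrix with zero diagonal.
#' @export
clr_scores <- function(mi) {
  mi <- as.matrix(mi)
  p <- nrow(mi)
  off <- mi; diag(off) <- NA
  mu <- rowMeans(off, na.rm = TRUE)
  sg <- apply(off, 1L, stats::sd, na.rm = TRUE)
  z <- (mi - mu) / ifelse(sg > 0, sg, Inf)  # zero-sd rows contribute 0
  z[z < 0] <- 0
  out <- sqrt(z^2 + t(z)^2)
  diag(out) <- 0
  dimnames(out) <- dimnames(mi)
  out
}

#' Keep the top fraction of scored edges as an undirected graph
#'
#' Retains the `ceiling(fraction * n * (n - 1) / 2)` highest-scoring
#' unordered pairs; ties are broken deterministically by `(i, j)` index
#' order.
#'
#' @param scores symmetric score matrix.
#' @param fraction fraction of all possible edges to keep (the benchmark's
#'   CLR rule keeps the top 10 percent).
#' @return an `spg_pdgraph` with only undirected edges.
#' @export
threshold_top_fraction <- function(scores, fraction = 0.1) {
  scores <- as.matrix(scores)
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  p <- nrow(scores)
  idx <- which(upper.tri(scores), arr.ind = TRUE)
  k <- ceiling(fraction * p * (p - 1) / 2)
  ord <- order(-scores[idx], idx[, 1L], idx[, 2L])
  keep <- idx[ord[seq_len(min(k, nrow(idx)))], , drop = FALSE]
  u <- matrix(0L, p, p)
  u[keep] <- 1L
  u <- u + t(u)
  storage.mode(u) <- "integer"
  partially_directed_graph(undirected = u, labels = rownames(scores))
}

#' ARACNE pruning: MI threshold plus data-processing inequality
#'
#' Drops pairs whose mutual information falls below `mi_threshold`, then for
#' every triangle removes the edge `(i, j)` whose MI is below
#' `min(MI(i,k), MI(j,k)) * (1 - dpi_tolerance)` — the data-processing
#' inequality marks the weakest edge of a triangle as an indirect
#' interaction.  All DPI removals are decided on the thresholded matrix
#' before any edge is deleted.
#'
#' @param mi symmetric mutual-information matrix.
#' @param mi_threshold minimum MI to keep a pair (see [mi_null_threshold()]).
#' @param dpi_tolerance slack in the DPI comparison (default 0).
#' @return an `spg_pdgraph` with only undirected edges.
#' @export
aracne_prune <- function(mi, mi_threshold, dpi_tolerance = 0) {
  mi <- as.matrix(mi)
  p <- nrow(mi)
  W <- mi
  W[W < mi_threshold] <- 0
  diag(W) <- 0
  drop <- matrix(FALSE, p, p)
  if (p >= 3L) {
    for (i in seq_len(p - 1L)) {
      for (j in (i + 1L):p) {
        if (W[i, j] == 0) next
        ks <- which(W[i, ] > 0 & W[j, ] > 0)
        ks <- setdiff(ks, c(i, j))
        for (k in ks) {
          if (W[i, j] < min(W[i, k], W[j, k]) * (1 - dpi_tolerance)) {
            drop[i, j] <- drop[j, i] <- TRUE
            break
          }
        }
      }
    }
  }
  u <- (W > 0 & !drop) * 1L
  storage.mode(u) <- "integer"
  partially_directed_graph(undirected = u, labels = rownames(mi))
}

#' Permutation-null mutual-information threshold
#'
#' Estimates the MI cutoff whose exceedance probability under the
#' no-association null is `p_value`.  Columns are permuted independently to
#' destroy all dependence, pairwise MI values are pooled across
#' permutations, and the cutoff is read off the empirical distribution; for
#' p-values beyond the reach of the permutation sample (the benchmark
#' default is 1e-8) an exponential fit to the upper tail extrapolates the
#' quantile.
#'
#' @param samples `spg_samples` or numeric matrix.
#' @param p_value target tail probability.
#' @param n_permutations number of column permutations.
#' @param seed integer seed.
#' @param estimator MI estimator passed to [mutual_information_matrix()].
#' @return the MI cutoff (a single number).
#' @export
mi_null_threshold <- function(samples, p_value = 1e-8, n_permutations = 100L,
                              seed = NULL, estimator = "gaussian") {
  samples <- as_sample_set(samples)
  x <- samples$data[observational_rows(samples), , drop = FALSE]
  if (nrow(x) < 3L || ncol(x) < 2L) stop("degenerate data for the permutation null")
  vals <- with_seed(seed, {
    out <- vector("list", n_permutations)
    for (b in seq_len(n_permutations)) {
      xp <- apply(x, 2L, sample)
      m <- mutual_information_matrix(sample_set(xp), estimator = estimator)
      out[[b]] <- m[upper.tri(m)]
    }
    unlist(out)
  })
  vals <- sort(vals)
  nv <- length(vals)
  if (p_value >= 10 / nv) {
    return(stats::quantile(vals, 1 - p_value, names = FALSE, type = 8))
  }
  # exponential tail fit above the 95th percentile
  q0 <- stats::quantile(vals, 0.95, names = FALSE, type = 8)
  exc <- vals[vals > q0] - q0
  p0 <- mean(vals > q0)
  rate <- 1 / mean(exc)
  q0 + log(p0 / p_value) / rate
}

#' Knockout deviation matrix
#'
#' Directed scores from single-knockout responses: entry `(i, j)` is the
#' absolute deviation of gene `j` in the knockout-of-`i` sample from its
#' observational mean, in units of its observational standard deviation.
#' Genes that respond to a knockout are downstream candidates.
#'
#' @param samples an `spg_samples` containing observational rows and one
#'   single-node knockout row per node (rows beyond the first per node are
#'   averaged).
#' @return an asymmetric `n x n` score matrix with zero diagonal.
#' @export
deviation_matrix <- function(samples) {
  stopifnot(inherits(samples, "spg_samples"))
  p <- ncol(samples$data)
  obs <- samples$data[observational_rows(samples), , drop = FALSE]
  if (nrow(obs) < 2L) stop("deviation_matrix needs observational rows")
  mu <- colMeans(obs)
  sg <- apply(obs, 2L, stats::sd)
  sg[sg == 0] <- 1
  single <- vapply(samples$targets, function(t) if (length(t) == 1L) t else NA_integer_,
                   integer(1))
  out <- matrix(0, p, p)
  for (i in seq_len(p)) {
    rows <- which(single == i)
    if (length(rows) == 0L) stop("missing knockout sample for node ", i)
    xi <- colMeans(samples$data[rows, , drop = FALSE])
    out[i, ] <- abs(xi - mu) / sg
  }
  diag(out) <- 0
  dimnames(out) <- list(samples$node_labels, samples$node_labels)
  out
}
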