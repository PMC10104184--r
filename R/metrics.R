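# Evaluation metrics for estimated networks: structural Hamming distance,
# structural intervention distance, and area under the precision-recall
# curve over directed edge predictions.

# directed 0/1 comparison matrix of an estimate: undirected edges are
# expanded to both ordered entries
estimate_adjacency <- function(estimate) {
  if (inherits(estimate, "spg_learner_result")) estimate <- estimate$graph
  if (inherits(estimate, "spg_dgraph")) return(estimate$adjacency)
  if (inherits(estimate, "spg_pdgraph")) {
    a <- estimate$directed + estimate$undirected
    storage.mode(a) <- "integer"
    return(a)
  }
  a <- as.matrix(estimate)
  storage.mode(a) <- "integer"
  a
}

#' Structural Hamming distance
#'
#' L1 distance between the binary adjacency matrices of truth and estimate.
#' Undirected estimated edges are expanded to both ordered entries before
#' the comparison; consequently a single reversed edge costs 2, and an
#' undirected estimate of a true directed edge costs 1.
#'
#' @param truth an `spg_dgraph` (the ground-truth DAG).
#' @param estimate an `spg_dgraph`, `spg_pdgraph`, `spg_learner_result` or
#'   binary matrix.
#' @return nonnegative integer.
#' @export
shd <- function(truth, estimate) {
  stopifnot(inherits(truth, "spg_dgraph"))
  b <- estimate_adjacency(estimate)
  if (any(dim(b) != truth$n_nodes)) stop("node-count mismatch")
  sum(abs(truth$adjacency - b))
}

#' Structural intervention distance
#'
#' Counts the ordered node pairs `(i, j)` for which the estimated graph
#' would lead to a wrong interventional claim: the estimate's parent set of
#' `i` is used as an adjustment set for the effect of `i` on `j`, and the
#' pair is a mistake when that set fails the adjustment criterion in the
#' true DAG (including wrongly claimed null effects when `j` is taken to be
#' a parent of `i` but is in truth a descendant).
#'
#' @param truth,estimate `spg_dgraph` DAGs on the same nodes (a learner
#'   result's `member_dag` is used automatically).
#' @return integer in `[0, n(n-1)]`.
#' @export
sid <- function(truth, estimate) {
  if (inherits(estimate, "spg_learner_result")) estimate <- estimate$member_dag
  stopifnot(inherits(truth, "spg_dgraph"), inherits(estimate, "spg_dgraph"))
  if (truth$n_nodes != estimate$n_nodes) stop("node-count mismatch")
  a <- truth$adjacency
  if (!is_acyclic(a) || !is_acyclic(estimate$adjacency)) {
    stop("sid requires DAG inputs")
  }
  n <- truth$n_nodes
  if (n > 2000L) warning("sid on more than 2000 nodes is expensive (quadratic-cubic)")
  desc <- lapply(seq_len(n), function(v) descendants_of(a, v))
  anc <- lapply(seq_len(n), function(v) ancestors_of(a, v))
  mistakes <- 0L
  for (i in seq_len(n)) {
    Z <- which(estimate$adjacency[, i] == 1L)
    de_i <- desc[[i]]
    for (j in seq_len(n)) {
      if (j == i) next
      if (j %in% Z) {
        # the estimate claims a null effect of i on j
        if (j %in% de_i) mistakes <- mistakes + 1L
        next
      }
      if (!adjustment_valid(a, i, j, Z, desc, anc)) mistakes <- mistakes + 1L
    }
  }
  mistakes
}

# Adjustment criterion: Z is valid for (i, j) in DAG a iff no element of Z
# is a (non-strict) descendant of a node on a proper causal path from i to
# j, and Z blocks every non-causal path, i.e. i and j are d-separated by Z
# in the proper back-door graph (first edges of proper causal paths
# removed).
adjustment_valid <- function(a, i, j, Z, desc, anc) {
  n <- nrow(a)
  # nodes (other than i) on a proper causal path i -> ... -> j
  cn <- intersect(desc[[i]], c(anc[[j]], j))
  if (length(cn) > 0L) {
    forbidden <- unique(c(cn, unlist(desc[cn])))
    if (any(Z %in% forbidden)) return(FALSE)
  }
  g <- a
  g[i, intersect(which(a[i, ] == 1L), cn)] <- 0L
  d_separated(g, i, j, Z)
}

# d-separation of x and y given Z in DAG adjacency a, via moralization of
# the ancestral subgraph.
d_separated <- function(a, x, y, Z) {
  n <- nrow(a)
  keep <- rep(FALSE, n)
  for (v in c(x, y, Z)) {
    keep[v] <- TRUE
    keep[ancestors_of(a, v)] <- TRUE
  }
  idx <- which(keep)
  sub <- a[idx, idx, drop = FALSE]
  # moralize: marry parents of every node, then drop orientations
  mor <- (sub + t(sub)) > 0
  for (k in seq_along(idx)) {
    pa <- which(sub[, k] == 1L)
    if (length(pa) > 1L) mor[pa, pa] <- TRUE
  }
  diag(mor) <- FALSE
  # connectivity from x to y avoiding Z
  xi <- match(x, idx); yi <- match(y, idx)
  zi <- match(Z, idx); zi <- zi[!is.na(zi)]
  blocked <- rep(FALSE, length(idx))
  blocked[zi] <- TRUE
  if (blocked[xi] || blocked[yi]) return(TRUE)
  seen <- rep(FALSE, length(idx))
  frontier <- xi
  seen[xi] <- TRUE
  while (length(frontier) > 0L) {
    nxt <- unique(unlist(lapply(frontier, function(u) which(mor[u, ]))))
    nxt <- nxt[!seen[nxt] & !blocked[nxt]]
    if (yi %in% nxt) return(FALSE)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  TRUE
}

#' Area under the precision-recall curve for edge recovery
#'
#' Ordered node pairs are ranked by score (a symmetric score matrix assigns
#' its value to both directions; a binary graph estimate is used as a
#' two-level score) and precision/recall are accumulated down the ranking
#' with tied scores handled as one block.  The default `"trapezoid"`
#' interpolation connects the PR points linearly starting from the
#' `(recall 0, precision 1)` anchor — under this convention an edgeless
#' (NULL) estimate scores `(1 + prevalence) / 2`, which matches the
#' benchmark tables' NULL rows.  `"step"` gives the average-precision sum
#' `sum_k (R_k - R_{k-1}) P_k`.  Both curves extend to recall 1, where
#' precision equals the edge prevalence.
#'
#' @param truth an `spg_dgraph`; positives are its directed edges.
#' @param estimate a score matrix, `spg_dgraph`, `spg_pdgraph`, or an
#'   `spg_learner_result` (its score matrix when present, else its graph).
#' @param interpolation `"trapezoid"` (default) or `"step"`.
#' @return area in `[0, 1]`.
#' @export
aucpr <- function(truth, estimate, interpolation = c("trapezoid", "step")) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(truth, "spg_dgraph"))
  n <- truth$n_nodes
  sc <- if (inherits(estimate, "spg_learner_result")) {
    if (!is.null(estimate$scores)) as.matrix(estimate$scores)
    else estimate_adjacency(estimate$graph)
  } else if (inherits(estimate, "spg_dgraph") || inherits(estimate, "spg_pdgraph")) {
    estimate_adjacency(estimate)
  } else {
    as.matrix(estimate)
  }
  if (any(dim(sc) != n)) stop("node-count mismatch")
  off <- !diag(n)
  scores <- sc[off]
  labels <- truth$adjacency[off] == 1L
  P <- sum(labels)
  if (P == 0L) stop("truth has no edges; precision-recall is undefined")
  lv <- sort(unique(scores), decreasing = TRUE)
  tp <- 0; fp <- 0; area <- 0
  r_prev <- 0
  p_prev <- 1  # anchor point (recall 0, precision 1)
  for (s in lv) {
    in_block <- scores == s
    tp <- tp + sum(labels & in_block)
    fp <- fp + sum(!labels & in_block)
    r <- tp / P
    prec <- tp / (tp + fp)
    if (interpolation == "trapezoid") {
      area <- area + (r - r_prev) * (prec + p_prev) / 2
    } else {
      area <- area + (r - r_prev) * prec
    }
    r_prev <- r
    p_prev <- prec
  }
  area
}

#' Evaluate an estimate against the ground truth
#'
#' Convenience wrapper computing the three benchmark metrics at once.
#'
#' @param truth an `spg_dgraph`.
#' @param estimate learner result or graph.
#' @param metrics subset of `c("shd", "sid", "aucpr")`.
#' @return named list of metric values.
#' @export
evaluate_estimate <- function(truth, estimate, metrics = c("shd", "sid", "aucpr")) {
  out <- list()
  if ("shd" %in% metrics) out$shd <- shd(truth, estimate)
  if ("sid" %in% metrics) out$sid <- sid(truth, estimate)
  if ("aucpr" %in% metrics) out$aucpr <- aucpr(truth, estimate)
  out
}
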