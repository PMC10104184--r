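#' Directed graph over labelled nodes
#'
#' Lightweight container for a directed graph stored as a binary adjacency
#' matrix with entry `(i, j) = 1` meaning an edge `i -> j`.  Used both for
#' ground-truth DAGs and for estimated networks.
#'
#' @param adjacency square binary matrix; `adjacency[i, j] == 1` iff there is
#'   an edge from node `i` to node `j`.  The diagonal must be zero.
#' @param labels optional character vector of node labels; defaults to
#'   `V1..Vn` (or the matrix dimnames, when present).
#' @param check_dag if `TRUE`, error when the graph contains a directed cycle.
#' @return an object of class `spg_dgraph` with fields `n_nodes`,
#'   `adjacency` and `node_labels`.
#' @examples
#' g <- directed_graph(rbind(c(0, 1, 0), c(0, 0, 1), c(0, 0, 0)))
#' is_acyclic(g)
#' @export
directed_graph <- function(adjacency, labels = NULL, check_dag = FALSE) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (ncol(adjacency) != n) stop("adjacency must be square")
  if (any(is.na(adjacency)) || !all(adjacency %in% c(0, 1))) {
    stop("adjacency must be binary (0/1)")
  }
  if (any(diag(adjacency) != 0)) stop("self-loops are not allowed")
  if (is.null(labels)) labels <- rownames(adjacency)
  if (is.null(labels)) labels <- paste0("V", seq_len(n))
  if (length(labels) != n) stop("labels length must equal node count")
  storage.mode(adjacency) <- "integer"
  dimnames(adjacency) <- list(labels, labels)
  g <- structure(
    list(n_nodes = n, adjacency = adjacency, node_labels = as.character(labels)),
    class = "spg_dgraph"
  )
  if (check_dag && !is_acyclic(g)) stop("graph contains a directed cycle")
  g
}

#' Partially directed graph (PDAG / essential graph)
#'
#' Mixed graph holding a directed and an undirected edge set on the same
#' nodes.  Essential graphs (CPDAGs) and interventional essential graphs are
#' represented this way, as are estimated skeletons (all edges undirected).
#'
#' @param directed binary matrix of directed edges (`(i,j)=1` iff `i -> j`),
#'   or `NULL` for none.
#' @param undirected symmetric binary matrix of undirected edges, or `NULL`.
#' @param labels optional node labels.
#' @param n_nodes node count, required when both matrices are `NULL`.
#' @return an object of class `spg_pdgraph` with fields `n_nodes`,
#'   `directed`, `undirected`, `node_labels`.
#' @export
partially_directed_graph <- function(directed = NULL, undirected = NULL,
                                     labels = NULL, n_nodes = NULL) {
  if (is.null(directed) && is.null(undirected)) {
    if (is.null(n_nodes)) stop("n_nodes required when no edge matrix is given")
    directed <- matrix(0L, n_nodes, n_nodes)
    undirected <- matrix(0L, n_nodes, n_nodes)
  }
  if (is.null(directed)) directed <- matrix(0L, nrow(undirected), ncol(undirected))
  if (is.null(undirected)) undirected <- matrix(0L, nrow(directed), ncol(directed))
  directed <- as.matrix(directed); undirected <- as.matrix(undirected)
  n <- nrow(directed)
  if (any(dim(directed) != n) || any(dim(undirected) != n)) {
    stop("edge matrices must be square and of equal dimension")
  }
  if (!all(directed %in% c(0, 1)) || !all(undirected %in% c(0, 1))) {
    stop("edge matrices must be binary (0/1)")
  }
  if (any(diag(directed) != 0) || any(diag(undirected) != 0)) {
    stop("self-loops are not allowed")
  }
  if (!isTRUE(all.equal(undirected, t(undirected)))) {
    stop("undirected matrix must be symmetric")
  }
  if (any((directed + t(directed) + undirected) > 1)) {
    stop("directed and undirected edge sets must be disjoint per node pair")
  }
  if (is.null(labels)) labels <- rownames(directed)
  if (is.null(labels)) labels <- paste0("V", seq_len(n))
  if (length(labels) != n) stop("labels length must equal node count")
  storage.mode(directed) <- "integer"
  storage.mode(undirected) <- "integer"
  dimnames(directed) <- dimnames(undirected) <- list(labels, labels)
  structure(
    list(n_nodes = n, directed = directed, undirected = undirected,
         node_labels = as.character(labels)),
    class = "spg_pdgraph"
  )
}

#' @export
print.spg_dgraph <- function(x, ...) {
  cat(sprintf("Directed graph: %d nodes, %d edges\n",
              x$n_nodes, sum(x$adjacency)))
  invisible(x)
}

#' @export
print.spg_pdgraph <- function(x, ...) {
  cat(sprintf("Partially directed graph: %d nodes, %d directed, %d undirected edges\n",
              x$n_nodes, sum(x$directed), sum(x$undirected) / 2L))
  invisible(x)
}

# total adjacency (any edge) of a pdgraph or dgraph, as a 0/1 matrix
any_adjacency <- function(g) {
  if (inherits(g, "spg_dgraph")) {
    a <- (g$adjacency + t(g$adjacency)) > 0
  } else {
    a <- (g$directed + t(g$directed) + g$undirected) > 0
  }
  storage.mode(a) <- "integer"
  a
}

#' Test whether a directed graph is acyclic
#'
#' Kahn-style topological sort; the graph is acyclic iff all nodes can be
#' removed in source-first order.
#'
#' @param g an `spg_dgraph` or a binary adjacency matrix.
#' @return `TRUE` iff a topological order exists.
#' @export
is_acyclic <- function(g) {
  a <- if (inherits(g, "spg_dgraph")) g$adjacency else as.matrix(g)
  n <- nrow(a)
  if (n == 0L) return(TRUE)
  indeg <- colSums(a)
  alive <- rep(TRUE, n)
  removed <- 0L
  repeat {
    src <- which(alive & indeg == 0)
    if (length(src) == 0L) break
    alive[src] <- FALSE
    removed <- removed + length(src)
    if (length(src) == 1L) {
      indeg <- indeg - a[src, ]
    } else {
      indeg <- indeg - colSums(a[src, , drop = FALSE])
    }
  }
  removed == n
}

# one valid topological order of a DAG adjacency matrix
topological_order <- function(a) {
  n <- nrow(a)
  indeg <- colSums(a)
  alive <- rep(TRUE, n)
  ord <- integer(n)
  for (k in seq_len(n)) {
    src <- which(alive & indeg == 0)
    if (length(src) == 0L) stop("graph contains a directed cycle")
    s <- src[1L]
    ord[k] <- s
    alive[s] <- FALSE
    indeg <- indeg - a[s, ]
  }
  ord
}

# strict descendants of node v (nodes reachable by a directed path)
descendants_of <- function(a, v) {
  n <- nrow(a)
  seen <- rep(FALSE, n)
  frontier <- which(a[v, ] == 1)
  while (length(frontier) > 0L) {
    seen[frontier] <- TRUE
    nxt <- unique(unlist(lapply(frontier, function(u) which(a[u, ] == 1))))
    frontier <- nxt[!seen[nxt]]
  }
  which(seen)
}

# strict ancestors of node v
ancestors_of <- function(a, v) descendants_of(t(a), v)

#' Skeleton of a directed graph
#'
#' Drops edge orientations: the output has an undirected edge `i -- j` iff
#' the input has `i -> j` or `j -> i`, and no directed edges.
#'
#' @param g an `spg_dgraph`.
#' @return an `spg_pdgraph` with only undirected edges.
#' @export
skeleton_of <- function(g) {
  stopifnot(inherits(g, "spg_dgraph"))
  sk <- (g$adjacency + t(g$adjacency)) > 0
  storage.mode(sk) <- "integer"
  partially_directed_graph(undirected = sk, labels = g$node_labels)
}

#' Number of directed edges of a partially directed graph
#'
#' The kernel of the edge-orientation utility used in experimental design:
#' the more edges an (interventional) essential graph orients, the more of
#' the causal structure is identified.
#'
#' @param p an `spg_pdgraph` (an `spg_dgraph` is accepted and counted by its
#'   adjacency).
#' @return integer count of directed edges.
#' @export
count_oriented <- function(p) {
  if (inherits(p, "spg_dgraph")) return(sum(p$adjacency))
  stopifnot(inherits(p, "spg_pdgraph"))
  sum(p$directed)
}

#' Intervention family
#'
#' Per-sample annotation of which nodes were clamped by a hard intervention;
#' an empty set marks an observational row.
#'
#' @param targets list with one entry per sample row, each an integer vector
#'   of clamped node indices (possibly empty).
#' @param n_nodes number of nodes the indices refer to.
#' @return object of class `spg_ifamily` (a validated list of integer sets).
#' @export
intervention_family <- function(targets, n_nodes) {
  targets <- lapply(targets, function(x) sort(unique(as.integer(x))))
  bad <- vapply(targets, function(x) length(x) > 0 && (min(x) < 1 || max(x) > n_nodes),
                logical(1))
  if (any(bad)) stop("intervention targets must be node indices in 1..n_nodes")
  structure(targets, class = "spg_ifamily", n_nodes = n_nodes)
}

# Deduplicate a family (list of target sets, spg_ifamily, or spg_samples)
# into the distinct target sets, always including the empty (observational)
# set: equivalence statements depend on which targets exist, not how many
# samples carry each, and observational information is assumed present.
distinct_targets <- function(family) {
  if (inherits(family, "spg_samples")) family <- family$targets
  if (is.null(family)) family <- list()
  if (is.numeric(family)) family <- list(family)
  sets <- lapply(family, function(x) sort(unique(as.integer(x))))
  sets <- c(list(integer(0)), sets)
  keys <- vapply(sets, function(x) paste(x, collapse = ","), character(1))
  sets[!duplicated(keys)]
}
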