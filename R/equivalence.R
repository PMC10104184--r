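# Markov-equivalence machinery: Meek orientation rules, essential graphs,
# interventional essential graphs, and a brute-force equivalence-class
# enumerator used as the testing oracle.

# v-structure signature of a DAG adjacency: matrix with one row per collider
# (i, k, j), i < j, i -> k <- j, i and j nonadjacent.
vstructure_signature <- function(a) {
  n <- nrow(a)
  sk <- (a + t(a)) > 0
  out <- list()
  for (k in seq_len(n)) {
    pa <- which(a[, k] == 1)
    if (length(pa) < 2L) next
    cmb <- utils::combn(pa, 2L)
    for (c in seq_len(ncol(cmb))) {
      i <- cmb[1L, c]; j <- cmb[2L, c]
      if (!sk[i, j]) out[[length(out) + 1L]] <- c(i, k, j)
    }
  }
  if (length(out) == 0L) return(matrix(integer(0), ncol = 3L))
  m <- do.call(rbind, out)
  m[order(m[, 1L], m[, 2L], m[, 3L]), , drop = FALSE]
}

# Apply the four Meek orientation rules to fixpoint on (D, U) matrices.
# Returns list(directed, undirected, conflict): conflict is TRUE when some
# undirected edge is forced in both directions (inconsistent input).
meek_apply <- function(D, U) {
  n <- nrow(D)
  conflict <- FALSE
  A <- function() (D + t(D) + U) > 0
  repeat {
    changed <- FALSE
    adj <- A()
    pairs <- which(U == 1, arr.ind = TRUE)
    pairs <- pairs[pairs[, 1L] < pairs[, 2L], , drop = FALSE]
    if (nrow(pairs) == 0L) break
    for (r in seq_len(nrow(pairs))) {
      a <- pairs[r, 1L]; b <- pairs[r, 2L]
      if (U[a, b] == 0L) next  # oriented earlier in this sweep
      force_ab <- meek_forces(D, U, adj, a, b)
      force_ba <- meek_forces(D, U, adj, b, a)
      if (force_ab && force_ba) { conflict <- TRUE; force_ba <- FALSE }
      if (force_ab) {
        D[a, b] <- 1L; U[a, b] <- U[b, a] <- 0L; changed <- TRUE
      } else if (force_ba) {
        D[b, a] <- 1L; U[a, b] <- U[b, a] <- 0L; changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(directed = D, undirected = U, conflict = conflict)
}

# TRUE iff some Meek rule orients the undirected edge a--b as a -> b.
meek_forces <- function(D, U, adj, a, b) {
  n <- nrow(D)
  others <- setdiff(seq_len(n), c(a, b))
  # R1: c -> a, c and b nonadjacent  =>  a -> b
  if (any(D[others, a] == 1L & !adj[others, b])) return(TRUE)
  # R2: a -> c -> b  =>  a -> b
  if (any(D[a, others] == 1L & D[others, b] == 1L)) return(TRUE)
  # R3: a -- c -> b, a -- d -> b, c and d nonadjacent  =>  a -> b
  cs <- others[U[a, others] == 1L & D[others, b] == 1L]
  if (length(cs) >= 2L) {
    for (x in seq_along(cs)) {
      for (y in seq_len(x - 1L)) {
        if (!adj[cs[x], cs[y]]) return(TRUE)
      }
    }
  }
  # R4: a ~ d, d -> c -> b, d and b nonadjacent  =>  a -> b
  ds <- others[adj[a, others] & !adj[others, b]]
  if (length(ds) > 0L) {
    cs4 <- others[D[others, b] == 1L]
    for (d in ds) {
      if (any(D[d, cs4] == 1L)) return(TRUE)
    }
  }
  FALSE
}

#' Meek orientation-rule closure of a partially directed graph
#'
#' Applies the four Meek rules until no further edge can be oriented.  The
#' skeleton is never changed; only undirected edges may become directed.
#' Inputs that admit no consistent DAG extension (an orientation is forced
#' both ways, the directed part is cyclic, or no extension exists) raise an
#' error.
#'
#' @param p an `spg_pdgraph`.
#' @return the closed `spg_pdgraph`.
#' @export
meek_closure <- function(p) {
  stopifnot(inherits(p, "spg_pdgraph"))
  res <- meek_apply(p$directed, p$undirected)
  if (res$conflict) stop("inconsistent input: an edge is forced in both directions")
  if (!is_acyclic(res$directed)) stop("inconsistent input: directed part is cyclic")
  if (is.null(pdag_extension(res$directed, res$undirected))) {
    stop("inconsistent input: no consistent DAG extension exists")
  }
  partially_directed_graph(res$directed, res$undirected, labels = p$node_labels)
}

# Dor-Tarsi consistent extension of a PDAG to a DAG.  Returns the DAG
# adjacency, or NULL when no consistent extension exists.
pdag_extension <- function(D, U) {
  n <- nrow(D)
  out <- D
  alive <- rep(TRUE, n)
  D <- D * 1L; U <- U * 1L
  while (any(alive)) {
    found <- FALSE
    for (v in which(alive)) {
      # sink: no outgoing directed edge among alive nodes
      if (any(D[v, alive] == 1L)) next
      und <- which(U[v, ] == 1L & alive)
      ok <- TRUE
      if (length(und) > 0L) {
        adjv <- which(alive & ((D[v, ] + D[, v] + U[v, ]) > 0))
        for (u in und) {
          adju <- (D[u, ] + D[, u] + U[u, ]) > 0
          need <- setdiff(adjv, u)
          if (!all(adju[need])) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      # orient undirected edges into v, remove v
      out[und, v] <- 1L
      out[v, und] <- 0L
      alive[v] <- FALSE
      D[v, ] <- D[, v] <- 0L
      U[v, ] <- U[, v] <- 0L
      found <- TRUE
      break
    }
    if (!found) return(NULL)
  }
  out
}

#' Essential graph (CPDAG) of a DAG
#'
#' The unique partially directed representation of the DAG's Markov
#' equivalence class: the skeleton is kept, v-structure edges are oriented,
#' and the Meek rules are applied to closure.  An edge ends up directed iff
#' it has the same orientation in every DAG of the class.
#'
#' @param g an `spg_dgraph` that is a DAG.
#' @return an `spg_pdgraph`.
#' @export
essential_graph <- function(g) {
  stopifnot(inherits(g, "spg_dgraph"))
  if (!is_acyclic(g)) stop("essential_graph requires a DAG")
  i_essential_graph(g, list())
}

#' Interventional essential graph of a DAG
#'
#' Representation of the interventional Markov equivalence class (I-MEC)
#' under a family of hard-intervention targets: beyond the v-structures, any
#' edge with exactly one endpoint in some target set is oriented (a knockout
#' severs incoming edges, so such edges are identified), and the Meek rules
#' are then run to closure.  Observational data is always assumed available,
#' i.e. the empty target set is implicitly part of the family; with an empty
#' family this reduces to [essential_graph()].
#'
#' @param g an `spg_dgraph` that is a DAG.
#' @param family intervention targets: an `spg_ifamily`, an `spg_samples`
#'   object, or a list of integer vectors of node indices.  Duplicated
#'   target sets are collapsed.
#' @return an `spg_pdgraph` whose directed edges are a superset of those of
#'   `essential_graph(g)`.
#' @export
i_essential_graph <- function(g, family) {
  stopifnot(inherits(g, "spg_dgraph"))
  a <- g$adjacency
  if (!is_acyclic(a)) stop("i_essential_graph requires a DAG")
  fam <- distinct_targets(family)
  n <- g$n_nodes
  D <- matrix(0L, n, n)
  # v-structure orientations
  vs <- vstructure_signature(a)
  if (nrow(vs) > 0L) {
    for (r in seq_len(nrow(vs))) {
      D[vs[r, 1L], vs[r, 2L]] <- 1L
      D[vs[r, 3L], vs[r, 2L]] <- 1L
    }
  }
  # edges cut by an intervention: exactly one endpoint in a target set
  for (I in fam) {
    if (length(I) == 0L) next
    inI <- seq_len(n) %in% I
    cut <- which((a == 1L) & (outer(inI, inI, xor)))
    D[cut] <- 1L
  }
  U <- (a + t(a) > 0) * 1L
  U[D == 1L | t(D) == 1L] <- 0L
  storage.mode(U) <- "integer"
  res <- meek_apply(D, U)
  partially_directed_graph(res$directed, res$undirected, labels = g$node_labels)
}

# I-equivalence of two DAG adjacencies under a list of distinct target sets
# (empty set included): for every target set I, the graphs obtained by
# deleting edges into I must share skeleton and v-structures.
i_equivalent <- function(a1, a2, fam) {
  a1 <- unname(a1); a2 <- unname(a2)
  for (I in fam) {
    m1 <- a1; m2 <- a2
    if (length(I) > 0L) { m1[, I] <- 0L; m2[, I] <- 0L }
    if (!all(((m1 + t(m1)) > 0) == ((m2 + t(m2)) > 0))) return(FALSE)
    v1 <- vstructure_signature(m1); v2 <- vstructure_signature(m2)
    if (nrow(v1) != nrow(v2) || !all(v1 == v2)) return(FALSE)
  }
  TRUE
}

#' Enumerate an (interventional) Markov equivalence class
#'
#' Brute-force oracle, intended for testing on small graphs: every
#' orientation of `g`'s skeleton is generated, acyclic ones are kept, and
#' those indistinguishable from `g` given observational data plus the given
#' intervention targets are returned.  Two DAGs are indistinguishable iff
#' for every target set (including the empty, observational one) the graphs
#' left after severing edges into the targets share skeleton and
#' v-structures.
#'
#' @param g an `spg_dgraph` DAG with at most 6 nodes.
#' @param family intervention targets as in [i_essential_graph()]; use
#'   `list()` for the purely observational class.
#' @return list of `spg_dgraph` members; `g` itself is always included.
#' @export
enumerate_mec <- function(g, family = list()) {
  stopifnot(inherits(g, "spg_dgraph"))
  if (g$n_nodes > 6L) stop("enumerate_mec is a brute-force oracle; n_nodes must be <= 6")
  if (!is_acyclic(g)) stop("enumerate_mec requires a DAG")
  fam <- distinct_targets(family)
  a <- g$adjacency
  n <- g$n_nodes
  sk <- which((a + t(a)) > 0 & upper.tri(a), arr.ind = TRUE)
  m <- nrow(sk)
  out <- list()
  for (code in seq_len(2^m) - 1L) {
    cand <- matrix(0L, n, n)
    bits <- as.integer(intToBits(code))[seq_len(max(m, 1L))]
    if (m > 0L) {
      for (e in seq_len(m)) {
        i <- sk[e, 1L]; j <- sk[e, 2L]
        if (bits[e] == 1L) cand[i, j] <- 1L else cand[j, i] <- 1L
      }
    }
    if (!is_acyclic(cand)) next
    if (i_equivalent(a, cand, fam)) {
      out[[length(out) + 1L]] <- directed_graph(cand, labels = g$node_labels)
    }
    if (m == 0L) break
  }
  out
}
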