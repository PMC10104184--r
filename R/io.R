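# Delimited-text I/O: sample sets with an intervention column, edge-list
# graph files, canonical test fixtures and run manifests.  Text-first on
# purpose: gene networks at this scale are small enough that portability
# beats compactness.

#' Write a sample set to delimited text
#'
#' Tab-separated, one column per node plus a final `intervention` column
#' holding the comma-separated labels of the clamped nodes (empty for
#' observational rows).  Row order is part of the contract.
#'
#' @param s an `spg_samples`.
#' @param path output file path.
#' @export
write_sampleset <- function(s, path) {
  stopifnot(inherits(s, "spg_samples"))
  iv <- vapply(s$targets, function(t) paste(s$node_labels[t], collapse = ","),
               character(1))
  df <- data.frame(s$data, check.names = FALSE)
  df$intervention <- iv
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample set from delimited text
#'
#' @param path file written by [write_sampleset()].
#' @return an `spg_samples`.
#' @export
read_sampleset <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE)
  if (!("intervention" %in% names(df))) {
    stop("malformed sample file: missing 'intervention' column")
  }
  iv <- as.character(df$intervention)
  iv[is.na(iv)] <- ""
  df$intervention <- NULL
  x <- as.matrix(df)
  if (!is.numeric(x)) stop("non-numeric expression cells in sample file")
  labels <- colnames(x)
  targets <- lapply(iv, function(s) {
    if (identical(s, "")) return(integer(0))
    toks <- strsplit(s, ",", fixed = TRUE)[[1]]
    ix <- match(toks, labels)
    if (any(is.na(ix))) {
      stop("unknown node label in intervention column: ",
           paste(toks[is.na(ix)], collapse = ", "))
    }
    ix
  })
  sample_set(x, targets = targets, labels = labels)
}

#' Write a graph as an edge list
#'
#' Header line `# nodes: <n>; labels: <l1,l2,...>`, then one edge per line
#' as `source<TAB>target<TAB>type` with type `directed` or `undirected`
#' (undirected edges written once, lower label-index first).
#'
#' @param g an `spg_dgraph` or `spg_pdgraph`.
#' @param path output file path.
#' @export
write_graph <- function(g, path) {
  labels <- g$node_labels
  lines <- sprintf("# nodes: %d; labels: %s", g$n_nodes,
                   paste(labels, collapse = ","))
  if (inherits(g, "spg_dgraph")) {
    D <- g$adjacency; U <- matrix(0L, g$n_nodes, g$n_nodes)
  } else {
    D <- g$directed; U <- g$undirected
  }
  de <- which(D == 1L, arr.ind = TRUE)
  de <- de[order(de[, 1L], de[, 2L]), , drop = FALSE]
  for (r in seq_len(nrow(de))) {
    lines <- c(lines, paste(labels[de[r, 1L]], labels[de[r, 2L]], "directed",
                            sep = "\t"))
  }
  ue <- which(U == 1L & upper.tri(U), arr.ind = TRUE)
  ue <- ue[order(ue[, 1L], ue[, 2L]), , drop = FALSE]
  for (r in seq_len(nrow(ue))) {
    lines <- c(lines, paste(labels[ue[r, 1L]], labels[ue[r, 2L]], "undirected",
                            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a graph from an edge list
#'
#' @param path file written by [write_graph()].
#' @param as one of `"auto"` (directed graph when no undirected edges are
#'   present, else partially directed), `"directed"`, `"pdgraph"`.
#' @return an `spg_dgraph` or `spg_pdgraph`.
#' @export
read_graph <- function(path, as = c("auto", "directed", "pdgraph")) {
  as <- match.arg(as)
  lines <- readLines(path)
  if (length(lines) == 0L || !grepl("^# nodes:", lines[1])) {
    stop("malformed graph file: missing header line")
  }
  hdr <- regmatches(lines[1],
                    regexec("^# nodes: ([0-9]+); labels: (.*)$", lines[1]))[[1]]
  if (length(hdr) != 3L) stop("malformed graph header")
  n <- as.integer(hdr[2])
  labels <- strsplit(hdr[3], ",", fixed = TRUE)[[1]]
  if (length(labels) != n) stop("graph header label count mismatch")
  D <- matrix(0L, n, n); U <- matrix(0L, n, n)
  body <- lines[-1]
  body <- body[nzchar(body)]
  for (ln in body) {
    tok <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(tok) != 3L) stop("malformed edge line: ", ln)
    i <- match(tok[1], labels); j <- match(tok[2], labels)
    if (is.na(i) || is.na(j)) stop("unknown node label in edge line: ", ln)
    if (i == j) stop("self-loop in graph file: ", ln)
    if (tok[3] == "directed") {
      if (D[i, j] == 1L) stop("duplicate edge: ", ln)
      D[i, j] <- 1L
    } else if (tok[3] == "undirected") {
      if (U[i, j] == 1L) stop("duplicate edge: ", ln)
      U[i, j] <- U[j, i] <- 1L
    } else {
      stop("unknown edge type: ", tok[3])
    }
  }
  if (as == "directed" || (as == "auto" && sum(U) == 0L)) {
    if (sum(U) > 0L) stop("graph contains undirected edges")
    directed_graph(D, labels = labels)
  } else {
    partially_directed_graph(D, U, labels = labels)
  }
}

#' Write a score matrix as delimited text with labels
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @export
write_scores <- function(m, path) {
  utils::write.table(as.data.frame(m), path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Read a score matrix written by [write_scores()]
#' @param path file path.
#' @return numeric matrix.
#' @export
read_scores <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}

#' Generate canonical small fixtures
#'
#' Writes deterministic fixtures used in examples and tests: the 3-node
#' chain and collider with benchmark-style data, and 10-node
#' Erdős–Rényi / scale-free / small-world benchmark instances (truth edge
#' list, SEM weights, and a 110-row sample file of 100 observational rows
#' plus one knockout per node).
#'
#' @param out_dir writable output directory (created if absent).
#' @param seed master integer seed.
#' @return invisibly, the written file paths.
#' @export
make_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(name, truth, sem, samples) {
    p1 <- file.path(out_dir, paste0(name, "_truth.tsv"))
    p2 <- file.path(out_dir, paste0(name, "_weights.tsv"))
    p3 <- file.path(out_dir, paste0(name, "_samples.tsv"))
    write_graph(truth, p1)
    write_scores(sem$weights, p2)
    write_sampleset(samples, p3)
    c(p1, p2, p3)
  }
  chain <- directed_graph(rbind(c(0, 1, 0), c(0, 0, 1), c(0, 0, 0)),
                          labels = c("G1", "G2", "G3"))
  coll <- directed_graph(rbind(c(0, 0, 1), c(0, 0, 1), c(0, 0, 0)),
                         labels = c("G1", "G2", "G3"))
  for (nm in c("chain3", "collider3")) {
    g <- if (nm == "chain3") chain else coll
    sem <- random_sem(g, seed = substream_seed(seed, paste0(nm, "_sem")))
    s <- sample_observational(sem, 100, seed = substream_seed(seed, paste0(nm, "_obs")))
    for (v in 1:3) {
      s <- rbind_samples(s, sample_intervention(
        sem, v, n = 1, seed = substream_seed(seed, paste0(nm, "_int"), v)))
    }
    paths <- c(paths, emit(nm, g, sem, s))
  }
  kinds <- c(er10 = "erdos_renyi", ba10 = "scale_free", ws10 = "small_world")
  for (nm in names(kinds)) {
    bm <- make_benchmark(kinds[[nm]], 10, params = list(p = 0.5, k = 2),
                         n_obs = 100, seed = substream_seed(seed, nm))
    paths <- c(paths, emit(nm, bm$graph, bm$sem, bm$samples))
  }
  invisible(paths)
}

#' Write a run manifest
#'
#' One manifest per run: command, full parameter set, master seed, package
#' version, input/output digests and a timestamp, as JSON.  A manifest can
#' re-drive the identical run through [rerun_manifest()].
#'
#' @param path manifest output path.
#' @param command command name.
#' @param params named list of all parameters.
#' @param seed master seed.
#' @param inputs,outputs character vectors of file paths to digest.
#' @export
write_manifest <- function(path, command, params, seed = NULL,
                           inputs = character(0), outputs = character(0)) {
  digest <- function(fs) {
    fs <- fs[file.exists(fs)]
    if (length(fs) == 0L) return(NULL)
    as.list(tools::md5sum(fs))
  }
  man <- list(
    command = command,
    params = params,
    seed = seed,
    version = as.character(utils::packageVersion("spgies")),
    inputs = digest(inputs),
    outputs = digest(outputs),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

#' Re-run a command from its manifest
#'
#' @param path manifest file written by [write_manifest()].
#' @return the result of the re-driven CLI command.
#' @export
rerun_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  argv <- c(man$command, unlist(lapply(names(man$params), function(k) {
    v <- man$params[[k]]
    if (isTRUE(v)) paste0("--", k)
    else if (isFALSE(v) || is.null(v)) character(0)
    else c(paste0("--", k), as.character(v))
  })))
  if (!is.null(man$seed)) argv <- c(argv, "--seed", as.character(man$seed))
  cli_main(argv)
}
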