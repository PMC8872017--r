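# Genotype encoding of a recurrent cell and its DAG phenotype.
#
# A cell with N nodes is encoded as:
#   * activations: one of tanh / relu / identity / sigmoid per node,
#   * parents:     node k (k >= 2) selects a single predecessor in {1..k-1},
#                  so edges always point from a lower to a higher index and the
#                  graph is acyclic by construction,
#   * weight genes: one hidden x hidden matrix per POSSIBLE edge (all
#                  N(N-1)/2 ordered pairs j < k), plus the input and recurrent
#                  projections of node 1.
# Node 1 receives the cell input and previous state; nodes with no outgoing
# edge are terminal and the cell output is the average of their outputs.
# The genotype space therefore has 4^N * (N-1)! distinct (activation, parent)
# configurations.

#' Supported node activation functions
#' @export
ACTIVATIONS <- c("tanh", "relu", "identity", "sigmoid")

act_apply <- function(name, x) {
  switch(name,
    tanh = tanh(x),
    relu = pmax(x, 0),
    identity = x,
    sigmoid = 1 / (1 + exp(-x)),
    stop_config("unknown activation '%s'", name)
  )
}

# derivative w.r.t. the pre-activation, expressed through pre/out as convenient
act_grad <- function(name, pre, out) {
  switch(name,
    tanh = 1 - out * out,
    relu = (pre > 0) * 1,
    identity = array(1, dim = dim(pre) %||% length(pre)),
    sigmoid = out * (1 - out),
    stop_config("unknown activation '%s'", name)
  )
}

edge_key <- function(j, k) sprintf("e_%d_%d", j, k)

# fixed ordering of all weight-gene keys for a chromosome
weight_gene_keys <- function(N) {
  keys <- c("in", "rec")
  if (N >= 2) {
    for (k in 2:N) for (j in 1:(k - 1)) keys <- c(keys, edge_key(j, k))
  }
  keys
}

init_weight <- function(nrow, ncol) {
  matrix(stats::rnorm(nrow * ncol, sd = 1 / sqrt(nrow)), nrow, ncol)
}

#' Create a random chromosome
#'
#' Activations are uniform over the four functions, each parent gene uniform
#' over the admissible predecessors. When `hidden` is given, weight genes for
#' every possible edge (and the node-1 input/recurrent projections) are drawn
#' from the initialization distribution; otherwise the chromosome is
#' genotype-only (used for enumeration and surrogate-fitness searches).
#'
#' @param N node count (>= 1).
#' @param hidden hidden width for weight genes, or `NULL` for genotype-only.
#' @param n_features input width (required when `hidden` is given).
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @param id optional integer identifier.
#' @return an object of class `nasga_chromosome`.
#' @export
random_chromosome <- function(N, hidden = NULL, n_features = NULL,
                              seed = NULL, id = NA_integer_) {
  if (!is.numeric(N) || N < 1) stop_config("N must be >= 1")
  N <- as.integer(N)
  maybe_seed(seed)
  acts <- sample(ACTIVATIONS, N, replace = TRUE)
  parents <- if (N >= 2) {
    vapply(seq_len(N - 1), function(i) sample.int(i, 1), integer(1))
  } else integer(0)
  weights <- NULL
  if (!is.null(hidden)) {
    stopifnot(!is.null(n_features))
    weights <- list()
    for (key in weight_gene_keys(N)) {
      weights[[key]] <- if (key == "in") init_weight(n_features, hidden)
                        else init_weight(hidden, hidden)
    }
  }
  new_chromosome(N, acts, parents, weights, id = id)
}

new_chromosome <- function(N, activations, parents, weights = NULL,
                           fitness = NA_real_, id = NA_integer_) {
  ch <- list(N = as.integer(N), activations = activations,
             parents = as.integer(parents), weights = weights,
             fitness = fitness, id = id)
  class(ch) <- "nasga_chromosome"
  validate_chromosome(ch)
  ch
}

#' Validate a chromosome's structural invariants
#' @param ch a `nasga_chromosome`.
#' @return the chromosome, invisibly; errors on violation.
#' @export
validate_chromosome <- function(ch) {
  if (length(ch$activations) != ch$N)
    stop_config("need %d activation genes, got %d", ch$N, length(ch$activations))
  if (!all(ch$activations %in% ACTIVATIONS))
    stop_config("unknown activation gene")
  if (length(ch$parents) != max(ch$N - 1L, 0L))
    stop_config("need %d parent genes, got %d", ch$N - 1L, length(ch$parents))
  if (ch$N >= 2) {
    ok <- ch$parents >= 1L & ch$parents <= seq_len(ch$N - 1L)
    if (!all(ok)) stop_config("parent gene out of range at position %d",
                              which(!ok)[1])
  }
  if (!is.null(ch$weights)) {
    bad <- setdiff(names(ch$weights), weight_gene_keys(ch$N))
    if (length(bad)) stop_config("unknown weight genes: %s",
                                 paste(bad, collapse = ", "))
  }
  invisible(ch)
}

#' @export
print.nasga_chromosome <- function(x, ...) {
  cat(sprintf("<chromosome N=%d acts=[%s] parents=[%s] fitness=%s>\n",
              x$N, paste(x$activations, collapse = ","),
              paste(x$parents, collapse = ","),
              ifelse(is.na(x$fitness), "unset", sprintf("%.4f", x$fitness))))
  invisible(x)
}

#' Convert a chromosome to its adjacency-matrix form
#'
#' Returns an N x N integer matrix whose diagonal holds activation codes
#' (indices into [ACTIVATIONS]) and whose strictly upper-triangular entries
#' are 1 where the parent genes select an edge. The lower triangle is always
#' zero (acyclicity by construction).
#'
#' @param ch a `nasga_chromosome`.
#' @return integer matrix with attribute `activations`.
#' @export
to_adjacency <- function(ch) {
  validate_chromosome(ch)
  N <- ch$N
  adj <- matrix(0L, N, N)
  diag(adj) <- match(ch$activations, ACTIVATIONS)
  if (N >= 2) {
    for (k in 2:N) adj[ch$parents[k - 1L], k] <- 1L
  }
  attr(adj, "activations") <- ch$activations
  adj
}

#' Build the DAG phenotype from an adjacency matrix
#'
#' @param adj matrix from [to_adjacency()].
#' @return a `nasga_celldag`: nodes, activations, edge list, parent vector,
#'   and the terminal-node set (out-degree zero; the cell output averages
#'   these nodes).
#' @export
build_dag <- function(adj) {
  N <- nrow(adj)
  stopifnot(ncol(adj) == N)
  off <- adj
  diag(off) <- 0L
  if (any(off[lower.tri(off)] != 0))
    stop_config("cycle: adjacency has lower-triangular edges")
  acts <- attr(adj, "activations") %||% ACTIVATIONS[diag(adj)]
  parents <- integer(max(N - 1L, 0L))
  if (N >= 2) {
    for (k in 2:N) {
      p <- which(off[, k] != 0)
      if (length(p) != 1) stop_config("node %d must have exactly one parent", k)
      parents[k - 1L] <- p
    }
  }
  terminals <- which(rowSums(off) == 0)
  if (!length(terminals)) stop_config("empty terminal set")
  edges <- if (N >= 2) data.frame(from = parents, to = 2:N) else
    data.frame(from = integer(0), to = integer(0))
  structure(list(N = N, activations = acts, parents = parents,
                 edges = edges, terminals = as.integer(terminals)),
            class = "nasga_celldag")
}

#' Recover the (activations, parents) genotype from a DAG
#' @param dag a `nasga_celldag`.
#' @param weights optional weight-gene list to attach.
#' @return a `nasga_chromosome`.
#' @export
chromosome_from_dag <- function(dag, weights = NULL) {
  new_chromosome(dag$N, dag$activations, dag$parents, weights)
}

#' Exact size of the cell search space
#'
#' With N nodes, A activation choices per node and single-predecessor wiring,
#' there are A^N * (N-1)! distinct genotypes. For N = 12, A = 4 this is
#' 669,692,775,628,800 (~6.7e14), i.e. on the order of 1e14 models.
#'
#' @param N node count.
#' @param A number of activation functions (default 4).
#' @return exact count as a double (exact below 2^53).
#' @export
count_search_space <- function(N, A = 4) {
  stopifnot(N >= 1, A >= 1)
  res <- A^N * prod(seq_len(N - 1))
  if (res >= 2^53) warning("count exceeds exact double range")
  res
}

#' Exhaustively enumerate all genotypes of the cell space
#'
#' Testing oracle: streams every (activations, parents) combination exactly
#' once. Refuses spaces larger than `limit` genotypes.
#'
#' @param N node count.
#' @param A number of activations to use (first `A` of [ACTIVATIONS]).
#' @param limit refusal threshold (default 1e6).
#' @return list of `nasga_chromosome` (genotype-only).
#' @export
enumerate_space <- function(N, A = 4, limit = 1e6) {
  total <- count_search_space(N, A)
  if (total > limit) stop_config("space too large to enumerate (%g > %g)",
                                 total, limit)
  acts_pool <- ACTIVATIONS[seq_len(A)]
  act_grid <- do.call(expand.grid,
                      c(rep(list(acts_pool), N), stringsAsFactors = FALSE))
  parent_grid <- if (N >= 2) {
    do.call(expand.grid, lapply(seq_len(N - 1), seq_len))
  } else data.frame(row.names = 1)
  out <- vector("list", nrow(act_grid) * nrow(parent_grid))
  i <- 0L
  for (a in seq_len(nrow(act_grid))) {
    acts <- unlist(act_grid[a, ], use.names = FALSE)
    for (p in seq_len(nrow(parent_grid))) {
      i <- i + 1L
      parents <- if (N >= 2) as.integer(parent_grid[p, ]) else integer(0)
      out[[i]] <- new_chromosome(N, acts, parents)
    }
  }
  out
}

#' Serialize / restore a chromosome as JSON
#'
#' Weight genes are stored as flat arrays with dimensions; genotype-only
#' chromosomes omit the `weights` field.
#' @param ch a `nasga_chromosome`.
#' @param path file path.
#' @return `write_chromosome`: the path, invisibly; `read_chromosome`: the
#'   chromosome.
#' @export
write_chromosome <- function(ch, path) {
  obj <- list(N = ch$N, activations = ch$activations,
              parents = ch$parents, fitness = ch$fitness)
  if (!is.null(ch$weights)) {
    obj$weights <- lapply(ch$weights, function(w)
      list(dim = dim(w), data = as.numeric(w)))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_chromosome
#' @export
read_chromosome <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  weights <- NULL
  if (!is.null(obj$weights)) {
    weights <- lapply(obj$weights, function(w)
      matrix(w$data, w$dim[1], w$dim[2]))
  }
  new_chromosome(obj$N, obj$activations, obj$parents, weights,
                 fitness = obj$fitness %||% NA_real_)
}
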