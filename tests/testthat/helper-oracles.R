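# Independent oracles, deliberately naive implementations used only to
# check the package's fast paths.

# AUROC by exhaustive pairwise comparison (ties count 1/2)
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# earliest start of a >= min_run TRUE-run by brute-force scanning
oracle_onset <- function(flags, min_run = 5) {
  n <- length(flags)
  if (n >= min_run) {
    for (s in 1:(n - min_run + 1)) {
      if (all(flags[s:(s + min_run - 1)])) return(s - 1L)  # 0-based
    }
  }
  NA_integer_
}

# enumerate emitted sliding windows by direct rule application
oracle_windows <- function(L, horizon, onset) {
  out <- list()
  for (s in 0:max(L, 0)) {
    if (s + 5 + horizon > L) break
    if (!is.na(onset) && onset < s + 5) next
    label <- as.integer(!is.na(onset) && onset == s + 5 + horizon)
    out[[length(out) + 1]] <- c(start = s, label = label)
  }
  out
}

# reference DAG-cell interpreter: evaluates node values recursively per
# timestep, one input row at a time (no batching, no shared code with the
# package's forward pass)
oracle_cell_forward <- function(ch, weights, X_row) {
  # X_row: T x F matrix for a single sequence
  acts <- list(tanh = tanh, relu = function(x) pmax(x, 0),
               identity = function(x) x,
               sigmoid = function(x) 1 / (1 + exp(-x)))
  N <- ch$N
  H <- ncol(weights[["rec"]])
  children_of <- function(j) {
    if (N < 2) return(integer(0))
    which(vapply(2:N, function(k) ch$parents[k - 1] == j, logical(1))) + 1L
  }
  terminals <- Filter(function(j) length(children_of(j)) == 0, 1:N)
  h <- rep(0, H)
  for (t in seq_len(nrow(X_row))) {
    node_val <- vector("list", N)
    eval_node <- function(k) {
      if (!is.null(node_val[[k]])) return(node_val[[k]])
      v <- if (k == 1) {
        X_row[t, ] %*% weights[["in"]] + h %*% weights[["rec"]]
      } else {
        j <- ch$parents[k - 1]
        eval_node(j) %*% weights[[sprintf("e_%d_%d", j, k)]]
      }
      node_val[[k]] <<- acts[[ch$activations[k]]](as.numeric(v))
      node_val[[k]]
    }
    term_vals <- lapply(terminals, eval_node)
    h <- Reduce(`+`, term_vals) / length(term_vals)
  }
  logits <- as.numeric(h %*% weights[["head_W"]]) + weights[["head_b"]]
  e <- exp(logits - max(logits))
  list(h = h, prob = e / sum(e))
}
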