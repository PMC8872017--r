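# Child networks: a chromosome is materialized into a recurrent classifier
# whose per-timestep cell evaluates the DAG --
#   node 1:    h1 = f1(x_t W_in + h_{t-1} W_rec)
#   node k>1:  hk = fk(h_parent(k) W_{parent(k),k})
#   cell out:  h_t = mean over terminal nodes (out-degree 0)
# -- and the last h_t feeds a global softmax head over 2 classes. The cell
# output is also the recurrent state. Edge weights live in a shared store:
# once any child has learned an edge, later children that select the same
# edge start from the learned matrix (weight sharing across the population
# and across generations). Training is Adam + cross-entropy with early
# stopping on validation loss, all in plain R with hand-written
# backpropagation through time.

#' Create a shared weight store
#'
#' Keys are weight-gene names: `"in"`, `"rec"`, `"e_j_k"` for edges, plus the
#' reserved `"head_W"`/`"head_b"` classifier head. A version counter is
#' incremented on every [commit_weights()].
#'
#' @param hidden hidden width.
#' @param n_features input width.
#' @return a `nasga_weight_store` (environment).
#' @export
weight_store <- function(hidden, n_features) {
  st <- new.env(parent = emptyenv())
  st$map <- list()
  st$version <- 0L
  st$hidden <- as.integer(hidden)
  st$n_features <- as.integer(n_features)
  class(st) <- "nasga_weight_store"
  st
}

#' @export
print.nasga_weight_store <- function(x, ...) {
  cat(sprintf("<weight store hidden=%d features=%d keys=%d version=%d>\n",
              x$hidden, x$n_features, length(x$map), x$version))
  invisible(x)
}

store_get <- function(store, key) store$map[[key]]
store_set <- function(store, key, value) {
  store$map[[key]] <- value
  invisible(store)
}

#' Training configuration for child models
#'
#' Learning rate 0.01 with Adam and cross-entropy loss; training stops when
#' the best validation loss fails to improve for `patience` consecutive
#' epochs or when `max_epochs` is reached. During the search, children run
#' under a reduced `max_epochs` cap (the full 10/200 rule is used for final
#' retraining).
#'
#' @param hidden hidden width of the cell (default 16).
#' @param batch_size minibatch size (default 32).
#' @param lr learning rate (default 0.01).
#' @param patience epochs without validation-loss improvement before stopping
#'   (default 10).
#' @param max_epochs epoch cap (default 200).
#' @param seed RNG seed for init and shuffling.
#' @return a `nasga_train_config`.
#' @export
train_config <- function(hidden = 16, batch_size = 32, lr = 0.01,
                         patience = 10, max_epochs = 200, seed = 1) {
  if (patience < 1 || max_epochs < 1)
    stop_config("patience and max_epochs must be >= 1")
  structure(list(hidden = as.integer(hidden), batch_size = batch_size,
                 lr = lr, patience = patience, max_epochs = max_epochs,
                 seed = seed),
            class = "nasga_train_config")
}

# keys actually used by a chromosome's selected topology
selected_keys <- function(ch) {
  keys <- c("in", "rec")
  if (ch$N >= 2)
    keys <- c(keys, vapply(2:ch$N, function(k)
      edge_key(ch$parents[k - 1L], k), character(1)))
  keys
}

#' Materialize a trainable recurrent classifier from a chromosome
#'
#' Weight resolution per gene key: shared-store value if present; else the
#' chromosome's own weight gene (which then seeds the store); else a fresh
#' random init. The classifier head is global and lives in the store under
#' reserved keys.
#'
#' @param ch a `nasga_chromosome`.
#' @param store a [weight_store()].
#' @param config a [train_config()].
#' @param seed optional seed for random initialization of absent genes.
#' @return a `nasga_child_model` (environment with weights and topology).
#' @export
materialize_model <- function(ch, store, config, seed = NULL) {
  validate_chromosome(ch)
  H <- store$hidden
  Fi <- store$n_features
  stopifnot(H == config$hidden)
  maybe_seed(seed)
  model <- new.env(parent = emptyenv())
  model$chromosome <- ch
  model$hidden <- H
  model$n_features <- Fi
  dag <- build_dag(to_adjacency(ch))
  model$terminals <- dag$terminals
  w <- list()
  for (key in selected_keys(ch)) {
    shape <- if (key == "in") c(Fi, H) else c(H, H)
    val <- store_get(store, key)
    if (is.null(val)) {
      gene <- ch$weights[[key]]
      if (!is.null(gene)) {
        val <- gene
        store_set(store, key, gene)   # chromosome gene seeds the store
      } else {
        val <- init_weight(shape[1], shape[2])
      }
    }
    stopifnot(all(dim(val) == shape))
    w[[key]] <- val
  }
  if (is.null(store_get(store, "head_W"))) {
    store_set(store, "head_W", init_weight(H, 2))
    store_set(store, "head_b", numeric(2))
  }
  w[["head_W"]] <- store_get(store, "head_W")
  w[["head_b"]] <- store_get(store, "head_b")
  model$weights <- w
  class(model) <- "nasga_child_model"
  model
}

# forward pass over a batch; X is n x T x F. Returns probabilities and,
# when cache = TRUE, everything backprop needs.
cell_forward <- function(model, X, cache = FALSE) {
  ch <- model$chromosome
  N <- ch$N
  H <- model$hidden
  n <- dim(X)[1]; Tt <- dim(X)[2]
  w <- model$weights
  terminals <- model$terminals
  h_prev <- matrix(0, n, H)
  steps <- if (cache) vector("list", Tt) else NULL
  h_states <- if (cache) vector("list", Tt) else NULL
  for (t in seq_len(Tt)) {
    Xt <- matrix(X[, t, ], n)
    pre <- vector("list", N); out <- vector("list", N)
    pre[[1]] <- Xt %*% w[["in"]] + h_prev %*% w[["rec"]]
    out[[1]] <- act_apply(ch$activations[1], pre[[1]])
    if (N >= 2) {
      for (k in 2:N) {
        j <- ch$parents[k - 1L]
        pre[[k]] <- out[[j]] %*% w[[edge_key(j, k)]]
        out[[k]] <- act_apply(ch$activations[k], pre[[k]])
      }
    }
    h_t <- Reduce(`+`, out[terminals]) / length(terminals)
    if (cache) {
      steps[[t]] <- list(Xt = Xt, pre = pre, out = out, h_prev = h_prev)
      h_states[[t]] <- h_t
    }
    h_prev <- h_t
  }
  logits <- h_prev %*% w[["head_W"]] +
    matrix(w[["head_b"]], n, 2, byrow = TRUE)
  p <- softmax_rows(logits)
  if (!cache) return(list(prob = p))
  list(prob = p, logits = logits, steps = steps, h_states = h_states)
}

#' Positive-class scores of a model on an episode set
#' @param model a `nasga_child_model`.
#' @param es a complete `nasga_episodes`.
#' @return numeric vector of P(class = 1).
#' @export
predict_scores <- function(model, es) {
  cell_forward(model, es$x)$prob[, 2]
}

# backward pass; fw must come from cell_forward(cache = TRUE).
# y in {0,1}. Returns named list of gradients matching model$weights keys.
cell_backward <- function(model, X, y, fw) {
  ch <- model$chromosome
  N <- ch$N
  n <- dim(X)[1]; Tt <- dim(X)[2]
  w <- model$weights
  terminals <- model$terminals
  grads <- lapply(w, function(m) array(0, dim = dim(m) %||% length(m)))
  Y <- cbind(1 - y, y)
  dZ <- (fw$prob - Y) / n
  h_T <- fw$h_states[[Tt]]
  grads[["head_W"]] <- crossprod(h_T, dZ)
  grads[["head_b"]] <- colSums(dZ)
  dh_next <- dZ %*% t(w[["head_W"]])   # gradient flowing into h_t at t = Tt
  for (t in Tt:1) {
    st <- fw$steps[[t]]
    dOut <- vector("list", N)
    share <- dh_next / length(terminals)
    for (k in terminals) dOut[[k]] <- share
    dh_prev <- matrix(0, n, model$hidden)
    for (k in N:1) {
      if (is.null(dOut[[k]])) next
      g <- dOut[[k]] * act_grad(ch$activations[k], st$pre[[k]], st$out[[k]])
      if (k > 1) {
        j <- ch$parents[k - 1L]
        ekey <- edge_key(j, k)
        grads[[ekey]] <- grads[[ekey]] + crossprod(st$out[[j]], g)
        dOut[[j]] <- (dOut[[j]] %||% 0) + g %*% t(w[[ekey]])
      } else {
        grads[["in"]] <- grads[["in"]] + crossprod(st$Xt, g)
        grads[["rec"]] <- grads[["rec"]] + crossprod(st$h_prev, g)
        dh_prev <- dh_prev + g %*% t(w[["rec"]])
      }
    }
    dh_next <- dh_prev
  }
  grads
}

model_loss_acc <- function(model, es) {
  p <- cell_forward(model, es$x)$prob
  list(loss = cross_entropy(p, es$label),
       acc = mean((p[, 2] >= 0.5) == (es$label == 1)))
}

#' Train a child model and score its fitness
#'
#' Adam + cross-entropy minibatch training with early stopping: stop when the
#' best validation loss has not improved for `patience` consecutive epochs,
#' or at `max_epochs`. The weights achieving the best validation loss are
#' restored into the model. Fitness is the validation accuracy at that point.
#'
#' @param model a `nasga_child_model` (modified in place).
#' @param train,validation disjoint, complete `nasga_episodes`.
#' @param config a [train_config()].
#' @return a `FitnessRecord` list: `chromosome_id`, `accuracy`, `epochs`,
#'   `best_val_loss`.
#' @export
train_child <- function(model, train, validation, config) {
  if (!n_episodes(train) || !n_episodes(validation))
    stop_config("train and validation splits must be non-empty")
  set.seed(as.integer(config$seed))
  params <- model$weights
  opt <- adam_new(params, lr = config$lr)
  n <- n_episodes(train)
  best_loss <- Inf; best_acc <- NA_real_; best_params <- params
  stale <- 0L; ep <- 0L
  while (ep < config$max_epochs) {
    ep <- ep + 1L
    ord <- sample.int(n)
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      Xb <- train$x[idx, , , drop = FALSE]
      yb <- train$label[idx]
      fw <- cell_forward(model, Xb, cache = TRUE)
      grads <- cell_backward(model, Xb, yb, fw)
      params <- adam_step(opt, params, grads)
      model$weights <- params
    }
    va <- model_loss_acc(model, validation)
    if (va$loss < best_loss - 1e-9) {
      best_loss <- va$loss; best_acc <- va$acc; best_params <- params
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$patience) break
    }
  }
  model$weights <- best_params
  list(chromosome_id = model$chromosome$id, accuracy = best_acc,
       epochs = ep, best_val_loss = best_loss)
}

#' Commit a trained model's weights to the shared store and chromosome
#'
#' Writes the matrices of the chromosome's selected edges, the node-1
#' projections and the global head back to the store (version + 1) and copies
#' them into the chromosome's weight genes, so both sharing routes (store
#' lookup and genetic inheritance) carry the learned values.
#'
#' @param model a trained `nasga_child_model`.
#' @param store the [weight_store()].
#' @return the updated chromosome (with learned weight genes).
#' @export
commit_weights <- function(model, store) {
  ch <- model$chromosome
  if (is.null(ch$weights)) ch$weights <- list()
  for (key in selected_keys(ch)) {
    store_set(store, key, model$weights[[key]])
    ch$weights[[key]] <- model$weights[[key]]
  }
  store_set(store, "head_W", model$weights[["head_W"]])
  store_set(store, "head_b", model$weights[["head_b"]])
  store$version <- store$version + 1L
  model$chromosome <- ch
  ch
}
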