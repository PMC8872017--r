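# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed and a purpose label
#'
#' One master seed drives a whole run; each component (generation, selection,
#' training, bootstrap, ...) forks its own stream so that component-level
#' tests are independently seedable. The result is always in [1, 2^31 - 2].
#'
#' @param seed integer master seed.
#' @param label character purpose label.
#' @return integer sub-seed.
#' @export
fork_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  h <- 0
  for (v in utf8ToInt(label)) h <- (h * 131 + v) %% 2100000000
  as.integer((abs(seed) * 7919 + h) %% 2147483629 + 1)
}

# set.seed unless seed is NULL (then the caller's RNG stream is used)
maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

# numerically stable row-wise softmax for an n x k matrix
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean cross-entropy of softmax probabilities p (n x 2) against labels y in {0,1}
cross_entropy <- function(p, y) {
  idx <- cbind(seq_along(y), y + 1L)
  -mean(log(pmax(p[idx], 1e-12)))
}

# Adam optimizer state over a named list of arrays; returns an environment
adam_new <- function(params, lr = 0.01, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(w) array(0, dim = dim(w) %||% length(w)))
  st$v <- st$m
  st$t <- 0L
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st
}

adam_step <- function(st, params, grads) {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  corr1 <- 1 - b1^st$t
  corr2 <- 1 - b2^st$t
  for (k in names(grads)) {
    g <- grads[[k]]
    st$m[[k]] <- b1 * st$m[[k]] + (1 - b1) * g
    st$v[[k]] <- b2 * st$v[[k]] + (1 - b2) * g * g
    mhat <- st$m[[k]] / corr1
    vhat <- st$v[[k]] / corr2
    params[[k]] <- params[[k]] - st$lr * mhat / (sqrt(vhat) + st$eps)
  }
  params
}
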