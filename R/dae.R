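# Denoising autoencoder, trained as an independent preprocessing module:
# episodes are flattened (5 h x 40 features -> 200), corrupted with Gaussian
# noise, and the network is trained to reconstruct the clean input. Once
# trained it is applied uniformly to every split. Plain R implementation:
# tanh hidden layers, linear output, Adam on minibatch MSE.

#' Denoising-autoencoder configuration
#'
#' Symmetric architecture `d -> widths... -> bottleneck -> rev(widths)... ->
#' d`. Defaults: one intermediate width of 128 and a bottleneck at half the
#' flattened episode width, Gaussian corruption sd 0.1 (inputs are z-scored,
#' so this is 10% of a typical feature sd).
#'
#' @param widths integer vector of intermediate encoder widths.
#' @param bottleneck bottleneck width; default `NA` = half the input width.
#' @param noise_sd corruption noise sd (>= 0).
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param seed RNG seed for init, corruption and shuffling.
#' @return a `nasga_dae_config`.
#' @export
dae_config <- function(widths = 128, bottleneck = NA, noise_sd = 0.1,
                       epochs = 30, lr = 1e-3, batch_size = 64, seed = 1) {
  if (any(widths < 1) || (!is.na(bottleneck) && bottleneck < 1))
    stop_config("layer widths must be >= 1")
  if (noise_sd < 0) stop_config("noise_sd must be >= 0")
  structure(list(widths = as.integer(widths), bottleneck = bottleneck,
                 noise_sd = noise_sd, epochs = epochs, lr = lr,
                 batch_size = batch_size, seed = seed),
            class = "nasga_dae_config")
}

dae_layer_sizes <- function(d, config) {
  bn <- if (is.na(config$bottleneck)) max(1L, d %/% 2L) else config$bottleneck
  c(d, config$widths, bn, rev(config$widths), d)
}

dae_forward <- function(weights, X) {
  L <- length(weights$W)
  a <- list(X)
  for (l in seq_len(L)) {
    z <- a[[l]] %*% weights$W[[l]] +
      matrix(weights$b[[l]], nrow(X), length(weights$b[[l]]), byrow = TRUE)
    a[[l + 1]] <- if (l < L) tanh(z) else z
  }
  a
}

#' Train a denoising autoencoder on the training split
#'
#' @param train a complete, normalized `nasga_episodes` (training split).
#' @param config a [dae_config()].
#' @return a `nasga_dae` (weights, layer sizes, training loss trace).
#' @export
train_dae <- function(train, config = dae_config()) {
  stopifnot(inherits(config, "nasga_dae_config"))
  set.seed(as.integer(config$seed))
  X <- matrix(train$x, n_episodes(train))   # n x (5*40)
  d <- ncol(X)
  sizes <- dae_layer_sizes(d, config)
  L <- length(sizes) - 1
  weights <- list(W = vector("list", L), b = vector("list", L))
  for (l in seq_len(L)) {
    weights$W[[l]] <- init_weight(sizes[l], sizes[l + 1])
    weights$b[[l]] <- numeric(sizes[l + 1])
  }
  flat <- function(w) c(stats::setNames(w$W, paste0("W", seq_len(L))),
                        stats::setNames(w$b, paste0("b", seq_len(L))))
  unflat <- function(p) list(W = unname(p[paste0("W", seq_len(L))]),
                             b = unname(p[paste0("b", seq_len(L))]))
  params <- flat(weights)
  opt <- adam_new(params, lr = config$lr)
  n <- nrow(X)
  losses <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      clean <- X[idx, , drop = FALSE]
      noisy <- clean + matrix(stats::rnorm(length(clean), 0, config$noise_sd),
                              nrow(clean))
      w <- unflat(params)
      a <- dae_forward(w, noisy)
      out <- a[[L + 1]]
      diff <- out - clean
      ep_loss <- ep_loss + mean(diff^2); nb <- nb + 1
      # backprop: dz at output layer, tanh grads inside
      grads <- list()
      dz <- 2 * diff / length(diff)
      for (l in L:1) {
        grads[[paste0("W", l)]] <- crossprod(a[[l]], dz)
        grads[[paste0("b", l)]] <- colSums(dz)
        if (l > 1) dz <- (dz %*% t(w$W[[l]])) * (1 - a[[l]]^2)
      }
      params <- adam_step(opt, params, grads)
    }
    losses[ep] <- ep_loss / nb
  }
  structure(list(weights = unflat(params), sizes = sizes, config = config,
                 loss = losses),
            class = "nasga_dae")
}

#' Denoise an episode set with a trained autoencoder
#'
#' Output shape equals input shape; the same module is applied to train,
#' validation and test data.
#'
#' @param es a complete, normalized `nasga_episodes`.
#' @param dae a `nasga_dae`.
#' @return denoised `nasga_episodes`.
#' @export
denoise <- function(es, dae) {
  X <- matrix(es$x, n_episodes(es))
  if (ncol(X) != dae$sizes[1])
    stop_config("episode width %d does not match trained DAE width %d",
                ncol(X), dae$sizes[1])
  a <- dae_forward(dae$weights, X)
  es$x <- array(a[[length(a)]], dim = dim(es$x), dimnames = dimnames(es$x))
  es
}

#' Persist / restore a trained DAE as JSON
#' @param dae a `nasga_dae`.
#' @param path file path.
#' @return `write_dae`: path invisibly; `read_dae`: the `nasga_dae`.
#' @export
write_dae <- function(dae, path) {
  obj <- list(sizes = dae$sizes,
              W = lapply(dae$weights$W, function(w)
                list(dim = dim(w), data = as.numeric(w))),
              b = dae$weights$b)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dae
#' @export
read_dae <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  W <- lapply(obj$W, function(w)
    matrix(unlist(w$data), w$dim[[1]], w$dim[[2]]))
  b <- lapply(obj$b, function(b) as.numeric(unlist(b)))
  structure(list(weights = list(W = W, b = b),
                 sizes = as.integer(unlist(obj$sizes)),
                 config = NULL, loss = NULL),
            class = "nasga_dae")
}
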