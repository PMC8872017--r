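# Genetic-algorithm search over cell genotypes: elitism (top 10% copied
# unchanged), roulette-wheel parent selection with the wheel compressed so
# the largest area is at most 3x the smallest (prevents starvation of
# low-fitness chromosomes), per-property single-point crossover (activations
# with activations, connections with connections, weight genes with weight
# genes), and single-gene mutation. Fitness is the validation accuracy of
# the trained child network.

#' GA configuration
#'
#' Defaults: population 100, elite fraction 0.10, crossover rate 0.7,
#' roulette cap 3. The mutation rate is not pinned down by the method
#' description; 0.1 is the package default and it is always reported in the
#' per-generation log. The outer loop stops after `plateau_patience`
#' generations without best-fitness improvement or at `max_generations`.
#'
#' @param pop_size population size (>= 2).
#' @param elite_frac elite fraction in (0, 1).
#' @param crossover_rate probability a selected pair is crossed (else cloned).
#' @param mutation_rate probability a child undergoes a single-gene mutation.
#' @param roulette_cap max/min wheel-area ratio after rescaling (> 1).
#' @param max_generations generation cap.
#' @param plateau_patience generations without improvement before stopping.
#' @param seed master seed.
#' @return a `nasga_ga_config`.
#' @export
ga_config <- function(pop_size = 100, elite_frac = 0.10, crossover_rate = 0.7,
                      mutation_rate = 0.1, roulette_cap = 3,
                      max_generations = 50, plateau_patience = 10, seed = 1) {
  if (pop_size < 2) stop_config("pop_size must be >= 2")
  if (elite_frac <= 0 || elite_frac >= 1)
    stop_config("elite_frac must be in (0, 1)")
  if (crossover_rate < 0 || crossover_rate > 1 ||
      mutation_rate < 0 || mutation_rate > 1)
    stop_config("rates must be in [0, 1]")
  if (roulette_cap <= 1) stop_config("roulette_cap must be > 1")
  structure(list(pop_size = as.integer(pop_size), elite_frac = elite_frac,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate, roulette_cap = roulette_cap,
                 max_generations = max_generations,
                 plateau_patience = plateau_patience, seed = seed),
            class = "nasga_ga_config")
}

#' Initialize a random population
#'
#' @param config a [ga_config()].
#' @param N node count per cell.
#' @param hidden,n_features dimensions for weight genes (`NULL` for
#'   genotype-only populations, e.g. surrogate-fitness tests).
#' @param seed optional seed.
#' @return a `nasga_population`: list with `generation`, `chromosomes`,
#'   `best` (best-so-far chromosome or NULL).
#' @export
init_population <- function(config, N, hidden = NULL, n_features = NULL,
                            seed = NULL) {
  maybe_seed(seed)
  chs <- lapply(seq_len(config$pop_size), function(i)
    random_chromosome(N, hidden = hidden, n_features = n_features, id = i))
  structure(list(generation = 0L, chromosomes = chs, best = NULL,
                 next_id = config$pop_size + 1L),
            class = "nasga_population")
}

#' @export
print.nasga_population <- function(x, ...) {
  fits <- vapply(x$chromosomes, function(c) c$fitness, numeric(1))
  cat(sprintf("<population gen=%d size=%d best=%s>\n", x$generation,
              length(x$chromosomes),
              if (all(is.na(fits))) "unset" else sprintf("%.4f",
                                                         max(fits, na.rm = TRUE))))
  invisible(x)
}

#' Compress fitness scores into roulette-wheel areas
#'
#' If the max/min ratio exceeds `cap` (or the minimum is zero), an additive
#' shift `b` is applied so that `max + b = cap * (min + b)`; otherwise the
#' scores pass through unchanged. Ordering is preserved and all areas are
#' strictly positive. All-equal scores yield uniform areas.
#'
#' @param fitnesses non-negative scores, at least one positive (all-zero
#'   input yields uniform areas).
#' @param cap maximum area ratio (default 3).
#' @return positive wheel areas.
#' @export
rescale_fitness <- function(fitnesses, cap = 3) {
  stopifnot(all(fitnesses >= 0))
  mx <- max(fitnesses); mn <- min(fitnesses)
  if (mx == mn) return(if (mx == 0) rep(1, length(fitnesses)) else fitnesses)
  if (mn > 0 && mx / mn <= cap) return(fitnesses)
  b <- (mx - cap * mn) / (cap - 1)
  fitnesses + b
}

#' Roulette-wheel draw
#'
#' @param areas positive wheel areas.
#' @param n number of draws (with replacement).
#' @return selected indices, drawn with probability proportional to area.
#' @export
roulette_select <- function(areas, n = 1) {
  stopifnot(all(areas > 0))
  if (length(areas) == 1) return(rep(1L, n))
  sample.int(length(areas), n, replace = TRUE, prob = areas)
}

#' Elite selection
#'
#' The `max(1, floor(fraction * size))` highest-fitness chromosomes, ties
#' broken by lower chromosome id, copied unchanged.
#'
#' @param population a `nasga_population` with all fitnesses evaluated.
#' @param fraction elite fraction.
#' @return list of elite chromosomes.
#' @export
elite_select <- function(population, fraction) {
  chs <- population$chromosomes
  fits <- vapply(chs, function(c) c$fitness, numeric(1))
  if (anyNA(fits)) stop_config("elite selection requires evaluated fitness")
  ids <- vapply(chs, function(c) as.numeric(c$id %||% NA), numeric(1))
  k <- max(1L, floor(fraction * length(chs)))
  ord <- order(-fits, ids)
  chs[ord[seq_len(k)]]
}

#' Per-property single-point crossover
#'
#' Applied independently to each genotype property (activation sequence,
#' parent-connection sequence, weight-gene sequence): a cut point is drawn
#' uniformly in `{1..len-1}` and the genes after the cut are swapped.
#' Because position i of the connection sequence always holds a value in
#' `{1..i}`, swapping cannot create a cycle. Properties of length < 2 pass
#' through unchanged.
#'
#' @param a,b parent chromosomes with equal N.
#' @param seed optional seed.
#' @return list of two child chromosomes (fitness unset).
#' @export
crossover <- function(a, b, seed = NULL) {
  if (a$N != b$N) stop_config("crossover requires equal N")
  maybe_seed(seed)
  swap_tail <- function(x, y) {
    len <- length(x)
    if (len >= 2) {
      cut <- sample.int(len - 1L, 1)
      tail_idx <- (cut + 1L):len
      tmp <- x[tail_idx]; x[tail_idx] <- y[tail_idx]; y[tail_idx] <- tmp
    }
    list(x, y)
  }
  acts <- swap_tail(a$activations, b$activations)
  pars <- swap_tail(a$parents, b$parents)
  wa <- a$weights; wb <- b$weights
  if (!is.null(wa) && !is.null(wb)) {
    keys <- intersect(weight_gene_keys(a$N),
                      intersect(names(wa), names(wb)))
    if (length(keys) >= 2) {
      cut <- sample.int(length(keys) - 1L, 1)
      for (key in keys[(cut + 1L):length(keys)]) {
        tmp <- wa[[key]]; wa[[key]] <- wb[[key]]; wb[[key]] <- tmp
      }
    }
  }
  list(new_chromosome(a$N, acts[[1]], pars[[1]], wa, id = a$id),
       new_chromosome(b$N, acts[[2]], pars[[2]], wb, id = b$id))
}

#' Single-gene mutation
#'
#' With probability `rate`, one gene is picked uniformly across all three
#' properties: an activation gene is replaced by one of the other three
#' functions, a connection gene at position i by a different value in
#' `{1..i}` (a no-op when i = 1), a weight gene by a fresh random matrix.
#'
#' @param ch a `nasga_chromosome`.
#' @param rate mutation probability.
#' @param seed optional seed.
#' @return the (possibly) mutated chromosome, fitness cleared on change.
#' @export
mutate <- function(ch, rate, seed = NULL) {
  maybe_seed(seed)
  if (stats::runif(1) >= rate) return(ch)
  n_act <- ch$N
  n_par <- length(ch$parents)
  wkeys <- if (!is.null(ch$weights))
    intersect(weight_gene_keys(ch$N), names(ch$weights)) else character(0)
  total <- n_act + n_par + length(wkeys)
  g <- sample.int(total, 1)
  if (g <= n_act) {
    others <- setdiff(ACTIVATIONS, ch$activations[g])
    ch$activations[g] <- sample(others, 1)
  } else if (g <= n_act + n_par) {
    i <- g - n_act
    if (i > 1) {
      choices <- setdiff(seq_len(i), ch$parents[i])
      ch$parents[i] <- if (length(choices) == 1) choices else
        sample(choices, 1)
    }
  } else {
    key <- wkeys[g - n_act - n_par]
    old <- ch$weights[[key]]
    ch$weights[[key]] <- init_weight(nrow(old), ncol(old))
  }
  ch$fitness <- NA_real_
  ch
}

#' Produce the next generation
#'
#' Elites are copied unchanged; the remaining slots are filled by
#' roulette-selected parent pairs that undergo crossover with probability
#' `crossover_rate` (otherwise they pass through as clones) followed by
#' mutation. Population size is preserved.
#'
#' @param population evaluated `nasga_population`.
#' @param config a [ga_config()].
#' @param seed optional seed.
#' @return the next `nasga_population` (elites keep their fitness).
#' @export
next_generation <- function(population, config, seed = NULL) {
  maybe_seed(seed)
  chs <- population$chromosomes
  size <- length(chs)
  elites <- elite_select(population, config$elite_frac)
  fits <- vapply(chs, function(c) c$fitness, numeric(1))
  areas <- rescale_fitness(fits, config$roulette_cap)
  nxt <- elites
  next_id <- population$next_id
  while (length(nxt) < size) {
    pi <- roulette_select(areas, 2)
    pa <- chs[[pi[1]]]; pb <- chs[[pi[2]]]
    if (stats::runif(1) < config$crossover_rate) {
      kids <- crossover(pa, pb)
    } else {
      kids <- list(pa, pb)
    }
    for (kid in kids) {
      if (length(nxt) >= size) break
      kid <- mutate(kid, config$mutation_rate)
      kid$id <- next_id; next_id <- next_id + 1L
      nxt[[length(nxt) + 1L]] <- kid
    }
  }
  structure(list(generation = population$generation + 1L, chromosomes = nxt,
                 best = population$best, next_id = next_id),
            class = "nasga_population")
}

#' Evolve a population against an arbitrary fitness function
#'
#' The engine behind [run_search()], also usable with surrogate fitness
#' functions for validation studies. Chromosomes with unset fitness are
#' evaluated by `fitness_fun(chromosome)`; elites carry their fitness over
#' and are not re-evaluated.
#'
#' @param fitness_fun function(chromosome) -> fitness in \[0, 1\].
#' @param config a [ga_config()].
#' @param N node count.
#' @param hidden,n_features weight-gene dimensions or `NULL`.
#' @param on_generation optional callback(population, stats_row).
#' @return list: `best` chromosome, `stats` data.frame (one row per
#'   generation: best/mean/min fitness, mutation rate, stop reason on the
#'   last row).
#' @export
ga_evolve <- function(fitness_fun, config, N, hidden = NULL,
                      n_features = NULL, on_generation = NULL) {
  set.seed(as.integer(fork_seed(config$seed, "ga")))
  pop <- init_population(config, N, hidden, n_features)
  best <- NULL
  best_fit <- -Inf
  stale <- 0L
  stats_rows <- list()
  for (gen in seq_len(config$max_generations)) {
    pop$generation <- gen - 1L
    for (i in seq_along(pop$chromosomes)) {
      if (is.na(pop$chromosomes[[i]]$fitness))
        pop$chromosomes[[i]]$fitness <- fitness_fun(pop$chromosomes[[i]])
    }
    fits <- vapply(pop$chromosomes, function(c) c$fitness, numeric(1))
    gen_best <- max(fits)
    if (gen_best > best_fit + 1e-12) {
      best_fit <- gen_best
      best <- pop$chromosomes[[which.max(fits)]]
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
    pop$best <- best
    row <- data.frame(generation = gen - 1L, best = gen_best,
                      best_so_far = best_fit, mean = mean(fits),
                      min = min(fits), mutation_rate = config$mutation_rate)
    stats_rows[[gen]] <- row
    if (!is.null(on_generation)) on_generation(pop, row)
    if (stale >= config$plateau_patience) break
    if (gen == config$max_generations) break
    pop <- next_generation(pop, config)
  }
  list(best = best, best_fitness = best_fit,
       stats = do.call(rbind, stats_rows), population = pop)
}

#' Architecture search over preprocessed episodes
#'
#' The full search loop: every unevaluated chromosome is materialized against
#' the shared weight store, trained briefly on the training split, scored on
#' validation accuracy (its fitness) and its learned weights are committed
#' back to the store; then selection/crossover/mutation produce the next
#' generation until the plateau or generation cap.
#'
#' @param episodes a preprocessed, split `nasga_episodes`.
#' @param config a [ga_config()].
#' @param tconfig a [train_config()]; `max_epochs` here is the per-child
#'   cap during search (default 10 via [search_train_config()]).
#' @param N node count per cell (the reference experiment uses 12; desk-scale
#'   runs use fewer).
#' @param store optional pre-existing [weight_store()].
#' @return list: `best` chromosome, `stats` log, `store`, plus a
#'   `fitness_log` of per-child records.
#' @export
run_search <- function(episodes, config, tconfig, N, store = NULL) {
  train <- episode_split(episodes, "train")
  val <- episode_split(episodes, "validation")
  if (!n_episodes(train) || !n_episodes(val))
    stop_config("episodes must carry non-empty train and validation splits")
  Fi <- length(episodes$features)
  if (is.null(store)) store <- weight_store(tconfig$hidden, Fi)
  fitness_log <- list()
  eval_child <- function(ch) {
    model <- materialize_model(ch, store, tconfig,
                               seed = fork_seed(config$seed,
                                                paste0("init", ch$id)))
    tc <- tconfig
    tc$seed <- fork_seed(config$seed, paste0("train", ch$id))
    rec <- train_child(model, train, val, tc)
    commit_weights(model, store)
    fitness_log[[length(fitness_log) + 1L]] <<- rec
    rec$accuracy
  }
  res <- ga_evolve(eval_child, config, N, hidden = tconfig$hidden,
                   n_features = Fi)
  res$store <- store
  res$fitness_log <- do.call(rbind, lapply(fitness_log, as.data.frame))
  res
}

#' Child training configuration used during search
#'
#' Same regime as [train_config()] but with a small epoch cap (default 10)
#' so a desk-scale search stays tractable; the full patience-10 / 200-epoch
#' rule is reserved for final retraining of the selected architecture.
#' @param ... overrides passed to [train_config()].
#' @param max_epochs per-child epoch cap during search.
#' @return a `nasga_train_config`.
#' @export
search_train_config <- function(..., max_epochs = 10) {
  train_config(..., max_epochs = max_epochs)
}
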