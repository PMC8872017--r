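# Fixtures built in code at test time.

# toy episode sets with a planted mean offset in the positive class;
# linearly separable for offset >= ~1.5
make_toy_episodes <- function(n = 120, n_features = 6, offset = 2, seed = 42,
                              split = TRUE) {
  set.seed(seed)
  label <- rep(0:1, length.out = n)
  x <- array(stats::rnorm(n * 5 * n_features), c(n, 5, n_features),
             dimnames = list(NULL, NULL, paste0("f", seq_len(n_features))))
  x[label == 1, , 1] <- x[label == 1, , 1] + offset
  es <- nasga:::new_episode_set(x, label, patient_id = seq_len(n),
                                admission_id = seq_len(n),
                                start = rep(0L, n), horizon = 3)
  if (split) es <- split_dataset(es, seed = seed + 1)
  es
}

# smooth sinusoid episodes (clean + noisy pair) for DAE/GPR tests; a fixed
# frequency keeps the clean manifold low-dimensional (one phase per feature)
make_sinusoid_episodes <- function(n = 80, n_features = 8, noise_sd = 0.3,
                                   seed = 7, freq = 0.5) {
  set.seed(seed)
  clean <- array(0, c(n, 5, n_features),
                 dimnames = list(NULL, NULL, paste0("f", seq_len(n_features))))
  for (i in seq_len(n)) for (j in seq_len(n_features)) {
    phase <- stats::runif(1, 0, 2 * pi)
    clean[i, , j] <- sin(freq * (0:4) + phase)
  }
  noisy <- clean + array(stats::rnorm(length(clean), 0, noise_sd), dim(clean))
  mk <- function(x) nasga:::new_episode_set(
    x, rep(0:1, length.out = n), seq_len(n), seq_len(n), rep(0L, n), 0,
    split = rep("train", n))
  list(clean = mk(clean), noisy = mk(noisy))
}

# memoized mid-size synthetic cohort shared across test files
.fixture_env <- new.env()
cached_cohort <- function(n_patients = 400, prevalence = 0.2, seed = 2024) {
  key <- sprintf("cohort_%d_%s_%d", n_patients, prevalence, seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_cohort(
      synth_config(n_patients = n_patients, sepsis_prevalence = prevalence,
                   seed = seed))
  }
  .fixture_env[[key]]
}
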