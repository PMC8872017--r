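test_that("cell forward matches the reference DAG interpreter", {
  set.seed(31)
  for (i in 1:20) {
    N <- sample(1:4, 1)
    H <- sample(2:8, 1)
    Fi <- sample(2:5, 1)
    ch <- random_chromosome(N, hidden = H, n_features = Fi)
    st <- weight_store(H, Fi)
    m <- materialize_model(ch, st, train_config(hidden = H))
    X <- array(stats::rnorm(3 * 4 * Fi), c(3, 4, Fi))
    p <- nasga:::cell_forward(m, X)$prob
    for (r in 1:3) {
      ref <- oracle_cell_forward(ch, m$weights, matrix(X[r, , ], 4))
      expect_lt(max(abs(p[r, ] - ref$prob)), 1e-5)
    }
  }
})

test_that("analytic gradients agree with finite differences", {
  set.seed(8)
  ch <- random_chromosome(4, hidden = 5, n_features = 3)
  st <- weight_store(5, 3)
  m <- materialize_model(ch, st, train_config(hidden = 5))
  X <- array(stats::rnorm(4 * 5 * 3), c(4, 5, 3))
  y <- c(0, 1, 1, 0)
  fw <- nasga:::cell_forward(m, X, cache = TRUE)
  gr <- nasga:::cell_backward(m, X, y, fw)
  loss_at <- function() {
    p <- nasga:::cell_forward(m, X)$prob
    -mean(log(p[cbind(seq_along(y), y + 1)]))
  }
  for (key in setdiff(names(m$weights), "head_b")) {
    i <- sample(nrow(m$weights[[key]]), 1)
    j <- sample(ncol(m$weights[[key]]), 1)
    w0 <- m$weights[[key]][i, j]
    eps <- 1e-6
    m$weights[[key]][i, j] <- w0 + eps; up <- loss_at()
    m$weights[[key]][i, j] <- w0 - eps; dn <- loss_at()
    m$weights[[key]][i, j] <- w0
    expect_lt(abs((up - dn) / (2 * eps) - gr[[key]][i, j]), 1e-5)
  }
})

test_that("identity chain on constant input is a fixed point", {
  # chain 1->2->3, all identity activations, identity edge weights, zero
  # recurrence: h_t equals the input projection at every timestep
  H <- 3
  ch <- nasga:::new_chromosome(3, rep("identity", 3), c(1L, 2L))
  st <- weight_store(H, H)
  m <- materialize_model(ch, st, train_config(hidden = H))
  m$weights[["in"]] <- diag(H)
  m$weights[["rec"]] <- matrix(0, H, H)
  m$weights[["e_1_2"]] <- diag(H)
  m$weights[["e_2_3"]] <- diag(H)
  x_const <- c(0.3, -1, 2)
  X <- array(rep(x_const, each = 2 * 6), c(2, 6, H))
  fw <- nasga:::cell_forward(m, X, cache = TRUE)
  for (t in 1:6) expect_equal(fw$h_states[[t]][1, ], x_const)
})

test_that("cell output averages the terminal nodes", {
  ch <- nasga:::new_chromosome(4, rep("identity", 4), c(1L, 1L, 2L))
  st <- weight_store(2, 2)
  m <- materialize_model(ch, st, train_config(hidden = 2))
  X <- array(stats::rnorm(1 * 1 * 2), c(1, 1, 2))
  fw <- nasga:::cell_forward(m, X, cache = TRUE)
  out <- fw$steps[[1]]$out
  expect_identical(m$terminals, c(3L, 4L))
  expect_equal(fw$h_states[[1]], (out[[3]] + out[[4]]) / 2)
})

test_that("weight store shares learned edges across chromosomes", {
  Fi <- 3; H <- 4
  st <- weight_store(H, Fi)
  tc <- train_config(hidden = H, max_epochs = 2, seed = 1)
  ch_a <- nasga:::new_chromosome(3, c("tanh", "relu", "tanh"), c(1L, 2L))
  ch_b <- nasga:::new_chromosome(3, c("sigmoid", "relu", "identity"),
                                 c(1L, 2L))  # same edges (1,2), (2,3)
  m_a <- materialize_model(ch_a, st, tc, seed = 2)
  es <- make_toy_episodes(n = 40, n_features = Fi)
  train_child(m_a, episode_split(es, "train"),
              episode_split(es, "validation"), tc)
  v0 <- st$version
  keys_before <- st$map
  commit_weights(m_a, st)
  expect_identical(st$version, v0 + 1L)
  # commit touches only the selected keys and the head
  touched <- c("in", "rec", "e_1_2", "e_2_3", "head_W", "head_b")
  for (k in setdiff(names(keys_before), touched))
    expect_identical(st$map[[k]], keys_before[[k]])
  m_b <- materialize_model(ch_b, st, tc, seed = 3)
  expect_identical(m_b$weights[["e_1_2"]], m_a$weights[["e_1_2"]])
  expect_identical(m_b$weights[["e_2_3"]], m_a$weights[["e_2_3"]])

  # commit then rematerialize: identical forward outputs
  m_a2 <- materialize_model(m_a$chromosome, st, tc, seed = 99)
  X <- array(stats::rnorm(2 * 5 * Fi), c(2, 5, Fi))
  expect_identical(nasga:::cell_forward(m_a2, X)$prob,
                   nasga:::cell_forward(m_a, X)$prob)
})

test_that("chromosome genes seed the store when the key is absent", {
  Fi <- 2; H <- 3
  ch <- random_chromosome(2, hidden = H, n_features = Fi, seed = 12)
  st <- weight_store(H, Fi)
  m <- materialize_model(ch, st, train_config(hidden = H))
  expect_identical(st$map[["e_1_2"]], ch$weights[["e_1_2"]])
  expect_identical(m$weights[["in"]], ch$weights[["in"]])
})

test_that("training separates a planted offset and is deterministic", {
  es <- make_toy_episodes(n = 120, n_features = 6, offset = 2, seed = 5)
  tc <- train_config(hidden = 8, max_epochs = 50, patience = 10, seed = 4)
  ch <- nasga:::new_chromosome(2, c("relu", "tanh"), 1L)
  run_once <- function() {
    st <- weight_store(8, 6)
    m <- materialize_model(ch, st, tc, seed = 6)
    train_child(m, episode_split(es, "train"),
                episode_split(es, "validation"), tc)
  }
  rec <- run_once()
  expect_gte(rec$accuracy, 0.95)
  expect_lte(rec$epochs, 50)
  expect_identical(rec, run_once())   # same seed, same record
  expect_error(train_child(NULL, es[0], es[0], tc), "non-empty")
})
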