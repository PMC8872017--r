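mk_events <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(patient_id = r$p %||% 1, admission_id = r$a %||% 1,
               time = r$t, feature_id = as.character(r$id),
               value = r$v, unit = r$u, source = r$s %||% "chart",
               stringsAsFactors = FALSE)))
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("merge_features maps duplicate ids and drops unmapped ones", {
  ev <- mk_events(list(t = 1, id = 211, v = 80, u = "bpm"),
                  list(t = 2, id = 220045, v = 85, u = "bpm"),
                  list(t = 3, id = 678, v = 98.6, u = "degF"),
                  list(t = 4, id = 676, v = 37.0, u = "degC"),
                  list(t = 5, id = 99999, v = 1, u = "?"))
  out <- merge_features(ev)
  expect_identical(out$feature[1:2], c("heart_rate", "heart_rate"))
  expect_identical(out$feature[3:4], c("temperature", "temperature"))
  expect_identical(out$unit[3:4], c("degF", "degC"))  # preserved for later
  expect_equal(nrow(out), 4)
  expect_equal(attr(out, "dropped_unmapped"), 1)
  expect_error(merge_features(ev, list(ids = data.frame())), "empty")
})

test_that("harmonize_units elects the majority unit and converts", {
  ev <- mk_events(list(t = 1, id = 762, v = 2, u = "kg"),
                  list(t = 2, id = 762, v = 300, u = "mg"),
                  list(t = 3, id = 762, v = 500, u = "mg"))
  out <- harmonize_units(merge_features(ev))
  expect_identical(out$unit, rep("mg", 3))
  expect_equal(sort(out$value), c(300, 500, 2e6))

  ev <- mk_events(list(t = 1, id = 678, v = 98.6, u = "degF"),
                  list(t = 2, id = 676, v = 37.0, u = "degC"),
                  list(t = 3, id = 676, v = 36.5, u = "degC"))
  out <- harmonize_units(merge_features(ev))
  expect_identical(out$unit, rep("degC", 3))
  expect_equal(out$value, c(37.0, 37.0, 36.5), tolerance = 1e-12)

  # single unit passes through untouched; inconvertible units are dropped
  ev <- mk_events(list(t = 1, id = 211, v = 80, u = "bpm"),
                  list(t = 2, id = 211, v = 90, u = "bpm"))
  out <- harmonize_units(merge_features(ev))
  expect_equal(out$value, c(80, 90))
})

test_that("lab values win same-hour conflicts; chart-only values survive", {
  ev <- mk_events(list(t = 5.2, id = 51301, v = 11, u = "K/uL", s = "chart"),
                  list(t = 5.7, id = 51300, v = 12, u = "K/uL", s = "lab"),
                  list(t = 9.1, id = 51301, v = 9, u = "K/uL", s = "chart"))
  out <- resolve_conflicts(merge_features(ev))
  expect_equal(nrow(out), 2)
  expect_setequal(out$value, c(12, 9))
})

test_that("hourly resampling averages within buckets and floors times", {
  ev <- mk_events(list(t = 3.2, id = 211, v = 80, u = "bpm"),
                  list(t = 3.9, id = 211, v = 90, u = "bpm"),
                  list(t = 2.17, id = 618, v = 18, u = "insp/min"))
  demo <- data.frame(patient_id = 1, admission_id = 1, age = 50,
                     gender = "F", stay_h = 6)
  g <- resample_hourly(merge_features(ev), demo)[["1"]]
  expect_equal(nrow(g), 6)
  expect_equal(unname(g[4, "heart_rate"]), 85)       # hour 3 (0-based)
  expect_equal(unname(g[3, "respiratory_rate"]), 18) # 02:10 -> bucket 2
  expect_true(is.na(g[3, "temperature"]))
  expect_warning(resample_hourly(merge_features(ev),
                                 rbind(demo, transform(demo, admission_id = 2))),
                 "no events")
})

test_that("SIRS criteria are counted per hour with missing contributing 0", {
  g <- matrix(NA_real_, 3, 40,
              dimnames = list(NULL, catalog_features()))
  g[1, c("temperature", "heart_rate", "respiratory_rate", "wbc")] <-
    c(39.0, 120, 25, 13)
  g[2, c("temperature", "heart_rate", "respiratory_rate", "wbc")] <-
    c(37.0, 80, 15, 8)
  g[3, "heart_rate"] <- 95
  ann <- detect_sirs(g)
  expect_equal(ann$count, c(4, 0, 1))
  expect_equal(ann$flag, c(TRUE, FALSE, FALSE))
})

test_that("onset rule: earliest >=5 h run, infection evidence required", {
  flags <- rep(FALSE, 20); flags[11:17] <- TRUE   # hours 10-16
  sirs <- data.frame(hour = 0:19, count = 2 * flags, flag = flags)
  expect_identical(find_sepsis_onset(sirs, infection_hours = 12), 10L)
  expect_identical(find_sepsis_onset(sirs, infection_hours = numeric(0)),
                   NA_integer_)
  short <- rep(FALSE, 10); short[4:7] <- TRUE     # 4 h only
  sirs4 <- data.frame(hour = 0:9, count = 2 * short, flag = short)
  expect_identical(find_sepsis_onset(sirs4, infection_hours = 5), NA_integer_)
})

test_that("onset detection agrees with the brute-force run scan", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(1:50, 1)
    flags <- stats::runif(n) < 0.45
    sirs <- data.frame(hour = seq_len(n) - 1L, count = 2 * flags,
                       flag = flags)
    expect_identical(find_sepsis_onset(sirs, infection_hours = 1),
                     oracle_onset(flags))
  }
})

test_that("cohort filters: age, record length, ambiguous SIRS", {
  g <- function(age, L, aid) {
    m <- matrix(1, L, 40, dimnames = list(NULL, catalog_features()))
    attr(m, "patient_id") <- aid; attr(m, "admission_id") <- aid
    attr(m, "age") <- age; attr(m, "gender") <- "M"
    m
  }
  grids <- list("1" = g(17, 20, 1), "2" = g(40, 7, 2), "3" = g(40, 9, 3))
  ann <- data.frame(admission_id = 1:3, patient_id = 1:3,
                    length_h = c(20, 7, 9), has_sirs_run = FALSE,
                    has_infection = FALSE, onset = NA_integer_)
  kept <- filter_cohort(grids, NULL, horizon = 3, ann)
  expect_identical(names(kept), "3")   # minor and 7 h < 8 h excluded
  # SIRS run without infection evidence is excluded as ambiguous
  ann$has_sirs_run[3] <- TRUE
  expect_length(filter_cohort(grids, NULL, 3, ann), 0)
})

test_that("episode extraction follows the sliding-window rule", {
  g <- matrix(1, 10, 4)
  eps <- extract_episodes(g, onset = NA, horizon = 3)
  expect_length(eps, 3)                       # L - 5 - T + 1 = 3
  expect_equal(vapply(eps, `[[`, integer(1), "start"), 0:2)
  expect_length(extract_episodes(matrix(1, 7, 4), NA, 3), 0)

  eps <- extract_episodes(g, onset = 8, horizon = 3)
  starts <- vapply(eps, `[[`, integer(1), "start")
  labels <- vapply(eps, `[[`, integer(1), "label")
  expect_equal(labels[starts == 0], 1)        # target hour 0 + 5 + 3 = 8
  expect_true(all(labels[starts != 0] == 0))
  expect_true(all(starts + 5 <= 8))           # nothing at/after onset
})

test_that("episode counts match the brute-force window enumerator", {
  set.seed(14)
  for (i in 1:50) {
    L <- sample(5:40, 1)
    Th <- sample(0:12, 1)
    onset <- if (stats::runif(1) < 0.5) sample(0:(L - 1), 1) else NA
    g <- matrix(stats::rnorm(L * 4), L, 4)
    eps <- extract_episodes(g, onset, Th)
    ora <- oracle_windows(L, Th, onset)
    expect_length(eps, length(ora))
    if (length(eps)) {
      expect_equal(vapply(eps, `[[`, integer(1), "start"),
                   vapply(ora, `[`, numeric(1), "start"), ignore_attr = TRUE)
      expect_equal(vapply(eps, `[[`, integer(1), "label"),
                   vapply(ora, `[`, numeric(1), "label"), ignore_attr = TRUE)
      expect_true(all(vapply(eps, function(e) all(dim(e$x) == c(5, 4)),
                             logical(1))))
    }
  }
})

test_that("episode feature filter keeps exactly-50% episodes", {
  n <- 3
  x <- array(NA_real_, c(n, 5, 40))
  x[1, 1, 1:19] <- 1   # 19/40 observed -> excluded
  x[2, 1, 1:20] <- 1   # 20/40 observed -> kept (boundary inclusive)
  x[3, , ] <- 1        # fully observed -> kept
  es <- nasga:::new_episode_set(x, c(0, 1, 0), 1:3, 1:3, rep(0L, 3), 3)
  kept <- filter_episodes(es)
  expect_equal(n_episodes(kept), 2)
  expect_equal(kept$label, c(1L, 0L))
})

test_that("class balancing hits the geometric-mean target", {
  es <- make_toy_episodes(n = 100, split = FALSE)
  es$label <- c(rep(1L, 10), rep(0L, 90))
  bal <- balance_classes(es, seed = 3)
  expect_equal(sum(bal$label == 1), 30)   # round(sqrt(10 * 90))
  expect_equal(sum(bal$label == 0), 30)
  # originals retained: every original positive id still present
  expect_true(all(1:10 %in% bal$patient_id[bal$label == 1]))

  even <- make_toy_episodes(n = 100, split = FALSE)
  even$label <- rep(0:1, 50)
  bal2 <- balance_classes(even, seed = 3)
  expect_equal(table(bal2$label), table(even$label), ignore_attr = TRUE)

  es$label <- rep(0L, 100)
  expect_error(balance_classes(es), "both classes")
})

test_that("5:3:2 split uses largest-remainder rounding, deterministically", {
  es <- make_toy_episodes(n = 100, split = FALSE)
  sp <- split_dataset(es, seed = 8)
  expect_equal(as.numeric(table(sp$split)[c("train", "validation", "test")]),
               c(50, 30, 20))
  sp10 <- split_dataset(make_toy_episodes(n = 10, split = FALSE), seed = 8)
  expect_equal(as.numeric(table(sp10$split)[c("train", "validation", "test")]),
               c(5, 3, 2))
  again <- split_dataset(make_toy_episodes(n = 100, split = FALSE), seed = 8)
  expect_identical(again$split, sp$split)
  expect_error(split_dataset(make_toy_episodes(n = 9, split = FALSE)),
               ">= 10 episodes")
})
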