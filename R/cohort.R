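# Cohort construction: harmonize raw event tables onto the 40-feature
# catalog, detect SIRS, label sepsis onset (start of the earliest >=5 h
# continuous SIRS run, given antibiotic-prescription infection evidence),
# extract 5 h sliding-window episodes at a prediction horizon T, filter,
# balance and split.

#' Map source feature ids to canonical feature names
#'
#' Events whose `feature_id` appears in the catalog gain a `feature` column
#' with the canonical name; unmapped events are dropped and counted in the
#' `dropped_unmapped` attribute.
#'
#' @param events event data.frame (patient_id, admission_id, time,
#'   feature_id, value, unit, source).
#' @param catalog a [feature_catalog()].
#' @return events with a `feature` column.
#' @export
merge_features <- function(events, catalog = feature_catalog()) {
  if (!nrow(catalog$ids)) stop_config("empty feature catalog")
  idx <- match(as.character(events$feature_id), catalog$ids$feature_id)
  dropped <- sum(is.na(idx))
  out <- events[!is.na(idx), , drop = FALSE]
  out$feature <- catalog$ids$name[idx[!is.na(idx)]]
  attr(out, "dropped_unmapped") <- dropped
  out
}

#' Unify units per canonical feature to the majority unit
#'
#' For each canonical feature the unit with the most records is elected and
#' all values are converted to it via the affine rules of [unit_table()].
#' Records in a unit with no conversion rule to the elected unit are dropped
#' and counted in the `dropped_units` attribute.
#'
#' @param events output of [merge_features()].
#' @param catalog a [feature_catalog()].
#' @return events with `value`/`unit` rewritten to the elected unit.
#' @export
harmonize_units <- function(events, catalog = feature_catalog()) {
  stopifnot("feature" %in% names(events))
  dropped <- 0L
  keep <- rep(TRUE, nrow(events))
  for (fname in unique(events$feature)) {
    rows <- which(events$feature == fname)
    units <- events$unit[rows]
    tab <- sort(table(units), decreasing = TRUE)
    elected <- names(tab)[1]
    for (u in names(tab)[-1]) {
      sub <- rows[units == u]
      conv <- convert_unit(events$value[sub], u, elected, catalog$units)
      if (is.null(conv)) {
        keep[sub] <- FALSE
        dropped <- dropped + length(sub)
      } else {
        events$value[sub] <- conv
        events$unit[sub] <- elected
      }
    }
  }
  out <- events[keep, , drop = FALSE]
  attr(out, "dropped_units") <- dropped
  out
}

#' Resolve same-hour chart/lab conflicts in favor of the lab table
#'
#' When the same canonical feature of the same admission has both chart and
#' lab records within one hour bucket, the chart records are discarded.
#'
#' @param events harmonized events.
#' @return events with conflicting chart rows removed.
#' @export
resolve_conflicts <- function(events) {
  stopifnot("feature" %in% names(events))
  key <- paste(events$admission_id, events$feature, floor(events$time))
  lab_keys <- unique(key[events$source == "lab"])
  drop <- events$source == "chart" & key %in% lab_keys
  events[!drop, , drop = FALSE]
}

#' Resample events onto hourly grids
#'
#' Per admission: a matrix of `L` hours (0-based, floor-to-hour bucketing,
#' hour 0 = first event hour... admission start) by 40 catalog features.
#' Multiple values within an hour are averaged; empty hours are `NA`.
#'
#' @param events harmonized, conflict-resolved events.
#' @param demographics data.frame with patient_id, admission_id, age, gender
#'   (and optionally stay_h, used to fix the grid length).
#' @param catalog a [feature_catalog()].
#' @return named list of grids (one per admission id), each a matrix with
#'   attributes `patient_id`, `admission_id`, `age`, `gender`.
#' @export
resample_hourly <- function(events, demographics, catalog = feature_catalog()) {
  feats <- catalog_features(catalog)
  grids <- list()
  for (aid in unique(demographics$admission_id)) {
    d <- demographics[demographics$admission_id == aid, ][1, ]
    ev <- events[events$admission_id == aid, , drop = FALSE]
    if (!nrow(ev)) {
      warning(sprintf("admission %s has no events", aid))
      next
    }
    L <- if ("stay_h" %in% names(d)) d$stay_h else floor(max(ev$time)) + 1
    L <- max(L, floor(max(ev$time)) + 1)
    g <- matrix(NA_real_, L, length(feats), dimnames = list(NULL, feats))
    hour <- pmin(floor(pmax(ev$time, 0)), L - 1)
    agg <- tapply(ev$value, list(hour, ev$feature), mean)
    hr_idx <- as.integer(rownames(agg)) + 1L
    ft_idx <- match(colnames(agg), feats)
    ok <- !is.na(ft_idx)
    g[hr_idx, ft_idx[ok]] <- agg[, ok, drop = FALSE]
    attr(g, "patient_id") <- d$patient_id
    attr(g, "admission_id") <- aid
    attr(g, "age") <- d$age
    attr(g, "gender") <- d$gender
    grids[[as.character(aid)]] <- g
  }
  grids
}

#' Default SIRS thresholds
#'
#' Two-of-four criteria: temperature > 38 or < 36 degC, heart rate > 90 bpm,
#' respiratory rate > 20 /min, WBC > 12 or < 4 x10^3/mm^3. (The PaCO2 and
#' band-count variants are omitted: those features are not in the grid.)
#' @return named list of thresholds.
#' @export
sirs_thresholds <- function() {
  list(temp_high = 38, temp_low = 36, hr = 90, rr = 20,
       wbc_high = 12, wbc_low = 4)
}

#' Per-hour SIRS annotation of an hourly grid
#'
#' Counts the criteria met each hour; a missing feature contributes 0. The
#' SIRS flag is true iff >= 2 criteria are met.
#'
#' @param grid hourly matrix from [resample_hourly()].
#' @param thresholds list as in [sirs_thresholds()].
#' @return data.frame with `hour` (0-based), `count` (0-4), `flag`.
#' @export
detect_sirs <- function(grid, thresholds = sirs_thresholds()) {
  gv <- function(col) if (col %in% colnames(grid)) grid[, col] else
    rep(NA_real_, nrow(grid))
  temp <- gv("temperature"); hr <- gv("heart_rate")
  rr <- gv("respiratory_rate"); wbc <- gv("wbc")
  crit <- cbind(
    !is.na(temp) & (temp > thresholds$temp_high | temp < thresholds$temp_low),
    !is.na(hr) & hr > thresholds$hr,
    !is.na(rr) & rr > thresholds$rr,
    !is.na(wbc) & (wbc > thresholds$wbc_high | wbc < thresholds$wbc_low))
  count <- rowSums(crit)
  data.frame(hour = seq_len(nrow(grid)) - 1L, count = count,
             flag = count >= 2)
}

#' Sepsis onset: start of the earliest >= `min_run` h continuous SIRS run
#'
#' Onset requires both criteria: a continuous SIRS run of at least
#' `min_run` hours AND infection evidence for the admission (any antibiotic
#' prescription). Returns `NA` when either is absent.
#'
#' @param sirs annotation from [detect_sirs()].
#' @param infection_hours numeric vector of infection-evidence hours (their
#'   presence, not their timing, is what matters).
#' @param min_run minimum run length in hours (default 5).
#' @return onset hour (0-based) or `NA`.
#' @export
find_sepsis_onset <- function(sirs, infection_hours, min_run = 5) {
  if (!length(infection_hours) || all(is.na(infection_hours)))
    return(NA_integer_)
  r <- rle(sirs$flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= min_run)
  if (!length(hit)) return(NA_integer_)
  sirs$hour[starts[hit[1]]]
}

#' Admission-level annotations: onset, SIRS-run and infection evidence
#'
#' @param grids list from [resample_hourly()].
#' @param prescriptions prescriptions data.frame.
#' @param antibiotics drug names counted as infection evidence.
#' @param thresholds SIRS thresholds.
#' @param min_run minimum SIRS run (hours).
#' @return data.frame: admission_id, patient_id, length_h, has_sirs_run,
#'   has_infection, onset.
#' @export
annotate_admissions <- function(grids, prescriptions,
                                antibiotics = default_antibiotics(),
                                thresholds = sirs_thresholds(), min_run = 5) {
  abx <- prescriptions[tolower(prescriptions$drug) %in%
                         tolower(antibiotics), , drop = FALSE]
  rows <- lapply(grids, function(g) {
    aid <- attr(g, "admission_id")
    sirs <- detect_sirs(g, thresholds)
    inf_hours <- abx$time[abx$admission_id == aid]
    onset <- find_sepsis_onset(sirs, inf_hours, min_run)
    r <- rle(sirs$flag)
    has_run <- any(r$values & r$lengths >= min_run)
    data.frame(admission_id = aid, patient_id = attr(g, "patient_id"),
               length_h = nrow(g), has_sirs_run = has_run,
               has_infection = length(inf_hours) > 0, onset = onset)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter admissions for episode extraction
#'
#' Keeps adults (age >= 18) whose record spans at least `5 + T` hours
#' (monitoring window plus prediction time; the stated rule is 8 h at
#' T = 3). Admissions showing a >= 5 h SIRS run without infection evidence
#' have ambiguous sepsis status and are excluded rather than kept as
#' negatives.
#'
#' @param grids list from [resample_hourly()].
#' @param demographics demographics data.frame.
#' @param horizon prediction horizon T in hours.
#' @param annotations output of [annotate_admissions()].
#' @return filtered list of grids.
#' @export
filter_cohort <- function(grids, demographics, horizon, annotations) {
  keep <- vapply(grids, function(g) {
    aid <- attr(g, "admission_id")
    a <- annotations[annotations$admission_id == aid, ]
    if (!nrow(a)) return(FALSE)
    if (attr(g, "age") < 18) return(FALSE)
    if (nrow(g) < 5 + horizon) return(FALSE)
    if (a$has_sirs_run && !a$has_infection) return(FALSE)
    TRUE
  }, logical(1))
  grids[keep]
}

#' Extract sliding-window episodes from one grid
#'
#' Windows of 5 hours starting at s = 0, 1, 2, ... are emitted while
#' `s + 5 + T <= L`. The label is 1 iff the onset falls exactly at the target
#' hour `s + 5 + T`. Windows that overlap or follow the onset are suppressed
#' (never emitted as negatives).
#'
#' @param grid hourly matrix.
#' @param onset onset hour or `NA`.
#' @param horizon prediction horizon T.
#' @return list of per-window records (matrix, label, start).
#' @export
extract_episodes <- function(grid, onset, horizon) {
  L <- nrow(grid)
  out <- list()
  s <- 0L
  while (s + 5 + horizon <= L) {
    if (is.na(onset) || onset >= s + 5) {
      label <- as.integer(!is.na(onset) && onset == s + 5 + horizon)
      out[[length(out) + 1L]] <- list(x = grid[(s + 1):(s + 5), , drop = FALSE],
                                      label = label, start = s)
    }
    s <- s + 1L
  }
  out
}

# --- episode-set container ---------------------------------------------------

new_episode_set <- function(x, label, patient_id, admission_id, start,
                            horizon, split = NULL, features = NULL) {
  n <- dim(x)[1]
  structure(list(x = x, label = as.integer(label),
                 patient_id = patient_id, admission_id = admission_id,
                 start = as.integer(start), horizon = horizon,
                 split = split %||% rep(NA_character_, n),
                 features = features %||% dimnames(x)[[3]]),
            class = "nasga_episodes")
}

#' Number of episodes in a set
#' @param es a `nasga_episodes`.
#' @return integer count.
#' @export
n_episodes <- function(es) dim(es$x)[1]

#' Subset an episode set
#' @param x a `nasga_episodes`.
#' @param i index vector.
#' @param ... ignored.
#' @return a `nasga_episodes`.
#' @export
`[.nasga_episodes` <- function(x, i, ...) {
  new_episode_set(x$x[i, , , drop = FALSE], x$label[i], x$patient_id[i],
                  x$admission_id[i], x$start[i], x$horizon, x$split[i],
                  x$features)
}

#' @export
print.nasga_episodes <- function(x, ...) {
  cat(sprintf("<episodes n=%d (%d positive) horizon=%s split=[%s]>\n",
              n_episodes(x), sum(x$label), x$horizon,
              paste(names(table(x$split, useNA = "ifany")), collapse = ",")))
  invisible(x)
}

#' Collect per-grid episodes into an episode set
#'
#' @param grids filtered grids.
#' @param annotations admission annotations (for onsets).
#' @param horizon prediction horizon T.
#' @param catalog feature catalog.
#' @return a `nasga_episodes`.
#' @export
collect_episodes <- function(grids, annotations, horizon,
                             catalog = feature_catalog()) {
  feats <- catalog_features(catalog)
  recs <- list()
  for (g in grids) {
    aid <- attr(g, "admission_id")
    a <- annotations[annotations$admission_id == aid, ]
    onset <- if (nrow(a)) a$onset else NA_integer_
    eps <- extract_episodes(g, onset, horizon)
    for (e in eps) {
      recs[[length(recs) + 1L]] <- list(x = e$x, label = e$label,
                                        start = e$start,
                                        patient_id = attr(g, "patient_id"),
                                        admission_id = aid)
    }
  }
  n <- length(recs)
  x <- array(NA_real_, c(n, 5, length(feats)),
             dimnames = list(NULL, NULL, feats))
  for (i in seq_len(n)) x[i, , ] <- recs[[i]]$x
  new_episode_set(x,
                  vapply(recs, `[[`, integer(1), "label"),
                  vapply(recs, `[[`, numeric(1), "patient_id"),
                  vapply(recs, `[[`, numeric(1), "admission_id"),
                  vapply(recs, `[[`, integer(1), "start"),
                  horizon)
}

#' Drop episodes with fewer than 50% of features observed
#'
#' A feature counts as observed when it has at least one non-missing value in
#' the 5 h window; episodes with an observed fraction below 0.5 are excluded
#' (exactly 50% is kept).
#'
#' @param es a `nasga_episodes`.
#' @return filtered `nasga_episodes`.
#' @export
filter_episodes <- function(es) {
  frac <- apply(es$x, 1, function(m) mean(colSums(!is.na(m)) > 0))
  es[frac >= 0.5]
}

#' Balance classes by oversampling positives and undersampling negatives
#'
#' Both classes are resized to the geometric mean of the class counts
#' (rounded): the minority class keeps all originals and adds duplicates
#' drawn with replacement; the majority class is subsampled without
#' replacement.
#'
#' @param es a `nasga_episodes` with both classes present.
#' @param seed optional seed.
#' @return balanced `nasga_episodes`.
#' @export
balance_classes <- function(es, seed = NULL) {
  pos <- which(es$label == 1)
  neg <- which(es$label == 0)
  if (!length(pos) || !length(neg))
    stop_config("both classes must be present to balance")
  maybe_seed(seed)
  target <- round(sqrt(length(pos) * length(neg)))
  resize <- function(idx) {
    if (length(idx) >= target) sample(idx, target)
    else c(idx, sample(idx, target - length(idx), replace = TRUE))
  }
  es[sort(c(resize(pos), resize(neg)))]
}

#' Random 5:3:2 train/validation/test split
#'
#' Largest-remainder rounding of the 0.5/0.3/0.2 proportions; assignment is
#' a random permutation, deterministic under `seed`.
#'
#' @param es a `nasga_episodes` with >= 10 episodes.
#' @param seed optional seed.
#' @return `nasga_episodes` with the `split` field set.
#' @export
split_dataset <- function(es, seed = NULL) {
  n <- n_episodes(es)
  if (n < 10) stop_config("need >= 10 episodes to split, got %d", n)
  maybe_seed(seed)
  props <- c(train = 0.5, validation = 0.3, test = 0.2)
  counts <- floor(n * props)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- n * props - counts
    extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  tags <- sample(rep(names(props), counts))
  es$split <- tags
  es
}

#' Select a split from an episode set
#' @param es a `nasga_episodes`.
#' @param which one of "train", "validation", "test".
#' @return a `nasga_episodes`.
#' @export
episode_split <- function(es, which) es[es$split == which]

#' Full cohort stage: events to balanced, split episode set
#'
#' Runs merge, unit harmonization, conflict resolution, hourly resampling,
#' SIRS/onset annotation, cohort filtering, window extraction, episode
#' filtering, class balancing and the 5:3:2 split.
#'
#' @param cohort a `nasga_cohort_data` (events, prescriptions, demographics).
#' @param horizon prediction horizon T in hours.
#' @param seed master seed for balancing and splitting.
#' @param catalog feature catalog.
#' @param balance,split stages toggles (both default TRUE).
#' @return list: `episodes` (a `nasga_episodes`), `annotations`, `grids`.
#' @export
build_cohort <- function(cohort, horizon, seed = 1,
                         catalog = feature_catalog(), balance = TRUE,
                         split = TRUE) {
  ev <- merge_features(cohort$events, catalog)
  ev <- harmonize_units(ev, catalog)
  ev <- resolve_conflicts(ev)
  grids <- resample_hourly(ev, cohort$demographics, catalog)
  ann <- annotate_admissions(grids, cohort$prescriptions)
  grids_f <- filter_cohort(grids, cohort$demographics, horizon, ann)
  es <- collect_episodes(grids_f, ann, horizon, catalog)
  es <- filter_episodes(es)
  if (balance) es <- balance_classes(es, seed = fork_seed(seed, "balance"))
  if (split) es <- split_dataset(es, seed = fork_seed(seed, "split"))
  list(episodes = es, annotations = ann, grids = grids_f)
}
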