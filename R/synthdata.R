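# Synthetic MIMIC-like cohort generator.
#
# Emits event tables with the structure of ICU chart/lab/prescription tables:
# irregular timestamps (mid-hour +/- 15 min jitter, so floor-to-hour
# bucketing recovers the nominal hour), ~40 features with
# per-feature measurement cadence, duplicate source ids for the same concept,
# a configurable fraction of events in non-canonical units, and row-level
# missingness. Sepsis patients carry (a) a >=5 h run of intended-SIRS hours
# whose start is the ground-truth onset, (b) a precursor drift in heart rate,
# respiratory rate, temperature, WBC (and lactate) that begins signal_lead_h
# before onset and is attenuated by signal_decay per hour of lead -- so a
# classifier's advantage decays with the prediction horizon -- and (c)
# antibiotic prescriptions near the infection time. Only structural realism
# is attempted; marginal distributions are not matched to any real cohort.

#' Configuration for the synthetic cohort generator
#'
#' @param n_patients number of patients (>= 1).
#' @param mean_stay_h mean ICU stay in hours (default 48; stays are clamped
#'   to \[24, 96\] h, sepsis stays to >= 32 h so the onset fits).
#' @param sepsis_prevalence fraction of patients with planted sepsis in
#'   \[0, 1\].
#' @param signal_lead_h hours before onset at which the precursor drift
#'   begins (default 12, matching the longest prediction horizon).
#' @param signal_decay per-hour attenuation of the drift in (0, 1]: at lead
#'   l hours the drift amplitude is `signal_decay^l` of its value at onset.
#' @param missing_rate probability that any single event row is dropped, in
#'   \[0, 1).
#' @param unit_mix_rate fraction of events emitted in a non-canonical unit
#'   (features with an alternate unit only).
#' @param seed RNG seed.
#' @return a validated `nasga_synth_config` list.
#' @export
synth_config <- function(n_patients = 100, mean_stay_h = 48,
                         sepsis_prevalence = 0.2, signal_lead_h = 12,
                         signal_decay = 0.9, missing_rate = 0.1,
                         unit_mix_rate = 0.1, seed = 1) {
  cfg <- list(n_patients = n_patients, mean_stay_h = mean_stay_h,
              sepsis_prevalence = sepsis_prevalence,
              signal_lead_h = signal_lead_h, signal_decay = signal_decay,
              missing_rate = missing_rate, unit_mix_rate = unit_mix_rate,
              seed = seed)
  if (!is.numeric(n_patients) || n_patients < 1)
    stop_config("n_patients must be >= 1")
  if (sepsis_prevalence < 0 || sepsis_prevalence > 1)
    stop_config("sepsis_prevalence must be in [0, 1]")
  if (signal_lead_h < 0) stop_config("signal_lead_h must be >= 0")
  if (signal_decay <= 0 || signal_decay > 1)
    stop_config("signal_decay must be in (0, 1]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop_config("missing_rate must be in [0, 1)")
  if (unit_mix_rate < 0 || unit_mix_rate > 1)
    stop_config("unit_mix_rate must be in [0, 1]")
  class(cfg) <- "nasga_synth_config"
  cfg
}

# intended values (mean, sd) for SIRS-relevant features during the septic run
# and at the end of the precursor drift (just short of the SIRS thresholds)
sepsis_signal_table <- function() {
  data.frame(
    name   = c("heart_rate", "temperature", "respiratory_rate", "wbc",
               "lactate"),
    septic = c(110, 38.8, 26, 14.5, 3.0),
    near   = c(86, 37.6, 19, 11, 2.2),
    run_sd = c(3, 0.2, 1.5, 0.8, 0.3),
    drift_sd = c(2, 0.15, 0.8, 0.6, 0.25),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic cohort
#'
#' @param config a [synth_config()].
#' @param catalog feature catalog (default [feature_catalog()]).
#' @return list with elements `events` (data.frame: patient_id, admission_id,
#'   time in hours since admission, feature_id, value, unit, source),
#'   `prescriptions`, `demographics` (patient_id, admission_id, age, gender,
#'   stay_h), and `truth` (ground truth: per-patient onset/infection times and
#'   intended-SIRS hour sets).
#' @export
generate_cohort <- function(config, catalog = feature_catalog()) {
  stopifnot(inherits(config, "nasga_synth_config"))
  set.seed(as.integer(config$seed))
  feats <- catalog$features
  sig <- sepsis_signal_table()
  n <- as.integer(config$n_patients)

  ev_list <- vector("list", n)
  rx_list <- vector("list", n)
  demo_list <- vector("list", n)
  truth_rows <- vector("list", n)
  sirs_hours <- vector("list", n)

  for (p in seq_len(n)) {
    pid <- p
    aid <- 100000L + p
    sepsis <- stats::runif(1) < config$sepsis_prevalence
    L <- round(stats::rnorm(1, config$mean_stay_h, 8))
    L <- max(24, min(96, L))
    if (sepsis) L <- max(L, 32)
    age <- if (!sepsis && stats::runif(1) < 0.03) sample(8:17, 1) else
      sample(19:89, 1)
    gender <- sample(c("M", "F"), 1)

    onset <- NA_integer_; infection <- NA_integer_; run_len <- 0L
    if (sepsis) {
      onset <- sample(18:(L - 8), 1)
      run_len <- 6L + stats::rpois(1, 3)
      run_len <- min(run_len, L - onset)
      infection <- max(0L, onset - sample(0:4, 1))
    }

    # intended hourly values: L x 40, hour h in row h+1
    vals <- matrix(NA_real_, L, nrow(feats))
    colnames(vals) <- feats$name
    patient_offset <- stats::rnorm(nrow(feats), 0, feats$base_sd * 0.5)
    for (j in seq_len(nrow(feats))) {
      mu <- feats$base_mean[j] + patient_offset[j]
      vals[, j] <- stats::rnorm(L, mu, feats$base_sd[j])
      si <- match(feats$name[j], sig$name)
      if (sepsis && !is.na(si)) {
        hours <- 0:(L - 1)
        in_run <- hours >= onset & hours < onset + run_len
        vals[in_run, j] <- stats::rnorm(sum(in_run), sig$septic[si],
                                        sig$run_sd[si])
        lead <- onset - hours
        in_drift <- lead > 0 & lead <= config$signal_lead_h
        if (any(in_drift)) {
          amp <- config$signal_decay^lead[in_drift]
          target <- mu + amp * (sig$near[si] - mu)
          vals[in_drift, j] <- stats::rnorm(sum(in_drift), target,
                                            sig$drift_sd[si])
        }
      }
    }
    if (sepsis) sirs_hours[[p]] <- seq.int(onset, onset + run_len - 1L)
    else sirs_hours[[p]] <- integer(0)

    # emit events: per feature x hour Bernoulli at the feature's cadence,
    # labs sampled more often during the septic run (escalation of care);
    # continuously monitored vitals are charted about twice an hour
    rows <- list()
    for (j in seq_len(nrow(feats))) {
      pvec <- rep(feats$event_p[j], L)
      if (sepsis && feats$source[j] == "lab") {
        run_idx <- seq.int(onset, onset + run_len - 1L) + 1L
        pvec[run_idx] <- pmin(0.95, 3 * pvec[run_idx])
      }
      reps <- if (feats$source[j] == "chart" && feats$event_p[j] >= 0.9)
        2L else 1L
      pvec <- rep(pvec, reps)
      hit <- which(stats::runif(L * reps) < pvec)
      if (!length(hit)) next
      hours <- (hit - 1L) %% L
      ids <- catalog$ids$feature_id[catalog$ids$name == feats$name[j]]
      value <- vals[hours + 1L, j] +
        stats::rnorm(length(hit), 0, feats$base_sd[j] * 0.1)
      unit <- rep(feats$unit[j], length(hit))
      if (!is.na(feats$alt_unit[j]) && config$unit_mix_rate > 0) {
        alt <- stats::runif(length(hit)) < config$unit_mix_rate
        if (any(alt)) {
          conv <- convert_unit(value[alt], feats$unit[j], feats$alt_unit[j],
                               catalog$units)
          if (!is.null(conv)) {
            value[alt] <- conv
            unit[alt] <- feats$alt_unit[j]
          }
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, admission_id = aid,
        time = hours + 0.5 + stats::runif(length(hit), -0.25, 0.25),
        feature_id = sample(ids, length(hit), replace = TRUE),
        value = value, unit = unit, source = feats$source[j],
        stringsAsFactors = FALSE)
      # occasionally a lab value is also charted (slightly perturbed) to
      # exercise the lab-priority conflict rule
      if (feats$source[j] == "lab") {
        dup <- stats::runif(length(hit)) < 0.05
        if (any(dup)) {
          d <- rows[[length(rows)]][dup, , drop = FALSE]
          d$value <- d$value * (1 + stats::rnorm(nrow(d), 0, 0.02))
          d$source <- "chart"
          rows[[length(rows) + 1L]] <- d
        }
      }
    }
    ev_list[[p]] <- do.call(rbind, rows)

    # prescriptions: antibiotics near infection for sepsis patients; some
    # controls also get an antibiotic (infection without SIRS); everyone may
    # get unrelated drugs
    rx <- list()
    if (sepsis) {
      drugs <- sample(default_antibiotics(), sample(1:2, 1))
      for (d in drugs) {
        rx[[length(rx) + 1L]] <- data.frame(
          patient_id = pid, admission_id = aid,
          time = infection + stats::runif(1, 0, 2),
          drug = d, dose = round(stats::runif(1, 250, 2000)), unit = "mg",
          stringsAsFactors = FALSE)
      }
    } else if (stats::runif(1) < 0.1) {
      rx[[length(rx) + 1L]] <- data.frame(
        patient_id = pid, admission_id = aid,
        time = stats::runif(1, 0, L - 1),
        drug = sample(default_antibiotics(), 1),
        dose = round(stats::runif(1, 250, 2000)), unit = "mg",
        stringsAsFactors = FALSE)
    }
    if (stats::runif(1) < 0.5) {
      rx[[length(rx) + 1L]] <- data.frame(
        patient_id = pid, admission_id = aid,
        time = stats::runif(1, 0, L - 1),
        drug = sample(c("Insulin", "Furosemide", "Acetaminophen", "Heparin"), 1),
        dose = round(stats::runif(1, 5, 100)), unit = "mg",
        stringsAsFactors = FALSE)
    }
    rx_list[[p]] <- if (length(rx)) do.call(rbind, rx) else NULL

    demo_list[[p]] <- data.frame(patient_id = pid, admission_id = aid,
                                 age = age, gender = gender, stay_h = L,
                                 stringsAsFactors = FALSE)
    truth_rows[[p]] <- data.frame(patient_id = pid, admission_id = aid,
                                  sepsis = sepsis, onset_time = onset,
                                  infection_time = infection,
                                  stay_h = L, stringsAsFactors = FALSE)
  }

  events <- do.call(rbind, ev_list)
  events <- inject_missingness(events, config$missing_rate,
                               seed = fork_seed(config$seed, "missingness"))
  rownames(events) <- NULL
  prescriptions <- do.call(rbind, rx_list)
  if (is.null(prescriptions))
    prescriptions <- data.frame(patient_id = integer(0),
                                admission_id = integer(0), time = numeric(0),
                                drug = character(0), dose = numeric(0),
                                unit = character(0))
  rownames(prescriptions) <- NULL
  truth <- list(patients = do.call(rbind, truth_rows),
                sirs_hours = stats::setNames(sirs_hours,
                                             as.character(seq_len(n))))
  rownames(truth$patients) <- NULL
  structure(list(events = events, prescriptions = prescriptions,
                 demographics = do.call(rbind, demo_list), truth = truth),
            class = "nasga_cohort_data")
}

#' Randomly drop event rows
#'
#' Each event row is independently dropped with probability `missing_rate`.
#' @param events event data.frame.
#' @param missing_rate drop probability in \[0, 1).
#' @param seed optional seed.
#' @return the thinned data.frame.
#' @export
inject_missingness <- function(events, missing_rate, seed = NULL) {
  if (missing_rate < 0 || missing_rate >= 1)
    stop_config("missing_rate must be in [0, 1)")
  if (missing_rate == 0 || !nrow(events)) return(events)
  maybe_seed(seed)
  keep <- stats::runif(nrow(events)) >= missing_rate
  events[keep, , drop = FALSE]
}

#' Write / read a synthetic cohort as plain-text tables
#'
#' Writes `chartevents.csv`, `labevents.csv`, `prescriptions.csv`,
#' `patients.csv` and `ground_truth.json` under `dir`.
#' @param cohort a `nasga_cohort_data` from [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return `write_cohort`: `dir`, invisibly; `read_cohort`: the cohort list.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ev <- cohort$events
  utils::write.csv(ev[ev$source != "lab", ],
                   file.path(dir, "chartevents.csv"), row.names = FALSE)
  utils::write.csv(ev[ev$source == "lab", ],
                   file.path(dir, "labevents.csv"), row.names = FALSE)
  utils::write.csv(cohort$prescriptions, file.path(dir, "prescriptions.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$demographics, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(list(patients = truth$patients,
                            sirs_hours = truth$sirs_hours),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  chart <- utils::read.csv(file.path(dir, "chartevents.csv"),
                           colClasses = c(feature_id = "character"))
  lab <- utils::read.csv(file.path(dir, "labevents.csv"),
                         colClasses = c(feature_id = "character"))
  events <- rbind(chart, lab)
  prescriptions <- utils::read.csv(file.path(dir, "prescriptions.csv"))
  demographics <- utils::read.csv(file.path(dir, "patients.csv"))
  truth <- NULL
  tj <- file.path(dir, "ground_truth.json")
  if (file.exists(tj)) {
    raw <- jsonlite::read_json(tj, simplifyVector = TRUE)
    truth <- list(patients = raw$patients,
                  sirs_hours = lapply(raw$sirs_hours, as.integer))
  }
  structure(list(events = events, prescriptions = prescriptions,
                 demographics = demographics, truth = truth),
            class = "nasga_cohort_data")
}
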