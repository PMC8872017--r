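# The 40-feature catalog: canonical names, source feature ids (several ids
# can map to one concept, as in real chart/lab tables), canonical units, and
# affine unit-conversion rules. Baseline mean/sd and measurement cadence are
# used by the synthetic generator; the SIRS columns mark the four features
# entering the SIRS criteria.

#' Unit conversion table
#'
#' Each unit is an affine map onto a base unit: `value_base = mult * value +
#' offset`. Two units are interconvertible iff they share a base unit.
#' @return data.frame with columns unit, base, mult, offset.
#' @export
unit_table <- function() {
  rbind(
    data.frame(unit = "degC", base = "degC", mult = 1, offset = 0),
    data.frame(unit = "degF", base = "degC", mult = 5 / 9, offset = -160 / 9),
    data.frame(unit = "mg",   base = "mg",   mult = 1, offset = 0),
    data.frame(unit = "g",    base = "mg",   mult = 1e3, offset = 0),
    data.frame(unit = "kg",   base = "mg",   mult = 1e6, offset = 0),
    data.frame(unit = "lb",   base = "mg",   mult = 453592.37, offset = 0)
  )
}

convert_unit <- function(values, from, to, units = unit_table()) {
  if (from == to) return(values)
  a <- units[units$unit == from, ]
  b <- units[units$unit == to, ]
  if (nrow(a) != 1 || nrow(b) != 1 || a$base != b$base) return(NULL)
  (a$mult * values + a$offset - b$offset) / b$mult
}

#' Built-in 40-feature catalog
#'
#' Maps source feature ids to 40 canonical features (vital signs, blood gas,
#' chemistry, hematology, neurological scores, vasoactive doses). Several
#' concepts carry duplicate ids, mirroring how the same measurement appears
#' under different ids in chart and lab tables; temperature and weight/dose
#' features additionally appear in alternate units.
#'
#' @return list with elements `features` (data.frame: one row per canonical
#'   feature with canonical unit, alternate unit if any, generator baseline
#'   mean/sd, hourly event probability, source table) and `ids` (data.frame:
#'   source id -> canonical name).
#' @export
feature_catalog <- function() {
  f <- function(name, unit, alt, mean, sd, p, src, ids)
    list(name = name, unit = unit, alt_unit = alt, base_mean = mean,
         base_sd = sd, event_p = p, source = src, ids = ids)
  defs <- list(
    f("heart_rate", "bpm", NA, 75, 5, 0.98, "chart", c("211", "220045")),
    f("temperature", "degC", "degF", 36.8, 0.25, 0.98, "chart",
      c("676", "223762", "678", "223761")),
    f("respiratory_rate", "insp/min", NA, 16, 1.5, 0.98, "chart",
      c("618", "220210")),
    f("wbc", "K/uL", NA, 8, 1.2, 0.3, "lab", c("51300", "51301")),
    f("systolic_bp", "mmHg", NA, 118, 8, 0.95, "chart",
      c("51", "442", "455", "220179")),
    f("diastolic_bp", "mmHg", NA, 72, 6, 0.95, "chart", c("8368", "220180")),
    f("mean_arterial_pressure", "mmHg", NA, 85, 7, 0.95, "chart",
      c("52", "220052")),
    f("pulse_pressure", "mmHg", NA, 45, 6, 0.9, "chart", "90001"),
    f("spo2", "%", NA, 97, 1, 0.95, "chart", c("646", "220277")),
    f("ph", "pH", NA, 7.4, 0.03, 0.25, "lab", "50820"),
    f("pao2", "mmHg", NA, 95, 8, 0.25, "lab", "50821"),
    f("fio2", "fraction", NA, 0.3, 0.05, 0.8, "chart", c("3420", "223835")),
    f("pf_ratio", "ratio", NA, 300, 40, 0.25, "lab", "90002"),
    f("gcs_eye", "score", NA, 4, 0.2, 0.9, "chart", c("184", "220739")),
    f("gcs_verbal", "score", NA, 5, 0.2, 0.9, "chart", c("723", "223900")),
    f("gcs_motor", "score", NA, 6, 0.2, 0.9, "chart", c("454", "223901")),
    f("urine_output", "mL", NA, 60, 15, 0.85, "chart", c("40055", "226559")),
    f("bun", "mg/dL", NA, 18, 4, 0.25, "lab", "51006"),
    f("sodium", "mmol/L", NA, 139, 2, 0.3, "lab", "50983"),
    f("potassium", "mmol/L", NA, 4.1, 0.3, 0.3, "lab", "50971"),
    f("bicarbonate", "mmol/L", NA, 24, 2, 0.3, "lab", "50882"),
    f("bilirubin", "mg/dL", NA, 0.8, 0.2, 0.2, "lab", "50885"),
    f("platelets", "K/uL", NA, 250, 40, 0.25, "lab", "51265"),
    f("creatinine", "mg/dL", NA, 1.0, 0.2, 0.3, "lab", "50912"),
    f("lactate", "mmol/L", NA, 1.4, 0.3, 0.25, "lab", "50813"),
    f("glucose", "mg/dL", NA, 110, 15, 0.35, "lab", c("50931", "807")),
    f("hematocrit", "%", NA, 33, 3, 0.3, "lab", "51221"),
    f("hemoglobin", "g/dL", NA, 11, 1, 0.3, "lab", "51222"),
    f("chloride", "mmol/L", NA, 103, 2, 0.3, "lab", "50902"),
    f("magnesium", "mg/dL", NA, 2.0, 0.2, 0.25, "lab", "50960"),
    f("calcium", "mg/dL", NA, 9.0, 0.4, 0.25, "lab", "50893"),
    f("phosphate", "mg/dL", NA, 3.5, 0.5, 0.2, "lab", "50970"),
    f("albumin", "g/dL", NA, 3.8, 0.3, 0.2, "lab", "50862"),
    f("ptt", "s", NA, 32, 4, 0.2, "lab", "51275"),
    f("inr", "ratio", NA, 1.1, 0.1, 0.2, "lab", "51237"),
    f("weight", "kg", "lb", 78, 10, 0.5, "chart", c("762", "224639")),
    f("dopamine_dose", "mg", "g", 5, 1, 0.3, "chart", "221662"),
    f("norepinephrine_dose", "mg", "g", 0.5, 0.1, 0.3, "chart", "221906"),
    f("epinephrine_dose", "mg", "g", 0.3, 0.1, 0.3, "chart", "221289"),
    f("svo2", "%", NA, 70, 4, 0.3, "chart", "90003")
  )
  features <- do.call(rbind, lapply(defs, function(d)
    data.frame(name = d$name, unit = d$unit, alt_unit = d$alt_unit,
               base_mean = d$base_mean, base_sd = d$base_sd,
               event_p = d$event_p, source = d$source,
               stringsAsFactors = FALSE)))
  ids <- do.call(rbind, lapply(defs, function(d)
    data.frame(feature_id = d$ids, name = d$name, stringsAsFactors = FALSE)))
  stopifnot(nrow(features) == 40, !anyDuplicated(ids$feature_id))
  list(features = features, ids = ids, units = unit_table())
}

#' Canonical feature names, in fixed column order
#' @param catalog a catalog from [feature_catalog()].
#' @return character vector of length 40.
#' @export
catalog_features <- function(catalog = feature_catalog()) catalog$features$name

#' Default antibiotic list used as infection evidence
#'
#' A prescription event whose drug matches this list (case-insensitive) marks
#' the admission as having suspected infection.
#' @return character vector of drug names.
#' @export
default_antibiotics <- function() {
  c("Vancomycin", "Piperacillin-Tazobactam", "Ceftriaxone",
    "Ciprofloxacin", "Meropenem", "Cefepime", "Levofloxacin")
}
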