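#' Default engine configuration
#'
#' Returns the shipped decision-table configuration: every numeric threshold,
#' lookback window and diagnosis keyword list the 23 metric evaluators
#' consult.  Only a handful of thresholds are fixed by the published rule
#' descriptions (hypoglycemia <= 70 mg/dL, mechanical-prophylaxis coverage
#' >= 75 percent of the current day, the coagulopathy cut-offs
#' platelets < 50 k/uL, INR >= 1.5, aPTT > 40 s over a 3-day lookback,
#' > 1 PRBC unit in 24 h, tidal volume 8 mL/kg predicted body weight, and the
#' 80 percent nutrition-adequacy target); the remainder are declared,
#' config-overridable defaults modelled on institutional critical-care
#' practice guidelines.  Override any entry with [load_config()].
#'
#' @return A named list of thresholds, windows and keyword lists.
#' @seealso [load_config()], [default_registry()]
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$hypoglycemia_mg_dl
default_config <- function() {
  list(
    tz = "UTC",

    # day-coverage rules abstain when less of the day has elapsed than this
    min_elapsed_hours = 4,

    # printed thresholds
    hypoglycemia_mg_dl   = 70,    # inclusive: <= 70 flags
    mech_vte_day_coverage = 0.75, # inclusive: >= 75% of elapsed day
    platelets_low_k      = 50,    # exclusive: < 50
    inr_high             = 1.5,   # inclusive: >= 1.5
    aptt_high_sec        = 40,    # exclusive: > 40
    coag_lookback_days   = 3,
    prbc_units_24h       = 1,     # flag-compatible only when <= 1 unit
    vt_per_kg_ml         = 8,     # flag when latest Vt/PBW exceeds this
    nutrition_adequacy   = 0.80,  # delivered/goal below this flags

    # declared defaults (not printed in any source table)
    nutrition_start_hours          = 48,
    sedation_min_infusion_hours    = 6,
    sbt_fio2_max                   = 0.5,
    sbt_peep_max                   = 8,
    sbt_vasopressor_lookback_hours = 4,
    line_vasopressor_lookback_hours = 12,
    abg_high_count_24h             = 4,
    dwell_limit_days = c(central_line = 7, arterial_line = 7,
                         hd_line = 7, picc = 30),

    # values substituted when a decision-relevant lab is absent
    normal_labs = c(glucose_mg_dl = 110, platelets_k_per_ul = 250,
                    inr = 1.0, aptt_sec = 30),

    # structured-diagnosis keyword lists (no free-text matching)
    bleeding_dx       = c("bleeding", "hematoma", "hemorrhage"),
    sedation_contraindication_dx = c("status_epilepticus",
                                     "intracranial_hypertension"),
    urinary_indication_dx = c("urinary_retention", "urinary_obstruction",
                              "bladder_irrigation"),
    central_indication_dx = c("active_hemodialysis"),
    picc_indication_dx    = c("long_course_iv_therapy"),
    skin_breakdown_dx     = c("skin_breakdown"),

    anticoagulant_classes = c("ufh_prophylactic", "lmwh_prophylactic",
                              "ufh_therapeutic", "lmwh_therapeutic",
                              "doac", "warfarin"),
    surveillance_line_devices = c("central_line", "picc", "hd_line")
  )
}

#' Load a configuration with YAML overrides
#'
#' Reads a YAML file whose keys mirror [default_config()] and merges it over
#' the defaults (shallow merge per top-level key; named numeric vectors such
#' as `normal_labs` are replaced wholesale when supplied).
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ov <- yaml::read_yaml(path)
  if (!is.list(ov)) stop("config file must be a YAML mapping", call. = FALSE)
  for (k in names(ov)) {
    v <- ov[[k]]
    if (k %in% c("dwell_limit_days", "normal_labs")) v <- unlist(v)
    cfg[[k]] <- v
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  num <- c("hypoglycemia_mg_dl", "mech_vte_day_coverage", "platelets_low_k",
           "inr_high", "aptt_high_sec", "coag_lookback_days", "prbc_units_24h",
           "vt_per_kg_ml", "nutrition_adequacy")
  for (k in num) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L || cfg[[k]] <= 0)
      stop("config entry '", k, "' must be a positive scalar", call. = FALSE)
  }
  if (cfg$mech_vte_day_coverage > 1 || cfg$nutrition_adequacy > 1)
    stop("coverage and adequacy thresholds must lie in (0, 1]", call. = FALSE)
  invisible(cfg)
}

# Devine predicted body weight (kg), floored at zero.
pbw_kg <- function(height_cm, sex) {
  base <- ifelse(sex == "female", 45.5, 50)
  pmax(0, base + 0.91 * (height_cm - 152.4))
}
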