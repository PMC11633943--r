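# Synthetic EHR patient-day generator.  Emits seeded patient-days with
# per-metric ground-truth labels, emulating the phenomena real ICU data
# shows: documentation variability (notes claiming medications the MAR never
# recorded), absent labs, and gaps that make exactly one metric actionable.
# One metric is perturbed per patient-day so labels are unambiguous; the one
# structural exception is the combined VTE metric, whose actionable state
# (no prophylaxis modality at all, no exclusions) necessarily makes the
# mechanical-prophylaxis metric actionable too, and both labels say so.

.syn_day_start <- function() as.POSIXct("2022-06-01 00:00:00", tz = "UTC")

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000003 + i * 7919) %% 2147483647)
}

#' Describe a synthetic cohort
#'
#' @param census_size Number of patient-days to generate.
#' @param seed Integer seed; identical seeds give byte-identical cohorts.
#' @param prevalence Probability that the perturbed metric of a patient-day
#'   is actionable: a scalar, or a named vector keyed by rule_id.
#' @param noise List with elements `note_claim` (probability of adding a
#'   flowsheet note claiming a medication the MAR never recorded),
#'   `lab_drop` (per-lab deletion probability) and `device_doc`
#'   (probability of a stray flowsheet device claim).
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(census_size = 50, seed = 1, prevalence = 0.5,
                          noise = list(note_claim = 0, lab_drop = 0,
                                       device_doc = 0)) {
  ids <- rule_ids()
  if (length(prevalence) == 1L && is.null(names(prevalence)))
    prevalence <- stats::setNames(rep(prevalence, length(ids)), ids)
  if (!all(names(prevalence) %in% ids))
    stop("prevalence names must be rule ids", call. = FALSE)
  prev <- stats::setNames(rep(0.5, length(ids)), ids)
  prev[names(prevalence)] <- prevalence
  if (any(prev < 0 | prev > 1)) stop("prevalence must lie in [0,1]", call. = FALSE)
  nz <- list(note_claim = 0, lab_drop = 0, device_doc = 0)
  nz[names(noise)] <- noise
  if (any(unlist(nz) < 0 | unlist(nz) > 1))
    stop("noise probabilities must lie in [0,1]", call. = FALSE)
  stopifnot(census_size >= 1)
  structure(list(census_size = as.integer(census_size),
                 seed = as.integer(seed), prevalence = prev, noise = nz),
            class = "scenario_spec")
}

# ---- per-rule scenario builders -----------------------------------------
# Each builder returns list(extra = list of events, drop_lmwh, drop_nutrition,
# admit_h, colabels).  The ambient baseline (built in scenario_patient) keeps
# every other metric non-actionable: normal glucose, an active prophylactic
# LMWH order, adequate enteral nutrition once 48 h post admission, full code,
# no devices.

syn_builders <- function() {
  ds <- .syn_day_start()
  ev <- function(h) ds + h * 3600
  base <- function(extra, drop_lmwh = FALSE, drop_nutrition = FALSE,
                   admit_h = 72, colabels = NULL)
    list(extra = extra, drop_lmwh = drop_lmwh,
         drop_nutrition = drop_nutrition, admit_h = admit_h,
         colabels = colabels)
  ventilated <- function(pid, fio2, vt = 400, peep = 6) list(
    clinical_event("device", pid, ev(-30), device = "ett", site = "other",
                   placed_outside = FALSE),
    clinical_event("vent_obs", pid, ev(6), vent_mode = "controlled",
                   tidal_volume_ml = vt, fio2 = fio2, peep_cmh2o = peep),
    clinical_event("med_order", pid, ev(-30),
                   drug_class = "acid_suppressant", status = "active",
                   route = "iv"))
  list(
    hypoglycemia = function(pid, act) base(list(
      clinical_event("lab", pid, ev(8), analyte = "glucose_mg_dl",
                     value = if (act) runif(1, 45, 70) else runif(1, 75, 100),
                     result_time = ev(8)))),
    vte_chemical = function(pid, act) base(
      drop_lmwh = act,
      extra = list(clinical_event("device", pid, ev(0), device = "compression_device",
                                  site = "other", placed_outside = FALSE))),
    vte_mechanical = function(pid, act) base(
      drop_lmwh = TRUE,
      extra = c(list(
        clinical_event("lab", pid, ev(-12), analyte = "inr",
                       value = runif(1, 1.6, 2.4), result_time = ev(-12)),
        clinical_event("med_order", pid, ev(-40),
                       drug_class = "acid_suppressant", status = "active",
                       route = "iv")),
        if (!act) list(clinical_event("device", pid, ev(0),
                                      device = "compression_device",
                                      site = "other", placed_outside = FALSE)))),
    vte_any = function(pid, act) base(
      drop_lmwh = TRUE,
      extra = if (!act) list(
        clinical_event("activity_order", pid, ev(-20), activity = "ambulate")),
      colabels = if (act) c(vte_mechanical = TRUE)),
    sup_start = function(pid, act) {
      vent <- ventilated(pid, fio2 = 0.6)
      if (act) vent <- vent[1:2]            # drop the acid suppressant
      base(vent)
    },
    sup_stop = function(pid, act) base(c(
      list(clinical_event("med_order", pid, ev(-40),
                          drug_class = "acid_suppressant", status = "active",
                          route = "iv")),
      if (!act) list(clinical_event("lab", pid, ev(-10), analyte = "inr",
                                    value = runif(1, 1.6, 2.2),
                                    result_time = ev(-10))))),
    low_tidal_volume = function(pid, act, pbw) base(
      ventilated(pid, fio2 = 0.6,
                 vt = pbw * if (act) runif(1, 8.5, 10) else runif(1, 6, 7.6))),
    sedation_wean = function(pid, act) base(c(list(
      clinical_event("med_order", pid, ev(-20),
                     drug_class = "sedative_infusion", status = "active",
                     route = "iv"),
      clinical_event("med_admin", pid, ev(8), end = ev(16),
                     drug_class = "sedative_infusion", action = "given",
                     dose_time = ev(8))),
      if (!act) list(clinical_event("med_order", pid, ev(-10),
                                    drug_class = "paralytic",
                                    status = "active", route = "iv")))),
    sbt_ready = function(pid, act) base(c(
      ventilated(pid, fio2 = 0.4, peep = 5),
      if (!act) list(clinical_event("med_admin", pid, ev(14),
                                    drug_class = "vasopressor",
                                    action = "given", dose_time = ev(14))))),
    sbt_passed = function(pid, act) base(c(
      ventilated(pid, fio2 = 0.4, peep = 5),
      list(clinical_event("vent_obs", pid, ev(8), vent_mode = "spontaneous",
                          sbt_result = if (act) "passed" else "failed")))),
    nutrition_start = function(pid, act) base(
      drop_nutrition = act, extra = list()),
    nutrition_adequacy = function(pid, act) base(
      drop_nutrition = TRUE,
      extra = list(clinical_event("nutrition", pid, ev(-8), end = NA,
                                  nutrition_route = "enteral",
                                  goal_kcal_day = 2000,
                                  delivered_kcal = if (act) runif(1, 900, 1400)
                                                   else runif(1, 1700, 1950)))),
    urinary_catheter_removal = function(pid, act) base(c(
      list(clinical_event("device", pid, ev(-40), device = "urinary_catheter",
                          site = "other", placed_outside = FALSE)),
      if (!act) list(clinical_event("diagnosis", pid, ev(-40),
                                    dx_code = "urinary_retention")))),
    central_line_removal = function(pid, act) base(c(
      list(clinical_event("device", pid, ev(-48), device = "central_line",
                          site = "ij", placed_outside = FALSE)),
      if (!act) list(clinical_event("med_admin", pid, ev(10),
                                    drug_class = "vasopressor",
                                    action = "given", dose_time = ev(10))))),
    arterial_line_removal = function(pid, act) base(c(
      list(clinical_event("device", pid, ev(-48), device = "arterial_line",
                          site = "radial", placed_outside = FALSE)),
      if (!act) lapply(seq(2, 14, by = 3), function(h)
        clinical_event("lab", pid, ev(h), analyte = "abg", value = 7.4,
                       result_time = ev(h))))),
    picc_removal = function(pid, act) base(c(
      list(clinical_event("device", pid, ev(-70), device = "picc",
                          site = "other", placed_outside = FALSE)),
      if (!act) list(clinical_event("diagnosis", pid, ev(-70),
                                    dx_code = "long_course_iv_therapy")))),
    surveillance_culture = function(pid, act) base(
      admit_h = 24,
      extra = c(list(
        clinical_event("device", pid, ev(-24), device = "picc",
                       site = "other", placed_outside = TRUE),
        clinical_event("diagnosis", pid, ev(-24),
                       dx_code = "long_course_iv_therapy")),
        if (!act) list(clinical_event("lab", pid, ev(-12),
                                      analyte = "blood_culture", value = 1,
                                      result_time = ev(-12))))),
    rectal_tube_removal = function(pid, act) base(c(
      list(clinical_event("device", pid, ev(-48), device = "rectal_tube",
                          site = "other", placed_outside = FALSE)),
      if (!act) list(
        clinical_event("flowsheet_doc", pid, ev(10),
                       doc_type = "liquid_stool"),
        clinical_event("diagnosis", pid, ev(-48),
                       dx_code = "skin_breakdown")))),
    ng_to_og = function(pid, act) base(c(
      list(clinical_event("device", pid, ev(-24), device = "ngt",
                          site = "other", placed_outside = FALSE)),
      if (act) ventilated(pid, fio2 = 0.6))),
    high_risk_central_line = function(pid, act) base(list(
      clinical_event("device", pid, ev(-48), device = "central_line",
                     site = if (act) "femoral" else "ij",
                     placed_outside = FALSE),
      clinical_event("med_admin", pid, ev(10), drug_class = "vasopressor",
                     action = "given", dose_time = ev(10)))),
    high_risk_arterial_line = function(pid, act) base(
      admit_h = 24 * 12,
      extra = list(
        clinical_event("device", pid, ev(if (act) -24 * 9 else -48),
                       device = "arterial_line", site = "radial",
                       placed_outside = FALSE),
        clinical_event("med_admin", pid, ev(10), drug_class = "vasopressor",
                       action = "given", dose_time = ev(10)))),
    high_risk_hd_line = function(pid, act) base(list(
      clinical_event("device", pid, ev(-48), device = "hd_line",
                     site = if (act) "femoral" else "ij",
                     placed_outside = FALSE))),
    high_risk_picc = function(pid, act) base(
      admit_h = 24 * 35,
      extra = list(
        clinical_event("device", pid, ev(if (act) -24 * 31 else -24 * 10),
                       device = "picc", site = "other",
                       placed_outside = FALSE),
        clinical_event("diagnosis", pid, ev(-24 * 31),
                       dx_code = "long_course_iv_therapy")))
  )
}

#' Generate one labelled patient-day
#'
#' Builds a patient-day whose ground truth for `rule_id` is `actionable`
#' under the shipped default decision tables, with every other metric driven
#' non-actionable (except the documented combined-VTE/mechanical-VTE
#' co-activation).  Deterministic per seed.
#'
#' @param rule_id A registered metric identifier.
#' @param actionable Logical ground truth for that metric.
#' @param seed Integer seed.
#' @param patient_id Identifier for the emitted patient.
#' @return `list(events, attributes, labels, eval_time)`; `labels` is a named
#'   logical vector over all registered metrics.
#' @export
generate_patient_day <- function(rule_id, actionable, seed = 1,
                                 patient_id = "p0001") {
  ids <- rule_ids()
  if (!rule_id %in% ids)
    stop("unknown rule_id: ", rule_id, call. = FALSE)
  with_seed(seed, {
    height_cm <- round(runif(1, 160, 190), 1)
    sex <- sample(c("male", "female"), 1)
    builder <- syn_builders()[[rule_id]]
    b <- if ("pbw" %in% names(formals(builder)))
      builder(patient_id, isTRUE(actionable), pbw_kg(height_cm, sex))
    else builder(patient_id, isTRUE(actionable))
    ds <- .syn_day_start()
    eval_time <- ds + 16 * 3600
    admit <- ds - b$admit_h * 3600
    attrs <- patient_attributes(patient_id, height_cm = height_cm, sex = sex,
                                admit_time = admit)
    baseline <- c(
      list(
        clinical_event("code_status", patient_id, admit,
                       code_status = "full_code"),
        clinical_event("lab", patient_id, ds + 6 * 3600,
                       analyte = "glucose_mg_dl",
                       value = runif(1, 90, 140),
                       result_time = ds + 6 * 3600)),
      if (!b$drop_lmwh) list(
        clinical_event("med_order", patient_id, admit,
                       drug_class = "lmwh_prophylactic", status = "active",
                       route = "sc")),
      if (!b$drop_nutrition && b$admit_h >= 48) list(
        clinical_event("nutrition", patient_id, ds - 8 * 3600, end = NA,
                       nutrition_route = "enteral", goal_kcal_day = 2000,
                       delivered_kcal = runif(1, 1700, 1950))))
    events <- bind_events(c(baseline, b$extra))
    labels <- stats::setNames(rep(FALSE, length(ids)), ids)
    labels[rule_id] <- isTRUE(actionable)
    if (isTRUE(actionable) && !is.null(b$colabels))
      labels[names(b$colabels)] <- b$colabels
    list(events = events, attributes = attrs, labels = labels,
         eval_time = eval_time)
  })
}

#' Generate a labelled synthetic cohort
#'
#' One perturbed metric per patient-day, drawn uniformly over the registry;
#' its actionable state is drawn from the per-metric prevalence.  Noise is
#' then injected per the spec.  Reproducible: the same spec yields an
#' identical cohort.
#'
#' @param spec A [scenario_spec()].
#' @return `list(events, patients, truth, eval_time)`: the pooled event
#'   table, a patient attribute table, the long ground-truth table
#'   (`patient_id, rule_id, actionable`), and the shared evaluation time.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  ids <- rule_ids()
  with_seed(spec$seed, {
    pick_rule <- sample(ids, spec$census_size, replace = TRUE)
    pick_act <- stats::runif(spec$census_size) < spec$prevalence[pick_rule]
    seeds <- vapply(seq_len(spec$census_size),
                    function(i) derive_seed(spec$seed, i), integer(1))
    days <- lapply(seq_len(spec$census_size), function(i)
      generate_patient_day(pick_rule[i], pick_act[i], seed = seeds[i],
                           patient_id = sprintf("p%04d", i)))
    events <- bind_events(lapply(days, `[[`, "events"))
    events <- inject_noise(events, spec$noise, seed = derive_seed(spec$seed, 0))
    patients <- do.call(rbind, lapply(days, function(d) data.frame(
      patient_id = d$attributes$patient_id,
      height_cm = d$attributes$height_cm,
      sex = d$attributes$sex,
      admit_time = format_time(d$attributes$admit_time),
      stringsAsFactors = FALSE)))
    truth <- do.call(rbind, lapply(days, function(d) data.frame(
      patient_id = d$attributes$patient_id,
      rule_id = names(d$labels),
      actionable = unname(d$labels),
      row.names = NULL, stringsAsFactors = FALSE)))
    list(events = events, patients = patients, truth = truth,
         eval_time = days[[1]]$eval_time)
  })
}

#' Inject documentation noise into an event stream
#'
#' Emulates the data phenomena that make naive chart logic unreliable:
#' provider flowsheet notes claiming a medication was given when the MAR
#' (medication administration record) has no such action, stray flowsheet
#' device claims, and labs that were simply never drawn.  MAR `med_admin`
#' events are never altered — they are the source of truth.
#'
#' @param events Event data.frame.
#' @param noise List as in [scenario_spec()].
#' @param seed Integer seed.
#' @return Perturbed event data.frame.
#' @export
inject_noise <- function(events, noise, seed = 1) {
  nz <- list(note_claim = 0, lab_drop = 0, device_doc = 0)
  nz[names(noise)] <- noise
  if (all(unlist(nz) == 0)) return(events)
  with_seed(seed, {
    pids <- unique(events$patient_id)
    add <- list()
    for (pid in pids) {
      if (stats::runif(1) < nz$note_claim) {
        mine <- events[events$patient_id == pid, ]
        claimed <- setdiff(DRUG_CLASSES,
                           mine$drug_class[mine$kind == "med_admin"])
        cls <- claimed[1 + floor(stats::runif(1) * length(claimed))]
        add <- c(add, list(clinical_event(
          "flowsheet_doc", pid, .syn_day_start() + 10 * 3600,
          doc_type = "med_given_claim", doc_value = cls)))
      }
      if (stats::runif(1) < nz$device_doc) {
        add <- c(add, list(clinical_event(
          "flowsheet_doc", pid, .syn_day_start() + 11 * 3600,
          doc_type = "device_claim", doc_value = "central_line")))
      }
    }
    if (nz$lab_drop > 0) {
      is_lab <- events$kind == "lab"
      drop <- is_lab & stats::runif(nrow(events)) < nz$lab_drop
      events <- events[!drop, , drop = FALSE]
    }
    bind_events(c(list(events), add))
  })
}

#' Evaluate every patient-day of a cohort
#'
#' @param cohort Output of [generate_cohort()] (or a compatible list with
#'   `events`, `patients`, `eval_time`).
#' @param config Engine configuration.
#' @return Flags data.frame: `patient_id, rule_id, flag, abstained, reasons`.
#' @export
evaluate_cohort <- function(cohort, config = default_config()) {
  registry <- default_registry(config)
  ev_split <- split(cohort$events, cohort$events$patient_id)
  out <- vector("list", nrow(cohort$patients))
  for (i in seq_len(nrow(cohort$patients))) {
    p <- cohort$patients[i, ]
    attrs <- patient_attributes(p$patient_id, p$height_cm, p$sex,
                                p$admit_time)
    evs <- ev_split[[p$patient_id]]
    if (is.null(evs)) evs <- empty_events()
    ctx <- assemble_patient_day(evs, attrs, cohort$eval_time, config)
    out[[i]] <- results_to_frame(evaluate_patient_day(ctx, registry, config))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
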