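# Patient-day context: the assembled, queryable view of one patient at one
# evaluation time.  All rule evaluation is a pure function of this object.

#' Patient attributes
#'
#' @param patient_id Identifier matching the event stream.
#' @param height_cm Height in cm, must lie in (100, 250).
#' @param sex `"female"` or `"male"` (used for predicted body weight).
#' @param admit_time Admission timestamp (ISO-8601 or POSIXct).
#' @return A `patient_attributes` list.
#' @export
patient_attributes <- function(patient_id, height_cm, sex, admit_time) {
  if (!is.numeric(height_cm) || is.na(height_cm) ||
      height_cm <= 100 || height_cm >= 250)
    stop("height_cm must lie in (100, 250)", call. = FALSE)
  if (!sex %in% c("female", "male"))
    stop("sex must be 'female' or 'male'", call. = FALSE)
  structure(list(patient_id = patient_id, height_cm = height_cm, sex = sex,
                 admit_time = parse_time(admit_time)),
            class = "patient_attributes")
}

#' Assemble a patient-day context
#'
#' Deduplicates, validates and time-sorts one patient's event stream and fixes
#' the evaluation instant.  The "current day" runs from local midnight
#' (`day_start`, in the configured time zone) to `eval_time`; day-coverage
#' denominators use this elapsed span.  Assembly is deterministic: permuting
#' the input rows yields an identical context.
#'
#' @param events Event data.frame (may be empty); all rows must share one
#'   `patient_id`.
#' @param attributes A [patient_attributes()] object for the same patient.
#' @param eval_time Evaluation timestamp.
#' @param config Engine configuration, see [default_config()].
#' @return A `patient_day` object.
#' @export
assemble_patient_day <- function(events, attributes, eval_time,
                                 config = default_config()) {
  validate_events(events)
  eval_time <- parse_time(eval_time, config$tz)
  if (nrow(events) > 0L) {
    pids <- unique(events$patient_id)
    if (length(pids) != 1L)
      stop("events mix patient_ids: ", paste(pids, collapse = ", "),
           call. = FALSE)
    if (!is.null(attributes$patient_id) && pids != attributes$patient_id)
      stop("events and attributes disagree on patient_id", call. = FALSE)
  }
  if (anyNA(events$recorded)) {
    miss <- is.na(events$recorded)
    events$recorded[miss] <- seq_len(nrow(events))[miss]
  }
  events <- dedup_events(events)
  o <- order(as.numeric(events$start), events$event_id)
  events <- events[o, , drop = FALSE]
  rownames(events) <- NULL

  early <- as.numeric(events$start) < as.numeric(attributes$admit_time)
  if (any(early))
    warning(sum(early), " event(s) precede admit_time; kept", call. = FALSE)

  day_start <- as.POSIXct(
    format(eval_time, "%Y-%m-%d", tz = config$tz), tz = config$tz)

  by_kind <- split(events, factor(events$kind, levels = EVENT_KINDS))
  structure(list(
    patient_id = attributes$patient_id,
    eval_time = eval_time,
    day_start = day_start,
    elapsed_s = as.numeric(eval_time) - as.numeric(day_start),
    events = events,
    by_kind = by_kind,
    attributes = attributes,
    config = config), class = "patient_day")
}

#' @export
print.patient_day <- function(x, ...) {
  cat("<patient_day> ", x$patient_id, " @ ", format_time(x$eval_time),
      " (", round(x$elapsed_s / 3600, 1), " h elapsed, ",
      nrow(x$events), " events)\n", sep = "")
  invisible(x)
}

kind_events <- function(ctx, kind) {
  df <- ctx$by_kind[[kind]]
  if (is.null(df)) empty_events() else df
}

#' Most recent lab of an analyte within a lookback window
#'
#' Scans labs with `result_time` in `[eval_time - lookback, eval_time]` and
#' returns the latest one; ties on `result_time` are broken by the
#' latest-recorded event.  Absence is a valid outcome (`NULL`), to be mapped
#' by the missing-data policy.
#'
#' @param ctx A `patient_day`.
#' @param analyte Lab analyte name.
#' @param lookback_s Lookback in seconds (> 0).
#' @return `list(value=, result_time=)` or `NULL`.
#' @export
latest_lab_in_window <- function(ctx, analyte, lookback_s) {
  stopifnot(lookback_s > 0)
  labs <- kind_events(ctx, "lab")
  if (nrow(labs) == 0L) return(NULL)
  t0 <- as.numeric(ctx$eval_time) - lookback_s
  rt <- as.numeric(labs$result_time)
  sel <- labs$analyte == analyte & rt >= t0 & rt <= as.numeric(ctx$eval_time)
  if (!any(sel)) return(NULL)
  cand <- labs[sel, , drop = FALSE]
  i <- order(as.numeric(cand$result_time), cand$recorded)
  top <- cand[i[length(i)], ]
  list(value = top$value, result_time = top$result_time)
}

# All values of an analyte with result_time in [from, to] (numeric seconds).
lab_values_in_window <- function(ctx, analyte, from, to) {
  labs <- kind_events(ctx, "lab")
  if (nrow(labs) == 0L) return(numeric(0))
  rt <- as.numeric(labs$result_time)
  labs$value[labs$analyte == analyte & rt >= from & rt <= to]
}

#' Medication orders active at an instant
#'
#' @param ctx A `patient_day`.
#' @param drug_classes Character vector of drug classes to match.
#' @param at Timestamp (defaults to the context's `eval_time`).
#' @return Data.frame of matching `med_order` events (status `active`, with
#'   effective interval containing `at`).
#' @export
active_orders_at <- function(ctx, drug_classes, at = ctx$eval_time) {
  ord <- kind_events(ctx, "med_order")
  if (nrow(ord) == 0L) return(ord)
  at <- as.numeric(parse_time(at))
  e <- as.numeric(ord$end)
  sel <- ord$status == "active" & ord$drug_class %in% drug_classes &
    as.numeric(ord$start) <= at & (is.na(e) | e > at)
  ord[sel, , drop = FALSE]
}

# Raw device episodes for one device type: start/end (end clipped at
# eval_time; NA end treated as ongoing) plus active-at-eval flag.
device_episodes <- function(ctx, device) {
  dev <- kind_events(ctx, "device")
  dev <- dev[dev$device == device, , drop = FALSE]
  if (nrow(dev) == 0L)
    return(data.frame(start = numeric(0), end = numeric(0),
                      active = logical(0), site = character(0),
                      placed_outside = logical(0)))
  ev <- as.numeric(ctx$eval_time)
  s <- as.numeric(dev$start); e <- as.numeric(dev$end)
  active <- s <= ev & (is.na(e) | e > ev)
  e[is.na(e)] <- Inf
  data.frame(start = s, end = pmin(e, ev), active = active,
             site = dev$site, placed_outside = dev$placed_outside,
             stringsAsFactors = FALSE)
}

#' Device presence intervals within the current day
#'
#' Episodes of one device type clipped to `[day_start, eval_time)`; open
#' episodes are clipped at `eval_time`.  Used for day-coverage criteria.
#'
#' @param ctx A `patient_day`.
#' @param device Device type name.
#' @return Data.frame with numeric `start`/`end` columns (seconds), possibly
#'   zero rows.
#' @export
device_active_intervals <- function(ctx, device) {
  ep <- device_episodes(ctx, device)
  if (nrow(ep) == 0L)
    return(data.frame(start = numeric(0), end = numeric(0)))
  ds <- as.numeric(ctx$day_start); ev <- as.numeric(ctx$eval_time)
  s <- pmax(ep$start, ds); e <- pmin(ep$end, ev)
  keep <- e > s
  data.frame(start = s[keep], end = e[keep])
}

device_active_at <- function(ctx, device) {
  any(device_episodes(ctx, device)$active)
}

# Comfort-care status at an instant: the latest code_status event with
# start <= at decides; no code_status events => not comfort care.
comfort_care_at <- function(ctx, at = ctx$eval_time) {
  cs <- kind_events(ctx, "code_status")
  if (nrow(cs) == 0L) return(FALSE)
  at <- as.numeric(parse_time(at))
  sel <- as.numeric(cs$start) <= at
  if (!any(sel)) return(FALSE)
  cand <- cs[sel, , drop = FALSE]
  i <- order(as.numeric(cand$start), cand$recorded)
  cand$code_status[i[length(i)]] == "comfort_care"
}

# Structured diagnoses with code in `codes` active at an instant.
dx_active_at <- function(ctx, codes, at = ctx$eval_time) {
  dx <- kind_events(ctx, "diagnosis")
  if (nrow(dx) == 0L) return(FALSE)
  at <- as.numeric(parse_time(at))
  e <- as.numeric(dx$end)
  any(dx$dx_code %in% codes & as.numeric(dx$start) <= at & (is.na(e) | e > at))
}

# PRBC units transfused with start in (eval_time - hours, eval_time].
prbc_units_in_window <- function(ctx, hours = 24) {
  tr <- kind_events(ctx, "transfusion")
  if (nrow(tr) == 0L) return(0)
  ev <- as.numeric(ctx$eval_time)
  s <- as.numeric(tr$start)
  sum(tr$units[tr$product == "prbc" & s > ev - hours * 3600 & s <= ev])
}

# Medication administrations (MAR).  This is the source of truth for whether
# a drug was actually given: flowsheet_doc claims without a matching
# med_admin are never consulted by medication-dependent queries.
admins_in_window <- function(ctx, drug_classes, from, to, action = "given") {
  ad <- kind_events(ctx, "med_admin")
  if (nrow(ad) == 0L) return(ad)
  dt <- as.numeric(ad$dose_time)
  ad[ad$drug_class %in% drug_classes & ad$action %in% action &
       dt > from & dt <= to, , drop = FALSE]
}

# Union-covered seconds of given-administration intervals of a drug class
# within the current day (for infusion-time criteria).
admin_covered_seconds_today <- function(ctx, drug_class) {
  ad <- kind_events(ctx, "med_admin")
  ad <- ad[ad$drug_class == drug_class & ad$action == "given", , drop = FALSE]
  if (nrow(ad) == 0L) return(0)
  ds <- as.numeric(ctx$day_start); ev <- as.numeric(ctx$eval_time)
  iv <- data.frame(start = as.numeric(ad$start), end = as.numeric(ad$end))
  iv$end[is.na(iv$end)] <- ev
  keep <- iv$end > iv$start
  if (!any(keep)) return(0)
  covered_seconds(iv[keep, ], c(ds, ev))
}

# Activity order (e.g. ambulate, strict_io) active at an instant.
activity_active_at <- function(ctx, activity, at = ctx$eval_time) {
  ao <- kind_events(ctx, "activity_order")
  if (nrow(ao) == 0L) return(FALSE)
  at <- as.numeric(parse_time(at))
  e <- as.numeric(ao$end)
  any(ao$activity %in% activity & as.numeric(ao$start) <= at &
        (is.na(e) | e > at))
}

# Latest ventilator observation at or before eval_time with a non-NA value in
# column `field` (NULL field = latest observation overall).
latest_vent_obs <- function(ctx, field = NULL) {
  vo <- kind_events(ctx, "vent_obs")
  if (nrow(vo) == 0L) return(NULL)
  ev <- as.numeric(ctx$eval_time)
  sel <- as.numeric(vo$start) <= ev
  if (!is.null(field)) sel <- sel & !is.na(vo[[field]])
  if (!any(sel)) return(NULL)
  cand <- vo[sel, , drop = FALSE]
  i <- order(as.numeric(cand$start), cand$recorded)
  cand[i[length(i)], ]
}

# Flowsheet documentation rows of a doc_type with start in [from, to].
flowsheet_in_window <- function(ctx, doc_type, from, to) {
  fs <- kind_events(ctx, "flowsheet_doc")
  if (nrow(fs) == 0L) return(fs)
  s <- as.numeric(fs$start)
  fs[fs$doc_type == doc_type & s >= from & s <= to, , drop = FALSE]
}
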