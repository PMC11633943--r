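# The 23 metric evaluators.  Each takes (ctx, cfg) and returns
# list(flag, reasons, inputs, abstained).  Comparator directions follow the
# published rule text exactly where printed (<=70; >=75%; <50; >=1.5; >40;
# >1 unit; 8 mL/kg; 80% of need); everything else is a declared default in
# default_config().

# ---- shared sub-criteria -------------------------------------------------

chem_anticoag_active <- function(ctx, cfg) {
  nrow(active_orders_at(ctx, cfg$anticoagulant_classes)) > 0L
}

compression_cov <- function(ctx) {
  iv <- device_active_intervals(ctx, "compression_device")
  coverage_fraction(iv, c(as.numeric(ctx$day_start), as.numeric(ctx$eval_time)))
}

# Coagulopathy over the lookback window: any platelets < 50 k/uL, INR >= 1.5
# or aPTT > 40 s.  Absent labs are assumed within normal limits.
coagulopathic <- function(ctx, cfg, inputs = NULL) {
  ev <- as.numeric(ctx$eval_time)
  from <- ev - cfg$coag_lookback_days * 86400
  plt  <- lab_values_in_window(ctx, "platelets_k_per_ul", from, ev)
  inr  <- lab_values_in_window(ctx, "inr", from, ev)
  aptt <- lab_values_in_window(ctx, "aptt_sec", from, ev)
  r_plt  <- resolve_missing("platelets", plt, "lab_missing",
                            cfg$normal_labs[["platelets_k_per_ul"]])
  r_inr  <- resolve_missing("inr", inr, "lab_missing",
                            cfg$normal_labs[["inr"]])
  r_aptt <- resolve_missing("aptt", aptt, "lab_missing",
                            cfg$normal_labs[["aptt_sec"]])
  coag <- any(r_plt$value < cfg$platelets_low_k) ||
    any(r_inr$value >= cfg$inr_high) ||
    any(r_aptt$value > cfg$aptt_high_sec)
  list(coag = coag,
       inputs = list(platelets = tag_input(r_plt), inr = tag_input(r_inr),
                     aptt = tag_input(r_aptt)))
}

tag_input <- function(r) {
  if (r$finding == "observed") r$value
  else if (r$finding == "assumed_normal")
    paste0("missing(assumed_normal=", r$value, ")")
  else paste0("missing(", r$finding, "_finding)")
}

ambulatory_at <- function(ctx) activity_active_at(ctx, "ambulate")

vaso_admin_within_h <- function(ctx, hours) {
  ev <- as.numeric(ctx$eval_time)
  nrow(admins_in_window(ctx, "vasopressor", ev - hours * 3600, ev)) > 0L
}

abstain_early_day <- function(ctx, cfg) {
  if (ctx$elapsed_s < cfg$min_elapsed_hours * 3600)
    list(flag = FALSE, abstained = TRUE,
         reasons = "insufficient_elapsed_day",
         inputs = list(elapsed_hours = ctx$elapsed_s / 3600))
  else NULL
}

# Shared VTE exclusion battery: criteria (c)-(g).  Returns NULL when no
# exclusion applies, otherwise the blocking reason codes.
vte_exclusions <- function(ctx, cfg) {
  cg <- coagulopathic(ctx, cfg)
  bleed   <- dx_active_at(ctx, cfg$bleeding_dx)
  comfort <- comfort_care_at(ctx)
  prbc    <- prbc_units_in_window(ctx, 24)
  amb     <- ambulatory_at(ctx)
  reasons <- c(
    if (cg$coag) "coagulopathic",
    if (bleed) "active_bleeding_dx",
    if (comfort) "comfort_care",
    if (prbc > cfg$prbc_units_24h) "prbc_gt_1_unit_24h",
    if (amb) "ambulatory")
  list(blocked = length(reasons) > 0L, reasons = reasons,
       inputs = c(cg$inputs, list(bleeding_dx = bleed, comfort_care = comfort,
                                  prbc_units_24h = prbc, ambulatory = amb)))
}

# ---- evaluators ----------------------------------------------------------

#' Metric evaluators
#'
#' The individual daily-metric evaluators.  Each is a pure function of a
#' `patient_day` context and a configuration, returning the flag decision,
#' ordered reason codes (one per satisfied or blocking criterion) and the
#' inputs consulted.  They are normally invoked through
#' [evaluate_patient_day()]; they are exported so a single metric can be run
#' or audited in isolation.
#'
#' @param ctx A `patient_day` context from [assemble_patient_day()].
#' @param cfg Engine configuration, see [default_config()].
#' @param device,line Device type for the removal / line-risk families.
#' @return `list(flag, reasons, inputs, abstained)`.
#' @name metric-evaluators
NULL

#' @rdname metric-evaluators
#' @export
eval_hypoglycemia <- function(ctx, cfg) {
  ds <- as.numeric(ctx$day_start); ev <- as.numeric(ctx$eval_time)
  glu <- lab_values_in_window(ctx, "glucose_mg_dl", ds, ev)
  r <- resolve_missing("glucose", glu, "lab_missing",
                       cfg$normal_labs[["glucose_mg_dl"]])
  low <- any(r$value <= cfg$hypoglycemia_mg_dl)
  list(flag = low,
       reasons = if (low) "glucose_le_70_today" else "no_hypoglycemia_today",
       inputs = list(glucose = tag_input(r)))
}

#' @rdname metric-evaluators
#' @export
eval_vte_chemical <- function(ctx, cfg) {
  ab <- abstain_early_day(ctx, cfg); if (!is.null(ab)) return(ab)
  cov <- compression_cov(ctx)
  chem <- chem_anticoag_active(ctx, cfg)
  ex <- vte_exclusions(ctx, cfg)
  inputs <- c(list(compression_coverage = cov, anticoagulant_active = chem),
              ex$inputs)
  if (cov < cfg$mech_vte_day_coverage)
    return(list(flag = FALSE, reasons = "mech_coverage_below_75pct",
                inputs = inputs))
  if (chem)
    return(list(flag = FALSE, reasons = "chemical_prophylaxis_active",
                inputs = inputs))
  if (ex$blocked)
    return(list(flag = FALSE, reasons = ex$reasons, inputs = inputs))
  list(flag = TRUE,
       reasons = c("mech_coverage_ge_75pct", "no_chemical_prophylaxis",
                   "no_exclusion"),
       inputs = inputs)
}

#' @rdname metric-evaluators
#' @export
eval_vte_mechanical <- function(ctx, cfg) {
  ab <- abstain_early_day(ctx, cfg); if (!is.null(ab)) return(ab)
  cov <- compression_cov(ctx)
  chem <- chem_anticoag_active(ctx, cfg)
  amb <- ambulatory_at(ctx)
  comfort <- comfort_care_at(ctx)
  inputs <- list(compression_coverage = cov, anticoagulant_active = chem,
                 ambulatory = amb, comfort_care = comfort)
  blocked <- c(if (chem) "chemical_prophylaxis_active",
               if (cov >= cfg$mech_vte_day_coverage) "mech_coverage_ge_75pct",
               if (amb) "ambulatory",
               if (comfort) "comfort_care")
  if (length(blocked))
    return(list(flag = FALSE, reasons = blocked, inputs = inputs))
  list(flag = TRUE,
       reasons = c("no_chemical_prophylaxis", "mech_coverage_below_75pct"),
       inputs = inputs)
}

#' @rdname metric-evaluators
#' @export
eval_vte_any <- function(ctx, cfg) {
  ab <- abstain_early_day(ctx, cfg); if (!is.null(ab)) return(ab)
  cov <- compression_cov(ctx)
  chem <- chem_anticoag_active(ctx, cfg)
  ex <- vte_exclusions(ctx, cfg)
  inputs <- c(list(compression_coverage = cov, anticoagulant_active = chem),
              ex$inputs)
  blocked <- c(if (chem) "chemical_prophylaxis_active",
               if (cov >= cfg$mech_vte_day_coverage) "mech_coverage_ge_75pct",
               ex$reasons)
  if (length(blocked))
    return(list(flag = FALSE, reasons = blocked, inputs = inputs))
  list(flag = TRUE, reasons = c("no_vte_prophylaxis_modality", "no_exclusion"),
       inputs = inputs)
}

sup_risk_factor <- function(ctx, cfg) {
  vent <- device_active_at(ctx, "ett")
  cg <- coagulopathic(ctx, cfg)
  list(risk = vent || cg$coag, vent = vent, coag = cg$coag,
       inputs = c(list(mech_vent = vent), cg$inputs))
}

#' @rdname metric-evaluators
#' @export
eval_sup_start <- function(ctx, cfg) {
  rf <- sup_risk_factor(ctx, cfg)
  acid <- nrow(active_orders_at(ctx, "acid_suppressant")) > 0L
  comfort <- comfort_care_at(ctx)
  inputs <- c(rf$inputs, list(acid_suppressant_active = acid,
                              comfort_care = comfort))
  flag <- rf$risk && !acid && !comfort
  reasons <- if (flag)
    c(if (rf$vent) "mech_vent_risk_factor",
      if (rf$coag) "coagulopathy_risk_factor", "no_acid_suppressant")
  else c(if (!rf$risk) "no_sup_risk_factor",
         if (acid) "acid_suppressant_active",
         if (comfort) "comfort_care")
  list(flag = flag, reasons = reasons, inputs = inputs)
}

#' @rdname metric-evaluators
#' @export
eval_sup_stop <- function(ctx, cfg) {
  rf <- sup_risk_factor(ctx, cfg)
  acid <- nrow(active_orders_at(ctx, "acid_suppressant")) > 0L
  inputs <- c(rf$inputs, list(acid_suppressant_active = acid))
  flag <- acid && !rf$risk
  reasons <- if (flag) c("acid_suppressant_active", "no_sup_risk_factor")
  else c(if (!acid) "no_acid_suppressant",
         if (rf$risk) "sup_risk_factor_active")
  list(flag = flag, reasons = reasons, inputs = inputs)
}

#' @rdname metric-evaluators
#' @export
eval_low_tidal_volume <- function(ctx, cfg) {
  ett <- device_active_at(ctx, "ett")
  obs <- latest_vent_obs(ctx)
  if (!ett || is.null(obs))
    return(list(flag = FALSE, reasons = "not_ventilated",
                inputs = list(ett_active = ett)))
  if (obs$vent_mode != "controlled")
    return(list(flag = FALSE, reasons = "not_controlled_mode",
                inputs = list(ett_active = ett, vent_mode = obs$vent_mode)))
  vt_obs <- latest_vent_obs(ctx, "tidal_volume_ml")
  if (is.null(vt_obs))
    return(list(flag = FALSE, reasons = "tidal_volume_undocumented",
                inputs = list(ett_active = ett, vent_mode = obs$vent_mode)))
  pbw <- pbw_kg(ctx$attributes$height_cm, ctx$attributes$sex)
  vt_kg <- vt_obs$tidal_volume_ml / pbw
  flag <- vt_kg > cfg$vt_per_kg_ml
  list(flag = flag,
       reasons = if (flag) "vt_exceeds_8_ml_per_kg_pbw"
                 else "vt_within_8_ml_per_kg_pbw",
       inputs = list(tidal_volume_ml = vt_obs$tidal_volume_ml, pbw_kg = pbw,
                     vt_ml_per_kg = vt_kg, vent_mode = obs$vent_mode))
}

#' @rdname metric-evaluators
#' @export
eval_sedation_wean <- function(ctx, cfg) {
  ab <- abstain_early_day(ctx, cfg); if (!is.null(ab)) return(ab)
  sed_order <- nrow(active_orders_at(ctx, "sedative_infusion")) > 0L
  infused_h <- admin_covered_seconds_today(ctx, "sedative_infusion") / 3600
  paralytic <- nrow(active_orders_at(ctx, "paralytic")) > 0L
  comfort <- comfort_care_at(ctx)
  contra <- dx_active_at(ctx, cfg$sedation_contraindication_dx)
  inputs <- list(sedative_order = sed_order, infused_hours_today = infused_h,
                 paralytic_active = paralytic, comfort_care = comfort,
                 contraindication_dx = contra)
  blocked <- c(if (!sed_order) "no_sedative_infusion",
               if (infused_h < cfg$sedation_min_infusion_hours)
                 "infusion_below_6h_today",
               if (paralytic) "paralytic_active",
               if (comfort) "comfort_care",
               if (contra) "contraindication_dx")
  if (length(blocked))
    return(list(flag = FALSE, reasons = blocked, inputs = inputs))
  list(flag = TRUE,
       reasons = c("sedative_infusion_ge_6h", "no_wean_contraindication"),
       inputs = inputs)
}

sbt_done_today <- function(ctx) {
  vo <- kind_events(ctx, "vent_obs")
  if (nrow(vo) == 0L) return(FALSE)
  s <- as.numeric(vo$start)
  today <- s >= as.numeric(ctx$day_start) & s <= as.numeric(ctx$eval_time)
  any(today & (vo$vent_mode == "sbt_in_progress" | !is.na(vo$sbt_result)))
}

#' @rdname metric-evaluators
#' @export
eval_sbt_ready <- function(ctx, cfg) {
  ett <- device_active_at(ctx, "ett")
  if (!ett)
    return(list(flag = FALSE, reasons = "not_intubated",
                inputs = list(ett_active = FALSE)))
  fo <- latest_vent_obs(ctx, "fio2")
  po <- latest_vent_obs(ctx, "peep_cmh2o")
  if (is.null(fo) || is.null(po))
    return(list(flag = FALSE, reasons = "vent_settings_undocumented",
                inputs = list(ett_active = TRUE)))
  vaso <- vaso_admin_within_h(ctx, cfg$sbt_vasopressor_lookback_hours)
  paralytic <- nrow(active_orders_at(ctx, "paralytic")) > 0L
  sbt_prior <- sbt_done_today(ctx)
  inputs <- list(ett_active = TRUE, fio2 = fo$fio2, peep = po$peep_cmh2o,
                 vasopressor_recent = vaso, paralytic_active = paralytic,
                 sbt_already_today = sbt_prior)
  blocked <- c(if (fo$fio2 > cfg$sbt_fio2_max) "fio2_above_threshold",
               if (po$peep_cmh2o > cfg$sbt_peep_max) "peep_above_threshold",
               if (vaso) "recent_vasopressor",
               if (paralytic) "paralytic_active",
               if (sbt_prior) "sbt_already_today")
  if (length(blocked))
    return(list(flag = FALSE, reasons = blocked, inputs = inputs))
  list(flag = TRUE, reasons = c("intubated", "low_support_settings",
                                "no_sbt_contraindication"),
       inputs = inputs)
}

#' @rdname metric-evaluators
#' @export
eval_sbt_passed <- function(ctx, cfg) {
  ett <- device_active_at(ctx, "ett")
  vo <- kind_events(ctx, "vent_obs")
  res <- NULL
  if (nrow(vo) > 0L) {
    s <- as.numeric(vo$start)
    sel <- !is.na(vo$sbt_result) & s >= as.numeric(ctx$day_start) &
      s <= as.numeric(ctx$eval_time)
    if (any(sel)) {
      cand <- vo[sel, , drop = FALSE]
      i <- order(as.numeric(cand$start), cand$recorded)
      res <- cand$sbt_result[i[length(i)]]
    }
  }
  inputs <- list(ett_active = ett, sbt_result_today = res %||% "none")
  flag <- ett && identical(res, "passed")
  reasons <- if (flag) c("sbt_passed_today", "still_intubated")
  else c(if (!ett) "not_intubated",
         if (is.null(res)) "no_sbt_result_today"
         else if (!identical(res, "passed")) "sbt_not_passed")
  list(flag = flag, reasons = reasons, inputs = inputs)
}

nutrition_intersecting <- function(ctx, from, to) {
  nu <- kind_events(ctx, "nutrition")
  if (nrow(nu) == 0L) return(nu)
  s <- as.numeric(nu$start); e <- as.numeric(nu$end)
  e[is.na(e)] <- Inf
  nu[s <= to & e > from, , drop = FALSE]
}

#' @rdname metric-evaluators
#' @export
eval_nutrition_start <- function(ctx, cfg) {
  ev <- as.numeric(ctx$eval_time)
  since_admit_h <- (ev - as.numeric(ctx$attributes$admit_time)) / 3600
  comfort <- comfort_care_at(ctx)
  recent <- nutrition_intersecting(ctx, ev - cfg$nutrition_start_hours * 3600, ev)
  inputs <- list(hours_since_admit = since_admit_h,
                 nutrition_records_48h = nrow(recent),
                 comfort_care = comfort)
  blocked <- c(if (since_admit_h < cfg$nutrition_start_hours)
                 "within_48h_of_admission",
               if (nrow(recent) > 0L) "nutrition_documented_48h",
               if (comfort) "comfort_care")
  if (length(blocked))
    return(list(flag = FALSE, reasons = blocked, inputs = inputs))
  list(flag = TRUE, reasons = c("admitted_over_48h", "no_nutrition_48h"),
       inputs = inputs)
}

#' @rdname metric-evaluators
#' @export
eval_nutrition_adequacy <- function(ctx, cfg) {
  ev <- as.numeric(ctx$eval_time)
  win <- c(ev - 86400, ev)
  recs <- nutrition_intersecting(ctx, win[1], win[2])
  comfort <- comfort_care_at(ctx)
  if (nrow(recs) == 0L)
    return(list(flag = FALSE, reasons = "no_active_nutrition",
                inputs = list(nutrition_active = FALSE)))
  if (comfort)
    return(list(flag = FALSE, reasons = "comfort_care",
                inputs = list(nutrition_active = TRUE, comfort_care = TRUE)))
  i <- order(as.numeric(recs$start), recs$recorded)
  goal <- recs$goal_kcal_day[i[length(i)]]
  s <- as.numeric(recs$start); e <- as.numeric(recs$end)
  e[is.na(e)] <- ev
  dur <- pmax(e - s, 1e-9)
  ov <- pmax(pmin(e, win[2]) - pmax(s, win[1]), 0)
  delivered <- sum(recs$delivered_kcal * ov / dur)
  frac <- delivered / goal
  flag <- frac < cfg$nutrition_adequacy - 1e-9
  list(flag = flag,
       reasons = if (flag) "delivered_below_80pct_goal"
                 else "delivered_ge_80pct_goal",
       inputs = list(goal_kcal_day = goal, delivered_kcal_24h = delivered,
                     adequacy_fraction = frac))
}

# Per-device continuing-indication sets for the removal family.
device_indication <- function(ctx, device, cfg) {
  switch(device,
    urinary_catheter = {
      dx <- dx_active_at(ctx, cfg$urinary_indication_dx)
      strict <- activity_active_at(ctx, "strict_io") &&
        nrow(active_orders_at(ctx, "vasopressor")) > 0L
      list(present = dx || strict,
           codes = c(if (dx) "urinary_indication_dx",
                     if (strict) "strict_io_with_vasopressor"))
    },
    central_line = {
      vaso <- vaso_admin_within_h(ctx, cfg$line_vasopressor_lookback_hours)
      vord <- nrow(active_orders_at(ctx, "vasopressor")) > 0L
      hd <- dx_active_at(ctx, cfg$central_indication_dx)
      list(present = vaso || vord || hd,
           codes = c(if (vaso) "recent_vasopressor_admin",
                     if (vord) "central_only_medication",
                     if (hd) "active_hemodialysis"))
    },
    arterial_line = {
      vaso <- vaso_admin_within_h(ctx, cfg$line_vasopressor_lookback_hours)
      ev <- as.numeric(ctx$eval_time)
      abg <- lab_values_in_window(ctx, "abg", ev - 86400, ev)
      freq <- length(abg) >= cfg$abg_high_count_24h
      list(present = vaso || freq,
           codes = c(if (vaso) "recent_vasopressor_admin",
                     if (freq) "frequent_abg_sampling"))
    },
    picc = {
      dx <- dx_active_at(ctx, cfg$picc_indication_dx)
      list(present = dx, codes = if (dx) "long_course_iv_therapy")
    },
    rectal_tube = {
      ds <- as.numeric(ctx$day_start); ev <- as.numeric(ctx$eval_time)
      stool <- nrow(flowsheet_in_window(ctx, "liquid_stool", ds, ev)) > 0L
      skin <- dx_active_at(ctx, cfg$skin_breakdown_dx)
      list(present = stool && skin,
           codes = if (stool && skin) "liquid_stool_with_skin_breakdown")
    },
    stop("no removal indication set for device: ", device))
}

#' @rdname metric-evaluators
#' @export
eval_device_removal <- function(ctx, device, cfg) {
  active <- device_active_at(ctx, device)
  if (!active)
    return(list(flag = FALSE, reasons = "device_absent",
                inputs = list(device = device, device_active = FALSE)))
  comfort <- comfort_care_at(ctx)
  ind <- device_indication(ctx, device, cfg)
  inputs <- list(device = device, device_active = TRUE,
                 comfort_care = comfort,
                 indications = if (length(ind$codes))
                   paste(ind$codes, collapse = ";") else "none")
  if (comfort)
    return(list(flag = FALSE, reasons = "comfort_care", inputs = inputs))
  if (ind$present)
    return(list(flag = FALSE, reasons = ind$codes, inputs = inputs))
  list(flag = TRUE, reasons = c("device_active", "no_continuing_indication"),
       inputs = inputs)
}

#' @rdname metric-evaluators
#' @export
eval_surveillance_culture <- function(ctx, cfg) {
  eps <- lapply(cfg$surveillance_line_devices, device_episodes, ctx = ctx)
  outside <- any(vapply(eps, function(e) any(e$active & e$placed_outside),
                        NA))
  if (!outside)
    return(list(flag = FALSE, reasons = "no_outside_line",
                inputs = list(outside_line_active = FALSE)))
  admit <- as.numeric(ctx$attributes$admit_time)
  cultures <- lab_values_in_window(ctx, "blood_culture", admit,
                                   as.numeric(ctx$eval_time))
  drawn <- length(cultures) > 0L
  inputs <- list(outside_line_active = TRUE, culture_drawn = drawn)
  if (drawn)
    return(list(flag = FALSE, reasons = "culture_drawn", inputs = inputs))
  list(flag = TRUE, reasons = c("outside_line_active", "no_blood_culture"),
       inputs = inputs)
}

#' @rdname metric-evaluators
#' @export
eval_ng_to_og <- function(ctx, cfg) {
  ngt <- device_active_at(ctx, "ngt")
  ett <- device_active_at(ctx, "ett")
  comfort <- comfort_care_at(ctx)
  inputs <- list(ngt_active = ngt, ett_active = ett, comfort_care = comfort)
  flag <- ngt && ett && !comfort
  reasons <- if (flag) c("ngt_active", "intubated")
  else c(if (!ngt) "no_ngt", if (ngt && !ett) "not_intubated",
         if (comfort) "comfort_care")
  list(flag = flag, reasons = reasons, inputs = inputs)
}

#' @rdname metric-evaluators
#' @export
eval_high_risk_line <- function(ctx, line, cfg) {
  eps <- device_episodes(ctx, line)
  act <- eps[eps$active, , drop = FALSE]
  if (nrow(act) == 0L)
    return(list(flag = FALSE, reasons = "line_absent",
                inputs = list(line = line, line_active = FALSE)))
  limit_s <- cfg$dwell_limit_days[[line]] * 86400
  dwell_s <- as.numeric(ctx$eval_time) - act$start
  femoral <- any(act$site == "femoral")
  long <- any(dwell_s > limit_s)
  inputs <- list(line = line, line_active = TRUE,
                 max_dwell_days = max(dwell_s) / 86400,
                 femoral_site = femoral)
  flag <- femoral || long
  reasons <- if (flag) c(if (femoral) "femoral_site",
                         if (long) "dwell_exceeds_limit")
  else "no_risk_criterion"
  list(flag = flag, reasons = reasons, inputs = inputs)
}
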