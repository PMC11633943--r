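# Randomized-scenario machinery: a feature sampler, an event-stream builder,
# and an independently coded straight-line decision-table oracle that maps
# the sampled features directly to expected flags for all 23 metrics.  The
# oracle never touches the engine's context queries, so agreement between
# engine and oracle is a genuine dual-route check.

.day0 <- as.POSIXct("2022-06-01 00:00:00", tz = "UTC")

sample_features <- function() {
  eval_h <- sample(c(2, 5, 8, 12, 16, 20, 23), 1,
                   prob = c(1, 2, 2, 3, 3, 2, 1))
  # disjoint compression segments via sorted breakpoints => exact coverage
  comp <- NULL
  if (runif(1) < 0.55) {
    k <- sample(1:3, 1)
    br <- sort(runif(2 * k, 0, eval_h))
    comp <- matrix(br, ncol = 2, byrow = TRUE)
    comp <- comp[comp[, 2] - comp[, 1] > 1e-6, , drop = FALSE]
  }
  lab <- function(p, lo, hi) if (runif(1) < p)
    list(value = runif(1, lo, hi), age_h = runif(1, 0, 120)) else NULL
  dev <- function(p = 0.45) {
    if (runif(1) >= p) return(NULL)
    list(placed_days = sample(c(0.3, 2, 6, 9, 35), 1),
         removed_h = if (runif(1) < 0.2) runif(1, 0.5, 6) else NA,
         site = sample(c("femoral", "ij", "radial", "other"), 1,
                       prob = c(0.25, 0.3, 0.25, 0.2)),
         outside = runif(1) < 0.2)
  }
  n_obs <- if (runif(1) < 0.6) sample(1:2, 1) else 0
  vent_obs <- if (n_obs > 0) lapply(seq_len(n_obs), function(i) list(
    at_h = runif(1, 0, max(eval_h - 0.1, 0.1)),
    mode = sample(c("controlled", "spontaneous", "sbt_in_progress"), 1,
                  prob = c(0.6, 0.3, 0.1)),
    vt = if (runif(1) < 0.9) runif(1, 250, 750) else NA,
    fio2 = runif(1, 0.25, 0.8),
    peep = runif(1, 3, 12),
    sbt_result = sample(c(NA, NA, NA, "passed", "failed"), 1))) else list()
  list(
    eval_h = eval_h,
    admit_days = sample(c(0.5, 1, 2, 3, 10, 40), 1),
    height = runif(1, 150, 200),
    sex = sample(c("male", "female"), 1),
    comfort = runif(1) < 0.15,
    comp = comp,
    anticoag = if (runif(1) < 0.5) list(
      class = sample(c("ufh_prophylactic", "lmwh_prophylactic",
                       "ufh_therapeutic", "doac", "warfarin", "insulin"), 1),
      status = sample(c("active", "discontinued", "held"), 1,
                      prob = c(0.6, 0.25, 0.15))) else NULL,
    platelets = lab(0.6, 20, 400),
    inr = lab(0.6, 0.8, 3),
    aptt = lab(0.6, 20, 80),
    glucose = if (runif(1) < 0.7)
      list(value = runif(1, 40, 200), at_h = runif(1, -20, eval_h)) else NULL,
    bleeding = runif(1) < 0.2,
    urinary_dx = runif(1) < 0.25,
    hd_dx = runif(1) < 0.2,
    long_course_dx = runif(1) < 0.25,
    skin_dx = runif(1) < 0.3,
    contra_dx = runif(1) < 0.15,
    prbc_units = sample(0:3, 1, prob = c(0.55, 0.2, 0.15, 0.1)),
    prbc_recent = runif(1) < 0.7,
    ambulate = runif(1) < 0.2,
    strict_io = runif(1) < 0.25,
    acid = runif(1) < 0.5,
    devices = list(urinary_catheter = dev(), central_line = dev(),
                   arterial_line = dev(), picc = dev(), hd_line = dev(0.3),
                   rectal_tube = dev(0.3), ngt = dev(0.3), ett = dev()),
    vent_obs = vent_obs,
    vaso_order = runif(1) < 0.3,
    vaso_admin_h = c(1, 3, 6, 10, 13, 30)[runif(6) < 0.22],
    paralytic = runif(1) < 0.15,
    sedative_order = runif(1) < 0.4,
    sedative_hours = runif(1, 0, 10),
    nutrition = if (runif(1) < 0.6) {
      start_off_h <- runif(1, 4, 80)
      list(start_off_h = start_off_h,
           open = runif(1) < 0.7,
           end_off_h = runif(1, 0.5, min(start_off_h - 0.5, 60)),
           delivered = runif(1, 600, 2400))
    } else NULL,
    culture_off_h = if (runif(1) < 0.3) runif(1, 0, 60) else NULL,
    n_abg = sample(0:6, 1, prob = c(0.5, 0.1, 0.1, 0.1, 0.08, 0.07, 0.05)),
    stool_today = runif(1) < 0.3)
}

features_to_ctx <- function(f, pid = "px") {
  ds <- .day0
  ev <- ds + f$eval_h * 3600
  admit <- ds - f$admit_days * 86400
  E <- list()
  add <- function(x) E[[length(E) + 1L]] <<- x
  add(clinical_event("code_status", pid, admit, code_status = "full_code"))
  if (f$comfort)
    add(clinical_event("code_status", pid, ev - 3600,
                       code_status = "comfort_care"))
  if (!is.null(f$comp))
    for (i in seq_len(nrow(f$comp)))
      add(clinical_event("device", pid, ds + f$comp[i, 1] * 3600,
                         end = ds + f$comp[i, 2] * 3600,
                         device = "compression_device", site = "other",
                         placed_outside = FALSE))
  if (!is.null(f$anticoag))
    add(clinical_event("med_order", pid, ev - 36 * 3600,
                       drug_class = f$anticoag$class,
                       status = f$anticoag$status, route = "sc"))
  for (nm in c("platelets", "inr", "aptt")) {
    l <- f[[nm]]
    if (!is.null(l)) {
      analyte <- c(platelets = "platelets_k_per_ul", inr = "inr",
                   aptt = "aptt_sec")[[nm]]
      t <- ev - l$age_h * 3600
      add(clinical_event("lab", pid, t, analyte = analyte, value = l$value,
                         result_time = t))
    }
  }
  if (!is.null(f$glucose)) {
    t <- ds + f$glucose$at_h * 3600
    add(clinical_event("lab", pid, t, analyte = "glucose_mg_dl",
                       value = f$glucose$value, result_time = t))
  }
  dxs <- c(if (f$bleeding) "bleeding", if (f$urinary_dx) "urinary_retention",
           if (f$hd_dx) "active_hemodialysis",
           if (f$long_course_dx) "long_course_iv_therapy",
           if (f$skin_dx) "skin_breakdown",
           if (f$contra_dx) "intracranial_hypertension")
  for (d in dxs)
    add(clinical_event("diagnosis", pid, ev - 50 * 3600, dx_code = d))
  if (f$prbc_units > 0) {
    t <- ev - (if (f$prbc_recent) 10 else 30) * 3600
    add(clinical_event("transfusion", pid, t, product = "prbc",
                       units = f$prbc_units))
  }
  if (f$ambulate)
    add(clinical_event("activity_order", pid, ev - 30 * 3600,
                       activity = "ambulate"))
  if (f$strict_io)
    add(clinical_event("activity_order", pid, ev - 30 * 3600,
                       activity = "strict_io"))
  if (f$acid)
    add(clinical_event("med_order", pid, ev - 40 * 3600,
                       drug_class = "acid_suppressant", status = "active",
                       route = "iv"))
  for (dn in names(f$devices)) {
    d <- f$devices[[dn]]
    if (is.null(d)) next
    add(clinical_event("device", pid, ev - d$placed_days * 86400,
                       end = if (is.na(d$removed_h)) NA
                             else ev - d$removed_h * 3600,
                       device = dn, site = d$site,
                       placed_outside = d$outside))
  }
  for (o in f$vent_obs)
    add(clinical_event("vent_obs", pid, ds + o$at_h * 3600,
                       vent_mode = o$mode, tidal_volume_ml = o$vt,
                       fio2 = o$fio2, peep_cmh2o = o$peep,
                       sbt_result = o$sbt_result))
  for (h in f$vaso_admin_h)
    add(clinical_event("med_admin", pid, ev - h * 3600,
                       drug_class = "vasopressor", action = "given",
                       dose_time = ev - h * 3600))
  if (f$vaso_order)
    add(clinical_event("med_order", pid, ev - 20 * 3600,
                       drug_class = "vasopressor", status = "active",
                       route = "iv"))
  if (f$paralytic)
    add(clinical_event("med_order", pid, ev - 20 * 3600,
                       drug_class = "paralytic", status = "active",
                       route = "iv"))
  if (f$sedative_order) {
    add(clinical_event("med_order", pid, ev - 20 * 3600,
                       drug_class = "sedative_infusion", status = "active",
                       route = "iv"))
    if (f$sedative_hours > 0)
      add(clinical_event("med_admin", pid, ev - f$sedative_hours * 3600,
                         end = ev, drug_class = "sedative_infusion",
                         action = "given",
                         dose_time = ev - f$sedative_hours * 3600))
  }
  if (!is.null(f$nutrition)) {
    n <- f$nutrition
    add(clinical_event("nutrition", pid, ev - n$start_off_h * 3600,
                       end = if (n$open) NA else ev - n$end_off_h * 3600,
                       nutrition_route = "enteral", goal_kcal_day = 2000,
                       delivered_kcal = n$delivered))
  }
  if (!is.null(f$culture_off_h)) {
    t <- admit + f$culture_off_h * 3600
    add(clinical_event("lab", pid, t, analyte = "blood_culture", value = 1,
                       result_time = t))
  }
  if (f$n_abg > 0)
    for (h in seq(1, 23, length.out = f$n_abg)) {
      t <- ev - h * 3600
      add(clinical_event("lab", pid, t, analyte = "abg", value = 7.4,
                         result_time = t))
    }
  if (f$stool_today && f$eval_h > 1)
    add(clinical_event("flowsheet_doc", pid, ds + (f$eval_h - 1) * 3600,
                       doc_type = "liquid_stool"))
  attrs <- patient_attributes(pid, f$height, f$sex, admit)
  suppressWarnings(
    assemble_patient_day(bind_events(E), attrs, ds + f$eval_h * 3600))
}

# ---- the independent decision-table oracle ------------------------------

oracle_flags <- function(f) {
  ev_abs <- f$eval_h                       # hours since day start
  dev_active <- function(dn) {
    d <- f$devices[[dn]]
    !is.null(d) && is.na(d$removed_h)
  }
  comp_cov <- if (is.null(f$comp)) 0 else
    sum(pmin(f$comp[, 2], ev_abs) - pmin(f$comp[, 1], ev_abs)) / ev_abs
  chem <- !is.null(f$anticoag) && f$anticoag$status == "active" &&
    f$anticoag$class %in% c("ufh_prophylactic", "lmwh_prophylactic",
                            "ufh_therapeutic", "lmwh_therapeutic", "doac",
                            "warfarin")
  in_3d <- function(l) !is.null(l) && l$age_h <= 72
  coag <- (in_3d(f$platelets) && f$platelets$value < 50) ||
    (in_3d(f$inr) && f$inr$value >= 1.5) ||
    (in_3d(f$aptt) && f$aptt$value > 40)
  prbc24 <- if (f$prbc_recent) f$prbc_units else 0
  excl <- coag || f$bleeding || f$comfort || prbc24 > 1 || f$ambulate
  early <- ev_abs < 4

  ett <- dev_active("ett")
  obs <- f$vent_obs
  latest <- function(sel_fun, field) {
    keep <- Filter(function(o) o$at_h <= ev_abs && sel_fun(o), obs)
    if (!length(keep)) return(NULL)
    keep[[which.max(vapply(keep, `[[`, 0, "at_h"))]][[field]]
  }
  latest_mode <- latest(function(o) TRUE, "mode")
  latest_vt <- latest(function(o) !is.na(o$vt), "vt")
  latest_fio2 <- latest(function(o) !is.na(o$fio2), "fio2")
  latest_peep <- latest(function(o) !is.na(o$peep), "peep")
  latest_sbt <- latest(function(o) !is.na(o$sbt_result), "sbt_result")
  sbt_today <- any(vapply(obs, function(o)
    o$at_h >= 0 && o$at_h <= ev_abs &&
      (o$mode == "sbt_in_progress" || !is.na(o$sbt_result)), NA))
  vaso4 <- any(f$vaso_admin_h <= 4)
  vaso12 <- any(f$vaso_admin_h <= 12)
  pbw <- (if (f$sex == "female") 45.5 else 50) + 0.91 * (f$height - 152.4)
  risk <- ett || coag

  nut <- f$nutrition
  since_admit_h <- f$admit_days * 24 + ev_abs
  nut_48 <- !is.null(nut) &&
    (nut$open || nut$end_off_h < 48) && nut$start_off_h > 0
  nut_24 <- !is.null(nut) && (nut$open || nut$end_off_h < 24)
  delivered24 <- if (is.null(nut)) 0 else {
    dur <- if (nut$open) nut$start_off_h else nut$start_off_h - nut$end_off_h
    covered <- max(min(nut$start_off_h, 24) -
                     (if (nut$open) 0 else nut$end_off_h), 0)
    nut$delivered * covered / dur
  }

  culture <- !is.null(f$culture_off_h) &&
    f$culture_off_h * 3600 <= (f$admit_days * 24 + ev_abs) * 3600
  outside_line <- any(vapply(c("central_line", "picc", "hd_line"),
                             function(dn) {
    d <- f$devices[[dn]]
    !is.null(d) && is.na(d$removed_h) && d$outside
  }, NA))

  removal <- function(dn, indication) {
    dev_active(dn) && !f$comfort && !indication
  }
  high_risk <- function(dn, limit) {
    d <- f$devices[[dn]]
    !is.null(d) && is.na(d$removed_h) &&
      (d$site == "femoral" || d$placed_days * 24 > limit * 24)
  }

  c(
    hypoglycemia = !is.null(f$glucose) && f$glucose$at_h >= 0 &&
      f$glucose$at_h <= ev_abs && f$glucose$value <= 70,
    vte_chemical = !early && comp_cov >= 0.75 && !chem && !excl,
    vte_mechanical = !early && !chem && comp_cov < 0.75 && !f$ambulate &&
      !f$comfort,
    vte_any = !early && !chem && comp_cov < 0.75 && !excl,
    sup_start = risk && !f$acid && !f$comfort,
    sup_stop = f$acid && !risk,
    low_tidal_volume = ett && !is.null(latest_mode) &&
      latest_mode == "controlled" && !is.null(latest_vt) &&
      latest_vt / pbw > 8,
    sedation_wean = !early && f$sedative_order &&
      pmin(f$sedative_hours, ev_abs) >= 6 && !f$paralytic && !f$comfort &&
      !f$contra_dx,
    sbt_ready = ett && !is.null(latest_fio2) && !is.null(latest_peep) &&
      latest_fio2 <= 0.5 && latest_peep <= 8 && !vaso4 && !f$paralytic &&
      !sbt_today,
    sbt_passed = ett && !is.null(latest_sbt) && latest_sbt == "passed",
    nutrition_start = since_admit_h >= 48 && !nut_48 && !f$comfort,
    nutrition_adequacy = nut_24 && !f$comfort &&
      delivered24 < 0.8 * 2000 - 1e-9,
    urinary_catheter_removal = removal("urinary_catheter",
      f$urinary_dx || (f$strict_io && f$vaso_order)),
    central_line_removal = removal("central_line",
      vaso12 || f$vaso_order || f$hd_dx),
    arterial_line_removal = removal("arterial_line",
      vaso12 || f$n_abg >= 4),
    picc_removal = removal("picc", f$long_course_dx),
    surveillance_culture = outside_line && !culture,
    rectal_tube_removal = removal("rectal_tube",
      (f$stool_today && f$eval_h > 1) && f$skin_dx),
    ng_to_og = dev_active("ngt") && ett && !f$comfort,
    high_risk_central_line = high_risk("central_line", 7),
    high_risk_arterial_line = high_risk("arterial_line", 7),
    high_risk_hd_line = high_risk("hd_line", 7),
    high_risk_picc = high_risk("picc", 30)
  )
}

# run engine + oracle on n random scenarios; returns mismatch description
oracle_disagreements <- function(n, seed = 424242) {
  set.seed(seed)
  bad <- list()
  for (i in seq_len(n)) {
    f <- sample_features()
    ctx <- features_to_ctx(f)
    got <- results_to_frame(evaluate_patient_day(ctx))
    want <- oracle_flags(f)
    mism <- got$rule_id[got$flag != want[got$rule_id]]
    if (length(mism)) bad[[length(bad) + 1L]] <- list(i = i, rules = mism,
                                                     features = f)
  }
  bad
}
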