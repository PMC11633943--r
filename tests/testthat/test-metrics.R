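# Boundary semantics of every printed comparator, plus the per-category
# behaviors of the declared defaults.

test_that("hypoglycemia threshold is inclusive at 70 mg/dL", {
  expect_true(flag_of(mk_day(e_lab("glucose_mg_dl", 70, 6)), "hypoglycemia"))
  expect_false(flag_of(mk_day(e_lab("glucose_mg_dl", 71, 6)), "hypoglycemia"))
  # absent glucose assumed normal
  expect_false(flag_of(mk_day(e_lab("inr", 1.0, 6)), "hypoglycemia"))
  # yesterday's low glucose is not today's finding
  expect_false(flag_of(mk_day(e_lab("glucose_mg_dl", 60, -6)),
                       "hypoglycemia"))
})

test_that("the chemical-VTE rule honors each printed criterion", {
  base <- function(...) mk_day(
    e_device("compression_device", start = 0, end = 12.8),  # 0.80 of 16 h
    e_lab("platelets_k_per_ul", 60, -20),
    e_lab("inr", 1.2, -20),
    ...)
  expect_true(flag_of(base(), "vte_chemical"))
  # an active prophylactic order suppresses it
  expect_false(flag_of(base(e_order("lmwh_prophylactic")), "vte_chemical"))
  # ... as does a therapeutic anticoagulant
  expect_false(flag_of(base(e_order("warfarin")), "vte_chemical"))
  # but not a discontinued one
  expect_true(flag_of(base(e_order("lmwh_prophylactic",
                                   status = "discontinued")), "vte_chemical"))
  # coagulopathy lookback: platelets 45 two days ago blocks
  expect_false(flag_of(base(e_lab("platelets_k_per_ul", 45, -48)),
                       "vte_chemical"))
  # boundary comparators: INR >= 1.5 blocks, 1.49 does not; aPTT > 40 blocks
  expect_false(flag_of(base(e_lab("inr", 1.5, -10)), "vte_chemical"))
  expect_true(flag_of(base(e_lab("inr", 1.49, -10)), "vte_chemical"))
  expect_false(flag_of(base(e_lab("aptt_sec", 40.5, -10)), "vte_chemical"))
  expect_true(flag_of(base(e_lab("aptt_sec", 40, -10)), "vte_chemical"))
  # stale coagulopathy outside the 3-day window does not block
  expect_true(flag_of(base(e_lab("inr", 2.0, -80)), "vte_chemical"))
  # >1 PRBC unit in the prior 24 h blocks; exactly 1 does not
  prbc <- function(u, at) clinical_event("transfusion", "p1", hrs(at),
                                         product = "prbc", units = u)
  expect_false(flag_of(base(prbc(2, 10)), "vte_chemical"))
  expect_true(flag_of(base(prbc(1, 10)), "vte_chemical"))
  expect_true(flag_of(base(prbc(2, -10)), "vte_chemical"))  # outside 24 h
  # bleeding diagnosis, comfort care, ambulation each block
  expect_false(flag_of(base(e_dx("hematoma")), "vte_chemical"))
  expect_false(flag_of(base(e_comfort()), "vte_chemical"))
  expect_false(flag_of(base(clinical_event("activity_order", "p1", hrs(-30),
                                           activity = "ambulate")),
                       "vte_chemical"))
})

test_that("mechanical-prophylaxis coverage is inclusive at 75%", {
  cov_day <- function(end_h) mk_day(
    e_device("compression_device", start = 0, end = end_h))
  expect_true(flag_of(cov_day(12), "vte_chemical"))      # 0.75 exactly
  expect_false(flag_of(cov_day(11.2), "vte_chemical"))   # 0.70
})

test_that("mechanical and combined VTE metrics complement the chemical one", {
  expect_true(flag_of(mk_day(), "vte_mechanical"))
  expect_true(flag_of(mk_day(), "vte_any"))
  expect_false(flag_of(mk_day(e_order("ufh_prophylactic")), "vte_mechanical"))
  expect_false(flag_of(mk_day(e_comfort()), "vte_mechanical"))
  # one modality present suppresses the combined metric
  expect_false(flag_of(mk_day(e_device("compression_device", start = 0,
                                       end = 14.4)), "vte_any"))   # 0.9
  expect_false(flag_of(mk_day(e_dx("bleeding")), "vte_any"))
  # combined actionable implies mechanical actionable (documented coupling)
  ctx <- mk_day()
  expect_true(flag_of(ctx, "vte_any") && flag_of(ctx, "vte_mechanical"))
})

test_that("SUP starts with a risk factor and stops without one", {
  vent <- function(...) mk_day(e_device("ett", start = -30),
                               e_vent(6, vt = 400, fio2 = 0.6, peep = 6),
                               ...)
  expect_true(flag_of(vent(), "sup_start"))
  expect_false(flag_of(vent(e_order("acid_suppressant", route = "iv")),
                       "sup_start"))
  # coagulopathy is the other risk factor
  expect_true(flag_of(mk_day(e_lab("inr", 1.8, -10)), "sup_start"))
  # stop: suppressant on, no risk factor
  expect_true(flag_of(mk_day(e_order("acid_suppressant")), "sup_stop"))
  expect_false(flag_of(vent(e_order("acid_suppressant")), "sup_stop"))
  bare <- assemble_patient_day(empty_events(), std_attrs(), hrs(16))
  expect_false(flag_of(bare, "sup_start"))
  expect_false(flag_of(bare, "sup_stop"))
})

test_that("tidal volume is scaled by Devine predicted body weight", {
  vent_vt <- function(vt, sex = "male", height = 175) mk_day(
    e_device("ett", start = -30),
    e_vent(6, vt = vt, fio2 = 0.6, peep = 6),
    attrs = std_attrs(height = height, sex = sex))
  # male 175 cm: PBW = 50 + 0.91*22.6 = 70.566... no: 50+0.91*(175-152.4)
  pbw <- 50 + 0.91 * (175 - 152.4)
  expect_equal(pbw, 70.566)
  expect_true(600 / pbw > 8)
  expect_false(flag_of(vent_vt(520), "low_tidal_volume"))  # 7.37 mL/kg
  expect_true(flag_of(vent_vt(600), "low_tidal_volume"))   # 8.50 mL/kg
  # female PBW is 4.5 kg lower at equal height
  expect_true(flag_of(vent_vt(540, sex = "female"), "low_tidal_volume"))
  expect_false(flag_of(vent_vt(540, sex = "male"), "low_tidal_volume"))
  # not ventilated or not on a controlled mode: no flag
  expect_false(flag_of(mk_day(), "low_tidal_volume"))
  expect_false(flag_of(mk_day(e_device("ett", start = -30),
                              e_vent(6, mode = "spontaneous", vt = 700)),
                       "low_tidal_volume"))
})

test_that("sedation wean needs 6 h of infusion and no blockers", {
  sed <- function(...) mk_day(
    e_order("sedative_infusion", route = "iv"),
    clinical_event("med_admin", "p1", hrs(8), end = hrs(16),
                   drug_class = "sedative_infusion", action = "given",
                   dose_time = hrs(8)),
    ...)
  expect_true(flag_of(sed(), "sedation_wean"))
  expect_false(flag_of(sed(e_order("paralytic", route = "iv")),
                       "sedation_wean"))
  expect_false(flag_of(sed(e_comfort()), "sedation_wean"))
  expect_false(flag_of(sed(e_dx("intracranial_hypertension")),
                       "sedation_wean"))
  expect_false(flag_of(mk_day(), "sedation_wean"))
  # only 4 h infused today: not yet
  short <- mk_day(e_order("sedative_infusion", route = "iv"),
                  clinical_event("med_admin", "p1", hrs(12), end = hrs(16),
                                 drug_class = "sedative_infusion",
                                 action = "given", dose_time = hrs(12)))
  expect_false(flag_of(short, "sedation_wean"))
})

test_that("SBT readiness and passed-SBT follow the ventilator course", {
  ready <- function(...) mk_day(
    e_device("ett", start = -30),
    e_order("acid_suppressant", route = "iv"),
    e_vent(6, vt = 400, fio2 = 0.4, peep = 5),
    ...)
  expect_true(flag_of(ready(), "sbt_ready"))
  expect_false(flag_of(ready(e_vent(8, fio2 = 0.6, peep = 5)), "sbt_ready"))
  expect_false(flag_of(ready(e_vent(8, fio2 = 0.4, peep = 10)), "sbt_ready"))
  expect_false(flag_of(ready(
    clinical_event("med_admin", "p1", hrs(14), drug_class = "vasopressor",
                   action = "given", dose_time = hrs(14))), "sbt_ready"))
  # an SBT already done today blocks a second prompt
  expect_false(flag_of(ready(e_vent(8, mode = "sbt_in_progress")),
                       "sbt_ready"))
  # passed at 08:00, still intubated at 16:00: prompt extubation
  passed <- ready(e_vent(8, mode = "spontaneous", sbt = "passed"))
  expect_true(flag_of(passed, "sbt_passed"))
  failed <- ready(e_vent(8, mode = "spontaneous", sbt = "failed"))
  expect_false(flag_of(failed, "sbt_passed"))
  # extubated after passing: nothing to prompt
  ext <- mk_day(e_device("ett", start = -30, end = 12),
                e_vent(8, mode = "spontaneous", sbt = "passed"))
  expect_false(flag_of(ext, "sbt_passed"))
})

test_that("nutrition metrics honor the 48 h start and 80% adequacy rules", {
  expect_true(flag_of(mk_day(), "nutrition_start"))   # 72 h in, never fed
  expect_false(flag_of(mk_day(attrs = std_attrs(admit_h = -30)),
                       "nutrition_start"))            # only 30 h in
  nut <- function(delivered) mk_day(
    clinical_event("nutrition", "p1", hrs(-8), nutrition_route = "enteral",
                   goal_kcal_day = 2000, delivered_kcal = delivered))
  expect_false(flag_of(nut(1800), "nutrition_start"))
  expect_true(flag_of(nut(1500), "nutrition_adequacy"))   # 0.75 of goal
  expect_false(flag_of(nut(1600), "nutrition_adequacy"))  # exactly 0.80
  expect_false(flag_of(mk_day(), "nutrition_adequacy"))   # nothing running
  expect_false(flag_of(mk_day(e_comfort()), "nutrition_start"))
})

test_that("device-removal prompts fire only without a continuing indication", {
  # central line, no vasopressor in 12 h, no central-only meds
  cvc <- function(...) mk_day(e_device("central_line", start = -48,
                                       site = "ij"), ...)
  expect_true(flag_of(cvc(), "central_line_removal"))
  expect_false(flag_of(cvc(
    clinical_event("med_admin", "p1", hrs(10), drug_class = "vasopressor",
                   action = "given", dose_time = hrs(10))),
    "central_line_removal"))
  expect_false(flag_of(cvc(e_order("vasopressor", route = "iv")),
                       "central_line_removal"))
  expect_false(flag_of(cvc(e_dx("active_hemodialysis")),
                       "central_line_removal"))
  # absent device: expected-absent => positive finding, no flag
  expect_false(flag_of(mk_day(), "central_line_removal"))
  # urinary catheter with retention stays
  uc <- function(...) mk_day(e_device("urinary_catheter", start = -48), ...)
  expect_true(flag_of(uc(), "urinary_catheter_removal"))
  expect_false(flag_of(uc(e_dx("urinary_retention")),
                       "urinary_catheter_removal"))
  expect_false(flag_of(uc(
    clinical_event("activity_order", "p1", hrs(-30), activity = "strict_io"),
    e_order("vasopressor", route = "iv")), "urinary_catheter_removal"))
  # arterial line kept by frequent ABG sampling
  art <- function(...) mk_day(e_device("arterial_line", start = -48,
                                       site = "radial"), ...)
  expect_true(flag_of(art(), "arterial_line_removal"))
  abgs <- lapply(c(2, 6, 10, 14), function(h) e_lab("abg", 7.4, h))
  expect_false(flag_of(do.call(art, abgs), "arterial_line_removal"))
  # rectal tube kept only with liquid stool AND skin breakdown
  rt <- function(...) mk_day(e_device("rectal_tube", start = -48), ...)
  expect_true(flag_of(rt(), "rectal_tube_removal"))
  expect_true(flag_of(rt(e_dx("skin_breakdown")), "rectal_tube_removal"))
  expect_false(flag_of(rt(e_dx("skin_breakdown"),
                          clinical_event("flowsheet_doc", "p1", hrs(10),
                                         doc_type = "liquid_stool")),
                       "rectal_tube_removal"))
  # PICC kept by a long-course therapy indication
  expect_true(flag_of(mk_day(e_device("picc", start = -72)), "picc_removal"))
  expect_false(flag_of(mk_day(e_device("picc", start = -72),
                              e_dx("long_course_iv_therapy")),
                       "picc_removal"))
})

test_that("surveillance cultures chase lines placed outside", {
  out_picc <- function(...) mk_day(
    e_device("picc", start = -24, outside = TRUE),
    e_dx("long_course_iv_therapy"),
    attrs = std_attrs(admit_h = -24), ...)
  expect_true(flag_of(out_picc(), "surveillance_culture"))
  expect_false(flag_of(out_picc(e_lab("blood_culture", 1, -12)),
                       "surveillance_culture"))
  # in-house lines need no surveillance culture
  expect_false(flag_of(mk_day(e_device("picc", start = -24),
                              e_dx("long_course_iv_therapy"),
                              attrs = std_attrs(admit_h = -24)),
                       "surveillance_culture"))
})

test_that("NG-to-OG conversion prompts only while intubated", {
  ng <- function(...) mk_day(e_device("ngt", start = -24), ...)
  expect_true(flag_of(ng(e_device("ett", start = -24),
                         e_order("acid_suppressant")), "ng_to_og"))
  expect_false(flag_of(ng(), "ng_to_og"))
  expect_false(flag_of(mk_day(e_device("ogt", start = -24)), "ng_to_og"))
})

test_that("line risk combines femoral site and dwell-time limits", {
  cvc_at <- function(days_ago, site) mk_day(
    e_device("central_line", start = -24 * days_ago, site = site),
    e_order("vasopressor", route = "iv"),
    attrs = std_attrs(admit_h = -24 * 12))
  expect_true(flag_of(cvc_at(2, "femoral"), "high_risk_central_line"))
  expect_true(flag_of(cvc_at(9, "ij"), "high_risk_central_line"))
  expect_false(flag_of(cvc_at(3, "ij"), "high_risk_central_line"))
  # PICC tolerates a month
  picc_at <- function(days_ago) mk_day(
    e_device("picc", start = -24 * days_ago),
    e_dx("long_course_iv_therapy"),
    attrs = std_attrs(admit_h = -24 * 40))
  expect_false(flag_of(picc_at(20), "high_risk_picc"))
  expect_true(flag_of(picc_at(31), "high_risk_picc"))
})

test_that("comfort care suppresses prophylaxis, nutrition and wean prompts", {
  suppressed <- c("vte_chemical", "vte_mechanical", "vte_any", "sup_start",
                  "sedation_wean", "nutrition_start", "nutrition_adequacy")
  for (rid in suppressed) {
    pd <- generate_patient_day(rid, TRUE, seed = 13)
    ctx_on <- suppressWarnings(
      assemble_patient_day(pd$events, pd$attributes, pd$eval_time))
    expect_true(flag_of(ctx_on, rid), info = rid)
    with_comfort <- bind_events(pd$events, e_comfort(pid = "p0001"))
    ctx_off <- suppressWarnings(
      assemble_patient_day(with_comfort, pd$attributes, pd$eval_time))
    expect_false(flag_of(ctx_off, rid), info = rid)
  }
})

test_that("every evaluator matches the independent decision-table oracle", {
  bad <- oracle_disagreements(150, seed = 2024)
  expect_length(bad, 0)
})
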