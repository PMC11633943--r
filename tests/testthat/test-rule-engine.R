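test_that("the three missing-data policies map absence as specified", {
  # expected-present-but-missing: negative finding
  r1 <- resolve_missing("chemoprophylaxis_order", NULL,
                        "expected_present_missing")
  expect_equal(r1$finding, "negative")
  expect_equal(r1$tag, "missing_negative_finding")
  # expected-absent-and-missing: positive finding
  r2 <- resolve_missing("central_line", NULL, "expected_absent_missing")
  expect_equal(r2$finding, "positive")
  # absent lab: assumed within normal limits
  r3 <- resolve_missing("inr", NULL, "lab_missing", 1.0)
  expect_equal(r3$value, 1.0)
  expect_equal(r3$tag, "assumed_normal")
  # present values pass through untouched
  r4 <- resolve_missing("inr", 2.2, "lab_missing", 1.0)
  expect_equal(r4$value, 2.2)
  expect_equal(r4$finding, "observed")
  expect_error(resolve_missing("inr", NULL, "lab_missing"),
               "requires a normal_default")
  expect_error(resolve_missing("x", 1, "no_such_policy"), "unknown")
})

test_that("rule results enforce their invariants", {
  expect_error(rule_result("r", flag = TRUE, reasons = character(0)),
               "at least one reason")
  expect_error(rule_result("r", flag = TRUE, reasons = "x",
                           abstained = TRUE), "cannot flag")
  ok <- rule_result("r", flag = FALSE, abstained = TRUE)
  expect_false(ok$flag)
})

test_that("an evaluator error abstains instead of raising a false alarm", {
  broken <- list(rule_id = "broken", category = "x",
                 evaluator = function(ctx, cfg) stop("boom"),
                 required_inputs = character(0))
  ctx <- assemble_patient_day(empty_events(), std_attrs(), hrs(16))
  res <- evaluate_rule(broken, ctx)
  expect_true(res$abstained)
  expect_false(res$flag)
  expect_true("evaluator_error" %in% res$reasons)
})

test_that("the registry covers every shipped metric across 7 categories", {
  reg <- default_registry()
  ids <- rule_ids(reg)
  expect_equal(anyDuplicated(ids), 0L)
  rows <- utils::read.csv(system.file("extdata", "validation_rows.csv",
                                      package = "icurounds"),
                          stringsAsFactors = FALSE)
  expect_setequal(ids, rows$rule_id)           # one rule per validation row
  cats <- unique(vapply(reg, `[[`, "", "category"))
  expect_length(cats, 7L)
  for (d in reg) {
    expect_true(all(d$required_inputs %in%
                      c("expected_present_missing",
                        "expected_absent_missing", "lab_missing")))
    expect_gt(length(d$required_inputs), 0L)
  }
})

test_that("a bare context evaluates all metrics without error, purely", {
  ctx <- assemble_patient_day(empty_events(), std_attrs(), hrs(16))
  res <- evaluate_patient_day(ctx)
  df <- results_to_frame(res)
  expect_equal(nrow(df), length(rule_ids()))
  expect_false(any(grepl("evaluator_error", df$reasons)))
  # an empty chart 72 h post admission: no VTE prophylaxis of either kind
  # and no nutrition yet, everything else quiescent
  expect_setequal(df$rule_id[df$flag],
                  c("vte_mechanical", "vte_any", "nutrition_start"))
  expect_identical(results_to_frame(evaluate_patient_day(ctx)), df)
})

test_that("abstention happens early in the day for day-coverage rules", {
  ctx <- mk_day(e_device("compression_device", start = -10), eval_h = 2)
  df <- results_to_frame(evaluate_patient_day(ctx))
  cov_rules <- c("vte_chemical", "vte_mechanical", "vte_any",
                 "sedation_wean")
  expect_true(all(df$abstained[df$rule_id %in% cov_rules]))
  expect_false(any(df$flag[df$rule_id %in% cov_rules]))
  expect_false(any(df$abstained[!df$rule_id %in% cov_rules]))
})

# Policy totality: for each rule, removing any subset of the event groups
# behind its declared inputs still yields a defined, non-crashing result.
input_event_filter <- function(events, input) {
  drop <- switch(input,
    glucose = events$kind == "lab" & events$analyte == "glucose_mg_dl",
    platelets = events$kind == "lab" & events$analyte == "platelets_k_per_ul",
    inr = events$kind == "lab" & events$analyte == "inr",
    aptt = events$kind == "lab" & events$analyte == "aptt_sec",
    abg_labs = events$kind == "lab" & events$analyte == "abg",
    blood_culture = events$kind == "lab" & events$analyte == "blood_culture",
    compression_device = events$kind == "device" &
      events$device == "compression_device",
    ett_device = events$kind == "device" & events$device == "ett",
    ngt_device = events$kind == "device" & events$device == "ngt",
    outside_line = events$kind == "device" &
      events$device %in% c("central_line", "picc", "hd_line"),
    device = events$kind == "device",
    anticoagulant_order = events$kind == "med_order" &
      events$drug_class %in% c("ufh_prophylactic", "lmwh_prophylactic",
                               "ufh_therapeutic", "lmwh_therapeutic",
                               "doac", "warfarin"),
    acid_suppressant_order = events$kind == "med_order" &
      events$drug_class == "acid_suppressant",
    sedative_order = events$kind == "med_order" &
      events$drug_class == "sedative_infusion",
    paralytic_order = events$kind == "med_order" &
      events$drug_class == "paralytic",
    vasopressor_order = events$kind == "med_order" &
      events$drug_class == "vasopressor",
    sedative_admin = events$kind == "med_admin" &
      events$drug_class == "sedative_infusion",
    vasopressor_admin = events$kind == "med_admin" &
      events$drug_class == "vasopressor",
    vent_obs = events$kind == "vent_obs",
    sbt_result = events$kind == "vent_obs" & !is.na(events$sbt_result),
    bleeding_dx = events$kind == "diagnosis" &
      events$dx_code %in% c("bleeding", "hematoma", "hemorrhage"),
    contraindication_dx = events$kind == "diagnosis" &
      events$dx_code %in% c("status_epilepticus", "intracranial_hypertension"),
    indication_dx = events$kind == "diagnosis",
    code_status = events$kind == "code_status",
    transfusions = events$kind == "transfusion",
    activity_order = events$kind == "activity_order",
    nutrition_record = events$kind == "nutrition",
    stool_doc = events$kind == "flowsheet_doc" &
      events$doc_type == "liquid_stool",
    rep(FALSE, nrow(events)))
  events[!drop, , drop = FALSE]
}

test_that("every rule is total over absent-input subsets", {
  set.seed(31)
  f <- sample_features()
  # force a rich chart so there is something to remove
  f$comfort <- FALSE
  ctx_full <- features_to_ctx(f)
  reg <- default_registry()
  for (rid in rule_ids(reg)) {
    inputs <- names(reg[[rid]]$required_inputs)
    k <- length(inputs)
    subsets <- if (2^k <= 64) {
      lapply(0:(2^k - 1), function(m) inputs[bitwAnd(m, 2^(seq_len(k) - 1)) > 0])
    } else {
      c(list(character(0), inputs), lapply(inputs, identity),
        lapply(1:40, function(i) sample(inputs, sample(2:(k - 1), 1))))
    }
    for (sub in subsets) {
      ev <- ctx_full$events
      for (inp in sub) ev <- input_event_filter(ev, inp)
      ctx <- suppressWarnings(
        assemble_patient_day(ev, ctx_full$attributes, ctx_full$eval_time))
      res <- evaluate_rule(reg[[rid]], ctx)
      expect_false("evaluator_error" %in% res$reasons,
                   info = paste(rid, paste(sub, collapse = "+")))
      expect_true(is.logical(res$flag) && length(res$flag) == 1L)
    }
  }
})

test_that("the three policy branches drive the documented rule behaviors", {
  # chemoprophylaxis expected but absent => negative finding => rule flags
  ctx <- mk_day(e_device("compression_device", start = 0))
  res <- evaluate_rule(default_registry()[["vte_chemical"]], ctx)
  expect_true(res$flag)
  # absent device => positive finding => nothing to remove, no flag
  ctx2 <- assemble_patient_day(empty_events(), std_attrs(), hrs(16))
  res2 <- evaluate_rule(default_registry()[["central_line_removal"]], ctx2)
  expect_false(res2$flag)
  expect_true("device_absent" %in% res2$reasons)
  # absent labs => assumed normal, recorded in the inputs audit trail
  expect_match(unlist(res$inputs_used[c("platelets", "inr", "aptt")]),
               "assumed_normal", all = TRUE)
})
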