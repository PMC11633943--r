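# Rule engine: missing-data policies, the rule registry, and per-patient-day
# evaluation producing binary actionable flags with auditable reason codes.

MISSING_POLICIES <- c("expected_present_missing", "expected_absent_missing",
                      "lab_missing")

#' Resolve an absent input under a declared missing-data policy
#'
#' Three situations are distinguished.  Data expected to be present but
#' absent (e.g. a chemoprophylaxis order in a patient expected to have one)
#' is a negative finding.  Data expected to be absent (e.g. no central line
#' in a patient who does not need one) is a positive finding — nothing to
#' act on.  An absent decision-relevant lab is assumed within normal limits,
#' on the premise that clinicians actively chose not to obtain it.
#'
#' @param input_name Name of the rule input (for the provenance record).
#' @param raw_value The observed value, or `NULL`/`NA` if absent.
#' @param policy One of `"expected_present_missing"`,
#'   `"expected_absent_missing"`, `"lab_missing"`.
#' @param normal_default Substitute value, required for `"lab_missing"`.
#' @return `list(input, value, finding, tag)`: `finding` is `"observed"`,
#'   `"negative"`, `"positive"` or `"assumed_normal"`; `tag` records which
#'   branch fired.
#' @export
#' @examples
#' resolve_missing("inr", NULL, "lab_missing", 1.0)
resolve_missing <- function(input_name, raw_value, policy,
                            normal_default = NULL) {
  if (!policy %in% MISSING_POLICIES)
    stop("unknown missing-data policy: ", policy, call. = FALSE)
  absent <- is.null(raw_value) ||
    (length(raw_value) == 1L && is.na(raw_value)) || length(raw_value) == 0L
  if (!absent)
    return(list(input = input_name, value = raw_value, finding = "observed",
                tag = "present"))
  switch(policy,
    expected_present_missing = list(input = input_name, value = NULL,
                                    finding = "negative",
                                    tag = "missing_negative_finding"),
    expected_absent_missing = list(input = input_name, value = NULL,
                                   finding = "positive",
                                   tag = "missing_positive_finding"),
    lab_missing = {
      if (is.null(normal_default))
        stop("policy 'lab_missing' requires a normal_default for input '",
             input_name, "'", call. = FALSE)
      list(input = input_name, value = normal_default,
           finding = "assumed_normal", tag = "assumed_normal")
    })
}

#' Construct a rule result
#'
#' @param rule_id Metric identifier.
#' @param flag Logical: actionable finding ("X" on the census).
#' @param reasons Character vector of stable snake_case reason codes; a
#'   raised flag must carry at least one.
#' @param inputs Named list recording the inputs consulted (resolved values
#'   or `"missing(<policy>)"` tags).
#' @param abstained Logical: the rule declined to evaluate (insufficient
#'   elapsed day, or evaluator failure); abstention never flags.
#' @return A `rule_result` list.
#' @export
rule_result <- function(rule_id, flag, reasons = character(0),
                        inputs = list(), abstained = FALSE) {
  if (abstained && flag)
    stop("an abstaining rule cannot flag", call. = FALSE)
  if (flag && length(reasons) == 0L)
    stop("a raised flag requires at least one reason code", call. = FALSE)
  structure(list(rule_id = rule_id, flag = flag, abstained = abstained,
                 reasons = reasons, inputs_used = inputs),
            class = "rule_result")
}

#' @export
print.rule_result <- function(x, ...) {
  cat("<rule_result> ", x$rule_id, ": ",
      if (x$abstained) "abstained" else if (x$flag) "X (actionable)" else "-",
      "\n", sep = "")
  if (length(x$reasons))
    cat("  reasons: ", paste(x$reasons, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# rule_id -> (category, evaluator, required inputs with policies)
rule_definition <- function(rule_id, category, evaluator, required_inputs) {
  list(rule_id = rule_id, category = category, evaluator = evaluator,
       required_inputs = required_inputs)
}

#' The default metric registry
#'
#' One entry per daily metric, in fixed census-column order, spanning the
#' seven categories (hypoglycemia, VTE prophylaxis, stress ulcer prophylaxis,
#' mechanical ventilation, sedation, nutrition, catheter removal/risk).  Each
#' entry names its evaluator and declares, per required input, which
#' missing-data policy absorbs that input's absence.
#'
#' @param config Engine configuration (thresholds, keyword lists).
#' @return Named list of rule definitions.
#' @export
default_registry <- function(config = default_config()) {
  lab <- "lab_missing"; pres <- "expected_present_missing"
  abs_ <- "expected_absent_missing"
  defs <- list(
    rule_definition("hypoglycemia", "hypoglycemia", eval_hypoglycemia,
      c(glucose = lab)),
    rule_definition("vte_chemical", "vte_prophylaxis", eval_vte_chemical,
      c(compression_device = pres, anticoagulant_order = pres,
        platelets = lab, inr = lab, aptt = lab, bleeding_dx = abs_,
        code_status = abs_, transfusions = abs_, activity_order = abs_)),
    rule_definition("vte_mechanical", "vte_prophylaxis", eval_vte_mechanical,
      c(compression_device = pres, anticoagulant_order = pres,
        code_status = abs_, activity_order = abs_)),
    rule_definition("vte_any", "vte_prophylaxis", eval_vte_any,
      c(compression_device = pres, anticoagulant_order = pres,
        platelets = lab, inr = lab, aptt = lab, bleeding_dx = abs_,
        code_status = abs_, transfusions = abs_, activity_order = abs_)),
    rule_definition("sup_start", "sup", eval_sup_start,
      c(acid_suppressant_order = pres, ett_device = abs_, platelets = lab,
        inr = lab, aptt = lab, code_status = abs_)),
    rule_definition("sup_stop", "sup", eval_sup_stop,
      c(acid_suppressant_order = pres, ett_device = abs_, platelets = lab,
        inr = lab, aptt = lab)),
    rule_definition("low_tidal_volume", "mechanical_ventilation",
      eval_low_tidal_volume,
      c(ett_device = abs_, vent_obs = pres)),
    rule_definition("sedation_wean", "sedation", eval_sedation_wean,
      c(sedative_order = pres, sedative_admin = pres, paralytic_order = abs_,
        code_status = abs_, contraindication_dx = abs_)),
    rule_definition("sbt_ready", "mechanical_ventilation", eval_sbt_ready,
      c(ett_device = abs_, vent_obs = pres, vasopressor_admin = abs_,
        paralytic_order = abs_)),
    rule_definition("sbt_passed", "mechanical_ventilation", eval_sbt_passed,
      c(ett_device = abs_, sbt_result = pres)),
    rule_definition("nutrition_start", "nutrition", eval_nutrition_start,
      c(nutrition_record = pres, code_status = abs_)),
    rule_definition("nutrition_adequacy", "nutrition", eval_nutrition_adequacy,
      c(nutrition_record = pres, code_status = abs_)),
    rule_definition("urinary_catheter_removal", "catheter",
      evaluator = function(ctx, cfg) eval_device_removal(ctx, "urinary_catheter", cfg),
      c(device = abs_, indication_dx = abs_, activity_order = abs_,
        vasopressor_order = abs_, code_status = abs_)),
    rule_definition("central_line_removal", "catheter",
      evaluator = function(ctx, cfg) eval_device_removal(ctx, "central_line", cfg),
      c(device = abs_, vasopressor_admin = abs_, vasopressor_order = abs_,
        indication_dx = abs_, code_status = abs_)),
    rule_definition("arterial_line_removal", "catheter",
      evaluator = function(ctx, cfg) eval_device_removal(ctx, "arterial_line", cfg),
      c(device = abs_, vasopressor_admin = abs_, abg_labs = abs_,
        code_status = abs_)),
    rule_definition("picc_removal", "catheter",
      evaluator = function(ctx, cfg) eval_device_removal(ctx, "picc", cfg),
      c(device = abs_, indication_dx = abs_, code_status = abs_)),
    rule_definition("surveillance_culture", "catheter",
      eval_surveillance_culture,
      c(outside_line = abs_, blood_culture = pres)),
    rule_definition("rectal_tube_removal", "catheter",
      evaluator = function(ctx, cfg) eval_device_removal(ctx, "rectal_tube", cfg),
      c(device = abs_, stool_doc = abs_, indication_dx = abs_,
        code_status = abs_)),
    rule_definition("ng_to_og", "catheter", eval_ng_to_og,
      c(ngt_device = abs_, ett_device = abs_, code_status = abs_)),
    rule_definition("high_risk_central_line", "catheter",
      evaluator = function(ctx, cfg) eval_high_risk_line(ctx, "central_line", cfg),
      c(device = abs_)),
    rule_definition("high_risk_arterial_line", "catheter",
      evaluator = function(ctx, cfg) eval_high_risk_line(ctx, "arterial_line", cfg),
      c(device = abs_)),
    rule_definition("high_risk_hd_line", "catheter",
      evaluator = function(ctx, cfg) eval_high_risk_line(ctx, "hd_line", cfg),
      c(device = abs_)),
    rule_definition("high_risk_picc", "catheter",
      evaluator = function(ctx, cfg) eval_high_risk_line(ctx, "picc", cfg),
      c(device = abs_))
  )
  names(defs) <- vapply(defs, `[[`, "", "rule_id")
  defs
}

#' Metric identifiers in census-column order
#' @param registry A registry from [default_registry()].
#' @export
rule_ids <- function(registry = default_registry()) names(registry)

#' Evaluate one rule on a patient-day
#'
#' Deterministic and fail-safe: missing data is absorbed by the declared
#' policies, and an internal evaluator error yields an abstaining result
#' (reason `evaluator_error`) rather than a false alarm.
#'
#' @param rule A rule definition from the registry.
#' @param ctx A `patient_day` context.
#' @param config Engine configuration.
#' @return A [rule_result()].
#' @export
evaluate_rule <- function(rule, ctx, config = ctx$config) {
  out <- tryCatch(rule$evaluator(ctx, config), error = function(e) {
    list(flag = FALSE, abstained = TRUE, reasons = "evaluator_error",
         inputs = list(error = conditionMessage(e)))
  })
  rule_result(rule$rule_id, flag = isTRUE(out$flag),
              reasons = out$reasons %||% character(0),
              inputs = out$inputs %||% list(),
              abstained = isTRUE(out$abstained))
}

#' Evaluate every registered metric on a patient-day
#'
#' @param ctx A `patient_day` context.
#' @param registry Rule registry (default: all shipped metrics, fixed order).
#' @param config Engine configuration.
#' @return A `rule_results` list, one [rule_result()] per registered metric.
#' @export
evaluate_patient_day <- function(ctx, registry = default_registry(ctx$config),
                                 config = ctx$config) {
  res <- lapply(registry, evaluate_rule, ctx = ctx, config = config)
  structure(res, class = "rule_results", patient_id = ctx$patient_id)
}

#' Tabulate rule results
#'
#' @param results A `rule_results` list (or plain list of [rule_result()]s).
#' @param patient_id Identifier to attach (taken from the results attribute
#'   when present).
#' @return Data.frame with columns `patient_id`, `rule_id`, `flag`,
#'   `abstained`, `reasons` (codes joined with `;`).
#' @export
results_to_frame <- function(results,
                             patient_id = attr(results, "patient_id")) {
  data.frame(
    patient_id = patient_id %||% NA_character_,
    rule_id = vapply(results, `[[`, "", "rule_id"),
    flag = vapply(results, `[[`, NA, "flag"),
    abstained = vapply(results, `[[`, NA, "abstained"),
    reasons = vapply(results, function(r)
      paste(r$reasons, collapse = ";"), ""),
    row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
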