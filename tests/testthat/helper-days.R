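# Small builders for hand-crafted patient-days used across test files.

day0 <- as.POSIXct("2022-06-01 00:00:00", tz = "UTC")
hrs <- function(h) day0 + h * 3600

std_attrs <- function(pid = "p1", height = 175, sex = "male",
                      admit_h = -72) {
  patient_attributes(pid, height, sex, hrs(admit_h))
}

# assemble a day at 16:00 from events built with clinical_event()
mk_day <- function(..., attrs = std_attrs(), eval_h = 16) {
  evs <- bind_events(list(...))
  suppressWarnings(assemble_patient_day(evs, attrs, hrs(eval_h)))
}

e_order <- function(class, status = "active", start = -40, end = NA,
                    pid = "p1", route = "sc")
  clinical_event("med_order", pid, hrs(start), end = if (is.na(end)) NA else hrs(end),
                 drug_class = class, status = status, route = route)

e_lab <- function(analyte, value, at_h, pid = "p1")
  clinical_event("lab", pid, hrs(at_h), analyte = analyte, value = value,
                 result_time = hrs(at_h))

e_device <- function(device, start, end = NA, site = "other",
                     outside = FALSE, pid = "p1")
  clinical_event("device", pid, hrs(start),
                 end = if (is.na(end)) NA else hrs(end),
                 device = device, site = site, placed_outside = outside)

e_dx <- function(code, start = -60, pid = "p1")
  clinical_event("diagnosis", pid, hrs(start), dx_code = code)

e_comfort <- function(at_h = -1, pid = "p1")
  clinical_event("code_status", pid, hrs(at_h), code_status = "comfort_care")

e_vent <- function(at_h, mode = "controlled", vt = NA, fio2 = NA, peep = NA,
                   sbt = NA, pid = "p1")
  clinical_event("vent_obs", pid, hrs(at_h), vent_mode = mode,
                 tidal_volume_ml = vt, fio2 = fio2, peep_cmh2o = peep,
                 sbt_result = sbt)

flag_of <- function(ctx, rule_id) {
  reg <- default_registry()
  evaluate_rule(reg[[rule_id]], ctx)$flag
}
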