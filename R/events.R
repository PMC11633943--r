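# Typed clinical event model.  Every raw input the rules consume is one of
# eleven event kinds carried in a single wide data.frame; kind determines
# which payload columns are required.  Times are POSIXct (UTC internally);
# the effective interval is half-open [start, end) with NA end = ongoing.

EVENT_KINDS <- c("med_order", "med_admin", "lab", "device", "diagnosis",
                 "vent_obs", "nutrition", "code_status", "transfusion",
                 "activity_order", "flowsheet_doc")

DRUG_CLASSES <- c("ufh_prophylactic", "lmwh_prophylactic", "ufh_therapeutic",
                  "lmwh_therapeutic", "doac", "warfarin", "acid_suppressant",
                  "sedative_infusion", "vasopressor", "paralytic", "insulin",
                  "other")

LAB_ANALYTES <- c("glucose_mg_dl", "platelets_k_per_ul", "inr", "aptt_sec",
                  "blood_culture", "abg", "other")

DEVICE_TYPES <- c("urinary_catheter", "central_line", "arterial_line", "picc",
                  "hd_line", "rectal_tube", "ngt", "ogt", "compression_device",
                  "ett")

# payload columns required (non-NA) per kind
REQUIRED_PAYLOAD <- list(
  med_order      = c("drug_class", "status", "route"),
  med_admin      = c("drug_class", "action", "dose_time"),
  lab            = c("analyte", "value", "result_time"),
  device         = c("device", "site", "placed_outside"),
  diagnosis      = c("dx_code"),
  vent_obs       = c("vent_mode"),
  nutrition      = c("nutrition_route", "goal_kcal_day", "delivered_kcal"),
  code_status    = c("code_status"),
  transfusion    = c("product", "units"),
  activity_order = c("activity"),
  flowsheet_doc  = c("doc_type")
)

PAYLOAD_COLUMNS <- c("drug_class", "status", "route", "action", "dose_time",
                     "analyte", "value", "result_time", "device", "site",
                     "placed_outside", "tidal_volume_ml", "vent_mode", "fio2",
                     "peep_cmh2o", "sbt_result", "dx_code", "nutrition_route",
                     "goal_kcal_day", "delivered_kcal", "code_status",
                     "product", "units", "activity", "doc_type", "doc_value")

EVENT_COLUMNS <- c("patient_id", "event_id", "kind", "start", "end",
                   "recorded", PAYLOAD_COLUMNS)

.time_cols <- c("start", "end", "dose_time", "result_time")

#' Parse ISO-8601 timestamps
#'
#' Accepts `2022-06-01T08:00:00+0000`, `...+00:00`, a trailing `Z`, or a bare
#' local time (interpreted in `tz`).  Returns POSIXct in `tz`.
#'
#' @param x Character vector (or POSIXct, returned re-zoned).
#' @param tz Target time zone, default UTC.
#' @export
parse_time <- function(x, tz = "UTC") {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- tz
    return(x)
  }
  if (all(is.na(x))) return(as.POSIXct(rep(NA_real_, length(x)), tz = tz, origin = "1970-01-01"))
  x <- as.character(x)
  y <- sub("Z$", "+0000", x)
  y <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", y)
  out <- as.POSIXct(strptime(y, "%Y-%m-%dT%H:%M:%OS%z", tz = tz))
  miss <- is.na(out) & !is.na(x)
  if (any(miss))
    out[miss] <- as.POSIXct(strptime(y[miss], "%Y-%m-%dT%H:%M:%OS", tz = tz))
  bad <- is.na(out) & !is.na(x)
  if (any(bad))
    stop("unparseable timestamp(s): ", paste(utils::head(x[bad], 3), collapse = ", "),
         call. = FALSE)
  attr(out, "tzone") <- tz
  out
}

#' Format POSIXct as ISO-8601 with offset
#' @param x POSIXct vector.
#' @export
format_time <- function(x) {
  out <- format(x, "%Y-%m-%dT%H:%M:%S%z")
  out[is.na(x)] <- NA_character_
  out
}

#' An empty, schema-complete event table
#' @return Zero-row data.frame with all event columns correctly typed.
#' @export
empty_events <- function() {
  tm <- as.POSIXct(numeric(0), tz = "UTC", origin = "1970-01-01")
  df <- data.frame(
    patient_id = character(0), event_id = character(0), kind = character(0),
    start = tm, end = tm, recorded = integer(0),
    drug_class = character(0), status = character(0), route = character(0),
    action = character(0), dose_time = tm,
    analyte = character(0), value = numeric(0), result_time = tm,
    device = character(0), site = character(0), placed_outside = logical(0),
    tidal_volume_ml = numeric(0), vent_mode = character(0), fio2 = numeric(0),
    peep_cmh2o = numeric(0), sbt_result = character(0),
    dx_code = character(0),
    nutrition_route = character(0), goal_kcal_day = numeric(0),
    delivered_kcal = numeric(0),
    code_status = character(0), product = character(0), units = numeric(0),
    activity = character(0), doc_type = character(0), doc_value = character(0),
    stringsAsFactors = FALSE)
  df
}

#' Construct one clinical event
#'
#' Convenience row constructor used by the synthetic generator and by tests.
#' Payload fields are passed by name; anything not given is NA.
#'
#' @param kind One of the eleven event kinds.
#' @param patient_id,event_id Opaque identifiers (`event_id` may be NA and be
#'   assigned later by [bind_events()]).
#' @param start,end Effective half-open interval; `end = NA` means ongoing.
#' @param ... Kind-specific payload fields (e.g. `drug_class`, `value`).
#' @return One-row event data.frame.
#' @export
clinical_event <- function(kind, patient_id, start, end = NA, ...,
                           event_id = NA_character_) {
  if (!kind %in% EVENT_KINDS)
    stop("unknown event kind: ", kind, call. = FALSE)
  row <- empty_events()[0, ]
  row[1, "patient_id"] <- patient_id
  row[1, "event_id"] <- event_id
  row[1, "kind"] <- kind
  row$start <- parse_time(start)
  row$end <- if (length(end) == 1L && is.na(end))
    as.POSIXct(NA_real_, tz = "UTC", origin = "1970-01-01") else parse_time(end)
  payload <- list(...)
  bad <- setdiff(names(payload), PAYLOAD_COLUMNS)
  if (length(bad))
    stop("unknown payload field(s): ", paste(bad, collapse = ", "), call. = FALSE)
  for (nm in names(payload)) {
    v <- payload[[nm]]
    if (nm %in% .time_cols) v <- parse_time(v)
    row[[nm]] <- v
  }
  row
}

#' Row-bind events, assigning recording order and missing ids
#'
#' @param ... Event data.frames (or a single list of them).
#' @return One event data.frame; `recorded` is 1..n in bind order where NA,
#'   and `event_id` is filled with `ev%06d` where NA.
#' @export
bind_events <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) && !is.data.frame(parts[[1]]))
    parts <- parts[[1]]
  parts <- Filter(function(p) !is.null(p) && nrow(p) > 0L, parts)
  if (!length(parts)) return(empty_events())
  df <- do.call(rbind, parts)
  rownames(df) <- NULL
  if (anyNA(df$recorded)) {
    miss <- is.na(df$recorded)
    df$recorded[miss] <- seq_len(nrow(df))[miss]
  }
  if (anyNA(df$event_id)) {
    miss <- is.na(df$event_id)
    df$event_id[miss] <- sprintf("ev%06d", seq_len(nrow(df))[miss])
  }
  df
}

#' Validate an event table against the schema
#'
#' Checks kinds, interval ordering (start < end where end present) and the
#' kind-specific required payload fields.  Errors name the offending rows and
#' fields; returns the table invisibly when clean.
#'
#' @param events Event data.frame.
#' @export
validate_events <- function(events) {
  if (!is.data.frame(events)) stop("events must be a data.frame", call. = FALSE)
  missing_cols <- setdiff(EVENT_COLUMNS, names(events))
  if (length(missing_cols))
    stop("events missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(events) == 0L) return(invisible(events))
  bad_kind <- !events$kind %in% EVENT_KINDS
  if (any(bad_kind))
    stop("unknown event kind in row(s) ",
         paste(utils::head(which(bad_kind), 5), collapse = ", "), ": ",
         paste(unique(events$kind[bad_kind]), collapse = ", "), call. = FALSE)
  has_end <- !is.na(events$end)
  bad_iv <- has_end & !(as.numeric(events$end) > as.numeric(events$start))
  if (any(bad_iv))
    stop("start must precede end in row(s) ",
         paste(utils::head(which(bad_iv), 5), collapse = ", "), call. = FALSE)
  for (k in unique(events$kind)) {
    rows <- which(events$kind == k)
    for (fld in REQUIRED_PAYLOAD[[k]]) {
      absent <- rows[is.na(events[[fld]][rows])]
      if (length(absent))
        stop("event kind '", k, "' requires field '", fld,
             "' (missing in row ", absent[1], ")", call. = FALSE)
    }
  }
  invisible(events)
}

#' Deduplicate events by id, latest-recorded wins
#'
#' Events sharing an `event_id` are amendments of the same record; the one
#' with the greatest `recorded` sequence number (ties: latest position)
#' replaces the rest.
#'
#' @param events Event data.frame.
#' @return Deduplicated event data.frame, original relative order retained.
#' @export
dedup_events <- function(events) {
  if (nrow(events) <= 1L) return(events)
  o <- order(events$event_id, events$recorded, seq_len(nrow(events)))
  ord <- events[o, , drop = FALSE]
  keep <- !duplicated(ord$event_id, fromLast = TRUE)
  kept <- ord[keep, , drop = FALSE]
  kept <- kept[order(kept$recorded, as.numeric(rownames(kept))), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}
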