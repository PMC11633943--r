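# JSON-Lines event I/O and the census-style flag report.

#' Read a JSON-Lines event stream
#'
#' One event object per line; keys are the snake_case schema fields
#' (`patient_id`, `event_id`, `kind`, `start`, `end`, plus the kind-specific
#' payload fields).  Timestamps are ISO-8601.  Malformed JSON or a schema
#' violation raises an error naming the line.
#'
#' @param path File path.
#' @param tz Time zone for parsed timestamps.
#' @return Validated event data.frame; `recorded` is the line number unless
#'   given explicitly.
#' @export
read_events_jsonl <- function(path, tz = "UTC") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_events())
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e)
                      stop("line ", i, ": malformed JSON (",
                           conditionMessage(e), ")", call. = FALSE))
    if (is.null(obj$kind) || !obj$kind %in% EVENT_KINDS)
      stop("line ", i, ": unknown or missing event kind", call. = FALSE)
    for (fld in c("patient_id", "start"))
      if (is.null(obj[[fld]]))
        stop("line ", i, ": missing required field '", fld, "'", call. = FALSE)
    for (fld in REQUIRED_PAYLOAD[[obj$kind]])
      if (is.null(obj[[fld]]) || (length(obj[[fld]]) == 1L && is.na(obj[[fld]])))
        stop("line ", i, ": event kind '", obj$kind,
             "' requires field '", fld, "'", call. = FALSE)
    row <- empty_events()[0, ]
    row[1, "kind"] <- obj$kind
    for (nm in intersect(names(obj), EVENT_COLUMNS)) {
      v <- obj[[nm]]
      if (nm %in% .time_cols) v <- parse_time(v, tz)
      if (nm == "recorded") v <- as.integer(v)
      row[[nm]] <- v
    }
    if (is.na(row$recorded)) row$recorded <- i
    rows[[i]] <- row
  }
  ev <- bind_events(rows)
  validate_events(ev)
  ev
}

#' Write events as JSON-Lines
#'
#' Inverse of [read_events_jsonl()]: NA payload fields are omitted per line,
#' timestamps serialize as ISO-8601 with offset.  Round-trips losslessly.
#'
#' @param events Event data.frame.
#' @param path Output path.
#' @export
write_events_jsonl <- function(events, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(events))) {
    row <- events[i, ]
    obj <- list()
    for (nm in EVENT_COLUMNS) {
      v <- row[[nm]]
      if (length(v) == 1L && is.na(v)) next
      if (nm %in% .time_cols) v <- format_time(v)
      obj[[nm]] <- v
    }
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read patient attributes from JSON-Lines
#'
#' One object per line: `patient_id`, `height_cm`, `sex`, `admit_time`.
#'
#' @param path File path.
#' @param tz Time zone for `admit_time`.
#' @return Data.frame of patient attributes.
#' @export
read_patients_jsonl <- function(path, tz = "UTC") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e)
                      stop("line ", i, ": malformed JSON", call. = FALSE))
    for (fld in c("patient_id", "height_cm", "sex", "admit_time"))
      if (is.null(obj[[fld]]))
        stop("line ", i, ": missing patient field '", fld, "'", call. = FALSE)
    data.frame(patient_id = obj$patient_id, height_cm = obj$height_cm,
               sex = obj$sex, admit_time = obj$admit_time,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write patient attributes as JSON-Lines
#' @param patients Data.frame with `patient_id, height_cm, sex, admit_time`.
#' @param path Output path.
#' @export
write_patients_jsonl <- function(patients, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(patients))) {
    writeLines(jsonlite::toJSON(as.list(patients[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  }
  invisible(path)
}

#' Render the census flag table
#'
#' One row per patient, one column per metric in registry order; an "X"
#' marks an actionable finding, an empty cell means no action required.
#'
#' @param flags Flags data.frame (`patient_id, rule_id, flag`), e.g. from
#'   [evaluate_cohort()].
#' @param registry Rule registry fixing the column order.
#' @return Data.frame: `patient_id` plus one character column per metric.
#' @export
render_census <- function(flags, registry = default_registry()) {
  ids <- rule_ids(registry)
  pids <- unique(flags$patient_id)
  m <- matrix("", nrow = length(pids), ncol = length(ids),
              dimnames = list(NULL, ids))
  if (nrow(flags)) {
    ri <- match(flags$rule_id, ids)
    pi_ <- match(flags$patient_id, pids)
    sel <- !is.na(ri) & as.logical(flags$flag)
    m[cbind(pi_[sel], ri[sel])] <- "X"
  }
  cbind(data.frame(patient_id = pids, stringsAsFactors = FALSE),
        as.data.frame(m, stringsAsFactors = FALSE))
}

#' Write a census table as CSV
#' @param census Output of [render_census()].
#' @param path Output path.
#' @export
write_census_csv <- function(census, path) {
  utils::write.csv(census, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
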