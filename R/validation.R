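# Confusion-matrix validation: count accumulation against ground truth, the
# five classification statistics, and exact integer reconstruction of
# confusion counts from rounded published statistic rows.

#' Round half away from zero
#'
#' The reporting convention for the classification statistics: 0.9655 prints
#' as 0.966, -0.0005 as -0.001.  (Base R's `round()` rounds half to even.)
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @export
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Accumulate confusion counts from flags and ground truth
#'
#' Pairs each engine flag with its ground-truth label on
#' `(patient_id, rule_id)` and tallies: TP = flag and truth, TN = neither,
#' FP = flag without truth, FN = truth without flag.  Unmatched rows on
#' either side are an error.
#'
#' @param flags Data.frame with `patient_id`, `rule_id`, `flag` (logical).
#' @param truth Data.frame with `patient_id`, `rule_id`, `actionable`.
#' @return Data.frame of counts per `rule_id` plus an `overall` row
#'   (elementwise sum), columns `rule_id, tp, fp, tn, fn, n`.
#' @export
accumulate_confusion <- function(flags, truth) {
  for (nm in c("patient_id", "rule_id", "flag"))
    if (!nm %in% names(flags)) stop("flags lacks column ", nm, call. = FALSE)
  for (nm in c("patient_id", "rule_id", "actionable"))
    if (!nm %in% names(truth)) stop("truth lacks column ", nm, call. = FALSE)
  fk <- paste(flags$patient_id, flags$rule_id, sep = "\r")
  tk <- paste(truth$patient_id, truth$rule_id, sep = "\r")
  if (anyDuplicated(fk)) stop("duplicate (patient, rule) in flags", call. = FALSE)
  if (anyDuplicated(tk)) stop("duplicate (patient, rule) in truth", call. = FALSE)
  if (length(setdiff(fk, tk)) || length(setdiff(tk, fk)))
    stop("flags and truth do not pair one-to-one", call. = FALSE)
  if (nrow(flags) == 0L) {
    return(data.frame(rule_id = "overall", tp = 0L, fp = 0L, tn = 0L,
                      fn = 0L, n = 0L, stringsAsFactors = FALSE))
  }
  m <- match(fk, tk)
  f <- as.logical(flags$flag)
  t_ <- as.logical(truth$actionable[m])
  rid <- flags$rule_id
  per <- lapply(split(seq_along(f), rid), function(i) {
    data.frame(tp = sum(f[i] & t_[i]), fp = sum(f[i] & !t_[i]),
               tn = sum(!f[i] & !t_[i]), fn = sum(!f[i] & t_[i]))
  })
  out <- do.call(rbind, per)
  out <- cbind(rule_id = names(per), out, row.names = NULL,
               stringsAsFactors = FALSE)
  overall <- data.frame(rule_id = "overall", tp = sum(out$tp),
                        fp = sum(out$fp), tn = sum(out$tn), fn = sum(out$fn),
                        stringsAsFactors = FALSE)
  out <- rbind(out, overall)
  out$n <- out$tp + out$fp + out$tn + out$fn
  out
}

#' Classification statistics from confusion counts
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), accuracy (tp+tn)/n,
#' PPV tp/(tp+fp), NPV tn/(tn+fn).  A zero denominator yields `NaN`
#' (undefined), the convention used when a metric saw no positive cases.
#' Values are returned unrounded; see [format_stats()] for the 3-decimal
#' reporting convention.
#'
#' @param counts Data.frame with `tp, fp, tn, fn` columns (and optionally
#'   `rule_id`), or a numeric vector `c(tp, fp, tn, fn)`.
#' @return Data.frame with `n, sensitivity, specificity, accuracy, ppv, npv`
#'   (and `rule_id` when supplied).
#' @export
classification_stats <- function(counts) {
  if (is.numeric(counts) && length(counts) == 4L)
    counts <- data.frame(tp = counts[1], fp = counts[2], tn = counts[3],
                         fn = counts[4])
  if (any(counts$tp < 0 | counts$fp < 0 | counts$tn < 0 | counts$fn < 0))
    stop("confusion counts must be non-negative", call. = FALSE)
  n <- counts$tp + counts$fp + counts$tn + counts$fn
  div <- function(num, den) ifelse(den == 0, NaN, num / den)
  out <- data.frame(
    n = n,
    sensitivity = div(counts$tp, counts$tp + counts$fn),
    specificity = div(counts$tn, counts$tn + counts$fp),
    accuracy = div(counts$tp + counts$tn, n),
    ppv = div(counts$tp, counts$tp + counts$fp),
    npv = div(counts$tn, counts$tn + counts$fn))
  if (!is.null(counts$rule_id)) out <- cbind(rule_id = counts$rule_id, out)
  out
}

#' Format statistics the way validation tables print them
#'
#' Rounds half away from zero to 3 decimals and truncates trailing zeros
#' ("0.970" prints as "0.97", "1.000" as "1"); undefined values print "NaN".
#'
#' @param x Numeric vector of statistics.
#' @export
format_stats <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    if (is.nan(x[i])) out[i] <- "NaN"
    else {
      s <- sprintf("%.3f", round_half_up(x[i], 3))
      s <- sub("0+$", "", s)
      s <- sub("\\.$", "", s)
      out[i] <- s
    }
  }
  out
}

.stat_names <- c("sensitivity", "specificity", "accuracy", "ppv", "npv")

#' Reconstruct integer confusion counts from a published statistic row
#'
#' Exhaustively enumerates every non-negative `(tp, fp, tn, fn)` summing to
#' `n` and keeps the tuples whose recomputed statistics round (half away
#' from zero, 3 decimals, trailing zeros truncated) to every supplied
#' printed value.  A printed `NaN` requires the corresponding denominator to
#' be zero.  This inverts the table-reporting step and lets a held-out
#' statistic be checked against the printed row.
#'
#' @param n Row total (number of evaluations), `n >= 1`.
#' @param printed Named numeric vector/list with at least three of
#'   `sensitivity, specificity, accuracy, ppv, npv` (values as printed, e.g.
#'   `0.97`, `0.8`, `1`; `NaN` allowed).
#' @return `list(counts = data.frame(tp, fp, tn, fn) of survivors,
#'   unique = logical)`.  Zero survivors is an error ("inconsistent row").
#' @export
#' @examples
#' reconstruct_counts(33, c(sensitivity = 1, ppv = 0.8, npv = 1))
reconstruct_counts <- function(n, printed) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  printed <- unlist(printed)
  printed <- printed[!is.na(names(printed)) & names(printed) %in% .stat_names]
  # NaN survives unlist/is.na screening: keep entries that are NaN or finite
  if (sum(!is.na(printed) | is.nan(printed)) < 3L)
    stop("need at least three printed statistics", call. = FALSE)
  grid <- expand.grid(tp = 0:n, fp = 0:n)
  grid <- grid[grid$tp + grid$fp <= n, , drop = FALSE]
  k <- n - grid$tp - grid$fp
  tp <- rep(grid$tp, k + 1L)
  fp <- rep(grid$fp, k + 1L)
  tn <- sequence(k + 1L) - 1L
  fn <- n - tp - fp - tn
  keep <- rep(TRUE, length(tp))
  stats <- list(
    sensitivity = function() ifelse(tp + fn == 0, NaN, tp / (tp + fn)),
    specificity = function() ifelse(tn + fp == 0, NaN, tn / (tn + fp)),
    accuracy = function() (tp + tn) / n,
    ppv = function() ifelse(tp + fp == 0, NaN, tp / (tp + fp)),
    npv = function() ifelse(tn + fn == 0, NaN, tn / (tn + fn)))
  for (nm in names(printed)) {
    p <- printed[[nm]]
    if (is.na(p) && !is.nan(p)) next
    v <- stats[[nm]]()
    keep <- keep & if (is.nan(p)) is.nan(v)
      else (!is.nan(v) & abs(round_half_up(v, 3) - p) < 1e-9)
  }
  if (!any(keep)) stop("inconsistent row", call. = FALSE)
  counts <- data.frame(tp = tp[keep], fp = fp[keep], tn = tn[keep],
                       fn = fn[keep])
  list(counts = counts, unique = nrow(counts) == 1L)
}
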