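# Half-open interval utilities.  All intervals are [start, end); an NA end
# means "ongoing" and is treated as unbounded on the right.

as_interval_matrix <- function(intervals) {
  if (is.null(intervals) || (is.data.frame(intervals) && nrow(intervals) == 0L))
    return(matrix(numeric(0), ncol = 2))
  if (is.data.frame(intervals)) {
    s <- as.numeric(intervals$start)
    e <- as.numeric(intervals$end)
  } else if (is.matrix(intervals)) {
    s <- as.numeric(intervals[, 1])
    e <- as.numeric(intervals[, 2])
  } else if (is.numeric(intervals) && length(intervals) == 2L) {
    s <- as.numeric(intervals[1]); e <- as.numeric(intervals[2])
  } else {
    stop("intervals must be a data.frame with start/end or a 2-column matrix",
         call. = FALSE)
  }
  e[is.na(e)] <- Inf
  if (any(is.na(s))) stop("interval start may not be NA", call. = FALSE)
  if (any(e <= s)) stop("intervals must satisfy start < end", call. = FALSE)
  cbind(s, e)
}

merge_interval_rows <- function(s, e) {
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  ms <- s[1]; me <- e[1]
  out_s <- numeric(0); out_e <- numeric(0)
  if (length(s) > 1L) {
    for (i in 2:length(s)) {
      if (s[i] > me) {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- s[i]; me <- e[i]
      } else me <- max(me, e[i])
    }
  }
  cbind(c(out_s, ms), c(out_e, me))
}

#' Fraction of a window covered by a union of intervals
#'
#' Computes the measure of the union of half-open intervals intersected with a
#' half-open window, divided by the window length.  Overlapping intervals are
#' merged before measuring, so double documentation never inflates coverage.
#' This is the primitive behind every "in place for at least 75\% of the
#' current day" style criterion.
#'
#' @param intervals A data.frame with `start`/`end` columns (POSIXct or
#'   numeric; `end = NA` means ongoing) or a two-column numeric matrix.
#' @param window Length-2 vector (POSIXct or numeric), `window[1] < window[2]`.
#' @return A fraction in `[0, 1]`.
#' @export
#' @examples
#' coverage_fraction(data.frame(start = 0, end = 18), c(0, 24)) # 0.75
coverage_fraction <- function(intervals, window) {
  w <- as.numeric(window)
  if (length(w) != 2L || is.na(w[1]) || is.na(w[2]) || w[2] <= w[1])
    stop("degenerate window", call. = FALSE)
  iv <- as_interval_matrix(intervals)
  if (nrow(iv) == 0L) return(0)
  s <- pmax(iv[, 1], w[1]); e <- pmin(iv[, 2], w[2])
  keep <- e > s
  if (!any(keep)) return(0)
  m <- merge_interval_rows(s[keep], e[keep])
  sum(m[, 2] - m[, 1]) / (w[2] - w[1])
}

# Total covered seconds of union(intervals) within window (absolute measure).
covered_seconds <- function(intervals, window) {
  w <- as.numeric(window)
  coverage_fraction(intervals, w) * (w[2] - w[1])
}
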