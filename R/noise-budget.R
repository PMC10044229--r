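#' Construct a noise-event table
#'
#' Normalizes labelled noise events to per-day intervals: events are
#' clipped to their day's 24 h span and events crossing a day boundary
#' are split. Times are seconds from the day's midnight (recorder-local
#' clock).
#'
#' @param day integer (or Date) day identifier per event
#' @param start,end event interval, s within the day `[0, 86400]`; events
#'   may extend past midnight and are then split onto the next day
#' @param source event tag, e.g. `"boat"`
#' @return data.frame with columns `day`, `start`, `end`, `source`
#' @export
noise_events <- function(day, start, end, source = "boat") {
  if (any(end <= start)) stop("negative- or zero-length event")
  if (any(start < 0)) stop("event starts before its day")
  ev <- data.frame(day = day, start = start, end = end, source = source,
                   stringsAsFactors = FALSE)
  # split events running past midnight
  over <- ev$end > 86400
  carry <- ev[over, , drop = FALSE]
  ev$end[over] <- 86400
  while (nrow(carry)) {
    nxt <- data.frame(day = carry$day + 1L, start = 0,
                      end = carry$end - 86400, source = carry$source,
                      stringsAsFactors = FALSE)
    over <- nxt$end > 86400
    carry <- nxt[over, , drop = FALSE]
    nxt$end[over] <- 86400
    ev <- rbind(ev, nxt)
  }
  ev[order(ev$day, ev$start), , drop = FALSE]
}

# union of intervals; returns merged matrix (start, end)
merge_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]
  end <- end[o]
  ms <- start[1]
  me <- end[1]
  out_s <- numeric(0)
  out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms)
      out_e <- c(out_e, me)
      ms <- start[i]
      me <- end[i]
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

union_length <- function(start, end) {
  if (length(start) == 0) return(0)
  m <- merge_intervals(start, end)
  sum(m[, 2] - m[, 1])
}

#' Mean hourly noise presence
#'
#' Per clock hour, the union of event intervals (overlaps merged) is
#' summed within each day and averaged over the recording days; each
#' entry is in `[0, 1]` hours.
#'
#' @param events data.frame from [noise_events()]
#' @param n_days number of recording days (days without events count as
#'   zero)
#' @return numeric length-24 vector, mean noise hours per clock hour
#' @export
hourly_presence <- function(events, n_days) {
  if (any(events$end < events$start)) stop("negative-length event")
  acc <- numeric(24)
  for (d in unique(events$day)) {
    ev <- events[events$day == d, , drop = FALSE]
    for (h in 0:23) {
      lo <- h * 3600
      hi <- lo + 3600
      s <- pmax(ev$start, lo)
      e <- pmin(ev$end, hi)
      keep <- e > s
      if (any(keep)) acc[h + 1] <- acc[h + 1] + union_length(s[keep], e[keep]) / 3600
    }
  }
  acc / n_days
}

#' Daily noise totals and quiet-day flags
#'
#' Merged-interval noise duration per day, flagged quiet when the total is
#' below `quiet_below` hours.
#'
#' @param events data.frame from [noise_events()]
#' @param quiet_below quiet-day threshold, h (default 12)
#' @return data.frame: `day`, `total_hours`, `quiet`
#' @export
daily_totals <- function(events, quiet_below = 12) {
  if (any(events$end < events$start)) stop("negative-length event")
  days <- sort(unique(events$day))
  tot <- vapply(days, function(d) {
    ev <- events[events$day == d, , drop = FALSE]
    union_length(ev$start, pmin(ev$end, 86400)) / 3600
  }, 0)
  data.frame(day = days, total_hours = tot, quiet = tot < quiet_below)
}

#' Cumulated call counts per clock hour
#'
#' @param call_times data.frame with columns `day` and `time` (s within
#'   the day) — one row per detected call
#' @param n_days unused for counts (kept for interface symmetry); counts
#'   are cumulated, not averaged
#' @return integer length-24 vector of call counts per clock hour summed
#'   across days
#' @export
calls_per_hour <- function(call_times, n_days = NULL) {
  out <- integer(24)
  if (nrow(call_times) == 0) return(out)
  h <- pmin(23L, floor(call_times$time / 3600))
  tab <- table(factor(h, levels = 0:23))
  as.integer(tab)
}
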