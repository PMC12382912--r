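#' Respiration-chamber gas trace
#'
#' A gas trace is the 5-minute record of O2, CO2 and CH4 exchange for one
#' pig, each interval flagged as fed or fasted.  The constructor validates
#' ordering and units; [summarize_trace()] converts a trace into daily total
#' and fasting heat production.
#'
#' @param time interval timestamps (numeric minutes or POSIXct), strictly
#'   increasing.
#' @param o2,co2,ch4 gas volumes exchanged during each interval, L.
#' @param state `"fed"` or `"fasted"` per interval.
#' @param pig_id optional identifier attached to every row.
#' @param interval interval length, minutes.
#' @return A data frame of class `gas_trace`.
#' @export
gas_trace <- function(time, o2, co2, ch4 = 0, state = "fed", pig_id = NA,
                      interval = 5) {
  n <- length(time)
  stopifnot(n > 0, interval > 0)
  ch4 <- rep_len(ch4, n)
  state <- rep_len(as.character(state), n)
  if (length(o2) != n || length(co2) != n) {
    stop("o2 and co2 must match time in length", call. = FALSE)
  }
  if (is.unsorted(as.numeric(time), strictly = TRUE)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (any(o2 < 0) || any(co2 < 0) || any(ch4 < 0)) {
    stop("gas volumes must be non-negative", call. = FALSE)
  }
  if (!all(state %in% c("fed", "fasted"))) {
    stop('state must be "fed" or "fasted"', call. = FALSE)
  }
  out <- data.frame(pig_id = pig_id, time = time, o2 = o2, co2 = co2,
                    ch4 = ch4, state = state, stringsAsFactors = FALSE)
  attr(out, "interval") <- interval
  class(out) <- c("gas_trace", "data.frame")
  out
}

#' Daily heat production from a gas trace
#'
#' Applies the Brouwer equation to each interval and scales the mean
#' interval heat production to a daily rate, separately over the fed
#' intervals (total heat production, THP) and the fasted intervals (fasting
#' heat production, FHP).  The urinary-nitrogen term is apportioned
#' uniformly over the day: both windows are corrected with the full daily
#' urinary N at their daily rate.
#'
#' @param trace a [gas_trace()] (or data frame with the same columns).
#' @param urinary_n daily urinary nitrogen of the pig, g/d.
#' @param coef a [brouwer_coefficients()] set.
#' @return A list with `thp` (kJ/d), `fhp` (kJ/d, `NA` if the trace has no
#'   fasted interval), `fhp_absent` flag, and the number of intervals used
#'   in each window.
#' @export
summarize_trace <- function(trace, urinary_n = 0,
                            coef = brouwer_coefficients()) {
  stopifnot(all(c("o2", "co2", "state") %in% names(trace)))
  interval <- attr(trace, "interval")
  if (is.null(interval)) interval <- 5
  ch4 <- if (is.null(trace$ch4)) 0 else trace$ch4
  hp_gas <- coef$o2 * trace$o2 + coef$co2 * trace$co2 + coef$ch4 * ch4
  per_day <- 1440 / interval

  window_rate <- function(sel) {
    if (!any(sel)) return(NA_real_)
    mean(hp_gas[sel]) * per_day + coef$urinary_n * urinary_n
  }
  fed <- trace$state == "fed"
  fasted <- trace$state == "fasted"
  if (!any(fed)) stop("trace contains no fed intervals", call. = FALSE)
  list(thp = window_rate(fed),
       fhp = window_rate(fasted),
       fhp_absent = !any(fasted),
       n_fed = sum(fed),
       n_fasted = sum(fasted))
}
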