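#' Summarize visitation-bout durations
#'
#' @param durations_s numeric vector of bout durations in seconds
#'   (time between a pollinator entering and escaping the flower).
#' @return list with `mean`, `sd` (sample SD, N-1 denominator; `NA` for
#'   a single bout), `min`, `max`, `n`.
#' @export
duration_summary <- function(durations_s) {
  n <- length(durations_s)
  if (n == 0L) stop("no visitation bouts")
  if (any(durations_s <= 0)) stop("durations must be positive")
  list(mean = mean(durations_s),
       sd = if (n >= 2L) stats::sd(durations_s) else NA_real_,
       min = min(durations_s), max = max(durations_s), n = n)
}

#' Peak visitation window
#'
#' Pools an observation-dates x hourly-windows visit-count matrix over
#' dates and returns the window with the most visits. Ties go to the
#' earliest window and are flagged.
#'
#' @param hourly matrix of non-negative counts; columns named by hourly
#'   window (e.g. `"1400-1500"`), rows by date.
#' @return list with `window`, `count` (pooled), `pooled` (all column
#'   sums), `tie` flag.
#' @export
peak_window <- function(hourly) {
  hourly <- as.matrix(hourly)
  if (ncol(hourly) == 0L) stop("at least one window is required")
  if (any(hourly < 0)) stop("visit counts must be non-negative")
  pooled <- colSums(hourly)
  i <- which.max(pooled)  # earliest on ties
  list(window = if (!is.null(colnames(hourly))) colnames(hourly)[i] else i,
       count = unname(pooled[i]),
       pooled = pooled,
       tie = sum(pooled == pooled[i]) > 1L)
}

#' Flowering duration in days
#'
#' Difference convention: `end_day - start_day` (a flower opening on day
#' 147 and closing on day 157 flowered for 10 days).
#'
#' @param start_day,end_day Julian days of year, `end_day >= start_day`.
#' @return number of days.
#' @export
flowering_duration <- function(start_day, end_day) {
  if (end_day < start_day) stop("end_day must not precede start_day")
  end_day - start_day
}
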