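#' Whole-day visit rate for one sex
#'
#' Number of visits divided by the duration of the total recording period
#' (the nest's full on-schedule for that day).
#'
#' @param nd a [nest_day()] object.
#' @param sex "F" or "M".
#' @return visits per hour (numeric scalar).
#' @export
daily_rate <- function(nd, sex) {
  dur <- on_duration_h(nd)
  if (dur <= 0) stop("zero recording duration")
  sum(nd$visits$sex == sex) / dur
}

#' Visit rate within one observation window
#'
#' The window \code{[start, start + duration)} stands in for a human
#' behavioral watch. It is \emph{covered} only when it lies entirely within
#' the nest-day's on-intervals; uncovered windows yield no rate (the nest is
#' dropped from that window's dataset rather than pro-rated).
#'
#' @param nd a [nest_day()] object.
#' @param sex "F" or "M".
#' @param start_s window start, seconds after midnight.
#' @param duration_h window duration in hours (> 0).
#' @return list with \code{rate} (visits/h, NA when uncovered) and
#'   \code{covered} (logical).
#' @export
window_rate <- function(nd, sex, start_s, duration_h) {
  stopifnot(duration_h > 0)
  end_s <- start_s + duration_h * 3600
  covered <- any(nd$schedule$on_start_s <= start_s &
                 end_s <= nd$schedule$on_end_s)
  if (!covered) return(list(rate = NA_real_, covered = FALSE))
  tt <- nd$visits$time_s[nd$visits$sex == sex]
  list(rate = sum(tt >= start_s & tt < end_s) / duration_h, covered = TRUE)
}

#' Enumerate observation windows over start and duration grids
#'
#' Cartesian product of start times and durations, dropping windows that end
#' after the configured end of day (the night shut-off, default 22:00).
#'
#' @param starts_s numeric vector of start times, seconds after midnight.
#' @param durations_h numeric vector of durations in hours.
#' @param day_end_s latest admissible window end, seconds after midnight.
#' @return data.frame with columns start_s, duration_h.
#' @export
enumerate_windows <- function(starts_s, durations_h, day_end_s = 22 * 3600) {
  stopifnot(length(starts_s) > 0, length(durations_h) > 0)
  g <- expand.grid(start_s = starts_s, duration_h = durations_h,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[g$start_s + g$duration_h * 3600 <= day_end_s, , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Assemble the regression dataset for one (sex, window) cell
#'
#' Pairs each covered nest's window rate (predictor) with its whole-day rate
#' (response). Nests whose schedule does not fully cover the window are
#' dropped, which is why sample size varies with start time when deployment
#' times are staggered.
#'
#' @param series list of [nest_day()] objects.
#' @param sex "F" or "M".
#' @param start_s,duration_h the window (see [window_rate()]).
#' @return object of class \code{rate_dataset}: list with sex, start_s,
#'   duration_h, nest_id, x (window rates), y (daily rates), n, and
#'   \code{usable} (FALSE when fewer than 3 nests cover the window).
#' @export
assemble_rate_dataset <- function(series, sex, start_s, duration_h) {
  wr <- lapply(series, window_rate, sex = sex, start_s = start_s,
               duration_h = duration_h)
  cov <- vapply(wr, `[[`, logical(1), "covered")
  x <- vapply(wr[cov], `[[`, numeric(1), "rate")
  y <- vapply(series[cov], daily_rate, numeric(1), sex = sex)
  ids <- vapply(series[cov], `[[`, character(1), "nest_id")
  structure(list(sex = sex, start_s = start_s, duration_h = duration_h,
                 nest_id = ids, x = unname(x), y = unname(y),
                 n = sum(cov), usable = sum(cov) >= 3L),
            class = "rate_dataset")
}

#' Windowed-rate export
#'
#' One row per nest x sex x window with the rate and coverage flag, in the
#' CSV schema \code{nest_id,sex,start,duration_h,rate,covered}.
#'
#' @param series list of [nest_day()] objects.
#' @param windows data.frame from [enumerate_windows()].
#' @param sexes sexes to include.
#' @param path optional CSV output path.
#' @return the table, invisibly when written to \code{path}.
#' @export
windowed_rate_table <- function(series, windows, sexes = c("F", "M"),
                                path = NULL) {
  rows <- do.call(rbind, lapply(seq_len(nrow(windows)), function(i) {
    do.call(rbind, lapply(sexes, function(sx) {
      do.call(rbind, lapply(series, function(nd) {
        r <- window_rate(nd, sx, windows$start_s[i], windows$duration_h[i])
        data.frame(nest_id = nd$nest_id, sex = sx,
                   start = sec_to_hms(windows$start_s[i]),
                   duration_h = windows$duration_h[i],
                   rate = r$rate, covered = r$covered)
      }))
    }))
  }))
  if (!is.null(path)) {
    utils::write.csv(rows, path, row.names = FALSE, na = "")
    return(invisible(rows))
  }
  rows
}
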