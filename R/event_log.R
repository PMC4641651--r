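#' Read an RFID detection log
#'
#' Reads a CSV detection log with columns \code{tag_id,timestamp}, where
#' \code{timestamp} is a naive local ISO 8601 time to one-second resolution
#' (\code{YYYY-MM-DDTHH:MM:SS}). Rows are returned sorted by timestamp.
#'
#' @param path path to the log file.
#' @param lenient if \code{FALSE} (default), any malformed row aborts with an
#'   error listing the offending file line numbers; if \code{TRUE}, malformed
#'   rows are dropped with a warning and attached as the \code{"bad_rows"}
#'   attribute of the result.
#' @return a data.frame with columns \code{tag_id} (character) and
#'   \code{timestamp} (POSIXct), sorted by timestamp.
#' @export
read_detections <- function(path, lenient = FALSE) {
  if (!file.exists(path)) stop("detection log not found: ", path)
  empty <- data.frame(tag_id = character(), timestamp = parse_iso_local(character()))
  if (length(readLines(path, n = 2L, warn = FALSE)) < 2L) return(empty)
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  if (!all(c("tag_id", "timestamp") %in% names(raw)))
    stop("detection log must have header tag_id,timestamp")
  ts <- parse_iso_local(raw$timestamp)
  bad <- is.na(ts) | !nzchar(raw$tag_id)
  if (any(bad)) {
    lines <- which(bad) + 1L  # +1 for the header line
    if (!lenient)
      stop("malformed detection rows at file line(s): ",
           paste(lines, collapse = ", "))
    warning(sum(bad), " malformed detection row(s) dropped (lenient mode)")
  }
  out <- data.frame(tag_id = raw$tag_id[!bad], timestamp = ts[!bad],
                    stringsAsFactors = FALSE)
  out <- out[order(out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  if (any(bad))
    attr(out, "bad_rows") <- data.frame(line = which(bad) + 1L,
                                        tag_id = raw$tag_id[bad],
                                        timestamp = raw$timestamp[bad])
  out
}

#' Read a tag registry
#'
#' CSV with columns \code{tag_id,nest_id,sex}, sex coded \code{F}/\code{M}.
#' Tag ids must be unique and each (nest, sex) may carry at most one tag.
#'
#' @param path path to the registry CSV.
#' @return data.frame with columns tag_id, nest_id, sex.
#' @export
read_registry <- function(path) {
  reg <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  if (!all(c("tag_id", "nest_id", "sex") %in% names(reg)))
    stop("registry must have header tag_id,nest_id,sex")
  if (!all(reg$sex %in% c("F", "M"))) stop("registry sex must be F or M")
  if (anyDuplicated(reg$tag_id)) stop("duplicate tag_id in registry")
  if (anyDuplicated(reg[c("nest_id", "sex")]))
    stop("more than one tag for the same (nest_id, sex)")
  reg[c("tag_id", "nest_id", "sex")]
}

#' Read a recording schedule
#'
#' CSV with columns \code{nest_id,date,on_start,on_end}; one row per
#' on-interval, times \code{HH:MM:SS} local, intervals half-open
#' \code{[on_start, on_end)}. Intervals are sorted and must be disjoint and
#' non-empty within a nest-date.
#'
#' @param path path to the schedule CSV.
#' @return data.frame with nest_id, date, on_start_s, on_end_s (seconds after
#'   midnight), sorted by nest, date, start.
#' @export
read_schedule <- function(path) {
  sc <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  if (!all(c("nest_id", "date", "on_start", "on_end") %in% names(sc)))
    stop("schedule must have header nest_id,date,on_start,on_end")
  out <- data.frame(nest_id = sc$nest_id, date = sc$date,
                    on_start_s = hms_to_sec(sc$on_start),
                    on_end_s = hms_to_sec(sc$on_end),
                    stringsAsFactors = FALSE)
  if (any(out$on_end_s <= out$on_start_s)) stop("empty or inverted on-interval")
  out <- out[order(out$nest_id, out$date, out$on_start_s), , drop = FALSE]
  by <- split(out, paste(out$nest_id, out$date))
  for (g in by) {
    if (nrow(g) > 1L && any(g$on_start_s[-1L] < g$on_end_s[-nrow(g)]))
      stop("overlapping on-intervals for nest ", g$nest_id[1L])
  }
  rownames(out) <- NULL
  out
}

#' Collapse continuous detections into visit events
#'
#' A perching bird adjacent to the antenna produces a read every reader duty
#' cycle (0.5 s); such runs must be merged into single visits. Detections of
#' one tag are partitioned into maximal runs in which every consecutive pair
#' is at most \code{gap_threshold} seconds apart; each run becomes one visit
#' whose start is the run's first detection and whose \code{n_reads} is the
#' run length. A return after a gap longer than the threshold is a new visit.
#'
#' @param times sorted detection times of a single tag: numeric seconds or
#'   POSIXct.
#' @param gap_threshold merge threshold in seconds (> 0). Default 2 s = four
#'   0.3 s + 0.2 s duty cycles, tolerating up to three missed reads within a
#'   perching bout.
#' @return data.frame with columns \code{start} (same type as input) and
#'   \code{n_reads}.
#' @export
collapse_to_visits <- function(times, gap_threshold = 2) {
  stopifnot(gap_threshold > 0)
  t <- as.numeric(times)
  if (is.unsorted(t)) stop("detections must be sorted in time")
  if (length(t) == 0L)
    return(data.frame(start = times, n_reads = integer()))
  new_run <- c(TRUE, diff(t) > gap_threshold)
  run_id <- cumsum(new_run)
  data.frame(start = times[new_run],
             n_reads = as.integer(tabulate(run_id)),
             stringsAsFactors = FALSE)
}

#' Construct a nest-day series
#'
#' Container for one nest-day: the recording schedule, per-sex visit events
#' and per-sex raw read counts.
#'
#' @param nest_id nest identifier.
#' @param date date string "YYYY-MM-DD".
#' @param schedule data.frame with on_start_s, on_end_s (seconds after
#'   midnight), disjoint sorted half-open intervals.
#' @param visits data.frame with sex, time_s (visit start, seconds after
#'   midnight), n_reads.
#' @param raw_reads named numeric, raw detection counts, names "F","M".
#' @return object of class \code{nest_day}.
#' @export
nest_day <- function(nest_id, date, schedule, visits,
                     raw_reads = c(F = 0, M = 0)) {
  stopifnot(is.data.frame(schedule),
            all(c("on_start_s", "on_end_s") %in% names(schedule)),
            nrow(schedule) >= 1L,
            all(schedule$on_end_s > schedule$on_start_s))
  if (is.unsorted(schedule$on_start_s)) stop("schedule must be sorted")
  stopifnot(is.data.frame(visits),
            all(c("sex", "time_s", "n_reads") %in% names(visits)))
  if (nrow(visits)) {
    inside <- vapply(visits$time_s, function(s)
      any(schedule$on_start_s <= s & s < schedule$on_end_s), logical(1))
    if (!all(inside)) stop("visit start outside the recording schedule")
  }
  structure(list(nest_id = nest_id, date = date,
                 schedule = schedule[c("on_start_s", "on_end_s")],
                 visits = visits[order(visits$sex, visits$time_s), ,
                                 drop = FALSE],
                 raw_reads = c(F = unname(raw_reads["F"]) %||% 0,
                               M = unname(raw_reads["M"]) %||% 0)),
            class = "nest_day")
}

#' @export
print.nest_day <- function(x, ...) {
  cat("<nest_day>", x$nest_id, x$date, "\n")
  cat("  on:", paste(sprintf("%s-%s", sec_to_hms(x$schedule$on_start_s),
                             sec_to_hms(x$schedule$on_end_s)),
                     collapse = ", "), "\n")
  cat("  visits: F =", sum(x$visits$sex == "F"),
      " M =", sum(x$visits$sex == "M"),
      " raw reads:", sum(x$raw_reads), "\n")
  invisible(x)
}

on_duration_h <- function(nd) sum(nd$schedule$on_end_s - nd$schedule$on_start_s) / 3600

# accept either the parsed schedule (on_start_s/on_end_s) or the raw CSV
# dialect (on_start/on_end as "HH:MM:SS")
as_schedule <- function(schedule) {
  if (all(c("on_start_s", "on_end_s") %in% names(schedule))) return(schedule)
  stopifnot(all(c("nest_id", "date", "on_start", "on_end") %in% names(schedule)))
  out <- data.frame(nest_id = schedule$nest_id, date = schedule$date,
                    on_start_s = hms_to_sec(schedule$on_start),
                    on_end_s = hms_to_sec(schedule$on_end),
                    stringsAsFactors = FALSE)
  out[order(out$nest_id, out$date, out$on_start_s), , drop = FALSE]
}

#' Build nest-day series from detections, registry and schedule
#'
#' Assigns detections to nests and sexes via the registry, restricts them to
#' the scheduled on-intervals of each nest-date, collapses them into visits,
#' and records per-sex raw read counts (all reads of that tag on that date,
#' before schedule restriction — the basis of the low-read exclusion filter).
#'
#' @param detections data.frame from [read_detections()].
#' @param registry data.frame from [read_registry()].
#' @param schedule data.frame from [read_schedule()].
#' @param gap_threshold seconds, see [collapse_to_visits()].
#' @return list of [nest_day()] objects, one per scheduled nest-date.
#' @export
build_nest_days <- function(detections, registry, schedule, gap_threshold = 2) {
  schedule <- as_schedule(schedule)
  det <- merge(detections, registry, by = "tag_id")
  det$date <- format(det$timestamp, "%Y-%m-%d", tz = "UTC")
  det$tod <- time_of_day_sec(det$timestamp)
  keys <- unique(schedule[c("nest_id", "date")])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    nid <- keys$nest_id[i]; d <- keys$date[i]
    sch <- schedule[schedule$nest_id == nid & schedule$date == d, , drop = FALSE]
    sub <- det[det$nest_id == nid & det$date == d, , drop = FALSE]
    raw <- c(F = sum(sub$sex == "F"), M = sum(sub$sex == "M"))
    vis <- data.frame(sex = character(), time_s = numeric(),
                      n_reads = integer())
    for (sx in c("F", "M")) {
      tt <- sort(sub$tod[sub$sex == sx])
      inside <- vapply(tt, function(s)
        any(sch$on_start_s <= s & s < sch$on_end_s), logical(1))
      v <- collapse_to_visits(tt[inside], gap_threshold)
      if (nrow(v))
        vis <- rbind(vis, data.frame(sex = sx, time_s = v$start,
                                     n_reads = v$n_reads))
    }
    out[[i]] <- nest_day(nid, d, sch, vis, raw)
  }
  out
}

#' Exclude nest-days with too few raw reads
#'
#' A nest-day whose combined male + female raw read count falls strictly below
#' \code{min_reads} indicates a malfunctioning tag or antenna (or an unusually
#' low provisioning rate) and is excluded from analysis.
#'
#' @param series list of [nest_day()] objects.
#' @param min_reads exclusion threshold; the default 200 excludes nest-days
#'   with "fewer than 200" combined reads (strict \code{<}).
#' @return list with elements \code{kept} and \code{excluded}, an exhaustive
#'   disjoint partition of the input.
#' @export
filter_low_read_nests <- function(series, min_reads = 200) {
  total <- vapply(series, function(nd) sum(nd$raw_reads), numeric(1))
  list(kept = series[total >= min_reads],
       excluded = series[total < min_reads])
}

#' Bin a nest-day's visits into fixed clock-time intervals
#'
#' Produces a long-format count table over all bins of the day. Bins not fully
#' covered by the recording schedule are flagged missing (NA), never zero, so
#' downstream rates are not diluted by off periods.
#'
#' @param series a [nest_day()] object or a list of them.
#' @param bin_minutes bin width in minutes; must divide 60. Default 15.
#' @return data.frame with columns nest_id, sex, interval_start ("HH:MM:SS"),
#'   visit_count (integer, NA when the bin is not fully covered).
#' @export
to_interval_counts <- function(series, bin_minutes = 15) {
  if (inherits(series, "nest_day")) series <- list(series)
  stopifnot(60 %% bin_minutes == 0)
  w <- bin_minutes * 60
  starts <- seq(0, 86400 - w, by = w)
  do.call(rbind, lapply(series, function(nd) {
    covered <- vapply(starts, function(b)
      any(nd$schedule$on_start_s <= b & b + w <= nd$schedule$on_end_s),
      logical(1))
    do.call(rbind, lapply(c("F", "M"), function(sx) {
      tt <- nd$visits$time_s[nd$visits$sex == sx]
      cnt <- vapply(starts, function(b)
        sum(tt >= b & tt < b + w), integer(1))
      cnt[!covered] <- NA_integer_
      data.frame(nest_id = nd$nest_id, sex = sx,
                 interval_start = sec_to_hms(starts), visit_count = cnt,
                 stringsAsFactors = FALSE)
    }))
  }))
}

#' Write / read a binned count table
#'
#' The CSV schema \code{nest_id,sex,interval_start,visit_count} (empty
#' visit_count = missing bin) is the plain-text equivalent of the 15-minute
#' per-nest per-sex feeding-rate tables distributed with provisioning studies
#' as R data files; such a file is converted with one line, e.g.
#' \code{load("counts.RData"); write.csv(x, "counts.csv", row.names = FALSE, na = "")}.
#'
#' @param counts data.frame as produced by [to_interval_counts()].
#' @param path output / input CSV path.
#' @return \code{read_interval_counts} returns the counts data.frame.
#' @export
write_interval_counts <- function(counts, path) {
  utils::write.csv(counts, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_interval_counts
#' @export
read_interval_counts <- function(path) {
  x <- utils::read.csv(path, colClasses = c("character", "character",
                                            "character", "integer"),
                       strip.white = TRUE)
  if (!all(c("nest_id", "sex", "interval_start", "visit_count") %in% names(x)))
    stop("count table must have header nest_id,sex,interval_start,visit_count")
  x
}

#' Reconstruct nest-day series from a binned count table
#'
#' The inverse of [to_interval_counts()] up to within-bin timing: each bin's
#' visits are placed at the bin start, and the schedule is taken as the union
#' of non-missing bins. Windowed rates computed on the result equal those from
#' the raw visits for any window aligned to bin boundaries. Raw read counts
#' are unknown in this representation and are set to the visit totals, so the
#' low-read filter should be applied before export, not after import.
#'
#' @param counts data.frame from [read_interval_counts()].
#' @param bin_minutes bin width used to create the table.
#' @param date nominal date assigned to the reconstructed nest-days.
#' @return list of [nest_day()] objects.
#' @export
counts_to_series <- function(counts, bin_minutes = 15, date = "2014-06-01") {
  w <- bin_minutes * 60
  lapply(split(counts, counts$nest_id), function(g) {
    s <- hms_to_sec(g$interval_start)
    cov_bins <- sort(unique(s[!is.na(g$visit_count)]))
    if (!length(cov_bins)) stop("nest ", g$nest_id[1L], " has no covered bins")
    brk <- c(0, which(diff(cov_bins) > w), length(cov_bins))
    sch <- data.frame(
      on_start_s = cov_bins[brk[-length(brk)] + 1L],
      on_end_s   = cov_bins[brk[-1L]] + w)
    ok <- !is.na(g$visit_count) & g$visit_count > 0
    vis <- data.frame(
      sex = rep(g$sex[ok], g$visit_count[ok]),
      time_s = rep(s[ok], g$visit_count[ok]),
      n_reads = 1L)
    nest_day(g$nest_id[1L], date, sch, vis,
             c(F = sum(g$visit_count[g$sex == "F"], na.rm = TRUE),
               M = sum(g$visit_count[g$sex == "M"], na.rm = TRUE)))
  })
}
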