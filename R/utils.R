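#' Convert "HH:MM[:SS]" clock time to seconds after midnight
#'
#' @param x character vector of clock times, e.g. "07:00" or "07:00:30".
#' @return numeric vector of seconds after midnight.
#' @export
hms_to_sec <- function(x) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- suppressWarnings(as.numeric(p))
    if (length(p) < 2L || length(p) > 3L || anyNA(p))
      stop("unparseable clock time", call. = FALSE)
    if (length(p) == 2L) p <- c(p, 0)
    p[1L] * 3600 + p[2L] * 60 + p[3L]
  }, numeric(1))
}

#' Convert seconds after midnight to "HH:MM:SS"
#'
#' @param s numeric vector of seconds after midnight.
#' @return character vector.
#' @export
sec_to_hms <- function(s) {
  s <- round(s)
  sprintf("%02d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, s %% 60)
}

# parse strict ISO 8601 local timestamps "YYYY-MM-DDTHH:MM:SS"; returns POSIXct
# (UTC used as a stand-in for naive local time -- no DST arithmetic) with NA
# for malformed entries
parse_iso_local <- function(x) {
  out <- as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  # strptime tolerates trailing junk; enforce the full fixed-width form
  out[!grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}$", x)] <- NA
  out
}

format_iso_local <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

# seconds after local midnight for a POSIXct vector
time_of_day_sec <- function(t) {
  as.numeric(t) - as.numeric(as.POSIXct(format(t, "%Y-%m-%d", tz = "UTC"),
                                        tz = "UTC"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
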