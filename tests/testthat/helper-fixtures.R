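# in-code fixtures: no data files are shipped, everything is built here

# one nest-day with given per-sex visit times (seconds after midnight)
make_nd <- function(f_times = numeric(), m_times = numeric(),
                    on = c(4, 22) * 3600, nest = "N1", date = "2014-06-05",
                    raw = c(F = 500, M = 500)) {
  vis <- rbind(
    if (length(f_times)) data.frame(sex = "F", time_s = f_times, n_reads = 1L),
    if (length(m_times)) data.frame(sex = "M", time_s = m_times, n_reads = 1L))
  if (is.null(vis)) vis <- data.frame(sex = character(), time_s = numeric(),
                                      n_reads = integer())
  nest_day(nest, date, data.frame(on_start_s = on[1], on_end_s = on[2]),
           vis, raw)
}

# write a detection-log CSV from (tag, iso-timestamp) rows
write_det_csv <- function(rows) {
  p <- withr::local_tempfile(fileext = ".csv",
                             .local_envir = parent.frame())
  writeLines(c("tag_id,timestamp", rows), p)
  p
}

# hand-built curve_fit objects, for exercising the optimizers without a fit
fake_fit <- function(family, coef, x = seq(0.25, 4, 0.25)) {
  cf <- c(b = NA_real_, c = NA_real_, d = NA_real_, e = NA_real_)
  cf[names(coef)] <- coef
  structure(list(family = family, coef = cf, edf = 3, rss = 0,
                 n = length(x), x = x, y = NULL, gam_model = NULL),
            class = "curve_fit")
}

mm3_fun <- function(x, c, d, e) c + (d - c) * x / (x + e)
ar3_fun <- function(x, c, d, e) c + (d - c) * (1 - exp(-x / e))
gom_fun <- function(x, b, d, e) d * exp(-exp(b * (x - e)))
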