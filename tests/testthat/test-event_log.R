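test_that("read_detections parses, sorts, and handles malformed rows", {
  # empty (header-only) file
  expect_identical(nrow(read_detections(write_det_csv(character()))), 0L)

  # out-of-order rows come back sorted
  p <- write_det_csv(c("A,2014-06-05T08:00:02",
                       "B,2014-06-05T07:59:59",
                       "A,2014-06-05T08:00:00"))
  d <- read_detections(p)
  expect_equal(d$tag_id, c("B", "A", "A"))
  expect_false(is.unsorted(as.numeric(d$timestamp)))

  # one bad timestamp: strict mode fails naming the line, lenient keeps 2
  p <- write_det_csv(c("A,2014-06-05T08:00:00",
                       "A,2014-06-05Tnot-a-time",
                       "A,2014-06-05T08:00:05"))
  expect_error(read_detections(p), "line\\(s\\): 3")
  expect_warning(d <- read_detections(p, lenient = TRUE), "1 malformed")
  expect_identical(nrow(d), 2L)
  expect_equal(attr(d, "bad_rows")$line, 3L)
})

test_that("registry and schedule readers validate their invariants", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("tag_id,nest_id,sex", "T1,N1,F", "T2,N1,M", "T3,N2,F"), p)
  expect_identical(nrow(read_registry(p)), 3L)
  writeLines(c("tag_id,nest_id,sex", "T1,N1,F", "T1,N2,M"), p)
  expect_error(read_registry(p), "duplicate tag_id")
  writeLines(c("tag_id,nest_id,sex", "T1,N1,F", "T2,N1,F"), p)
  expect_error(read_registry(p), "more than one tag")

  writeLines(c("nest_id,date,on_start,on_end",
               "N1,2014-06-05,04:00:00,22:00:00"), p)
  sc <- read_schedule(p)
  expect_equal(sc$on_start_s, 4 * 3600)
  writeLines(c("nest_id,date,on_start,on_end",
               "N1,2014-06-05,08:00:00,07:00:00"), p)
  expect_error(read_schedule(p), "inverted")
  writeLines(c("nest_id,date,on_start,on_end",
               "N1,2014-06-05,04:00:00,12:00:00",
               "N1,2014-06-05,11:00:00,22:00:00"), p)
  expect_error(read_schedule(p), "overlapping")
})

test_that("collapse_to_visits merges runs of reads into visits", {
  # identity case
  e <- collapse_to_visits(numeric(), 2)
  expect_identical(nrow(e), 0L)

  # all gaps below the threshold: one visit of three reads
  v <- collapse_to_visits(c(0, 0.5, 1.0), 2)
  expect_equal(v$start, 0)
  expect_equal(v$n_reads, 3L)

  # independent single-pass merge oracle (two-line loop)
  oracle <- function(t, gap) {
    s <- integer(0); n <- integer(0)
    for (i in seq_along(t)) {
      if (i == 1L || t[i] - t[i - 1L] > gap) { s <- c(s, i); n <- c(n, 1L) }
      else n[length(n)] <- n[length(n)] + 1L
    }
    data.frame(start = t[s], n_reads = n)
  }
  t5 <- c(0, 0.5, 10, 10.5, 300)
  v <- collapse_to_visits(t5, 2)
  expect_equal(v$start, c(0, 10, 300))
  expect_equal(v, oracle(t5, 2))

  expect_error(collapse_to_visits(c(3, 1, 2), 2), "sorted")
})

test_that("collapse_to_visits invariants: idempotence, monotonicity, conservation", {
  set.seed(41)
  for (i in 1:25) {
    t <- sort(cumsum(rexp(sample(0:40, 1), rate = 0.5)))
    v2 <- collapse_to_visits(t, 2)
    # conservation
    expect_identical(sum(v2$n_reads), length(t))
    # monotonicity: larger threshold never yields more visits
    v5 <- collapse_to_visits(t, 5)
    expect_lte(nrow(v5), nrow(v2))
    # idempotence on already-collapsed events with all gaps > threshold
    if (nrow(v5) > 0) {
      again <- collapse_to_visits(v5$start, 5 - 1e-9)
      expect_equal(again$start, v5$start)
      expect_true(all(again$n_reads == 1L))
    }
  }
})

test_that("filter_low_read_nests applies the strict <200 combined-read rule", {
  low <- make_nd(3600 * 8, raw = c(F = 100, M = 99))   # 199 combined
  edge <- make_nd(3600 * 8, raw = c(F = 100, M = 100)) # exactly 200: kept
  part <- filter_low_read_nests(list(low, edge))
  expect_length(part$kept, 1L)
  expect_length(part$excluded, 1L)
  expect_identical(part$kept[[1]]$raw_reads[["F"]], 100)
  # empty input, and exhaustive/disjoint partition
  expect_identical(filter_low_read_nests(list()), list(kept = list(),
                                                       excluded = list()))
})

test_that("to_interval_counts bins visits and flags uncovered bins missing", {
  nd <- make_nd(f_times = hms_to_sec("07:03:00"), on = c(4, 22) * 3600)
  ct <- to_interval_counts(nd)
  expect_equal(ct$visit_count[ct$sex == "F" & ct$interval_start == "07:00:00"], 1L)
  expect_equal(sum(ct$visit_count[ct$sex == "F"], na.rm = TRUE), 1L)

  # schedule starting 07:30: the 07:00 and 07:15 bins are partially covered
  # hence missing, the 07:30 bin is a true zero
  nd <- make_nd(f_times = hms_to_sec("08:10:00"),
                on = c(hms_to_sec("07:30:00"), 22 * 3600))
  ct <- to_interval_counts(nd)
  f <- ct[ct$sex == "F", ]
  expect_true(is.na(f$visit_count[f$interval_start == "07:00:00"]))
  expect_true(is.na(f$visit_count[f$interval_start == "07:15:00"]))
  expect_identical(f$visit_count[f$interval_start == "07:30:00"], 0L)
  expect_true(is.na(f$visit_count[f$interval_start == "03:00:00"]))
})

test_that("count-table round trip preserves bin-aligned windowed rates", {
  set.seed(7)
  nd <- make_nd(f_times = sort(runif(60, 4 * 3600, 22 * 3600)),
                m_times = sort(runif(45, 4 * 3600, 22 * 3600)))
  ct <- to_interval_counts(nd)
  p <- withr::local_tempfile(fileext = ".csv")
  write_interval_counts(ct, p)
  back <- counts_to_series(read_interval_counts(p))[[1]]
  for (w in list(c(8, 2), c(13, 1), c(16.25, 0.25), c(4, 18))) {
    for (sx in c("F", "M")) {
      a <- window_rate(nd, sx, w[1] * 3600, w[2])
      b <- window_rate(back, sx, w[1] * 3600, w[2])
      expect_identical(b$covered, a$covered)
      expect_equal(b$rate, a$rate)
    }
  }
  # daily rate survives the round trip too (schedule is bin-aligned)
  expect_equal(daily_rate(back, "F"), daily_rate(nd, "F"))
})

test_that("build_nest_days assigns reads to nests and respects the schedule", {
  det <- read_detections(write_det_csv(c(
    "T1,2014-06-05T08:00:00", "T1,2014-06-05T08:00:01",  # one F visit, 2 reads
    "T1,2014-06-05T09:30:00",                            # second F visit
    "T2,2014-06-05T03:30:00",                            # before schedule: no visit
    "T2,2014-06-05T10:00:00")))
  reg <- data.frame(tag_id = c("T1", "T2"), nest_id = "N1", sex = c("F", "M"))
  sch <- data.frame(nest_id = "N1", date = "2014-06-05",
                    on_start = "04:00:00", on_end = "22:00:00")
  nds <- build_nest_days(det, reg, sch)
  expect_length(nds, 1L)
  nd <- nds[[1]]
  expect_equal(sum(nd$visits$sex == "F"), 2L)
  expect_equal(sum(nd$visits$sex == "M"), 1L)      # 03:30 read excluded
  expect_equal(nd$raw_reads, c(F = 3, M = 2))      # raw counts keep all reads
  expect_equal(nd$visits$n_reads[nd$visits$sex == "F"], c(2L, 1L))
})
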