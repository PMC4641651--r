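#' Simulation configuration for a synthetic provisioning study
#'
#' The defaults emulate a one-day nest-box study at realistic scale: 64 nests;
#' readers on 04:00-22:00 (night shut-off outside) with a fraction of nests
#' recording the full day and the rest deployed during the morning
#' (07:00-10:00); per-sex provisioning rates drawn from gamma distributions
#' with female mean above male but male among-nest variation above female;
#' near-constant diel rate; perching bursts at the 0.5 s reader duty cycle;
#' and a small per-read detection failure rate. With the defaults, combined
#' daily reads per nest average on the order of 1.3k.
#'
#' @param n_nests number of nests.
#' @param date nominal study date.
#' @param day_start_s,day_end_s reader operating window (night shut-off
#'   outside), seconds after midnight.
#' @param mu_F,mu_M mean visit rates (visits/h).
#' @param cv_F,cv_M among-nest coefficients of variation (cv_F < cv_M).
#' @param diel_amplitude relative amplitude of a sinusoidal within-day rate
#'   modulation (0 = constant rate, the default).
#' @param perch_prob probability that a visit includes a perching bout.
#' @param perch_mean_s mean perching-bout length, seconds (exponential).
#' @param detect_fail per-read detection failure probability.
#' @param duty_cycle_s reader cycle length (0.3 s read + 0.2 s pause).
#' @param full_day_frac fraction of nests recording from \code{day_start_s}.
#' @param deploy_range_s start-time range (seconds) for late-deployed nests.
#' @param seed integer seed.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_nests = 64L, date = "2014-06-05",
                       day_start_s = 4 * 3600, day_end_s = 22 * 3600,
                       mu_F = 8, mu_M = 6, cv_F = 0.35, cv_M = 0.55,
                       diel_amplitude = 0, perch_prob = 0.3,
                       perch_mean_s = 10, detect_fail = 0.05,
                       duty_cycle_s = 0.5, full_day_frac = 18 / 64,
                       deploy_range_s = c(7, 10) * 3600, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(mu_F >= 0, mu_M >= 0, cv_F >= 0, cv_M >= 0,
            perch_prob >= 0, perch_prob <= 1,
            detect_fail >= 0, detect_fail <= 1,
            diel_amplitude >= 0, diel_amplitude <= 1,
            day_end_s > day_start_s)
  structure(cfg, class = "sim_config")
}

rgamma_mean_cv <- function(n, mean, cv) {
  if (mean == 0) return(rep(0, n))
  if (cv == 0) return(rep(mean, n))
  stats::rgamma(n, shape = 1 / cv^2, scale = mean * cv^2)
}

#' Simulate a full RFID provisioning study
#'
#' Generates detection logs, a tag registry, a recording schedule and the
#' ground truth behind them. Per nest and sex, a true rate is drawn from the
#' gamma distribution; visit times follow a (optionally diel-modulated)
#' Poisson process over the nest's on-period; each visit emits a read with
#' probability 1 - detect_fail, and with probability perch_prob an additional
#' burst of reads at the duty-cycle spacing for an exponentially distributed
#' bout. Timestamps are floored to whole seconds, matching reader resolution.
#'
#' @param config a [sim_config()].
#' @param dir optional directory; when given, writes detections.csv,
#'   registry.csv, schedule.csv and truth.csv there (reproducible byte for
#'   byte under a fixed seed).
#' @return list with detections, registry, schedule (data.frames in the
#'   package's CSV dialects), truth (nest_id, sex, true_rate, deploy_start_s,
#'   n_true_visits) and truth_visits (nest_id, sex, time_s: the true visit
#'   times behind the emitted detections).
#' @export
simulate_study <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_nests
  nest_id <- sprintf("N%03d", seq_len(n))
  deploy <- ifelse(stats::runif(n) < config$full_day_frac,
                   config$day_start_s,
                   stats::runif(n, config$deploy_range_s[1],
                                config$deploy_range_s[2]))
  registry <- data.frame(
    tag_id = sprintf("T%03d%s", rep(seq_len(n), each = 2), c("F", "M")),
    nest_id = rep(nest_id, each = 2),
    sex = rep(c("F", "M"), n), stringsAsFactors = FALSE)
  schedule <- data.frame(nest_id = nest_id, date = config$date,
                         on_start = sec_to_hms(deploy),
                         on_end = sec_to_hms(rep(config$day_end_s, n)),
                         stringsAsFactors = FALSE)
  rate <- list(F = rgamma_mean_cv(n, config$mu_F, config$cv_F),
               M = rgamma_mean_cv(n, config$mu_M, config$cv_M))
  day0 <- as.POSIXct(paste0(config$date, "T00:00:00"), tz = "UTC",
                     format = "%Y-%m-%dT%H:%M:%S")
  det_rows <- list(); truth_rows <- list(); visit_rows <- list()
  for (i in seq_len(n)) for (sx in c("F", "M")) {
    lam <- rate[[sx]][i]
    dur_h <- (config$day_end_s - deploy[i]) / 3600
    a <- config$diel_amplitude
    n_vis <- stats::rpois(1, lam * dur_h * (1 + a))
    tt <- sort(stats::runif(n_vis, deploy[i], config$day_end_s))
    if (a > 0 && n_vis > 0) {  # thin against the sinusoidal envelope
      keep <- stats::runif(n_vis) <
        (1 + a * sin(2 * pi * (tt / 86400 - 0.25))) / (1 + a)
      tt <- tt[keep]
    }
    reads <- numeric(0)
    for (t in tt) {
      r <- t
      if (stats::runif(1) < config$perch_prob) {
        bout <- stats::rexp(1, 1 / config$perch_mean_s)
        r <- c(r, t + seq_len(floor(bout / config$duty_cycle_s)) *
                 config$duty_cycle_s)
      }
      r <- r[stats::runif(length(r)) >= config$detect_fail]
      reads <- c(reads, r)
    }
    reads <- reads[reads < config$day_end_s]
    if (length(reads))
      det_rows[[length(det_rows) + 1L]] <- data.frame(
        tag_id = registry$tag_id[registry$nest_id == nest_id[i] &
                                 registry$sex == sx],
        timestamp = day0 + floor(reads))
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      nest_id = nest_id[i], sex = sx, true_rate = lam,
      deploy_start_s = deploy[i], n_true_visits = length(tt))
    if (length(tt))
      visit_rows[[length(visit_rows) + 1L]] <- data.frame(
        nest_id = nest_id[i], sex = sx, time_s = tt)
  }
  detections <- if (length(det_rows)) do.call(rbind, det_rows)
                else data.frame(tag_id = character(),
                                timestamp = day0[0])
  detections <- detections[order(detections$timestamp,
                                 detections$tag_id), , drop = FALSE]
  rownames(detections) <- NULL
  truth <- do.call(rbind, truth_rows)
  truth_visits <- if (length(visit_rows)) do.call(rbind, visit_rows)
                  else data.frame(nest_id = character(), sex = character(),
                                  time_s = numeric())
  out <- list(detections = detections, registry = registry,
              schedule = schedule, truth = truth,
              truth_visits = truth_visits)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    dd <- detections; dd$timestamp <- format_iso_local(dd$timestamp)
    utils::write.csv(dd, file.path(dir, "detections.csv"), row.names = FALSE)
    utils::write.csv(registry, file.path(dir, "registry.csv"),
                     row.names = FALSE)
    utils::write.csv(schedule, file.path(dir, "schedule.csv"),
                     row.names = FALSE)
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
    utils::write.csv(truth_visits, file.path(dir, "truth_visits.csv"),
                     row.names = FALSE)
  }
  out
}

#' Plug-in approximation of the expected window-rate R-squared
#'
#' For nests with true rates of mean \code{mu} and between-nest variance
#' \code{sigma2_between}, and visit counts Poisson within nests, the squared
#' correlation between a window rate over \code{duration_h} hours and the true
#' rate is approximately
#' \deqn{R^2 \approx \sigma^2_b / (\sigma^2_b + \mu / t).}
#' Approximate only (ignores window/day overlap and finite-day effects); used
#' to sanity-check simulated profiles, not as exact truth.
#'
#' @param mu mean visit rate (visits/h).
#' @param sigma2_between between-nest variance of the true rate.
#' @param duration_h window duration in hours.
#' @return approximate R-squared.
#' @export
expected_r2 <- function(mu, sigma2_between, duration_h) {
  sigma2_between / (sigma2_between + mu / duration_h)
}
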