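#' Run the full accuracy-versus-duration pipeline
#'
#' Orchestrates every stage: read (or accept) detection logs, registry and
#' schedule; collapse detections into visits; exclude low-read nest-days;
#' build the hourly accuracy table; build per-sex accuracy-versus-duration
#' profiles; fit and rank the saturation-curve families; and compute the
#' optimal observation duration per sex by both rules (Euclidean rule on the
#' AICc-best curve; concavity rule on the Gompertz fit). Deterministic given
#' inputs and \code{seed}.
#'
#' @param detections detection data.frame from [read_detections()] or a path.
#' @param registry registry data.frame from [read_registry()] or a path.
#' @param schedule schedule data.frame from [read_schedule()] or a path.
#' @param gap_threshold visit-merge threshold, seconds.
#' @param min_reads low-read exclusion threshold (combined reads).
#' @param table_starts_s start grid for the hourly accuracy table.
#' @param profile_starts_s start grid for the duration sweep.
#' @param durations_h duration grid for the sweep.
#' @param day_end_s latest admissible window end.
#' @param n_boot bootstrap replicates for the accuracy-table CIs.
#' @param families curve families to fit and rank.
#' @param opt_grid candidate-duration grid for the Euclidean rule.
#' @param seed integer seed for all resampling.
#' @param out_dir optional directory for stage outputs (accuracy_table.tsv,
#'   profile_F/M.csv, model_comparison_F/M.tsv, optima.tsv).
#' @return list with series (kept nest-days), exclusions (counts reconciling
#'   input = kept + excluded), accuracy (data.frame), profiles (per sex),
#'   model_tables (per sex, with fits attached), and optima (data.frame
#'   sex, method, family, duration_h, objective).
#' @export
run_pipeline <- function(detections, registry, schedule,
                         gap_threshold = 2, min_reads = 200,
                         table_starts_s = seq(6, 19) * 3600,
                         profile_starts_s = seq(7, 17) * 3600,
                         durations_h = seq(0.25, 4, by = 0.25),
                         day_end_s = 22 * 3600, n_boot = 10000,
                         families = c("mm3", "gompertz3", "ar3", "spline"),
                         opt_grid = seq(0.25, 4, by = 0.25), seed = 1L,
                         out_dir = NULL) {
  if (is.character(detections)) detections <- read_detections(detections)
  if (is.character(registry)) registry <- read_registry(registry)
  if (is.character(schedule)) schedule <- read_schedule(schedule)
  series <- build_nest_days(detections, registry, schedule, gap_threshold)
  part <- filter_low_read_nests(series, min_reads)
  if (!length(part$kept))
    stop("no nests remain after the low-read filter (", length(part$excluded),
         " excluded)")
  exclusions <- c(input = length(series), kept = length(part$kept),
                  excluded_low_reads = length(part$excluded))
  acc <- accuracy_table(part$kept, starts_s = table_starts_s,
                        duration_h = 1, n_boot = n_boot, seed = seed)
  profiles <- lapply(c(F = "F", M = "M"), function(sx)
    duration_profile(part$kept, sx, profile_starts_s, durations_h, day_end_s))
  model_tables <- lapply(profiles, compare_models, families = families)
  optima <- do.call(rbind, lapply(c("F", "M"), function(sx) {
    fits <- attr(model_tables[[sx]], "fits")
    best_family <- model_tables[[sx]]$family[
      model_tables[[sx]]$family != "spline"][1]
    eu <- euclidean_optimum(fits[[best_family]], grid = opt_grid)
    rows <- data.frame(sex = sx, method = "euclidean", family = best_family,
                       duration_h = eu$duration_h, objective = eu$objective)
    if ("gompertz3" %in% names(fits)) {
      co <- tryCatch(concavity_optimum(fits[["gompertz3"]]),
                     error = function(e) NULL)
      if (!is.null(co))
        rows <- rbind(rows, data.frame(sex = sx, method = "concavity",
                                       family = "gompertz3",
                                       duration_h = co$duration_h,
                                       objective = co$objective))
    }
    rows
  }))
  res <- list(series = part$kept, exclusions = exclusions, accuracy = acc,
              profiles = profiles, model_tables = model_tables,
              optima = optima)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_accuracy_table(acc, file.path(out_dir, "accuracy_table.tsv"))
    for (sx in c("F", "M")) {
      utils::write.csv(profiles[[sx]],
                       file.path(out_dir, paste0("profile_", sx, ".csv")),
                       row.names = FALSE)
      utils::write.table(model_tables[[sx]],
                         file.path(out_dir,
                                   paste0("model_comparison_", sx, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    utils::write.table(optima, file.path(out_dir, "optima.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  res
}

#' Cumulative visit counts over the day
#'
#' Step-function points of the running visit count per sex, for checking
#' that visits accrue linearly (negligible diel variation).
#'
#' @param nd a [nest_day()] object.
#' @return data.frame with sex, time_s, cumulative.
#' @export
cumulative_series <- function(nd) {
  do.call(rbind, lapply(c("F", "M"), function(sx) {
    tt <- sort(nd$visits$time_s[nd$visits$sex == sx])
    data.frame(sex = rep(sx, length(tt)), time_s = tt,
               cumulative = seq_along(tt))
  }))
}
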