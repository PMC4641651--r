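as_xy <- function(pairs, x, y) {
  if (inherits(pairs, "rate_dataset")) list(x = pairs$x, y = pairs$y)
  else list(x = pairs, y = x)
}

#' Simple linear regression accuracy of a window rate
#'
#' Ordinary least squares of the whole-day rate on the window rate; the
#' R-squared is the accuracy currency: the proportion of between-nest variance
#' in daily rate explained by the short sample. For simple regression it
#' equals the squared Pearson correlation.
#'
#' @param pairs a \code{rate_dataset} from [assemble_rate_dataset()], or a
#'   numeric predictor vector (then \code{y} must be given).
#' @param y response vector when \code{pairs} is numeric.
#' @return list with n, r_squared, p_value (two-sided slope t-test), slope,
#'   intercept.
#' @export
linear_r2 <- function(pairs, y = NULL) {
  d <- as_xy(pairs, y)
  x <- d$x; y <- d$y
  n <- length(x)
  stopifnot(n == length(y), n >= 3L)
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0) {
    warning("zero predictor variance; R-squared defined as 0")
    return(list(n = n, r_squared = 0, p_value = NA_real_,
                slope = NA_real_, intercept = mean(y)))
  }
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r2 <- if (syy > 0) sxy^2 / (sxx * syy) else 0
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  rss <- syy - slope * sxy
  se <- sqrt(max(rss, 0) / (n - 2) / sxx)
  p <- if (se > 0) 2 * stats::pt(-abs(slope / se), n - 2) else 0
  list(n = n, r_squared = r2, p_value = p, slope = slope,
       intercept = intercept)
}

#' Pearson correlation between two rate measurements
#'
#' Used to validate automatically inferred visit rates against simultaneous
#' human observation counts.
#'
#' @param x,y paired rate vectors.
#' @return list with r, p (two-sided), n.
#' @export
pearson_r <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the inputs")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Nonparametric bootstrap confidence interval for R-squared
#'
#' Percentile interval over \code{n_boot} resamples of the (window rate,
#' daily rate) pairs with replacement; the resampling unit is the nest.
#' Degenerate resamples with zero predictor variance contribute R-squared 0.
#'
#' @param pairs a \code{rate_dataset} or numeric predictor vector.
#' @param y response vector when \code{pairs} is numeric.
#' @param n_boot number of bootstrap replicates (default 10000).
#' @param level confidence level (default 0.95).
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @return numeric c(ci_low, ci_high).
#' @export
bootstrap_r2_ci <- function(pairs, y = NULL, n_boot = 10000, level = 0.95,
                            seed = NULL) {
  d <- as_xy(pairs, y)
  x <- d$x; y <- d$y
  n <- length(x)
  stopifnot(n == length(y), n >= 3L)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  r2 <- boot_r2_vec(x, y, n_boot)
  unname(stats::quantile(r2, c((1 - level) / 2, 1 - (1 - level) / 2)))
}

# vectorized bootstrap R^2: one column per resample, closed-form correlation
boot_r2_vec <- function(x, y, n_boot, chunk = 2000L) {
  n <- length(x)
  out <- numeric(n_boot)
  done <- 0L
  while (done < n_boot) {
    m <- min(chunk, n_boot - done)
    idx <- matrix(sample.int(n, n * m, replace = TRUE), nrow = n)
    xb <- matrix(x[idx], nrow = n); yb <- matrix(y[idx], nrow = n)
    sx <- colSums(xb); sy <- colSums(yb)
    vx <- colSums(xb * xb) - sx^2 / n
    vy <- colSums(yb * yb) - sy^2 / n
    cxy <- colSums(xb * yb) - sx * sy / n
    r2 <- numeric(m)
    ok <- vx > 1e-12 * pmax(1, sx^2 / n) & vy > 0
    r2[ok] <- cxy[ok]^2 / (vx[ok] * vy[ok])
    out[done + seq_len(m)] <- pmin(r2, 1)
    done <- done + m
  }
  out
}

#' Flag influential points in the accuracy regression
#'
#' Standard leverage/influence screens on the simple OLS fit: Cook's distance
#' above 4/n or hat value above 2(k+1)/n with k = 1 predictor. Flagged nests
#' are reported, never excluded, so published estimates stay conservative.
#'
#' @param pairs a \code{rate_dataset} or numeric predictor vector.
#' @param y response vector when \code{pairs} is numeric.
#' @return logical vector, one flag per pair (named by nest when available).
#' @export
influence_flags <- function(pairs, y = NULL) {
  d <- as_xy(pairs, y)
  n <- length(d$x)
  if (n < 4L) stop("influence diagnostics need at least 4 points")
  fit <- stats::lm(d$y ~ d$x)
  cd <- stats::cooks.distance(fit)
  # (numerically) zero-residual fits carry no influence signal
  if (stats::sigma(fit) <= 1e-8 * max(stats::sd(d$y), 1e-300)) cd[] <- 0
  cd[!is.finite(cd)] <- 0
  fl <- unname(cd > 4 / n | stats::hatvalues(fit) > 2 * 2 / n)
  if (inherits(pairs, "rate_dataset")) names(fl) <- pairs$nest_id
  fl
}

#' Accuracy table over window start times
#'
#' For each start time, regresses each sex's daily rate on its windowed rate
#' (default duration 1 h) across the nests covering the window, reporting
#' R-squared with a bootstrap CI and the slope p-value. Sample size n is
#' shared between the sexes because coverage depends only on the schedule.
#'
#' @param series list of [nest_day()] objects (already low-read filtered).
#' @param starts_s window start times, seconds after midnight; default hourly
#'   06:00-19:00.
#' @param duration_h window duration in hours, default 1.
#' @param sexes sexes to tabulate.
#' @param n_boot,level bootstrap settings (see [bootstrap_r2_ci()]).
#' @param seed integer seed controlling all bootstrap resampling.
#' @return data.frame with one row per start time: time, then per sex
#'   r2, ci_low, ci_high, p, and the shared n. Unusable cells (fewer than 3
#'   covered nests) are NA.
#' @export
accuracy_table <- function(series, starts_s = seq(6, 19) * 3600,
                           duration_h = 1, sexes = c("F", "M"),
                           n_boot = 10000, level = 0.95, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rows <- lapply(starts_s, function(st) {
    row <- list(time = sec_to_hms(st))
    n_shared <- NA_integer_
    for (sx in sexes) {
      ds <- assemble_rate_dataset(series, sx, st, duration_h)
      n_shared <- ds$n
      if (ds$usable && stats::sd(ds$x) > 0) {
        est <- linear_r2(ds)
        ci <- bootstrap_r2_ci(ds, n_boot = n_boot, level = level)
        row[paste0(c("r2_", "ci_low_", "ci_high_", "p_"), sx)] <-
          list(est$r_squared, ci[1], ci[2], est$p_value)
      } else {
        row[paste0(c("r2_", "ci_low_", "ci_high_", "p_"), sx)] <-
          list(NA_real_, NA_real_, NA_real_, NA_real_)
      }
    }
    row$n <- n_shared
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Export an accuracy table as TSV
#'
#' Formats per-sex columns as \code{R2 [low; high]} alongside p and N.
#'
#' @param tab data.frame from [accuracy_table()].
#' @param path output TSV path.
#' @export
write_accuracy_table <- function(tab, path) {
  fmt <- function(r2, lo, hi) ifelse(is.na(r2), "",
    sprintf("%.2f [%.2f; %.2f]", r2, lo, hi))
  out <- data.frame(time = tab$time,
                    r2_female = fmt(tab$r2_F, tab$ci_low_F, tab$ci_high_F),
                    p_female = signif(tab$p_F, 2),
                    r2_male = fmt(tab$r2_M, tab$ci_low_M, tab$ci_high_M),
                    p_male = signif(tab$p_M, 2),
                    n = tab$n)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
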