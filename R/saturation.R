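#' Accuracy-versus-duration profile
#'
#' For every combination of start time and window duration, computes the
#' R-squared of the regression of daily rate on window rate across covered
#' nests. Multiple start times per duration provide the replication needed by
#' the lack-of-fit test, so fits are performed on this pooled point cloud.
#'
#' @param series list of [nest_day()] objects (low-read filtered).
#' @param sex "F" or "M".
#' @param starts_s start-time grid, default hourly 07:00-17:00.
#' @param durations_h duration grid in hours, default 0.25-4 by 0.25.
#' @param day_end_s windows ending after this are dropped (default 22:00).
#' @return data.frame with start_s, duration_h, r_squared, n (covered nests);
#'   windows with fewer than 3 covered nests are omitted.
#' @export
duration_profile <- function(series, sex, starts_s = seq(7, 17) * 3600,
                             durations_h = seq(0.25, 4, by = 0.25),
                             day_end_s = 22 * 3600) {
  wins <- enumerate_windows(starts_s, durations_h, day_end_s)
  rows <- lapply(seq_len(nrow(wins)), function(i) {
    ds <- assemble_rate_dataset(series, sex, wins$start_s[i],
                                wins$duration_h[i])
    if (!ds$usable || stats::sd(ds$x) == 0) return(NULL)
    data.frame(start_s = wins$start_s[i], duration_h = wins$duration_h[i],
               r_squared = linear_r2(ds)$r_squared, n = ds$n)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(start_s = numeric(),
                                      duration_h = numeric(),
                                      r_squared = numeric(), n = integer())
  out
}

#' Collapse a duration profile to per-duration means
#'
#' Alternative to fitting the pooled point cloud: averages R-squared over
#' start times at each duration. Note the lack-of-fit test needs the pooled
#' profile (it uses start-time replication as pure error).
#'
#' @param profile data.frame from [duration_profile()].
#' @return data.frame with duration_h, r_squared (mean), n_points.
#' @export
profile_means <- function(profile) {
  sp <- split(profile$r_squared, profile$duration_h)
  data.frame(duration_h = as.numeric(names(sp)),
             r_squared = vapply(sp, mean, numeric(1)),
             n_points = lengths(sp), row.names = NULL)
}

# ---- curve families --------------------------------------------------------

# saturating basis functions, linear in (c, d) given the nonlinear parameter e
mm_basis <- function(x, e) x / (x + e)            # Michaelis-Menten
ar_basis <- function(x, e) 1 - exp(-x / e)        # asymptotic regression

# profiled linear solve for f = c*(1-g) + d*g; returns c, d, rss
solve_cd <- function(g, y) {
  A <- cbind(1 - g, g)
  fit <- stats::lm.fit(A, y)
  cf <- fit$coefficients
  if (anyNA(cf)) return(list(c = NA_real_, d = NA_real_, rss = Inf))
  list(c = unname(cf[1]), d = unname(cf[2]), rss = sum(fit$residuals^2))
}

# profile RSS over log(e) for the two-basis families: coarse log-grid scan
# followed by golden-section refinement in the bracketing interval
fit_basis_family <- function(x, y, basis) {
  rss_of <- function(loge) solve_cd(basis(x, exp(loge)), y)$rss
  lo <- log(max(min(x) / 100, 1e-8)); hi <- log(max(x) * 100)
  grid <- seq(lo, hi, length.out = 160L)
  vals <- vapply(grid, rss_of, numeric(1))
  i <- which.min(vals)
  br <- c(grid[max(i - 1L, 1L)], grid[min(i + 1L, length(grid))])
  opt <- stats::optimize(rss_of, interval = br, tol = 1e-12)
  e <- exp(opt$minimum)
  sol <- solve_cd(basis(x, e), y)
  list(coef = c(b = NA_real_, c = sol$c, d = sol$d, e = e), rss = sol$rss)
}

gompertz_mean <- function(x, b, d, e) d * exp(-exp(b * (x - e)))

# profiled RSS over (b, e) with d solved in closed form
fit_gompertz <- function(x, y) {
  prof <- function(th) {
    w <- exp(-exp(th[1] * (x - th[2])))
    sw2 <- sum(w * w)
    if (!is.finite(sw2) || sw2 < 1e-300) return(sum(y^2))
    d <- sum(w * y) / sw2
    sum((y - d * w)^2)
  }
  starts <- expand.grid(b = c(-2, -1, -0.5),
                        e = unname(stats::quantile(x, c(0.25, 0.5, 0.75))))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(as.numeric(starts[i, ]), prof, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  # polish: quasi-Newton then a final simplex pass from the polished point
  o <- stats::optim(best$par, prof, method = "BFGS",
                    control = list(maxit = 500, reltol = 1e-15))
  if (o$value <= best$value) best <- o
  o <- stats::optim(best$par, prof, method = "Nelder-Mead",
                    control = list(maxit = 2000, reltol = 1e-15))
  if (o$value <= best$value) best <- o
  b <- best$par[1]; e <- best$par[2]
  w <- exp(-exp(b * (x - e)))
  d <- sum(w * y) / sum(w * w)
  list(coef = c(b = b, c = 0, d = d, e = e), rss = sum((y - d * w)^2))
}

#' Fit a saturation curve to an accuracy profile
#'
#' Least-squares fit of R-squared as a function of observation duration.
#' Families: \code{gompertz3} \eqn{f(x) = d\,e^{-e^{b(x-e)}}} (increasing for
#' b < 0, lower limit fixed at 0, has an inflection), \code{mm3}
#' \eqn{f(x) = c + (d-c)/(1+e/x)} (Michaelis-Menten, half-saturation e),
#' \code{ar3} \eqn{f(x) = c + (d-c)(1 - e^{-x/e})} (asymptotic regression),
#' and \code{spline}, a penalized cubic regression spline with smoothness by
#' GCV (via \pkg{mgcv}). The parametric fits profile out the linear
#' parameters, so only the one- or two-dimensional nonlinear part is searched
#' (deterministic multi-start grid; no random restarts needed).
#'
#' @param profile a data.frame from [duration_profile()] (columns duration_h,
#'   r_squared), or a numeric x vector with \code{y} supplied.
#' @param family one of "gompertz3", "mm3", "ar3", "spline".
#' @param y response values when \code{profile} is numeric.
#' @return object of class \code{curve_fit}: family, coef (b, c, d, e), edf
#'   (effective number of mean-function parameters), rss, n, and the data.
#' @export
fit_curve <- function(profile, family = c("mm3", "gompertz3", "ar3", "spline"),
                      y = NULL) {
  family <- match.arg(family)
  if (is.data.frame(profile)) {
    x <- profile$duration_h; yv <- profile$r_squared
  } else {
    x <- as.numeric(profile); yv <- y
  }
  stopifnot(length(x) == length(yv), length(unique(x)) >= 6L)
  gam_model <- NULL
  if (family == "spline") {
    k <- min(10L, length(unique(x)) - 1L)
    dat <- data.frame(x = x, y = yv)
    gam_model <- mgcv::gam(y ~ s(x, bs = "cr", k = k), data = dat,
                           method = "GCV.Cp")
    fitted <- list(coef = c(b = NA_real_, c = NA_real_, d = NA_real_,
                            e = NA_real_),
                   rss = sum(stats::residuals(gam_model)^2))
    edf <- sum(gam_model$edf) + 1  # + intercept
  } else {
    fitted <- switch(family,
      mm3 = fit_basis_family(x, yv, mm_basis),
      ar3 = fit_basis_family(x, yv, ar_basis),
      gompertz3 = fit_gompertz(x, yv))
    edf <- 3
    if (!all(is.finite(fitted$coef[c("d")])) || !is.finite(fitted$rss))
      stop("curve fit failed to converge for family ", family)
    if (fitted$coef["d"] < 0 || fitted$coef["d"] > 1.05)
      warning("fitted asymptote d = ", signif(fitted$coef["d"], 4),
              " outside [0, 1.05]")
  }
  structure(list(family = family, coef = fitted$coef, edf = edf,
                 rss = fitted$rss, n = length(x), x = x, y = yv,
                 gam_model = gam_model),
            class = "curve_fit")
}

#' Evaluate a fitted saturation curve
#'
#' @param object a \code{curve_fit}.
#' @param newx durations (hours) at which to evaluate.
#' @param ... unused.
#' @return numeric vector of fitted values.
#' @export
predict.curve_fit <- function(object, newx, ...) {
  cf <- object$coef
  switch(object$family,
    gompertz3 = gompertz_mean(newx, cf["b"], cf["d"], cf["e"]),
    mm3 = cf["c"] + (cf["d"] - cf["c"]) * mm_basis(newx, cf["e"]),
    ar3 = cf["c"] + (cf["d"] - cf["c"]) * ar_basis(newx, cf["e"]),
    spline = as.numeric(stats::predict(object$gam_model,
                                       newdata = data.frame(x = newx))))
}

#' @export
print.curve_fit <- function(x, ...) {
  cat("<curve_fit>", x$family, " n =", x$n, " rss =", signif(x$rss, 5),
      " AICc =", signif(aicc(x), 6), "\n")
  cf <- x$coef[!is.na(x$coef)]
  if (length(cf)) cat(" ", paste(names(cf), signif(cf, 5), sep = " = ",
                                 collapse = ", "), "\n")
  invisible(x)
}

#' Small-sample corrected Akaike Information Criterion
#'
#' Gaussian AICc with the full log-likelihood constant, so values match
#' standard likelihood-based implementations:
#' \deqn{AICc = n\log(2\pi\,rss/n) + n + 2p + 2p(p+1)/(n-p-1)}
#' with p = (effective) mean parameters + 1 for the residual variance.
#'
#' @param fit a \code{curve_fit}, or the rss when using the default method.
#' @param n,npar sample size and mean-parameter count (default method).
#' @return AICc value.
#' @export
aicc <- function(fit, n = NULL, npar = NULL) {
  if (inherits(fit, "curve_fit")) { rss <- fit$rss; n <- fit$n; npar <- fit$edf }
  else rss <- fit
  p <- npar + 1
  if (n <= p + 1) stop("AICc undefined: n <= p + 1")
  n * log(2 * pi * rss / n) + n + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

#' Lack-of-fit F test against the per-duration group-means model
#'
#' Compares the fitted curve's residual sum of squares with that of the
#' saturated model fitting one mean per distinct duration (pure error from
#' replicated start times). A significant value indicates lack of fit.
#'
#' @param fit a \code{curve_fit} (carries its data).
#' @return list with F, p, df1, df2.
#' @export
lack_of_fit_test <- function(fit) {
  x <- fit$x; y <- fit$y
  groups <- split(y, x)
  if (length(groups) == length(y))
    stop("lack-of-fit test needs replicated duration values")
  rss_means <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  df_means <- length(y) - length(groups)
  df_model <- length(y) - fit$edf
  df1 <- df_model - df_means
  Fstat <- ((fit$rss - rss_means) / df1) / (rss_means / df_means)
  Fstat <- max(Fstat, 0)
  list(F = Fstat, p = stats::pf(Fstat, df1, df_means, lower.tail = FALSE),
       df1 = df1, df2 = df_means)
}

#' Fit and rank several saturation-curve families
#'
#' @param profile data.frame from [duration_profile()].
#' @param families families to fit (see [fit_curve()]).
#' @return data.frame sorted by AICc with family, parameters, edf, rss, aicc,
#'   delta_aicc and lack-of-fit statistics; the \code{"fits"} attribute holds
#'   the \code{curve_fit} objects (named by family).
#' @export
compare_models <- function(profile,
                           families = c("mm3", "gompertz3", "ar3", "spline")) {
  fits <- lapply(families, function(f) fit_curve(profile, f))
  names(fits) <- families
  rows <- lapply(fits, function(f) {
    lof <- tryCatch(lack_of_fit_test(f), error = function(e) list(F = NA, p = NA))
    data.frame(family = f$family, b = f$coef[["b"]], c = f$coef[["c"]],
               d = f$coef[["d"]], e = f$coef[["e"]], edf = f$edf,
               rss = f$rss, aicc = aicc(f), lof_F = lof$F, lof_p = lof$p)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$aicc), , drop = FALSE]
  tab$delta_aicc <- tab$aicc - tab$aicc[1]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}
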