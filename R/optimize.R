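#' Optimal duration by the Euclidean minimally-important-change rule
#'
#' Durations (cost) and fitted accuracy values (benefit) are min-max
#' normalized over the evaluated range; the optimum is the candidate duration
#' whose normalized point lies nearest the ideal corner (zero cost, maximal
#' accuracy), i.e. minimizing \eqn{\sqrt{x_n^2 + (1 - y_n)^2}}. Ties break
#' toward the shorter duration. Works with any monotone fitted curve.
#'
#' @param fit a \code{curve_fit}.
#' @param grid candidate durations in hours; default the 15-min data grid
#'   0.25-4 h (which is why optima land on quarter-hour values).
#' @param y_norm "curve" (default) normalizes y over the fitted curve's range
#'   on the grid; "unit" treats accuracy as already on [0, 1].
#' @return list of class \code{optimal_duration}: method, duration_h,
#'   objective (minimized distance), and the normalization bounds used.
#' @export
euclidean_optimum <- function(fit, grid = seq(0.25, 4, by = 0.25),
                              y_norm = c("curve", "unit")) {
  y_norm <- match.arg(y_norm)
  grid <- sort(grid)
  yv <- predict(fit, grid)
  xb <- range(grid)
  yb <- if (y_norm == "curve") range(yv) else c(0, 1)
  if (diff(yb) <= 0) {
    warning("flat fitted curve; returning the shortest duration")
    return(structure(list(method = "euclidean", duration_h = grid[1],
                          objective = NA_real_, x_bounds = xb, y_bounds = yb),
                     class = "optimal_duration"))
  }
  xn <- (grid - xb[1]) / diff(xb)
  yn <- (yv - yb[1]) / diff(yb)
  d <- sqrt(xn^2 + (1 - yn)^2)
  i <- which.min(d)  # grid ascending: first minimum is the shortest duration
  structure(list(method = "euclidean", duration_h = grid[i],
                 objective = d[i], x_bounds = xb, y_bounds = yb),
            class = "optimal_duration")
}

#' Analytic second derivative of the Gompertz curve
#'
#' For \eqn{f(x) = d\,e^{-u}} with \eqn{u = e^{b(x-e)}}:
#' \eqn{f''(x) = -d\,b^2\,u\,e^{-u}(1-u)}.
#'
#' @param x durations (hours).
#' @param b,d,e Gompertz parameters (b < 0 for an increasing curve).
#' @return f''(x).
#' @export
gompertz_d2 <- function(x, b, d, e) {
  u <- exp(b * (x - e))
  -d * b^2 * u * exp(-u) * (1 - u)
}

#' Optimal duration by the Gompertz concavity rule
#'
#' Locates the local minimum of the fitted Gompertz curve's second derivative
#' — the inflection point of the first derivative, where accuracy gains per
#' unit time begin their asymptotic decline. Dense-grid scan followed by
#' golden-section refinement on the analytic second derivative. Only defined
#' for the Gompertz family; the other families have monotonically decreasing
#' steepness and no such point.
#'
#' @param fit a \code{curve_fit} with family "gompertz3".
#' @param search_range numeric length-2; default the fitted data range.
#' @param n_scan dense-scan resolution.
#' @return list of class \code{optimal_duration}: method, duration_h,
#'   objective (f'' at the optimum).
#' @export
concavity_optimum <- function(fit, search_range = NULL, n_scan = 4096L) {
  if (!inherits(fit, "curve_fit") || fit$family != "gompertz3")
    stop("the concavity rule only works with the Gompertz growth function")
  sr <- search_range %||% range(fit$x)
  cf <- fit$coef
  f2 <- function(x) gompertz_d2(x, cf[["b"]], cf[["d"]], cf[["e"]])
  xs <- seq(sr[1], sr[2], length.out = n_scan)
  v <- f2(xs)
  i <- which.min(v)
  if (i == 1L || i == n_scan)
    stop("no interior local minimum of f'' in [", signif(sr[1], 4), ", ",
         signif(sr[2], 4), "]; f'' is monotone there")
  opt <- stats::optimize(f2, interval = c(xs[i - 1L], xs[i + 1L]),
                         tol = .Machine$double.eps^0.5)
  structure(list(method = "concavity", duration_h = opt$minimum,
                 objective = opt$objective, x_bounds = sr),
            class = "optimal_duration")
}

#' @export
print.optimal_duration <- function(x, ...) {
  cat("<optimal_duration>", x$method, ":", signif(x$duration_h, 4), "h",
      "(objective", signif(x$objective, 4), ")\n")
  invisible(x)
}
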