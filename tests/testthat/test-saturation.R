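pooled_x <- rep(seq(0.25, 4, 0.25), 11)  # the 11-start x 16-duration design

test_that("fit_curve recovers exact parameters from noiseless data", {
  y <- mm3_fun(pooled_x, 0.1, 0.7, 0.5)
  f <- fit_curve(pooled_x, "mm3", y = y)
  expect_equal(unname(f$coef[c("c", "d", "e")]), c(0.1, 0.7, 0.5),
               tolerance = 1e-6)
  # half-saturation identity f(e) = c + (d - c)/2
  expect_equal(unname(predict(f, f$coef[["e"]])),
               f$coef[["c"]] + (f$coef[["d"]] - f$coef[["c"]]) / 2,
               tolerance = 1e-9)

  y <- ar3_fun(pooled_x, 0.15, 0.8, 0.9)
  f <- fit_curve(pooled_x, "ar3", y = y)
  expect_equal(unname(f$coef[c("c", "d", "e")]), c(0.15, 0.8, 0.9),
               tolerance = 1e-6)

  y <- gom_fun(pooled_x, -1.2, 0.75, 0.6)
  f <- fit_curve(pooled_x, "gompertz3", y = y)
  expect_equal(unname(f$coef[c("b", "d", "e")]), c(-1.2, 0.75, 0.6),
               tolerance = 1e-6)
  expect_lt(f$rss, 1e-12)
})

test_that("fitted saturation curves are monotone and reach their asymptote", {
  set.seed(61)
  y <- mm3_fun(pooled_x, 0.1, 0.7, 0.5) + rnorm(length(pooled_x), 0, 0.05)
  for (fam in c("mm3", "ar3")) {
    f <- fit_curve(pooled_x, fam, y = y)
    expect_true(f$coef[["d"]] > f$coef[["c"]])
    expect_true(all(diff(predict(f, seq(0.25, 4, 0.01))) >= 0))
    expect_equal(unname(predict(f, 1e6)), f$coef[["d"]], tolerance = 1e-6)
  }
  fg <- fit_curve(pooled_x, "gompertz3", y = y)
  expect_equal(unname(predict(fg, 1e6)), fg$coef[["d"]], tolerance = 1e-6)
})

test_that("spline fit has sane effective df and the asymptote warning fires", {
  set.seed(62)
  y <- mm3_fun(pooled_x, 0.1, 0.7, 0.5) + rnorm(length(pooled_x), 0, 0.05)
  f <- fit_curve(pooled_x, "spline", y = y)
  expect_gte(f$edf, 1)
  expect_lte(f$edf, length(unique(pooled_x)))
  expect_equal(unname(predict(f, 2)[1]), mm3_fun(2, 0.1, 0.7, 0.5),
               tolerance = 0.1)
  # asymptote fitted above 1.05 triggers a warning, not an error
  y_hi <- mm3_fun(pooled_x, 0.2, 1.6, 1.2)
  expect_warning(fit_curve(pooled_x, "mm3", y = y_hi), "outside \\[0, 1.05\\]")
})

test_that("aicc follows the small-sample formula", {
  # identical rss and parameter count: no difference
  expect_equal(aicc(0.5, 176, 3), aicc(0.5, 176, 3))

  # equal rss, 3 vs 4 mean parameters (p = 4 vs 5 with the variance),
  # n = 176: the smaller model wins by the penalty difference ~2.12
  pen <- function(p) 2 * p + 2 * p * (p + 1) / (176 - p - 1)
  expect_equal(aicc(0.5, 176, 4) - aicc(0.5, 176, 3), pen(5) - pen(4),
               tolerance = 1e-12)
  expect_equal(pen(5) - pen(4), 2.119, tolerance = 0.01)

  # algebraic tie: larger model's rss lower by exactly the penalty offset
  rss1 <- 0.5
  rss2 <- rss1 * exp(-(pen(5) - pen(4)) / 176)
  expect_equal(aicc(rss2, 176, 4), aicc(rss1, 176, 3), tolerance = 1e-10)

  expect_error(aicc(0.5, 5, 4), "n <= p \\+ 1")
})

test_that("lack_of_fit_test: zero when group means lie on the curve", {
  x <- rep(seq(0.25, 4, 0.25), each = 4)
  mu <- mm3_fun(x, 0.1, 0.7, 0.5)
  y <- mu + rep(c(-0.02, -0.01, 0.01, 0.02), times = 16)  # zero-mean in group
  f <- fit_curve(x, "mm3", y = y)
  lof <- lack_of_fit_test(f)
  expect_equal(lof$F, 0, tolerance = 1e-6)
  expect_equal(lof$p, 1, tolerance = 1e-6)

  # misspecification: a step function is not a Michaelis-Menten curve
  y_step <- 0.2 + 0.5 * (x >= 2) + rep(c(-0.02, -0.01, 0.01, 0.02), 16)
  f <- suppressWarnings(fit_curve(x, "mm3", y = y_step))
  expect_lt(lack_of_fit_test(f)$p, 0.05)

  # no replication: error
  f1 <- fit_curve(seq(0.25, 4, 0.25), "mm3",
                  y = mm3_fun(seq(0.25, 4, 0.25), 0.1, 0.7, 0.5))
  expect_error(lack_of_fit_test(f1), "replicated")
})

test_that("compare_models ranks the generating family first most of the time", {
  # model-selection consistency: at low noise the generating family wins.
  # At the residual scale of real profiles (~0.05) the saturation families
  # are near-indistinguishable by design (their shapes differ little), so
  # this check uses sigma = 0.02 where discrimination is identifiable.
  # 60 replicates (scaled down from 200 for runtime; same check).
  set.seed(63)
  mu <- mm3_fun(pooled_x, 0.1, 0.7, 0.5)
  wins <- 0L
  for (i in 1:60) {
    prof <- data.frame(duration_h = pooled_x,
                       r_squared = mu + rnorm(length(pooled_x), 0, 0.02))
    tab <- suppressWarnings(compare_models(prof))
    if (tab$family[1] == "mm3") wins <- wins + 1L
  }
  expect_gte(wins / 60, 0.9)
})

test_that("compare_models returns a complete ranked table", {
  set.seed(64)
  prof <- data.frame(duration_h = pooled_x,
                     r_squared = gom_fun(pooled_x, -1.1, 0.7, 0.5) +
                       rnorm(length(pooled_x), 0, 0.04))
  tab <- suppressWarnings(compare_models(prof))
  expect_identical(nrow(tab), 4L)
  expect_true(!is.unsorted(tab$aicc))
  expect_equal(tab$delta_aicc[1], 0)
  expect_true(all(tab$rss >= 0))
  # single family: table of one
  tab1 <- compare_models(prof, families = "mm3")
  expect_identical(nrow(tab1), 1L)
  # AICc -> AIC: correction negligible at large n
  expect_lt(aicc(1, 1e5, 3) - (1e5 * log(2 * pi * 1 / 1e5) + 1e5 + 2 * 4),
            0.01)
})

test_that("profile_means averages over start times and stays fittable", {
  prof <- data.frame(duration_h = rep(c(0.25, 0.5, 1, 2, 3, 4), each = 3),
                     r_squared = rep(mm3_fun(c(0.25, 0.5, 1, 2, 3, 4),
                                             0.1, 0.7, 0.5), each = 3) +
                       rep(c(-0.01, 0, 0.01), 6))
  pm <- profile_means(prof)
  expect_identical(nrow(pm), 6L)
  expect_true(all(pm$n_points == 3L))
  f <- fit_curve(pm, "mm3")
  expect_equal(unname(f$coef[c("c", "d", "e")]), c(0.1, 0.7, 0.5),
               tolerance = 1e-6)
})
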