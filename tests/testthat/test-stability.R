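lb_oracle <- function(series, spec_limit = 90, confidence = 0.95) {
  # brute-force reconstruction of the one-sided lower bound on the mean line
  x <- series$months; y <- series$assay; n <- length(x)
  fit <- stats::lm(y ~ x); b <- unname(coef(fit))
  s <- sqrt(sum(resid(fit)^2) / (n - 2))
  tcrit <- stats::qt(confidence, n - 2)
  function(t) b[1] + b[2] * t - tcrit * s * sqrt(1 / n + (t - mean(x))^2 /
                                                   sum((x - mean(x))^2))
}

test_that("zero residual variance collapses the bound onto the fitted line", {
  s <- stability_series("exact", c(0, 3, 6), 100 - 0.5 * c(0, 3, 6))
  est <- estimate_shelf_life(s, spec_limit = 90)
  expect_equal(est$shelf_life, 20, tolerance = 1e-9)
  expect_equal(est$slope, -0.5, tolerance = 1e-12)
  # near-zero noise converges to the analytic crossing
  s2 <- gen_stability(5, intercept = 100, slope = -0.5, noise_sd = 1e-6)
  expect_equal(estimate_shelf_life(s2)$shelf_life, 20, tolerance = 1e-3)
})

test_that("bisection agrees with a 0.001-month grid scan of the bound", {
  for (seed in 1:10) {
    s <- gen_stability(seed, intercept = 99.5, slope = -0.2, noise_sd = 0.3)
    est <- estimate_shelf_life(s, spec_limit = 90)
    g <- lb_oracle(s)
    grid <- seq(0, 120, by = 0.001)
    hit <- grid[which(vapply(grid, g, numeric(1)) <= 90)[1]]
    expect_false(is.na(hit))
    expect_equal(est$shelf_life, hit, tolerance = 2e-3)
  }
})

test_that("shelf life is monotone in the specification limit and confidence level", {
  for (seed in 1:5) {
    s <- gen_stability(seed, intercept = 99, slope = -0.3, noise_sd = 0.3)
    sl_spec <- vapply(c(85, 88, 90, 92, 95),
                      function(sp) estimate_shelf_life(s, spec_limit = sp)$shelf_life,
                      numeric(1))
    expect_true(all(diff(sl_spec) <= 1e-9))  # raising the limit never lengthens
    # at very high confidence with 1 residual df the bound can sit below
    # the limit from the start (shelf life 0, warned) -- still monotone
    sl_conf <- suppressWarnings(
      vapply(c(0.80, 0.90, 0.95, 0.99),
             function(cf) estimate_shelf_life(s, confidence = cf)$shelf_life,
             numeric(1)))
    expect_true(all(diff(sl_conf) <= 1e-9))  # raising confidence never lengthens
    # the bound crossing never exceeds the naive mean-line crossing
    est <- estimate_shelf_life(s)
    naive <- (90 - est$intercept) / est$slope
    expect_lte(est$shelf_life, naive + 1e-9)
  }
})

test_that("degradation slope is recovered within 5 % median error over 500 series", {
  slope_true <- -0.2
  est <- vapply(1:500, function(seed) {
    s <- gen_stability(seed, intercept = 100, slope = slope_true, noise_sd = 0.3)
    estimate_shelf_life(s)$slope
  }, numeric(1))
  expect_lt(abs(stats::median(est) / slope_true - 1), 0.05)
})

test_that("the nine bundled assay series all give finite positive shelf lives", {
  for (s in flurbiprofen_stability()) {
    est <- estimate_shelf_life(s)
    expect_true(is.finite(est$shelf_life))
    expect_gt(est$shelf_life, 0)
  }
})

test_that("degenerate and edge series are handled explicitly", {
  flat <- stability_series("flat", c(0, 3, 6), rep(99, 3))
  expect_warning(est <- estimate_shelf_life(flat), "no crossing")
  expect_identical(est$shelf_life, Inf)
  grow <- stability_series("grow", c(0, 3, 6), c(98, 98.5, 99))
  expect_warning(est2 <- estimate_shelf_life(grow))
  expect_identical(est2$shelf_life, Inf)
  low <- stability_series("low", c(0, 3, 6), c(89, 88, 87))
  expect_warning(est3 <- estimate_shelf_life(low), "t = 0")
  expect_identical(est3$shelf_life, 0)
  expect_error(estimate_shelf_life(stability_series("s", c(0, 3), c(99, 98))),
               "at least 3")
  # a crossing beyond an explicit reporting horizon is reported as Inf
  s <- stability_series("slow", c(0, 3, 6), c(99.5, 99.4, 99.3))
  expect_warning(capped <- estimate_shelf_life(s, horizon = 24), "horizon")
  expect_identical(capped$shelf_life, Inf)
})
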