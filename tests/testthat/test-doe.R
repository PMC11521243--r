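make_design <- function(alpha = sqrt(2), n_center = 1) {
  generate_ccd(factor_spec("ludipress", 52, 3),
               factor_spec("croscarmellose", 3, 2),
               alpha = alpha, n_center = n_center)
}

test_that("the rotatable CCD reproduces the published factor levels", {
  d <- make_design()
  expect_equal(nrow(d), 9)
  # 4 factorial, 4 axial, 1 center
  expect_equal(sum(abs(d$c1) == 1 & abs(d$c2) == 1), 4)
  expect_equal(sum(d$c1 == 0 & d$c2 == 0), 1)
  expect_equal(d$ludipress_display[d$c1 == sqrt(2)], 56.242)

  # every printed level is the truncation of the exact level at its
  # printed precision
  exact <- c(56.2426407, 47.7573593, 5.8284271, 0.1715729)
  for (i in seq_len(nrow(printed_axials))) {
    fac <- printed_axials$factor[i]
    lev <- d[[fac]][abs(d[[if (fac == "ludipress") "c1" else "c2"]] -
                          printed_axials$coded[i]) < 1e-9]
    expect_equal(lev, exact[i], tolerance = 1e-6)
    expect_equal(trunc_dec(lev, printed_axials$digits[i]), printed_axials$printed[i])
  }
  # all nine factorial/center levels are exact
  expect_setequal(round(d$ludipress[abs(d$c1) <= 1], 6), c(49, 52, 55))
  expect_setequal(round(d$croscarmellose[abs(d$c2) <= 1], 6), c(1, 3, 5))

  # face-centered variant: axial levels coincide with the +/-1 faces
  fc <- make_design(alpha = 1)
  expect_setequal(round(fc$ludipress, 6), c(49, 52, 55))
  expect_error(factor_spec("x", 52, 0), "positive")
})

test_that("composition arithmetic reproduces the published tablet table", {
  des <- flurbiprofen_design()
  for (i in seq_len(nrow(des))) {
    comp <- composition_from_point(des$ludipress[i], des$croscarmellose[i])
    exp_row <- printed_compositions[printed_compositions$run == des$run[i], ]
    expect_equal(comp$tablet_weight_display, exp_row$tablet_weight,
                 info = des$run[i])
    got <- comp$mg_display
    expect_equal(unname(got[c("ludipress", "croscarmellose", "aerosil", "talc",
                              "aspartame", "magnesium_stearate")]),
                 unname(unlist(exp_row[c("ludipress_mg", "croscarmellose_mg",
                                         "aerosil_mg", "talc_mg", "aspartame_mg",
                                         "magnesium_stearate_mg")])),
                 info = des$run[i])
    expect_equal(unname(got["api"]), 100)
    # invariants: percents close at 100, mg close at the tablet weight
    expect_equal(sum(comp$percents), 100)
    expect_equal(sum(comp$mg), comp$tablet_weight)
  }
  # no excipients at all: the tablet is pure API
  bare <- composition_from_point(0, 0, fixed = c(), api_dose = 100)
  expect_equal(bare$tablet_weight, 100)
  expect_error(composition_from_point(95, 5), ">= 100")
})

test_that("response-surface fitting recovers noise-free coefficients exactly", {
  d <- make_design()
  y <- 2 + 3 * d$c1 - 1 * d$c2
  fit <- fit_response_surface(d, y, "linear")
  expect_equal(unname(fit$coefficients), c(2, 3, -1), tolerance = 1e-9)
  expect_lt(fit$anova$sum_sq[2], 1e-18)

  yq <- 5 + 1.5 * d$c1 - 0.5 * d$c2 + 0.8 * d$c1^2 - 0.3 * d$c2^2 + 0.2 * d$c1 * d$c2
  fq <- fit_response_surface(d, yq, "quadratic")
  expect_equal(unname(fq$coefficients[c("c1", "c2", "I(c1^2)", "I(c2^2)", "c1:c2")]),
               c(1.5, -0.5, 0.8, -0.3, 0.2), tolerance = 1e-9)

  # constant response is degenerate, F flagged 0
  fc <- fit_response_surface(d, rep(3, 9), "linear")
  expect_true(fc$degenerate)
  expect_equal(fc$anova$F[1], 0)

  # aliased factors are reported
  d2 <- d
  d2$c2 <- d2$c1
  expect_error(fit_response_surface(d2, y, "linear"), "aliased")
})

test_that("F statistic and adequate precision match brute-force oracles over replicates", {
  d <- make_design()
  X <- cbind(1, d$c1, d$c2)
  xtx_inv <- solve(t(X) %*% X)
  hat <- X %*% xtx_inv %*% t(X)
  n <- nrow(X); p <- ncol(X)
  set.seed(2024)
  for (rep in 1:200) {
    y <- 10 + 2 * d$c1 - 1.5 * d$c2 + stats::rnorm(n, 0, 0.8)
    fit <- fit_response_surface(d, y, "linear")
    # explicit matrix-algebra oracle, no lm
    yhat <- as.vector(hat %*% y)
    ss_res <- sum((y - yhat)^2)
    ss_mod <- sum((yhat - mean(y))^2)
    f_oracle <- (ss_mod / (p - 1)) / (ss_res / (n - p))
    expect_equal(fit$anova$F[1], f_oracle, tolerance = 1e-8)
    ap_oracle <- (max(yhat) - min(yhat)) / sqrt(p * (ss_res / (n - p)) / n)
    expect_equal(as.numeric(fit$adequate_precision), ap_oracle, tolerance = 1e-8)
  }
})

test_that("adequate precision is scale invariant and handles degenerate fits", {
  d <- make_design()
  set.seed(11)
  y <- 10 + 2 * d$c1 - 1.5 * d$c2 + stats::rnorm(9, 0, 0.5)
  f1 <- fit_response_surface(d, y, "linear")
  f2 <- fit_response_surface(d, 2 * y, "linear")
  expect_equal(as.numeric(f1$adequate_precision),
               as.numeric(f2$adequate_precision), tolerance = 1e-9)
  # zero fitted range -> 0; zero residual MS with signal -> Inf
  expect_equal(as.numeric(fit_response_surface(d, rep(1, 9), "linear")$adequate_precision), 0)
  exact <- fit_response_surface(d, 1 + d$c1, "linear")
  expect_true(is.infinite(as.numeric(exact$adequate_precision)))
})

test_that("the alpha = sqrt(2) design is rotatable", {
  d <- make_design()
  yq <- 5 + d$c1 - d$c2 + 0.5 * d$c1^2 + 0.2 * d$c2^2
  mm <- cbind(1, d$c1, d$c2, d$c1^2, d$c2^2, d$c1 * d$c2)
  xtx_inv <- solve(t(mm) %*% mm)
  pred_var <- function(c1, c2) {
    x0 <- c(1, c1, c2, c1^2, c2^2, c1 * c2)
    as.numeric(t(x0) %*% xtx_inv %*% x0)
  }
  for (rho in c(0.5, 1, 1.3)) {
    angles <- seq(0, 2 * pi, length.out = 13)[-13]
    v <- vapply(angles, function(a) pred_var(rho * cos(a), rho * sin(a)), numeric(1))
    expect_lt(max(v) - min(v), 1e-6)
  }
})
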