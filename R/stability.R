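#' Construct a stability series
#'
#' Assay (percent of label claim) measured at successive storage times,
#' e.g. 0, 3 and 6 months under accelerated conditions (40 C / 75 % RH).
#'
#' @param label formulation name.
#' @param months non-negative, strictly increasing sampling times.
#' @param assay percent of label claim, in (0, 110].
#' @return object of class `stability_series`.
#' @export
stability_series <- function(label, months, assay) {
  if (length(months) != length(assay)) {
    stop("'months' and 'assay' must have the same length", call. = FALSE)
  }
  if (any(!is.finite(months)) || any(months < 0) || any(diff(months) <= 0)) {
    stop("'months' must be non-negative and strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(assay)) || any(assay <= 0) || any(assay > 110)) {
    stop("'assay' must lie in (0, 110]", call. = FALSE)
  }
  structure(list(label = label, months = as.numeric(months),
                 assay = as.numeric(assay)),
            class = "stability_series")
}

#' Estimate shelf life from a stability series
#'
#' ICH-style shelf-life estimation: ordinary least squares of assay on
#' time, then the earliest time at which the one-sided lower confidence
#' bound on the *mean* regression line crosses the specification limit.
#' The bound at time `t` is
#' `yhat(t) - qt(conf, n-2) * s * sqrt(1/n + (t - tbar)^2 / Sxx)`;
#' with zero residual variance it collapses onto the fitted line, so the
#' estimate equals the analytic crossing `(intercept - limit) / |slope|`.
#'
#' The bound is a concave function of time whose asymptotic slope is
#' `slope - qt(conf, n-2) * s / sqrt(Sxx)`: when that is negative a
#' crossing is guaranteed and is located by bracketing plus bisection to
#' 0.001 month; when it is non-negative the bound never descends to the
#' limit and the shelf life is `Inf` (with a warning). `horizon` is an
#' optional reporting cap: a crossing beyond it is also reported as
#' `Inf`. By default no cap is applied --- the estimate is the crossing
#' time wherever it lies, as stability-analysis software reports it.
#'
#' @param series a [stability_series()].
#' @param spec_limit specification limit as percent of label claim
#'   (default 90).
#' @param confidence one-sided confidence level for the lower bound
#'   (default 0.95).
#' @param horizon reporting cap in months (default `Inf`, no cap).
#' @return object of class `shelf_life_estimate`: list with `slope`,
#'   `intercept`, `sigma` (residual SD), `spec_limit`, `confidence`,
#'   `horizon` and `shelf_life` (months; may be 0 or `Inf`).
#' @export
#' @examples
#' s <- stability_series("demo", c(0, 3, 6), 100 - 0.5 * c(0, 3, 6))
#' estimate_shelf_life(s)$shelf_life  # 20.000 months
estimate_shelf_life <- function(series, spec_limit = 90, confidence = 0.95,
                                horizon = Inf) {
  if (!inherits(series, "stability_series")) {
    stop("'series' must be a stability_series", call. = FALSE)
  }
  stopifnot_scalar_number(spec_limit, "spec_limit", 0, 110)
  stopifnot_scalar_number(confidence, "confidence", 0.5, 1 - 1e-9)
  if (!is.numeric(horizon) || length(horizon) != 1L || is.na(horizon) || horizon <= 0) {
    stop("'horizon' must be a single positive number (possibly Inf)", call. = FALSE)
  }
  n <- length(series$months)
  if (n < 3) stop("need at least 3 time points", call. = FALSE)
  x <- series$months
  y <- series$assay
  fit <- stats::lm(y ~ x)
  b <- unname(stats::coef(fit))
  s2 <- sum(stats::residuals(fit)^2) / (n - 2)
  sxx <- sum((x - mean(x))^2)
  tcrit <- stats::qt(confidence, df = n - 2)
  lower_bound <- function(t) {
    b[1] + b[2] * t - tcrit * sqrt(s2) * sqrt(1 / n + (t - mean(x))^2 / sxx)
  }
  g <- function(t) lower_bound(t) - spec_limit

  # asymptotic slope of the (concave) bound: crossing exists iff negative
  slope_inf <- b[2] - tcrit * sqrt(s2) / sqrt(sxx)

  shelf <- NA_real_
  if (g(0) <= 0) {
    warning("lower confidence bound is already at or below the limit at t = 0",
            call. = FALSE)
    shelf <- 0
  } else if (sqrt(s2) < 1e-10) {
    # zero-noise collapse: the bound is the fitted line itself
    shelf <- if (b[2] < -1e-12) (spec_limit - b[1]) / b[2] else Inf
    if (!is.finite(shelf)) {
      warning("non-negative degradation slope with zero residual variance: no crossing",
              call. = FALSE)
    }
  } else if (slope_inf >= 0) {
    warning("confidence bound never descends to the limit: no crossing", call. = FALSE)
    shelf <- Inf
  } else {
    # bracket the guaranteed crossing, then bisect to 1e-3 month
    hi <- max(1, 2 * mean(x))
    while (g(hi) > 0) hi <- hi * 2
    lo <- 0
    while (hi - lo > 1e-3) {
      mid <- (lo + hi) / 2
      if (g(mid) <= 0) hi <- mid else lo <- mid
    }
    shelf <- (lo + hi) / 2
  }
  if (shelf > horizon) {
    warning("crossing lies beyond the reporting horizon", call. = FALSE)
    shelf <- Inf
  }
  structure(list(label = series$label, slope = b[2], intercept = b[1],
                 sigma = sqrt(s2), spec_limit = spec_limit,
                 confidence = confidence, horizon = horizon,
                 shelf_life = shelf),
            class = "shelf_life_estimate")
}

#' @export
print.shelf_life_estimate <- function(x, ...) {
  cat(sprintf("Shelf life%s: %s months (limit %.1f %%, one-sided %.0f %% bound)\n",
              if (nzchar(x$label)) paste0(" (", x$label, ")") else "",
              if (is.finite(x$shelf_life)) sprintf("%.3f", x$shelf_life) else "Inf",
              x$spec_limit, 100 * x$confidence))
  cat(sprintf("  fit: assay = %.3f %+.4f * month (residual SD %.4f)\n",
              x$intercept, x$slope, x$sigma))
  invisible(x)
}
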