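#' Construct a dissolution profile
#'
#' Cumulative percent of label claim released at each sampling time. The
#' bundled study sampled at 2, 4, 6, 8, 10, 12 and 15 minutes.
#'
#' @param times sampling times, strictly increasing and positive. Units
#'   are whatever the data were recorded in; fitted rate constants are in
#'   the reciprocal of that unit.
#' @param release cumulative percent released (0--110; a few percent of
#'   assay overage is tolerated).
#' @param label profile name.
#' @param q0 initial amount on the percent scale (default 100).
#' @return object of class `dissolution_profile`.
#' @export
dissolution_profile <- function(times, release, label = "", q0 = 100) {
  if (length(times) != length(release)) {
    stop("'times' and 'release' must have the same length", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(times <= 0) || any(diff(times) <= 0)) {
    stop("'times' must be positive and strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(release)) || any(release < 0) || any(release > 110)) {
    stop("'release' must lie in [0, 110]", call. = FALSE)
  }
  structure(list(times = as.numeric(times), release = as.numeric(release),
                 label = label, q0 = q0),
            class = "dissolution_profile")
}

#' Predicted cumulative release under a kinetic model
#'
#' Release-scale forms of the four classical dissolution models:
#' \itemize{
#'   \item first order: `Qt = Q0 (1 - exp(-k1 t))`;
#'   \item Higuchi: `Qt = kH sqrt(t)`;
#'   \item Hixson-Crowell cube root: `Qt = Q0 - (Q0^(1/3) - kHC t)^3`,
#'     plateauing at `Q0`;
#'   \item Weibull: `Qt = Q0 (1 - exp(-((t - Ti)^beta) / alpha))`, `Ti`
#'     a lag time (0 before the lag).
#' }
#'
#' @param model one of `"first_order"`, `"higuchi"`, `"hixson_crowell"`,
#'   `"weibull"`.
#' @param parameters named list/vector: `k1`, `kH`, `kHC`, or
#'   `alpha`/`beta` (and optional `Ti`).
#' @param times evaluation times.
#' @param q0 initial amount (percent scale), default 100.
#' @return numeric vector of predicted cumulative release.
#' @export
#' @examples
#' predict_release("higuchi", c(kH = 26.301), times = c(2, 4, 6))
predict_release <- function(model, parameters, times, q0 = 100) {
  p <- as.list(parameters)
  switch(model,
    first_order = q0 * (1 - exp(-p$k1 * times)),
    higuchi = p$kH * sqrt(times),
    hixson_crowell = {
      core <- pmax(q0^(1 / 3) - p$kHC * times, 0)
      q0 - core^3
    },
    weibull = {
      ti <- if (is.null(p$Ti)) 0 else p$Ti
      tt <- pmax(times - ti, 0)
      q0 * (1 - exp(-(tt^p$beta) / p$alpha))
    },
    stop("unknown model '", model, "'", call. = FALSE)
  )
}

kinetic_model_npar <- c(first_order = 1L, higuchi = 1L, hixson_crowell = 1L, weibull = 3L)

# Keep points below complete release plus the first point at/over 100 %:
# the cube-root and exponential forms degenerate once release is complete.
trim_plateau <- function(times, release, q0 = 100) {
  over <- which(release >= q0)
  keep <- release < q0
  if (length(over)) keep[over[1]] <- TRUE
  list(times = times[keep], release = release[keep])
}

#' Fit a dissolution release-kinetics model
#'
#' Least-squares fit of one of the four classical models (see
#' [predict_release()]) on the observed-release scale, so that the
#' coefficients of determination are comparable across models:
#' `r2 = 1 - SS_res / SS_tot` with `SS_tot` about the mean observed
#' release. One-parameter models are fitted by golden-section/parabolic
#' 1-D minimisation; the Weibull model by bounded Levenberg-Marquardt
#' least squares started from five deterministic shape values (lag time
#' `Ti` fixed at 0 unless `fit_lag = TRUE`). Points at or beyond complete
#' release are trimmed except the first (plateau trimming). The
#' first-order model can alternatively be fitted in its log-decay form
#' (`ln Qremaining` regressed on time) via `form = "decay"`.
#'
#' @param profile a [dissolution_profile()].
#' @param model model name.
#' @param fit_lag fit the Weibull lag time `Ti` (default `FALSE`).
#' @param form first-order fitting scale: `"release"` (default) or
#'   `"decay"`.
#' @return object of class `kinetic_fit`: list with `model`, named
#'   `parameters`, `r_squared`, `fitted`, `n_parameters`, and the trimmed
#'   `times`/`release` actually fitted.
#' @export
#' @examples
#' t <- c(2, 4, 6, 8, 10, 12, 15)
#' prof <- dissolution_profile(t, 26.301 * sqrt(t))
#' fit_kinetic_model(prof, "higuchi")$parameters
fit_kinetic_model <- function(profile,
                              model = c("first_order", "higuchi",
                                        "hixson_crowell", "weibull"),
                              fit_lag = FALSE,
                              form = c("release", "decay")) {
  model <- match.arg(model)
  form <- match.arg(form)
  if (!inherits(profile, "dissolution_profile")) {
    stop("'profile' must be a dissolution_profile", call. = FALSE)
  }
  q0 <- profile$q0
  tr <- trim_plateau(profile$times, profile$release, q0)
  t <- tr$times
  q <- tr$release
  min_n <- if (model == "weibull") 4L else 3L
  if (length(t) < min_n) {
    stop("need at least ", min_n, " usable points for the ", model, " model",
         call. = FALSE)
  }
  if (stats::sd(q) < 1e-12) stop("degenerate profile: release values are constant",
                                 call. = FALSE)

  ss <- function(pred) sum((q - pred)^2)
  params <- switch(model,
    higuchi = {
      # linear through the origin in sqrt(t): closed form
      c(kH = sum(q * sqrt(t)) / sum(t))
    },
    first_order = {
      if (form == "decay") {
        # ln(Q0 - Qt) = ln Q0 - k1 t on points with release < Q0
        ok <- q < q0
        if (sum(ok) < 2) stop("decay form needs >= 2 incomplete-release points",
                              call. = FALSE)
        fit <- stats::lm(log(q0 - q[ok]) ~ t[ok])
        c(k1 = max(-unname(stats::coef(fit)[2]), 1e-12))
      } else {
        opt <- stats::optimize(function(k) ss(q0 * (1 - exp(-k * t))),
                               interval = c(1e-9, 10), tol = 1e-12)
        c(k1 = opt$minimum)
      }
    },
    hixson_crowell = {
      kmax <- q0^(1 / 3) / max(t)  # complete release at the last point
      opt <- stats::optimize(function(k) ss(predict_release("hixson_crowell",
                                                            c(kHC = k), t, q0)),
                             interval = c(1e-12, kmax), tol = 1e-12)
      c(kHC = opt$minimum)
    },
    weibull = fit_weibull(t, q, q0, fit_lag)
  )
  fitted_all <- predict_release(model, params, profile$times, q0)
  fitted_fit <- predict_release(model, params, t, q0)
  if (any(params < 0)) stop("fit produced a negative parameter", call. = FALSE)
  r2 <- 1 - ss(fitted_fit) / sum((q - mean(q))^2)
  structure(list(model = model, parameters = params, r_squared = r2,
                 fitted = fitted_all, times = t, release = q,
                 n_parameters = unname(kinetic_model_npar[model]),
                 label = profile$label),
            class = "kinetic_fit")
}

# Bounded nonlinear least squares for the Weibull model, multi-started from
# five deterministic shape values; the scale start solves the median point.
fit_weibull <- function(t, q, q0, fit_lag) {
  m <- pmin(pmax(q / q0, 1e-6), 1 - 1e-6)
  med <- ceiling(length(t) / 2)
  starts <- lapply(c(0.4, 0.7, 1, 1.4, 2), function(b) {
    a <- t[med]^b / (-log(1 - m[med]))
    if (fit_lag) list(alpha = a, beta = b, Ti = 0) else list(alpha = a, beta = b)
  })
  lower <- if (fit_lag) c(1e-8, 1e-8, 0) else c(1e-8, 1e-8)
  upper <- if (fit_lag) c(Inf, 20, max(t) - 1e-6) else c(Inf, 20)
  dat <- data.frame(t = t, q = q)
  form <- if (fit_lag) {
    q ~ q0 * (1 - exp(-(pmax(t - Ti, 0)^beta) / alpha))
  } else {
    q ~ q0 * (1 - exp(-(t^beta) / alpha))
  }
  best <- NULL
  fails <- character()
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = st, lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200,
                                                             ftol = 1e-14,
                                                             ptol = 1e-14)),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      fails <- c(fails, conditionMessage(fit))
      next
    }
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    stop("Weibull fit failed to converge from starts beta = 0.4/0.7/1/1.4/2: ",
         paste(unique(fails), collapse = "; "), call. = FALSE)
  }
  cf <- stats::coef(best$fit)
  if (!fit_lag) cf <- c(cf, Ti = 0)
  cf[c("alpha", "beta", "Ti")]
}

#' Fit all release models to one profile
#'
#' @param profile a [dissolution_profile()].
#' @param models models to fit (default all four).
#' @param ... passed to [fit_kinetic_model()].
#' @return named list of `kinetic_fit` objects.
#' @export
fit_all_kinetics <- function(profile, models = names(kinetic_model_npar), ...) {
  fits <- lapply(models, function(m) fit_kinetic_model(profile, m, ...))
  stats::setNames(fits, models)
}

#' Select the best-fitting release model
#'
#' Picks the model with the largest coefficient of determination; ties
#' (within `tol`) are broken in favour of the model with fewer parameters.
#'
#' @param fits a named list of `kinetic_fit` objects, or a named numeric
#'   vector of r-squared values (names must be model names known to the
#'   package).
#' @param tol absolute r-squared difference treated as a tie (default 0).
#' @return the selected model name (character scalar).
#' @export
#' @examples
#' select_best_model(c(first_order = 0.902, higuchi = 0.953,
#'                     hixson_crowell = 0.819, weibull = 0.944))
select_best_model <- function(fits, tol = 0) {
  if (!length(fits)) stop("empty fit list", call. = FALSE)
  if (is.numeric(fits)) {
    r2 <- fits
  } else {
    r2 <- vapply(fits, function(f) f$r_squared, numeric(1))
  }
  if (is.null(names(r2)) || !all(names(r2) %in% names(kinetic_model_npar))) {
    stop("fits must be named with known model names", call. = FALSE)
  }
  if (length(r2) < 2) stop("need at least 2 fits to select among", call. = FALSE)
  npar <- kinetic_model_npar[names(r2)]
  contenders <- which(r2 >= max(r2) - tol)
  names(r2)[contenders[order(npar[contenders], names(r2)[contenders])][1]]
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("%s fit%s: r2 = %.4f\n", x$model,
              if (nzchar(x$label)) paste0(" (", x$label, ")") else "", x$r_squared))
  print(signif(x$parameters, 6))
  invisible(x)
}
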