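#' Synthetic powder parameter set
#'
#' Seed-controlled generator of SeDeM parameter measurements. By default
#' each experimental value is drawn uniformly within its parameter's
#' limit range (so every radius is uniform on 0--10). With a
#' `target_ipp`, radii are drawn from a normal distribution centered on
#' the target (SD `spread`) and clipped to 0--10 before inversion, biasing
#' the set toward a desired parameter profile index; `spread = 0` pins
#' every radius at the target exactly.
#'
#' @param seed integer seed; identical seeds give identical sets.
#' @param variant scoring variant.
#' @param target_ipp optional target mean radius in \[0, 10\].
#' @param spread SD of the radius draw around `target_ipp` (default 1.5).
#' @param label material name.
#' @return a [powder_parameter_set()].
#' @export
#' @examples
#' gen_powder_set(1, target_ipp = 7)
gen_powder_set <- function(seed, variant = c("odt15", "classic12"),
                           target_ipp = NULL, spread = 1.5,
                           label = sprintf("synthetic-%d", seed)) {
  variant <- match.arg(variant)
  rules <- sedem_rules(variant)
  with_fixed_seed(seed, {
    radii <- if (is.null(target_ipp)) {
      stats::runif(nrow(rules), 0, 10)
    } else {
      stopifnot_scalar_number(target_ipp, "target_ipp", 0, 10)
      pmin(pmax(stats::rnorm(nrow(rules), target_ipp, spread), 0), 10)
    }
    names(radii) <- rules$parameter
    values <- invert_radii(radii, rules)
    powder_parameter_set(label, values, variant)
  })
}

#' Synthetic dissolution profile
#'
#' Evaluates a release model on a sampling grid and adds independent
#' Gaussian noise, clipping to \[0, 105\] (assay overage tolerated). A
#' Weibull lag beyond the last sampling time produces an all-zero
#' profile, flagged degenerate via the `"degenerate"` attribute.
#'
#' @param seed integer seed.
#' @param model release model name (see [predict_release()]).
#' @param parameters generating parameters.
#' @param times sampling grid (default the study's 2, 4, 6, 8, 10, 12,
#'   15 minute grid).
#' @param noise_sd additive noise SD in release percent (default 0).
#' @param label profile name.
#' @return a [dissolution_profile()] (attribute `degenerate` set if the
#'   signal is identically zero).
#' @export
#' @examples
#' gen_dissolution(1, "higuchi", c(kH = 26.301), noise_sd = 1)
gen_dissolution <- function(seed, model = "higuchi", parameters = c(kH = 26.301),
                            times = c(2, 4, 6, 8, 10, 12, 15), noise_sd = 0,
                            label = sprintf("synthetic-%d", seed)) {
  signal <- predict_release(model, parameters, times)
  prof <- with_fixed_seed(seed, {
    q <- signal + stats::rnorm(length(times), 0, noise_sd)
    dissolution_profile(times, pmin(pmax(q, 0), 105), label = label)
  })
  if (all(signal == 0)) attr(prof, "degenerate") <- TRUE
  prof
}

#' Synthetic stability series
#'
#' Linear degradation signal `intercept + slope * month` plus Gaussian
#' noise at the sampling months.
#'
#' @param seed integer seed.
#' @param intercept assay at time zero, percent (default 100).
#' @param slope degradation rate, percent per month (default -0.2).
#' @param months sampling times (default 0, 3, 6).
#' @param noise_sd noise SD in assay percent (default 0.3).
#' @param label series name.
#' @return a [stability_series()].
#' @export
gen_stability <- function(seed, intercept = 100, slope = -0.2,
                          months = c(0, 3, 6), noise_sd = 0.3,
                          label = sprintf("synthetic-%d", seed)) {
  with_fixed_seed(seed, {
    assay <- intercept + slope * months + stats::rnorm(length(months), 0, noise_sd)
    stability_series(label, months, pmin(pmax(assay, 1e-6), 110))
  })
}

#' Synthetic response-surface observations on a design
#'
#' Evaluates `y = b0 + b1 c1 + b2 c2 (+ b11 c1^2 + b22 c2^2 + b12 c1 c2)`
#' on the coded runs of a design and adds Gaussian noise. Coefficient
#' names: `b0`, `b1`, `b2` and optionally `b11`, `b22`, `b12` (absent
#' quadratic terms are treated as zero).
#'
#' @param seed integer seed.
#' @param design a [generate_ccd()] design.
#' @param coefficients named numeric vector of generating coefficients.
#' @param noise_sd noise SD (default 0).
#' @return numeric response vector, one value per run.
#' @export
#' @examples
#' d <- generate_ccd(factor_spec("x1", 52, 3), factor_spec("x2", 3, 2))
#' gen_response_surface(1, d, c(b0 = 2, b1 = 3, b2 = -1), noise_sd = 0.1)
gen_response_surface <- function(seed, design, coefficients, noise_sd = 0) {
  b <- function(name) if (name %in% names(coefficients)) coefficients[[name]] else 0
  y <- b("b0") + b("b1") * design$c1 + b("b2") * design$c2 +
    b("b11") * design$c1^2 + b("b22") * design$c2^2 + b("b12") * design$c1 * design$c2
  with_fixed_seed(seed, y + stats::rnorm(nrow(design), 0, noise_sd))
}
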