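#' Reference SeDeM radii of flurbiprofen and ludipress
#'
#' Published 12-parameter radius values of flurbiprofen (the API) and
#' ludipress (the co-processed direct-compression excipient) from a
#' flurbiprofen ODT development campaign, bundled as a worked example and
#' golden fixture. Note that the ludipress interparticle-porosity radius
#' is 10.19: radii above 10 occur when the experimental value exceeds the
#' method's limit range and no cap is applied.
#'
#' @return named list of two [radius_profile()] objects
#'   (`flurbiprofen`, `ludipress`), variant `"classic12"`.
#' @export
#' @examples
#' index_summary(flurbiprofen_sedem()$flurbiprofen)
flurbiprofen_sedem <- function() {
  pars <- sedem_parameter_names("classic12")
  list(
    flurbiprofen = radius_profile("flurbiprofen",
      stats::setNames(c(4.80, 6.20, 3.92, 4.52, 0.56, 6.55,
                        3.49, 4.50, 6.00, 5.70, 9.99, 0.49), pars),
      variant = "classic12"),
    ludipress = radius_profile("ludipress",
      stats::setNames(c(3.80, 7.10, 10.19, 9.30, 1.71, 5.66,
                        3.96, 5.95, 7.23, 9.90, 8.18, 7.71), pars),
      variant = "classic12")
  )
}

#' Reference SeDeM-ODT radii of the nine formulation blends
#'
#' Published 15-parameter radius values of the nine flurbiprofen ODT
#' powder blends F1--F9 produced by the central composite design.
#'
#' @return named list of nine [radius_profile()] objects, variant
#'   `"odt15"`.
#' @export
#' @examples
#' sapply(flurbiprofen_blends(), function(p) index_summary(p)$ipp_2dp)
flurbiprofen_blends <- function() {
  pars <- sedem_parameter_names("odt15")
  radii <- rbind(
    F1 = c(3.70, 6.46, 9.50, 8.44, 1.51, 6.30, 3.35, 4.50, 8.64, 8.60, 9.99, 0.32, 9.54, 9.45, 9.32),
    F2 = c(3.40, 5.10, 8.16, 6.66, 1.49, 6.38, 3.49, 5.67, 6.60, 8.46, 9.99, 0.34, 9.56, 9.32, 9.27),
    F3 = c(3.31, 5.41, 9.82, 7.78, 1.52, 6.81, 3.17, 4.99, 5.89, 8.28, 9.99, 0.41, 9.56, 9.38, 9.32),
    F4 = c(3.30, 5.00, 8.58, 6.80, 1.52, 6.07, 2.98, 4.83, 5.88, 8.28, 9.99, 0.44, 9.60, 9.27, 9.45),
    F5 = c(3.58, 6.18, 9.79, 8.41, 1.55, 6.14, 3.20, 4.16, 6.95, 8.33, 9.99, 0.34, 9.50, 9.32, 9.38),
    F6 = c(3.50, 5.50, 8.65, 7.27, 1.56, 5.16, 3.20, 4.66, 7.43, 8.42, 9.98, 0.45, 9.48, 9.32, 9.32),
    F7 = c(3.54, 5.88, 9.36, 7.95, 1.53, 5.80, 3.19, 4.61, 7.23, 8.40, 9.99, 0.27, 9.56, 9.38, 9.22),
    F8 = c(3.50, 5.50, 8.65, 7.27, 1.55, 5.98, 2.76, 4.54, 7.70, 8.31, 9.99, 0.30, 9.53, 9.27, 9.32),
    F9 = c(3.40, 5.20, 8.48, 6.92, 1.57, 5.63, 2.99, 3.83, 5.89, 8.41, 9.99, 0.28, 9.56, 9.27, 9.32)
  )
  colnames(radii) <- pars
  out <- lapply(rownames(radii), function(f) {
    radius_profile(f, radii[f, ], variant = "odt15")
  })
  stats::setNames(out, rownames(radii))
}

#' Reference formulation design levels
#'
#' Percent levels of the two variable excipients for runs F1--F9 of the
#' study's rotatable central composite design (ludipress centered at 52 %
#' with step 3; croscarmellose sodium centered at 3 % with step 2; axial
#' distance sqrt(2)). Levels are recorded at the precision the study's
#' design software displayed, which is the precision its composition
#' arithmetic used (axial levels mix 2--4 decimals); the exact levels are
#' recoverable from [generate_ccd()] with the same factors.
#'
#' @return data frame with columns `run`, `c1`, `c2` (coded levels),
#'   `ludipress`, `croscarmellose` (percent levels as used in the study's
#'   arithmetic).
#' @export
flurbiprofen_design <- function() {
  a <- sqrt(2)
  data.frame(
    run = paste0("F", 1:9),
    c1 = c(-1, a, -1, 0, 0, -a, 0, 1, 1),
    c2 = c(-1, 0, 1, 0, a, 0, -a, -1, 1),
    ludipress = c(49, 56.2426, 49, 52, 52, 47.75, 52, 55, 55),
    croscarmellose = c(1, 3, 5, 3, 5.82, 3, 0.171, 1, 5),
    stringsAsFactors = FALSE
  )
}

#' Reference release-kinetics summary of F1--F9
#'
#' Published model-fit summary for the nine formulations at pH 7.2: the
#' coefficient of determination of each of the four release models and
#' the fitted constants (first-order `k1`, Higuchi `kH`, Hixson-Crowell
#' `kHC`, Weibull `beta`/`alpha`). Rate constants are interpreted in the
#' reciprocal of the sampling-grid time unit. Used as the model-selection
#' fixture and as generating constants for synthetic profiles; the raw
#' dissolution curves behind it are not available as data.
#'
#' @return data frame, one row per formulation.
#' @export
#' @examples
#' rk <- flurbiprofen_release_kinetics()
#' select_best_model(c(first_order = rk$r2_first_order[1],
#'                     higuchi = rk$r2_higuchi[1],
#'                     hixson_crowell = rk$r2_hixson_crowell[1],
#'                     weibull = rk$r2_weibull[1]))
flurbiprofen_release_kinetics <- function() {
  data.frame(
    run = paste0("F", 1:9),
    r2_first_order = c(0.902, 0.812, 0.774, 0.764, 0.833, 0.891, 0.797, 0.781, 0.891),
    k1 = c(0.198, 0.163, 0.160, 0.152, 0.180, 0.171, 0.171, 0.157, 0.193),
    r2_higuchi = c(0.953, 0.940, 0.923, 0.925, 0.936, 0.972, 0.930, 0.929, 0.961),
    kH = c(26.301, 24.559, 24.207, 23.755, 25.312, 24.940, 24.813, 24.054, 26.116),
    r2_hixson_crowell = c(0.819, 0.740, 0.662, 0.659, 0.708, 0.810, 0.674, 0.671, 0.802),
    kHC = c(0.052, 0.043, 0.042, 0.041, 0.047, 0.045, 0.045, 0.042, 0.051),
    r2_weibull = c(0.944, 0.876, 0.887, 0.879, 0.929, 0.941, 0.908, 0.892, 0.939),
    beta = c(0.792, 0.748, 0.693, 0.691, 0.715, 0.776, 0.699, 0.695, 0.780),
    alpha = c(3.456, 3.748, 3.425, 3.553, 3.240, 3.806, 3.281, 3.487, 3.440),
    stringsAsFactors = FALSE
  )
}

#' Reference quality attributes of F1--F9
#'
#' Published physicochemical quality measurements of the nine tablet
#' batches: mean tablet weight +/- SD (n = 20), thickness, hardness,
#' friability, disintegration time, single-point dissolution, assay and
#' wetting time. The F4 dissolution entry was published as 990.66 %,
#' an evident typographical slip for 99.66 %; the corrected value is
#' shipped here.
#'
#' @return data frame, one row per formulation.
#' @export
flurbiprofen_quality <- function() {
  data.frame(
    run = paste0("F", 1:9),
    weight_mean = c(219.9, 275.8, 240.9, 246.9, 265.3, 223.4, 230.7, 253.1, 281.6),
    weight_sd = c(2.231, 2.567, 2.560, 2.277, 1.593, 2.583, 2.922, 2.573, 2.927),
    thickness_mm = c(4.29, 4.36, 4.75, 4.18, 4.59, 4.95, 4.62, 4.10, 4.81),
    hardness_kg = c(3.09, 3.16, 3.10, 3.05, 3.17, 3.18, 3.12, 3.01, 3.21),
    friability = c(0.56, 0.52, 0.54, 0.53, 0.51, 0.53, 0.55, 0.58, 0.57),
    disintegration_s = c(11, 12, 10, 13, 12, 12, 11, 13, 13),
    dissolution = c(98.00, 99.92, 98.65, 99.66, 99.23, 99.26, 98.06, 99.03, 98.36),
    assay = c(99.30, 99.01, 98.68, 98.48, 98.84, 98.56, 98.39, 98.40, 99.00),
    wetting_s = c(9, 13, 12, 9, 8, 10, 8, 11, 10),
    stringsAsFactors = FALSE
  )
}

#' Reference accelerated-stability assay series of F1--F9
#'
#' Published mean assay (percent of label claim, n = 3) at 0, 3 and 6
#' months of accelerated storage (40 C / 75 % RH) for the nine
#' formulations.
#'
#' @return named list of nine [stability_series()] objects.
#' @export
#' @examples
#' estimate_shelf_life(flurbiprofen_stability()$F1)
flurbiprofen_stability <- function() {
  assay <- rbind(
    F1 = c(99.30, 99.21, 99.19),
    F2 = c(99.12, 98.20, 98.10),
    F3 = c(99.03, 98.02, 98.01),
    F4 = c(98.48, 98.10, 98.02),
    F5 = c(98.45, 98.10, 97.92),
    F6 = c(99.63, 98.30, 98.01),
    F7 = c(98.46, 98.01, 97.99),
    F8 = c(99.62, 98.01, 98.01),
    F9 = c(98.33, 99.01, 98.23)
  )
  out <- lapply(rownames(assay), function(f) {
    stability_series(f, c(0, 3, 6), assay[f, ])
  })
  stats::setNames(out, rownames(assay))
}

#' Synthetic 20-tablet weight reconstruction for a batch
#'
#' The bundled quality table reports only the mean and standard deviation
#' of 20 tablet weights per batch. For weight-variation testing this
#' helper deterministically reconstructs a synthetic set of 20 weights
#' with exactly the reported mean and SD, by scaling a fixed standardized
#' template (equispaced quantile-like scores). It is a stand-in for the
#' unavailable individual weighings, not measured data.
#'
#' @param mean_mg reported mean weight, mg.
#' @param sd_mg reported standard deviation, mg.
#' @param n number of tablets (default 20).
#' @return numeric vector of `n` synthetic weights with the exact mean
#'   and SD requested.
#' @export
synthetic_tablet_weights <- function(mean_mg, sd_mg, n = 20) {
  z <- stats::qnorm(seq(0.5 / n, 1 - 0.5 / n, length.out = n))
  z <- (z - mean(z)) / stats::sd(z)
  mean_mg + sd_mg * z
}
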