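#' SeDeM parameter conversion rules
#'
#' The SeDeM expert system scores a powder on 12 experimental parameters
#' (the classic diagram) or 15 (the ODT variant, which adds a
#' disgregability incidence of effervescence time and disintegration times
#' with and without disc). Each experimental value `v` is rescaled to a
#' radius `r` on a nominal 0--10 scale, 10 being most favourable for
#' direct compression, by an affine transform `r = intercept + slope * v`
#' anchored at the method's standard limit values. For example the Carr
#' (compressibility) index maps 0--50\% to 0--10 (`r = v/5`), while loss
#' on drying maps 0--10\% to 10--0 (`r = 10 - v`): quantities that are bad
#' when large run downhill.
#'
#' @param variant `"classic12"` for the 12-parameter diagram or `"odt15"`
#'   for the ODT variant with the disgregability group.
#' @return A data frame with one row per parameter: `parameter` (canonical
#'   short name), `label`, `unit`, `incidence` (the incidence group),
#'   `lower`, `upper` (experimental limit values), `intercept`, `slope`
#'   (the affine radius transform), and `direction` (`"up"` if larger
#'   experimental values score higher).
#' @export
#' @examples
#' sedem_rules("classic12")
sedem_rules <- function(variant = c("odt15", "classic12")) {
  variant <- match.arg(variant)
  r <- function(parameter, label, unit, incidence, lower, upper, intercept, slope) {
    data.frame(parameter = parameter, label = label, unit = unit,
               incidence = incidence, lower = lower, upper = upper,
               intercept = intercept, slope = slope,
               direction = if (slope > 0) "up" else "down",
               stringsAsFactors = FALSE)
  }
  rules <- rbind(
    r("Da",      "Bulk density",                   "g/mL",  "dimension",          0, 1,    0,  10),
    r("Dc",      "Tapped density",                 "g/mL",  "dimension",          0, 1,    0,  10),
    r("Ie",      "Interparticle porosity",         "",      "compressibility",    0, 1.2,  0,  10 / 1.2),
    r("IC",      "Carr (compressibility) index",   "%",     "compressibility",    0, 50,   0,  1 / 5),
    r("Icd",     "Cohesion index",                 "N",     "compressibility",    0, 200,  0,  1 / 20),
    r("IH",      "Hausner ratio",                  "",      "flowability",        1, 3,   15, -5),
    r("theta",   "Angle of repose",                "deg",   "flowability",        0, 50,  10, -1 / 5),
    r("t_flow",  "Powder flow time",               "s",     "flowability",        0, 20,  10, -1 / 2),
    r("HR",      "Loss on drying",                 "%",     "lubricity_stability", 0, 10, 10, -1),
    r("H",       "Hygroscopicity",                 "%",     "lubricity_stability", 0, 20, 10, -1 / 2),
    r("Pf",      "Particles < 50 um",              "%",     "lubricity_dosage",   0, 50,  10, -1 / 5),
    r("Itheta",  "Homogeneity index",              "",      "lubricity_dosage",   0, 0.02, 0, 500)
  )
  if (variant == "odt15") {
    rules <- rbind(
      rules,
      r("effervescence", "Effervescence time",              "min", "disgregability", 0, 5,   10, -2),
      r("DCD",           "Disintegration time with disc",    "s",   "disgregability", 0, 180, 10, -1 / 18),
      r("DSD",           "Disintegration time without disc", "s",   "disgregability", 0, 180, 10, -1 / 18)
    )
  }
  rules
}

#' Canonical SeDeM parameter names
#'
#' @param variant scoring variant; see [sedem_rules()].
#' @return character vector of parameter names in canonical (table/radar)
#'   order.
#' @export
sedem_parameter_names <- function(variant = c("odt15", "classic12")) {
  sedem_rules(match.arg(variant))$parameter
}

#' SeDeM incidence groups
#'
#' @param variant scoring variant; see [sedem_rules()].
#' @return named list mapping each incidence group to its member parameters.
#' @export
sedem_incidence_groups <- function(variant = c("odt15", "classic12")) {
  rules <- sedem_rules(match.arg(variant))
  split(rules$parameter, factor(rules$incidence, levels = unique(rules$incidence)))
}

#' Derived powder rheology indices
#'
#' Standard descriptors computed from bulk (`da`) and tapped (`dc`)
#' density: the Carr index `100 (dc - da) / dc`, the Hausner ratio
#' `dc / da` and the interparticle porosity `(dc - da) / (dc da)`.
#'
#' @param da bulk density, g/mL.
#' @param dc tapped density, g/mL.
#' @return numeric vector.
#' @export
#' @examples
#' carr_index(0.38, 0.71)             # 46.48 %
#' hausner_ratio(0.38, 0.71)          # 1.868
#' interparticle_porosity(0.38, 0.71) # 1.223
carr_index <- function(da, dc) 100 * (dc - da) / dc

#' @rdname carr_index
#' @export
hausner_ratio <- function(da, dc) dc / da

#' @rdname carr_index
#' @export
interparticle_porosity <- function(da, dc) (dc - da) / (dc * da)

#' Construct a powder parameter set
#'
#' Experimental SeDeM measurements for one material or blend.
#'
#' @param label material name.
#' @param values named numeric vector or list, one experimental value per
#'   parameter of the chosen variant (see [sedem_parameter_names()]).
#' @param variant scoring variant.
#' @return an object of class `powder_parameter_set`.
#' @export
#' @examples
#' vals <- c(Da = 0.38, Dc = 0.71, Ie = 1.223, IC = 46.48, Icd = 34.2,
#'           IH = 1.868, theta = 19.8, t_flow = 8.1, HR = 2.77, H = 0.2,
#'           Pf = 9.1, Itheta = 0.0154)
#' powder_parameter_set("ludipress", vals, variant = "classic12")
powder_parameter_set <- function(label, values, variant = c("odt15", "classic12")) {
  variant <- match.arg(variant)
  values <- unlist(values)
  expected <- sedem_parameter_names(variant)
  missing <- setdiff(expected, names(values))
  if (length(missing)) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(values), expected)
  if (length(extra)) {
    stop("unknown parameter(s) for variant '", variant, "': ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  values <- values[expected]
  if (any(!is.finite(values))) stop("all parameter values must be finite", call. = FALSE)
  if (any(values < 0)) {
    stop("negative value for parameter(s): ",
         paste(expected[values < 0], collapse = ", "), call. = FALSE)
  }
  structure(list(label = label, variant = variant, values = values),
            class = "powder_parameter_set")
}

#' Convert experimental parameter values to SeDeM radii
#'
#' Applies the limit-anchored affine transforms of [sedem_rules()] to an
#' experimental parameter set, yielding the radius profile that all index
#' arithmetic and radar geometry consume. Values outside a parameter's
#' limit range are physically possible (e.g. an interparticle porosity
#' above 1.2 gives a radius above 10) and produce a warning, not an error.
#'
#' @param params a [powder_parameter_set()].
#' @param rules conversion rule table; defaults to the standard rules for
#'   the set's variant.
#' @param cap if `TRUE`, radii are capped at 10 (and floored at 0).
#' @return a [radius_profile()].
#' @export
#' @examples
#' vals <- c(Da = 0.38, Dc = 0.71, Ie = 1.223, IC = 46.48, Icd = 34.2,
#'           IH = 1.868, theta = 19.8, t_flow = 8.1, HR = 2.77, H = 0.2,
#'           Pf = 9.1, Itheta = 0.0154)
#' pp <- powder_parameter_set("ludipress", vals, variant = "classic12")
#' convert_parameters(pp)
convert_parameters <- function(params, rules = sedem_rules(params$variant), cap = FALSE) {
  if (!inherits(params, "powder_parameter_set")) {
    stop("'params' must be a powder_parameter_set", call. = FALSE)
  }
  missing <- setdiff(names(params$values), rules$parameter)
  if (length(missing)) {
    stop("no conversion rule for parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rules <- rules[match(names(params$values), rules$parameter), ]
  v <- params$values
  out_of_range <- v < pmin(rules$lower, rules$upper) | v > pmax(rules$lower, rules$upper)
  if (any(out_of_range)) {
    warning("value(s) outside the SeDeM limit range for: ",
            paste(rules$parameter[out_of_range], collapse = ", "),
            call. = FALSE)
  }
  radii <- rules$intercept + rules$slope * v
  names(radii) <- rules$parameter
  if (cap) radii <- pmin(pmax(radii, 0), 10)
  radius_profile(params$label, radii, variant = params$variant, cap_applied = cap)
}

#' Invert a radius back to its experimental value
#'
#' @param radii named numeric vector of radii.
#' @param rules conversion rule table.
#' @return named numeric vector of experimental values.
#' @export
invert_radii <- function(radii, rules) {
  rules <- rules[match(names(radii), rules$parameter), ]
  if (anyNA(rules$parameter)) stop("radius name(s) not found in rules", call. = FALSE)
  v <- (radii - rules$intercept) / rules$slope
  names(v) <- rules$parameter
  v
}
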