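#' Construct a radius profile
#'
#' The 0--10 radius values of a material, one per SeDeM parameter, in the
#' canonical parameter order. Radii may exceed 10 when the experimental
#' value lies beyond the method's limit range and capping was not applied.
#'
#' @param label material name.
#' @param radii named numeric vector of radii.
#' @param variant scoring variant, `"odt15"` or `"classic12"`.
#' @param cap_applied whether radii were capped to the 0--10 band.
#' @return object of class `radius_profile`.
#' @export
radius_profile <- function(label, radii, variant = c("odt15", "classic12"),
                           cap_applied = FALSE) {
  variant <- match.arg(variant)
  radii <- unlist(radii)
  expected <- sedem_parameter_names(variant)
  if (!setequal(names(radii), expected)) {
    stop("radii must carry exactly the ", length(expected),
         " parameters of variant '", variant, "'", call. = FALSE)
  }
  radii <- radii[expected]
  if (any(!is.finite(radii)) || any(radii < 0)) {
    stop("radii must be finite and non-negative", call. = FALSE)
  }
  if (cap_applied && any(radii > 10)) {
    stop("cap_applied = TRUE but radii exceed 10", call. = FALSE)
  }
  structure(list(label = label, variant = variant, radii = radii,
                 cap_applied = cap_applied),
            class = "radius_profile")
}

#' @export
print.radius_profile <- function(x, ...) {
  cat("SeDeM radius profile:", x$label, sprintf("(%s)\n", x$variant))
  print(round_half_up(x$radii, 2))
  invisible(x)
}

#' Mean incidence factors
#'
#' Averages the radii within each incidence group: dimension (Da, Dc),
#' compressibility (Ie, IC, Icd), flowability (IH, angle of repose, flow
#' time), lubricity/stability (loss on drying, hygroscopicity),
#' lubricity/dosage (fines, homogeneity index) and, for the ODT variant,
#' disgregability (effervescence and the two disintegration times).
#'
#' @param profile a [radius_profile()].
#' @return data frame with columns `incidence`, `mean` (full precision)
#'   and `mean_2dp` (reported value, half-up rounding).
#' @export
#' @examples
#' prof <- radius_profile("demo", stats::setNames(rep(6, 12),
#'   sedem_parameter_names("classic12")), variant = "classic12")
#' incidence_means(prof)
incidence_means <- function(profile) {
  if (!inherits(profile, "radius_profile")) {
    stop("'profile' must be a radius_profile", call. = FALSE)
  }
  groups <- sedem_incidence_groups(profile$variant)
  m <- vapply(groups, function(p) mean(profile$radii[p]), numeric(1))
  data.frame(incidence = names(groups), mean = unname(m),
             mean_2dp = unname(round_half_up(m, 2)),
             stringsAsFactors = FALSE)
}

#' SeDeM index summary
#'
#' Computes the three global indices of the expert system from a radius
#' profile:
#' \itemize{
#'   \item IP (index parameter): the fraction of parameters whose radius
#'     is at least 5 (a radius of exactly 5 counts as acceptable);
#'   \item IPP (parameter profile index): the arithmetic mean of all radii;
#'   \item IGC / IGCB (index of good compressibility, with
#'     bucodispersibility for the 15-parameter variant): IPP multiplied by
#'     a polygon-to-circle reliability factor `f`.
#' }
#' An index of at least 5 reads "acceptable for direct compression" (grade
#' A); 3 to 5 is corrigible with a suitable excipient; below 3 inadequate.
#'
#' @param profile a [radius_profile()].
#' @param f reliability factor in (0, 1]; defaults to 0.952 for the
#'   12-parameter diagram and 0.950 for the 15-parameter ODT variant.
#' @param acceptable_radius radius threshold counted as acceptable in IP
#'   (default 5).
#' @return object of class `sedem_index`: a list with unrounded `ip`,
#'   `ipp`, `index` plus 2-decimal reported values (`ip_2dp`, `ipp_2dp`,
#'   `index_2dp`), the factor `f`, the index name (`"IGC"` or `"IGCB"`)
#'   and the `verdict`.
#' @export
#' @examples
#' prof <- radius_profile("demo", stats::setNames(rep(10, 12),
#'   sedem_parameter_names("classic12")), variant = "classic12")
#' index_summary(prof)  # IPP 10, IGC 9.52
index_summary <- function(profile, f = NULL, acceptable_radius = 5) {
  if (!inherits(profile, "radius_profile")) {
    stop("'profile' must be a radius_profile", call. = FALSE)
  }
  radii <- profile$radii
  if (!length(radii)) stop("empty radius profile", call. = FALSE)
  if (is.null(f)) f <- if (profile$variant == "classic12") 0.952 else 0.950
  stopifnot_scalar_number(f, "f", lower = 1e-12, upper = 1)
  ip <- sum(radii >= acceptable_radius) / length(radii)
  ipp <- mean(radii)
  index <- ipp * f
  verdict <- if (index >= 5) "A" else if (index >= 3) "corrigible" else "inadequate"
  structure(list(
    label = profile$label, variant = profile$variant,
    n = length(radii), f = f,
    index_name = if (profile$variant == "classic12") "IGC" else "IGCB",
    ip = ip, ipp = ipp, index = index,
    ip_2dp = round_half_up(ip, 2), ipp_2dp = round_half_up(ipp, 2),
    index_2dp = round_half_up(index, 2),
    verdict = verdict
  ), class = "sedem_index")
}

#' @export
print.sedem_index <- function(x, ...) {
  cat(sprintf("SeDeM indices: %s (%s, n = %d)\n", x$label, x$variant, x$n))
  cat(sprintf("  IP   = %.2f\n  IPP  = %.2f\n  %s%s = %.2f (f = %.3f)\n  verdict: %s\n",
              x$ip_2dp, x$ipp_2dp, x$index_name,
              if (x$index_name == "IGC") " " else "", x$index_2dp, x$f, x$verdict))
  invisible(x)
}

#' Corrective excipient dose
#'
#' Percent of a corrective excipient needed so that the blended value of a
#' deficient incidence reaches the target radius `target` (5 by default),
#' assuming the blend radius mixes linearly in the mass fractions of the
#' excipient (radius `re`) and the API (radius `rp`):
#' `CP (RE) + (100 - CP) (RP) = 100 R`, hence
#' `CP = 100 (R - RP) / (RE - RP)`.
#' The complementary quantity `100 (RE - R) / (RE - RP)` is the API
#' proportion of the corrected blend.
#'
#' @param re excipient incidence radius; must exceed both `rp` and
#'   `target` for a correction to be possible.
#' @param rp API (deficient material) incidence radius.
#' @param target target radius, default 5.
#' @return dose as percent of the blend, in \[0, 100\]. Returns 0 when the
#'   API already meets the target; values above 100 are clamped with a
#'   warning.
#' @export
#' @examples
#' # ludipress vs flurbiprofen compressibility incidences
#' corrective_dose(re = 7.07, rp = 3.00)  # 49.14 %
corrective_dose <- function(re, rp, target = 5) {
  stopifnot_scalar_number(re, "re", 0)
  stopifnot_scalar_number(rp, "rp", 0)
  stopifnot_scalar_number(target, "target", 0)
  if (rp >= target) return(0)
  if (re <= rp) stop("no correction possible: excipient radius 're' must exceed 'rp'",
                     call. = FALSE)
  if (re <= target) stop("excipient cannot correct: 're' does not exceed the target radius",
                         call. = FALSE)
  cp <- 100 * (target - rp) / (re - rp)
  if (cp > 100) {
    warning("corrective dose formula exceeded 100 %; clamped", call. = FALSE)
    cp <- 100
  }
  cp
}

#' Radar polygon of a radius profile
#'
#' Places the radii of a profile (or any numeric vector of length >= 3)
#' at equally spaced angles starting at twelve o'clock and proceeding
#' clockwise (the usual radar-chart layout), and computes the polygon area
#' by the shoelace formula. With all radii equal to `R0` the area is the
#' regular n-gon value `(n/2) sin(2 pi / n) R0^2`.
#'
#' @param profile a [radius_profile()] or a numeric vector of radii.
#' @return list with `vertices` (data frame: parameter, radius, angle, x,
#'   y) and `area`.
#' @export
#' @examples
#' radar_polygon(rep(10, 12))$area  # regular 12-gon: 300
radar_polygon <- function(profile) {
  radii <- if (inherits(profile, "radius_profile")) profile$radii else unlist(profile)
  n <- length(radii)
  if (n < 3) stop("a radar polygon needs at least 3 radii", call. = FALSE)
  if (any(!is.finite(radii)) || any(radii < 0)) {
    stop("radii must be finite and non-negative", call. = FALSE)
  }
  k <- seq_len(n) - 1
  angle <- pi / 2 - 2 * pi * k / n
  x <- radii * cos(angle)
  y <- radii * sin(angle)
  nxt <- c(seq_len(n)[-1], 1L)
  area <- abs(sum(x * y[nxt] - x[nxt] * y)) / 2
  vertices <- data.frame(
    parameter = if (is.null(names(radii))) paste0("p", seq_len(n)) else names(radii),
    radius = unname(radii), angle = angle, x = x, y = y,
    stringsAsFactors = FALSE
  )
  list(vertices = vertices, area = area)
}

#' Plot a SeDeM radar diagram
#'
#' Base-graphics radar plot of a radius profile with labelled axes and a
#' reference circle at the acceptability radius. Wrap in [grDevices::svg()]
#' (or any other device) to write a figure file.
#'
#' @param profile a [radius_profile()].
#' @param ref reference (acceptability) radius drawn as a dashed circle.
#' @param main plot title; defaults to the profile label.
#' @param ... further arguments passed to [graphics::plot()].
#' @return invisibly, the [radar_polygon()] of the profile.
#' @export
plot_sedem_radar <- function(profile, ref = 5, main = NULL, ...) {
  poly <- radar_polygon(profile)
  v <- poly$vertices
  rmax <- max(10, v$radius)
  if (is.null(main)) main <- if (inherits(profile, "radius_profile")) profile$label else ""
  graphics::plot(NA, xlim = c(-rmax, rmax) * 1.25, ylim = c(-rmax, rmax) * 1.25,
                 asp = 1, axes = FALSE, xlab = "", ylab = "", main = main, ...)
  th <- seq(0, 2 * pi, length.out = 241)
  for (rr in seq(2, 10, by = 2)) {
    graphics::lines(rr * cos(th), rr * sin(th), col = "grey85")
  }
  graphics::lines(ref * cos(th), ref * sin(th), col = "grey40", lty = 2)
  graphics::segments(0, 0, rmax * cos(v$angle), rmax * sin(v$angle), col = "grey85")
  graphics::polygon(v$x, v$y, border = "steelblue4", col = grDevices::adjustcolor("steelblue2", 0.4))
  graphics::text(1.15 * rmax * cos(v$angle), 1.15 * rmax * sin(v$angle),
                 labels = v$parameter, cex = 0.7)
  invisible(poly)
}
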