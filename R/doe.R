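#' Specify a design factor
#'
#' @param name factor name.
#' @param center actual level (percent of blend) at coded 0.
#' @param step percent change per coded unit; coded -1/+1 sit at
#'   `center - step` / `center + step`.
#' @return object of class `factor_spec`.
#' @export
#' @examples
#' factor_spec("ludipress", center = 52, step = 3)
factor_spec <- function(name, center, step) {
  stopifnot_scalar_number(center, "center")
  stopifnot_scalar_number(step, "step")
  if (step <= 0) stop("'step' must be positive", call. = FALSE)
  structure(list(name = name, center = center, step = step,
                 low = center - step, high = center + step),
            class = "factor_spec")
}

#' Generate a two-factor central composite design
#'
#' Builds the 4 factorial points (+/-1, +/-1), 4 axial points at coded
#' distance `alpha` and `n_center` center runs. For two factors
#' `alpha = sqrt(2)` makes the design rotatable (prediction variance of
#' the fitted quadratic depends only on distance from the center). Runs
#' are emitted in a fixed canonical order --- (-1,-1), (+alpha,0),
#' (-1,+1), (0,0), (0,+alpha), (-alpha,0), (0,-alpha), (+1,-1), (+1,+1),
#' extra center runs appended --- so a design is reproducible run-for-run;
#' randomization of run order is out of scope.
#'
#' @param factor1,factor2 [factor_spec()] objects.
#' @param alpha axial coded distance (default `sqrt(2)`; `alpha = 1` gives
#'   a face-centered design).
#' @param n_center number of center runs (default 1).
#' @return object of class `ccd_design`: a data frame with columns `run`,
#'   coded levels `c1`, `c2`, the actual levels under each factor's name,
#'   and 3-decimal truncated display levels (`<name>_display`); the factor
#'   specs and `alpha` are attached as attributes.
#' @export
#' @examples
#' generate_ccd(factor_spec("ludipress", 52, 3), factor_spec("ccs", 3, 2))
generate_ccd <- function(factor1, factor2, alpha = sqrt(2), n_center = 1) {
  if (!inherits(factor1, "factor_spec") || !inherits(factor2, "factor_spec")) {
    stop("'factor1' and 'factor2' must be factor_spec objects", call. = FALSE)
  }
  stopifnot_scalar_number(alpha, "alpha")
  if (alpha <= 0) stop("'alpha' must be positive", call. = FALSE)
  if (n_center < 1) stop("'n_center' must be at least 1", call. = FALSE)
  coded <- rbind(
    c(-1, -1), c(alpha, 0), c(-1, 1), c(0, 0), c(0, alpha),
    c(-alpha, 0), c(0, -alpha), c(1, -1), c(1, 1)
  )
  if (n_center > 1) {
    coded <- rbind(coded, matrix(0, nrow = n_center - 1, ncol = 2))
  }
  design <- data.frame(run = paste0("F", seq_len(nrow(coded))),
                       c1 = coded[, 1], c2 = coded[, 2],
                       stringsAsFactors = FALSE)
  design[[factor1$name]] <- factor1$center + design$c1 * factor1$step
  design[[factor2$name]] <- factor2$center + design$c2 * factor2$step
  design[[paste0(factor1$name, "_display")]] <- trunc_dec(design[[factor1$name]], 3)
  design[[paste0(factor2$name, "_display")]] <- trunc_dec(design[[factor2$name]], 3)
  structure(design, class = c("ccd_design", "data.frame"),
            factors = list(factor1, factor2), alpha = alpha, n_center = n_center)
}

#' Tablet composition from percent factor levels
#'
#' Composition arithmetic of a direct-compression tablet: the two design
#' factors and the fixed excipients are given as percent of tablet weight,
#' the API as a fixed dose in mg. The API percentage is whatever the
#' excipients leave (`100 - sum of excipient percents`), the tablet weight
#' follows as `api_dose / (api_percent/100)`, and each ingredient's mg
#' content as `percent x weight / 100`. Reported mg values and the tablet
#' weight are truncated to 3 decimals (display convention of the bundled
#' formulation table); unrounded values are kept alongside.
#'
#' @param ludipress,croscarmellose percent levels of the two variable
#'   excipients.
#' @param fixed named vector of fixed excipient percents (default: aerosil
#'   0.14, talc 2.36, aspartame 1, magnesium stearate 1).
#' @param api_dose API dose per tablet in mg (default 100).
#' @return object of class `odt_composition`: list with `percents`
#'   (including `api`), `api_percent`, `tablet_weight`, `mg`, and the
#'   3-decimal truncated `tablet_weight_display` / `mg_display`.
#' @export
#' @examples
#' composition_from_point(49, 1)$tablet_weight_display  # 219.780 mg
composition_from_point <- function(ludipress, croscarmellose,
                                   fixed = c(aerosil = 0.14, talc = 2.36,
                                             aspartame = 1, magnesium_stearate = 1),
                                   api_dose = 100) {
  stopifnot_scalar_number(ludipress, "ludipress", 0)
  stopifnot_scalar_number(croscarmellose, "croscarmellose", 0)
  stopifnot_scalar_number(api_dose, "api_dose", 1e-9)
  excip <- c(ludipress = unname(ludipress), croscarmellose = unname(croscarmellose), fixed)
  total <- sum(excip)
  if (total >= 100) {
    stop("excipient percents sum to ", format(total),
         " >= 100: no room for the API", call. = FALSE)
  }
  api_percent <- 100 - total
  tablet_weight <- api_dose / (api_percent / 100)
  percents <- c(excip, api = api_percent)
  mg <- percents * tablet_weight / 100
  structure(list(
    percents = percents, api_percent = api_percent, api_dose = api_dose,
    tablet_weight = tablet_weight, mg = mg,
    tablet_weight_display = trunc_dec(tablet_weight, 3),
    mg_display = trunc_dec(mg, 3)
  ), class = "odt_composition")
}

#' @export
print.odt_composition <- function(x, ...) {
  cat(sprintf("ODT composition: tablet weight %.3f mg (API %.3f %%)\n",
              x$tablet_weight_display, x$api_percent))
  print(data.frame(percent = x$percents, mg = x$mg_display))
  invisible(x)
}

#' Composition table for a whole design
#'
#' @param design a [generate_ccd()] design (or any data frame with the two
#'   factor-level columns).
#' @param levels which levels feed the arithmetic: the exact generated
#'   levels (`"exact"`) or the 3-decimal display levels (`"display"`).
#' @param ... passed to [composition_from_point()].
#' @return data frame, one row per run: percent levels, tablet weight and
#'   mg of every ingredient (3-decimal truncated display values).
#' @export
formulation_table <- function(design, levels = c("exact", "display"), ...) {
  levels <- match.arg(levels)
  factors <- attr(design, "factors")
  if (is.null(factors)) stop("'design' must come from generate_ccd()", call. = FALSE)
  n1 <- factors[[1]]$name
  n2 <- factors[[2]]$name
  col1 <- if (levels == "display") paste0(n1, "_display") else n1
  col2 <- if (levels == "display") paste0(n2, "_display") else n2
  rows <- lapply(seq_len(nrow(design)), function(i) {
    comp <- composition_from_point(design[[col1]][i], design[[col2]][i], ...)
    out <- data.frame(run = design$run[i],
                      t(c(stats::setNames(c(design[[col1]][i], design[[col2]][i]),
                                          c(n1, n2)),
                          tablet_weight = comp$tablet_weight_display)),
                      stringsAsFactors = FALSE)
    mg <- comp$mg_display
    names(mg) <- paste0(names(mg), "_mg")
    cbind(out, t(mg))
  })
  do.call(rbind, rows)
}

#' Fit a response-surface model on coded factors
#'
#' Ordinary least squares of a response measured on the design runs
#' against the coded factor levels: `y ~ c1 + c2` (linear) or the full
#' second-order model with squares and the interaction (quadratic). The
#' ANOVA compares the model to the intercept-only null: `SS_model =
#' SS_total - SS_residual`, `F = MS_model / MS_residual`, p-value from the
#' F distribution.
#'
#' @param design a [generate_ccd()] design.
#' @param response numeric response vector, one value per run.
#' @param order `"linear"` or `"quadratic"`.
#' @return object of class `rsm_fit`: list with the `lm` fit,
#'   `coefficients`, `fitted`, `residuals`, an `anova` data frame
#'   (df, SS, MS, F, p), `adequate_precision`, and a `degenerate` flag for
#'   constant responses.
#' @export
#' @examples
#' d <- generate_ccd(factor_spec("x1", 52, 3), factor_spec("x2", 3, 2))
#' y <- 2 + 3 * d$c1 - d$c2
#' fit_response_surface(d, y, "linear")$coefficients
fit_response_surface <- function(design, response, order = c("linear", "quadratic")) {
  order <- match.arg(order)
  if (length(response) != nrow(design)) {
    stop("'response' must have one value per design run", call. = FALSE)
  }
  dat <- data.frame(y = response, c1 = design$c1, c2 = design$c2)
  form <- if (order == "linear") y ~ c1 + c2
          else y ~ c1 + c2 + I(c1^2) + I(c2^2) + c1:c2
  p <- if (order == "linear") 3L else 6L
  if (nrow(dat) < p + 1L) {
    stop("need at least ", p + 1L, " runs to fit ", p, " coefficients", call. = FALSE)
  }
  fit <- stats::lm(form, data = dat)
  if (anyNA(stats::coef(fit))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  n <- nrow(dat)
  ss_tot <- sum((dat$y - mean(dat$y))^2)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_mod <- ss_tot - ss_res
  df_mod <- p - 1L
  df_res <- n - p
  degenerate <- ss_tot < 1e-12
  ms_mod <- ss_mod / df_mod
  ms_res <- ss_res / df_res
  fstat <- if (degenerate) 0 else ms_mod / ms_res
  pval <- if (degenerate) NA_real_ else stats::pf(fstat, df_mod, df_res, lower.tail = FALSE)
  anova_tab <- data.frame(
    source = c("model", "residual", "total"),
    df = c(df_mod, df_res, n - 1L),
    sum_sq = c(ss_mod, ss_res, ss_tot),
    mean_sq = c(ms_mod, ms_res, NA),
    F = c(fstat, NA, NA),
    p = c(pval, NA, NA)
  )
  out <- structure(list(
    model = fit, order = order, n = n, p = p,
    coefficients = stats::coef(fit),
    fitted = stats::fitted(fit), residuals = stats::residuals(fit),
    anova = anova_tab, degenerate = degenerate
  ), class = "rsm_fit")
  out$adequate_precision <- adequate_precision(out)
  out
}

#' Adequate-precision signal-to-noise statistic
#'
#' The design-of-experiments diagnostic
#' `(max fitted - min fitted) / sqrt(p * MS_residual / n)`, with `p` model
#' coefficients (including the intercept) and `n` runs; values above 4
#' indicate the model carries an adequate signal to navigate the design
#' space. With zero residual mean square the statistic is infinite and
#' flagged.
#'
#' @param fit an [fit_response_surface()] result.
#' @return numeric value (possibly `Inf`), with attribute `adequate`
#'   (logical: exceeds 4).
#' @export
adequate_precision <- function(fit) {
  if (!inherits(fit, "rsm_fit")) stop("'fit' must be an rsm_fit", call. = FALSE)
  ms_res <- fit$anova$mean_sq[2]
  span <- max(fit$fitted) - min(fit$fitted)
  # an exact fit leaves only floating-point dust in the residuals
  if (ms_res <= .Machine$double.eps^0.75 * (1 + span^2)) ms_res <- 0
  ap <- if (ms_res <= 0) {
    if (span > 0) Inf else 0
  } else {
    span / sqrt(fit$p * ms_res / fit$n)
  }
  structure(ap, adequate = is.finite(ap) && ap > 4 || is.infinite(ap))
}

#' @export
print.rsm_fit <- function(x, ...) {
  cat(sprintf("Response-surface fit (%s, n = %d)\n", x$order, x$n))
  print(round(x$coefficients, 6))
  cat(sprintf("F = %.4g on (%d, %d) df, p = %.4g; adequate precision = %.4g\n",
              x$anova$F[1], x$anova$df[1], x$anova$df[2], x$anova$p[1],
              as.numeric(x$adequate_precision)))
  invisible(x)
}
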