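#' Compendial quality limits
#'
#' Default acceptance limits applied by [limit_checks()]: friability below
#' 1 % mass loss, disintegration below 180 s (the pharmacopoeial ODT
#' limit of 3 minutes), assay within 95--105 % of label claim, and weight
#' variation within +/- 7.5 % (the USP tier for tablets of 130--324 mg).
#'
#' @param friability_max maximum friability, percent.
#' @param disintegration_max maximum disintegration time, seconds.
#' @param assay_range length-2 acceptance band for assay, percent.
#' @param weight_tolerance_pct weight-variation tolerance, percent.
#' @return named list of limits.
#' @export
quality_limits <- function(friability_max = 1, disintegration_max = 180,
                           assay_range = c(95, 105), weight_tolerance_pct = 7.5) {
  list(friability_max = friability_max,
       disintegration_max = disintegration_max,
       assay_range = assay_range,
       weight_tolerance_pct = weight_tolerance_pct)
}

#' Weight-variation test
#'
#' Pass if every individual tablet weight lies within `tolerance_pct`
#' percent of the batch mean weight (the simple single-tier check; the
#' full two-stage compendial procedure is out of scope).
#'
#' @param weights individual tablet weights, mg.
#' @param tolerance_pct allowed deviation from the mean, percent
#'   (default 7.5, the 130--324 mg tier).
#' @return list with `pass`, `mean`, `max_deviation_pct`, `tolerance_pct`
#'   and `n`.
#' @export
#' @examples
#' weight_variation(rep(220, 20))$pass
weight_variation <- function(weights, tolerance_pct = 7.5) {
  weights <- as.numeric(weights)
  if (length(weights) < 2) stop("need at least 2 tablet weights", call. = FALSE)
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("weights must be positive and finite", call. = FALSE)
  }
  m <- mean(weights)
  dev <- 100 * abs(weights - m) / m
  list(pass = all(dev <= tolerance_pct), mean = m,
       max_deviation_pct = max(dev), tolerance_pct = tolerance_pct,
       n = length(weights))
}

#' Quality-attribute limit checks for a tablet batch
#'
#' Evaluates a batch against the limits of [quality_limits()]. `batch` is
#' a list (or one-row data frame) with any of the fields `label`,
#' `weights` (individual tablet weights, mg), `weight_mean` and
#' `weight_nominal` (mg; used for a mean-vs-theoretical weight check when
#' individual weights are absent), `friability` (%), `disintegration_s`,
#' `assay` (%). Absent fields are reported as not evaluated and do not
#' affect the overall verdict.
#'
#' @param batch batch measurements (see Details).
#' @param limits a [quality_limits()] list.
#' @return object of class `quality_report`: data frame with one row per
#'   test (`test`, `value`, `limit`, `pass`) plus attributes `label` and
#'   `overall_pass` (all evaluated tests pass).
#' @export
#' @examples
#' limit_checks(list(label = "F1", friability = 0.56, disintegration_s = 11))
limit_checks <- function(batch, limits = quality_limits()) {
  batch <- as.list(batch)
  rows <- list()
  add <- function(test, value, limit, pass) {
    rows[[length(rows) + 1]] <<- data.frame(test = test, value = value,
                                            limit = limit, pass = pass,
                                            stringsAsFactors = FALSE)
  }
  if (!is.null(batch$weights)) {
    wv <- weight_variation(batch$weights, limits$weight_tolerance_pct)
    add("weight_variation", wv$max_deviation_pct,
        sprintf("<= %.1f %% of mean", limits$weight_tolerance_pct), wv$pass)
  } else if (!is.null(batch$weight_mean) && !is.null(batch$weight_nominal)) {
    dev <- 100 * abs(batch$weight_mean - batch$weight_nominal) / batch$weight_nominal
    add("mean_weight_vs_nominal", dev,
        sprintf("<= %.1f %% of nominal", limits$weight_tolerance_pct),
        dev <= limits$weight_tolerance_pct)
  }
  if (!is.null(batch$friability)) {
    add("friability", batch$friability,
        sprintf("< %g %%", limits$friability_max),
        batch$friability < limits$friability_max)
  }
  if (!is.null(batch$disintegration_s)) {
    add("disintegration", batch$disintegration_s,
        sprintf("< %g s", limits$disintegration_max),
        batch$disintegration_s < limits$disintegration_max)
  }
  if (!is.null(batch$assay)) {
    add("assay", batch$assay,
        sprintf("%g--%g %%", limits$assay_range[1], limits$assay_range[2]),
        batch$assay >= limits$assay_range[1] & batch$assay <= limits$assay_range[2])
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(test = character(), value = numeric(), limit = character(),
               pass = logical(), stringsAsFactors = FALSE)
  structure(report, class = c("quality_report", "data.frame"),
            label = if (is.null(batch$label)) "" else batch$label,
            overall_pass = nrow(report) > 0 && all(report$pass))
}

#' @export
print.quality_report <- function(x, ...) {
  cat("Quality report", attr(x, "label"),
      if (attr(x, "overall_pass")) "- PASS\n" else "- FAIL\n")
  print.data.frame(x)
  invisible(x)
}
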