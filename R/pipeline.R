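#' Pipeline configuration
#'
#' Default settings of the tablet-development workflow; every entry can
#' be overridden. The defaults reproduce the bundled study's conditions:
#' the 15-parameter ODT scoring variant with reliability factor 0.950
#' (0.952 for 12-parameter profiles), ludipress 52 +/- 3 % and
#' croscarmellose sodium 3 +/- 2 % in a rotatable CCD with one center
#' run, a 100 mg API dose with the standard fixed excipients, all four
#' release models, and a 90 % specification limit with a one-sided 95 %
#' bound for shelf life.
#'
#' @param ... named overrides of the defaults.
#' @return named list of settings.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    variant = "odt15",
    factor1 = list(name = "ludipress", center = 52, step = 3),
    factor2 = list(name = "croscarmellose", center = 3, step = 2),
    alpha = sqrt(2),
    n_center = 1,
    api_dose = 100,
    fixed_excipients = c(aerosil = 0.14, talc = 2.36,
                         aspartame = 1, magnesium_stearate = 1),
    kinetic_models = c("first_order", "higuchi", "hixson_crowell", "weibull"),
    spec_limit = 90,
    confidence = 0.95,
    horizon = Inf
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the full tablet-development analysis pipeline
#'
#' Binds the package's stages into the study workflow: SeDeM(-ODT)
#' scoring of the supplied radius profiles, design generation and
#' composition arithmetic, quality limit checks, release-kinetics fitting
#' with best-model selection, and shelf-life estimation. Each stage is
#' optional: pass `NULL` to skip it. Stage errors are collected and
#' re-raised together with their stage names.
#'
#' @param profiles named list of [radius_profile()] objects (default: the
#'   bundled blend radii).
#' @param quality data frame of batch measurements in the layout of
#'   [flurbiprofen_quality()], or `NULL`.
#' @param dissolution named list of [dissolution_profile()] objects, or
#'   `NULL`.
#' @param stability named list of [stability_series()] objects, or `NULL`.
#' @param config a [pipeline_config()] list.
#' @param out_json optional path; the report is serialized there
#'   deterministically (no timestamps; identical inputs give
#'   byte-identical files).
#' @return object of class `odt_pipeline_report`: list with elements
#'   `sedem` (index report data frame), `incidences`, `design`,
#'   `compositions`, `quality`, `kinetics`, `shelf_life`.
#' @export
#' @examples
#' rep <- run_odt_pipeline(profiles = flurbiprofen_blends(),
#'                         quality = flurbiprofen_quality(),
#'                         stability = flurbiprofen_stability())
#' rep$sedem
run_odt_pipeline <- function(profiles = flurbiprofen_blends(),
                             quality = flurbiprofen_quality(),
                             dissolution = NULL,
                             stability = flurbiprofen_stability(),
                             config = pipeline_config(),
                             out_json = NULL) {
  report <- list()
  errors <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors <<- c(errors, sprintf("%s: %s", name, conditionMessage(e)))
      NULL
    })
  }

  if (!is.null(profiles)) {
    report$sedem <- stage("sedem_scoring", {
      sums <- lapply(profiles, index_summary)
      df <- do.call(rbind, lapply(sums, function(s) {
        data.frame(label = s$label, IP = s$ip_2dp, IPP = s$ipp_2dp,
                   index = s$index_name, value = s$index_2dp,
                   verdict = s$verdict, stringsAsFactors = FALSE)
      }))
      rownames(df) <- NULL
      df
    })
    report$incidences <- stage("incidence_means", {
      inc <- lapply(profiles, incidence_means)
      df <- do.call(rbind, Map(function(label, d) {
        cbind(label = label, d[, c("incidence", "mean_2dp")])
      }, names(inc), inc))
      rownames(df) <- NULL
      df
    })
  }

  report$design <- stage("doe_design", {
    f1 <- do.call(factor_spec, config$factor1)
    f2 <- do.call(factor_spec, config$factor2)
    generate_ccd(f1, f2, alpha = config$alpha, n_center = config$n_center)
  })
  if (!is.null(report$design)) {
    report$compositions <- stage("composition", {
      formulation_table(report$design, fixed = config$fixed_excipients,
                        api_dose = config$api_dose)
    })
  }

  if (!is.null(quality)) {
    report$quality <- stage("quality_attributes", {
      nominal <- if (!is.null(report$compositions)) {
        stats::setNames(report$compositions$tablet_weight,
                        report$compositions$run)
      } else {
        NULL
      }
      rows <- lapply(seq_len(nrow(quality)), function(i) {
        b <- as.list(quality[i, ])
        b$label <- b$run
        if (!is.null(nominal) && b$run %in% names(nominal)) {
          b$weight_nominal <- nominal[[b$run]]
        }
        rep_i <- limit_checks(b)
        data.frame(label = b$label, overall_pass = attr(rep_i, "overall_pass"),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
  }

  if (!is.null(dissolution)) {
    report$kinetics <- stage("release_kinetics", {
      rows <- lapply(dissolution, function(p) {
        fits <- fit_all_kinetics(p, models = config$kinetic_models)
        r2 <- vapply(fits, function(f) f$r_squared, numeric(1))
        data.frame(label = p$label, best_model = select_best_model(fits),
                   t(round(r2, 4)), stringsAsFactors = FALSE)
      })
      df <- do.call(rbind, rows)
      rownames(df) <- NULL
      df
    })
  }

  if (!is.null(stability)) {
    report$shelf_life <- stage("stability_shelf_life", {
      rows <- lapply(stability, function(s) {
        est <- estimate_shelf_life(s, spec_limit = config$spec_limit,
                                   confidence = config$confidence,
                                   horizon = config$horizon)
        data.frame(label = est$label, slope = est$slope,
                   intercept = est$intercept,
                   shelf_life_months = est$shelf_life,
                   stringsAsFactors = FALSE)
      })
      df <- do.call(rbind, rows)
      rownames(df) <- NULL
      df
    })
  }

  if (length(errors)) {
    stop("pipeline stage error(s):\n  ", paste(errors, collapse = "\n  "),
         call. = FALSE)
  }
  class(report) <- "odt_pipeline_report"
  if (!is.null(out_json)) {
    serial <- report
    class(serial) <- NULL
    if (!is.null(serial$design)) serial$design <- as.data.frame(serial$design)
    jsonlite::write_json(serial, out_json, digits = 10, pretty = TRUE,
                         dataframe = "rows", na = "string")
  }
  report
}

#' @export
print.odt_pipeline_report <- function(x, ...) {
  cat("ODT development pipeline report; stages:",
      paste(names(x), collapse = ", "), "\n")
  if (!is.null(x$sedem)) {
    cat("\nSeDeM indices:\n")
    print(x$sedem)
  }
  if (!is.null(x$shelf_life)) {
    cat("\nShelf life (months):\n")
    print(x$shelf_life)
  }
  invisible(x)
}
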