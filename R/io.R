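#' Read SeDeM material data from CSV
#'
#' Reads a comma-separated file (UTF-8, header row mandatory, decimal
#' point) with one row per material: a `label` column plus one column per
#' SeDeM parameter of the chosen variant. Columns may hold experimental
#' values (`mode = "values"`) or pre-converted radii (`mode = "radii"`).
#'
#' @param path CSV file path.
#' @param variant scoring variant.
#' @param mode whether columns are experimental values or radii.
#' @return named list of [radius_profile()] objects (values are converted
#'   via [convert_parameters()]).
#' @export
read_sedem_csv <- function(path, variant = c("odt15", "classic12"),
                           mode = c("radii", "values")) {
  variant <- match.arg(variant)
  mode <- match.arg(mode)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"label" %in% names(df)) stop("CSV needs a 'label' column", call. = FALSE)
  pars <- sedem_parameter_names(variant)
  missing <- setdiff(pars, names(df))
  if (length(missing)) {
    stop("CSV missing parameter column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    vals <- unlist(df[i, pars])
    if (mode == "radii") {
      radius_profile(df$label[i], vals, variant = variant)
    } else {
      convert_parameters(powder_parameter_set(df$label[i], vals, variant))
    }
  })
  stats::setNames(out, df$label)
}

#' Read dissolution profiles from CSV
#'
#' Expects columns `label`, `time_min`, `release_pct`; one profile per
#' label.
#'
#' @param path CSV file path.
#' @return named list of [dissolution_profile()] objects.
#' @export
read_dissolution_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "time_min", "release_pct")
  if (!all(need %in% names(df))) {
    stop("CSV needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  out <- lapply(split(df, df$label), function(d) {
    d <- d[order(d$time_min), ]
    dissolution_profile(d$time_min, d$release_pct, label = d$label[1])
  })
  out[unique(df$label)]
}

#' Read stability series from CSV
#'
#' Expects columns `label`, `month`, `assay_pct`; one series per label.
#'
#' @param path CSV file path.
#' @return named list of [stability_series()] objects.
#' @export
read_stability_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "month", "assay_pct")
  if (!all(need %in% names(df))) {
    stop("CSV needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  out <- lapply(split(df, df$label), function(d) {
    d <- d[order(d$month), ]
    stability_series(d$label[1], d$month, d$assay_pct)
  })
  out[unique(df$label)]
}

#' Write an index report
#'
#' Serializes a list of [index_summary()] results to JSON (or CSV). JSON
#' output is deterministic: identical inputs give byte-identical files.
#'
#' @param summaries list of `sedem_index` objects.
#' @param path output file; format chosen by extension (`.json` / `.csv`).
#' @return invisibly, the report data frame.
#' @export
write_index_report <- function(summaries, path) {
  df <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(label = s$label, variant = s$variant, n = s$n,
               IP = s$ip_2dp, IPP = s$ipp_2dp, f = s$f,
               index = s$index_name, value = s$index_2dp,
               verdict = s$verdict, stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, digits = NA, pretty = TRUE)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(df)
}
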