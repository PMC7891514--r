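#' Analyte configuration
#'
#' Per-analyte settings used throughout the package: the conventional
#' population (inter-individual) reference range — overall and, where
#' published, per sex — the analytical coefficient of variation CVa (percent),
#' the number of decimals used when formatting results, and the normal quantile
#' `z` for 95% intervals. The configuration is a tidy tibble with one row per
#' (analyte, stratum):
#'
#' * `analyte`, `units`
#' * `sex` — `"overall"`, `"M"` or `"F"`
#' * `lower`, `upper` — population reference range in analyte units
#' * `cva_percent` — analytical CV in percent
#' * `display_decimals`, `z_value`
#'
#' `analyte_defaults()` ships the four serum nutrition markers the package is
#' built around: transferrin (TRF), albumin (ALB), retinol-binding protein
#' (RBP) and transthyretin (TTR), with routinely used Japanese adult reference
#' ranges and the analytical CVs of the assay lot used to motivate them.
#' `read_analyte_config()` loads the same structure from YAML or JSON, either
#' as a list keyed by analyte or as a flat table.
#'
#' @return A config tibble as described above.
#' @export
#' @examples
#' analyte_defaults()
#' population_range(analyte_defaults(), "TRF", sex = "F")
analyte_defaults <- function() {
  tibble::tribble(
    ~analyte, ~units,    ~sex,      ~lower, ~upper, ~cva_percent, ~display_decimals,
    "TRF",    "mg/dL",   "overall", 190,    340,    1.07,         0L,
    "TRF",    "mg/dL",   "M",       190,    300,    1.07,         0L,
    "TRF",    "mg/dL",   "F",       200,    340,    1.07,         0L,
    "ALB",    "g/dL",    "overall", 3.8,    5.2,    2.88,         1L,
    "RBP",    "mg/dL",   "overall", 2.7,    6.0,    1.38,         1L,
    "RBP",    "mg/dL",   "M",       2.7,    6.0,    1.38,         1L,
    "RBP",    "mg/dL",   "F",       1.9,    4.6,    1.38,         1L,
    "TTR",    "mg/dL",   "overall", 22.0,   44.0,   1.83,         1L
  ) |>
    dplyr::mutate(z_value = 1.96)
}

validate_config <- function(config) {
  needed <- c("analyte", "sex", "lower", "upper", "cva_percent",
              "display_decimals", "z_value")
  missing <- setdiff(needed, names(config))
  if (length(missing) > 0L) {
    stop_persref(sprintf("Analyte config is missing column(s): %s",
                         paste(missing, collapse = ", ")),
                 "persref_schema_error")
  }
  if (any(config$lower >= config$upper)) {
    stop_persref("Analyte config: every population range needs lower < upper.",
                 "persref_validation_error")
  }
  if (any(!is.finite(config$cva_percent) | config$cva_percent < 0)) {
    stop_persref("Analyte config: cva_percent must be finite and >= 0.",
                 "persref_validation_error")
  }
  if (any(config$z_value <= 0)) {
    stop_persref("Analyte config: z_value must be positive.",
                 "persref_validation_error")
  }
  invisible(config)
}

#' @rdname analyte_defaults
#' @param path YAML or JSON file. Either a flat table of the config columns or
#'   a mapping `analyte -> {units, cva_percent, display_decimals, z_value,
#'   range: {lower, upper}, range_m: ..., range_f: ...}`.
#' @export
read_analyte_config <- function(path) {
  if (!file.exists(path)) {
    stop_persref(sprintf("Config file not found: %s", path), "persref_io_error")
  }
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  rows <- purrr::imap(doc, function(entry, analyte) {
    ranges <- list(overall = entry$range, M = entry$range_m, F = entry$range_f)
    ranges <- purrr::compact(ranges)
    purrr::imap_dfr(ranges, function(rg, sexname) {
      tibble::tibble(
        analyte = analyte,
        units = entry$units %||% "",
        sex = sexname,
        lower = as.numeric(rg$lower),
        upper = as.numeric(rg$upper),
        cva_percent = as.numeric(entry$cva_percent %||% 0),
        display_decimals = as.integer(entry$display_decimals %||% 1L),
        z_value = as.numeric(entry$z_value %||% 1.96)
      )
    })
  })
  config <- dplyr::bind_rows(rows)
  validate_config(config)
  config
}

#' Look up the population reference range for an analyte
#'
#' Sex-specific ranges are used when published for the record's sex;
#' `"U"` (unspecified) and analytes without sexed ranges fall back to the
#' overall range.
#'
#' @param config a config tibble, e.g. [analyte_defaults()].
#' @param analyte analyte code.
#' @param sex `"M"`, `"F"`, `"U"` or `"overall"`.
#' @return One-row tibble `method, lower, upper, center, half_width, n_used`
#'   (method `"population"`), pipeline-compatible with the interval
#'   constructors.
#' @export
population_range <- function(config, analyte, sex = "overall") {
  validate_config(config)
  rows <- config[config$analyte == analyte, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop_persref(sprintf("Analyte '%s' not present in config.", analyte),
                 "persref_lookup_error")
  }
  hit <- rows[rows$sex == sex, , drop = FALSE]
  if (nrow(hit) == 0L) hit <- rows[rows$sex == "overall", , drop = FALSE]
  if (nrow(hit) == 0L) {
    stop_persref(sprintf("No overall population range for analyte '%s'.", analyte),
                 "persref_lookup_error")
  }
  new_interval("population",
               center = (hit$lower[1] + hit$upper[1]) / 2,
               lower = hit$lower[1], upper = hit$upper[1], n_used = 0L)
}
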