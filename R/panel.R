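#' Longitudinal laboratory panels
#'
#' A *panel* is a tidy tibble of repeated measurements of one analyte, one row
#' per (subject, visit):
#'
#' * `subject_id` — character subject identifier,
#' * `sex` — `"M"`, `"F"` or `"U"` (unspecified),
#' * `visit_index` — integer visit number, contiguous from 1 per subject,
#' * `analyte` — analyte code (e.g. `"TRF"`),
#' * `value` — measured concentration, finite and non-negative.
#'
#' All downstream functions take this tibble as their first argument, so panels
#' flow through the pipe. `read_panel()` reads a delimited file (comma by
#' default, tab autodetected) and returns the validated rows for one analyte;
#' `write_panel()` writes a panel back in the same format; `as_panel()`
#' validates and normalises an in-memory data frame.
#'
#' @param path file path of a delimited text file with header
#'   `subject_id,sex,visit_index,analyte,value`.
#' @param analyte analyte code to extract; must be present in the file.
#' @param reindex_visits if `TRUE`, the observed visits of each subject are
#'   renumbered 1..k in increasing order of the stored index, so panels with
#'   gaps (e.g. a missed visit) become contiguous. Default `FALSE`: gaps are a
#'   validation error, because cumulative interval estimation depends on visit
#'   order.
#' @param x data frame with the panel columns above.
#' @param panel a panel tibble.
#' @param delim field delimiter for `write_panel()` (default comma).
#'
#' @return `read_panel()` and `as_panel()` return a panel tibble ordered by
#'   `(subject_id, visit_index)`. `write_panel()` returns `path` invisibly.
#' @name panel_io
NULL

panel_columns <- c("subject_id", "sex", "visit_index", "analyte", "value")

#' @rdname panel_io
#' @export
read_panel <- function(path, analyte, reindex_visits = FALSE) {
  if (!file.exists(path)) {
    stop_persref(sprintf("File not found: %s", path), "persref_io_error")
  }
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  raw <- readr::read_delim(
    path,
    delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  missing <- setdiff(panel_columns, names(raw))
  if (length(missing) > 0L) {
    stop_persref(sprintf("Missing required column(s): %s",
                         paste(missing, collapse = ", ")),
                 "persref_schema_error")
  }
  value_num <- suppressWarnings(as.numeric(raw$value))
  bad <- which(!is.na(raw$value) & is.na(value_num))
  if (length(bad) > 0L) {
    stop_persref(sprintf("Non-numeric value(s) in column `value` at data row(s): %s",
                         paste(utils::head(bad, 5L), collapse = ", ")),
                 "persref_parse_error")
  }
  raw$value <- value_num
  raw$visit_index <- suppressWarnings(as.integer(raw$visit_index))
  out <- dplyr::filter(raw, .data$analyte == .env$analyte)
  if (nrow(out) == 0L) {
    stop_persref(sprintf("No rows for analyte '%s' in %s", analyte, path),
                 "persref_validation_error")
  }
  as_panel(out, reindex_visits = reindex_visits)
}

#' @rdname panel_io
#' @export
as_panel <- function(x, reindex_visits = FALSE) {
  x <- tibble::as_tibble(x)[panel_columns]
  x$subject_id <- as.character(x$subject_id)
  x$sex <- as.character(x$sex)
  x$visit_index <- as.integer(x$visit_index)
  x$value <- as.numeric(x$value)
  x <- dplyr::arrange(x, .data$subject_id, .data$visit_index)
  if (reindex_visits) {
    x <- x |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::mutate(visit_index = dplyr::row_number()) |>
      dplyr::ungroup()
  }
  assert_panel(x)
  x
}

# hard invariants shared by as_panel() and validate_panel()
panel_breaches <- function(panel) {
  breaches <- character(0)
  if (nrow(panel) == 0L) {
    return("no records")
  }
  if (length(unique(panel$analyte)) > 1L) {
    breaches <- c(breaches, sprintf(
      "multiple analytes in one panel: %s",
      paste(unique(panel$analyte), collapse = ", ")))
  }
  bad_sex <- setdiff(unique(panel$sex), c("M", "F", "U"))
  if (length(bad_sex) > 0L) {
    breaches <- c(breaches, sprintf("invalid sex code(s): %s",
                                    paste(bad_sex, collapse = ", ")))
  }
  dup <- panel |>
    dplyr::count(.data$subject_id, .data$visit_index) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    breaches <- c(breaches, sprintf(
      "duplicate (subject, visit) pair(s): %s",
      paste(sprintf("(%s, %d)", dup$subject_id, dup$visit_index), collapse = "; ")))
  }
  gaps <- panel |>
    dplyr::summarise(
      ok = identical(sort(.data$visit_index), seq_along(.data$visit_index)),
      .by = "subject_id"
    ) |>
    dplyr::filter(!.data$ok)
  if (nrow(gaps) > 0L) {
    breaches <- c(breaches, sprintf(
      "visit indices not contiguous from 1 for subject(s): %s (use reindex_visits = TRUE to renumber)",
      paste(gaps$subject_id, collapse = ", ")))
  }
  if (anyNA(panel$value) || any(!is.finite(panel$value)) || any(panel$value < 0, na.rm = TRUE)) {
    breaches <- c(breaches, "values must be finite and non-negative")
  }
  breaches
}

assert_panel <- function(panel) {
  breaches <- panel_breaches(panel)
  if (length(breaches) > 0L) {
    stop_persref(paste0("Invalid panel:\n  - ",
                        paste(breaches, collapse = "\n  - ")),
                 "persref_validation_error")
  }
  invisible(panel)
}

#' @rdname panel_io
#' @export
write_panel <- function(panel, path, delim = ",") {
  readr::write_delim(panel[panel_columns], path, delim = delim)
  invisible(path)
}

#' Validate a panel against the balanced-design requirements
#'
#' Runs every structural invariant (single analyte, no duplicate visits,
#' contiguous visit numbering, finite non-negative values) plus minimum-size
#' requirements, and returns the result as a tidy report rather than an error,
#' so callers can display all problems at once.
#'
#' @param panel a panel tibble (see [read_panel()]).
#' @param min_subjects minimum number of subjects required (default 2).
#' @param min_visits minimum number of visits required of *every* subject
#'   (default 2).
#' @return A tibble with one row per check: `check`, `passed`, `detail`.
#'   The attribute `"passed"` carries the overall verdict and
#'   `"visit_counts"` a per-subject count table.
#' @export
#' @examples
#' p <- simulate_panel(n_subjects = 4, n_visits = 3, mu0 = 100, sigma0 = 10,
#'                     sigma_eps = 5, seed = 1)
#' validate_panel(p, min_subjects = 4, min_visits = 3)
validate_panel <- function(panel, min_subjects = 2L, min_visits = 2L) {
  counts <- if (nrow(panel) > 0L) {
    dplyr::count(panel, .data$subject_id, name = "n_visits")
  } else {
    tibble::tibble(subject_id = character(0), n_visits = integer(0))
  }
  breaches <- panel_breaches(panel)
  struct_ok <- length(breaches) == 0L
  n_subj <- nrow(counts)
  short <- counts$subject_id[counts$n_visits < min_visits]
  report <- tibble::tibble(
    check = c("structure", "min_subjects", "min_visits"),
    passed = c(struct_ok,
               n_subj >= min_subjects,
               n_subj > 0L && length(short) == 0L),
    detail = c(
      if (struct_ok) "all invariants hold" else paste(breaches, collapse = "; "),
      sprintf("%d subject(s), %d required", n_subj, min_subjects),
      if (length(short) == 0L) {
        sprintf("all subjects have >= %d visits", min_visits)
      } else {
        sprintf("subject(s) below %d visits: %s", min_visits,
                paste(short, collapse = ", "))
      }
    )
  )
  attr(report, "passed") <- all(report$passed)
  attr(report, "visit_counts") <- counts
  report
}

#' @rdname validate_panel
#' @export
panel_is_valid <- function(panel, min_subjects = 2L, min_visits = 2L) {
  isTRUE(attr(validate_panel(panel, min_subjects, min_visits), "passed"))
}

# TRUE iff every subject has the same visits 1..T
panel_is_balanced <- function(panel) {
  counts <- dplyr::count(panel, .data$subject_id)
  nrow(counts) > 0L && length(unique(counts$n)) == 1L
}

assert_balanced <- function(panel, min_subjects = 2L, min_visits = 2L) {
  assert_panel(panel)
  counts <- dplyr::count(panel, .data$subject_id)
  if (length(unique(counts$n)) != 1L) {
    stop_persref("Panel must be balanced (every subject measured at every visit).",
                 "persref_precondition_error")
  }
  if (nrow(counts) < min_subjects || counts$n[1] < min_visits) {
    stop_persref(sprintf("Panel must have >= %d subjects and >= %d visits.",
                         min_subjects, min_visits),
                 "persref_precondition_error")
  }
  invisible(panel)
}
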