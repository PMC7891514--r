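#' Flag an observation against a reference interval
#'
#' Closed-interval convention: boundary values count as `"within"`, matching
#' how reference ranges are conventionally read.
#'
#' @param value numeric observation(s).
#' @param lower,upper interval bounds (recycled against `value`), or pass a
#'   one-row interval tibble as `interval`.
#' @param interval optional interval tibble (overrides `lower`/`upper`).
#' @return character vector: `"within"`, `"below"` or `"above"`.
#' @export
#' @examples
#' flag_observation(c(0.5, 5, 10, 12), lower = 1, upper = 10)
flag_observation <- function(value, lower = NULL, upper = NULL, interval = NULL) {
  if (!is.null(interval)) {
    lower <- interval$lower
    upper <- interval$upper
  }
  check_number(value, "value")
  check_number(lower, "lower")
  check_number(upper, "upper")
  dplyr::case_when(
    value < lower ~ "below",
    value > upper ~ "above",
    .default = "within"
  )
}

#' Cumulative interval trajectory for one subject
#'
#' Re-estimates a personal reference interval at every visit as measurements
#' accrue, the construction behind per-subject monitoring charts. Two modes:
#'
#' * `"prospective"` (default): the interval judging visit k is built from
#'   visits 1..k−1 only — the clinically meaningful alarm semantics, since a
#'   new result must be compared against what was known before it arrived.
#' * `"retrospective"`: the interval at step k uses visits 1..k, reproducing
#'   cumulative trajectory curves.
#'
#' Availability per method: the naive and prediction-interval methods need a
#' sample SD, so they first become evaluable once two prior (prospective) or
#' current (retrospective) visits exist; the RCV method likewise needs the
#' cumulative CV; the Bayesian method is evaluable from the first observation
#' (and even before any, where it equals the population prior). Whenever a
#' method is not yet evaluable — including every method at the very first
#' visit — the subject's population reference range stands in, so the first
#' measurement is judged against the conventional range. Steps whose interval
#' cannot be formed at all are flagged `not_evaluable`.
#'
#' @param panel a panel tibble.
#' @param subject_id subject to follow.
#' @param method one of `"naive"`, `"rcv"`, `"tango"`, `"bayes"`,
#'   `"population"`.
#' @param config analyte config tibble (default [analyte_defaults()]), used
#'   for the population range, CVa and z.
#' @param components `ref_components` for the Bayesian method; if `NULL` and
#'   needed, estimated from the full panel.
#' @param mode `"prospective"` or `"retrospective"`.
#' @param alpha error rate for the prediction-interval multiplier.
#' @param z normal quantile for naive/rcv/bayes.
#' @param cvi_source `"subject"` (cumulative own CV, default) or `"panel"`.
#' @return A `ref_trajectory` tibble, one row per visit: `subject_id, method,
#'   mode, k, observation, interval_method, center, lower, upper, flag`.
#'   `interval_method` records which interval actually judged the step (the
#'   requested method, or `"population"` while it is not yet evaluable).
#' @export
#' @examples
#' p <- simulate_panel(mu0 = 280, sigma0 = 27.77, sigma_eps = 12.88,
#'                     seed = 1, analyte = "TRF")
#' cumulative_trajectory(p, "S01", "tango")
cumulative_trajectory <- function(panel, subject_id, method,
                                  config = analyte_defaults(),
                                  components = NULL,
                                  mode = c("prospective", "retrospective"),
                                  alpha = 0.05, z = 1.96,
                                  cvi_source = c("subject", "panel")) {
  assert_panel(panel)
  mode <- match.arg(mode)
  cvi_source <- match.arg(cvi_source)
  known <- c("naive", "rcv", "tango", "bayes", "population")
  if (!(length(method) == 1L && method %in% known)) {
    stop_persref(sprintf("Unknown method '%s' (valid: %s).",
                         paste(method, collapse = ","),
                         paste(known, collapse = ", ")),
                 "persref_usage_error")
  }
  rows <- panel[panel$subject_id == subject_id, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop_persref(sprintf("Unknown subject '%s'.", subject_id),
                 "persref_lookup_error")
  }
  rows <- dplyr::arrange(rows, .data$visit_index)
  analyte <- rows$analyte[1]
  pop <- population_range(config, analyte, sex = rows$sex[1])
  cva <- config_field(config, analyte, "cva_percent", default = 0)
  if (method == "bayes" && is.null(components)) {
    components <- estimate_components(panel)
  }
  panel_cvi <- if (cvi_source == "panel") {
    mean(subject_summaries(panel)$cv_percent)
  } else {
    NA_real_
  }

  values <- rows$value
  steps <- purrr::map(seq_along(values), function(k) {
    hist <- if (mode == "prospective") values[seq_len(k - 1L)] else values[seq_len(k)]
    iv <- interval_from_history(method, hist, pop, components, cva,
                                panel_cvi, cvi_source, alpha, z)
    tibble::tibble(
      subject_id = subject_id,
      method = method,
      mode = mode,
      k = k,
      observation = values[k],
      interval_method = if (is.null(iv)) NA_character_ else iv$method,
      center = if (is.null(iv)) NA_real_ else iv$center,
      lower = if (is.null(iv)) NA_real_ else iv$lower,
      upper = if (is.null(iv)) NA_real_ else iv$upper,
      flag = if (is.null(iv)) "not_evaluable" else
        flag_observation(values[k], iv$lower, iv$upper)
    )
  })
  out <- dplyr::bind_rows(steps)
  class(out) <- c("ref_trajectory", class(out))
  out
}

# the interval a method can offer given a history of h observations;
# NULL if not evaluable at all, population range while not yet evaluable
interval_from_history <- function(method, hist, pop, components, cva,
                                  panel_cvi, cvi_source, alpha, z) {
  h <- length(hist)
  switch(method,
    population = pop,
    naive = if (h >= 2L) {
      naive_interval(mean(hist), sample_sd(hist), z = z, n_used = h)
    } else {
      pop
    },
    tango = if (h >= 2L) tango_interval(hist, alpha = alpha) else pop,
    rcv = if (h >= 2L && mean(hist) > 0) {
      cvi <- if (cvi_source == "panel") panel_cvi else 100 * sample_sd(hist) / mean(hist)
      rcv_interval(mean(hist), rcv(cva, cvi, z = z), n_used = h)
    } else {
      pop
    },
    bayes = {
      if (is.null(components)) return(NULL)
      post <- posterior(hist, mu0 = components$mu0,
                        sigma0_sq = components$between_var,
                        within_var = components$within_var)
      bayes_interval(post, within_var = components$within_var, z = z)
    }
  )
}

#' Trajectories for every subject and method
#'
#' Convenience wrapper running [cumulative_trajectory()] over all subjects of
#' a panel and several methods, returning one stacked tidy table.
#'
#' @inheritParams cumulative_trajectory
#' @param methods character vector of method tags.
#' @return A `ref_trajectory` tibble (see [cumulative_trajectory()]).
#' @export
panel_trajectories <- function(panel, methods = c("naive", "rcv", "tango", "bayes"),
                               config = analyte_defaults(), components = NULL,
                               mode = c("prospective", "retrospective"),
                               alpha = 0.05, z = 1.96,
                               cvi_source = c("subject", "panel")) {
  assert_panel(panel)
  mode <- match.arg(mode)
  cvi_source <- match.arg(cvi_source)
  if ("bayes" %in% methods && is.null(components)) {
    components <- estimate_components(panel)
  }
  subjects <- unique(panel$subject_id)
  grid <- tidyr::expand_grid(s = subjects, m = methods)
  out <- purrr::map2(grid$s, grid$m, function(s, m) {
    cumulative_trajectory(panel, s, m, config = config,
                          components = components, mode = mode,
                          alpha = alpha, z = z, cvi_source = cvi_source)
  }) |>
    dplyr::bind_rows()
  class(out) <- c("ref_trajectory", class(out))
  out
}

#' Compare personal-range methods against the population range
#'
#' The package's headline analysis for one panel: panel summary, variance
#' components, the per-subject intervals of every method from the full series,
#' how many subjects have CV(intra) below CV(inter), and each method's mean
#' interval width next to the population-range width. When within-subject
#' variation is small relative to between-subject variation, every personal
#' method produces substantially narrower ranges than the population interval
#' — the case for individualised monitoring.
#'
#' @param panel a validated balanced panel tibble.
#' @param config analyte config tibble.
#' @param components optional `ref_components`; estimated from the panel if
#'   absent.
#' @param cvi_source CVi source for the RCV method (see [panel_intervals()]);
#'   defaults to `"panel"` here so the report carries one RCV per analyte.
#' @return A `ref_report` list: `analyte`, `summary` (one row,
#'   [panel_summary()] plus `rcv_percent`), `components` (tidy components),
#'   `intervals` (per subject x method), `widths` (per method: mean width,
#'   population width, ratio), `cv_intra_below_inter` (count of subjects).
#' @export
#' @examples
#' p <- simulate_panel(mu0 = 280, sigma0 = 27.77, sigma_eps = 12.88,
#'                     seed = 1, analyte = "TRF")
#' rep <- comparison_report(p)
#' rep$widths
comparison_report <- function(panel, config = analyte_defaults(),
                              components = NULL,
                              cvi_source = c("panel", "subject")) {
  assert_balanced(panel)
  cvi_source <- match.arg(cvi_source)
  analyte <- panel$analyte[1]
  if (is.null(components)) components <- estimate_components(panel)
  summ <- panel_summary(panel)
  subj <- subject_summaries(panel)
  cva <- config_field(config, analyte, "cva_percent", default = 0)
  z <- config_field(config, analyte, "z_value", default = 1.96)
  rcv_pct <- rcv(cva, summ$mean_cv_intra_percent, z = z)

  ivs <- panel_intervals(panel,
                         methods = c("naive", "rcv", "tango", "bayes"),
                         config = config, components = components,
                         cvi_source = cvi_source, z = z)
  pop <- population_range(config, analyte)
  widths <- ivs |>
    dplyr::summarise(mean_width = mean(.data$upper - .data$lower),
                     .by = "method") |>
    dplyr::mutate(
      population_width = pop$upper - pop$lower,
      width_ratio = .data$mean_width / .data$population_width
    )
  cv_below <- sum(subj$cv_percent < summ$cv_inter_percent)

  structure(
    list(
      analyte = analyte,
      summary = dplyr::mutate(summ, rcv_percent = rcv_pct),
      components = tidy.ref_components(components),
      intervals = ivs,
      widths = widths,
      cv_intra_below_inter = cv_below,
      population = pop
    ),
    class = "ref_report"
  )
}

#' @export
print.ref_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Personal reference range comparison - %s\n", x$analyte))
  cat(sprintf("  %d subjects x %d visits; grand mean %.4g, CV(inter) %.3g%%, mean CV(intra) %.3g%%\n",
              s$n_subjects, s$n_visits, s$grand_mean, s$cv_inter_percent,
              s$mean_cv_intra_percent))
  cat(sprintf("  RCV %.3g%%; subjects with CV(intra) < CV(inter): %d / %d\n",
              s$rcv_percent, x$cv_intra_below_inter, s$n_subjects))
  cat(sprintf("  population range %.4g-%.4g (width %.4g)\n",
              x$population$lower, x$population$upper,
              x$population$upper - x$population$lower))
  w <- x$widths
  for (i in seq_len(nrow(w))) {
    cat(sprintf("  mean width %-6s %8.4g  (%.2f x population)\n",
                w$method[i], w$mean_width[i], w$width_ratio[i]))
  }
  invisible(x)
}
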