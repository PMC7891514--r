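#' Per-subject summaries of a longitudinal panel
#'
#' For each subject: visit count, mean, sample SD (n − 1 denominator) and
#' coefficient of variation `100 * sd / mean` in percent. A subject observed
#' once has no SD — it is reported as `NA` (flagged), never as 0. A subject
#' whose mean is 0 gets an `NA` CV: these analytes are strictly positive, so a
#' zero mean signals bad input rather than an infinite CV.
#'
#' @param panel a panel tibble (see [read_panel()]).
#' @param subjects optional character vector restricting to some subjects; an
#'   unknown id is an error.
#' @return Tibble, one row per subject: `subject_id, n, mean, sd, cv_percent`.
#' @export
#' @examples
#' p <- simulate_panel(mu0 = 280, sigma0 = 27.77, sigma_eps = 12.88, seed = 1)
#' subject_summaries(p)
subject_summaries <- function(panel, subjects = NULL) {
  assert_panel(panel)
  if (!is.null(subjects)) {
    unknown <- setdiff(subjects, unique(panel$subject_id))
    if (length(unknown) > 0L) {
      stop_persref(sprintf("Unknown subject(s): %s",
                           paste(unknown, collapse = ", ")),
                   "persref_lookup_error")
    }
    panel <- panel[panel$subject_id %in% subjects, , drop = FALSE]
  }
  panel |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = sample_sd(.data$value),
      .by = "subject_id"
    ) |>
    dplyr::mutate(
      cv_percent = dplyr::if_else(.data$mean > 0, 100 * .data$sd / .data$mean,
                                  NA_real_)
    ) |>
    dplyr::arrange(.data$subject_id)
}

#' Panel-level summary: the inter- vs intra-individual decomposition
#'
#' Summarises a panel the way a biological-variation study tabulates it:
#' the grand mean and SD *of subject means* (so CV(inter) describes how much
#' people differ from each other), and the mean and SD of the per-subject CVs
#' (CV(intra), how much one person varies across their own visits). Whenever
#' within-subject variation is small relative to between-subject variation —
#' the premise of personal reference ranges — mean CV(intra) falls well below
#' CV(inter).
#'
#' @param panel a panel tibble; every subject needs >= 2 visits.
#' @return One-row tibble: `n_subjects, n_visits, grand_mean,
#'   sd_of_subject_means, cv_inter_percent, mean_cv_intra_percent,
#'   sd_cv_intra_percent, max_value, min_value, max_subject_mean,
#'   min_subject_mean`. `max_value`/`min_value` range over all observations;
#'   the subject-mean extremes are also reported since printed summary tables
#'   sometimes use either convention.
#' @export
#' @examples
#' p <- simulate_panel(mu0 = 280, sigma0 = 27.77, sigma_eps = 12.88, seed = 1)
#' panel_summary(p)
panel_summary <- function(panel) {
  assert_panel(panel)
  subj <- subject_summaries(panel)
  short <- subj$subject_id[subj$n < 2L]
  if (length(short) > 0L) {
    stop_persref(sprintf("Every subject needs >= 2 visits; offender(s): %s",
                         paste(short, collapse = ", ")),
                 "persref_precondition_error")
  }
  grand <- mean(subj$mean)
  sd_means <- sample_sd(subj$mean)
  tibble::tibble(
    n_subjects = nrow(subj),
    n_visits = max(subj$n),
    grand_mean = grand,
    sd_of_subject_means = sd_means,
    cv_inter_percent = if (grand > 0) 100 * sd_means / grand else NA_real_,
    mean_cv_intra_percent = mean(subj$cv_percent),
    sd_cv_intra_percent = sample_sd(subj$cv_percent),
    max_value = max(panel$value),
    min_value = min(panel$value),
    max_subject_mean = max(subj$mean),
    min_subject_mean = min(subj$mean)
  )
}

#' Per-subject t and F tests against the panel
#'
#' Screens each subject of a balanced panel for a mean or a dispersion that
#' stands out: a one-sample two-sided t test of the subject's visits against
#' the grand mean (of subject means), and a two-sided variance-ratio F test of
#' the subject's visit variance against the pooled within-subject variance of
#' all other subjects. No multiplicity correction is applied; flags mark
#' p < alpha per subject, as in per-subject asterisks on a summary figure.
#' Degenerate statistics (a subject with zero SD, or zero pooled variance) are
#' reported as `NA` and flagged `not_evaluable` via the `degenerate` column.
#'
#' @param panel a balanced panel tibble, >= 2 subjects and >= 2 visits.
#' @param alpha significance level for the flags (default 0.05).
#' @return Tibble, one row per subject: `subject_id, n, mean, t_stat, t_p,
#'   t_flag, f_stat, f_p, f_flag, degenerate`.
#' @export
subject_vs_grand_tests <- function(panel, alpha = 0.05) {
  assert_balanced(panel)
  subj <- subject_summaries(panel)
  grand <- mean(subj$mean)
  nv <- subj$n
  # pooled within-subject variance over the *other* subjects, so a single
  # volatile subject does not mask itself
  ss <- (subj$n - 1L) * subj$sd^2
  df <- subj$n - 1L
  res <- purrr::pmap(
    list(subj$subject_id, subj$n, subj$mean, subj$sd, ss, df),
    function(id, n, m, s, ss_i, df_i) {
      pooled_var <- (sum(ss) - ss_i) / (sum(df) - df_i)
      t_stat <- if (s > 0) (m - grand) / (s / sqrt(n)) else NA_real_
      t_p <- if (!is.na(t_stat)) 2 * pt(-abs(t_stat), df = n - 1L) else NA_real_
      f_stat <- if (pooled_var > 0) s^2 / pooled_var else NA_real_
      f_p <- if (!is.na(f_stat)) {
        p1 <- pf(f_stat, df1 = df_i, df2 = sum(df) - df_i)
        2 * min(p1, 1 - p1)
      } else NA_real_
      tibble::tibble(
        subject_id = id, n = n, mean = m,
        t_stat = t_stat, t_p = t_p,
        t_flag = !is.na(t_p) & t_p < alpha,
        f_stat = f_stat, f_p = f_p,
        f_flag = !is.na(f_p) & f_p < alpha,
        degenerate = is.na(t_stat) || is.na(f_stat)
      )
    }
  )
  dplyr::bind_rows(res)
}
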