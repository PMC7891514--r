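#' @importFrom rlang .data .env %||%
#' @importFrom stats qt pt pf rnorm sd var
NULL

# common one-row interval tibble used by every method
new_interval <- function(method, center, lower, upper, n_used) {
  tibble::tibble(
    method = method,
    n_used = as.integer(n_used),
    center = center,
    lower = lower,
    upper = upper,
    half_width = (upper - lower) / 2
  )
}

#' Naive personal reference interval (mean +/- z * SD)
#'
#' The simplest personal range: treat the subject's own sample SD from
#' repeated measurements as the true dispersion and take `mean +/- z * sd`.
#' With few visits this understates the uncertainty in both the mean and the
#' SD, which is exactly what the prediction-interval method corrects; the two
#' are compared throughout the package.
#'
#' @param mean sample mean of the subject's measurements (analyte units).
#' @param sd sample SD (n − 1 denominator), must be >= 0.
#' @param z normal quantile; 1.96 for a 95% range (default), 2.58 for 99%.
#' @param n_used number of observations behind `mean` and `sd`, recorded as
#'   provenance (`NA` if unknown).
#' @return One-row interval tibble: `method, n_used, center, lower, upper,
#'   half_width`.
#' @seealso [tango_interval()], [rcv_interval()], [bayes_interval()]
#' @export
#' @examples
#' naive_interval(29.8, 6.93)         # transthyretin panel mean / SD
#' naive_interval(3.5, 1.08, n_used = 5)
naive_interval <- function(mean, sd, z = 1.96, n_used = NA_integer_) {
  check_number(mean, "mean")
  check_number(sd, "sd", min = 0)
  check_number(z, "z", min = 0, strict_min = TRUE)
  new_interval("naive", center = mean, lower = mean - z * sd,
               upper = mean + z * sd, n_used = n_used)
}

#' Reference change value (RCV)
#'
#' The smallest relative difference between two serial results that exceeds
#' combined analytical and within-subject biological variation:
#' \deqn{RCV = \sqrt{2}\, Z \sqrt{CV_a^2 + CV_i^2}}
#' with all CVs in percent. The \eqn{\sqrt 2} reflects that a change compares
#' two measured values, each carrying the full variation.
#'
#' @param cva_percent analytical CV in percent (>= 0).
#' @param cvi_percent within-subject biological CV in percent (>= 0).
#' @param z normal quantile: 1.96 (95%, default) or 2.58 (99%); any positive
#'   value is accepted.
#' @return RCV in percent (numeric, vectorised over its arguments).
#' @export
#' @examples
#' rcv(3, 4)                 # sqrt(2) * 1.96 * 5 = 13.86
#' rcv(1.07, 4.06)           # transferrin-like inputs
rcv <- function(cva_percent, cvi_percent, z = 1.96) {
  check_number(cva_percent, "cva_percent", min = 0)
  check_number(cvi_percent, "cvi_percent", min = 0)
  check_number(z, "z", min = 0, strict_min = TRUE)
  sqrt(2) * z * sqrt(cva_percent^2 + cvi_percent^2)
}

#' RCV-based personal reference interval
#'
#' Converts an RCV percentage into an absolute half-width around the subject's
#' cumulative mean: `half_width = mean * rcv_percent / 100`, giving
#' `mean ∓ half_width`.
#'
#' @param mean subject's mean, must be > 0 (the RCV is a relative quantity).
#' @param rcv_percent RCV in percent, from [rcv()].
#' @param n_used observation count recorded as provenance.
#' @return One-row interval tibble (method `"rcv"`).
#' @export
#' @examples
#' rcv_interval(280, 11.64)  # 248 - 312 for a transferrin mean of 280
rcv_interval <- function(mean, rcv_percent, n_used = NA_integer_) {
  check_number(mean, "mean", min = 0, strict_min = TRUE)
  check_number(rcv_percent, "rcv_percent", min = 0)
  hw <- mean * rcv_percent / 100
  new_interval("rcv", center = mean, lower = mean - hw, upper = mean + hw,
               n_used = n_used)
}

#' Prediction-interval multiplier Cn
#'
#' Half-width multiplier of the Student-t prediction interval for one future
#' observation given `n` past ones:
#' \deqn{C_n = t_{n-1}(\alpha/2)\,\sqrt{(n+1)/n}}
#' where \eqn{t_{n-1}(\alpha/2)} is the upper-\eqn{\alpha/2} quantile of the t
#' distribution with `n - 1` degrees of freedom. `cn(5) = 3.041`: with only
#' five measurements the correct 95% multiplier is half again as large as the
#' naive 1.96. Strictly decreasing in `n`, approaching 1.96 as `n` grows.
#'
#' @param n number of past observations (integer >= 2; vectorised).
#' @param alpha two-sided error rate, in (0, 1); default 0.05.
#' @return numeric multiplier(s).
#' @export
#' @examples
#' cn(5)               # 3.041
#' cn(c(3, 5, 10, 1e5))
cn <- function(n, alpha = 0.05) {
  check_number(n, "n", min = 2)
  check_number(alpha, "alpha", min = 0, strict_min = TRUE)
  if (any(alpha >= 1)) {
    stop_persref("`alpha` must be in (0, 1).", "persref_domain_error")
  }
  qt(1 - alpha / 2, df = n - 1) * sqrt((n + 1) / n)
}

#' Student-t prediction interval for one future observation
#'
#' The acceptance region of the t test of a new observation X against the
#' subject's history \eqn{X_1..X_n}: with
#' \eqn{T = (X - \bar X) / (S\sqrt{1 + 1/n})}, the null "X comes from the same
#' normal distribution" is retained iff X lies in
#' \eqn{\bar X \pm C_n S}. Unlike the naive interval it accounts for the
#' estimation error of both the mean and the SD, so a fresh draw lands inside
#' with probability exactly \eqn{1 - \alpha} under i.i.d. normal sampling, at
#' any `n`.
#'
#' @param values numeric vector of the subject's past measurements (>= 2).
#' @param alpha two-sided error rate (default 0.05).
#' @return One-row interval tibble (method `"tango"`), with
#'   `center = mean(values)` and `half_width = cn(n, alpha) * sd(values)`.
#' @export
#' @examples
#' tango_interval(c(1, 2, 3, 4, 5))  # 3 +/- 3.041 * 1.581
tango_interval <- function(values, alpha = 0.05) {
  if (length(values) < 2L) {
    stop_persref("tango_interval() needs at least 2 values (an SD is required).",
                 "persref_domain_error")
  }
  check_number(values, "values")
  m <- mean(values)
  s <- sample_sd(values)
  hw <- cn(length(values), alpha) * s
  new_interval("tango", center = m, lower = m - hw, upper = m + hw,
               n_used = length(values))
}

#' Per-subject intervals for every requested method
#'
#' Computes, for each subject in a balanced panel, the personal reference
#' interval by each requested method from the subject's full measurement
#' series, plus the population range when asked. Method `"rcv"` uses the
#' analyte's configured CVa and, by default, the subject's own CV as CVi;
#' set `cvi_source = "panel"` to use the panel-level mean CV(intra) (one RCV
#' per analyte, as in a summary table). Method `"bayes"` needs variance
#' components, either supplied or estimated from the panel.
#'
#' @param panel a panel tibble.
#' @param methods subset of `c("naive", "rcv", "tango", "bayes", "population")`.
#' @param config analyte config tibble (default [analyte_defaults()]).
#' @param components a `ref_components` fit from [estimate_components()], or
#'   `NULL` to estimate from `panel` when `"bayes"` is requested.
#' @param cvi_source `"subject"` (each subject's own CV, default) or
#'   `"panel"` (mean CV(intra) shared by all subjects).
#' @param alpha two-sided error rate for `"tango"`.
#' @param z normal quantile for `"naive"`, `"rcv"`, `"bayes"`.
#' @return Tibble with one row per (subject, method):
#'   `subject_id, method, n_used, center, lower, upper, half_width`.
#' @export
#' @examples
#' p <- simulate_panel(mu0 = 280, sigma0 = 27.77, sigma_eps = 12.88, seed = 1)
#' panel_intervals(p, methods = c("naive", "tango"))
panel_intervals <- function(panel,
                            methods = c("naive", "rcv", "tango", "bayes"),
                            config = analyte_defaults(),
                            components = NULL,
                            cvi_source = c("subject", "panel"),
                            alpha = 0.05, z = 1.96) {
  assert_panel(panel)
  cvi_source <- match.arg(cvi_source)
  known <- c("naive", "rcv", "tango", "bayes", "population")
  bad <- setdiff(methods, known)
  if (length(methods) == 0L || length(bad) > 0L) {
    stop_persref(sprintf("Unknown or empty method list (valid: %s).",
                         paste(known, collapse = ", ")),
                 "persref_usage_error")
  }
  analyte <- panel$analyte[1]
  cva <- config_field(config, analyte, "cva_percent", default = 0)
  subj <- subject_summaries(panel)
  if ("bayes" %in% methods && is.null(components)) {
    components <- estimate_components(panel)
  }
  panel_cvi <- mean(subj$cv_percent)

  rows <- purrr::map(methods, function(method) {
    switch(method,
      naive = purrr::map2(subj$mean, subj$sd, naive_interval, z = z) |>
        dplyr::bind_rows() |>
        dplyr::mutate(n_used = subj$n, subject_id = subj$subject_id),
      tango = purrr::map(subj$subject_id, function(s) {
        tango_interval(panel$value[panel$subject_id == s], alpha = alpha)
      }) |>
        dplyr::bind_rows() |>
        dplyr::mutate(subject_id = subj$subject_id),
      rcv = {
        cvi <- if (cvi_source == "panel") rep(panel_cvi, nrow(subj)) else subj$cv_percent
        purrr::map2(subj$mean, rcv(cva, cvi, z = z), rcv_interval) |>
          dplyr::bind_rows() |>
          dplyr::mutate(n_used = subj$n, subject_id = subj$subject_id)
      },
      bayes = purrr::map(subj$subject_id, function(s) {
        obs <- panel$value[panel$subject_id == s]
        post <- posterior(obs, mu0 = components$mu0,
                          sigma0_sq = components$between_var,
                          within_var = components$within_var)
        bayes_interval(post, within_var = components$within_var, z = z)
      }) |>
        dplyr::bind_rows() |>
        dplyr::mutate(subject_id = subj$subject_id),
      population = purrr::map(subj$subject_id, function(s) {
        population_range(config, analyte, sex = panel$sex[panel$subject_id == s][1])
      }) |>
        dplyr::bind_rows() |>
        dplyr::mutate(subject_id = subj$subject_id)
    )
  })
  dplyr::bind_rows(rows) |>
    dplyr::select("subject_id", "method", "n_used", "center", "lower",
                  "upper", "half_width")
}

config_field <- function(config, analyte, field, default = NA_real_) {
  rows <- config[config$analyte == analyte & config$sex == "overall", , drop = FALSE]
  if (nrow(rows) == 0L) rows <- config[config$analyte == analyte, , drop = FALSE]
  if (nrow(rows) == 0L) return(default)
  rows[[field]][1]
}
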