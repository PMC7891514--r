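#' Variance components of a balanced longitudinal panel
#'
#' Fits the additive mixed model behind all the personal-range methods,
#' \deqn{X_{ij} = \mu_i + v_j + e_{ij},}
#' with subject means \eqn{\mu_i \sim N(\mu_0, \sigma_0^2)} (random), visit
#' effects \eqn{v_j} fixed, and within-subject noise
#' \eqn{e_{ij} \sim N(0, \sigma^2)} pooling temporal biological variation and
#' measurement error — the two are not separable with one measurement per
#' visit, so only their sum is reported.
#'
#' The estimator is the closed-form method-of-moments solution for a balanced
#' design: visit effects are the visit means minus the grand mean; the
#' residual mean square (divisor \eqn{(S-1)(T-1)}, which keeps it unbiased
#' after removing subject and visit means) estimates \eqn{\sigma^2}; and the
#' between-subject mean square gives
#' \eqn{\hat\sigma_0^2 = (MS_{between} - MS_{within}) / T}. In balance this
#' coincides with the REML solution; a negative moment estimate is truncated
#' to 0 with a warning.
#'
#' @param panel a balanced panel tibble, >= 2 subjects, >= 2 visits.
#' @return A `ref_components` object: list with `analyte`, `mu0` (grand mean),
#'   `between_var`, `within_var`, `between_sd`, `within_sd`, `total_sd`
#'   (`sqrt(between_var + within_var)`), `visit_effects` (mean-centred),
#'   `n_subjects`, `n_visits`. Has [tidy()] and [glance()] methods.
#' @export
#' @examples
#' p <- simulate_panel(n_subjects = 100, n_visits = 5, mu0 = 280,
#'                     sigma0 = 27.77, sigma_eps = 12.88, seed = 7)
#' fit <- estimate_components(p)
#' tidy(fit)
#' glance(fit)
estimate_components <- function(panel) {
  assert_balanced(panel)
  wide <- panel |>
    dplyr::select("subject_id", "visit_index", "value") |>
    tidyr::pivot_wider(names_from = "visit_index", values_from = "value",
                       names_sort = TRUE)
  x <- as.matrix(wide[, -1, drop = FALSE])
  s_n <- nrow(x) # subjects
  t_n <- ncol(x) # visits
  grand <- mean(x)
  subject_means <- rowMeans(x)
  visit_means <- colMeans(x)
  visit_effects <- visit_means - grand

  resid <- x - outer(subject_means, rep(1, t_n)) -
    outer(rep(1, s_n), visit_effects)
  ss_resid <- sum(resid^2)
  if (ss_resid == 0 && var(subject_means) == 0) {
    warning("Panel has zero total variance; all components reported as 0.",
            call. = FALSE)
    within_var <- 0
    between_var <- 0
  } else {
    within_var <- ss_resid / ((s_n - 1) * (t_n - 1))
    ms_between <- t_n * sum((subject_means - grand)^2) / (s_n - 1)
    between_var <- (ms_between - within_var) / t_n
    if (between_var < 0) {
      warning(sprintf(
        "Between-subject moment estimate was negative (%.4g); truncated to 0.",
        between_var), call. = FALSE)
      between_var <- 0
    }
  }
  structure(
    list(
      analyte = panel$analyte[1],
      mu0 = grand,
      between_var = between_var,
      within_var = within_var,
      between_sd = sqrt(between_var),
      within_sd = sqrt(within_var),
      total_sd = sqrt(between_var + within_var),
      visit_effects = unname(visit_effects),
      n_subjects = s_n,
      n_visits = t_n
    ),
    class = "ref_components"
  )
}

#' Build a components object from known dispersions
#'
#' Wraps externally supplied variance components (for instance a published
#' mixed-model table) in the same `ref_components` structure that
#' [estimate_components()] returns, so they can drive [bayes_interval()],
#' [cumulative_trajectory()] and [comparison_report()] without refitting.
#'
#' @param mu0 population mean.
#' @param between_var between-subject variance \eqn{\sigma_0^2} (>= 0).
#' @param within_var within-subject variance \eqn{\sigma^2} (>= 0).
#' @param analyte analyte code (optional label).
#' @param visit_effects mean-centred fixed visit effects (default none).
#' @return A `ref_components` object.
#' @export
#' @examples
#' ref_components(mu0 = 280, between_var = 770.96, within_var = 165.95,
#'                analyte = "TRF")
ref_components <- function(mu0, between_var, within_var, analyte = NA_character_,
                           visit_effects = numeric(0)) {
  check_number(mu0, "mu0")
  check_number(between_var, "between_var", min = 0)
  check_number(within_var, "within_var", min = 0)
  if (length(visit_effects) > 0L && abs(sum(visit_effects)) > 1e-9) {
    stop_persref("`visit_effects` must sum to 0.", "persref_domain_error")
  }
  structure(
    list(
      analyte = analyte, mu0 = mu0,
      between_var = between_var, within_var = within_var,
      between_sd = sqrt(between_var), within_sd = sqrt(within_var),
      total_sd = sqrt(between_var + within_var),
      visit_effects = visit_effects,
      n_subjects = NA_integer_, n_visits = NA_integer_
    ),
    class = "ref_components"
  )
}

#' @export
print.ref_components <- function(x, ...) {
  cat(sprintf("Variance components%s\n",
              if (is.na(x$analyte)) "" else paste0(" (", x$analyte, ")")))
  cat(sprintf("  between-subject: var %.4g (sd %.4g)\n", x$between_var, x$between_sd))
  cat(sprintf("  within-subject:  var %.4g (sd %.4g)\n", x$within_var, x$within_sd))
  cat(sprintf("  total sd:        %.4g\n", x$total_sd))
  if (length(x$visit_effects) > 0L) {
    cat("  visit effects:   ", paste(sprintf("%.3g", x$visit_effects), collapse = " "), "\n")
  }
  invisible(x)
}

#' Tidy a variance-components fit
#'
#' @param x a `ref_components` object.
#' @param ... unused.
#' @return `tidy()`: tibble with one row per component (`between`, `within`,
#'   `total`), columns `component, variance, sd`. `glance()`: one-row tibble
#'   with the fit's scalars.
#' @method tidy ref_components
#' @export
tidy.ref_components <- function(x, ...) {
  tibble::tibble(
    component = c("between", "within", "total"),
    variance = c(x$between_var, x$within_var, x$between_var + x$within_var),
    sd = c(x$between_sd, x$within_sd, x$total_sd)
  )
}

#' @rdname tidy.ref_components
#' @method glance ref_components
#' @export
glance.ref_components <- function(x, ...) {
  tibble::tibble(
    analyte = x$analyte,
    mu0 = x$mu0,
    between_sd = x$between_sd,
    within_sd = x$within_sd,
    total_sd = x$total_sd,
    n_subjects = x$n_subjects,
    n_visits = x$n_visits
  )
}

#' Normal-normal posterior for a subject's mean
#'
#' Conjugate update of the population prior \eqn{N(\mu_0, \sigma_0^2)} for a
#' subject's true level, given `n` observations with known within-subject
#' variance \eqn{\sigma^2}:
#' \deqn{\mu_n = \frac{\sigma^2}{n\sigma_0^2+\sigma^2}\,\mu_0 +
#'       \frac{\sigma_0^2}{n\sigma_0^2+\sigma^2}\sum_j X_j, \qquad
#'       \sigma_n^2 = \frac{\sigma^2\sigma_0^2}{\sigma^2+n\sigma_0^2}.}
#' The posterior mean shrinks the subject's observed total toward the
#' population mean in proportion to relative noise; with no observations the
#' prior is returned unchanged.
#'
#' @param observations numeric vector of the subject's measurements (may be
#'   empty).
#' @param mu0 prior (population) mean.
#' @param sigma0_sq prior (between-subject) variance, >= 0.
#' @param within_var known within-subject variance \eqn{\sigma^2} (>= 0).
#'   At exactly 0 the continuous limit is returned: noise-free observations
#'   pin the posterior at their mean (at `mu0` if the prior is a point mass).
#' @return One-row tibble: `mu_n, sigma_n_sq, n, shrinkage_weight` where
#'   `shrinkage_weight` is the weight on `mu0` (1 at n = 0, downhill to 0 as
#'   observations accumulate).
#' @export
#' @examples
#' posterior(240, mu0 = 280, sigma0_sq = 770.96, within_var = 165.95)
posterior <- function(observations, mu0, sigma0_sq, within_var) {
  check_number(mu0, "mu0")
  check_number(sigma0_sq, "sigma0_sq", min = 0)
  n <- length(observations)
  if (n == 0L) {
    return(tibble::tibble(mu_n = mu0, sigma_n_sq = sigma0_sq, n = 0L,
                          shrinkage_weight = 1))
  }
  check_number(observations, "observations")
  check_number(within_var, "within_var", min = 0)
  if (within_var == 0) {
    # sigma^2 -> 0 limit: noise-free data pin the posterior at the observed
    # mean; with a point-mass prior it stays at mu0
    if (sigma0_sq > 0) {
      return(tibble::tibble(mu_n = mean(observations), sigma_n_sq = 0,
                            n = as.integer(n), shrinkage_weight = 0))
    }
    return(tibble::tibble(mu_n = mu0, sigma_n_sq = 0, n = as.integer(n),
                          shrinkage_weight = 1))
  }
  denom <- n * sigma0_sq + within_var
  w <- within_var / denom
  mu_n <- w * mu0 + (sigma0_sq / denom) * sum(observations)
  sigma_n_sq <- within_var * sigma0_sq / denom
  tibble::tibble(mu_n = mu_n, sigma_n_sq = sigma_n_sq, n = as.integer(n),
                 shrinkage_weight = w)
}

#' Empirical-Bayes personal reference interval
#'
#' The 95% range for the subject's *next measurement* under the posterior:
#' posterior uncertainty about the subject's level plus within-subject
#' variation,
#' \deqn{\mu_n \pm z\sqrt{\sigma_n^2 + \sigma^2}.}
#' At n = 0 this is the population range \eqn{\mu_0 \pm z\sqrt{\sigma_0^2 +
#' \sigma^2}} (population mean +/- z times the total SD); as n grows the width
#' falls monotonically to the floor \eqn{2z\sigma} set by irreducible
#' within-subject variation.
#'
#' @param post a posterior tibble from [posterior()] (or anything with
#'   `mu_n`, `sigma_n_sq`, `n`).
#' @param within_var within-subject variance \eqn{\sigma^2}, >= 0.
#' @param z normal quantile (default 1.96).
#' @return One-row interval tibble (method `"bayes"`).
#' @export
#' @examples
#' post <- posterior(c(240, 250), mu0 = 280, sigma0_sq = 770.96,
#'                   within_var = 165.95)
#' bayes_interval(post, within_var = 165.95)
bayes_interval <- function(post, within_var, z = 1.96) {
  check_number(within_var, "within_var", min = 0)
  check_number(z, "z", min = 0, strict_min = TRUE)
  hw <- z * sqrt(post$sigma_n_sq + within_var)
  new_interval("bayes", center = post$mu_n, lower = post$mu_n - hw,
               upper = post$mu_n + hw, n_used = post$n)
}
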