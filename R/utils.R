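#' Round half away from zero
#'
#' Decimal rounding in the convention used by clinical laboratory reports:
#' ties go away from zero (`43.35 -> 43.4`, `-43.35 -> -43.4`), unlike base
#' [round()], which rounds half to even. Used only at formatting time; all
#' computation keeps full precision.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return numeric vector rounded to `digits` decimals.
#' @export
#' @examples
#' round_half_up(43.3828, 1) # 43.4
#' round_half_up(2.5)        # 3
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# sample SD without the overhead of stats::sd dispatch; NA for n < 2
sample_sd <- function(x) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / (n - 1))
}

stop_persref <- function(msg, class) {
  rlang::abort(msg, class = c(class, "persref_error"))
}

check_number <- function(x, what, finite = TRUE, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x)) {
    stop_persref(sprintf("`%s` must be numeric and non-missing.", what),
                 "persref_domain_error")
  }
  if (finite && any(!is.finite(x))) {
    stop_persref(sprintf("`%s` must be finite.", what), "persref_domain_error")
  }
  bad <- if (strict_min) any(x <= min) else any(x < min)
  if (bad) {
    cmp <- if (strict_min) ">" else ">="
    stop_persref(sprintf("`%s` must be %s %s.", what, cmp, format(min)),
                 "persref_domain_error")
  }
  invisible(x)
}
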