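# Build a panel tibble from a subjects x visits value matrix (rows = subjects).
panel_from_matrix <- function(x, analyte = "TST", sex = NULL) {
  s <- nrow(x)
  t <- ncol(x)
  ids <- sprintf("S%02d", seq_len(s))
  if (is.null(sex)) sex <- rep("U", s)
  tibble::tibble(
    subject_id = rep(ids, each = t),
    sex = rep(sex, each = t),
    visit_index = rep(seq_len(t), times = s),
    analyte = analyte,
    value = as.numeric(t(x))
  )
}

# Study-scale transferrin-like panel used across tests.
trf_panel <- function(seed = 1, n_subjects = 20, n_visits = 5) {
  simulate_panel(
    n_subjects = n_subjects, n_visits = n_visits,
    mu0 = 280, sigma0 = 27.77, sigma_eps = 12.88,
    seed = seed, analyte = "TRF"
  )
}

# Independent brute-force mean-squares oracle for the variance components:
# direct sums over the two-way layout, written against the textbook formulas
# rather than the package's matrix implementation.
brute_force_components <- function(x) {
  s <- nrow(x)
  t <- ncol(x)
  grand <- sum(x) / (s * t)
  ss_between <- 0
  for (i in seq_len(s)) {
    ss_between <- ss_between + t * (mean(x[i, ]) - grand)^2
  }
  ss_visit <- 0
  for (j in seq_len(t)) {
    ss_visit <- ss_visit + s * (mean(x[, j]) - grand)^2
  }
  ss_total <- sum((x - grand)^2)
  ss_resid <- ss_total - ss_between - ss_visit
  ms_within <- ss_resid / ((s - 1) * (t - 1))
  ms_between <- ss_between / (s - 1)
  list(
    within_var = ms_within,
    between_var = max(0, (ms_between - ms_within) / t)
  )
}
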