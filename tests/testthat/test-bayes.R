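test_that("estimate_components handles degenerate and tiny exact cases", {
  flat <- panel_from_matrix(matrix(100, nrow = 3, ncol = 4), analyte = "A")
  expect_warning(fit <- estimate_components(flat), "zero total variance")
  expect_equal(fit$between_var, 0)
  expect_equal(fit$within_var, 0)
  expect_equal(fit$visit_effects, rep(0, 4))

  # 2 subjects x 2 visits, all variation between subjects
  x <- rbind(c(0, 0), c(2, 2))
  fit2 <- estimate_components(panel_from_matrix(x, analyte = "A"))
  expect_equal(fit2$visit_effects, c(0, 0))
  expect_equal(fit2$within_var, 0)
  expect_equal(fit2$between_var, 2)
  expect_equal(fit2$total_sd, sqrt(2))

  p <- trf_panel(seed = 1)
  unbal <- p[!(p$subject_id == "S01" & p$visit_index == 5L), ]
  expect_error(estimate_components(unbal), class = "persref_precondition_error")
})

test_that("component contracts hold: sds are square roots, effects centred", {
  fit <- estimate_components(trf_panel(seed = 6))
  expect_equal(fit$between_sd^2, fit$between_var)
  expect_equal(fit$within_sd^2, fit$within_var)
  expect_equal(fit$total_sd, sqrt(fit$between_var + fit$within_var))
  expect_equal(sum(fit$visit_effects), 0)
  td <- tidy(fit)
  expect_equal(td$sd, sqrt(td$variance))
  expect_equal(glance(fit)$n_subjects, 20L)
})

test_that("moment estimator equals the brute-force mean-squares oracle", {
  set.seed(31)
  for (rep in 1:50) {
    s <- sample(2:4, 1)
    t <- sample(2:4, 1)
    x <- matrix(rnorm(s * t, 50, 8), nrow = s)
    # occasionally add real subject separation and visit trends
    if (rep %% 2 == 0) x <- x + rnorm(s, 0, 10)
    if (rep %% 3 == 0) x <- x + rep(seq(-2, 2, length.out = t), each = s)
    x <- abs(x) # panels require non-negative values
    fit <- suppressWarnings(
      estimate_components(panel_from_matrix(x, analyte = "A")))
    oracle <- brute_force_components(x)
    expect_equal(fit$within_var, oracle$within_var, tolerance = 1e-10)
    expect_equal(fit$between_var, oracle$between_var, tolerance = 1e-10)
  }
})

test_that("moment estimator matches REML (lme4) on a balanced panel", {
  skip_if_not_installed("lme4")
  p <- trf_panel(seed = 13)
  fit <- estimate_components(p)
  lf <- lme4::lmer(value ~ factor(visit_index) + (1 | subject_id), data = p,
                   REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$between_var, vc$vcov[vc$grp == "subject_id"],
               tolerance = 1e-6)
  expect_equal(fit$within_var, vc$vcov[vc$grp == "Residual"],
               tolerance = 1e-6)
})

test_that("nonzero visit effects are removed before the decomposition", {
  eff <- c(-6, 0, 2, 4, 0)
  p <- simulate_panel(n_subjects = 200, n_visits = 5, mu0 = 280,
                      sigma0 = 27.77, sigma_eps = 12.88,
                      visit_effects = eff, seed = 17, analyte = "TRF")
  fit <- estimate_components(p)
  # each visit mean carries an SE of 12.88 / sqrt(200) ~ 0.91
  expect_lt(max(abs(fit$visit_effects - eff)), 3)
  expect_gt(stats::cor(fit$visit_effects, eff), 0.9)
  expect_equal(fit$within_sd, 12.88, tolerance = 0.1 * 12.88)
})

test_that("posterior reproduces the conjugate normal-normal update", {
  # no data: the prior is returned unchanged
  p0 <- posterior(numeric(0), mu0 = 280, sigma0_sq = 770.96,
                  within_var = 165.95)
  expect_equal(p0$mu_n, 280)
  expect_equal(p0$sigma_n_sq, 770.96)
  expect_equal(p0$shrinkage_weight, 1)

  # one observation, published transferrin components, hand-checked
  p1 <- posterior(240, mu0 = 280, sigma0_sq = 770.96, within_var = 165.95)
  expect_equal(p1$shrinkage_weight, 165.95 / (770.96 + 165.95))
  expect_equal(p1$shrinkage_weight, 0.177, tolerance = 1e-3)
  expect_equal(p1$mu_n, 247.1, tolerance = 1e-3)
  expect_equal(p1$sigma_n_sq, 136.5, tolerance = 1e-3)

  # zero within-variance limit: noise-free data are believed exactly
  pz <- posterior(5, mu0 = 0, sigma0_sq = 1, within_var = 0)
  expect_equal(pz$mu_n, 5)
  expect_equal(pz$sigma_n_sq, 0)
  expect_equal(pz$shrinkage_weight, 0)
})

test_that("posterior mean is a convex combination converging to the data mean", {
  set.seed(41)
  mu0 <- 280
  s0 <- 770.96
  s2 <- 165.95
  for (i in 1:20) {
    n <- sample(1:50, 1)
    x <- rnorm(n, 250, 12)
    p <- posterior(x, mu0 = mu0, sigma0_sq = s0, within_var = s2)
    lo <- min(mu0, mean(x))
    hi <- max(mu0, mean(x))
    expect_gte(p$mu_n, lo)
    expect_lte(p$mu_n, hi)
    if (abs(mean(x) - mu0) > 1e-8) {
      expect_gt(p$mu_n, lo)
      expect_lt(p$mu_n, hi)
    }
    expect_lte(p$sigma_n_sq, s0)
  }
  # shrinkage limit: huge n pins the posterior at the data mean
  xs <- rep(c(240, 260), 5000)
  pl <- posterior(xs, mu0 = mu0, sigma0_sq = s0, within_var = s2)
  expect_equal(pl$mu_n, mean(xs), tolerance = 0.01)
  expect_lt(pl$sigma_n_sq, 0.02)
})

test_that("bayes_interval has the stated n = 0 form, floor, and monotone width", {
  # n = 0: population mean +/- z * total SD
  p0 <- posterior(numeric(0), mu0 = 280, sigma0_sq = 770.96, within_var = 165.95)
  iv0 <- bayes_interval(p0, within_var = 165.95)
  expect_equal(iv0$lower, 280 - 1.96 * sqrt(936.91))
  expect_equal(iv0$upper, 280 + 1.96 * sqrt(936.91))
  expect_equal(iv0$lower, 220.0, tolerance = 5e-4)
  expect_equal(iv0$upper, 340.0, tolerance = 5e-4)

  # width decreases in n, bounded below by 2*z*within_sd
  set.seed(43)
  x <- rnorm(50, 250, 12)
  widths <- vapply(0:50, function(n) {
    p <- posterior(x[seq_len(n)], mu0 = 280, sigma0_sq = 770.96,
                   within_var = 165.95)
    iv <- bayes_interval(p, within_var = 165.95)
    iv$upper - iv$lower
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_true(all(widths > 2 * 1.96 * sqrt(165.95)))
  # and converges to that floor
  pbig <- posterior(rnorm(1e5, 250, 12), mu0 = 280, sigma0_sq = 770.96,
                    within_var = 165.95)
  ivbig <- bayes_interval(pbig, within_var = 165.95)
  expect_equal(ivbig$upper - ivbig$lower, 2 * 1.96 * sqrt(165.95),
               tolerance = 1e-4)

  # degenerate prior: interval centred at mu0 regardless of data
  pz <- posterior(c(500, 600), mu0 = 280, sigma0_sq = 0, within_var = 165.95)
  ivz <- bayes_interval(pz, within_var = 165.95)
  expect_equal(ivz$center, 280)
  expect_equal(ivz$upper - ivz$lower, 2 * 1.96 * sqrt(165.95))
})

test_that("with published transferrin components the n = 5 personal range is
           narrower than the population range", {
  set.seed(47)
  x <- rnorm(5, 280, sqrt(165.95))
  p5 <- posterior(x, mu0 = 280, sigma0_sq = 770.96, within_var = 165.95)
  iv5 <- bayes_interval(p5, within_var = 165.95)
  pop_width <- 2 * 1.96 * sqrt(936.91)
  expect_lt(iv5$upper - iv5$lower, pop_width)
})
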