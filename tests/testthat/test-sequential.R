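test_that("flag_observation uses the closed-interval convention", {
  expect_equal(flag_observation(5, 1, 10), "within")
  expect_equal(flag_observation(0.5, 1, 10), "below")
  expect_equal(flag_observation(c(1, 10, 10.001), 1, 10),
               c("within", "within", "above"))
  iv <- naive_interval(5, 1)
  expect_equal(flag_observation(5 + 1.96, interval = iv), "within")
})

test_that("a constant series collapses the data-driven intervals onto itself", {
  p <- panel_from_matrix(rbind(rep(250, 5), rep(260, 5)), analyte = "TRF",
                         sex = c("M", "F"))
  for (m in c("naive", "tango")) {
    tr <- cumulative_trajectory(p, "S01", m)
    expect_equal(tr$flag, rep("within", 5))
    # once the method is evaluable its interval is the degenerate point
    expect_equal(tr$interval_method, c("population", "population",
                                       rep(m, 3)))
    expect_equal(tr$lower[3:5], rep(250, 3))
    expect_equal(tr$upper[3:5], rep(250, 3))
  }
})

test_that("prospective mode judges visit k by visits 1..k-1 only", {
  p <- panel_from_matrix(rbind(c(100, 100, 100, 100, 200),
                               c(100, 101, 99, 100, 100)),
                         analyte = "TRF")
  tr <- cumulative_trajectory(p, "S01", "naive", mode = "prospective")
  # visit 5 judged by the zero-variance interval (100, 100) from visits 1-4
  expect_equal(tr$lower[5], 100)
  expect_equal(tr$upper[5], 100)
  expect_equal(tr$flag[5], "above")

  retro <- cumulative_trajectory(p, "S01", "naive", mode = "retrospective")
  # retrospectively the aberrant visit is inside its own wide interval
  expect_equal(retro$center[5], 120)
  expect_equal(retro$flag[5], "within")
  # the two modes agree wherever the value is strictly inside both intervals
  # (steps 3-4: both judge by the subject's own degenerate history)
  expect_equal(tr$flag[3:4], retro$flag[3:4])
  # and at step 1, where both fall back to the population range
  expect_equal(tr$flag[1], retro$flag[1])
})

test_that("step-1 evaluation falls back to the population range, sex-aware", {
  p <- panel_from_matrix(rbind(rep(195, 5), rep(195, 5)), analyte = "TRF",
                         sex = c("M", "F"))
  trm <- cumulative_trajectory(p, "S01", "tango")
  trf_ <- cumulative_trajectory(p, "S02", "tango")
  expect_equal(trm$interval_method[1], "population")
  # male range 190-300 contains 195; female range 200-340 does not
  expect_equal(trm$flag[1], "within")
  expect_equal(trf_$flag[1], "below")
})

test_that("bayes trajectory is evaluable from the first visit and narrows", {
  p <- trf_panel(seed = 9)
  comp <- ref_components(mu0 = 280, between_var = 770.96, within_var = 165.95,
                         analyte = "TRF")
  tr <- cumulative_trajectory(p, "S01", "bayes", components = comp,
                              mode = "retrospective")
  expect_equal(tr$interval_method, rep("bayes", 5))
  w <- tr$upper - tr$lower
  expect_true(all(diff(w) < 0))
  # after five visits the personal range beats the population range (190-340)
  expect_lt(w[5], 150)
})

test_that("expected width ordering at study scale: naive < bayes < tango < population", {
  comp <- ref_components(mu0 = 280, between_var = 770.96, within_var = 165.95,
                         analyte = "TRF")
  # mean width per method and visit over 100 simulated subjects
  widths <- vapply(1:100, function(seed) {
    p <- trf_panel(seed = 2000 + seed, n_subjects = 2)
    vapply(c("naive", "tango", "bayes"), function(m) {
      tr <- cumulative_trajectory(p, "S01", m, components = comp,
                                  mode = "retrospective")
      tr$upper[3:5] - tr$lower[3:5]
    }, numeric(3))
  }, matrix(0, 3, 3))
  mean_w <- apply(widths, c(1, 2), mean) # visit k x method
  pop_width <- 340 - 190
  for (k in 1:3) {
    expect_lt(mean_w[k, "naive"], mean_w[k, "bayes"])
    expect_lt(mean_w[k, "bayes"], mean_w[k, "tango"])
    expect_lt(mean_w[k, "tango"], pop_width)
  }
})

test_that("naive/tango trajectory centres converge to the subject mean", {
  p <- trf_panel(seed = 10)
  subj <- subject_summaries(p)
  tr <- cumulative_trajectory(p, "S05", "tango", mode = "retrospective")
  mu_hat <- subj$mean[subj$subject_id == "S05"]
  gaps <- abs(tr$center[2:5] - mu_hat)
  expect_lt(gaps[4], gaps[1] + 1e-9)
  expect_equal(tr$center[5], mu_hat)
})

test_that("comparison_report assembles widths, components and CV counts", {
  p <- trf_panel(seed = 14)
  rep <- comparison_report(p)
  expect_s3_class(rep, "ref_report")
  expect_equal(nrow(rep$widths), 4)
  expect_setequal(rep$widths$method, c("naive", "rcv", "tango", "bayes"))
  # within-SD far below between-SD: every personal method beats the population
  expect_true(all(rep$widths$mean_width < rep$widths$population_width))
  expect_gte(rep$cv_intra_below_inter, 18)
  expect_lte(rep$cv_intra_below_inter, 20)
  expect_output(print(rep), "population range 190-340")

  # identical constants and a noise-free assay: every personal width collapses
  flat <- panel_from_matrix(matrix(250, 4, 5), analyte = "TRF")
  cfg0 <- dplyr::mutate(analyte_defaults(), cva_percent = 0)
  rep0 <- suppressWarnings(comparison_report(flat, config = cfg0))
  expect_true(all(rep0$widths$mean_width == 0))
})

test_that("unknown method or subject raises a usage/lookup error", {
  p <- trf_panel(seed = 1)
  expect_error(cumulative_trajectory(p, "S01", "magic"),
               class = "persref_usage_error")
  expect_error(cumulative_trajectory(p, "nobody", "naive"),
               class = "persref_lookup_error")
})

test_that("trajectory and cv plots build without error", {
  p <- trf_panel(seed = 1)
  tr <- panel_trajectories(p[p$subject_id %in% c("S01", "S02"), ],
                           methods = c("naive", "tango"),
                           components = ref_components(280, 770.96, 165.95))
  gg <- autoplot(tr)
  expect_s3_class(gg, "ggplot")
  expect_s3_class(plot_cv_comparison(p), "ggplot")
  ivs <- panel_intervals(p, methods = c("naive", "tango"))
  expect_s3_class(plot_intervals(ivs, population_range(analyte_defaults(), "TRF")),
                  "ggplot")
})
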