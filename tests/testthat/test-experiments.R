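# End-to-end study pipelines and report rendering.

test_that("identification study detects an induced beta decline", {
  env <- flat_envelopes()
  env$beta <- data.frame(minute = c(0, 8), amp = c(1, 0.6))
  template <- scenario_config(duration_min = 8, n_subjects = 1,
                              band_envelopes = env, seed = 1)
  coh <- make_cohort(template, n_subjects = 5, seed = 61)
  res <- run_identification_study(coh, pre_min = 1, post_min = 7)

  tests <- res$tests
  expect_setequal(tests$variable, c("R_ab", "R_t_ab", "R_at_ab"))
  rab <- tests[tests$variable == "R_ab", ]
  expect_lt(rab$diff, 0)                 # index rose over the drive
  expect_lt(rab$t, 0)
  expect_lt(rab$p, 0.05)
  expect_equal(rab$diff, rab$mean_pre - rab$mean_post, tolerance = 1e-12)

  # cohort-mean 2-min series: one block per 2 minutes, beta declining
  expect_equal(res$series_2min$block_start_min, c(0, 2, 4, 6))
  expect_lt(tail(res$series_2min$G_beta, 1), res$series_2min$G_beta[1])
})

test_that("identification study stays null under a drift-free scenario", {
  template <- scenario_config(duration_min = 6, n_subjects = 1,
                              band_envelopes = flat_envelopes(), seed = 1)
  ps <- unlist(lapply(1:20, function(s) {
    coh <- make_cohort(template, n_subjects = 8, seed = 1000 + s)
    run_identification_study(coh, pre_min = 1, post_min = 5)$tests$p
  }))
  expect_length(ps, 60)
  expect_lte(mean(ps < 0.05), 0.12)
})

test_that("short recordings are excluded with a warning; too few is an error", {
  template <- scenario_config(duration_min = 6, n_subjects = 1, seed = 1)
  coh <- make_cohort(template, n_subjects = 3, seed = 71)
  short_cfg <- scenario_config(duration_min = 3, n_subjects = 1, seed = 8)
  coh$recordings[["S04.control"]] <- simulate_eeg(short_cfg)
  coh$meta <- rbind(coh$meta,
                    data.frame(key = "S04.control", subject_id = "S04",
                               group = "control"))
  expect_warning(res <- run_identification_study(coh, pre_min = 1,
                                                 post_min = 5),
                 "excluding.*S04")
  expect_equal(res$n, 3)
  expect_equal(res$excluded, "S04.control")

  coh$recordings <- coh$recordings[4]
  coh$meta <- coh$meta[4, ]
  expect_error(suppressWarnings(
    run_identification_study(coh, pre_min = 1, post_min = 5)
  ), "fewer than 2")
})

test_that("intervention study produces the full result set on a small cohort", {
  coh <- simulate_cohort("intervention", n_subjects = 3, seed = 81,
                         duration_min = 41)
  res <- run_intervention_study(coh)

  expect_equal(nrow(res$kss_within), 4)
  expect_equal(nrow(res$kss_between), 3)
  expect_equal(nrow(res$rab_tests), 3 * 5)
  expect_true(all(res$rab_tests$minute %in% c(32, 34, 36, 38, 40)))
  # reported differences always equal the difference of the reported means
  expect_equal(res$rab_tests$diff,
               res$rab_tests$mean_pre - res$rab_tests$mean_post,
               tolerance = 1e-12)
  expect_equal(res$kss_within$diff,
               res$kss_within$mean_pre - res$kss_within$mean_post,
               tolerance = 1e-12)
  # control sleepiness rises (negative 28-minus-40 diff) under default drift
  expect_lt(res$kss_within$diff[res$kss_within$group == "control"], 0)
  # RM ANOVA over 3 scents x 5 minutes with n = 3
  expect_equal(res$rm_anova$df1, c(2, 4, 8))
  expect_equal(res$rm_anova$df2, c(4, 8, 16))
  # per-minute cohort series covers all four groups
  expect_setequal(unique(res$rab_series$group), scent_groups())

  # determinism end-to-end
  res2 <- run_intervention_study(simulate_cohort("intervention",
                                                 n_subjects = 3, seed = 81,
                                                 duration_min = 41))
  expect_identical(res$rab_tests, res2$rab_tests)
})

test_that("intervention study validates its inputs", {
  coh <- simulate_cohort("intervention", n_subjects = 2, seed = 82,
                         duration_min = 41)
  broken <- coh
  drop <- broken$meta$group == "lavender"
  broken$meta <- broken$meta[!drop, ]
  expect_error(run_intervention_study(broken), "lavender")

  broken2 <- coh
  broken2$kss <- broken2$kss[!(broken2$kss$group == "peppermint" &
                                 broken2$kss$time_min == 40), ]
  expect_error(run_intervention_study(broken2), "peppermint.*40")

  broken3 <- simulate_cohort("intervention", n_subjects = 2, seed = 83,
                             duration_min = 35)
  expect_error(run_intervention_study(broken3), "shorter")
})

test_that("reports are schema-complete, internally consistent, deterministic", {
  coh <- simulate_cohort("intervention", n_subjects = 3, seed = 81,
                         duration_min = 41)
  res <- run_intervention_study(coh)
  dir1 <- withr::local_tempdir()
  files <- render_report(res, dir1)
  expect_true(all(file.exists(files)))

  tab2 <- read.csv(file.path(dir1, "kss_tests.csv"))
  expect_true(all(c("group", "m_28", "sd_28", "m_40", "sd_40", "diff",
                    "t", "p") %in% names(tab2)))
  # printed diff equals difference of printed means, after the same rounding
  expect_equal(tab2$diff, round(tab2$m_28 - tab2$m_40, 3), tolerance = 1e-9)

  tab3 <- read.csv(file.path(dir1, "rab_tests.csv"))
  expect_equal(tab3$diff, round(tab3$mean_pre - tab3$mean_post, 3),
               tolerance = 1e-9)

  js <- jsonlite::read_json(file.path(dir1, "summary.json"))
  expect_equal(js$study, "intervention")
  expect_equal(js$n, 3)

  dir2 <- withr::local_tempdir()
  render_report(res, dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), label = f)
  }

  # identification report
  coh_id <- simulate_cohort("identification", n_subjects = 3, seed = 84,
                            duration_min = 8)
  res_id <- run_identification_study(coh_id, pre_min = 1, post_min = 7)
  dir3 <- withr::local_tempdir()
  render_report(res_id, dir3)
  tab1 <- read.csv(file.path(dir3, "identification_tests.csv"))
  expect_setequal(tab1$variable, c("R_ab", "R_t_ab", "R_at_ab", "KSS"))
  expect_equal(tab1$diff, round(tab1$mean_pre - tab1$mean_post, 3),
               tolerance = 1e-9)
})
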