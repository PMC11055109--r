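# Synthetic EEG + KSS generator.

test_that("null generator produces an all-zero recording", {
  cfg <- scenario_config(duration_min = 1, n_subjects = 1, noise_sd = 0,
                         band_envelopes = zero_envelopes(), seed = 1)
  rec <- simulate_eeg(cfg)
  expect_equal(nrow(rec$samples), 1 * 60 * 128)
  expect_true(all(rec$samples == 0))
})

test_that("single-band process has unit variance confined to its band", {
  for (b in c("theta", "alpha", "beta", "gamma")) {
    cfg <- scenario_config(duration_min = 1, n_subjects = 1, noise_sd = 0,
                           band_envelopes = single_band_envelopes(b),
                           seed = 11)
    rec <- simulate_eeg(cfg)
    x <- rec$samples[, 1]
    expect_equal(mean(x^2), 1, tolerance = 0.01)
    ps <- periodogram(x, sampling_rate = 128)
    edges <- eeg_bands()
    i <- match(b, edges$band)
    in_band <- band_average(ps, b) * (edges$high[i] - edges$low[i])
    # >= 95% of total power inside the nominal band (here: all of it)
    expect_gte(in_band / mean(x^2), 0.95)
    out <- sum(ps$psd) * ps$resolution - in_band
    expect_lt(out, 1e-9)
  }
})

test_that("band power scales with the squared envelope amplitude", {
  g_at <- function(amp, seed) {
    cfg <- scenario_config(duration_min = 1, n_subjects = 1, noise_sd = 0,
                           band_envelopes = single_band_envelopes("alpha", amp),
                           seed = seed)
    ps <- periodogram(simulate_eeg(cfg)$samples[, 1], sampling_rate = 128)
    band_average(ps, "alpha")
  }
  # same phases: doubling the amplitude quadruples band power exactly
  expect_equal(g_at(2, 5) / g_at(1, 5), 4, tolerance = 1e-10)
  # against theory (unit variance over 4 Hz bandwidth): G = amp^2 / 4
  expect_equal(g_at(3, 6), 9 / 4, tolerance = 0.1 * 9 / 4)
})

test_that("beta-envelope decline scales the alpha/beta ratio as 1/a_beta^2", {
  env <- flat_envelopes()
  env$beta <- data.frame(minute = c(0, 8), amp = c(1, 0.5))
  cfg <- scenario_config(duration_min = 8, n_subjects = 1, noise_sd = 0,
                         band_envelopes = env, seed = 21)
  s <- compute_index_series(simulate_eeg(cfg))
  # analytic oracle at epoch midpoints: ratio of squared beta amplitudes
  b <- eval_envelope(env$beta, c(0.5, 7.5))
  expected <- (b[1] / b[2])^2
  expect_equal(s$R_ab[8] / s$R_ab[1], expected, tolerance = 0.15)
})

test_that("default fatigue envelopes encode the published drift pattern", {
  env <- default_fatigue_envelopes()
  base <- vapply(env, function(e) eval_envelope(e, 0), numeric(1))
  expect_true(all(base > 0))
  rel_change <- function(e) {
    (eval_envelope(e, 30) - eval_envelope(e, 0)) / eval_envelope(e, 0)
  }
  # beta falls hardest; alpha slightly; theta rises; gamma falls
  expect_gt(abs(rel_change(env$beta)), abs(rel_change(env$alpha)))
  expect_lt(rel_change(env$alpha), 0)
  expect_lt(rel_change(env$gamma), 0)
  theta_grid <- eval_envelope(env$theta, seq(0, 30, by = 0.5))
  expect_true(all(diff(theta_grid) >= 0))
})

test_that("intervention multipliers start at identity and stay positive", {
  for (s in c("peppermint", "grapefruit", "lavender")) {
    m <- intervention_multiplier(s, c(0, 1, 5, 20))
    expect_equal(unname(m[1, ]), rep(1, 4))
    expect_true(all(m > 0))
    # beta boosted, alpha mildly suppressed during the effect
    expect_gt(m[2, "beta"], 1)
    expect_lt(m[2, "alpha"], 1)
    expect_gt(m[2, "beta"] - 1, 1 - m[2, "alpha"])
  }
  expect_true(all(intervention_multiplier("control", c(0, 5, 10)) == 1))
  expect_error(intervention_multiplier("vanilla", 1), "unknown scent")
})

test_that("induced alpha/beta effect has the published nadir order and persistence", {
  u <- seq(0, 16, by = 0.01)
  rho <- function(s) {
    m <- intervention_multiplier(s, u)
    (m[, "alpha"] / m[, "beta"])^2
  }
  nadir <- vapply(c("grapefruit", "peppermint", "lavender"),
                  function(s) u[which.min(rho(s))], numeric(1))
  expect_lt(nadir["grapefruit"], nadir["peppermint"])
  expect_lt(nadir["peppermint"], nadir["lavender"])
  # lavender stays below its pre-release value for at least 10 min
  rl <- rho("lavender")
  expect_true(all(rl[u > 0 & u <= 10] < 1))
  # peppermint recovers fastest
  at7 <- function(s) rho(s)[which.min(abs(u - 7))]
  expect_gt(at7("peppermint"), at7("lavender"))
  expect_gt(at7("peppermint"), at7("grapefruit"))
})

test_that("KSS generator is exact in the noise-free case and always in 1..9", {
  cfg <- scenario_config(
    n_subjects = 4, seed = 2,
    kss = list(ref_min = 0, baseline = 5, drift = 0, drop = 0,
               schedule = c(0, 30), trait_sd = 0, noise_sd = 0)
  )
  k <- simulate_kss(cfg)
  expect_true(all(k$score == 5L))
  expect_equal(nrow(k), 8)

  # extreme latent means still clip to the ordinal scale
  for (b in c(-5, 15)) {
    cfg$kss$baseline <- b
    cfg$kss$noise_sd <- 3
    cfg$kss$trait_sd <- 2
    k <- simulate_kss(cfg)
    expect_true(all(k$score >= 1 & k$score <= 9))
  }
})

test_that("control-condition KSS rise matches its calibrated mean", {
  d <- vapply(1:200, function(s) {
    cfg <- scenario_config(group = "control", study = "intervention",
                           duration_min = 45, n_subjects = 11, seed = s)
    k <- simulate_kss(cfg)
    mean(k$score[k$time_min == 40]) - mean(k$score[k$time_min == 28])
  }, numeric(1))
  expect_lt(abs(mean(d) - 2.273), 0.5)
})

test_that("cohorts have the right bookkeeping and are seed-deterministic", {
  c1 <- simulate_cohort("identification", n_subjects = 2, seed = 7,
                        duration_min = 2)
  expect_length(c1$recordings, 2)
  expect_true(all(vapply(c1$recordings, function(r) nrow(r$samples),
                         numeric(1)) == 2 * 60 * 128))
  expect_equal(nrow(c1$kss), 4)  # 2 subjects x 2 questionnaire times

  c2 <- simulate_cohort("intervention", n_subjects = 2, seed = 7,
                        duration_min = 1)
  expect_length(c2$recordings, 8)      # 4 conditions x 2 subjects
  expect_equal(nrow(c2$kss), 16)       # 4 conditions x 2 subjects x 2 times
  expect_setequal(unique(c2$meta$group), scent_groups())

  c3 <- simulate_cohort("intervention", n_subjects = 2, seed = 7,
                        duration_min = 1)
  expect_identical(c2, c3)
  c4 <- simulate_cohort("intervention", n_subjects = 2, seed = 8,
                        duration_min = 1)
  expect_false(identical(c2$recordings[[1]]$samples,
                         c4$recordings[[1]]$samples))
})

test_that("sub-Nyquist sampling rates are rejected with a clear message", {
  expect_error(scenario_config(sampling_rate = 80), "Nyquist")
  expect_error(scenario_config(duration_min = -1), "duration")
})
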