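# Shared fixtures: small scenario builders and a hand-rolled cohort
# constructor for custom configurations.

flat_envelopes <- function(amps = c(theta = 0.7, alpha = 0.575,
                                    beta = 1.0, gamma = 0.5)) {
  lapply(as.list(amps), function(a) {
    data.frame(minute = c(0, 45), amp = c(a, a))
  })
}

zero_envelopes <- function() flat_envelopes(c(theta = 0, alpha = 0,
                                              beta = 0, gamma = 0))

single_band_envelopes <- function(band, amp = 1) {
  amps <- c(theta = 0, alpha = 0, beta = 0, gamma = 0)
  amps[band] <- amp
  flat_envelopes(amps)
}

# cohort of identical-design subjects from a template config (distinct
# per-subject seeds), bypassing simulate_cohort's default study designs
make_cohort <- function(template, n_subjects, seed, study = "identification") {
  seeds <- withr::with_seed(seed, sample.int(1e8, n_subjects))
  recordings <- list()
  meta <- list()
  for (i in seq_len(n_subjects)) {
    cfg <- template
    cfg$seed <- seeds[i]
    key <- sprintf("S%02d.%s", i, template$group)
    recordings[[key]] <- simulate_eeg(cfg)
    meta[[key]] <- data.frame(key = key, subject_id = sprintf("S%02d", i),
                              group = template$group,
                              stringsAsFactors = FALSE)
  }
  structure(list(study = study, recordings = recordings,
                 meta = do.call(rbind, c(meta, list(make.row.names = FALSE))),
                 kss = NULL),
            class = "fatigue_cohort")
}

# steady-state amplitude of a sinusoidal response at frequency f,
# estimated by quadrature projection over an integer number of periods
# at the end of the signal
steady_amp <- function(y, f, fs, periods = 8) {
  n_win <- round(periods / f * fs)
  y <- tail(y, n_win)
  t <- (seq_along(y) - 1) / fs
  a <- 2 * mean(y * sin(2 * pi * f * t))
  b <- 2 * mean(y * cos(2 * pi * f * t))
  sqrt(a^2 + b^2)
}
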