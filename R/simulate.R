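# Synthetic EEG and KSS generation.

#' Construct an EEG recording object
#'
#' @param samples Numeric matrix, time in rows and channels in columns.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_labels Channel names; defaults to the column names of
#'   `samples`.
#' @param events Named numeric vector of event minute marks (e.g.
#'   `c(task_start = 0, intervention = 30)`).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, sampling_rate,
                          channel_labels = colnames(samples),
                          events = c(task_start = 0)) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) abort("samples must be numeric")
  rng <- suppressWarnings(range(samples))
  if (!all(is.finite(rng))) abort("samples contain non-finite values")
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(ncol(samples)))
  }
  if (length(channel_labels) != ncol(samples)) {
    abort("channel_labels length must match the number of channels")
  }
  colnames(samples) <- channel_labels
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         channel_labels = channel_labels, events = events),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$samples), " samples x ",
      ncol(x$samples), " channels (",
      paste(x$channel_labels, collapse = ", "), ") at ",
      x$sampling_rate, " Hz = ",
      round(nrow(x$samples) / x$sampling_rate / 60, 2), " min\n", sep = "")
  if (length(x$events)) {
    cat("  events:", paste(names(x$events), "=", x$events, "min",
                           collapse = "; "), "\n")
  }
  invisible(x)
}

#' Duration of a recording in minutes
#' @param recording An [eeg_recording()].
#' @return Duration in minutes.
#' @export
recording_minutes <- function(recording) {
  nrow(recording$samples) / recording$sampling_rate / 60
}

# Zero-mean, unit-variance processes exactly confined to half-open
# frequency bands: sums of equal-amplitude, random-phase sinusoids on
# the DFT frequency grid (spacing fs/n) inside each band, synthesized by
# inverse FFT.  Variance over the full record is exactly 1 because
# distinct DFT frequencies are orthogonal over the record.  Two bands
# are packed per complex FFT (one in the real part, one in the
# imaginary part) since each symmetric spectrum yields a real signal.
.band_limited_process <- function(n, fs, band) {
  .band_processes(n, fs, list(band))[[1]]
}

.band_bins <- function(n, fs, band) {
  lo <- ceiling(band[1] * n / fs)
  hi <- ceiling(band[2] * n / fs) - 1L       # f in [band1, band2)
  hi <- min(hi, floor((n - 1) / 2))
  lo <- max(lo, 1L)
  if (hi < lo) {
    abort("no DFT grid frequency falls inside [", band[1], ", ", band[2],
          ") Hz at n = ", n, ", fs = ", fs)
  }
  seq.int(lo, hi)
}

.band_processes <- function(n, fs, bands) {
  out <- vector("list", length(bands))
  i <- 1L
  while (i <= length(bands)) {
    z <- complex(length.out = n)
    for (j in 0:1) {                         # pack up to two bands per FFT
      if (i + j > length(bands)) break
      k <- .band_bins(n, fs, bands[[i + j]])
      amp <- sqrt(2 / length(k))             # sum of amp^2/2 = 1
      phases <- runif(length(k), 0, 2 * pi)
      spec <- (amp * n / 2) * exp(1i * phases)
      mirror <- Conj(spec)
      if (j == 1) {                          # imaginary-part channel: i * z
        spec <- 1i * spec
        mirror <- 1i * mirror
      }
      z[k + 1]     <- z[k + 1] + spec
      z[n - k + 1] <- z[n - k + 1] + mirror
    }
    x <- fft(z, inverse = TRUE) / n
    out[[i]] <- Re(x)
    if (i + 1L <= length(bands)) out[[i + 1L]] <- Im(x)
    i <- i + 2L
  }
  out
}

#' Simulate a multichannel EEG recording
#'
#' Generates `x_c(t) = sum_b a_b(t) m_b(t) s_b(t) + e_c(t)` where `s_b`
#' is a zero-mean unit-variance process band-limited to band `b` (sum of
#' random-phase sinusoids on a dense frequency grid inside the band),
#' `a_b(t)` the fatigue envelope, `m_b(t)` the intervention multiplier
#' (1 before the release and in the control condition) and `e_c` white
#' sensor noise, independent per channel.  All channels share the same
#' latent band processes.  The variance contributed by band `b` over a
#' stationary stretch is `(a_b m_b)^2`, so band-average PSD scales with
#' the squared envelope.
#'
#' @param config A [scenario_config()].  The `seed` field determines the
#'   output bit-for-bit.
#' @return An [eeg_recording()] with `duration_min * 60 * sampling_rate`
#'   samples per channel.
#' @export
#' @examples
#' cfg <- scenario_config(duration_min = 2, n_subjects = 1, seed = 7)
#' rec <- simulate_eeg(cfg)
#' rec
simulate_eeg <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  fs <- config$sampling_rate
  n <- round(config$duration_min * 60 * fs)
  withr::with_seed(config$seed, {
    t_min <- (seq_len(n) - 1) / (fs * 60)
    bands <- eeg_bands()
    procs <- .band_processes(
      n, fs, lapply(seq_len(nrow(bands)),
                    function(i) c(bands$low[i], bands$high[i]))
    )
    latent <- numeric(n)
    for (i in seq_len(nrow(bands))) {
      b <- bands$band[i]
      a <- eval_envelope(config$band_envelopes[[b]], t_min)
      m <- .multiplier_series(config, b, t_min)
      latent <- latent + a * m * procs[[i]]
    }
    k <- length(config$channel_labels)
    samples <- matrix(latent, nrow = n, ncol = k)
    if (config$noise_sd > 0) {
      samples <- samples + matrix(rnorm(n * k, sd = config$noise_sd), n, k)
    }
    events <- c(task_start = 0)
    if (!is.null(config$intervention_effect)) {
      events <- c(events, intervention = config$intervention_minute)
    }
    eeg_recording(samples, fs, config$channel_labels, events)
  })
}

# Per-sample intervention multiplier for one band (1 before release).
.multiplier_series <- function(config, band, t_min) {
  eff <- config$intervention_effect
  if (is.null(eff)) return(1)
  u <- t_min - config$intervention_minute
  m <- approx(eff$minute, eff[[band]], xout = pmax(u, 0), rule = 2)$y
  m[u <= 0] <- 1
  m
}

# round-half-up, the convention for ordinal questionnaire scores
.round_half_up <- function(x) floor(x + 0.5)

#' Simulate Karolinska Sleepiness Scale responses
#'
#' Per subject, latent sleepiness at questionnaire minute `t` is
#' `baseline + drift * (t - ref_min) - drop * [t > intervention & scented]
#'  + trait + noise`, rounded half-up and clipped to the ordinal 1-9
#' range.  `trait` is a subject-level offset (shared across conditions
#' when supplied by the caller), `noise` is Gaussian on the latent scale.
#'
#' @param config A [scenario_config()]; its `kss` element holds the
#'   latent-model parameters and the questionnaire schedule.
#' @param traits Optional numeric vector of per-subject trait offsets
#'   (length `n_subjects`); drawn internally when `NULL`.
#' @return Data frame with columns `subject_id`, `group`, `time_min`,
#'   `score` (integer 1-9).
#' @export
#' @examples
#' cfg <- scenario_config(n_subjects = 3, seed = 2)
#' simulate_kss(cfg)
simulate_kss <- function(config, traits = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  p <- config$kss
  n <- config$n_subjects
  withr::with_seed(config$seed + 1L, {
    if (is.null(traits)) traits <- rnorm(n, 0, p$trait_sd)
    stopifnot(length(traits) == n)
    out <- lapply(seq_len(n), function(i) {
      t <- p$schedule
      scented <- config$group != "control"
      latent <- p$baseline + p$drift * (t - p$ref_min) -
        p$drop * as.numeric(scented & t > config$intervention_minute) +
        traits[i] + rnorm(length(t), 0, p$noise_sd)
      data.frame(
        subject_id = sprintf("S%02d", i),
        group = config$group,
        time_min = t,
        score = as.integer(pmin(9, pmax(1, .round_half_up(latent)))),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, out)
  })
}

#' Simulate a full study cohort
#'
#' Generates the dataset each study pipeline consumes.  The
#' identification study yields one 30-min recording per subject plus KSS
#' at minutes 0 and 30.  The intervention study yields, for each of the
#' four conditions (control, peppermint, grapefruit, lavender), one
#' 45-min recording per subject with the scent released at minute 30,
#' plus KSS at minutes 28 and 40.  Every subject appears in every
#' condition with a shared sleepiness trait; subjects also carry an
#' individual fatigue-progression rate and (per condition) a scent
#' response depth, so cohort statistics have realistic between-subject
#' spread.
#'
#' @param study `"identification"` or `"intervention"`.
#' @param n_subjects Cohort size (>= 2); defaults to 14 for
#'   identification and 11 for intervention.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param duration_min,sampling_rate,noise_sd Overrides passed to
#'   [scenario_config()] (mainly for small test scenarios).
#' @param intervention_minute Release minute for the intervention study.
#' @return A list of class `fatigue_cohort` with elements `study`,
#'   `recordings` (named list of [eeg_recording()]), `meta` (data frame
#'   `key`, `subject_id`, `group`) and `kss` (data frame).
#' @export
#' @examples
#' coh <- simulate_cohort("identification", n_subjects = 2, seed = 1,
#'                        duration_min = 2)
#' coh$meta
simulate_cohort <- function(study = c("identification", "intervention"),
                            n_subjects = NULL, seed = 1L,
                            duration_min = NULL, sampling_rate = 128,
                            noise_sd = 0.2, intervention_minute = 30) {
  study <- match.arg(study)
  if (is.null(n_subjects)) {
    n_subjects <- if (study == "identification") 14L else 11L
  }
  if (n_subjects < 2) abort("n_subjects must be at least 2")
  if (is.null(duration_min)) {
    duration_min <- if (study == "identification") 30 else 45
  }
  groups <- if (study == "identification") "control" else scent_groups()

  withr::with_seed(seed, {
    sub_seeds <- matrix(
      sample.int(.Machine$integer.max - 2L, n_subjects * length(groups)),
      nrow = n_subjects
    )
    kss_seeds <- sample.int(.Machine$integer.max - 2L, length(groups))
    traits <- rnorm(n_subjects, 0, 1.1)
    rates <- .clip_scale(rnorm(n_subjects, 1, .subject_rate_sd))
    responses <- matrix(
      .clip_scale(rnorm(n_subjects * length(groups), 1, .subject_response_sd)),
      nrow = n_subjects
    )
  })

  recordings <- list()
  meta <- list()
  kss <- list()
  for (g in seq_along(groups)) {
    group <- groups[g]
    for (i in seq_len(n_subjects)) {
      cfg <- scenario_config(
        group = group, study = study, duration_min = duration_min,
        sampling_rate = sampling_rate, n_subjects = 1L,
        intervention_minute = intervention_minute, noise_sd = noise_sd,
        fatigue_rate = rates[i], response_scale = responses[i, g],
        seed = sub_seeds[i, g]
      )
      key <- sprintf("S%02d.%s", i, group)
      recordings[[key]] <- simulate_eeg(cfg)
      meta[[key]] <- data.frame(key = key,
                                subject_id = sprintf("S%02d", i),
                                group = group, stringsAsFactors = FALSE)
    }
    # one KSS table per condition, subject traits shared across conditions
    kss_cfg <- scenario_config(
      group = group, study = study, duration_min = duration_min,
      sampling_rate = sampling_rate, n_subjects = n_subjects,
      intervention_minute = intervention_minute,
      seed = kss_seeds[g]
    )
    kss[[group]] <- simulate_kss(kss_cfg, traits = traits)
  }

  structure(
    list(study = study, recordings = recordings,
         meta = do.call(rbind, c(meta, list(make.row.names = FALSE))),
         kss = do.call(rbind, c(kss, list(make.row.names = FALSE)))),
    class = "fatigue_cohort"
  )
}

.clip_scale <- function(x) {
  pmin(.subject_scale_limits[2], pmax(.subject_scale_limits[1], x))
}

#' @export
print.fatigue_cohort <- function(x, ...) {
  cat("<fatigue_cohort> study:", x$study, "\n")
  cat("  ", length(x$recordings), "recordings;",
      length(unique(x$meta$subject_id)), "subjects x",
      length(unique(x$meta$group)), "condition(s)\n")
  cat("  ", nrow(x$kss), "KSS records at minutes",
      paste(sort(unique(x$kss$time_min)), collapse = ", "), "\n")
  invisible(x)
}
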