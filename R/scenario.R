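# Scenario configuration and the calibration constants behind the
# synthetic cohort generator.  All default magnitudes live here so the
# "study conditions" the generator emulates are defined in one place.

# ---- calibration constants -------------------------------------------------
#
# Band amplitude envelopes (arbitrary signal units; only ratios matter).
# Baselines are chosen so that with unit-variance band processes the
# band-average PSDs reproduce realistic early-drive index values:
# R(alpha/beta) ~ 1.13 and R(theta/(alpha+beta)) ~ 0.83 at minute 5.
# Over 30 min of monotonous driving theta drifts slightly up, alpha
# slightly down, beta down most strongly (the classic alertness
# signature) and gamma down; the drift continues more slowly to 45 min.
.envelope_defaults <- list(
  theta = data.frame(minute = c(0, 30, 45), amp = c(0.700, 0.770, 0.805)),
  alpha = data.frame(minute = c(0, 30, 45), amp = c(0.575, 0.546, 0.535)),
  beta  = data.frame(minute = c(0, 30, 45), amp = c(1.000, 0.820, 0.730)),
  gamma = data.frame(minute = c(0, 30, 45), amp = c(0.500, 0.425, 0.400))
)

# Scent effects are specified as a multiplier rho(u) on the R(alpha/beta)
# scale (u = minutes since odor release): 1 at release, a scent-specific
# nadir, then recovery.  Grapefruit acts fastest (nadir at +2 min),
# peppermint at +3 min with the quickest full recovery, lavender at
# +4 min with the slowest recovery (still suppressed 15 min later).
.rab_effect_knots <- list(
  peppermint = data.frame(minute = c(0, 3, 7),
                          rho    = c(1.00, 0.65, 1.00)),
  grapefruit = data.frame(minute = c(0, 2, 12),
                          rho    = c(1.00, 0.68, 0.98)),
  lavender   = data.frame(minute = c(0, 3, 4, 15),
                          rho    = c(1.00, 0.68, 0.62, 0.72))
)

# rho is realized through the band amplitudes as a beta boost with a mild
# alpha suppression: a_alpha *= rho^(1/8), a_beta *= rho^(-3/8), so that
# R(alpha/beta) = G_alpha/G_beta picks up the factor rho exactly
# (band power scales with amplitude squared).
.rho_alpha_exp <- 1 / 8
.rho_beta_exp  <- -3 / 8

# Between-subject heterogeneity: multiplicative jitter on the fatigue
# progression rate and on the scent response depth.  Truncation keeps all
# amplitudes strictly positive.
.subject_rate_sd      <- 0.4
.subject_response_sd  <- 0.3
.subject_scale_limits <- c(0.2, 1.8)

# KSS latent-scale defaults.  `baseline` is the latent sleepiness at
# `ref_min`; scores drift linearly with time and drop by `drop` after the
# intervention in scented conditions.  Values reproduce the usual
# questionnaire means: identification cohorts move ~2.9 -> ~4.9 over
# 30 min; intervention cohorts move ~ +2.3 over 28-40 min in the control
# condition while scented conditions fall to ~3-4.
.kss_defaults <- function(study, group) {
  if (study == "identification") {
    return(list(ref_min = 0, baseline = 2.929, drift = 2.000 / 30,
                drop = 0, schedule = c(0, 30),
                trait_sd = 1.1, noise_sd = 0.8))
  }
  base <- switch(group,
    control    = list(baseline = 3.000, drop = 0),
    peppermint = list(baseline = 5.000, drop = 4.182),
    grapefruit = list(baseline = 5.000, drop = 4.000),
    lavender   = list(baseline = 5.727, drop = 4.000),
    abort("unknown group '", group, "'")
  )
  c(base, list(ref_min = 28, drift = 2.273 / 12, schedule = c(28, 40),
               trait_sd = 1.1, noise_sd = 0.8))
}

# ---- envelopes -------------------------------------------------------------

#' Default fatigue envelopes for the four EEG bands
#'
#' Piecewise-linear amplitude trajectories (signal units vs minute of
#' driving) encoding the fatigue signature of a monotonous drive: theta
#' amplitude rises slightly, alpha falls slightly, beta falls most
#' strongly of the four bands, and gamma falls.  Band power scales with
#' the squared amplitude, so the beta decline drives the rise of
#' R(alpha/beta) over the session.
#'
#' @return Named list (`theta`, `alpha`, `beta`, `gamma`) of data frames
#'   with columns `minute` and `amp`.
#' @export
#' @examples
#' env <- default_fatigue_envelopes()
#' sapply(env, function(e) e$amp[1])
default_fatigue_envelopes <- function() .envelope_defaults

#' Evaluate a piecewise-linear envelope at given minutes
#'
#' Linear interpolation between knots; constant extrapolation beyond the
#' first/last knot.
#'
#' @param envelope Data frame with columns `minute` and `amp`.
#' @param minute Numeric vector of minutes.
#' @return Numeric vector of amplitudes.
#' @export
eval_envelope <- function(envelope, minute) {
  stopifnot(is.data.frame(envelope), all(c("minute", "amp") %in% names(envelope)))
  approx(envelope$minute, envelope$amp, xout = minute, rule = 2)$y
}

# Scale the *change* of an envelope relative to its baseline (minute-0
# value) by `rate`; models subjects who fatigue faster or slower.
.scale_envelope <- function(envelope, rate) {
  base <- envelope$amp[1]
  envelope$amp <- base + rate * (envelope$amp - base)
  if (any(envelope$amp < 0)) abort("envelope scaling produced a negative amplitude")
  envelope
}

# ---- intervention multipliers ---------------------------------------------

#' Per-band multipliers induced by a scent release
#'
#' Returns the multiplicative effect of a scent on the four band
#' amplitudes as a function of time since the odor release.  The effect
#' is a beta boost with a mild alpha suppression, shaped so the induced
#' R(alpha/beta) trajectory equals a piecewise-linear factor `rho(u)`
#' with nadir at release +2 min (grapefruit), +3 min (peppermint) or
#' +4 min (lavender), recovering fastest for peppermint and slowest for
#' lavender.  At `minutes_since_release = 0` all multipliers are 1 (the
#' effect onsets after release); `"control"` returns identity
#' multipliers.
#'
#' @param scent One of `"peppermint"`, `"grapefruit"`, `"lavender"`,
#'   `"control"`.
#' @param minutes_since_release Numeric vector, minutes elapsed since the
#'   release (values < 0 are treated as pre-release, multiplier 1).
#' @param response_scale Scales the effect depth: the induced factor is
#'   `1 - response_scale * (1 - rho(u))`.  Default 1.
#' @return Numeric matrix, `length(minutes_since_release)` rows and one
#'   column per band (`theta`, `alpha`, `beta`, `gamma`).
#' @export
#' @examples
#' intervention_multiplier("peppermint", c(0, 3, 10))
intervention_multiplier <- function(scent, minutes_since_release,
                                    response_scale = 1) {
  if (!is.character(scent) || length(scent) != 1 ||
      !scent %in% scent_groups()) {
    abort("unknown scent '", paste(scent, collapse = ","),
          "'; expected one of: ", paste(scent_groups(), collapse = ", "))
  }
  u <- as.numeric(minutes_since_release)
  m <- matrix(1, nrow = length(u), ncol = 4,
              dimnames = list(NULL, .band_names))
  if (scent == "control") return(m)
  rho <- .rab_effect(scent, u, response_scale)
  m[, "alpha"] <- rho^.rho_alpha_exp
  m[, "beta"]  <- rho^.rho_beta_exp
  m
}

# Induced R(alpha/beta) factor rho(u) for a scent (vectorized over u).
.rab_effect <- function(scent, u, response_scale = 1) {
  knots <- .rab_effect_knots[[scent]]
  rho <- approx(knots$minute, knots$rho, xout = pmax(u, 0), rule = 2)$y
  rho <- 1 - response_scale * (1 - rho)
  rho[u <= 0] <- 1
  if (any(rho <= 0)) abort("intervention effect collapsed to a non-positive multiplier")
  rho
}

# Materialize the per-band multiplier trajectory as a knot table
# (minutes-since-release grid), the form stored in a ScenarioConfig.
.intervention_effect_table <- function(scent, response_scale = 1,
                                       grid = seq(0, 16, by = 0.25)) {
  m <- intervention_multiplier(scent, grid, response_scale)
  cbind(data.frame(minute = grid), as.data.frame(m))
}

# ---- scenario configuration ------------------------------------------------

#' Scenario configuration for the synthetic cohort generator
#'
#' Bundles everything the generator needs for one condition: session
#' duration, sampling rate, cohort size, condition label, intervention
#' timing, per-band amplitude envelopes, per-band intervention multiplier
#' trajectory, white-noise level, KSS latent-model parameters and the
#' random seed.  Identical `(config, seed)` pairs reproduce identical
#' output.
#'
#' @param group Condition label; one of [scent_groups()].
#' @param duration_min Session length in minutes (> 0).
#' @param sampling_rate Sampling rate in Hz; must be at least 90 Hz
#'   (twice the 45 Hz upper edge of the gamma band).  Default 128 Hz,
#'   the nominal delivery rate of consumer 14-channel headsets.
#' @param n_subjects Number of subjects in the cohort.
#' @param intervention_minute Minute of the scent release (default 30).
#' @param band_envelopes Named list of per-band envelope data frames, as
#'   returned by [default_fatigue_envelopes()].
#' @param intervention_effect `NULL` (derive from `group`) or a data
#'   frame with columns `minute` (minutes since release), `theta`,
#'   `alpha`, `beta`, `gamma` giving the multiplier trajectory.
#' @param noise_sd Standard deviation of the additive white sensor noise
#'   (signal units), independent per channel.  Default 0.2.
#' @param kss `NULL` (defaults for `study`/`group`) or a list with
#'   elements `ref_min`, `baseline`, `drift`, `drop`, `schedule`,
#'   `trait_sd`, `noise_sd`.
#' @param study `"identification"` or `"intervention"`; selects the KSS
#'   questionnaire schedule defaults.
#' @param channel_labels Channel names; default the two temporal-lobe
#'   electrodes `T7`, `T8`.
#' @param fatigue_rate Multiplier on the envelope drift (1 = nominal).
#' @param response_scale Multiplier on the scent effect depth.
#' @param seed Integer seed.
#' @return An object of class `scenario_config` (a validated list).
#' @export
#' @examples
#' cfg <- scenario_config(group = "lavender", study = "intervention",
#'                        duration_min = 45, n_subjects = 11, seed = 1)
#' cfg$intervention_minute
scenario_config <- function(group = "control",
                            duration_min = 30,
                            sampling_rate = 128,
                            n_subjects = 14,
                            intervention_minute = 30,
                            band_envelopes = default_fatigue_envelopes(),
                            intervention_effect = NULL,
                            noise_sd = 0.2,
                            kss = NULL,
                            study = c("identification", "intervention"),
                            channel_labels = c("T7", "T8"),
                            fatigue_rate = 1,
                            response_scale = 1,
                            seed = 1L) {
  study <- match.arg(study)
  group <- match.arg(group, scent_groups())
  if (!is.numeric(duration_min) || duration_min <= 0) {
    abort("duration_min must be positive")
  }
  if (!is.numeric(sampling_rate) || sampling_rate < 2 * .max_band_hz) {
    abort("sampling_rate must be at least ", 2 * .max_band_hz,
          " Hz: twice the ", .max_band_hz,
          " Hz upper edge of the gamma band (Nyquist)")
  }
  if (n_subjects < 1) abort("n_subjects must be at least 1")
  if (!is.list(band_envelopes) ||
      !all(.band_names %in% names(band_envelopes))) {
    abort("band_envelopes must be a named list with elements ",
          paste(.band_names, collapse = ", "))
  }
  if (fatigue_rate != 1) {
    band_envelopes <- lapply(band_envelopes, .scale_envelope, rate = fatigue_rate)
  }
  for (b in .band_names) {
    if (any(band_envelopes[[b]]$amp < 0)) {
      abort("band envelope '", b, "' has a negative amplitude")
    }
  }
  if (is.null(intervention_effect) && group != "control") {
    intervention_effect <- .intervention_effect_table(group, response_scale)
  }
  if (!is.null(intervention_effect)) {
    need <- c("minute", .band_names)
    if (!all(need %in% names(intervention_effect))) {
      abort("intervention_effect must have columns ",
            paste(need, collapse = ", "))
    }
    if (any(as.matrix(intervention_effect[.band_names]) <= 0)) {
      abort("intervention multipliers must be strictly positive")
    }
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) abort("noise_sd must be >= 0")
  if (is.null(kss)) kss <- .kss_defaults(study, group)
  structure(
    list(
      study = study,
      group = group,
      duration_min = duration_min,
      sampling_rate = sampling_rate,
      n_subjects = as.integer(n_subjects),
      intervention_minute = intervention_minute,
      band_envelopes = band_envelopes,
      intervention_effect = intervention_effect,
      noise_sd = noise_sd,
      kss = kss,
      channel_labels = channel_labels,
      seed = as.integer(seed)
    ),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat("  study:", x$study, "  group:", x$group, "\n")
  cat("  duration:", x$duration_min, "min at", x$sampling_rate, "Hz;",
      x$n_subjects, "subjects\n")
  cat("  intervention at minute", x$intervention_minute,
      if (is.null(x$intervention_effect)) "(no scent effect)" else "", "\n")
  cat("  noise_sd:", x$noise_sd, "  seed:", x$seed, "\n")
  invisible(x)
}
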