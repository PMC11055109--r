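# The three band-power ratio fatigue indices.

.check_band_power <- function(G, need) {
  if (!is.data.frame(G) && !is.list(G)) {
    abort("band power input must be a list or data frame of G_ values")
  }
  if (!all(need %in% names(G))) {
    abort("band power input must have elements ", paste(need, collapse = ", "))
  }
  G
}

#' Alpha/beta fatigue ratio
#'
#' `R(alpha/beta) = G_alpha / G_beta`, the ratio of alpha to beta
#' band-average PSD.  Rises as drivers tire because beta (fast-wave)
#' power falls more steeply than alpha power.
#'
#' @param G A list or one-row data frame with `G_alpha` and `G_beta`.
#' @return The index value.
#' @export
#' @examples
#' ratio_alpha_beta(list(G_alpha = 1.129, G_beta = 1))
ratio_alpha_beta <- function(G) {
  G <- .check_band_power(G, c("G_alpha", "G_beta"))
  if (any(G$G_beta <= 0)) {
    abort("R(alpha/beta) is undefined: G_beta must be strictly positive")
  }
  G$G_alpha / G$G_beta
}

#' Theta/(alpha+beta) fatigue ratio
#'
#' `R(theta/(alpha+beta)) = G_theta / (G_alpha + G_beta)`, computed on
#' band-average PSD values.
#'
#' @inheritParams ratio_alpha_beta
#' @return The index value.
#' @export
ratio_theta_ab <- function(G) {
  G <- .check_band_power(G, c("G_theta", "G_alpha", "G_beta"))
  den <- G$G_alpha + G$G_beta
  if (any(den <= 0)) {
    abort("R(theta/(alpha+beta)) is undefined: G_alpha + G_beta must be positive")
  }
  G$G_theta / den
}

#' (Alpha+theta)/(alpha+beta) fatigue ratio
#'
#' `R((alpha+theta)/(alpha+beta)) = (G_alpha + G_theta) / (G_alpha +
#' G_beta)`.  For positive inputs it always exceeds the theta ratio by
#' `G_alpha / (G_alpha + G_beta)`, a quantity in (0, 1).
#'
#' @inheritParams ratio_alpha_beta
#' @return The index value.
#' @export
ratio_alphatheta_ab <- function(G) {
  G <- .check_band_power(G, c("G_theta", "G_alpha", "G_beta"))
  den <- G$G_alpha + G$G_beta
  if (any(den <= 0)) {
    abort("R((alpha+theta)/(alpha+beta)) is undefined: G_alpha + G_beta must be positive")
  }
  (G$G_alpha + G$G_theta) / den
}

#' Per-epoch fatigue index series
#'
#' Computes the three ratio indices for every row of a band-power series,
#' preserving epoch order.
#'
#' @param band_powers Data frame from [band_power_series()].
#' @param subject_id,condition Optional labels carried into the output.
#' @return Data frame with columns `start_min`, `R_ab`, `R_t_ab`,
#'   `R_at_ab` (plus `subject_id`/`condition` when given).
#' @export
index_series <- function(band_powers, subject_id = NULL, condition = NULL) {
  if (!nrow(band_powers)) abort("band_powers must be non-empty")
  out <- data.frame(
    start_min = band_powers$start_min,
    R_ab = ratio_alpha_beta(band_powers),
    R_t_ab = ratio_theta_ab(band_powers),
    R_at_ab = ratio_alphatheta_ab(band_powers)
  )
  if (!is.null(subject_id)) out$subject_id <- subject_id
  if (!is.null(condition)) out$condition <- condition
  out
}

#' Full per-minute analysis of one recording
#'
#' The standard pipeline: first-order 0.16 Hz high-pass, temporal-channel
#' averaging, 1-min epoching, periodogram band powers and the three ratio
#' indices.
#'
#' @param recording An [eeg_recording()].
#' @param window_s Epoch length in seconds (default 60).
#' @param cutoff_hz High-pass cutoff in Hz (default 0.16).
#' @param channels Channels to average (default all).
#' @return Data frame with `start_min`, the four `G_` band powers and the
#'   three `R_` indices, one row per epoch.
#' @export
#' @examples
#' cfg <- scenario_config(duration_min = 3, n_subjects = 1, seed = 1)
#' head(compute_index_series(simulate_eeg(cfg)), 3)
compute_index_series <- function(recording, window_s = 60,
                                 cutoff_hz = 0.16, channels = NULL) {
  stopifnot(inherits(recording, "eeg_recording"))
  rec <- highpass(recording, cutoff_hz)
  rec <- aggregate_temporal(rec, channels)
  g <- band_power_series(epoch_recording(rec, window_s))
  cbind(g, index_series(g)[c("R_ab", "R_t_ab", "R_at_ab")])
}
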