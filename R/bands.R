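#' Canonical EEG frequency bands
#'
#' The four bands used throughout the fatigue analysis: theta (4-8 Hz),
#' alpha (8-12 Hz), beta (12-25 Hz) and gamma (25-45 Hz).  Band intervals
#' are treated as half-open `[low, high)` everywhere in the package, so a
#' shared edge (e.g. 8 Hz) belongs to exactly one band and the four bands
#' partition 4-45 Hz without double counting.
#'
#' @return A data frame with columns `band`, `low` and `high` (Hz).
#' @export
#' @examples
#' eeg_bands()
eeg_bands <- function() {
  data.frame(
    band = c("theta", "alpha", "beta", "gamma"),
    low  = c(4, 8, 12, 25),
    high = c(8, 12, 25, 45),
    stringsAsFactors = FALSE
  )
}

.band_names <- c("theta", "alpha", "beta", "gamma")

.band_edges <- function(band) {
  bands <- eeg_bands()
  i <- match(band, bands$band)
  if (is.na(i)) {
    abort("unknown band '", band, "'; expected one of: ",
          paste(bands$band, collapse = ", "))
  }
  c(low = bands$low[i], high = bands$high[i])
}

# Highest band edge; the sampling rate must resolve it (Nyquist).
.max_band_hz <- 45

#' Condition labels used by the intervention study
#' @return Character vector of the four condition labels.
#' @export
scent_groups <- function() c("control", "peppermint", "grapefruit", "lavender")
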