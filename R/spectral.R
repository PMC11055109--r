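# Classical direct-method spectral estimation and band-average PSD.

#' Periodogram of one epoch (classical direct method)
#'
#' One-sided power spectral density estimated as the squared magnitude
#' of the epoch's DFT with a rectangular window and no segment averaging
#' (the classical "direct method").  Scaled as a density so that the
#' rectangle-rule integral of `psd` over frequency equals the epoch's
#' mean squared amplitude (Parseval).
#'
#' @param epoch An epoch from [epoch_recording()], or a numeric vector
#'   with `sampling_rate` supplied.
#' @param sampling_rate Required for vector input.
#' @return Object of class `power_spectrum`: list with `freqs` (Hz, from
#'   0 to Nyquist), `psd` (signal-units^2/Hz) and `resolution`
#'   (`fs / n` Hz).
#' @export
#' @examples
#' fs <- 128
#' x <- sin(2 * pi * 10 * (0:(fs * 4 - 1)) / fs)
#' ps <- periodogram(x, sampling_rate = fs)
#' sum(ps$psd) * ps$resolution  # ~ mean(x^2) = 0.5
periodogram <- function(epoch, sampling_rate = NULL) {
  if (inherits(epoch, "eeg_epoch")) {
    x <- epoch$samples
    fs <- epoch$sampling_rate
  } else {
    x <- as.numeric(epoch)
    if (is.null(sampling_rate)) abort("sampling_rate is required for vector input")
    fs <- sampling_rate
  }
  n <- length(x)
  if (n < 2) abort("epoch must contain at least 2 samples")
  if (!all(is.finite(x))) abort("epoch contains non-finite samples")
  X <- fft(x)
  two_sided <- (Mod(X)^2) / (n * fs)      # density: sum * (fs/n) = mean(x^2)
  half <- floor(n / 2)
  idx <- seq_len(half + 1L)               # DC .. Nyquist (n even)
  psd <- two_sided[idx]
  dbl <- 2:(if (n %% 2 == 0) half else half + 1L)  # bins with a mirror image
  psd[dbl] <- 2 * psd[dbl]
  structure(
    list(freqs = (idx - 1L) * fs / n, psd = psd, resolution = fs / n),
    class = "power_spectrum"
  )
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat("<power_spectrum> ", length(x$freqs), " bins, 0-",
      max(x$freqs), " Hz, resolution ", signif(x$resolution, 4), " Hz\n",
      sep = "")
  invisible(x)
}

#' Band-average power spectral density
#'
#' The integral of the PSD over a half-open band `[low, high)` divided by
#' the bandwidth `high - low`: `G_band = (1 / (b - a)) * int_a^b P(f) df`.
#' Integration uses the rectangle rule (bin value times the grid
#' resolution), which matches the periodogram's Parseval scaling exactly.
#'
#' @param spectrum A `power_spectrum` from [periodogram()].
#' @param band A band name (`"theta"`, `"alpha"`, `"beta"`, `"gamma"`) or
#'   a numeric `c(low, high)` in Hz.
#' @return The band-average PSD (signal-units^2/Hz).
#' @export
#' @examples
#' fs <- 128
#' x <- sin(2 * pi * 10 * (0:(fs * 60 - 1)) / fs)
#' ps <- periodogram(x, sampling_rate = fs)
#' band_average(ps, "alpha")  # ~ 0.5 / 4
band_average <- function(spectrum, band) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  if (is.character(band)) band <- .band_edges(band)
  if (length(band) != 2 || band[2] <= band[1]) {
    abort("band must be c(low, high) with high > low")
  }
  nyq <- max(spectrum$freqs)
  if (band[1] < 0 || band[2] > nyq + spectrum$resolution / 2) {
    abort("band [", band[1], ", ", band[2],
          ") exceeds the spectrum's 0-", nyq, " Hz range")
  }
  band <- unname(band)
  sel <- spectrum$freqs >= band[1] & spectrum$freqs < band[2]
  if (!any(sel)) {
    abort("no grid frequency falls inside [", band[1], ", ", band[2],
          ") Hz at resolution ", signif(spectrum$resolution, 4), " Hz")
  }
  sum(spectrum$psd[sel]) * spectrum$resolution / (band[2] - band[1])
}

#' Per-epoch band-average PSD series
#'
#' Applies [periodogram()] and [band_average()] to every epoch, giving
#' one set of the four band powers `G_theta, G_alpha, G_beta, G_gamma`
#' per epoch, ordered by epoch start time.
#'
#' @param epochs List of epochs from [epoch_recording()].
#' @return Data frame with columns `start_min`, `G_theta`, `G_alpha`,
#'   `G_beta`, `G_gamma`.
#' @export
band_power_series <- function(epochs) {
  if (!length(epochs)) abort("epochs must be a non-empty list")
  bands <- eeg_bands()
  rows <- lapply(epochs, function(ep) {
    ps <- periodogram(ep)
    g <- vapply(seq_len(nrow(bands)),
                function(i) band_average(ps, c(bands$low[i], bands$high[i])),
                numeric(1))
    data.frame(start_min = ep$start_min,
               G_theta = g[1], G_alpha = g[2], G_beta = g[3], G_gamma = g[4])
  })
  out <- do.call(rbind, rows)
  out[order(out$start_min), , drop = FALSE]
}
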