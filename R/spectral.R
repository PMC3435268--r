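# The three spectral estimators: Hann-tapered PSD snapshots per epoch,
# Morlet wavelet dynamic spectra (5 cycles by default), and
# Butterworth-filtered Hilbert analytic bands.

#' Hann-window PSD snapshots
#'
#' One-sided Hann-tapered periodogram of each epoch, normalised to uV^2/Hz
#' with the taper power correction so that `sum(P) * df` equals the variance
#' of the tapered signal divided by the mean squared taper. The frequency
#' resolution is `1/T` for epochs of duration `T`.
#'
#' @param x numeric vector (one channel's samples) or a
#'   `recording_session` (then `channel` selects the row).
#' @param epochs an `epoch_set` of constant duration.
#' @param rate sampling rate; taken from the session when `x` is one.
#' @param channel channel index when `x` is a session.
#' @param drop_dc drop the 0 Hz bin (default TRUE).
#' @param line_noise_hz,line_noise_halfwidth when non-NULL, bins inside the
#'   line-noise bands (base and harmonics, +/- halfwidth) are removed from
#'   the grid.
#' @return object of class `spectral_snapshot`: list with `freq` (Hz),
#'   `power` (freq x epoch matrix), `condition` (per epoch), `rate`.
#' @export
psd_snapshots <- function(x, epochs, rate = NULL, channel = 1,
                          drop_dc = TRUE, line_noise_hz = NULL,
                          line_noise_halfwidth = 3) {
  if (inherits(x, "recording_session")) {
    rate <- x$rate
    x <- x$samples[channel, ]
  }
  if (is.null(rate)) stop("rate required")
  stopifnot(length(unique(epochs$duration)) == 1)
  nfft <- epochs$duration[1]
  if (any(epochs$start < 0 | epochs$start + nfft > length(x)))
    stop("epoch outside record")
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nfft - 1) / nfft))  # periodic Hann
  u <- sum(w^2)                                           # taper power
  nf <- nfft %/% 2
  freq <- seq(0, nf) * rate / nfft
  pw <- vapply(seq_len(nrow(epochs)), function(i) {
    seg <- x[epochs$start[i] + seq_len(nfft)] * w
    X <- stats::fft(seg)[seq_len(nf + 1)]
    p <- Mod(X)^2 / (rate * u)
    # one-sided: double all but DC (and Nyquist when present)
    if (nfft %% 2 == 0) p[2:nf] <- 2 * p[2:nf] else p[2:(nf + 1)] <- 2 * p[2:(nf + 1)]
    p
  }, numeric(nf + 1))
  keep <- rep(TRUE, length(freq))
  if (drop_dc) keep[1] <- FALSE
  if (!is.null(line_noise_hz))
    keep <- keep & !line_noise_mask(freq, line_noise_hz, line_noise_halfwidth)
  structure(list(freq = freq[keep], power = pw[keep, , drop = FALSE],
                 condition = epochs$condition, rate = rate),
            class = "spectral_snapshot")
}

#' Morlet wavelet dynamic spectrum
#'
#' Convolves the signal with a unit-energy complex Morlet wavelet at each
#' grid frequency (Gaussian envelope of `cycles / (2*pi*f)` SD), giving a
#' complex time-varying Fourier coefficient per frequency and sample. The
#' first and last `cycles` periods at each frequency are flagged as edge
#' samples.
#'
#' @param x numeric signal.
#' @param grid frequencies in Hz, all below Nyquist.
#' @param rate sampling rate.
#' @param cycles wavelet cycles (default 5).
#' @return object of class `dynamic_spectrum`: list with `freq`, `coef`
#'   (freq x time complex matrix), `edge` (freq x time logical), `cycles`,
#'   `rate`.
#' @export
morlet_spectrogram <- function(x, grid, rate, cycles = 5) {
  if (any(grid >= rate / 2)) stop("frequency at or above Nyquist")
  if (any(grid <= 0)) stop("frequencies must be positive")
  n <- length(x)
  coef <- matrix(0i, length(grid), n)
  edge <- matrix(FALSE, length(grid), n)
  for (i in seq_along(grid)) {
    coef[i, ] <- conv_same(x, morlet_kernel(grid[i], rate, cycles))
    ne <- min(n, ceiling(cycles / grid[i] * rate))
    edge[i, seq_len(ne)] <- TRUE
    edge[i, n - seq_len(ne) + 1] <- TRUE
  }
  structure(list(freq = grid, coef = coef, edge = edge, cycles = cycles,
                 rate = rate),
            class = "dynamic_spectrum")
}

#' Band-limited analytic signal
#'
#' Band-passes the signal with a zero-phase (forward-backward) Butterworth
#' filter and extends it to its analytic signal with the Hilbert transform,
#' yielding the analytic amplitude `a(t) = Mod(z)` and phase
#' `phi(t) = Arg(z)` in `(-pi, pi]`. Phase 0 marks the most surface-positive
#' point of the band-limited potential.
#'
#' @param x numeric signal.
#' @param band `c(low, high)` in Hz inside `(0, rate/2)`.
#' @param rate sampling rate.
#' @param order Butterworth prototype order (default 3; forward-backward
#'   application makes the effective magnitude response order 6).
#' @return object of class `analytic_band`: list with `z` (complex series),
#'   `amplitude`, `phase`, `band`, `order`, `rate`.
#' @export
analytic_band <- function(x, band, rate, order = 3) {
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] ||
      band[2] >= rate / 2)
    stop("degenerate band: need 0 < low < high < rate/2")
  coefs <- butter_bandpass(band[1], band[2], rate, order)
  filt <- filtfilt_iir(coefs, x, padlen = min(length(x) - 1,
                                              round(3 * rate / band[1])))
  z <- hilbert_analytic(filt)
  structure(list(z = z, amplitude = Mod(z), phase = Arg(z), band = band,
                 order = order, rate = rate),
            class = "analytic_band")
}
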