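# Low-level signal-processing primitives: Butterworth band-pass design,
# zero-phase filtering, and the FFT Hilbert transform. The environment has no
# filter-design package, so the classic bilinear-transform recipe is spelled
# out here and pinned down by frequency-response tests.

#' Digital Butterworth band-pass coefficients
#'
#' Designs an order-`order` analog Butterworth low-pass prototype, transforms
#' it to a band-pass (doubling the order), and maps it to the digital domain
#' with the bilinear transform (cutoffs prewarped). Returns transfer-function
#' coefficients normalised so `a[1] == 1`.
#'
#' @param low,high band edges in Hz; `0 < low < high < rate/2`.
#' @param rate sampling rate in samples/s.
#' @param order analog prototype order (default 3, giving a 6th-order
#'   band-pass).
#' @return list with numeric vectors `b` (numerator) and `a` (denominator).
#' @export
butter_bandpass <- function(low, high, rate, order = 3) {
  if (!(low > 0 && high > low && high < rate / 2))
    stop("band edges must satisfy 0 < low < high < rate/2")
  n <- as.integer(order)
  fs2 <- 2 * rate
  w1 <- fs2 * tan(pi * low / rate)
  w2 <- fs2 * tan(pi * high / rate)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  k <- seq_len(n)
  proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))  # LHP poles, |p| = 1
  # low-pass -> band-pass: each prototype pole splits into two
  s <- bw * proto / 2
  poles <- c(s + sqrt(s^2 - w0^2), s - sqrt(s^2 - w0^2))
  zeros <- rep(0 + 0i, n)
  gain <- bw^n
  # bilinear transform
  zd_p <- (fs2 + poles) / (fs2 - poles)
  zd_z <- (fs2 + zeros) / (fs2 - zeros)
  gain_d <- gain * Re(prod(fs2 - zeros) / prod(fs2 - poles))
  zd_z <- c(zd_z, rep(-1 + 0i, length(poles) - length(zeros)))
  b <- Re(poly_from_roots(zd_z)) * gain_d
  a <- Re(poly_from_roots(zd_p))
  list(b = b / a[1], a = a / a[1])
}

# Monic polynomial coefficients (descending powers) from complex roots.
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

# Complex frequency response H(e^{i 2 pi f / rate}) of (b, a) at f in Hz.
filter_response <- function(coef, f, rate) {
  z <- exp(-1i * 2 * pi * f / rate)
  nb <- length(coef$b); na <- length(coef$a)
  num <- vapply(z, function(zi) sum(coef$b * zi^(0:(nb - 1))), complex(1))
  den <- vapply(z, function(zi) sum(coef$a * zi^(0:(na - 1))), complex(1))
  num / den
}

# Zero-phase (forward-backward) IIR filtering with odd-reflection padding.
# Pad length defaults to enough samples to let band transients die out.
filtfilt_iir <- function(coef, x, padlen = NULL) {
  n <- length(x)
  ord <- max(length(coef$a), length(coef$b)) - 1
  if (is.null(padlen)) padlen <- min(n - 1, max(3 * ord, 250L))
  if (padlen > 0) {
    left <- 2 * x[1] - x[seq(padlen + 1, 2)]
    right <- 2 * x[n] - x[seq(n - 1, n - padlen)]
    xe <- c(left, x, right)
  } else xe <- x
  y <- iir_filter_cpp(coef$b, coef$a, xe)
  y <- rev(iir_filter_cpp(coef$b, coef$a, rev(y)))
  y[seq(padlen + 1, padlen + n)]
}

# Analytic signal via the FFT method: z(t) = x(t) + i * H[x](t).
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Unit-energy complex Morlet kernel for frequency f (Hz): Gaussian envelope
# with sigma_t = cycles / (2 pi f), truncated at +/- 4 sigma.
morlet_kernel <- function(f, rate, cycles = 5) {
  sigma <- cycles / (2 * pi * f)
  half <- ceiling(4 * sigma * rate)
  t <- seq(-half, half) / rate
  w <- exp(-t^2 / (2 * sigma^2)) * exp(1i * 2 * pi * f * t)
  w / sqrt(sum(Mod(w)^2))
}

# FFT convolution of x with complex kernel k ("same" alignment, reflect pad).
conv_same <- function(x, k) {
  n <- length(x); m <- length(k); half <- (m - 1) / 2
  pad <- min(n - 1, half + 1)
  xe <- c(x[seq(pad + 1, 2)], x, x[seq(n - 1, n - pad)])
  ne <- length(xe) + m - 1
  nfft <- stats::nextn(ne, 2)
  X <- stats::fft(c(xe, rep(0, nfft - length(xe))))
  K <- stats::fft(c(k, rep(0, nfft - m)))
  y <- stats::fft(X * K, inverse = TRUE) / nfft
  y[seq(pad + half + 1, pad + half + n)]
}

# Gaussian smoothing with kernel standard deviation sd_samp (in samples).
gauss_smooth <- function(x, sd_samp) {
  if (sd_samp <= 0) return(x)
  half <- ceiling(4 * sd_samp)
  k <- exp(-(seq(-half, half))^2 / (2 * sd_samp^2))
  k <- k / sum(k)
  Re(conv_same(x, as.complex(k)))
}
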