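# Shared fixtures and independent oracles used across the suite.

# Independent PSD-slope oracle: segment-averaged Hann periodogram computed
# from first principles (base fft only), then a log-log regression.
fit_psd_slope <- function(x, rate, nseg = 32, fmin = 1, fmax = 0.375 * rate) {
  L <- length(x) %/% nseg
  w <- 0.5 * (1 - cos(2 * pi * seq(0, L - 1) / L))
  P <- 0
  for (s in seq_len(nseg))
    P <- P + Mod(stats::fft(x[(s - 1) * L + 1:L] * w)[2:(L %/% 2)])^2
  f <- seq_len(L %/% 2 - 1) * rate / L
  keep <- f >= fmin & f <= fmax
  unname(stats::coef(stats::lm(log(P[keep]) ~ log(f[keep])))[2])
}

# Analytic sideband-attenuation oracle for envelope modulation through the
# band-power chain: ratio of modulation passed at rhythm frequency fr given
# a 1/f^chi input spectrum and the zero-phase Butterworth responses. Closed
# form up to numerical quadrature; independent of the measurement path.
kappa_bandpower <- function(band, rate, fr, chi, line_noise_hz = 50,
                            line_noise_halfwidth = 5) {
  subs <- list(band)
  if (!is.null(line_noise_hz)) {
    cuts <- seq(line_noise_hz, band[2], by = line_noise_hz)
    cuts <- cuts[cuts > band[1] & cuts < band[2]]
    if (length(cuts) > 0) {
      edges <- sort(c(band, cuts - line_noise_halfwidth,
                      cuts + line_noise_halfwidth))
      subs <- lapply(seq(1, length(edges) - 1, by = 2),
                     function(i) edges[c(i, i + 1)])
    }
  }
  f <- seq(0.5, rate / 2 - 0.5, by = 0.25)
  G <- rep(0, length(f))
  for (sb in subs) {
    co <- butter_bandpass(sb[1], sb[2], rate)
    G <- G + Mod(ecogpac:::filter_response(co, f, rate))^2
  }
  Gat <- function(ff) {
    out <- stats::approx(f, G, xout = ff, rule = 2)$y
    out[ff < min(f) | ff > max(f)] <- 0
    out
  }
  S <- function(ff) ifelse(ff > 0, ff^(-chi), 0)
  sum(Gat(f) * (Gat(f - fr) * S(f - fr) + Gat(f + fr) * S(f + fr))) /
    (2 * sum(Gat(f)^2 * S(f)))
}

# first Fourier cosine coefficient of ln(1 + d cos x), and its inverse
log_envelope_a1 <- function(d) 2 * (1 - sqrt(1 - d^2)) / d
invert_a1 <- function(y) 4 * y / (4 + y^2)

# 95% binomial interval for an observed fraction under nominal p
binom_ci <- function(n, p) stats::qbinom(c(0.025, 0.975), n, p) / n

# small task session shared by several files (cached per run)
small_task_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(n_channels = 4, rate = 400,
                          task = list(fingers = c("thumb", "index"),
                                      cues_per_finger = 4,
                                      move_s = 2, rest_s = 2),
                          seed = 42)
      cache <<- make_session(cfg)
    }
    cache
  }
})

# constructed array: shared 16 Hz rhythm on the first n_in channels only
coh_session <- function(n_in = 3, n_out = 3, rate = 400, secs = 40,
                        noise_in = 0.2, noise_out = 0.6, seed = 4) {
  set.seed(seed)
  n <- secs * rate
  phi <- (2 * pi * 16 * seq_len(n) / rate + 0.05 * cumsum(rnorm(n))) %%
    (2 * pi) - pi
  amps <- seq(1.4, 1.0, length.out = n_in)
  m <- rbind(matrix(rnorm(n_in * n, sd = noise_in), n_in, n) +
               outer(amps, cos(phi)),
             matrix(rnorm(n_out * n, sd = noise_out), n_out, n))
  list(session = recording_session(m, rate),
       epochs = epoch_set(seq(0, n - rate, by = rate), rate, "rest"),
       phi = phi)
}
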