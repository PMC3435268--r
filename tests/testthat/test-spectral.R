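test_that("Hann PSD puts an on-grid tone in its exact bin", {
  rate <- 1000
  x <- cos(2 * pi * 10 * seq(0, 4, by = 1 / rate))
  ep <- epoch_set(c(0, 1000, 2000), 1000, "tone")
  ps <- psd_snapshots(x, ep, rate)
  expect_equal(ps$freq[apply(ps$power, 2, which.max)], rep(10, 3))
  expect_equal(diff(ps$freq)[1], 1)   # grid resolution 1/T
  expect_true(all(ps$power >= 0))
})

test_that("white-noise PSD is flat and Parseval holds with taper correction", {
  rate <- 500
  set.seed(3)
  x <- rnorm(300 * rate)
  ep <- epoch_set(seq(0, length(x) - rate, by = rate), rate, "noise")
  ps <- psd_snapshots(x, ep, rate, drop_dc = FALSE)
  m <- rowMeans(ps$power)
  mid <- which(ps$freq > 5 & ps$freq < rate / 2 - 5)
  # per-bin means keep 1/sqrt(n_epochs) fluctuation; flatness is asserted
  # on 20-bin block averages
  blocks <- split(m[mid], (seq_along(mid) - 1) %/% 20)
  bm <- vapply(blocks, mean, numeric(1))
  expect_lt(max(abs(bm / mean(bm) - 1)), 0.05)
  # Parseval: sum(P) * df == sum((x*w)^2) / sum(w^2), per epoch
  i <- 5
  seg <- x[ep$start[i] + 1:rate]
  w <- 0.5 * (1 - cos(2 * pi * seq(0, rate - 1) / rate))
  expect_equal(sum(ps$power[, i]) * 1, sum((seg * w)^2) / sum(w^2),
               tolerance = 1e-10)
})

test_that("line-noise bins are omitted on request", {
  ps <- psd_snapshots(rnorm(2000), epoch_set(0, 1000), rate = 1000,
                      line_noise_hz = 60, line_noise_halfwidth = 3)
  expect_false(any(abs(ps$freq - 60) <= 3 | abs(ps$freq - 120) <= 3))
  expect_error(psd_snapshots(rnorm(100), epoch_set(50, 100), rate = 100),
               "outside record")
})

test_that("Morlet spectrogram localises tones in frequency and phase", {
  rate <- 400
  t <- seq(0, 10, by = 1 / rate)
  f0 <- 16
  x <- cos(2 * pi * f0 * t)
  dyn <- morlet_spectrogram(x, c(8, 12, 16, 20, 24), rate)
  interior <- which(!dyn$edge[3, ])
  expect_true(all(apply(Mod(dyn$coef[, interior]), 2, which.max) == 3))
  # phase advances at 2*pi*f0 rad/s against the tone's analytic phase
  ph <- Arg(dyn$coef[3, interior])
  true_ph <- ((2 * pi * f0 * t[interior] + pi) %% (2 * pi)) - pi
  dphi <- Arg(exp(1i * (ph - true_ph)))
  expect_lt(max(abs(dphi)), 0.02)
  expect_error(morlet_spectrogram(x, c(10, 300), rate), "Nyquist")
})

test_that("impulse response envelope width scales as cycles/frequency", {
  rate <- 1000
  x <- numeric(8000); x[4000] <- 1
  cycles <- 5
  widths <- vapply(c(10, 20), function(f) {
    dyn <- morlet_spectrogram(x, f, rate, cycles)
    env <- Mod(dyn$coef[1, ])
    sum(env >= max(env) * exp(-0.5))      # 2 sigma_t in samples
  }, numeric(1))
  sigma_expect <- cycles / (2 * pi * c(10, 20)) * rate
  expect_equal(widths, 2 * sigma_expect, tolerance = 0.1)
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.05)
})

test_that("analytic band recovers a passband tone's amplitude and phase", {
  rate <- 1000
  t <- seq(0, 5, by = 1 / rate)
  ab <- analytic_band(cos(2 * pi * 16 * t), c(12, 20), rate)
  ss <- 1000:4000
  expect_equal(mean(ab$amplitude[ss]), 1, tolerance = 0.05)
  # phase 0 at the surface-positive peaks of the tone
  peaks <- which(abs((16 * t) %% 1) < 1e-9)
  peaks <- peaks[peaks > 1000 & peaks < 4000]
  expect_lt(max(abs(ab$phase[peaks])), 0.02)
  expect_true(all(ab$phase > -pi & ab$phase <= pi))
  expect_error(analytic_band(rnorm(100), c(20, 12), 1000), "degenerate")
})

test_that("stopband attenuation matches the filter-response oracle", {
  rate <- 1000
  t <- seq(0, 5, by = 1 / rate)
  # forward-backward filtering applies |H|^2; at 25 Hz the attenuation is
  # moderate enough to be measured above edge-transient residue
  ab25 <- analytic_band(cos(2 * pi * 25 * t), c(12, 20), rate)
  H25 <- Mod(ecogpac:::filter_response(butter_bandpass(12, 20, rate),
                                       25, rate))^2
  expect_equal(mean(ab25$amplitude[1000:4000]), H25, tolerance = 0.1 * H25)
  # far stopband: tiny residual
  ab40 <- analytic_band(cos(2 * pi * 40 * t), c(12, 20), rate)
  expect_lt(mean(ab40$amplitude[1000:4000]), 1e-3)
})

test_that("analytic amplitude ignores an out-of-band tone", {
  rate <- 1000
  t <- seq(0, 6, by = 1 / rate)
  x <- cos(2 * pi * 16 * t)
  ab0 <- analytic_band(x, c(12, 20), rate)
  ab1 <- analytic_band(x + 2 * cos(2 * pi * 55 * t), c(12, 20), rate)
  ss <- 1000:5000
  expect_lt(max(abs(ab1$amplitude[ss] - ab0$amplitude[ss])), 0.01)
})

test_that("Morlet and Hann band powers agree on a stationary signal", {
  rate <- 400
  n <- 2^15
  set.seed(9)
  x <- rnorm(n) + 0.5 * cos(2 * pi * 16 * seq_len(n) / rate)
  ep <- epoch_set(seq(0, n - rate, by = rate), rate, "a")
  ps <- psd_snapshots(x, ep, rate, drop_dc = FALSE)
  sel <- ps$freq >= 10 & ps$freq <= 30
  hann_bp <- sum(rowMeans(ps$power)[sel])
  dyn <- morlet_spectrogram(x, 10:30, rate)
  mor <- rowMeans(Mod(dyn$coef[, !dyn$edge[1, ]])^2)
  mor_bp <- sum(mor) * 2 / rate       # unit-energy wavelet -> uV^2/Hz
  expect_equal(mor_bp / hann_bp, 1, tolerance = 0.1)
})
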