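# Constructed spectral ensembles with known factor structure drive the PSC
# tests: power = exp(broadband factor * flat weights + rhythm factor * beta
# weights + mean spectrum).
# The frequency grid spans 1-200 Hz as in the standard decomposition: a
# narrow rhythm bump is then nearly orthogonal to the flat broadband
# loading, which is what makes the factors separable by PCA.
make_two_factor <- function(n_epochs = 80, rhythm_sd = 0.5, seed = 21) {
  set.seed(seed)
  freq <- 1:200
  meanlog <- -2 * log(freq)
  cond <- rep(c("movement", "rest"), each = n_epochs / 2)
  bb <- rnorm(n_epochs, 0, 0.4)                       # spectrum-wide factor
  bb <- bb - mean(bb)
  ry <- rnorm(n_epochs, 0, rhythm_sd)
  ry <- ry - bb * sum(ry * bb) / sum(bb^2)            # in-sample orthogonal
  ry <- ry + ifelse(cond == "movement", -1, 1)
  g <- exp(-(freq - 16)^2 / (2 * 3^2))                # beta-shaped weights
  P <- exp(outer(rep(1, length(freq)), bb) + outer(g, ry) + meanlog)
  structure(list(freq = freq, power = P, condition = cond, rate = 400),
            class = "spectral_snapshot")
}

test_that("a rank-1 common-gain ensemble gives a flat 1st PSC at ~100%", {
  set.seed(4)
  freq <- 1:50
  P <- exp(outer(rep(1, 50), rnorm(40, 0, 0.5)) - 2 * log(freq))
  snap <- structure(list(freq = freq, power = P,
                         condition = rep("a", 40), rate = 400),
                    class = "spectral_snapshot")
  d <- psc_decompose(snap)
  expect_gt(d$eigenvalues[1] / sum(d$eigenvalues), 0.999)
  e1 <- d$vectors[, 1]
  expect_lt(max(abs(e1 - mean(e1))), 1e-6)            # flat
  expect_gt(mean(e1), 0)                              # sign convention
})

test_that("decompositions are orthonormal with conserved eigenvalue sum", {
  for (seed in 1:3) {
    snap <- make_two_factor(seed = seed)
    d <- psc_decompose(snap)
    K <- ncol(d$vectors)
    expect_equal(crossprod(d$vectors), diag(K), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(sum(d$eigenvalues), length(d$freq), tolerance = 1e-8)
    expect_true(all(diff(d$eigenvalues) <= 1e-12))
  }
})

test_that("an independent beta block loads one of PSCs 2-4", {
  d <- psc_decompose(make_two_factor())
  beta <- d$freq >= 12 & d$freq <= 20
  conc <- vapply(2:4, function(k)
    sum(d$vectors[beta, k]^2) / sum(d$vectors[, k]^2), numeric(1))
  expect_gt(max(conc), 0.5)
})

test_that("full reconstruction is an exact round trip", {
  snap <- make_two_factor()
  d <- psc_decompose(snap)
  rec <- reconstruct_spectra(d, seq_along(d$eigenvalues))
  expect_equal(rec$power, snap$power, tolerance = 1e-12)
  # empty set returns the ensemble geometric-mean spectrum
  rec0 <- reconstruct_spectra(d, integer(0))
  expect_equal(rec0$power[, 1], exp(d$mean_log), ignore_attr = TRUE)
  expect_error(reconstruct_spectra(d, 999), "invalid")
})

test_that("excluding the rhythm PSC removes the beta condition difference", {
  snap <- make_two_factor()
  d <- psc_decompose(snap)
  beta <- d$freq >= 12 & d$freq <= 20
  conc <- vapply(seq_along(d$eigenvalues), function(k)
    sum(d$vectors[beta, k]^2) / sum(d$vectors[, k]^2), numeric(1))
  ratio <- function(P) {
    mv <- rowMeans(P[, snap$condition == "movement"])
    rs <- rowMeans(P[, snap$condition == "rest"])
    mean(mv[beta] / rs[beta])
  }
  expect_lt(ratio(snap$power), 0.6)                   # difference present
  rec <- reconstruct_spectra(d, setdiff(seq_along(d$eigenvalues), 2:4))
  expect_equal(ratio(rec$power), 1, tolerance = 0.05) # removed
  # rhythm-only reconstruction confines change to the beta block
  ronly <- reconstruct_spectra(d, 2:4)
  lr <- abs(log(rowMeans(ronly$power[, snap$condition == "movement"]) /
                rowMeans(ronly$power[, snap$condition == "rest"])))
  expect_gt(mean(lr[beta]), 10 * mean(lr[d$freq > 35]))
})

test_that("broadband timecourse recovers an amplitude step", {
  rate <- 400
  n <- 120 * rate
  amp <- rep(1, n)
  move <- rep(FALSE, n)
  starts <- seq(10 * rate, n - 10 * rate, by = 8 * rate)
  for (s in starts) { amp[s + 1:(2 * rate)] <- 2; move[s + 1:(2 * rate)] <- TRUE }
  x <- make_colored_noise(n, 2, rate, seed = 8) * amp
  ep <- epoch_set(seq(0, n - rate, by = rate), rate,
                  ifelse(move[seq(0, n - rate, by = rate) + rate / 2],
                         "movement", "rest"))
  snap <- psd_snapshots(x, ep, rate)
  d <- psc_decompose(snap)
  B <- broadband_timecourse(x, d, rate)
  expect_gt(mean(B$B[move]), mean(B$B[!move]) + 0.5)
  # recovery invariant: correlation with the true log coefficient at epoch
  # resolution (pointwise values carry estimator noise)
  em <- function(v) vapply(seq_len(nrow(ep)), function(i)
    mean(v[ep$start[i] + seq_len(ep$duration[i])]), numeric(1))
  expect_gt(cor(em(B$B), em(log(amp))), 0.8)
  # display variant is the smoothed trace, re-z-scored and exponentiated
  expect_gt(cor(log(B$display), ecogpac:::gauss_smooth(B$B, 0.05 * rate)),
            0.999)
})

test_that("projection onto the decomposition grid validates compatibility", {
  snap <- make_two_factor()
  d <- psc_decompose(snap)
  dyn <- morlet_spectrogram(rnorm(2000), 1:10, 400)
  expect_error(broadband_timecourse(dyn, d), "grid mismatch")
})

test_that("stationary noise shows no movement/rest broadband difference", {
  rate <- 400
  n <- 60 * rate
  x <- make_colored_noise(n, 2, rate, seed = 13)
  B <- bandpower_broadband(x, c(65, 135), rate, line_noise_hz = NULL)
  half <- rep(c(TRUE, FALSE), each = rate)
  lab <- rep_len(half, n)
  em <- function(sel) {
    st <- seq(0, n - rate, by = rate)
    keep <- lab[st + 1] == sel
    vapply(st[keep], function(s) mean(B$B[s + 1:rate]), numeric(1))
  }
  expect_lt(abs(signed_r2(em(TRUE), em(FALSE))), 0.05)
})

test_that("band-power broadband tracks the PSC projection", {
  rate <- 400
  n <- 100 * rate
  set.seed(5)
  lg <- 0.5 * as.numeric(scale(ecogpac:::gauss_smooth(rnorm(n), 0.5 * rate)))
  amp <- exp(lg)                                     # slow log-gain, sd 0.5
  x <- make_colored_noise(n, 2, rate, seed = 5) * amp
  ep <- epoch_set(seq(0, n - rate, by = rate), rate)
  d <- psc_decompose(psd_snapshots(x, ep, rate))
  Bp <- broadband_timecourse(x, d, rate)
  Bb <- bandpower_broadband(x, c(65, 135), rate, line_noise_hz = NULL)
  keep <- !Bp$edge
  expect_gt(cor(Bp$B[keep], Bb$B[keep]), 0.5)
  # recovery at epoch resolution (pointwise values carry estimator noise)
  em <- function(v) vapply(seq_len(nrow(ep)), function(i)
    mean(v[ep$start[i] + seq_len(ep$duration[i])]), numeric(1))
  expect_gt(cor(em(Bb$B), em(lg)), 0.8)
})

test_that("the line-noise notch makes band power tone-invariant", {
  rate <- 400
  n <- 30 * rate
  x <- make_colored_noise(n, 2, rate, seed = 6)
  tone <- 0.01 * cos(2 * pi * 100 * seq_len(n) / rate)
  B0 <- bandpower_broadband(x, c(65, 135), rate, line_noise_hz = 50,
                            line_noise_halfwidth = 10)
  B1 <- bandpower_broadband(x + tone, c(65, 135), rate, line_noise_hz = 50,
                            line_noise_halfwidth = 10)
  expect_gt(cor(B0$B, B1$B), 0.995)
  # without the notch the tone distorts the trace
  C0 <- bandpower_broadband(x, c(65, 135), rate, line_noise_hz = NULL)
  C1 <- bandpower_broadband(x + tone, c(65, 135), rate, line_noise_hz = NULL)
  expect_lt(cor(C0$B, C1$B), cor(B0$B, B1$B))
})

test_that("PSC-projected log-broadband is approximately normal", {
  # the 1 Hz wavelet smooths over ~0.8 s, so samples are thinned to 2 s
  # spacing for approximate independence before Jarque-Bera
  rate <- 400
  ok <- vapply(1:12, function(seed) {
    n <- 120 * rate
    x <- make_colored_noise(n, 2, rate, seed = 200 + seed)
    ep <- epoch_set(seq(0, n - rate, by = rate), rate)
    d <- psc_decompose(psd_snapshots(x, ep, rate))
    B <- broadband_timecourse(x, d, rate)
    v <- B$B[!B$edge][seq(1, sum(!B$edge), by = 2 * rate)]
    ecogpac:::jarque_bera(v)$p.value > 0.01
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})
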