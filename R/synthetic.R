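# Synthetic sessions with the statistical structure the analysis assumes:
# 1/f^chi broadband whose high-frequency envelope is modulated by the phase
# of an imposed narrow-band rhythm, rhythm amplitude and coupling depth
# reduced during movement trials, somatotopic per-finger broadband gains,
# and a cued finger-movement task (2 s movement / 2 s rest, 30 cues per
# finger). Ground truth (rhythm phases, gates, flexion events) travels with
# the session so recovery tests can compare against it.

#' Colored-noise generator
#'
#' Draws a Gaussian series whose expected power spectral density follows
#' `1/f^chi`, by shaping a white spectrum in the frequency domain. The
#' output is scaled to unit variance.
#'
#' @param n number of samples (>= 2).
#' @param chi power-law exponent (>= 0; 0 gives white noise).
#' @param rate sampling rate (only sets the physical frequency axis).
#' @param seed integer seed; the same seed gives a bit-identical series.
#' @return numeric vector of length `n`.
#' @export
make_colored_noise <- function(n, chi, rate = 1, seed = 1L) {
  if (n < 2) stop("parameter error: n must be >= 2")
  if (chi < 0) stop("parameter error: chi must be >= 0")
  with_local_seed(seed, {
    nf <- n %/% 2
    f <- seq_len(nf) * rate / n
    amp <- f^(-chi / 2)
    re <- stats::rnorm(nf); im <- stats::rnorm(nf)
    spec <- complex(real = re, imaginary = im) * amp
    if (n %% 2 == 0) spec[nf] <- complex(real = re[nf], imaginary = 0) * amp[nf]
    full <- c(0 + 0i, spec,
              if (n %% 2 == 0) Conj(rev(spec[-nf])) else Conj(rev(spec)))
    x <- Re(stats::fft(full, inverse = TRUE)) / n
    as.numeric(scale(x))
  })
}

#' Random-walk generator
#'
#' Cumulative sum of unit white noise; its power spectral density falls as
#' `1/f^2`. Used as a negative control for the coupling pipeline.
#'
#' @inheritParams make_colored_noise
#' @return numeric vector of length `n`.
#' @export
make_random_walk <- function(n, seed = 1L) {
  if (n < 2) stop("parameter error: n must be >= 2")
  with_local_seed(seed, cumsum(stats::rnorm(n)))
}

#' Synthetic-session configuration
#'
#' Defaults state the emulated world: 8 channels at 1000 samples/s with
#' `chi = 2` broadband; one 12-20 Hz rhythm shared across all channels whose
#' amplitude drops to 0.4x during movement; sinusoidal phase coupling of
#' depth 0.4 at preferred phase `0.81*pi` on every channel, also reduced to
#' 0.4x during movement; a five-finger task with 30 cues per finger, 2 s
#' movement and 2 s rest trials; somatotopic broadband amplitude gain 2 on
#' channels 1-5 (thumb..little) leading finger-trace onset by 75 ms. The
#' white noise floor defaults to 5e-4 (relative to unit-variance
#' broadband) so it sits at least 20 dB below the 65-135 Hz broadband —
#' which is itself about 40 dB below the low-frequency knee for
#' `chi = 2` — as in usable surface recordings.
#'
#' @param n_channels,rate,chi array size, sampling rate (Hz), power-law
#'   exponent (recycled per channel).
#' @param rhythms list of rhythm specs: `band` (Hz), `base_amp` (amplitude
#'   relative to unit-variance broadband; a scalar, a per-channel vector, or
#'   `NULL` for the default gradient `seq(1.5, 0.5)` across the array —
#'   rhythm amplitude varies across real arrays, and a spatially uniform
#'   shared rhythm would be annihilated by the common average reference),
#'   `move_mult` (amplitude multiplier inside movement trials), `channels`
#'   (indices), `shared_phase` (logical).
#' @param couplings list of coupling specs: `channel`, `rhythm` (index into
#'   `rhythms`), `depth` in `[0, 1]`, `phase` in `(-pi, pi]`, `move_mult`
#'   (depth multiplier inside movement trials).
#' @param task list with `fingers`, `cues_per_finger`, `move_s`, `rest_s`;
#'   `NULL` for a task-free (all-rest) record of `duration_s` seconds.
#' @param duration_s record length when `task = NULL`.
#' @param somatotopy named integer vector finger -> channel; `gain` is the
#'   broadband amplitude multiplier during that finger's movement and
#'   `lead_s` how far it precedes trace onset.
#' @param gain,lead_s see `somatotopy`.
#' @param noise_sd white noise floor (relative to unit broadband).
#' @param amplitude_uv overall scale to microvolts.
#' @param modulation `"sinusoidal"` (default) or `"pulse"` modulation law.
#' @param seed integer seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_channels = 8, rate = 1000, chi = 2,
                         rhythms = list(list(band = c(12, 20), base_amp = NULL,
                                             move_mult = 0.4, channels = NULL,
                                             shared_phase = TRUE)),
                         couplings = NULL,
                         task = list(fingers = c("thumb", "index", "middle",
                                                 "ring", "little"),
                                     cues_per_finger = 30,
                                     move_s = 2, rest_s = 2),
                         duration_s = 60,
                         somatotopy = NULL, gain = 2, lead_s = 0.075,
                         noise_sd = 5e-4, amplitude_uv = 20,
                         modulation = c("sinusoidal", "pulse"), seed = 1L) {
  modulation <- match.arg(modulation)
  chi <- rep_len(chi, n_channels)
  if (any(chi < 0)) stop("parameter error: chi must be >= 0")
  for (r in rhythms) {
    if (r$band[1] <= 0 || r$band[2] >= rate / 2 || r$band[1] >= r$band[2])
      stop("parameter error: rhythm band outside (0, rate/2)")
    if (!is.null(r$channels) && any(r$channels < 1 | r$channels > n_channels))
      stop("parameter error: rhythm channel subset out of range")
  }
  if (is.null(couplings)) {
    couplings <- lapply(seq_len(n_channels), function(ch)
      list(channel = ch, rhythm = 1, depth = 0.4, phase = 0.81 * pi,
           move_mult = 0.4))
  }
  for (cp in couplings) {
    if (cp$depth < 0 || cp$depth > 1)
      stop("parameter error: coupling depth must lie in [0, 1]")
    if (cp$channel < 1 || cp$channel > n_channels)
      stop("parameter error: coupling channel out of range")
    if (cp$rhythm < 1 || cp$rhythm > length(rhythms))
      stop("parameter error: coupling rhythm index out of range")
  }
  if (!is.null(task) && is.null(somatotopy)) {
    somatotopy <- seq_len(min(length(task$fingers), n_channels))
    names(somatotopy) <- task$fingers[seq_along(somatotopy)]
  }
  structure(list(n_channels = n_channels, rate = rate, chi = chi,
                 rhythms = rhythms, couplings = couplings, task = task,
                 duration_s = duration_s, somatotopy = somatotopy,
                 gain = gain, lead_s = lead_s, noise_sd = noise_sd,
                 amplitude_uv = amplitude_uv, modulation = modulation,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Trial schedule: interleaved (randomised) movement cues with a rest trial
# after each, plus 2 s lead-in/out. Returns data.frame of trial windows.
build_task_schedule <- function(task, rate) {
  fingers <- rep(task$fingers, each = task$cues_per_finger)
  fingers <- sample(fingers)
  move_n <- round(task$move_s * rate)
  rest_n <- round(task$rest_s * rate)
  pad <- 2 * rate
  starts_move <- pad + (seq_along(fingers) - 1) * (move_n + rest_n)
  data.frame(finger = fingers, move_start = starts_move,
             move_end = starts_move + move_n,
             rest_start = starts_move + move_n,
             rest_end = starts_move + move_n + rest_n,
             stringsAsFactors = FALSE)
}

# 0/1 gate over samples for a set of [start, end) windows, smoothed with a
# 100 ms Gaussian so amplitude transitions are not step-like.
window_gate <- function(n, starts, ends, rate, smooth_s = 0.1) {
  g <- numeric(n)
  for (i in seq_along(starts)) {
    a <- max(1, starts[i] + 1); b <- min(n, ends[i])
    if (b >= a) g[a:b] <- 1
  }
  if (smooth_s > 0) g <- pmin(pmax(gauss_smooth(g, smooth_s * rate), 0), 1)
  g
}

# Narrow-band rhythm with exact instantaneous phase: centre-frequency
# rotation plus a bounded random frequency jitter inside the band.
make_rhythm_phase <- function(n, band, rate) {
  fc <- mean(band)
  sd_f <- (band[2] - band[1]) / 6
  jitter <- gauss_smooth(stats::rnorm(n, 0, 1), 0.2 * rate)
  jitter <- jitter / max(stats::sd(jitter), 1e-12) * sd_f
  finst <- pmin(pmax(fc + jitter, band[1]), band[2])
  phi0 <- stats::runif(1, -pi, pi)
  (phi0 + cumsum(2 * pi * finst / rate)) %% (2 * pi) - pi
}

#' Generate a synthetic recording session
#'
#' Builds the multichannel record described by a [synth_config()]: per
#' channel, colored-noise broadband whose high-frequency part (above twice
#' the rhythm centre frequency) is amplitude-modulated as
#' `1 + d(t) * cos(phi(t) - phi0)`, plus the rhythm and a white noise floor;
#' rhythm amplitude and coupling depth are multiplied by their movement
#' multipliers inside movement trials; the somatotopic channel's broadband
#' is raised during its finger's movement, leading trace onset. Finger
#' traces are smoothed flexion pulse trains (2-5 per movement trial), and
#' the event table carries cues, flexion markers and rule-conforming rest
#' events.
#'
#' @param config a [synth_config()].
#' @return a `recording_session`; ground truth is attached as
#'   `attr(, "truth")` (rhythm phase matrix, movement gate, schedule,
#'   coupling and somatotopy specs).
#' @export
make_session <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_local_seed(config$seed, {
    rate <- config$rate
    if (!is.null(config$task)) {
      sched <- build_task_schedule(config$task, rate)
      n <- max(sched$rest_end) + 2 * rate
    } else {
      sched <- NULL
      n <- round(config$duration_s * rate)
    }
    nch <- config$n_channels

    move_gate <- if (is.null(sched)) numeric(n) else
      window_gate(n, sched$move_start, sched$move_end, rate)

    # rhythms: phase series per rhythm per channel (shared or independent)
    phases <- vector("list", length(config$rhythms))
    rhythm_wave <- vector("list", length(config$rhythms))
    for (ri in seq_along(config$rhythms)) {
      r <- config$rhythms[[ri]]
      chans <- r$channels %||% seq_len(nch)
      ph <- matrix(NA_real_, nch, n)
      if (isTRUE(r$shared_phase)) {
        p <- make_rhythm_phase(n, r$band, rate)
        for (ch in chans) ph[ch, ] <- p
      } else {
        for (ch in chans) ph[ch, ] <- make_rhythm_phase(n, r$band, rate)
      }
      base <- r$base_amp %||% seq(1.5, 0.5, length.out = nch)
      base <- rep_len(base, nch)
      gate_amp <- 1 + (r$move_mult - 1) * move_gate
      phases[[ri]] <- ph
      rhythm_wave[[ri]] <- list(base = base, gate = gate_amp, chans = chans)
    }

    modfun <- switch(config$modulation,
      sinusoidal = function(x) cos(x),
      pulse = function(x) 2 * exp(2 * (cos(x) - 1)) - 2 * besselI_ratio())
    samples <- matrix(0, nch, n)
    for (ch in seq_len(nch)) {
      bb <- make_colored_noise(n, config$chi[ch], rate,
                               seed = config$seed + 1000L + ch)
      # split at twice the (first coupled) rhythm centre frequency
      cps <- Filter(function(cp) cp$channel == ch, config$couplings)
      if (length(cps) > 0) {
        fsplit <- 2 * mean(config$rhythms[[cps[[1]]$rhythm]]$band)
        bp <- butter_bandpass(fsplit, 0.45 * rate, rate, order = 3)
        hi <- filtfilt_iir(bp, bb)
        lo <- bb - hi
        mod <- rep(1, n)
        for (cp in cps) {
          d <- cp$depth * (1 + (cp$move_mult - 1) * move_gate)
          mod <- mod * (1 + d * modfun(phases[[cp$rhythm]][ch, ] - cp$phase))
        }
        bb <- lo + hi * mod
      }
      # somatotopic gain for this channel's finger
      if (!is.null(config$somatotopy) && ch %in% config$somatotopy) {
        finger <- names(config$somatotopy)[config$somatotopy == ch][1]
        rows <- sched[sched$finger == finger, , drop = FALSE]
        lead <- round(config$lead_s * rate)
        g <- window_gate(n, rows$move_start - lead, rows$move_end, rate)
        bb <- bb * (1 + (config$gain - 1) * g)
      }
      sig <- bb
      for (ri in seq_along(config$rhythms)) {
        if (ch %in% rhythm_wave[[ri]]$chans)
          sig <- sig + rhythm_wave[[ri]]$base[ch] * rhythm_wave[[ri]]$gate *
            cos(phases[[ri]][ch, ])
      }
      sig <- sig + config$noise_sd * stats::rnorm(n)
      samples[ch, ] <- config$amplitude_uv * sig
    }

    traces <- NULL
    events <- data.frame(label = character(), effector = character(),
                         sample = integer(), stringsAsFactors = FALSE)
    if (!is.null(sched)) {
      gen <- make_traces_events(sched, config$task, n, rate)
      traces <- gen$traces
      events <- gen$events
    }
    sess <- recording_session(samples, rate,
                              channels = data.frame(
                                id = sprintf("ch%02d", seq_len(nch)),
                                region = "unknown", excluded = FALSE,
                                stringsAsFactors = FALSE),
                              events = events, finger_traces = traces)
    attr(sess, "truth") <- list(phases = phases, move_gate = move_gate,
                                schedule = sched,
                                couplings = config$couplings,
                                somatotopy = config$somatotopy,
                                config = config)
    sess
  })
}

# mean of the pulse kernel over phase, so the pulse law is zero-mean
besselI_ratio <- function() {
  x <- seq(-pi, pi, length.out = 4096)
  mean(exp(2 * (cos(x) - 1)))
}

# Finger traces as Gaussian flexion bumps (2-5 per movement trial) plus the
# event table: cue at each trial start, init/peak/term per flexion, and rest
# events >= 500 ms from movement markers and >= 250 ms apart.
make_traces_events <- function(sched, task, n, rate) {
  fingers <- task$fingers
  traces <- matrix(0, length(fingers), n, dimnames = list(fingers, NULL))
  sd_n <- round(0.05 * rate)           # ~50 ms flexion half-width
  half <- 3 * sd_n
  kern <- exp(-(seq(-half, half))^2 / (2 * sd_n^2))
  ev <- list()
  for (i in seq_len(nrow(sched))) {
    fg <- sched$finger[i]
    ev[[length(ev) + 1]] <- data.frame(label = "cue", effector = fg,
                                       sample = sched$move_start[i])
    nflex <- sample(2:5, 1)
    span <- sched$move_end[i] - sched$move_start[i]
    # one flexion per slot, jittered, so pulses never merge and the count
    # is exactly recoverable from the trace
    slot <- (span - 2 * half) %/% nflex
    jitter <- sample.int(max(1, slot - 2 * half), nflex, replace = TRUE) - 1L
    centers <- sched$move_start[i] + half + (seq_len(nflex) - 1) * slot +
      jitter
    for (ctr in centers) {
      idx <- (ctr - half):(ctr + half)
      ok <- idx >= 0 & idx < n
      row <- match(fg, fingers)
      traces[row, idx[ok] + 1] <- pmax(traces[row, idx[ok] + 1], kern[ok])
      ev[[length(ev) + 1]] <- data.frame(
        label = c("movement_init", "movement_peak", "movement_term"),
        effector = fg, sample = c(ctr - 2 * sd_n, ctr, ctr + 2 * sd_n))
    }
  }
  evdf <- do.call(rbind, ev)
  # rest events inside rest trials, honouring the distance rules
  move_marks <- evdf$sample[evdf$label %in% c("movement_init", "movement_term")]
  min_gap <- round(0.25 * rate); move_gap <- round(0.5 * rate)
  rest <- integer()
  for (i in seq_len(nrow(sched))) {
    cand <- sched$rest_start[i] + sample.int(sched$rest_end[i] -
                                             sched$rest_start[i], 1) - 1L
    if (all(abs(cand - move_marks) >= move_gap) &&
        (length(rest) == 0 || all(abs(cand - rest) >= min_gap)))
      rest <- c(rest, cand)
  }
  if (length(rest) > 0)
    evdf <- rbind(evdf, data.frame(label = "rest", effector = "none",
                                   sample = rest))
  evdf <- evdf[order(evdf$sample), ]
  rownames(evdf) <- NULL
  evdf$sample <- as.integer(evdf$sample)
  list(traces = traces, events = evdf)
}
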