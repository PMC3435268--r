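# Domain containers shared by all pipeline stages. A RecordingSession is the
# root input: a channels x time matrix of surface potentials (uV), the
# sampling rate, a channel metadata table, an event table, and optional
# per-digit finger position traces. Sample indexing is 0-based with half-open
# windows [start, start + duration); event times are integer sample indices.

EVENT_LABELS <- c("movement_init", "movement_peak", "movement_term", "rest", "cue")
EFFECTORS <- c("thumb", "index", "middle", "ring", "little", "none")

#' Construct a recording session
#'
#' @param samples numeric matrix, channels x time, in microvolts.
#' @param rate sampling rate (samples/s), > 0.
#' @param channels data.frame with columns `id` (character), `region`
#'   (character), `excluded` (logical). Defaults to generic labels.
#' @param events data.frame with columns `label` (one of movement_init,
#'   movement_peak, movement_term, rest, cue), `effector` (thumb, index,
#'   middle, ring, little, none), `sample` (0-based integer index).
#' @param finger_traces optional numeric matrix, digits x time, arbitrary
#'   units, with rownames naming the digits.
#' @return object of class `recording_session`.
#' @export
recording_session <- function(samples, rate, channels = NULL, events = NULL,
                              finger_traces = NULL) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (is.null(channels)) {
    channels <- data.frame(id = sprintf("ch%02d", seq_len(nrow(samples))),
                           region = "unknown", excluded = FALSE,
                           stringsAsFactors = FALSE)
  }
  if (is.null(events)) {
    events <- data.frame(label = character(), effector = character(),
                         sample = integer(), stringsAsFactors = FALSE)
  }
  s <- structure(list(samples = samples, rate = as.numeric(rate),
                      channels = channels, events = events,
                      finger_traces = finger_traces),
                 class = "recording_session")
  validate_session(s)
  s
}

#' Validate a recording session
#'
#' Checks the container invariants: positive rate, channel metadata matching
#' the sample matrix, event labels/effectors from the allowed vocabulary, and
#' every event index inside the record.
#'
#' @param session a `recording_session`.
#' @return the session, invisibly; stops with a validation error otherwise.
#' @export
validate_session <- function(session) {
  if (!is.matrix(session$samples) || !is.numeric(session$samples))
    stop("validation error: samples must be a numeric channels x time matrix")
  if (!is.numeric(session$rate) || length(session$rate) != 1 ||
      !is.finite(session$rate) || session$rate <= 0)
    stop("validation error: rate must be a single positive number")
  ch <- session$channels
  if (!all(c("id", "region", "excluded") %in% names(ch)))
    stop("validation error: channels table needs id, region, excluded")
  if (nrow(ch) != nrow(session$samples))
    stop("validation error: channels table does not match sample matrix rows")
  if (anyDuplicated(ch$id))
    stop("validation error: duplicated channel ids")
  ev <- session$events
  if (!all(c("label", "effector", "sample") %in% names(ev)))
    stop("validation error: events table needs label, effector, sample")
  if (nrow(ev) > 0) {
    if (!all(ev$label %in% EVENT_LABELS))
      stop("validation error: unknown event label")
    if (!all(ev$effector %in% EFFECTORS))
      stop("validation error: unknown effector")
    n <- ncol(session$samples)
    if (any(ev$sample < 0 | ev$sample >= n))
      stop("validation error: event sample index out of range")
  }
  if (!is.null(session$finger_traces)) {
    ft <- session$finger_traces
    if (!is.matrix(ft) || ncol(ft) != ncol(session$samples))
      stop("validation error: finger traces must match record length")
  }
  invisible(session)
}

#' @export
print.recording_session <- function(x, ...) {
  cat(sprintf("<recording_session> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$rate,
              ncol(x$samples) / x$rate))
  cat(sprintf("  channels excluded: %d; events: %d; finger traces: %s\n",
              sum(x$channels$excluded), nrow(x$events),
              if (is.null(x$finger_traces)) "none"
              else paste(rownames(x$finger_traces), collapse = ", ")))
  invisible(x)
}

# Indices (1-based, into the sample matrix rows) of non-excluded channels.
included_idx <- function(session) which(!session$channels$excluded)

#' Epoch set: fixed-duration condition-labelled windows
#'
#' Windows are half-open `[start, start + duration)` in 0-based samples; the
#' duration is constant within a set (default 1 s worth of samples).
#'
#' @param starts integer vector of 0-based start samples.
#' @param duration window length in samples (scalar).
#' @param condition character vector of condition labels (recycled).
#' @param n_samples record length the windows must fit inside (optional
#'   check).
#' @return object of class `epoch_set` (data.frame with attributes).
#' @export
epoch_set <- function(starts, duration, condition = "epoch", n_samples = NULL) {
  starts <- as.integer(starts)
  duration <- as.integer(duration)
  if (length(duration) != 1 || duration < 1) stop("duration must be a positive scalar")
  if (any(starts < 0)) stop("epoch starts before record")
  if (!is.null(n_samples) && any(starts + duration > n_samples))
    stop("epoch outside record")
  out <- data.frame(start = starts,
                    duration = rep_len(duration, length(starts)),
                    condition = rep_len(as.character(condition),
                                        length(starts)),
                    stringsAsFactors = FALSE)
  class(out) <- c("epoch_set", "data.frame")
  out
}

#' Build an epoch set around events of one label
#'
#' Extracts windows of `duration_s` seconds centred on each matching event
#' (flanking the event marker), dropping windows that fall outside the
#' record.
#'
#' @param session a `recording_session`.
#' @param label event label to select.
#' @param effector optional effector filter.
#' @param duration_s window duration in seconds (default 1).
#' @param condition condition label for the windows (default the event
#'   label).
#' @return an `epoch_set`.
#' @export
epochs_around_events <- function(session, label, effector = NULL,
                                 duration_s = 1, condition = label) {
  ev <- session$events
  keep <- ev$label == label
  if (!is.null(effector)) keep <- keep & ev$effector %in% effector
  idx <- ev$sample[keep]
  dur <- round(duration_s * session$rate)
  starts <- idx - dur %/% 2
  n <- ncol(session$samples)
  ok <- starts >= 0 & starts + dur <= n
  epoch_set(starts[ok], dur, condition, n)
}

#' Pipeline configuration defaults
#'
#' Collects the tunable analysis parameters with their standard defaults:
#' 1 s PSD epochs, a 1-50 Hz palette grid, 5 wavelet cycles, beta 12-20 Hz,
#' theta 4-8 Hz, K = 24 phase bins, line-noise exclusion, and the 65-135 Hz
#' band-power approximation of broadband.
#'
#' @param psd_grid PSD frequency grid in Hz.
#' @param palette_grid rhythm frequencies for coupling palettes.
#' @param cycles Morlet wavelet cycles.
#' @param beta_band,theta_band rhythm bands (Hz).
#' @param n_phase_bins number of phase bins K (even).
#' @param line_noise_hz line-noise base frequency (50 or 60).
#' @param line_noise_halfwidth half-width of the exclusion band (Hz).
#' @param broadband_band band for the band-power broadband approximation.
#' @param n_perm permutation count for overlap tests.
#' @param seed random seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(psd_grid = 1:200, palette_grid = 1:50, cycles = 5,
                            beta_band = c(12, 20), theta_band = c(4, 8),
                            n_phase_bins = 24, line_noise_hz = 60,
                            line_noise_halfwidth = 3,
                            broadband_band = c(65, 135),
                            n_perm = 1e4, seed = 1L) {
  stopifnot(beta_band[1] < beta_band[2], theta_band[1] < theta_band[2],
            n_phase_bins %% 2 == 0, all(diff(psd_grid) > 0),
            all(diff(palette_grid) > 0))
  structure(list(psd_grid = psd_grid, palette_grid = palette_grid,
                 cycles = cycles, beta_band = beta_band,
                 theta_band = theta_band, n_phase_bins = n_phase_bins,
                 line_noise_hz = line_noise_hz,
                 line_noise_halfwidth = line_noise_halfwidth,
                 broadband_band = broadband_band, n_perm = n_perm,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Frequencies of `grid` falling inside line-noise bands (base + harmonics).
line_noise_mask <- function(grid, base_hz, halfwidth) {
  mask <- rep(FALSE, length(grid))
  if (is.null(base_hz) || base_hz <= 0 || max(grid) + halfwidth < base_hz)
    return(mask)
  for (h in seq(base_hz, max(grid) + halfwidth, by = base_hz))
    mask <- mask | abs(grid - h) <= halfwidth
  mask
}

#' Save a session to the native container
#'
#' The native container is a single RDS file holding the sample matrix,
#' rate, channel table, event table and finger traces; round trips are
#' bit-exact.
#'
#' @param session a validated `recording_session`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
save_session <- function(session, path) {
  validate_session(session)
  saveRDS(unclass(session), path, version = 2)
  invisible(path)
}

#' Load a recording session
#'
#' @param path file path.
#' @param format `"container"` (native RDS), `"edf"` (EDF/EDF+ signals), or
#'   `"table"` (delimited numeric table, one column per channel, header row
#'   of channel ids).
#' @param rate sampling rate, required for `format = "table"`.
#' @param events_path optional CSV of events (columns label, effector,
#'   sample) merged into the loaded session.
#' @return a validated `recording_session`.
#' @export
load_session <- function(path, format = c("container", "edf", "table"),
                         rate = NULL, events_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("format error: file not found: ", path)
  s <- switch(format,
    container = {
      raw <- tryCatch(readRDS(path),
                      error = function(e) stop("format error: not a native container"))
      structure(raw, class = "recording_session")
    },
    edf = read_edf_session(path),
    table = {
      tab <- utils::read.csv(path, check.names = FALSE)
      if (is.null(rate)) stop("rate is required for table import")
      m <- t(as.matrix(tab))
      if (!is.numeric(m)) stop("format error: non-numeric table")
      recording_session(m, rate,
                        channels = data.frame(id = colnames(tab),
                                              region = "unknown",
                                              excluded = FALSE,
                                              stringsAsFactors = FALSE))
    })
  if (!is.null(events_path)) {
    ev <- utils::read.csv(events_path, stringsAsFactors = FALSE)
    s$events <- ev[, c("label", "effector", "sample")]
  }
  validate_session(s)
  s
}

#' Write an events table as CSV
#'
#' @param events data.frame with columns label, effector, sample.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}
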