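# Re-referencing, automatic channel rejection, and event extraction from
# finger position traces.

#' Common average reference
#'
#' Subtracts the instantaneous mean of the included channels from each
#' included channel. Excluded channels (the union of the session's excluded
#' flags and `excluded`) pass through untouched but stay flagged, and never
#' contribute to the average.
#'
#' @param session a `recording_session`.
#' @param excluded channel ids (or indices) to exclude in addition to the
#'   session's flags.
#' @return a re-referenced `recording_session`.
#' @export
common_average_reference <- function(session, excluded = NULL) {
  excl <- session$channels$excluded
  if (!is.null(excluded)) {
    if (is.character(excluded)) excl <- excl | session$channels$id %in% excluded
    else excl <- excl | seq_len(nrow(session$channels)) %in% excluded
  }
  if (all(excl)) stop("all channels excluded; cannot re-reference")
  inc <- which(!excl)
  avg <- colMeans(session$samples[inc, , drop = FALSE])
  session$samples[inc, ] <- sweep(session$samples[inc, , drop = FALSE], 2, avg)
  session$channels$excluded <- excl
  session
}

#' Automatic channel rejection
#'
#' Replaces interactive visual rejection with a simple rule: a channel is
#' flagged when its amplitude exceeds `sd_limit` standard deviations of the
#' array-median SD, or when it is (near-)flat.
#'
#' @param session a `recording_session`.
#' @param sd_limit amplitude limit in multiples of the median channel SD.
#' @return the session with `channels$excluded` updated.
#' @export
reject_channels <- function(session, sd_limit = 10) {
  sds <- apply(session$samples, 1, stats::sd)
  med <- stats::median(sds)
  peak <- apply(abs(session$samples), 1, max)
  bad <- peak > sd_limit * med | sds < 1e-12 * max(med, 1e-300)
  session$channels$excluded <- session$channels$excluded | bad
  session
}

#' Extract movement and rest events from finger traces
#'
#' Each digit trace is z-scored; a flexion starts at an upward crossing of
#' `threshold` SD with positive derivative, peaks at the local maximum, and
#' terminates at the next downward crossing. Rest events are drawn uniformly
#' from samples at least `move_gap_s` from any movement initiation or
#' termination and at least `rest_gap_s` from any other rest event.
#'
#' @param session a `recording_session` with finger traces.
#' @param threshold detection threshold in SD units (default 0.5).
#' @param move_gap_s minimum distance of a rest event from movement markers
#'   (default 0.5 s).
#' @param rest_gap_s minimum spacing between rest events (default 0.25 s).
#' @param n_rest number of rest events to attempt (default 150).
#' @param lag_s constant shift applied to trace-derived markers, for
#'   recordings where the position sensor lags the amplifier (default 0).
#' @param seed seed for the rest-event draw.
#' @return event data.frame (label, effector, sample), sorted by sample.
#' @export
build_events <- function(session, threshold = 0.5, move_gap_s = 0.5,
                         rest_gap_s = 0.25, n_rest = 150, lag_s = 0,
                         seed = 1L) {
  if (is.null(session$finger_traces)) stop("no finger traces in session")
  rate <- session$rate
  n <- ncol(session$samples)
  shift <- round(lag_s * rate)
  ev <- list()
  for (fg in rownames(session$finger_traces)) {
    x <- session$finger_traces[fg, ]
    if (stats::sd(x) < 1e-12) next
    z <- as.numeric(scale(x))
    above <- z > threshold
    up <- which(!above[-length(above)] & above[-1]) + 1L
    down <- which(above[-length(above)] & !above[-1])
    for (u in up) {
      d <- down[down > u]
      if (length(d) == 0) next
      d <- d[1]
      pk <- u - 1L + which.max(z[u:d])
      ev[[length(ev) + 1]] <- data.frame(
        label = c("movement_init", "movement_peak", "movement_term"),
        effector = fg,
        sample = as.integer(c(u, pk, d) - 1L + shift))
    }
  }
  evdf <- if (length(ev)) do.call(rbind, ev) else
    data.frame(label = character(), effector = character(),
               sample = integer(), stringsAsFactors = FALSE)
  move_marks <- evdf$sample[evdf$label %in% c("movement_init", "movement_term")]
  move_gap <- round(move_gap_s * rate)
  rest_gap <- round(rest_gap_s * rate)
  ok <- rep(TRUE, n)
  for (m in move_marks) {
    a <- max(1, m + 1 - move_gap); b <- min(n, m + 1 + move_gap)
    ok[a:b] <- FALSE
  }
  cand <- which(ok) - 1L
  rest <- integer()
  if (length(cand) == 0) {
    if (n_rest > 0) warning("rest rules unsatisfiable; empty rest set")
  } else if (n_rest > 0) {
    rest <- with_local_seed(seed, {
      picked <- integer()
      pool <- sample(cand)
      for (p in pool) {
        if (length(picked) >= n_rest) break
        if (length(picked) == 0 || all(abs(p - picked) >= rest_gap))
          picked <- c(picked, p)
      }
      sort(picked)
    })
    if (length(rest) == 0) warning("rest rules unsatisfiable; empty rest set")
  }
  if (n_rest == 0) rest <- integer()
  if (length(rest) > 0)
    evdf <- rbind(evdf, data.frame(label = "rest", effector = "none",
                                   sample = as.integer(rest)))
  evdf <- evdf[order(evdf$sample), ]
  rownames(evdf) <- NULL
  evdf
}
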