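# Seed-referenced complex phase coherence of a rhythm band across the
# array, and its projection onto the dominant phase lag. The complex value
# is kept because common-average referencing introduces pi-shifted
# coherence at sites where the rhythm is otherwise absent.

#' Select the seed channel
#'
#' The channel with the strongest effector-movement-associated broadband
#' change: per channel, per-epoch mean broadband is contrasted between that
#' effector's movement epochs and rest epochs with signed r2, and the
#' argmax wins (ties broken by the lowest channel index). Excluded channels
#' never win.
#'
#' @param session a `recording_session`.
#' @param traces list of `broadband_trace` (one per channel, session row
#'   order).
#' @param move_epochs,rest_epochs `epoch_set`s for the effector's movement
#'   and for rest.
#' @return list with `channel` (index), `id`, `stat` (per-channel signed
#'   r2), `low_confidence` (TRUE when the winning statistic is near zero).
#' @export
select_seed <- function(session, traces, move_epochs, rest_epochs) {
  if (nrow(move_epochs) == 0) stop("no movement epochs")
  epoch_means <- function(B, ep) vapply(seq_len(nrow(ep)), function(i)
    mean(B[ep$start[i] + seq_len(ep$duration[i])]), numeric(1))
  stat <- vapply(seq_along(traces), function(ch) {
    B <- traces[[ch]]$B
    signed_r2(epoch_means(B, move_epochs), epoch_means(B, rest_epochs))
  }, numeric(1))
  stat[session$channels$excluded] <- -Inf
  best <- which(stat == max(stat))[1]
  list(channel = best, id = session$channels$id[best], stat = stat,
       low_confidence = is.finite(stat[best]) && stat[best] < 0.05)
}

#' Seed-referenced complex phase coherence map
#'
#' For each channel j, per rest epoch e:
#' `gamma_e = mean_t exp(1i * (phi_seed(t) - phi_j(t)))`, then the complex
#' mean over epochs. Phases come from the band's analytic signal on the
#' (already re-referenced) data. `Mod(gamma) <= 1` always and the seed's
#' self-coherence is exactly 1.
#'
#' @param session a (CAR'd) `recording_session`.
#' @param seed seed channel index.
#' @param epochs `epoch_set` of rest epochs (>= 1).
#' @param band rhythm band in Hz (default 12-20).
#' @return object of class `phase_coherence_map`: `seed`, `band`, `gamma`
#'   (complex per channel, NA for excluded), `n_epochs`, `channels`.
#' @export
phase_coherence_map <- function(session, seed, epochs, band = c(12, 20)) {
  if (session$channels$excluded[seed]) stop("seed channel is excluded")
  if (nrow(epochs) == 0) stop("need >= 1 epoch")
  inc <- included_idx(session)
  phases <- matrix(NA_real_, nrow(session$samples), ncol(session$samples))
  for (ch in inc)
    phases[ch, ] <- analytic_band(session$samples[ch, ], band, session$rate)$phase
  gamma <- rep(NA_complex_, nrow(session$samples))
  for (ch in inc) {
    per_epoch <- vapply(seq_len(nrow(epochs)), function(i) {
      idx <- epochs$start[i] + seq_len(epochs$duration[i])
      mean(exp(1i * (phases[seed, idx] - phases[ch, idx])))
    }, complex(1))
    gamma[ch] <- mean(per_epoch)
  }
  structure(list(seed = seed, band = band, gamma = gamma,
                 n_epochs = nrow(epochs), channels = session$channels),
            class = "phase_coherence_map")
}

#' Project a coherence map onto the dominant phase lag
#'
#' Finds the non-seed channel with the highest `|gamma|`, takes its phase
#' lag `psi`, and returns `Re(gamma_j * exp(-1i * psi))` per channel. Sites
#' phase-locked near `psi` project to `+|gamma|`; pi-out-of-phase sites
#' (the CAR artifact) project negative.
#'
#' @param map a `phase_coherence_map`.
#' @return list with `projected` (per channel), `psi` (reference lag),
#'   `ref_channel`.
#' @export
project_coherence <- function(map) {
  g <- map$gamma
  cand <- Mod(g)
  cand[map$seed] <- -Inf
  cand[is.na(cand)] <- -Inf
  ref <- which.max(cand)
  psi <- Arg(g[ref])
  list(projected = Re(g * exp(-1i * psi)), psi = psi, ref_channel = ref)
}

#' Write a coherence table as CSV
#'
#' @param map a `phase_coherence_map`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_coherence_csv <- function(map, path) {
  pr <- project_coherence(map)
  utils::write.csv(data.frame(channel = map$channels$id,
                              re = Re(map$gamma), im = Im(map$gamma),
                              mod = Mod(map$gamma), phase = Arg(map$gamma),
                              projected = pr$projected),
                   path, row.names = FALSE)
  invisible(path)
}
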