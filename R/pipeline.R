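# End-to-end orchestration: movement-related spectral change, coupling at
# rest vs movement, coherence and spatial-overlap maps, plus the negative
# control. All outputs are CSV tables and a JSON run manifest.

#' Run the full analysis on a session
#'
#' Stages: automatic channel rejection, common average reference, epoch
#' construction (1 s windows flanking movement peaks and rest events; 1 s
#' trials cut from movement and rest stretches), per-channel PSD snapshots
#' and PSC decomposition, broadband timecourses, beta analytic amplitude,
#' trial-wise coupling vectors with condition contrast, per-finger
#' broadband change maps with pairwise spatial overlap, seed-referenced
#' phase coherence, and one coupling palette per channel.
#'
#' @param session a `recording_session` (or path to a native container).
#' @param out_dir output directory (created if missing).
#' @param config a [pipeline_config()].
#' @param broadband_source `"bandpower"` (default, fast) or `"psc"`.
#' @param palette TRUE to write a coupling palette per channel (the slowest
#'   stage).
#' @return invisibly, a list with the per-channel results table, overlap
#'   matrices, coherence map, and output paths.
#' @export
run_full <- function(session, out_dir, config = pipeline_config(),
                     broadband_source = c("bandpower", "psc"),
                     palette = TRUE) {
  broadband_source <- match.arg(broadband_source)
  if (is.character(session)) session <- load_session(session)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))

  sess <- stage("preprocess", {
    s <- reject_channels(session)
    common_average_reference(s)
  })
  rate <- sess$rate
  inc <- included_idx(sess)

  ep <- stage("epochs", {
    move1 <- epochs_around_events(sess, "movement_peak", duration_s = 1,
                                  condition = "movement")
    rest1 <- epochs_around_events(sess, "rest", duration_s = 1,
                                  condition = "rest")
    if (nrow(rest1) == 0) stop("no rest epochs in session")
    if (nrow(move1) == 0) stop("no movement epochs in session")
    list(move = move1, rest = rest1)
  })
  fingers <- setdiff(unique(sess$events$effector), "none")

  res <- stage("coupling", {
    rows <- list()
    traces <- vector("list", nrow(sess$samples))
    bbmap <- matrix(NA_real_, nrow(sess$samples), length(fingers),
                    dimnames = list(sess$channels$id, fingers))
    for (ch in inc) {
      x <- sess$samples[ch, ]
      B <- if (broadband_source == "bandpower")
        bandpower_broadband(x, config$broadband_band, rate,
                            line_noise_hz = config$line_noise_hz)
      else {
        snaps <- psd_snapshots(x, rbind(ep$move, ep$rest), rate,
                               line_noise_hz = config$line_noise_hz,
                               line_noise_halfwidth = config$line_noise_halfwidth)
        broadband_timecourse(x, psc_decompose(snaps), rate)
      }
      traces[[ch]] <- B
      beta <- analytic_band(x, config$beta_band, rate)
      em <- function(v, e) vapply(seq_len(nrow(e)), function(i)
        mean(v[e$start[i] + seq_len(e$duration[i])]), numeric(1))
      bb_shift <- signed_r2(em(B$B, ep$move), em(B$B, ep$rest))
      beta_shift <- signed_r2(em(beta$amplitude, ep$move),
                              em(beta$amplitude, ep$rest))
      for (fg in fingers) {
        mv <- epochs_around_events(sess, "movement_peak", effector = fg,
                                   duration_s = 1)
        if (nrow(mv) > 0)
          bbmap[ch, fg] <- signed_r2(em(B$B, mv), em(B$B, ep$rest))
      }
      st_r <- trial_coupling_stats(B, beta$phase,
                                   segment_trials(ep$rest, rate, 1),
                                   K = config$n_phase_bins,
                                   condition = "rest")
      st_m <- trial_coupling_stats(B, beta$phase,
                                   segment_trials(ep$move, rate, 1),
                                   K = config$n_phase_bins,
                                   condition = "movement")
      cc <- condition_contrast(st_m, st_r, direction = "b")
      rows[[length(rows) + 1]] <- data.frame(
        channel = sess$channels$id[ch],
        broadband_shift_r2 = bb_shift, beta_amp_shift_r2 = beta_shift,
        Z_mod_rest = st_r$Z_mod, phi_c_rest = st_r$phi_c, p_rest = st_r$p,
        Z_mod_move = st_m$Z_mod, phi_c_move = st_m$phi_c, p_move = st_m$p,
        contrast_r2 = cc$signed_r2, contrast_p = cc$p,
        stringsAsFactors = FALSE)
    }
    list(table = do.call(rbind, rows), traces = traces, bbmap = bbmap)
  })
  res$table$p_rest_bonf <- pmin(1, res$table$p_rest * nrow(res$table))
  res$table$p_move_bonf <- pmin(1, res$table$p_move * nrow(res$table))

  ov <- stage("overlap", {
    m <- res$bbmap[inc, , drop = FALSE]
    m <- m[, colSums(is.na(m)) == 0, drop = FALSE]
    if (ncol(m) >= 2) overlap_matrix(m, config$n_perm, config$seed) else NULL
  })

  coh <- stage("coherence", {
    eff <- if ("index" %in% fingers) "index" else fingers[1]
    mv <- epochs_around_events(sess, "movement_peak", effector = eff,
                               duration_s = 1)
    seed_ch <- select_seed(sess, res$traces, mv, ep$rest)
    map <- phase_coherence_map(sess, seed_ch$channel, ep$rest,
                               config$beta_band)
    list(seed = seed_ch, map = map)
  })

  paths <- list(results = file.path(out_dir, "channel_results.csv"),
                coherence = file.path(out_dir, "coherence.csv"),
                manifest = file.path(out_dir, "manifest.json"))
  utils::write.csv(res$table, paths$results, row.names = FALSE)
  write_coherence_csv(coh$map, paths$coherence)
  if (!is.null(ov)) {
    utils::write.csv(ov$omega, file.path(out_dir, "overlap_omega.csv"))
    utils::write.csv(ov$p, file.path(out_dir, "overlap_p.csv"))
  }
  pal <- NULL
  if (palette) {
    pal <- stage("palette", {
      lapply(inc, function(ch) {
        p <- coupling_palette(res$traces[[ch]], sess$samples[ch, ], rate,
                              grid = config$palette_grid,
                              K = config$n_phase_bins, cycles = config$cycles)
        write_palette_csv(p, file.path(out_dir,
          sprintf("palette_%s.csv", sess$channels$id[ch])))
        p
      })
    })
  }
  write_manifest(paths$manifest, config, session, paths)
  invisible(list(table = res$table, overlap = ov, coherence = coh,
                 palettes = pal, paths = paths))
}

#' Negative-control run
#'
#' Generates independent colored-noise (or random-walk) channels, runs the
#' full coupling pipeline on each (band-power broadband, beta-phase trials,
#' Hotelling significance), and reports the empirical fraction significant
#' at `alpha` against its 95% binomial interval.
#'
#' @param n_channels number of independent channels (>= 50 for the control).
#' @param alpha nominal level (default 0.01).
#' @param kind `"colored"` or `"walk"`.
#' @param chi power-law exponent for colored noise.
#' @param duration_s,rate record length and sampling rate per channel.
#' @param seed integer seed.
#' @param config a [pipeline_config()].
#' @return list with per-channel `p`, `rate` (fraction < alpha), `alpha`,
#'   `ci` (95% binomial interval of the fraction under the nominal rate),
#'   `pass`.
#' @export
run_negative_control <- function(n_channels = 50, alpha = 0.01,
                                 kind = c("colored", "walk"), chi = 2,
                                 duration_s = 60, rate = 400, seed = 1L,
                                 config = pipeline_config()) {
  kind <- match.arg(kind)
  n <- round(duration_s * rate)
  p <- vapply(seq_len(n_channels), function(ch) {
    x <- if (kind == "colored") make_colored_noise(n, chi, rate, seed + ch)
         else make_random_walk(n, seed + ch)
    B <- bandpower_broadband(x, config$broadband_band, rate,
                             line_noise_hz = config$line_noise_hz)
    beta <- analytic_band(x, config$beta_band, rate)
    trials <- epoch_set(seq(0, n - rate, by = rate), rate, "rest")
    trial_coupling_stats(B, beta$phase, trials, K = config$n_phase_bins)$p
  }, numeric(1))
  ci <- stats::qbinom(c(0.025, 0.975), n_channels, alpha) / n_channels
  emp <- mean(p < alpha)
  list(p = p, rate = emp, alpha = alpha, ci = ci,
       pass = emp >= ci[1] && emp <= ci[2])
}

# Tiny JSON writer (strings/numbers/lists) to avoid a hard dependency.
to_json <- function(x, indent = "") {
  esc <- function(s) gsub('"', '\\\\"', s)
  if (is.null(x)) return("null")
  if (is.list(x)) {
    if (length(x) == 0) return("{}")
    items <- vapply(seq_along(x), function(i)
      sprintf('%s  "%s": %s', indent, esc(names(x)[i]),
              to_json(x[[i]], paste0(indent, "  "))), character(1))
    return(sprintf("{\n%s\n%s}", paste(items, collapse = ",\n"), indent))
  }
  if (is.character(x)) {
    if (length(x) == 1) return(sprintf('"%s"', esc(x)))
    return(sprintf("[%s]", paste(sprintf('"%s"', esc(x)), collapse = ", ")))
  }
  if (length(x) == 1) return(format(x, digits = 15))
  sprintf("[%s]", paste(format(x, digits = 15), collapse = ", "))
}

write_manifest <- function(path, config, session, paths) {
  man <- list(
    package = "ecogpac",
    version = as.character(utils::packageVersion("ecogpac")),
    seed = config$seed,
    config = lapply(unclass(config), function(v) v),
    input = list(channels = nrow(session$samples),
                 samples = ncol(session$samples), rate = session$rate,
                 sample_hash = digest_vector(session$samples)),
    outputs = lapply(paths, basename))
  writeLines(to_json(man), path)
  invisible(path)
}

# Cheap deterministic content hash (sum-based; not cryptographic).
digest_vector <- function(m) {
  v <- as.numeric(m)
  sprintf("%.8e:%.8e:%d", sum(v), sum(v * seq_along(v) %% 997), length(v))
}
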