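# Phase-coupling palettes, coupling vectors, trial-projection statistics
# and condition contrasts: the dependence of z-scored log-broadband
# amplitude on the phase of low-frequency rhythms.

#' Phase-bin centres
#'
#' Bin k (1-based) spans `((k-1)*2*pi/K - pi, k*2*pi/K - pi]`; the K bins
#' partition `(-pi, pi]` and the centre of bin k is
#' `(2*k - 1)*pi/K - pi`.
#'
#' @param K number of bins (>= 4).
#' @return numeric vector of K bin centres.
#' @export
phase_bin_centers <- function(K) (2 * seq_len(K) - 1) * pi / K - pi

# bin index in 1..K for phases in (-pi, pi]; the small epsilon keeps exact
# right edges (multiples of the bin width) in their own bin under floating
# point
phase_bin_index <- function(phi, K) {
  k <- ceiling((phi + pi) / (2 * pi / K) - 1e-9)
  k[k < 1] <- 1L
  k[k > K] <- K
  k
}

#' Mean broadband per rhythm-phase bin
#'
#' Averages the z-scored log-broadband over samples whose rhythm phase
#' falls in each of K equal bins of `(-pi, pi]`, with per-bin SEM. Samples
#' flagged as wavelet/filter edges are excluded.
#'
#' @param B a `broadband_trace` or numeric vector of z-scored log-broadband.
#' @param phi rhythm phase series in `(-pi, pi]`, same length.
#' @param K number of phase bins (default 24).
#' @param exclude logical vector of samples to drop (defaults to the
#'   trace's edge flags).
#' @return list with `centers`, `mean`, `sem`, `n` (per-bin counts), `K`;
#'   empty bins have `NA` mean and are reported in `empty`.
#' @export
phase_bin_means <- function(B, phi, K = 24, exclude = NULL) {
  if (inherits(B, "broadband_trace")) {
    if (is.null(exclude)) exclude <- B$edge
    B <- B$B
  }
  if (length(B) != length(phi)) stop("B and phi lengths differ")
  if (K < 4) stop("K must be >= 4")
  keep <- if (is.null(exclude)) rep(TRUE, length(B)) else !exclude
  b <- B[keep]; p <- phi[keep]
  idx <- phase_bin_index(p, K)
  n <- tabulate(idx, K)
  s <- vapply(seq_len(K), function(k) sum(b[idx == k]), numeric(1))
  m <- ifelse(n > 0, s / n, NA_real_)
  ss <- vapply(seq_len(K), function(k) sum((b[idx == k] - m[k])^2), numeric(1))
  sem <- ifelse(n > 1, sqrt(ss / (n - 1) / n), NA_real_)
  list(centers = phase_bin_centers(K), mean = m, sem = sem, n = n, K = K,
       empty = which(n == 0))
}

#' Coupling vector from binned means
#'
#' `Z = (2/K) * sum_k m_k * exp(1i * center_k)`; with this normalisation a
#' pure cosine modulation of amplitude A at preferred phase phi0 yields
#' exactly `Z_mod = A`, `phi_c = phi0`. `Z_mod` is therefore read in
#' z-units: roughly the amount of variation in the z-scored log-broadband
#' that tracks the rhythm phase.
#'
#' @param bins result of [phase_bin_means()] (no empty bins allowed).
#' @param K number of bins (taken from `bins` when omitted).
#' @return list with `z` (complex), `Z_mod`, `phi_c`.
#' @export
coupling_vector <- function(bins, K = bins$K) {
  if (length(bins$empty) > 0)
    stop("empty phase bin(s): ", paste(bins$empty, collapse = ", "))
  z <- (2 / K) * sum(bins$mean * exp(1i * bins$centers))
  list(z = z, Z_mod = Mod(z), phi_c = Arg(z))
}

#' Phase-coupling palette across rhythm frequencies
#'
#' For each frequency of the grid (default 1-50 Hz), takes the rhythm phase
#' from the Morlet spectrogram at that frequency and bins the broadband
#' trace by it, assembling a frequency x phase-bin matrix of mean z-scored
#' log-broadband with per-bin SEM. Wavelet edge samples at each row's
#' frequency are excluded from that row.
#'
#' @param B a `broadband_trace`.
#' @param x the raw (re-referenced) signal the rhythms are read from.
#' @param rate sampling rate.
#' @param grid rhythm frequencies (Hz), default 1-50.
#' @param K phase bins (default 24).
#' @param cycles Morlet cycles (default 5).
#' @return object of class `coupling_palette`: `freq`, `centers`, `mean`
#'   and `sem` (freq x K matrices), `scale` (max |mean|), `K`.
#' @export
coupling_palette <- function(B, x, rate, grid = 1:50, K = 24, cycles = 5) {
  if (any(grid >= rate / 2)) stop("palette frequency at or above Nyquist")
  n <- length(x)
  M <- matrix(NA_real_, length(grid), K)
  S <- matrix(NA_real_, length(grid), K)
  for (i in seq_along(grid)) {
    w <- conv_same(x, morlet_kernel(grid[i], rate, cycles))
    ne <- min(n, ceiling(cycles / grid[i] * rate))
    excl <- B$edge
    excl[seq_len(ne)] <- TRUE
    excl[n - seq_len(ne) + 1] <- TRUE
    bins <- phase_bin_means(B$B, Arg(w), K, exclude = excl)
    M[i, ] <- bins$mean
    S[i, ] <- bins$sem
  }
  structure(list(freq = grid, centers = phase_bin_centers(K), mean = M,
                 sem = S, scale = max(abs(M), na.rm = TRUE), K = K),
            class = "coupling_palette")
}

#' Write a palette as a CSV matrix
#'
#' Rows are rhythm frequencies, columns phase-bin centres (radians).
#'
#' @param palette a `coupling_palette`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_palette_csv <- function(palette, path) {
  m <- palette$mean
  dimnames(m) <- list(palette$freq, sprintf("%.4f", palette$centers))
  utils::write.csv(m, path)
  invisible(path)
}

#' Split same-condition stretches into fixed trials
#'
#' Cuts each contiguous same-condition window into non-overlapping segments
#' of `trial_s` seconds (default 1 s), dropping shorter remainders.
#'
#' @param epochs an `epoch_set` (condition-labelled windows).
#' @param rate sampling rate.
#' @param trial_s trial length in seconds.
#' @return an `epoch_set` of trial windows.
#' @export
segment_trials <- function(epochs, rate, trial_s = 1) {
  len <- round(trial_s * rate)
  starts <- integer(); cond <- character()
  for (i in seq_len(nrow(epochs))) {
    k <- (epochs$duration[i]) %/% len
    if (k < 1) next
    starts <- c(starts, epochs$start[i] + (seq_len(k) - 1) * len)
    cond <- c(cond, rep(epochs$condition[i], k))
  }
  epoch_set(starts, len, cond)
}

#' Trial-wise coupling statistics
#'
#' Computes a coupling vector per trial, the mean vector, and the projected
#' distribution `zeta_i = Re(z_i * exp(-1i * phi_mean))` whose mean equals
#' the mean vector's magnitude; tests `zeta` against zero with a two-sided
#' one-sample t-test. Projection onto a common direction keeps the values
#' signed, so chance-level coupling averages to zero instead of biasing
#' upward the way raw magnitudes would.
#'
#' @param B z-scored log-broadband (vector or `broadband_trace`).
#' @param phi rhythm phase series.
#' @param trials an `epoch_set` of >= 2 trial windows (0-based starts).
#' @param K phase bins per trial (default 24).
#' @param condition optional label stored with the result.
#' @param direction optional complex unit direction to project on; default
#'   the trials' own mean vector.
#' @details Projecting onto the trials' own mean direction makes the mean
#'   of `zeta` equal `Mod(mean_vector)`, which is non-negative by
#'   construction; a t-test on that projection is therefore
#'   anticonservative under the null. The significance reported in `p` is
#'   the calibrated one-sample Hotelling T-squared test of the complex
#'   trial vectors against the origin (exact under bivariate normality);
#'   the descriptive projected t-test is kept in `p_projected_t`.
#'
#' @return object of class `coupling_stats`: `vectors` (complex per trial),
#'   `mean_vector`, `Z_mod`, `phi_c`, `zeta`, `mean`, `sem`, `p`
#'   (Hotelling), `p_projected_t`, `condition`.
#' @export
trial_coupling_stats <- function(B, phi, trials, K = 24, condition = "all",
                                 direction = NULL) {
  if (inherits(B, "broadband_trace")) B <- B$B
  if (nrow(trials) < 2) stop("need >= 2 trials")
  z <- vapply(seq_len(nrow(trials)), function(i) {
    idx <- trials$start[i] + seq_len(trials$duration[i])
    bins <- phase_bin_means(B[idx], phi[idx], K)
    coupling_vector(bins)$z
  }, complex(1))
  zbar <- mean(z)
  dir_ang <- if (is.null(direction)) Arg(zbar) else Arg(direction)
  zeta <- Re(z * exp(-1i * dir_ang))
  p_t <- tryCatch(stats::t.test(zeta, mu = 0)$p.value,
                  error = function(e)       # degenerate: identical trials
                    if (abs(mean(zeta)) > 0) 0 else NA_real_)
  structure(list(vectors = z, mean_vector = zbar, Z_mod = Mod(zbar),
                 phi_c = Arg(zbar), zeta = zeta, mean = mean(zeta),
                 sem = stats::sd(zeta) / sqrt(length(zeta)),
                 p = hotelling_t2_p(z), p_projected_t = p_t,
                 condition = condition),
            class = "coupling_stats")
}

# One-sample Hotelling T^2 of complex values against 0 (F(2, n-2) null).
hotelling_t2_p <- function(z) {
  n <- length(z)
  if (n < 3) return(NA_real_)
  X <- cbind(Re(z), Im(z))
  mu <- colMeans(X)
  S <- stats::cov(X)
  if (det(S) <= 0) return(if (sum(mu^2) > 0) 0 else 1)
  t2 <- n * drop(t(mu) %*% solve(S, mu))
  f <- (n - 2) / (2 * (n - 1)) * t2
  stats::pf(f, 2, n - 2, lower.tail = FALSE)
}

#' Signed-r2 contrast between two conditions' coupling
#'
#' Re-projects both conditions' trial vectors onto one common direction
#' (by default the second condition's mean vector — conventionally rest —
#' or `"pooled"` for the grand mean) and returns the signed r2 between the
#' two projected distributions with a two-sample t-test p-value.
#'
#' @param stats_a,stats_b `coupling_stats` for the two conditions.
#' @param direction `"b"` (default), `"a"`, `"pooled"`, or a complex value
#'   whose angle is used.
#' @return list with `signed_r2`, `p`, `direction` (angle used), `zeta_a`,
#'   `zeta_b`.
#' @export
condition_contrast <- function(stats_a, stats_b, direction = "b") {
  if (length(stats_a$vectors) < 2 || length(stats_b$vectors) < 2)
    stop("need >= 2 trials in each condition")
  ang <- if (is.character(direction)) {
    switch(direction,
           a = Arg(stats_a$mean_vector),
           b = Arg(stats_b$mean_vector),
           pooled = Arg(mean(c(stats_a$vectors, stats_b$vectors))),
           stop("unknown direction"))
  } else Arg(direction)
  za <- Re(stats_a$vectors * exp(-1i * ang))
  zb <- Re(stats_b$vectors * exp(-1i * ang))
  r2 <- signed_r2(za, zb)
  p <- stats::t.test(za, zb)$p.value
  list(signed_r2 = r2, p = p, direction = ang, zeta_a = za, zeta_b = zb)
}
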