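# Principal spectral component (PSC) decoupling: separates spectrum-wide
# (broadband, 1/f-coefficient) covariation from band-limited rhythmic
# covariation, and extracts the broadband timecourse used for all coupling
# analyses.

#' PSC decomposition of an epoch ensemble
#'
#' Each epoch's PSD is divided by the ensemble geometric-mean spectrum and
#' log-transformed; the eigenvectors of the resulting inter-frequency
#' correlation matrix (via SVD of the per-frequency standardised matrix) are
#' the Principal Spectral Components, ordered by eigenvalue. The 1st PSC's
#' sign is fixed so its mean weight is positive ("broadband up" positive).
#'
#' @param snapshots a `spectral_snapshot` (>= 2 epochs, >= 2 frequencies).
#' @return object of class `psc_decomposition`: `freq`, `eigenvalues`
#'   (descending, summing to the number of frequencies), `vectors`
#'   (freq x component orthonormal matrix), `mean_log` (ensemble mean log
#'   spectrum), `sd_log` (per-frequency SD of the normalised log spectra),
#'   `projections` (component x epoch), `condition`.
#' @export
psc_decompose <- function(snapshots) {
  P <- snapshots$power
  if (ncol(P) < 2 || nrow(P) < 2) stop("need >= 2 epochs and >= 2 frequencies")
  if (any(P <= 0)) stop("power values must be positive")
  lnP <- log(P)
  mean_log <- rowMeans(lnP)
  V <- lnP - mean_log
  sd_log <- apply(V, 1, stats::sd)
  if (any(sd_log < 1e-14)) stop("degenerate: constant spectra at some frequency")
  U <- V / sd_log
  sv <- svd(U)
  m <- ncol(P)
  eig <- sv$d^2 / (m - 1)
  E <- sv$u
  proj <- t(sv$v) * sv$d             # component x epoch scores, E %*% proj = U
  flip <- ifelse(colMeans(E) < 0, -1, 1)
  E <- sweep(E, 2, flip, `*`)
  proj <- proj * flip
  structure(list(freq = snapshots$freq, eigenvalues = eig, vectors = E,
                 mean_log = mean_log, sd_log = sd_log, projections = proj,
                 condition = snapshots$condition, rate = snapshots$rate),
            class = "psc_decomposition")
}

#' Reconstruct spectra from selected PSCs
#'
#' Rebuilds per-epoch spectra from a subset of components plus the ensemble
#' mean log spectrum, mapped back to power units. With all components this
#' is an exact round trip; excluding the rhythm components (typically the
#' 2nd-4th) yields spectra with rhythmic change removed.
#'
#' @param decomp a `psc_decomposition`.
#' @param included integer component indices to keep; `integer(0)` returns
#'   the ensemble mean spectrum for every epoch.
#' @return a `spectral_snapshot` of reconstructed power.
#' @export
reconstruct_spectra <- function(decomp, included) {
  k <- ncol(decomp$vectors)
  if (length(included) > 0 && (any(included < 1) || any(included > k)))
    stop("invalid component indices")
  U <- if (length(included) == 0) matrix(0, nrow(decomp$vectors),
                                         ncol(decomp$projections))
       else decomp$vectors[, included, drop = FALSE] %*%
            decomp$projections[included, , drop = FALSE]
  P <- exp(U * decomp$sd_log + decomp$mean_log)
  structure(list(freq = decomp$freq, power = P, condition = decomp$condition,
                 rate = decomp$rate),
            class = "spectral_snapshot")
}

#' Broadband timecourse by PSC projection
#'
#' Projects the per-sample normalised log wavelet power spectrum onto the
#' 1st PSC, giving the log of the timecourse of the power-law coefficient;
#' the result is z-scored. A display variant (50 ms Gaussian smoothing,
#' re-z-scored, exponentiated) is attached for plotting only and is never
#' used in coupling computations. Frequencies are streamed so the full
#' dynamic spectrum is never held in memory.
#'
#' @param x numeric signal, or a `dynamic_spectrum` on the decomposition
#'   grid.
#' @param decomp a `psc_decomposition`.
#' @param rate sampling rate (required when `x` is a signal).
#' @param component which PSC to project onto (default 1).
#' @return object of class `broadband_trace`: `B` (z-scored log-broadband),
#'   `display`, `edge` (logical, wavelet edge at the lowest frequency),
#'   `source`, `rate`.
#' @export
broadband_timecourse <- function(x, decomp, rate = NULL, component = 1) {
  e1 <- decomp$vectors[, component]
  if (inherits(x, "dynamic_spectrum")) {
    if (length(x$freq) != length(decomp$freq) ||
        any(x$freq != decomp$freq)) stop("grid mismatch")
    rate <- x$rate
    n <- ncol(x$coef)
    acc <- numeric(n)
    for (i in seq_along(decomp$freq)) {
      lp <- log(Mod(x$coef[i, ])^2 + 1e-300)
      acc <- acc + e1[i] * ((lp - mean(lp)) / stats::sd(lp))
    }
    edge <- x$edge[which.min(x$freq), ]
    cycles <- x$cycles
  } else {
    if (is.null(rate)) stop("rate required")
    n <- length(x)
    acc <- numeric(n)
    cycles <- 5
    for (f in decomp$freq) {
      w <- conv_same(x, morlet_kernel(f, rate, cycles))
      lp <- log(Mod(w)^2 + 1e-300)
      acc <- acc + e1[match(f, decomp$freq)] * ((lp - mean(lp)) / stats::sd(lp))
    }
    ne <- min(n, ceiling(cycles / min(decomp$freq) * rate))
    edge <- rep(FALSE, n)
    edge[seq_len(ne)] <- TRUE
    edge[n - seq_len(ne) + 1] <- TRUE
  }
  B <- as.numeric(scale(acc))
  disp <- exp(as.numeric(scale(gauss_smooth(B, 0.05 * rate))))
  structure(list(B = B, display = disp, edge = edge,
                 sd_log = stats::sd(acc), mean_log = mean(acc),
                 source = "psc-projection", rate = rate),
            class = "broadband_trace")
}

#' Band-power approximation of the broadband timecourse
#'
#' Log analytic amplitude of a high-frequency band (default 65-135 Hz),
#' z-scored. Line-noise harmonics inside the band are notched by splitting
#' the band into sub-bands around them and summing their analytic powers.
#'
#' @param x numeric signal or a `recording_session`.
#' @param band `c(low, high)` in Hz.
#' @param rate sampling rate (from the session if given).
#' @param channel channel index when `x` is a session.
#' @param line_noise_hz,line_noise_halfwidth harmonics of this base inside
#'   the band are excluded (+/- halfwidth); `NULL` disables the notch.
#' @return a `broadband_trace` with `source = "bandpower"`.
#' @export
bandpower_broadband <- function(x, band = c(65, 135), rate = NULL,
                                channel = 1, line_noise_hz = 50,
                                line_noise_halfwidth = 5) {
  if (inherits(x, "recording_session")) {
    rate <- x$rate
    x <- x$samples[channel, ]
  }
  if (is.null(rate)) stop("rate required")
  if (band[2] >= rate / 2) stop("band above Nyquist")
  subs <- list(band)
  if (!is.null(line_noise_hz)) {
    cuts <- seq(line_noise_hz, band[2], by = line_noise_hz)
    cuts <- cuts[cuts > band[1] & cuts < band[2]]
    if (length(cuts) > 0) {
      edges <- sort(c(band[1], band[2],
                      cuts - line_noise_halfwidth, cuts + line_noise_halfwidth))
      subs <- list()
      for (i in seq(1, length(edges) - 1, by = 2))
        if (edges[i + 1] - edges[i] > 1)
          subs[[length(subs) + 1]] <- c(edges[i], edges[i + 1])
    }
  }
  pow <- numeric(length(x))
  for (sb in subs) pow <- pow + analytic_band(x, sb, rate)$amplitude^2
  lg <- log(pow + 1e-300) / 2          # log analytic amplitude
  B <- as.numeric(scale(lg))
  disp <- exp(as.numeric(scale(gauss_smooth(B, 0.05 * rate))))
  structure(list(B = B, display = disp, edge = rep(FALSE, length(x)),
                 sd_log = stats::sd(lg), mean_log = mean(lg),
                 source = "bandpower", rate = rate),
            class = "broadband_trace")
}

# Jarque-Bera normality statistic and p-value (chi-squared, 2 df).
jarque_bera <- function(x) {
  n <- length(x)
  z <- x - mean(x)
  s2 <- mean(z^2)
  skew <- mean(z^3) / s2^1.5
  kurt <- mean(z^4) / s2^2
  jb <- n / 6 * (skew^2 + (kurt - 3)^2 / 4)
  list(statistic = jb, p.value = stats::pchisq(jb, df = 2, lower.tail = FALSE))
}
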