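# Cross-cutting statistics: the signed r2 condition contrast and the
# permutation spatial-overlap metric.

#' Signed r-squared contrast
#'
#' Squared point-biserial correlation between group membership and value,
#' signed by the direction of the mean difference: positive when `a`'s mean
#' exceeds `b`'s. Returns 0 when the pooled variance is zero.
#'
#' @param a,b numeric samples (each n >= 2).
#' @return value in `[-1, 1]`.
#' @export
signed_r2 <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 in each group")
  v <- c(a, b)
  g <- c(rep(1, length(a)), rep(0, length(b)))
  if (stats::var(v) == 0) return(0)
  r <- stats::cor(v, g)
  sign(mean(a) - mean(b)) * r^2
}

#' Permutation spatial-overlap statistic
#'
#' The "true" overlap of two per-channel measures is their dot product; the
#' reported overlap is the true overlap divided by the maximum possible
#' overlap — the dot product after re-sorting both vectors in ascending
#' order (the rearrangement-inequality maximum). Significance comes from
#' scrambling the channel labels of `b`: the p-value is the fraction of
#' surrogate overlaps at least as large as the true one (at most as small,
#' when the true overlap is negative), with the +1 continuity correction so
#' `p` lies in `(0, 1]`.
#'
#' Because the counting direction is chosen from the sign of the observed
#' overlap, that fraction is a folded (one-tail-of-two) quantity whose null
#' distribution concentrates below 0.5; `p_two` doubles it (capped at 1)
#' and is the calibrated two-sided p-value, uniform under the null.
#'
#' @param a,b numeric vectors of equal length >= 2 (per-channel measures).
#' @param n_perm number of label permutations (analysis default 1e6; use
#'   less for tests).
#' @param seed integer seed for the permutation stream.
#' @param exact when TRUE (and `length(a)! <= n_perm`), enumerate all
#'   permutations instead of sampling.
#' @return object of class `overlap_result`: `omega`, `p` (sign-adapted
#'   fraction), `p_two` (calibrated two-sided), `n_perm`, `seed`, `exact`.
#' @export
spatial_overlap <- function(a, b, n_perm = 1e4, seed = 1L, exact = FALSE) {
  if (length(a) != length(b) || length(a) < 2) stop("need equal lengths >= 2")
  if (all(a == 0) || all(b == 0)) stop("all-zero vector: overlap undefined")
  true <- sum(a * b)
  maxo <- sum(sort(a) * sort(b))
  omega <- true / maxo
  n <- length(a)
  if (exact) {
    perms <- all_permutations(n)
    surro <- vapply(seq_len(nrow(perms)), function(i) sum(a * b[perms[i, ]]),
                    numeric(1))
    hits <- if (omega >= 0) sum(surro >= true) else sum(surro <= true)
    p <- hits / length(surro)
    n_used <- nrow(perms)
  } else {
    surro <- with_local_seed(seed, vapply(seq_len(n_perm), function(i)
      sum(a * b[sample.int(n)]), numeric(1)))
    hits <- if (omega >= 0) sum(surro >= true) else sum(surro <= true)
    p <- (hits + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(omega = omega, p = p, p_two = min(1, 2 * p),
                 n_perm = n_used, seed = seed, exact = exact),
            class = "overlap_result")
}

# all n! permutations of 1..n as rows (n <= 7 intended)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      r <- r + 1L
      out[r, ] <- c(k, rest[sub[i, ]])
    }
  }
  out
}

#' Pairwise overlap matrix
#'
#' Overlap statistic and p-value for every column pair of a channel x
#' measure matrix (e.g. per-digit broadband change maps).
#'
#' @param m numeric matrix, channels x measures.
#' @param n_perm,seed passed to [spatial_overlap()].
#' @return list with `omega` and `p` (measure x measure matrices).
#' @export
overlap_matrix <- function(m, n_perm = 1e4, seed = 1L) {
  k <- ncol(m)
  om <- diag(1, k); pv <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    res <- spatial_overlap(m[, i], m[, j], n_perm, seed + i * 131L + j)
    om[i, j] <- res$omega; pv[i, j] <- res$p
  }
  dimnames(om) <- dimnames(pv) <- list(colnames(m), colnames(m))
  list(omega = om, p = pv)
}
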