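## Temporal side of the generator: Wishart-linked precision hierarchy,
## low-frequency semi-Gaussian neural time courses, haemodynamic convolution.

#' Random sparse group precision matrix for mode time courses
#'
#' Draws a symmetric positive-definite precision matrix with unit diagonal
#' and a sparse pattern of off-diagonal couplings, used as the group-level
#' temporal connectivity in the simulator.
#'
#' @param n_modes matrix dimension.
#' @param density probability that a given mode pair is coupled.
#' @param strength maximum magnitude of off-diagonal precision entries.
#' @param seed optional integer seed.
#' @return an SPD `n_modes` x `n_modes` matrix with unit diagonal.
#' @export
make_group_precision <- function(n_modes, density = 0.25, strength = 0.3,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- diag(n_modes)
  for (i in seq_len(n_modes - 1)) for (j in (i + 1):n_modes) {
    if (stats::runif(1) < density) {
      v <- sample(c(-1, 1), 1) * stats::runif(1, 0.1, strength)
      p[i, j] <- p[j, i] <- v
    }
  }
  ## guarantee positive definiteness, then rescale to unit diagonal
  ev <- eigen(p, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 0.1) p <- p + diag(0.1 - min(ev), n_modes)
  d <- sqrt(diag(p))
  p / tcrossprod(d)
}

#' Draw subject precision matrices hierarchically linked to the group
#'
#' Subject temporal precision matrices are Wishart draws with expectation
#' equal to the group precision: `alpha_s ~ Wishart(dof, group_precision /
#' dof)`. Larger `dof` concentrates the subjects around the group.
#'
#' @param group_precision SPD group-level precision matrix.
#' @param dof Wishart degrees of freedom; must exceed `nrow - 1`.
#' @param n_subjects number of draws.
#' @param seed optional integer seed.
#' @return a list of SPD matrices, one per subject.
#' @export
sample_connectivity <- function(group_precision, dof, n_subjects,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is_spd(group_precision))
    stop("`group_precision` must be symmetric positive-definite")
  nm <- nrow(group_precision)
  if (dof < nm) stop("`dof` must be >= the matrix dimension")
  draws <- stats::rWishart(n_subjects, df = dof,
                           Sigma = group_precision / dof)
  lapply(seq_len(n_subjects), function(s) {
    m <- draws[, , s]
    (m + t(m)) / 2
  })
}

#' Simulate low-frequency neural time courses with a given precision
#'
#' Rows are zero-mean, unit-SD time courses whose between-mode (partial)
#' correlation structure follows the inverse of `precision`. Low frequencies
#' are amplified: the series is an ideal low-pass component below
#' `lowpass_hz` plus a small broadband remainder, so that the large majority
#' of spectral power sits in the neural band. The same linear filter is
#' applied to every row, which preserves the cross-mode correlation
#' structure exactly.
#'
#' @param precision SPD N_m x N_m precision matrix.
#' @param n_timepoints series length N_t (must be >= N_m).
#' @param tr sampling interval in seconds.
#' @param lowpass_hz neural-band cutoff in Hz.
#' @param highband_gain relative amplitude retained above the cutoff
#'   (default 0.15; 0 gives a strictly band-limited series).
#' @param seed optional integer seed.
#' @return an N_m x N_t matrix.
#' @export
sample_timecourses <- function(precision, n_timepoints, tr, lowpass_hz,
                               highband_gain = 0.15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is_spd(precision)) stop("`precision` must be SPD")
  nm <- nrow(precision)
  if (n_timepoints < nm)
    stop("`n_timepoints` must be at least the number of modes")
  sigma <- solve(precision)
  x <- rmvn_cols(n_timepoints, sigma)
  lo <- lowpass_rows(x, tr, lowpass_hz)
  x <- lo + highband_gain * (x - lo)
  x <- x - rowMeans(x)
  sds <- apply(x, 1, stats::sd)
  sds[sds == 0] <- 1
  x / sds
}

#' Haemodynamic response basis (canonical + derivatives)
#'
#' A three-function linear basis of plausible haemodynamic response shapes:
#' the canonical double-gamma response, its temporal derivative, and its
#' dispersion derivative, sampled at the repetition time.
#'
#' @param tr sampling interval in seconds.
#' @param duration kernel length in seconds.
#' @return a matrix with one column per basis function.
#' @export
hrf_basis <- function(tr, duration = 32) {
  t <- seq(0, duration, by = tr)
  dg <- function(t, p1 = 6, p2 = 16, ratio = 1 / 6) {
    stats::dgamma(t, shape = p1, rate = 1) -
      ratio * stats::dgamma(t, shape = p2, rate = 1)
  }
  h <- dg(t)
  dt <- 0.1
  h_d <- (dg(t) - dg(t - dt)) / dt            # temporal derivative
  h_s <- (dg(t, p1 = 6 * 1.01, p2 = 16 * 1.01) - dg(t)) / 0.01  # dispersion
  b <- cbind(canonical = h, temporal = h_d, dispersion = h_s)
  sweep(b, 2, apply(b, 2, function(v) max(abs(v))), "/")
}

#' Draw a random haemodynamic response kernel from the basis
#'
#' Canonical shape plus random derivative loadings, rejected until the kernel
#' has a positive peak with latency between 3 and 9 seconds. The kernel is
#' scaled to unit peak.
#'
#' @param basis matrix from [hrf_basis()].
#' @param tr sampling interval in seconds.
#' @param sd_loading SD of the derivative loadings.
#' @return a numeric kernel vector.
#' @export
draw_hrf <- function(basis, tr, sd_loading = 0.3) {
  for (try in 1:100) {
    w <- c(1, stats::rnorm(ncol(basis) - 1, sd = sd_loading))
    k <- drop(basis %*% w)
    pk <- which.max(k)
    lat <- (pk - 1) * tr
    if (k[pk] > 0 && lat >= 3 && lat <= 9) return(k / k[pk])
  }
  basis[, 1] / max(basis[, 1])
}

#' Convolve neural time courses with haemodynamic response kernels
#'
#' Causal, same-length convolution of each mode's neural time course with a
#' haemodynamic response kernel. By default one random kernel is drawn per
#' mode; a fixed kernel can be supplied instead.
#'
#' @param neural_tc N_m x N_t matrix of neural time courses.
#' @param tr sampling interval in seconds.
#' @param kernel optional fixed kernel applied to every row; if `NULL`, a
#'   fresh [draw_hrf()] per row.
#' @param seed optional integer seed.
#' @return an N_m x N_t matrix of BOLD time courses.
#' @export
convolve_hrf <- function(neural_tc, tr, kernel = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (tr <= 0) stop("`tr` must be positive")
  neural_tc <- rbind(neural_tc)
  nt <- ncol(neural_tc)
  basis <- if (is.null(kernel)) hrf_basis(tr) else NULL
  out <- matrix(0, nrow(neural_tc), nt)
  for (m in seq_len(nrow(neural_tc))) {
    k <- if (is.null(kernel)) draw_hrf(basis, tr) else kernel
    full <- stats::convolve(neural_tc[m, ], rev(k), type = "open")
    out[m, ] <- full[seq_len(nt)]
  }
  out
}
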