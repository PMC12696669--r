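#' @keywords internal
"_PACKAGE"

## Internal numerical helpers shared across modules.

#' Column-wise Pearson correlation between two matrices
#'
#' @param a,b numeric matrices with the same number of rows.
#' @return matrix of correlations, `ncol(a)` x `ncol(b)`.
#' @keywords internal
#' @noRd
colcor <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(nrow(a) == nrow(b))
  suppressWarnings(stats::cor(a, b))
}

## Pearson r between two vectors; returns 0 if either is constant
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

## scale columns to unit L2 norm; zero columns left at zero
unit_cols <- function(x) {
  nrm <- sqrt(colSums(x^2))
  nrm[nrm == 0] <- 1
  sweep(x, 2, nrm, "/")
}

## fix sign so the largest-|weight| entry of each column is positive
fix_sign <- function(x) {
  s <- apply(x, 2, function(v) sign(v[which.max(abs(v))]))
  s[s == 0] <- 1
  sweep(x, 2, s, "*")
}

## symmetric matrix check with tolerance
is_spd <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) return(FALSE)
  if (max(abs(m - t(m))) > tol * max(1, max(abs(m)))) return(FALSE)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  all(ev > 0)
}

## draw from N(0, Sigma) via Cholesky: n samples as columns
rmvn_cols <- function(n, sigma) {
  p <- nrow(sigma)
  L <- chol(sigma)
  t(L) %*% matrix(stats::rnorm(p * n), p, n)
}

## Low-pass filter rows of a matrix with an ideal circular FFT filter.
## Returns the filtered matrix; cutoff_hz relative to sampling interval tr.
lowpass_rows <- function(x, tr, cutoff_hz) {
  nt <- ncol(x)
  freqs <- (seq_len(nt) - 1) / (nt * tr)
  freqs <- pmin(freqs, 1 / tr - freqs)  # two-sided spectrum
  keep <- freqs <= cutoff_hz
  xf <- t(stats::mvfft(t(x)))
  xf[, !keep] <- 0
  Re(t(stats::mvfft(t(xf), inverse = TRUE))) / nt
}

## fraction of spectral power at frequencies <= cutoff_hz, per row, averaged
lowfreq_power_fraction <- function(x, tr, cutoff_hz) {
  nt <- ncol(x)
  x <- x - rowMeans(x)
  xf <- Mod(t(stats::mvfft(t(x))))^2
  freqs <- (seq_len(nt) - 1) / (nt * tr)
  freqs <- pmin(freqs, 1 / tr - freqs)
  keep <- freqs <= cutoff_hz & freqs > 0
  pos <- freqs > 0
  mean(rowSums(xf[, keep, drop = FALSE]) / rowSums(xf[, pos, drop = FALSE]))
}
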