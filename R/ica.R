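## FastICA with logcosh contrast and symmetric decorrelation. Used for
## spatial ICA of the group basis, variational-style initial maps, and the
## temporal ICA of the subcomponent pipeline.

## symmetric decorrelation: W <- (W W')^{-1/2} W
.sym_decorrelate <- function(w) {
  e <- eigen(tcrossprod(w), symmetric = TRUE)
  vals <- pmax(e$values, .Machine$double.eps)
  e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors) %*% w
}

#' FastICA (logcosh contrast, symmetric decorrelation, restarts)
#'
#' Extracts `n_comp` maximally non-Gaussian components from the rows of a
#' data matrix (variables x samples). The best of `n_restarts` random
#' re-initialisations by the negentropy surrogate is returned; an error is
#' raised if no restart converges.
#'
#' @param x variables x samples matrix (rows are mixed signals).
#' @param n_comp number of components to extract.
#' @param n_restarts random re-initialisations (default 10).
#' @param max_iter,tol iteration budget and convergence tolerance.
#' @param seed optional integer seed.
#' @return list with `s` (n_comp x samples source estimates), `w` (unmixing
#'   matrix in whitened space), `whitening`, `objective`, `converged`.
#' @export
fast_ica <- function(x, n_comp, n_restarts = 10, max_iter = 500,
                     tol = 1e-7, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- as.matrix(x)
  p <- nrow(x); n <- ncol(x)
  if (n_comp > p) stop("fast_ica: more components than variables")
  x <- x - rowMeans(x)
  ## whiten to n_comp dimensions
  e <- eigen(tcrossprod(x) / n, symmetric = TRUE)
  if (e$values[n_comp] < 1e-12 * e$values[1])
    stop("fast_ica: data rank below `n_comp`; cannot whiten")
  k <- diag(1 / sqrt(e$values[seq_len(n_comp)]), n_comp) %*%
    t(e$vectors[, seq_len(n_comp), drop = FALSE])
  z <- k %*% x                              # n_comp x n, identity covariance

  negentropy <- function(w) {
    ## logcosh surrogate: sum_i (E[log cosh(w_i'z)] - E[log cosh(gauss)])^2
    g0 <- 0.3745232  # E log cosh(N(0,1))
    wz <- w %*% z
    sum((rowMeans(log(cosh(wz))) - g0)^2)
  }

  best <- NULL
  for (r in seq_len(n_restarts)) {
    w <- matrix(stats::rnorm(n_comp * n_comp), n_comp)
    w <- .sym_decorrelate(w)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      wz <- w %*% z
      gwz <- tanh(wz)
      w_new <- gwz %*% t(z) / n - diag(rowMeans(1 - gwz^2), n_comp) %*% w
      w_new <- .sym_decorrelate(w_new)
      crit <- max(abs(abs(diag(w_new %*% t(w))) - 1))
      w <- w_new
      if (crit < tol) { converged <- TRUE; break }
    }
    if (!converged) next
    obj <- negentropy(w)
    if (is.null(best) || obj > best$objective)
      best <- list(w = w, objective = obj, converged = TRUE)
  }
  if (is.null(best))
    stop("fast_ica: no restart converged in ", max_iter,
         " iterations (data may be Gaussian or degenerate)")
  list(s = best$w %*% z, w = best$w, whitening = k,
       objective = best$objective, converged = TRUE)
}

#' Group spatial ICA on a reduced spatial basis
#'
#' Spatial ICA of the group basis: voxels are treated as samples and the
#' basis maps as mixed variables, so the extracted sources are spatially
#' independent group maps. Maps are z-scored across voxels and their sign is
#' fixed so the largest-magnitude voxel is positive.
#'
#' @param basis N_v x K spatial basis, e.g. from [migp_reduce()].
#' @param n_modes number of independent components.
#' @param n_restarts random re-initialisations (default 10).
#' @param seed optional integer seed.
#' @return N_v x `n_modes` matrix of group IC maps.
#' @export
group_ica <- function(basis, n_modes, n_restarts = 10, seed = NULL) {
  basis <- as.matrix(basis)
  if (n_modes > ncol(basis))
    stop("group_ica: `n_modes` exceeds the basis dimension")
  res <- fast_ica(t(basis), n_modes, n_restarts = n_restarts, seed = seed)
  maps <- t(res$s)
  maps <- scale(maps)
  attr(maps, "scaled:center") <- NULL
  attr(maps, "scaled:scale") <- NULL
  fix_sign(maps)
}
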