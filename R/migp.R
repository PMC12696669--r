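## Incremental group PCA over temporally concatenated runs.

#' Incremental group PCA (MIGP-style) spatial basis
#'
#' Maintains a working set of at most `block_size` temporal pseudo-time-series
#' while streaming over runs: each run is voxel-wise demeaned, appended to
#' the working set, and the set is re-truncated to its leading left singular
#' subspace. The result spans the dominant group spatial subspace of the
#' temporal concatenation without ever holding all runs in memory.
#'
#' @param datasets list of [bold_dataset()] objects (or N_v x N_t matrices).
#' @param n_components number of spatial basis maps to return.
#' @param block_size size of the working set (default `2 * n_components`).
#' @param seed optional seed controlling the (randomised) visiting order.
#' @return N_v x `n_components` matrix of spatial basis maps, scaled by the
#'   singular values of the working set.
#' @export
migp_reduce <- function(datasets, n_components,
                        block_size = 2L * n_components, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mats <- lapply(datasets, function(d) if (inherits(d, "bold_dataset")) d$data else as.matrix(d))
  nv <- nrow(mats[[1]])
  if (n_components > nv)
    stop("migp_reduce: `n_components` exceeds the voxel dimension")
  order_idx <- sample(seq_along(mats))
  w <- NULL  # working set: rows are pseudo-time-points (t x N_v)
  for (i in order_idx) {
    d <- mats[[i]]
    if (nrow(d) != nv) stop("migp_reduce: inconsistent voxel dimension")
    d <- t(d - rowMeans(d))                 # N_t x N_v, voxel-wise demeaned
    w <- rbind(w, d)
    if (nrow(w) > block_size) {
      ## re-truncate: keep the top singular pseudo-time-series d_i * v_i',
      ## which preserves the spatial covariance w'w of the leading subspace
      sv <- svd(w, nu = 0, nv = block_size)
      w <- diag(sv$d[seq_len(block_size)], block_size) %*%
        t(sv$v[, seq_len(block_size), drop = FALSE])
    }
  }
  if (n_components > nrow(w))
    stop("migp_reduce: `n_components` exceeds the accumulated temporal rank")
  sv <- svd(w, nu = 0, nv = n_components)
  basis <- sv$v %*% diag(sv$d[seq_len(n_components)], n_components)
  dimnames(basis) <- NULL
  basis
}
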