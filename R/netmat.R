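## Connectivity features: spatial and partial temporal network matrices,
## Fisher transform, block splitting, SVD feature reduction, consistency.

#' Partial temporal network matrix (Tikhonov-regularised)
#'
#' Partial correlations between mode time courses from the inverse of the
#' regularised sample covariance `cov + rho * mean(diag(cov)) * I` (a
#' scale-invariant Tikhonov form): element (i, j) is
#' `-theta_ij / sqrt(theta_ii * theta_jj)`, with a unit diagonal.
#'
#' @param timecourses N_m x N_t matrix of mode time courses.
#' @param rho Tikhonov regularisation parameter (default 0.01).
#' @return an object of class `"netmat"` (`kind = "TNET"`).
#' @export
tnet <- function(timecourses, rho = 0.01) {
  a <- as.matrix(timecourses)
  if (ncol(a) < 2) stop("tnet: need more than one time point")
  sds <- apply(a, 1, stats::sd)
  if (any(sds == 0))
    stop("tnet: constant time course for mode(s) ",
         paste(which(sds == 0), collapse = ", "))
  cv <- stats::cov(t(a))
  theta <- solve(cv + rho * mean(diag(cv)) * diag(nrow(cv)))
  d <- sqrt(diag(theta))
  r <- -theta / tcrossprod(d)
  diag(r) <- 1
  structure(list(values = (r + t(r)) / 2, kind = "TNET", fisher = FALSE,
                 rho = rho), class = "netmat")
}

#' Spatial network matrix
#'
#' Full Pearson correlation across voxels between mode spatial maps.
#'
#' @param spatial_maps N_v x N_m matrix.
#' @return an object of class `"netmat"` (`kind = "SNET"`).
#' @export
snet <- function(spatial_maps) {
  p <- as.matrix(spatial_maps)
  if (ncol(p) < 2) stop("snet: need at least two modes")
  sds <- apply(p, 2, stats::sd)
  if (any(sds == 0))
    stop("snet: zero-variance map for mode(s) ",
         paste(which(sds == 0), collapse = ", "))
  r <- stats::cor(p)
  structure(list(values = (r + t(r)) / 2, kind = "SNET", fisher = FALSE,
                 rho = NA_real_), class = "netmat")
}

#' Fisher r-to-z transform of a network matrix
#'
#' Applies `atanh` element-wise to the off-diagonal entries, after clipping
#' correlations to +/- (1 - 1e-6).
#'
#' @param netmat a `"netmat"` object (or plain correlation matrix).
#' @return the transformed object (diagonal left untouched).
#' @export
fisher_z <- function(netmat) {
  plain <- !inherits(netmat, "netmat")
  v <- if (plain) as.matrix(netmat) else netmat$values
  z <- atanh(pmax(pmin(v, 1 - 1e-6), -(1 - 1e-6)))
  diag(z) <- diag(v)
  if (plain) return(z)
  netmat$values <- z
  netmat$fisher <- TRUE
  netmat
}

#' @export
print.netmat <- function(x, ...) {
  cat(sprintf("%s network matrix: %d modes%s%s\n", x$kind, nrow(x$values),
              if (isTRUE(x$fisher)) ", Fisher z" else "",
              if (!is.na(x$rho)) sprintf(", rho = %g", x$rho) else ""))
  invisible(x)
}

#' Split a network matrix into primary/secondary feature blocks
#'
#' Vectorises the primary-primary and secondary-secondary blocks from their
#' strict upper triangles and the rectangular primary-secondary block fully.
#' With 25 primary and 75 secondary modes the lengths are 300, 2775 and
#' 1875.
#'
#' @param netmat a `"netmat"` or plain symmetric matrix.
#' @param primary_indices indices of the primary modes.
#' @return list with `pri2pri`, `sec2sec`, `pri2sec` feature vectors and the
#'   index sets used.
#' @export
split_blocks <- function(netmat, primary_indices) {
  v <- if (inherits(netmat, "netmat")) netmat$values else as.matrix(netmat)
  nm <- nrow(v)
  pri <- sort(unique(as.integer(primary_indices)))
  if (any(pri < 1 | pri > nm)) stop("split_blocks: invalid primary indices")
  sec <- setdiff(seq_len(nm), pri)
  pp <- v[pri, pri, drop = FALSE]
  ss <- v[sec, sec, drop = FALSE]
  list(pri2pri = pp[upper.tri(pp)],
       sec2sec = ss[upper.tri(ss)],
       pri2sec = as.vector(v[pri, sec, drop = FALSE]),
       primary = pri, secondary = sec)
}

#' Reassemble a network matrix from its feature blocks
#'
#' Inverse of [split_blocks()] (unit diagonal restored).
#'
#' @param blocks result of [split_blocks()].
#' @param n_modes total mode count.
#' @return symmetric `n_modes` x `n_modes` matrix.
#' @export
unsplit_blocks <- function(blocks, n_modes) {
  v <- diag(n_modes)
  pri <- blocks$primary; sec <- blocks$secondary
  pp <- diag(length(pri)); pp[upper.tri(pp)] <- blocks$pri2pri
  pp <- pp + t(pp) - diag(diag(pp))
  ss <- diag(length(sec)); ss[upper.tri(ss)] <- blocks$sec2sec
  ss <- ss + t(ss) - diag(diag(ss))
  v[pri, pri] <- pp
  v[sec, sec] <- ss
  v[pri, sec] <- matrix(blocks$pri2sec, length(pri), length(sec))
  v[sec, pri] <- t(v[pri, sec])
  v
}

#' SVD feature reduction of a subject-by-feature matrix
#'
#' Column-demeaned SVD; returns the top-k left singular vectors scaled by
#' their singular values (principal component scores).
#'
#' @param x n_subjects x n_features matrix.
#' @param k target dimension (default 200); truncated with a warning when it
#'   exceeds `min(dim(x))`.
#' @return n_subjects x k score matrix.
#' @export
svd_reduce <- function(x, k = 200) {
  x <- as.matrix(x)
  x <- sweep(x, 2, colMeans(x))
  kmax <- min(dim(x))
  if (k > kmax) {
    warning("svd_reduce: k truncated from ", k, " to ", kmax)
    k <- kmax
  }
  sv <- svd(x, nu = k, nv = 0)
  sv$u %*% diag(sv$d[seq_len(k)], k)
}

#' Between-subject consistency of connectivity
#'
#' Leave-one-out consistency: for each subject, the Pearson correlation
#' between its vectorised off-diagonal network matrix and the element-wise
#' mean network matrix of all other subjects. A mean-pairwise alternative is
#' available.
#'
#' @param netmats list of `"netmat"` objects or matrices (one per subject).
#' @param method `"loo"` (default) or `"pairwise"`.
#' @return list with `per_subject`, `mean`, `sd`.
#' @export
consistency <- function(netmats, method = c("loo", "pairwise")) {
  method <- match.arg(method)
  mats <- lapply(netmats, function(m)
    if (inherits(m, "netmat")) m$values else as.matrix(m))
  if (length(mats) < 3) stop("consistency: need at least three subjects")
  ut <- upper.tri(mats[[1]])
  vecs <- sapply(mats, function(m) m[ut])
  if (method == "loo") {
    tot <- rowSums(vecs)
    per <- vapply(seq_len(ncol(vecs)), function(s)
      safe_cor(vecs[, s], (tot - vecs[, s]) / (ncol(vecs) - 1)), numeric(1))
  } else {
    cm <- stats::cor(vecs)
    per <- (colSums(cm) - 1) / (ncol(vecs) - 1)
  }
  list(per_subject = per, mean = mean(per), sd = stats::sd(per))
}

#' Parcel-average time courses
#'
#' Averages voxel time courses within each labelled parcel (label 0 =
#' unassigned).
#'
#' @param dataset a [bold_dataset()] or N_v x N_t matrix.
#' @param parcel_labels integer vector of length N_v.
#' @return N_parcels x N_t matrix, rows named by parcel label.
#' @export
parcel_timecourses <- function(dataset, parcel_labels) {
  d <- if (inherits(dataset, "bold_dataset")) dataset$data else as.matrix(dataset)
  labs <- as.integer(parcel_labels)
  if (length(labs) != nrow(d))
    stop("parcel_timecourses: labels must cover all voxels")
  ids <- sort(unique(labs[labs > 0]))
  empty <- setdiff(seq_len(max(c(0L, ids))), ids)
  if (length(empty))
    stop("parcel_timecourses: empty parcel(s) ",
         paste(empty, collapse = ", "))
  out <- t(vapply(ids, function(p)
    colMeans(d[labs == p, , drop = FALSE]), numeric(ncol(d))))
  rownames(out) <- ids
  out
}
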