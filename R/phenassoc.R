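## Phenotype machinery: fold-safe deconfounded, Gaussianised elastic-net
## prediction with nested cross-validation, and CCA with block-permutation
## family-wise error control.

#' Reduce a confound table to a design matrix
#'
#' Conventional confounds are kept verbatim; the remaining columns are
#' PCA-reduced to the smallest number of components explaining more than
#' `var_threshold` of their variance, and the two sets are concatenated.
#'
#' @param confounds data frame or matrix of confound variables.
#' @param conventional column names (or indices) to keep verbatim.
#' @param var_threshold variance fraction for the PCA-reduced remainder
#'   (default 0.85).
#' @return numeric design matrix.
#' @export
reduce_confounds <- function(confounds, conventional = character(0),
                             var_threshold = 0.85) {
  if (var_threshold <= 0 || var_threshold >= 1)
    stop("reduce_confounds: `var_threshold` must lie in (0, 1)")
  x <- as.matrix(as.data.frame(confounds))
  if (any(colSums(is.finite(x)) == 0))
    stop("reduce_confounds: all-missing confound column")
  keep_idx <- if (is.character(conventional))
    match(conventional, colnames(x)) else as.integer(conventional)
  keep_idx <- keep_idx[!is.na(keep_idx)]
  rest <- x[, setdiff(seq_len(ncol(x)), keep_idx), drop = FALSE]
  out <- x[, keep_idx, drop = FALSE]
  if (ncol(rest) > 0) {
    rest <- scale(rest)
    rest[!is.finite(rest)] <- 0
    sv <- svd(rest, nv = 0)
    ev <- sv$d^2 / sum(sv$d^2)
    k <- which(cumsum(ev) > var_threshold)[1]
    pcs <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
    colnames(pcs) <- paste0("confPC", seq_len(k))
    out <- cbind(out, pcs)
  }
  out
}

#' Fold-safe deconfounding
#'
#' Regression betas of the data on the confounds are estimated on the
#' training rows only and applied to residualise both training and test
#' rows; no test statistic enters the fit.
#'
#' @param train,test numeric matrices (or vectors) with the same columns.
#' @param confounds_train,confounds_test confound design matrices for the
#'   two row sets.
#' @return list with residualised `train` and `test`.
#' @export
deconfound_fold <- function(train, test, confounds_train, confounds_test) {
  tr <- as.matrix(train); te <- as.matrix(test)
  ctr <- cbind(1, as.matrix(confounds_train))
  cte <- cbind(1, as.matrix(confounds_test))
  beta <- qr.coef(qr(ctr), tr)
  beta[!is.finite(beta)] <- 0
  list(train = tr - ctr %*% beta, test = te - cte %*% beta)
}

#' Fold-safe quantile Gaussianisation
#'
#' Maps each variable through its training-set empirical quantiles to the
#' standard normal; test values are interpolated on the training quantile
#' grid and clipped to the extreme training quantiles.
#'
#' @param train,test numeric matrices (or vectors) with matching columns.
#' @return list with transformed `train` and `test`.
#' @export
gaussianise_fold <- function(train, test) {
  tr <- as.matrix(train); te <- as.matrix(test)
  n <- nrow(tr)
  if (n < 10) stop("gaussianise_fold: need >= 10 training samples")
  out_tr <- tr; out_te <- te
  for (j in seq_len(ncol(tr))) {
    if (stats::sd(tr[, j]) == 0)
      stop("gaussianise_fold: constant variable in column ", j)
    ranks <- rank(tr[, j], ties.method = "average")
    out_tr[, j] <- stats::qnorm(ranks / (n + 1))
    srt <- sort(tr[, j])
    probs <- seq_len(n) / (n + 1)
    ## piecewise-linear empirical CDF, clipped to the training range
    pt <- stats::approx(srt, probs, xout = te[, j], rule = 2,
                        ties = "ordered")$y
    out_te[, j] <- stats::qnorm(pmin(pmax(pt, probs[1]), probs[n]))
  }
  list(train = out_tr, test = out_te)
}

#' Elastic-net phenotype prediction with nested cross-validation
#'
#' Outer 5-fold cross-validation (each fold a 20% test set); within each
#' training set, variables are Gaussianised and deconfounded fold-safely,
#' the elastic-net mixing and penalty parameters are chosen by an inner
#' cross-validated grid (`l1_ratios` x `n_alphas` penalties), the model is
#' refitted, and held-out subjects are predicted. Accuracy is the Pearson
#' correlation between predicted and actual phenotype on the test rows.
#'
#' @param x n x p feature matrix.
#' @param y phenotype vector.
#' @param confounds optional confound design matrix (deconfounded
#'   fold-safely from both `x` and `y`).
#' @param n_outer_folds outer folds (default 5).
#' @param l1_ratios elastic-net mixing grid.
#' @param n_alphas penalties per mixing value (inner grid).
#' @param inner_folds inner cross-validation folds.
#' @param seed integer seed.
#' @return object of class `"enet_prediction"`: list with `fold_accuracy`,
#'   `pooled_accuracy` (correlation over all held-out predictions),
#'   `predictions`, `folds`, `chosen` (per-fold l1 ratio and lambda).
#' @export
elasticnet_predict <- function(x, y, confounds = NULL, n_outer_folds = 5,
                               l1_ratios = c(0.1, 0.5, 0.7, 0.9, 0.95,
                                             0.99, 1.0),
                               n_alphas = 10, inner_folds = 5, seed = 1L) {
  set.seed(seed)
  x <- as.matrix(x); y <- as.numeric(y)
  n <- length(y)
  if (n < 50) stop("elasticnet_predict: need at least 50 subjects")
  folds <- sample(rep(seq_len(n_outer_folds), length.out = n))
  pred <- rep(NA_real_, n)
  fold_acc <- rep(NA_real_, n_outer_folds)
  chosen <- vector("list", n_outer_folds)
  for (f in seq_len(n_outer_folds)) {
    te <- which(folds == f); tr <- which(folds != f)
    if (stats::sd(y[tr]) == 0) {
      warning("elasticnet_predict: constant phenotype in training fold ", f,
              "; fold skipped")
      next
    }
    gx <- gaussianise_fold(x[tr, , drop = FALSE], x[te, , drop = FALSE])
    gy <- gaussianise_fold(y[tr], y[te])
    xtr <- gx$train; xte <- gx$test
    ytr <- drop(gy$train); yte <- drop(gy$test)
    if (!is.null(confounds)) {
      cf <- as.matrix(confounds)
      dx <- deconfound_fold(xtr, xte, cf[tr, , drop = FALSE],
                            cf[te, , drop = FALSE])
      dy <- deconfound_fold(ytr, yte, cf[tr, , drop = FALSE],
                            cf[te, , drop = FALSE])
      xtr <- dx$train; xte <- dx$test
      ytr <- drop(dy$train); yte <- drop(dy$test)
    }
    inner_id <- sample(rep(seq_len(inner_folds), length.out = length(tr)))
    best <- NULL
    for (l1 in l1_ratios) {
      cv <- glmnet::cv.glmnet(xtr, ytr, alpha = l1, nlambda = n_alphas,
                              foldid = inner_id, standardize = TRUE)
      i <- which.min(cv$cvm)
      if (is.null(best) || cv$cvm[i] < best$cvm) {
        best <- list(cvm = cv$cvm[i], l1 = l1, lambda = cv$lambda[i])
      }
    }
    fit <- glmnet::glmnet(xtr, ytr, alpha = best$l1, lambda = best$lambda,
                          standardize = TRUE)
    ph <- drop(stats::predict(fit, xte))
    pred[te] <- ph
    fold_acc[f] <- safe_cor(ph, yte)
    chosen[[f]] <- c(l1_ratio = best$l1, lambda = best$lambda)
  }
  ok <- !is.na(pred)
  structure(list(fold_accuracy = fold_acc,
                 pooled_accuracy = if (any(ok)) safe_cor(pred[ok], y[ok]) else NA_real_,
                 predictions = pred, folds = folds, chosen = chosen),
            class = "enet_prediction")
}

#' @export
print.enet_prediction <- function(x, ...) {
  cat(sprintf("Elastic-net prediction: pooled accuracy r = %.3f (folds: %s)\n",
              x$pooled_accuracy,
              paste(sprintf("%.2f", x$fold_accuracy), collapse = ", ")))
  invisible(x)
}

#' Canonical correlation analysis on SVD-reduced features
#'
#' Demeans both sides, reduces each to `n_dim` components by SVD, and
#' computes canonical correlations (sorted non-increasing) with the
#' corresponding transforms and variates.
#'
#' @param x_features,y_phenotypes numeric matrices with matching rows.
#' @param n_dim reduction dimension per side (default 50).
#' @return object of class `"cca_result"`: `correlations`, `u`, `v`
#'   (canonical variates), `xcoef`, `ycoef`, `n_dim`.
#' @export
cca_fit <- function(x_features, y_phenotypes, n_dim = 50) {
  x <- as.matrix(x_features); y <- as.matrix(y_phenotypes)
  if (nrow(x) != nrow(y)) stop("cca_fit: row mismatch")
  if (n_dim > min(dim(x)) || n_dim > min(dim(y)))
    stop("cca_fit: `n_dim` exceeds a side's dimension")
  xr <- svd_reduce(x, n_dim)
  yr <- svd_reduce(y, n_dim)
  qx <- qr(xr); qy <- qr(yr)
  if (qx$rank < n_dim || qy$rank < n_dim)
    stop("cca_fit: rank deficiency after reduction")
  cc <- stats::cancor(xr, yr)
  u <- xr %*% cc$xcoef
  v <- yr %*% cc$ycoef
  structure(list(correlations = cc$cor, u = u, v = v,
                 xcoef = cc$xcoef, ycoef = cc$ycoef, n_dim = n_dim),
            class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("CCA (%d dims): leading correlations %s\n", x$n_dim,
              paste(sprintf("%.3f", utils::head(x$correlations, 5)),
                    collapse = ", ")))
  invisible(x)
}

## permute subject indices respecting exchangeability blocks: whole blocks
## of equal size may swap, and subjects shuffle within blocks
block_permute <- function(blocks) {
  blocks <- as.integer(factor(blocks))
  n <- length(blocks)
  sizes <- tabulate(blocks)
  if (all(sizes == 1L)) return(sample.int(n))   # free permutation
  out <- integer(n)
  for (sz in unique(sizes)) {
    ids <- which(sizes == sz)
    tgt <- if (length(ids) > 1L) sample(ids) else ids
    for (k in seq_along(ids)) {
      from <- which(blocks == ids[k])
      to <- which(blocks == tgt[k])
      out[from] <- if (length(to) > 1L) sample(to) else to
    }
  }
  out
}

#' Permutation inference for CCA with exchangeability blocks
#'
#' Builds a null distribution of the first canonical correlation by
#' repeatedly permuting the rows of `y` while respecting family structure:
#' whole blocks of equal size are exchanged and subjects are shuffled
#' within blocks (a two-level exchangeability scheme). The family-wise
#' error threshold is the 95th percentile of that null, and every canonical
#' component whose correlation exceeds it is declared significant.
#'
#' @param x_features,y_phenotypes numeric matrices with matching rows.
#' @param blocks vector assigning each subject to an exchangeability block
#'   (family); singletons allowed. Default: all singletons (free
#'   permutation).
#' @param n_perm number of permutations (default 10000).
#' @param n_dim CCA reduction dimension.
#' @param alpha tail probability for the threshold (default 0.05).
#' @param seed integer seed.
#' @return object of class `"cca_permutation"`: `fit` (the observed
#'   [cca_fit()]), `null_first` (permutation null of the first
#'   correlation), `threshold`, `n_significant`.
#' @export
cca_permutation_test <- function(x_features, y_phenotypes, blocks = NULL,
                                 n_perm = 10000, n_dim = 50, alpha = 0.05,
                                 seed = 1L) {
  set.seed(seed)
  x <- as.matrix(x_features); y <- as.matrix(y_phenotypes)
  n <- nrow(x)
  if (is.null(blocks)) blocks <- seq_len(n)
  if (length(blocks) != n) stop("cca_permutation_test: bad block vector")
  if (n_perm < 100) warning("cca_permutation_test: fewer than 100 permutations")
  ## reduce once; permutation of rows commutes with the per-side SVD basis
  xr <- svd_reduce(x, n_dim)
  yr <- svd_reduce(y, n_dim)
  obs <- stats::cancor(xr, yr)$cor
  null_first <- vapply(seq_len(n_perm), function(i) {
    perm <- block_permute(blocks)
    stats::cancor(xr, yr[perm, , drop = FALSE])$cor[1]
  }, numeric(1))
  threshold <- stats::quantile(null_first, 1 - alpha, names = FALSE)
  structure(list(correlations = obs, null_first = null_first,
                 threshold = threshold,
                 n_significant = sum(obs > threshold), n_perm = n_perm),
            class = "cca_permutation")
}

#' @export
print.cca_permutation <- function(x, ...) {
  cat(sprintf("CCA permutation test (%d perms): FWE threshold %.3f, %d significant component(s)\n",
              x$n_perm, x$threshold, x$n_significant))
  invisible(x)
}
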