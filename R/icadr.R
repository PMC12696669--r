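## Baseline decomposition: group spatial ICA + two-stage dual regression.

#' Two-stage dual regression of one run against group maps
#'
#' Stage 1 regresses the run's data on the group maps jointly (multivariate
#' least squares across voxels) to obtain subject time courses; stage 2
#' regresses the data on the (optionally variance-normalised) stage-1 time
#' courses to obtain subject spatial maps. Amplitudes are the SDs of the
#' stage-1 time courses.
#'
#' @param dataset a [bold_dataset()] or N_v x N_t matrix.
#' @param group_maps N_v x N_m group map matrix.
#' @param normalise_tc variance-normalise stage-1 time courses before stage 2
#'   (default `TRUE`, matching common dual-regression practice).
#' @return list with `timecourses` (N_m x N_t), `subject_maps` (N_v x N_m),
#'   `amplitudes` (length N_m).
#' @export
dual_regression <- function(dataset, group_maps, normalise_tc = TRUE) {
  d <- if (inherits(dataset, "bold_dataset")) dataset$data else as.matrix(dataset)
  p <- as.matrix(group_maps)
  if (nrow(d) != nrow(p)) stop("dual_regression: voxel dimension mismatch")
  qr_p <- qr(p)
  if (qr_p$rank < ncol(p)) {
    warning("dual_regression: rank-deficient group maps; using pseudo-inverse")
    tc <- MASS_ginv(p) %*% d
  } else {
    tc <- qr.coef(qr_p, d)                    # stage 1: N_m x N_t
  }
  amplitudes <- apply(tc, 1, stats::sd)
  tc2 <- tc
  if (normalise_tc) {
    s <- amplitudes; s[s == 0] <- 1
    tc2 <- tc / s
  }
  maps <- t(qr.coef(qr(t(tc2)), t(d)))        # stage 2: N_v x N_m
  list(timecourses = tc, subject_maps = maps, amplitudes = amplitudes)
}

## minimal Moore-Penrose pseudo-inverse (SVD)
MASS_ginv <- function(x, tol = sqrt(.Machine$double.eps)) {
  sv <- svd(x)
  pos <- sv$d > tol * sv$d[1]
  sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

#' Group spatial ICA with dual regression (baseline decomposition)
#'
#' Fits the standard baseline: an incremental group PCA (MIGP) basis over
#' all runs, group spatial ICA on that basis, then two-stage dual regression
#' per run. Subject maps are averaged across a subject's runs.
#'
#' @param datasets list of [bold_dataset()] objects.
#' @param n_modes number of independent components.
#' @param basis optional precomputed N_v x K spatial basis; when supplied
#'   (e.g. shared with a `pfm` fit), MIGP is skipped.
#' @param n_basis basis dimension for MIGP when `basis` is `NULL`.
#' @param n_restarts ICA restarts.
#' @param seed integer seed.
#' @return an object of class `"icadr"` with `group_maps` (N_v x N_m),
#'   `subject_maps` (list per subject), `timecourses` (nested list
#'   `[[subject]][[run]]`), `amplitudes`, `subjects`, `method = "ICA-DR"`.
#' @export
icadr <- function(datasets, n_modes, basis = NULL, n_basis = 2L * n_modes,
                  n_restarts = 10, seed = 1L) {
  set.seed(seed)
  subjects <- vapply(datasets, function(d) d$subject_id, numeric(1))
  if (is.null(basis))
    basis <- migp_reduce(datasets, n_components = min(n_basis,
                                                      nrow(datasets[[1]]$data)))
  gmaps <- group_ica(basis, n_modes, n_restarts = n_restarts)
  usub <- unique(subjects)
  subject_maps <- vector("list", length(usub))
  timecourses <- vector("list", length(usub))
  amplitudes <- vector("list", length(usub))
  for (si in seq_along(usub)) {
    runs <- which(subjects == usub[si])
    maps_acc <- 0
    timecourses[[si]] <- vector("list", length(runs))
    amp_acc <- 0
    for (k in seq_along(runs)) {
      dr <- dual_regression(datasets[[runs[k]]], gmaps)
      timecourses[[si]][[k]] <- dr$timecourses
      maps_acc <- maps_acc + dr$subject_maps
      amp_acc <- amp_acc + dr$amplitudes
    }
    subject_maps[[si]] <- maps_acc / length(runs)
    amplitudes[[si]] <- amp_acc / length(runs)
  }
  structure(list(group_maps = gmaps, subject_maps = subject_maps,
                 timecourses = timecourses, amplitudes = amplitudes,
                 subjects = usub, n_modes = n_modes, basis = basis,
                 method = "ICA-DR", seed = seed),
            class = "icadr")
}

#' @export
print.icadr <- function(x, ...) {
  cat(sprintf("Group spatial ICA + dual regression: %d modes, %d subjects\n",
              x$n_modes, length(x$subjects)))
  invisible(x)
}

#' @export
coef.icadr <- function(object, ...) object$group_maps
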