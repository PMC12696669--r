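## Assembly of space x time data matrices and the umbrella simulator.

#' Construct a BOLD dataset container
#'
#' @param data N_v x N_t numeric matrix (space x time).
#' @param subject_id,run_id identifiers.
#' @param tr_seconds repetition time in seconds.
#' @return an object of class `"bold_dataset"`.
#' @export
bold_dataset <- function(data, subject_id, run_id = 1L, tr_seconds) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("bold_dataset: non-finite entries in data")
  structure(list(data = data, subject_id = subject_id, run_id = run_id,
                 tr_seconds = tr_seconds), class = "bold_dataset")
}

#' @export
print.bold_dataset <- function(x, ...) {
  cat(sprintf("BOLD dataset: subject %s run %s, %d voxels x %d timepoints, TR %.3g s\n",
              x$subject_id, x$run_id, nrow(x$data), ncol(x$data),
              x$tr_seconds))
  invisible(x)
}

#' Assemble space x time data from maps and time courses
#'
#' Builds one dataset per subject and run as the outer product of the
#' subject's spatial maps with that run's BOLD time courses, plus i.i.d.
#' Gaussian observation noise: `D = P %*% A + E`.
#'
#' @param truth a `"ground_truth"` with `subject_maps` and
#'   `bold_timecourses` filled in.
#' @param config the generating [sim_config()].
#' @param seed optional integer seed (noise only).
#' @return a list of [bold_dataset()] objects, ordered subject-major.
#' @export
assemble_dataset <- function(truth, config = truth$config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(!is.null(truth$subject_maps), !is.null(truth$bold_timecourses))
  out <- list()
  for (s in seq_len(config$n_subjects)) {
    p <- truth$subject_maps[[s]]
    for (r in seq_len(config$n_runs)) {
      a <- truth$bold_timecourses[[s]][[r]]
      if (ncol(p) != nrow(a))
        stop("assemble_dataset: map/timecourse shape mismatch")
      d <- p %*% a
      if (config$obs_noise_sd > 0)
        d <- d + matrix(stats::rnorm(length(d), sd = config$obs_noise_sd),
                        nrow(d), ncol(d))
      out[[length(out) + 1L]] <- bold_dataset(d, subject_id = s, run_id = r,
                                              tr_seconds = config$tr_seconds)
    }
  }
  out
}

#' Simulate a complete multiscale resting-state dataset
#'
#' Runs the full generative chain: group maps (overlapping distributed modes
#' with localised sub-modes), subject maps (smooth spatial warps + background
#' noise), a group temporal precision with Wishart-linked subject precisions,
#' low-frequency neural time courses per subject/run, haemodynamic
#' convolution, and the final outer-product data with observation noise.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to `config$seed`. All randomness flows
#'   from this single seed.
#' @return an object of class `"mode_sim"`: a list with `datasets` (list of
#'   [bold_dataset()]) and `truth` (a `"ground_truth"` carrying group and
#'   subject maps, neural and BOLD time courses, group and subject precision
#'   matrices, mode classes and parent links).
#' @export
#' @examples
#' sim <- simulate_modes(sim_config(n_voxels = 400, n_subjects = 3,
#'                                  n_timepoints = 120, n_datasets = 1),
#'                       seed = 7)
#' sim$datasets[[1]]
simulate_modes <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  truth <- make_group_maps(config)
  truth <- make_subject_maps(truth, config)
  truth$group_precision <- make_group_precision(config$n_modes)
  truth$subject_precisions <- sample_connectivity(
    truth$group_precision, config$wishart_dof, config$n_subjects)
  truth$neural_timecourses <- vector("list", config$n_subjects)
  truth$bold_timecourses <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    truth$neural_timecourses[[s]] <- vector("list", config$n_runs)
    truth$bold_timecourses[[s]] <- vector("list", config$n_runs)
    for (r in seq_len(config$n_runs)) {
      neural <- sample_timecourses(truth$subject_precisions[[s]],
                                   config$n_timepoints, config$tr_seconds,
                                   config$lowpass_hz)
      bold <- convolve_hrf(neural, config$tr_seconds)
      bold <- bold - rowMeans(bold)
      sds <- apply(bold, 1, stats::sd); sds[sds == 0] <- 1
      bold <- bold / sds
      truth$neural_timecourses[[s]][[r]] <- neural
      truth$bold_timecourses[[s]][[r]] <- bold
    }
  }
  datasets <- assemble_dataset(truth, config)
  structure(list(datasets = datasets, truth = truth, config = config,
                 seed = seed), class = "mode_sim")
}

#' @export
print.mode_sim <- function(x, ...) {
  cat("Simulated multiscale resting-state dataset\n")
  print(x$config)
  cat(sprintf("  overlap statistic: %.3f distributed modes per covered voxel\n",
              mode_overlap_count(x$truth)))
  cat(sprintf("  subject-group support Dice: %.3f\n",
              subject_group_overlap(x$truth)))
  invisible(x)
}

#' Synthetic phenotypes with confound contamination
#'
#' Generates phenotype and confound tables from subject-level connectivity
#' features under a linear-Gaussian model. A signal factor `s` is a sparse
#' linear combination of (standardised) features; observed confounds load on
#' both `s` and an independent factor, and phenotypes are
#' `y = sqrt(effect_size) * s + confound_strength * g + noise`, where `g` is
#' the common confound factor. With `effect_size = 0` and positive
#' `confound_strength` the phenotype is confound-driven only, which is the
#' leakage-detection scenario for the prediction pipeline.
#'
#' @param features n_subjects x n_features numeric matrix.
#' @param n_phenotypes number of phenotype columns to generate.
#' @param effect_size proportion of phenotype variance explained by the
#'   feature signal; must lie in `[0, 1)`.
#' @param confound_strength loading of the phenotype on the common confound
#'   factor.
#' @param n_confounds number of observed confound columns.
#' @param sparsity fraction of features with non-zero signal weight.
#' @param seed optional integer seed.
#' @return a list with `phenotypes` (n x n_phenotypes), `confounds`
#'   (n x n_confounds), and the latent `signal` factor.
#' @export
make_synthetic_phenotypes <- function(features, n_phenotypes = 1,
                                      effect_size = 0.5,
                                      confound_strength = 0,
                                      n_confounds = 5, sparsity = 0.2,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (effect_size < 0 || effect_size >= 1)
    stop("`effect_size` must lie in [0, 1)")
  x <- scale(as.matrix(features))
  x[is.na(x)] <- 0
  n <- nrow(x); p <- ncol(x)
  nw <- max(1L, round(sparsity * p))
  w <- rep(0, p)
  w[sample.int(p, nw)] <- stats::rnorm(nw)
  s <- drop(x %*% w)
  s <- (s - mean(s)) / max(stats::sd(s), .Machine$double.eps)
  u <- stats::rnorm(n)                      # confound-only factor
  g <- (0.5 * s + 0.5 * u) / sqrt(0.5)      # common confound factor, unit var
  conf <- sapply(seq_len(n_confounds), function(j)
    0.5 * s + 0.5 * u + sqrt(1 - 0.5) * stats::rnorm(n))
  a <- sqrt(effect_size)
  varexp <- a^2 + confound_strength^2 + 2 * a * confound_strength * sqrt(0.5)
  if (varexp >= 1)
    stop("effect_size and confound_strength jointly exceed unit variance")
  pheno <- sapply(seq_len(n_phenotypes), function(k)
    a * s + confound_strength * g + sqrt(1 - varexp) * stats::rnorm(n))
  colnames(pheno) <- paste0("pheno", seq_len(n_phenotypes))
  colnames(conf) <- paste0("conf", seq_len(n_confounds))
  list(phenotypes = pheno, confounds = conf, signal = s)
}
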