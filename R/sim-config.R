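#' Configuration for the multiscale resting-state simulator
#'
#' Collects and validates every tunable of the synthetic data generator. The
#' defaults reproduce the desk-scale simulation study this package's benchmark
#' is built around: 10 datasets of 50 subjects x 2 runs, 10,000 voxels and 300
#' time points at a TR of 0.72 s, with 12 modes (6 distributed, 6 localised).
#' Distributed modes overlap so that, over covered voxels, on average ~1.3
#' distributed modes include any given voxel, and subject maps are spatially
#' warped so that their supports overlap the group supports with a mean Dice
#' of ~0.83. The two calibration constants (`mode_coverage`,
#' `warp_magnitude`) were fixed once against those two summary statistics.
#'
#' @param n_datasets number of independent datasets to simulate.
#' @param n_subjects subjects per dataset.
#' @param n_runs runs (sessions) per subject.
#' @param n_voxels voxels on the 1-D lattice (N_v).
#' @param n_timepoints time points per run (N_t).
#' @param tr_seconds repetition time in seconds.
#' @param n_distributed number of distributed modes (>= 2 blocks each).
#' @param n_localised number of localised modes (exactly 1 block each).
#' @param gamma_shape,gamma_scale Gamma parameters for per-voxel mode weights.
#' @param weight_smoothness correlation length of the smooth weight field,
#'   as a fraction of the lattice length.
#' @param mode_coverage fraction of the lattice covered by each distributed
#'   mode; controls between-mode overlap.
#' @param allow_overlap if `FALSE`, distributed-mode blocks are placed on
#'   disjoint stretches of the lattice (no overlap).
#' @param warp_magnitude RMS displacement of the smooth subject-level spatial
#'   warp, as a fraction of the lattice length.
#' @param background_noise_sd SD of the Gaussian background added to subject
#'   spatial maps.
#' @param wishart_dof degrees of freedom tying subject temporal precision
#'   matrices to the group precision; must exceed `n_modes - 1`.
#' @param obs_noise_sd SD of the additive observation noise on the data.
#' @param lowpass_hz neural-band cutoff; low frequencies are amplified so that
#'   most spectral power lies below this value. Must not exceed Nyquist.
#' @param seed integer RNG seed from which all randomness flows.
#'
#' @return an object of class `"sim_config"` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_voxels = 500, n_subjects = 4, seed = 1)
#' cfg
sim_config <- function(n_datasets = 10,
                       n_subjects = 50,
                       n_runs = 2,
                       n_voxels = 10000,
                       n_timepoints = 300,
                       tr_seconds = 0.72,
                       n_distributed = 6,
                       n_localised = 6,
                       gamma_shape = 3,
                       gamma_scale = 0.5,
                       weight_smoothness = 0.015,
                       mode_coverage = 0.11,
                       allow_overlap = TRUE,
                       warp_magnitude = 0.0063,
                       background_noise_sd = 0.15,
                       wishart_dof = 50,
                       obs_noise_sd = 3.0,
                       lowpass_hz = 0.1,
                       seed = 1L) {
  cfg <- list(
    n_datasets = as.integer(n_datasets), n_subjects = as.integer(n_subjects),
    n_runs = as.integer(n_runs), n_voxels = as.integer(n_voxels),
    n_timepoints = as.integer(n_timepoints), tr_seconds = tr_seconds,
    n_distributed = as.integer(n_distributed),
    n_localised = as.integer(n_localised),
    gamma_shape = gamma_shape, gamma_scale = gamma_scale,
    weight_smoothness = weight_smoothness,
    mode_coverage = mode_coverage, allow_overlap = isTRUE(allow_overlap),
    warp_magnitude = warp_magnitude,
    background_noise_sd = background_noise_sd,
    wishart_dof = wishart_dof, obs_noise_sd = obs_noise_sd,
    lowpass_hz = lowpass_hz, seed = as.integer(seed)
  )
  counts <- c("n_datasets", "n_subjects", "n_runs", "n_voxels",
              "n_timepoints", "n_distributed", "n_localised")
  for (f in counts[counts != "n_localised"]) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop("sim_config: `", f, "` must be a count >= 1", call. = FALSE)
  }
  if (cfg$n_localised < 0L) stop("sim_config: `n_localised` must be >= 0")
  if (cfg$tr_seconds <= 0) stop("sim_config: `tr_seconds` must be positive")
  if (cfg$gamma_shape <= 0 || cfg$gamma_scale <= 0)
    stop("sim_config: Gamma parameters must be positive")
  n_modes <- cfg$n_distributed + cfg$n_localised
  if (cfg$wishart_dof <= n_modes - 1)
    stop("sim_config: `wishart_dof` must exceed n_modes - 1 = ", n_modes - 1)
  if (cfg$lowpass_hz > 1 / (2 * cfg$tr_seconds))
    stop("sim_config: `lowpass_hz` exceeds the Nyquist frequency ",
         signif(1 / (2 * cfg$tr_seconds), 4), " Hz")
  if (cfg$mode_coverage <= 0 || cfg$mode_coverage >= 1)
    stop("sim_config: `mode_coverage` must lie in (0, 1)")
  if (cfg$weight_smoothness <= 0)
    stop("sim_config: `weight_smoothness` must be positive")
  if (cfg$warp_magnitude < 0 || cfg$background_noise_sd < 0 ||
      cfg$obs_noise_sd < 0)
    stop("sim_config: noise/warp magnitudes must be non-negative")
  cfg$n_modes <- n_modes
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Multiscale resting-state simulation configuration\n")
  cat(sprintf("  %d dataset(s): %d subjects x %d run(s)\n",
              x$n_datasets, x$n_subjects, x$n_runs))
  cat(sprintf("  %d voxels x %d timepoints, TR %.3g s\n",
              x$n_voxels, x$n_timepoints, x$tr_seconds))
  cat(sprintf("  %d modes (%d distributed + %d localised)\n",
              x$n_modes, x$n_distributed, x$n_localised))
  cat(sprintf("  weights ~ Gamma(%.3g, %.3g); coverage %.3g; warp %.3g\n",
              x$gamma_shape, x$gamma_scale, x$mode_coverage,
              x$warp_magnitude))
  cat(sprintf("  Wishart dof %d; obs noise SD %.3g; lowpass %.3g Hz; seed %d\n",
              as.integer(x$wishart_dof), x$obs_noise_sd, x$lowpass_hz, x$seed))
  invisible(x)
}
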