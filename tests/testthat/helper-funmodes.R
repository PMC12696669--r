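## Small simulation fixtures built in code.

small_config <- function(..., seed = 1L) {
  sim_config(n_datasets = 1, n_subjects = 4, n_runs = 1, n_voxels = 400,
             n_timepoints = 120, n_distributed = 3, n_localised = 3,
             seed = seed, ...)
}

## crisp block maps plus band-limited unit-SD time courses
tiny_truth <- function(nv = 300, nm = 4, nt = 100, seed = 2) {
  set.seed(seed)
  maps <- matrix(0, nv, nm)
  width <- floor(nv / (nm + 1))
  for (m in seq_len(nm))
    maps[((m - 1) * width + 1):((m - 1) * width + width), m] <-
      stats::rgamma(width, 3, scale = 0.5)
  a <- funmodes:::lowpass_rows(matrix(stats::rnorm(nm * nt), nm), 0.72, 0.1)
  a <- a / apply(a, 1, stats::sd)
  list(maps = maps, tc = a)
}

## heavy-tailed band-limited sources (temporal-ICA identifiable)
bursty_tc <- function(n, nt, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(stats::rnorm(n * nt), n)
  x <- funmodes:::lowpass_rows(x, 1, 0.15) + 0.15 * x
  x <- sign(x) * abs(x)^1.5
  (x - rowMeans(x)) / apply(x, 1, stats::sd)
}

light_control <- function(seed = 1L, ...) {
  pfm_control(min_group_updates = 2, consolidation_rounds = 1,
              batch_cycles = 2, final_cycles = 4, n_restarts = 3,
              reseed = FALSE, seed = seed, ...)
}
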