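test_that("sim_config validates its fields", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_subjects = 0), "count")
  expect_error(sim_config(wishart_dof = 5), "wishart_dof")
  expect_error(sim_config(lowpass_hz = 2, tr_seconds = 0.72), "Nyquist")
  expect_error(sim_config(mode_coverage = 1.5), "mode_coverage")
  expect_error(sim_config(gamma_shape = -1), "Gamma")
})

test_that("group maps have the requested multiscale structure", {
  cfg <- small_config(seed = 4)
  truth <- make_group_maps(cfg, seed = 4)
  expect_equal(ncol(truth$group_maps), 6)
  expect_equal(as.vector(table(truth$mode_class)), c(3, 3))
  ## localised modes are single blocks nested inside their parent's support
  for (m in which(truth$mode_class == "localised")) {
    sup <- which(truth$group_maps[, m] > 0)
    expect_equal(sup, seq(min(sup), max(sup)))  # one contiguous block
    parent <- truth$parent_of[m]
    inside <- mean(truth$group_maps[sup, parent] > 0)
    expect_gte(inside, 0.9)
  }
  ## distributed modes have >= 2 disjoint blocks
  for (m in which(truth$mode_class == "distributed"))
    expect_gte(nrow(truth$blocks[[m]]), 2)
})

test_that("disabling overlap gives disjoint distributed supports", {
  cfg <- small_config(allow_overlap = FALSE, mode_coverage = 0.08, seed = 5)
  truth <- make_group_maps(cfg, seed = 5)
  expect_equal(mode_overlap_count(truth), 1.0)
})

test_that("overlap calibration sits near 1.3 modes per covered voxel", {
  ## replicate draws at the default full-scale geometry
  ov <- vapply(1:10, function(s)
    mode_overlap_count(make_group_maps(sim_config(seed = s), seed = s)),
    numeric(1))
  expect_gt(mean(ov), 1.2)
  expect_lt(mean(ov), 1.4)
})

test_that("zero warp and zero background noise reproduce the group maps", {
  cfg <- small_config(warp_magnitude = 0, background_noise_sd = 0, seed = 6)
  truth <- make_subject_maps(make_group_maps(cfg, seed = 6), cfg, seed = 7)
  expect_equal(truth$subject_maps[[1]], truth$group_maps)
  expect_equal(subject_group_overlap(truth), 1.0)
})

test_that("subject-group overlap decreases monotonically with warp size", {
  overlaps <- vapply(c(0.002, 0.008, 0.03), function(w) {
    cfg <- sim_config(n_subjects = 8, n_voxels = 2000, warp_magnitude = w,
                      seed = 9)
    truth <- make_subject_maps(make_group_maps(cfg, seed = 9), cfg, seed = 10)
    subject_group_overlap(truth)
  }, numeric(1))
  expect_true(all(diff(overlaps) < 0))
})

test_that("Wishart hierarchy concentrates on the group precision", {
  gp <- make_group_precision(3, seed = 11)
  expect_true(funmodes:::is_spd(gp))
  ## dof -> infinity: draws converge to the group precision
  big <- sample_connectivity(gp, 1e6, 3, seed = 12)
  for (m in big)
    expect_lt(norm(m - gp, "F") / norm(gp, "F"), 0.01)
  ## moments: mean of many draws near the group precision
  draws <- sample_connectivity(diag(3), 20, 2000, seed = 13)
  avg <- Reduce(`+`, draws) / length(draws)
  expect_lt(max(abs(avg - diag(3))), 0.05)
  ## minimal dof still yields SPD draws
  lowdof <- sample_connectivity(diag(3), 3, 20, seed = 14)
  expect_true(all(vapply(lowdof, funmodes:::is_spd, logical(1))))
  ## dispersion shrinks as dof grows
  disp <- vapply(c(15, 60, 240), function(d) {
    dr <- sample_connectivity(diag(3), d, 200, seed = 15)
    mean(vapply(dr, function(m) norm(m - diag(3), "F"), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(disp) < 0))
  expect_error(sample_connectivity(matrix(c(1, 2, 2, 1), 2), 10, 1),
               "positive-definite")
})

test_that("neural time courses follow the precision and the neural band", {
  prec <- matrix(c(1, -0.5, -0.5, 1), 2)
  x <- sample_timecourses(prec, 2e4, tr = 0.72, lowpass_hz = 0.1, seed = 16)
  ## closed form from the 2x2 precision: correlation = +0.5; the filter is
  ## applied identically to both rows so the correlation is preserved
  expect_equal(stats::cor(x[1, ], x[2, ]), 0.5, tolerance = 0.05)
  ## spectral power concentrated below the cutoff
  frac <- funmodes:::lowfreq_power_fraction(x, 0.72, 0.1)
  expect_gte(frac, 0.8)
  ## independent modes decorrelate
  y <- sample_timecourses(diag(3), 2e4, 0.72, 0.1, seed = 17)
  expect_lt(max(abs(stats::cor(t(y))[upper.tri(diag(3))])), 0.05)
  expect_error(sample_timecourses(diag(3), 2, 0.72, 0.1), "at least")
})

test_that("haemodynamic convolution behaves like its kernel", {
  tr <- 0.72
  basis <- hrf_basis(tr)
  k <- basis[, 1] / max(basis[, 1])
  ## impulse in, kernel out
  imp <- matrix(0, 1, 120); imp[1, 1] <- 1
  out <- drop(convolve_hrf(imp, tr, kernel = k))
  expect_equal(out[seq_along(k)], k, tolerance = 1e-10)
  expect_equal(out[(length(k) + 1):120], rep(0, 120 - length(k)),
               tolerance = 1e-10)
  ## sine at 0.01 Hz: output amplitude matches the kernel's transfer gain
  nt <- 5000
  f <- 0.01
  s <- sin(2 * pi * f * (0:(nt - 1)) * tr)
  o <- drop(convolve_hrf(matrix(s, 1), tr, kernel = k))
  steady <- 200:(nt - 1)
  gain_emp <- max(abs(o[steady])) / 1
  hf <- sum(k * exp(-2i * pi * f * tr * (seq_along(k) - 1)))
  expect_equal(gain_emp, Mod(hf), tolerance = 0.02 * Mod(hf))
  ## random kernels peak positive within 3-9 s
  set.seed(18)
  for (i in 1:200) {
    kk <- draw_hrf(basis, tr)
    pk <- which.max(kk)
    expect_gt(kk[pk], 0)
    lat <- (pk - 1) * tr
    expect_gte(lat, 3); expect_lte(lat, 9)
  }
})

test_that("assembled data reconstruct exactly without noise", {
  cfg <- small_config(obs_noise_sd = 0, background_noise_sd = 0, seed = 19)
  sim <- simulate_modes(cfg, seed = 19)
  d <- sim$datasets[[1]]$data
  expect_lte(qr(d)$rank, cfg$n_modes)
  s <- sim$datasets[[1]]$subject_id
  recon <- sim$truth$subject_maps[[s]] %*% sim$truth$bold_timecourses[[s]][[1]]
  expect_equal(d, recon, tolerance = 1e-12)
  ## regression of maps onto noiseless data returns the time courses
  a_hat <- qr.coef(qr(sim$truth$subject_maps[[s]]), d)
  expect_equal(a_hat, sim$truth$bold_timecourses[[s]][[1]], tolerance = 1e-8)
})

test_that("identical seed gives bit-identical simulations", {
  s1 <- simulate_modes(small_config(seed = 20), seed = 20)
  s2 <- simulate_modes(small_config(seed = 20), seed = 20)
  expect_identical(s1$datasets[[1]]$data, s2$datasets[[1]]$data)
  expect_identical(s1$truth$group_maps, s2$truth$group_maps)
})

test_that("synthetic phenotypes carry the requested effect structure", {
  set.seed(21)
  x <- matrix(rnorm(300 * 20), 300)
  expect_error(make_synthetic_phenotypes(x, effect_size = 1.2), "effect_size")
  p0 <- make_synthetic_phenotypes(x, effect_size = 0, seed = 22)
  expect_lt(abs(stats::cor(p0$phenotypes[, 1], p0$signal)), 0.15)
  p5 <- make_synthetic_phenotypes(x, effect_size = 0.5, seed = 23)
  expect_equal(stats::cor(p5$phenotypes[, 1], p5$signal), sqrt(0.5),
               tolerance = 0.1)
  ## confounds correlate with both the features' signal and the phenotype
  pc <- make_synthetic_phenotypes(x, effect_size = 0.3,
                                  confound_strength = 0.5, seed = 24)
  expect_gt(abs(stats::cor(pc$confounds[, 1], pc$signal)), 0.2)
  expect_gt(abs(stats::cor(pc$confounds[, 1], pc$phenotypes[, 1])), 0.2)
})
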