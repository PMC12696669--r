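test_that("the stochastic step-size schedule is the stated one", {
  ## rho_t = (t + tau)^(-beta)
  expect_equal((1 + 5)^(-0.6), 0.3413, tolerance = 1e-4)
  expect_error(pfm_control(forget_rate = 0.4), "forget_rate")
  expect_error(pfm_control(delay = -1), "delay")
  grp <- funmodes:::.new_group_model(matrix(rnorm(40), 20, 2), 0.72,
                                     pfm_control())
  expect_error(pfm_update_group(list(), grp, 1), "empty")
  expect_error(pfm_update_group(list(1), grp, 1, beta = 2), "beta")
})

test_that("a full batch with beta = 0 equals the non-stochastic update", {
  tt <- tiny_truth(nv = 120, nm = 3, nt = 60, seed = 1)
  d <- tt$maps %*% tt$tc + matrix(rnorm(120 * 60), 120)
  grp <- funmodes:::.new_group_model(tt$maps, 0.72, pfm_control())
  post <- list(pfm_fit_subject(list(d), grp, max_cycles = 2))
  g1 <- pfm_update_group(post, grp, t = 1, beta = 0, tau = 0)
  ## rho = 1: parameters equal the batch statistics exactly
  mu_batch <- post[[1]]$resp * post[[1]]$p / pmax(post[[1]]$resp, 1e-3)
  expect_equal(g1$mu, mu_batch, tolerance = 1e-12)
  expect_equal(g1$pi, post[[1]]$resp, tolerance = 1e-12)
})

test_that("repeated identical batches drive the group to a fixed point", {
  tt <- tiny_truth(nv = 150, nm = 3, nt = 80, seed = 2)
  d <- tt$maps %*% tt$tc + matrix(rnorm(150 * 80, sd = 0.5), 150)
  grp <- funmodes:::.new_group_model(tt$maps, 0.72, pfm_control())
  deltas <- numeric(0)
  for (t in 1:6) {
    post <- list(pfm_fit_subject(list(d), grp, max_cycles = 3))
    g2 <- pfm_update_group(post, grp, t, beta = 0.6, tau = 5)
    deltas <- c(deltas, norm(g2$mu - grp$mu, "F"))
    grp <- g2
  }
  ## update magnitudes shrink (Cauchy-like behaviour under the schedule)
  expect_lt(deltas[6], deltas[1])
})

test_that("subject free energy is monotone within a cycle", {
  tt <- tiny_truth(nv = 250, nm = 4, nt = 90, seed = 3)
  d <- tt$maps %*% tt$tc + matrix(rnorm(250 * 90, sd = 2), 250)
  grp <- funmodes:::.new_group_model(tt$maps, 0.72, pfm_control())
  st <- pfm_fit_subject(list(d), grp, max_cycles = 5, trace = TRUE)
  for (steps in st$fe_steps) {
    rel <- diff(steps) / (abs(steps[-length(steps)]) + 1e-12)
    expect_gte(min(rel), -1e-8)
  }
  expect_true(all(is.finite(st$free_energy)))
})

test_that("noiseless data generated from the group model are recovered", {
  tt <- tiny_truth(nv = 300, nm = 4, nt = 100, seed = 4)
  d <- tt$maps %*% tt$tc
  grp <- funmodes:::.new_group_model(tt$maps, 0.72, pfm_control())
  st <- pfm_fit_subject(list(d), grp, max_cycles = 10)
  r <- abs(diag(cor(t(st$h[[1]] * st$a[[1]]), t(tt$tc))))
  expect_gt(min(r), 0.99)
  rp <- abs(diag(cor(st$p, tt$maps)))
  expect_gt(min(rp), 0.99)
})

test_that("pure-noise data land in the background component", {
  tt <- tiny_truth(nv = 200, nm = 3, nt = 80, seed = 5)
  d <- matrix(rnorm(200 * 80), 200)
  grp <- funmodes:::.new_group_model(tt$maps, 0.72, pfm_control())
  st <- pfm_fit_subject(list(d), grp, max_cycles = 6)
  expect_lt(mean(st$resp), 0.35)
})

test_that("the full fit is deterministic and recovers a single mode", {
  ## rank-1 data, one mode
  set.seed(6)
  nv <- 200; nt <- 80
  map <- c(rgamma(50, 3, scale = 0.5), rep(0, nv - 50))
  tc <- funmodes:::lowpass_rows(matrix(rnorm(nt), 1), 0.72, 0.1)
  tc <- tc / sd(drop(tc))
  datasets <- lapply(1:3, function(s)
    bold_dataset(map %*% tc + matrix(rnorm(nv * nt, sd = 0.5), nv),
                 subject_id = s, tr_seconds = 0.72))
  fit1 <- pfm(datasets, n_modes = 1, control = light_control(seed = 7))
  fit2 <- pfm(datasets, n_modes = 1, control = light_control(seed = 7))
  expect_identical(fit1$group_maps, fit2$group_maps)
  expect_gt(abs(cor(fit1$group_maps[, 1], map)), 0.99)
})

test_that("mode QC applies the similarity thresholds", {
  tt <- tiny_truth(nv = 150, nm = 3, nt = 50, seed = 8)
  fake <- structure(list(
    n_modes = 3, subjects = 1:2,
    group_maps = tt$maps,
    subject_maps = list(tt$maps,                                 # reverted
                        matrix(rnorm(450), 150))                 # noise
  ), class = "pfm")
  qc <- qc_modes(fake)
  s1 <- qc[qc$subject == 1, ]
  s2 <- qc[qc$subject == 2, ]
  expect_true(all(s1$flag == "reverted"))
  expect_true(all(s2$flag == "noisy"))
})
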