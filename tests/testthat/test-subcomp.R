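test_that("map weighting rescales voxel rows only", {
  set.seed(1)
  d <- matrix(rnorm(30 * 20), 30)
  expect_equal(weight_data(d, rep(1, 30)), d)
  ind <- c(rep(0, 20), rep(1, 10))
  w <- weight_data(d, ind)
  expect_true(all(w[1:20, ] == 0))
  expect_equal(w[21:30, ], d[21:30, ])
  w2 <- weight_data(d, c(2, rep(1, 29)))
  expect_equal(var(w2[1, ]), 4 * var(d[1, ]), tolerance = 1e-12)
  expect_error(weight_data(d, 1:5), "length")
})

test_that("explained-variance profile reflects subcomponent multiplicity", {
  set.seed(2)
  nv <- 100; nt <- 60
  ## rank-1 weighted data for every subject: PC1 carries everything
  m <- rnorm(nv)
  one <- lapply(1:3, function(s) m %*% t(rnorm(nt)))
  prof <- suppressWarnings(explained_variance_profile(one, 5, 5))
  expect_equal(prof[1], 1, tolerance = 1e-8)
  ## two equal-power orthogonal subcomponents: PC1 near one half
  q <- qr.Q(qr(matrix(rnorm(nv * 2), nv)))
  two <- lapply(1:4, function(s)
    q[, 1] %*% t(rnorm(nt)) + q[, 2] %*% t(rnorm(nt)))
  prof2 <- suppressWarnings(explained_variance_profile(two, 5, 5))
  expect_equal(prof2[1], 0.5, tolerance = 0.15)
  expect_error(explained_variance_profile(one[1]), "two subjects")
})

test_that("temporal ICA recovers planted independent subcomponents", {
  set.seed(3)
  nv <- 150; nt <- 250
  maps <- cbind(c(rgamma(70, 3, 0.5), rep(0, 80)),
                c(rep(0, 80), rgamma(70, 3, 0.5)))
  truth_tc <- list()
  wl <- lapply(1:4, function(s) {
    tc <- bursty_tc(2, nt)
    truth_tc[[s]] <<- tc
    maps %*% tc + matrix(rnorm(nv * nt, sd = 0.1), nv)
  })
  sub <- tica_subcomponents(wl, k = 2, seed = 4)
  for (s in 1:4) {
    r <- abs(cor(t(sub$timecourses[[s]]), t(truth_tc[[s]])))
    perm <- solve_assignment(-r)
    expect_gt(min(r[cbind(1:2, perm)]), 0.9)
  }
  ## deterministic under a fixed seed
  sub2 <- tica_subcomponents(wl, k = 2, seed = 4)
  expect_identical(sub$timecourses, sub2$timecourses)
})

test_that("winner-takes-all assigns copies exactly and flags noise", {
  set.seed(5)
  nt <- 200
  cand <- lapply(1:5, function(s)
    list(lowD = matrix(rnorm(2 * nt), 2),
         primary = matrix(rnorm(2 * nt), 2),
         secondary = matrix(rnorm(3 * nt), 3)))
  classes <- list(lowD = lapply(cand, `[[`, "lowD"),
                  primary = lapply(cand, `[[`, "primary"),
                  secondary = lapply(cand, `[[`, "secondary"))
  ## subcomponent 1 copies secondary mode 2; subcomponent 2 is fresh noise
  subc <- lapply(1:5, function(s)
    rbind(classes$secondary[[s]][2, ], rnorm(nt)))
  wta <- winner_takes_all(subc, classes)
  expect_equal(wta$winner_class[1], "secondary")
  expect_equal(wta$winner_mode[1], 2L)
  expect_equal(wta$mean_winner_r[1], 1, tolerance = 1e-10)
  ## the noise subcomponent wins with a weak correlation
  expect_lt(wta$mean_winner_r[2], 0.35)
  expect_equal(sum(attr(wta, "counts")), 2)
})

test_that("temporal exclusivity removes exactly the spanned signal", {
  set.seed(6)
  nt <- 100
  other <- matrix(rnorm(2 * nt), 2)
  ## data exactly spanned by the other time courses vanish
  wd <- matrix(rnorm(20 * 2), 20) %*% other
  res <- exclusive_temporal(wd, other)
  expect_lt(max(abs(res)), 1e-10)
  ## orthogonal data pass through
  q <- qr.Q(qr(cbind(1, t(other), rnorm(nt))))[, 4]
  wd2 <- matrix(rnorm(20), 20) %*% t(q)
  expect_equal(exclusive_temporal(wd2, other), wd2, tolerance = 1e-10)
})

test_that("spatial exclusivity preserves disjoint maps", {
  set.seed(7)
  nv <- 60
  map <- c(rgamma(20, 3, 0.5), rep(0, 40))
  others <- cbind(c(rep(0, 20), rgamma(20, 3, 0.5), rep(0, 20)),
                  c(rep(0, 40), rgamma(20, 3, 0.5)))
  d <- matrix(rnorm(nv * 30), nv)
  ex <- exclusive_spatial(map, others, d)
  expect_equal(ex$map, map, tolerance = 1e-10)
  ## a map identical to another mode's residualises to ~0
  ex2 <- exclusive_spatial(others[, 1], others, d)
  expect_lt(max(abs(ex2$map)), 1e-10)
})
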