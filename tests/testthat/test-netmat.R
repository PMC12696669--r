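test_that("partial temporal netmat matches the closed-form precision", {
  prec <- matrix(c(2, -1, 0, -1, 2, -1, 0, -1, 2), 3)
  set.seed(1)
  x <- funmodes:::rmvn_cols(1e5, solve(prec))
  nm <- tnet(x, rho = 1e-6)
  ## partial r(i,j) = -theta_ij / sqrt(theta_ii theta_jj)
  expect_equal(nm$values[1, 2], 0.5, tolerance = 1e-2)
  expect_equal(nm$values[2, 3], 0.5, tolerance = 1e-2)
  expect_equal(nm$values[1, 3], 0, tolerance = 1e-2)
  expect_equal(diag(nm$values), rep(1, 3))
})

test_that("tnet agrees with an explicit covariance-inversion oracle", {
  set.seed(2)
  x <- matrix(rnorm(4 * 200), 4)
  rho <- 0.01
  nm <- tnet(x, rho = rho)
  cv <- cov(t(x))
  theta <- solve(cv + rho * mean(diag(cv)) * diag(4))
  oracle <- -theta / tcrossprod(sqrt(diag(theta)))
  diag(oracle) <- 1
  expect_lt(max(abs(nm$values - oracle)), 1e-8)
})

test_that("regularisation shrinks partial correlations monotonically", {
  set.seed(3)
  x <- funmodes:::rmvn_cols(500, solve(matrix(c(1, -0.4, -0.4, 1), 2)))
  vals <- vapply(c(0.01, 0.1, 1, 10, 100), function(r)
    abs(tnet(x, rho = r)$values[1, 2]), numeric(1))
  expect_true(all(diff(vals) < 0))
  ## independent series give near-zero off-diagonals
  y <- matrix(rnorm(3 * 5000), 3)
  expect_lt(max(abs(tnet(y)$values[upper.tri(diag(3))])), 0.06)
  expect_error(tnet(rbind(rnorm(50), rep(1, 50))), "constant")
})

test_that("spatial netmat is the plain map correlation", {
  set.seed(4)
  m <- matrix(rnorm(100 * 3), 100)
  m[, 3] <- -m[, 1]
  sn <- snet(m)
  expect_equal(sn$values[1, 3], -1)
  expect_equal(diag(sn$values), rep(1, 3))
  expect_error(snet(cbind(m[, 1], rep(2, 100))), "zero-variance")
})

test_that("Fisher transform uses atanh with clipping", {
  r <- diag(2); r[1, 2] <- r[2, 1] <- 0.5
  z <- fisher_z(r)
  expect_equal(z[1, 2], 0.5493, tolerance = 1e-4)
  r[1, 2] <- r[2, 1] <- 0
  expect_equal(fisher_z(r)[1, 2], 0)
  r[1, 2] <- r[2, 1] <- 1
  expect_equal(fisher_z(r)[1, 2], atanh(1 - 1e-6), tolerance = 1e-10)
  expect_equal(fisher_z(r)[1, 2], 7.2543, tolerance = 1e-4)
})

test_that("block splitting has the stated lengths and inverts", {
  set.seed(5)
  v <- cov2cor(crossprod(matrix(rnorm(120 * 100), 120)))
  pri <- 1:25
  bl <- split_blocks(v, pri)
  expect_length(bl$pri2pri, 300)
  expect_length(bl$sec2sec, 2775)
  expect_length(bl$pri2sec, 1875)
  back <- unsplit_blocks(bl, 100)
  expect_equal(back, v, tolerance = 1e-12)
  expect_error(split_blocks(v, c(0, 5)), "invalid")
})

test_that("SVD reduction preserves low-rank structure", {
  set.seed(6)
  x <- matrix(rnorm(50 * 3), 50) %*% matrix(rnorm(3 * 30), 3)
  z <- svd_reduce(x, 3)
  xc <- sweep(x, 2, colMeans(x))
  ## exact reconstruction via regression on the 3 scores
  recon <- z %*% qr.coef(qr(z), xc)
  expect_lt(max(abs(recon - xc)), 1e-8)
  ## scores are orthogonal
  g <- crossprod(z)
  expect_lt(max(abs(g - diag(diag(g)))), 1e-8)
  expect_warning(svd_reduce(x, 45), "truncated")
})

test_that("between-subject consistency behaves as expected", {
  set.seed(7)
  base <- cov2cor(crossprod(matrix(rnorm(40 * 8), 40)))
  same <- replicate(5, base, simplify = FALSE)
  expect_equal(consistency(same)$per_subject, rep(1, 5), tolerance = 1e-12)
  noise_at <- function(sd) {
    mats <- lapply(1:6, function(i) base + matrix(rnorm(64, sd = sd), 8))
    consistency(mats)$mean
  }
  expect_gt(noise_at(0.1), noise_at(0.4))   # halved noise -> higher consistency
  rand <- lapply(1:6, function(i) matrix(rnorm(64), 8))
  expect_lt(abs(consistency(rand)$mean), 0.35)
  expect_error(consistency(same[1:2]), "three")
})

test_that("parcel averaging returns per-parcel mean time courses", {
  d <- rbind(1:10, 1:10, -(1:10), rep(5, 10))
  labs <- c(1, 1, 1, 2)
  tc <- parcel_timecourses(d, labs)
  expect_equal(tc["1", ], (1:10) / 3)
  expect_equal(tc["2", ], rep(5, 10))
  expect_error(parcel_timecourses(d, c(1, 1, 3, 3)), "empty")
  expect_error(parcel_timecourses(d, c(1, 1, 2)), "cover")
})
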