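test_that("confound reduction keeps conventional columns and top PCs", {
  set.seed(1)
  n <- 120
  conv <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  ## remaining block of exact rank 2
  f <- matrix(rnorm(n * 2), n)
  rest <- f %*% matrix(rnorm(2 * 6), 2)
  x <- cbind(conv, rest)
  colnames(x) <- c("age", "sex", paste0("v", 1:6))
  out <- reduce_confounds(x, conventional = c("age", "sex"))
  expect_equal(ncol(out), 2 + 2)
  ## duplicated columns do not add components
  out2 <- reduce_confounds(cbind(x, x[, 3:8]), conventional = c("age", "sex"))
  expect_equal(ncol(out2), ncol(out))
  ## a stringent threshold on a full-rank block keeps nearly all PCs
  xr <- cbind(conv, matrix(rnorm(n * 5), n))
  colnames(xr) <- c("age", "sex", paste0("w", 1:5))
  out3 <- reduce_confounds(xr, c("age", "sex"), var_threshold = 0.999)
  expect_gte(ncol(out3), 2 + 4)
  expect_error(reduce_confounds(x, var_threshold = 2), "var_threshold")
})

test_that("deconfounding is fold-safe and matches the train-only oracle", {
  set.seed(2)
  n <- 80
  cf <- matrix(rnorm(n * 3), n)
  y <- cf %*% c(1, -2, 0.5) + rnorm(n, sd = 0.1)
  tr <- 1:60; te <- 61:80
  out <- deconfound_fold(y[tr], y[te], cf[tr, ], cf[te, ])
  beta <- solve(crossprod(cbind(1, cf[tr, ])),
                crossprod(cbind(1, cf[tr, ]), y[tr]))
  expect_lt(max(abs(out$train - (y[tr] - cbind(1, cf[tr, ]) %*% beta))), 1e-10)
  expect_lt(max(abs(out$test - (y[te] - cbind(1, cf[te, ]) %*% beta))), 1e-10)
  ## perturbing test rows leaves the fitted betas (hence train output) alone
  out2 <- deconfound_fold(y[tr], y[te] + 100, cf[tr, ], cf[te, ])
  expect_identical(out$train, out2$train)
  ## y exactly equal to a confound residualises to ~0 on train
  out3 <- deconfound_fold(cf[tr, 1], cf[te, 1], cf[tr, ], cf[te, ])
  expect_lt(max(abs(out3$train)), 1e-10)
  ## confounds orthogonal to the training data leave the train rows alone
  qtr <- qr.Q(qr(cbind(1, cf[tr, ])))
  z <- rnorm(n)
  z[tr] <- z[tr] - qtr %*% crossprod(qtr, z[tr])
  out4 <- deconfound_fold(z[tr], z[te], cf[tr, ], cf[te, ])
  expect_equal(drop(out4$train), z[tr], tolerance = 1e-8)
})

test_that("quantile Gaussianisation normalises and preserves order", {
  set.seed(3)
  x <- rexp(1e4)
  g <- gaussianise_fold(x, x[1:100])
  sk <- mean((g$train - mean(g$train))^3) / sd(g$train)^3
  expect_lt(abs(sk), 0.2)
  expect_equal(order(x), order(g$train))
  ## near-normal input passes through almost linearly
  z <- rnorm(500)
  gz <- gaussianise_fold(z, z[1:10])
  expect_gt(cor(z, gz$train), 0.99)
  ## test values outside the training range are clipped
  gt <- gaussianise_fold(rnorm(100), c(-50, 50))
  expect_lte(max(gt$test), max(gt$train) + 1e-8)
  expect_error(gaussianise_fold(rep(1, 50), 1), "constant")
  expect_error(gaussianise_fold(rnorm(5), 1), "10 training")
})

test_that("elastic-net prediction recovers the theoretical accuracy", {
  set.seed(4)
  x <- matrix(rnorm(400 * 30), 400)
  ph <- make_synthetic_phenotypes(x, effect_size = 0.5, sparsity = 0.3,
                                  seed = 5)
  fit <- elasticnet_predict(x, ph$phenotypes[, 1], seed = 6)
  expect_equal(fit$pooled_accuracy, sqrt(0.5), tolerance = 0.12)
  ## null phenotype: accuracy compatible with zero
  ph0 <- make_synthetic_phenotypes(x, effect_size = 0, seed = 7)
  fit0 <- elasticnet_predict(x, ph0$phenotypes[, 1], seed = 8)
  expect_lt(abs(fit0$pooled_accuracy), 0.15)
  expect_error(elasticnet_predict(x[1:30, ], rnorm(30)), "50 subjects")
})

test_that("deconfounding blocks confound-driven leakage", {
  set.seed(9)
  x <- matrix(rnorm(400 * 30), 400)
  ph <- make_synthetic_phenotypes(x, effect_size = 0,
                                  confound_strength = 0.6, seed = 10)
  with_dc <- elasticnet_predict(x, ph$phenotypes[, 1],
                                confounds = ph$confounds, seed = 11)
  without <- elasticnet_predict(x, ph$phenotypes[, 1], seed = 11)
  expect_lt(abs(with_dc$pooled_accuracy), 0.15)
  expect_gt(without$pooled_accuracy, 0.3)
})

test_that("CCA reaches perfect correlation on identical sides", {
  set.seed(12)
  x <- matrix(rnorm(100 * 8), 100)
  cc <- cca_fit(x, x, n_dim = 5)
  expect_equal(unname(cc$correlations), rep(1, 5), tolerance = 1e-8)
  expect_true(all(diff(cc$correlations) <= 1e-12))
  expect_error(cca_fit(x, x, n_dim = 50), "exceeds")
})

test_that("a planted shared component is estimated at its strength", {
  set.seed(13)
  n <- 1000
  z <- rnorm(n)
  x <- cbind(sqrt(0.8) * z + sqrt(0.2) * rnorm(n), matrix(rnorm(n * 4), n))
  y <- cbind(sqrt(0.8) * z + sqrt(0.2) * rnorm(n), matrix(rnorm(n * 4), n))
  cc <- cca_fit(x, y, n_dim = 5)
  expect_equal(cc$correlations[1], 0.8, tolerance = 0.05)
  expect_lt(cc$correlations[2], 0.25)
})

test_that("block permutation preserves family structure", {
  set.seed(14)
  blocks <- rep(1:10, times = rep(c(2, 3), 5))
  perm <- funmodes:::block_permute(blocks)
  expect_equal(sort(perm), seq_along(blocks))
  ## family members stay together under the permutation
  for (b in unique(blocks)) {
    moved <- unique(blocks[perm[blocks == b]])
    expect_length(moved, 1)
    expect_equal(sum(blocks == moved), sum(blocks == b))
  }
})

test_that("permuting either side gives the same null in law", {
  set.seed(15)
  n <- 120
  x <- matrix(rnorm(n * 4), n)
  y <- matrix(rnorm(n * 4), n)
  xr <- svd_reduce(x, 3); yr <- svd_reduce(y, 3)
  null_y <- replicate(150, stats::cancor(xr, yr[sample(n), ])$cor[1])
  null_x <- replicate(150, stats::cancor(xr[sample(n), ], yr)$cor[1])
  expect_gt(stats::ks.test(null_y, null_x)$p.value, 0.01)
})

test_that("a strong planted component is declared significant", {
  set.seed(16)
  n <- 300
  z <- rnorm(n)
  x <- cbind(sqrt(0.8) * z + sqrt(0.2) * rnorm(n), matrix(rnorm(n * 3), n))
  y <- cbind(sqrt(0.8) * z + sqrt(0.2) * rnorm(n), matrix(rnorm(n * 3), n))
  res <- cca_permutation_test(x, y, n_perm = 199, n_dim = 4, seed = 17)
  expect_equal(res$n_significant, 1)
  expect_warning(cca_permutation_test(x, y, n_perm = 50, n_dim = 2, seed = 1),
                 "100 permutations")
})
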